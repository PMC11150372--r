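# small labeled cohorts for unit tests; generated fresh, never stored
small_cohort <- function(n = 60, seed = 101, ...) {
  generate_cohort(generator_config(n_cells = n, seed = seed, ...))
}

# light EI configuration that keeps unit tests fast
light_ei <- function(seed = 1, base_roster = c("lr", "dt"),
                     stacker_roster = c("mean", "lr"), inner_folds = 3,
                     num_trees = 100) {
  ei_config(base_roster = base_roster, stacker_roster = stacker_roster,
            inner_folds = inner_folds, num_trees = num_trees, seed = seed)
}

# feature matrix with a planted informative column, for interpretation tests
planted_features <- function(n = 120, p = 10, signal_col = 4, seed = 9,
                             strength = 2) {
  set.seed(seed)
  y <- rep(c("divided", "undivided"), length.out = n)
  X <- matrix(rnorm(n * p), n, p)
  X[, signal_col] <- X[, signal_col] + strength * (y == "divided")
  colnames(X) <- sprintf("M|raw|c%02d", seq_len(p))
  list(X = X, y = y)
}
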