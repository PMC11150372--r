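#' Permutation-based feature ranks of a single base classifier
#'
#' Measures, for each feature column, the mean drop in training F-max when
#' that column is randomly permuted (`n_repeats` independent seeded
#' permutations), then converts the drops to fractional ranks scaled to
#' \[0, 1\] with the largest drop mapped to 1. Permutation (rather than
#' removal) preserves the model's input contract, so the fitted model can
#' be interrogated unchanged.
#'
#' @param base_model A fitted base model (an element of an `ei_model`'s
#'   `base_models`).
#' @param base_name Name of the base learner (`"lr"`, `"rf"`, ...), needed
#'   to dispatch its predict method.
#' @param features Feature matrix the model was trained on (columns in
#'   training order).
#' @param labels Fate labels.
#' @param n_repeats Permutations per column (default 10).
#' @param seed Integer seed.
#' @return Numeric vector of scaled ranks in \[0, 1\], one per column.
#' @export
base_permutation_ranks <- function(base_model, base_name, features, labels,
                                   n_repeats = 10L, seed = 1L) {
  stopifnot(n_repeats >= 1L)
  X <- unclass(features)
  y <- as_fate_factor(labels)
  pred_fun <- .base_learners[[base_name]]$predict
  base_f <- f_max(y, pred_fun(base_model, X))$f_max
  p <- ncol(X)
  drops <- numeric(p)
  for (j in seq_len(p)) {
    dj <- numeric(n_repeats)
    for (r in seq_len(n_repeats)) {
      set.seed(child_seed(seed, "perm", j, r))
      Xp <- X
      Xp[, j] <- X[sample.int(nrow(X)), j]
      dj[r] <- base_f - f_max(y, pred_fun(base_model, Xp))$f_max
    }
    drops[j] <- mean(dj)
  }
  if (p == 1L) return(1)
  (rank(drops, ties.method = "average") - 1) / (p - 1)
}

#' Per-time-point importance profile of a multi-modal EI model
#'
#' The EI interpretation algorithm: for each modality, the permutation
#' ranks of every base classifier's features are averaged with weights
#' proportional to the absolute stacker coefficient of the corresponding
#' base column (renormalized to sum to 1 within the modality), and the
#' resulting profile is min-max normalized to \[0, 1\]. Applied to level-3
#' DWT features, each coefficient index anchors to the center of its ~2-h
#' input window, giving an importance score per (modality, time window).
#'
#' Requires a linear stacker (`"lr"` or `"mean"`); random-forest stacking
#' has no coefficient weights and is rejected.
#'
#' @param model An `ei_model` with a linear stacker.
#' @param features Named list of training feature matrices.
#' @param labels Fate labels.
#' @param n_repeats Permutations per column (default 10).
#' @param seed Integer seed.
#' @return An `importance_profile`: data.frame with columns `modality`,
#'   `index`, `time_h`, `score`; attributes `repeats` and `seed`.
#' @export
ei_importance <- function(model, features, labels, n_repeats = 10L, seed = 1L) {
  stopifnot(inherits(model, "ei_model"))
  w_all <- stacker_weights(model)  # errors for non-linear stackers
  rows <- list()
  for (m in names(model$base_models)) {
    X <- features[[m]]
    if (is.null(X)) stop("features for modality '", m, "' missing")
    if (!identical(colnames(X), model$feature_names[[m]]))
      stop("feature names of modality '", m, "' do not match training")
    bases <- names(model$base_models[[m]])
    w <- w_all[paste(m, bases, sep = "|")]
    if (sum(w) == 0) w[] <- 1  # degenerate stacker: fall back to equal weights
    w <- w / sum(w)
    ranks <- vapply(bases, function(b)
      base_permutation_ranks(model$base_models[[m]][[b]], b, X, labels,
                             n_repeats = n_repeats,
                             seed = child_seed(seed, "imp", m, b)),
      numeric(ncol(X)))
    score <- as.numeric(ranks %*% w)
    rng <- range(score)
    if (rng[2] > rng[1]) score <- (score - rng[1]) / (rng[2] - rng[1])
    t_h <- attr(X, "time_h")
    if (is.null(t_h)) t_h <- rep(NA_real_, ncol(X))
    rows[[m]] <- data.frame(modality = m, index = seq_len(ncol(X)),
                            time_h = t_h, score = score)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("importance_profile", "data.frame"),
            repeats = as.integer(n_repeats), seed = as.integer(seed))
}

#' Per-coefficient median difference between fate classes
#'
#' For each modality, the absolute difference between the divided and
#' undivided cells' median transformed values at each coefficient (or raw
#' time point under the identity transform) — the simple descriptive
#' signal against which model importance can be checked.
#'
#' @param pp A [preprocess_cohort()] result.
#' @param spec A [transform_spec()] (default: level-3 Haar DWT).
#' @return Named list (per modality) of numeric vectors, with a `time_h`
#'   attribute where the transform defines one.
#' @export
median_class_difference <- function(pp, spec = transform_spec()) {
  features <- transform_cohort(pp, spec)
  labs <- cohort_labels(pp$cohort)
  if (!all(c("divided", "undivided") %in% labs))
    stop("both classes must be present")
  lapply(features, function(M) {
    d <- abs(apply(M[labs == "divided", , drop = FALSE], 2, stats::median) -
             apply(M[labs == "undivided", , drop = FALSE], 2, stats::median))
    attr(d, "time_h") <- attr(M, "time_h")
    d
  })
}

#' Concordance between model importance and class median differences
#'
#' Spearman rank correlation, per modality, between the importance profile
#' and the median class differences at matching coefficient indices. High
#' concordance means the model relies on time windows where the classes
#' actually differ.
#'
#' @param profile An [ei_importance()] result.
#' @param diffs A [median_class_difference()] result with matching
#'   coefficient indexing.
#' @return Named numeric vector of Spearman correlations, one per
#'   modality.
#' @export
importance_concordance <- function(profile, diffs) {
  stopifnot(inherits(profile, "importance_profile"))
  mods <- unique(profile$modality)
  out <- vapply(mods, function(m) {
    s <- profile$score[profile$modality == m]
    d <- diffs[[m]]
    if (is.null(d) || length(d) != length(s))
      stop("diffs for modality '", m, "' missing or length-mismatched")
    stats::cor(s, as.numeric(d), method = "spearman")
  }, numeric(1))
  names(out) <- mods
  out
}
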