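fit_lr_base <- function(X, y, seed = 1) {
  kinfate:::.base_learners$lr$fit(X, kinfate:::as_fate_factor(y),
                                  ei_config(), seed)
}

test_that("a planted informative column earns the top permutation rank", {
  pf <- planted_features(n = 150, p = 8, signal_col = 3, seed = 9)
  fit <- fit_lr_base(pf$X, pf$y)
  r <- base_permutation_ranks(fit, "lr", pf$X, pf$y, n_repeats = 5, seed = 2)
  expect_length(r, 8L)
  expect_true(all(r >= 0 & r <= 1))
  expect_equal(r[3], 1)
})

test_that("a constant column never outranks a planted signal column", {
  pf <- planted_features(n = 150, p = 6, signal_col = 2, seed = 10)
  pf$X[, 5] <- 1  # constant: permutation cannot change predictions
  fit <- fit_lr_base(pf$X, pf$y)
  r <- base_permutation_ranks(fit, "lr", pf$X, pf$y, n_repeats = 5, seed = 3)
  expect_lt(r[5], r[2])
})

test_that("permutation ranks are stable across repeat counts", {
  # graded signal strengths give the rank vector real structure to preserve
  set.seed(11)
  n <- 200; p <- 10
  y <- rep(c("divided", "undivided"), length.out = n)
  X <- matrix(rnorm(n * p), n, p)
  for (j in seq_len(p)) X[, j] <- X[, j] + 0.15 * j * (y == "divided")
  colnames(X) <- sprintf("M|raw|c%02d", seq_len(p))
  fit <- fit_lr_base(X, y)
  r1 <- base_permutation_ranks(fit, "lr", X, y, n_repeats = 1, seed = 4)
  r8 <- base_permutation_ranks(fit, "lr", X, y, n_repeats = 8, seed = 5)
  expect_gt(cor(r1, r8, method = "spearman"), 0.5)
})

test_that("importance profiles span [0,1] and carry time anchors", {
  co <- small_cohort(n = 100, seed = 37)
  pp <- preprocess_cohort(co, seed = 37)
  fx <- transform_cohort(pp)
  labs <- cohort_labels(co)
  m <- train_ei(fx, labs, light_ei(seed = 37, stacker_roster = "lr"))
  imp <- ei_importance(m, fx, labs, n_repeats = 3, seed = 37)
  expect_s3_class(imp, "importance_profile")
  for (mod in c("ERK", "Akt")) {
    s <- imp$score[imp$modality == mod]
    expect_length(s, 25L)
    expect_equal(min(s), 0)
    expect_equal(max(s), 1)
  }
  expect_equal(imp$time_h[imp$modality == "ERK"], -1 + (1:25 - 0.5) * 2)
  # deterministic under identical seed
  imp2 <- ei_importance(m, fx, labs, n_repeats = 3, seed = 37)
  expect_equal(imp$score, imp2$score, tolerance = 1e-12)
})

test_that("a single-base model's profile equals its normalized rank vector", {
  co <- small_cohort(n = 100, seed = 41)
  pp <- preprocess_cohort(co, seed = 41)
  fx <- transform_cohort(pp)["ERK"]
  labs <- cohort_labels(co)
  m <- train_ei(fx, labs, light_ei(seed = 41, base_roster = "lr",
                                   stacker_roster = "mean"))
  imp <- ei_importance(m, fx, labs, n_repeats = 3, seed = 41)
  r <- base_permutation_ranks(m$base_models$ERK$lr, "lr", fx$ERK, labs,
                              n_repeats = 3,
                              seed = kinfate:::child_seed(41, "imp", "ERK", "lr"))
  r_norm <- (r - min(r)) / (max(r) - min(r))
  expect_equal(imp$score, r_norm, tolerance = 1e-12)
})

test_that("non-linear stackers are rejected by the interpretation algorithm", {
  co <- small_cohort(n = 80, seed = 43)
  pp <- preprocess_cohort(co, seed = 43)
  fx <- transform_cohort(pp)
  labs <- cohort_labels(co)
  m_rf <- train_ei(fx, labs, light_ei(seed = 43, stacker_roster = "rf"))
  expect_error(ei_importance(m_rf, fx, labs, n_repeats = 2, seed = 1),
               "not linear")
})

test_that("median class differences localize a planted effect window", {
  cfg <- generator_config(n_cells = 300, effect_window = c(20, 40),
                          erk_effect = 0.3, seed = 47)
  co <- generate_cohort(cfg)
  pp <- preprocess_cohort(co, seed = 47)
  d <- median_class_difference(pp, transform_spec())
  expect_named(d, c("ERK", "Akt"))
  expect_length(d$ERK, 25L)
  t_h <- attr(d$ERK, "time_h")
  expect_gt(mean(d$ERK[t_h >= 20 & t_h <= 40]),
            2 * mean(d$ERK[t_h < 15]))
  # identical class distributions: differences stay at sampling-noise level,
  # well below 10% of the typical coefficient magnitude
  cfg0 <- generator_config(n_cells = 300, erk_effect = 0, akt_effect = 0,
                           seed = 48)
  pp0 <- preprocess_cohort(generate_cohort(cfg0), 48)
  d0 <- median_class_difference(pp0)
  coef_scale <- median(abs(transform_cohort(pp0)$ERK))
  expect_lt(max(d0$ERK), 0.1 * coef_scale)
  expect_lt(mean(d0$ERK), 0.25 * mean(d$ERK[t_h >= 20 & t_h <= 40]))
})

test_that("concordance is Spearman correlation per modality", {
  imp <- structure(data.frame(modality = rep("ERK", 25), index = 1:25,
                              time_h = NA_real_,
                              score = seq(0, 1, length.out = 25)),
                   class = c("importance_profile", "data.frame"))
  # a monotone transform of the scores correlates perfectly
  diffs <- list(ERK = (seq(0, 1, length.out = 25))^3 + 0.2)
  expect_equal(unname(importance_concordance(imp, diffs)["ERK"]), 1)
  expect_error(importance_concordance(imp, list(ERK = 1:10)), "mismatch")
  # null behavior: independent vectors rarely reach |rho| = 0.5 at n = 25
  set.seed(49)
  hits <- 0
  for (i in 1:200) {
    rho <- cor(runif(25), runif(25), method = "spearman")
    if (abs(rho) < 0.5) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.95)
})
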