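test_that("undersampling keeps the minority class and balances the majority", {
  labels <- rep(c("divided", "undivided"), c(246, 756))
  idx <- undersample_majority(labels, seed = 4)
  expect_length(idx, 492L)
  expect_true(all(which(labels == "divided") %in% idx))
  expect_equal(sum(labels[idx] == "undivided"), 246L)
  # balanced input: everything retained
  bal <- rep(c("divided", "undivided"), each = 10)
  expect_identical(undersample_majority(bal, 1), 1:20)
  # determinism
  expect_identical(undersample_majority(labels, 4), idx)
  expect_false(identical(undersample_majority(labels, 5), idx))
  expect_error(undersample_majority(rep("divided", 5), 1), "both classes")
})

test_that("stratified folds preserve fold sizes and class ratios", {
  labels <- rep(c("divided", "undivided"), c(246, 756))
  fold <- stratified_folds(labels, 10, seed = 2)
  sizes <- tabulate(fold, 10)
  expect_true(all(sizes %in% c(100L, 101L)))
  div_per_fold <- vapply(1:10, function(f)
    sum(labels[fold == f] == "divided"), integer(1))
  expect_true(all(div_per_fold %in% c(24L, 25L)))
  expect_error(stratified_folds(rep(c("divided", "undivided"), c(3, 50)), 10),
               "fewer than k")
})

test_that("the base layer emits one probability column per modality-classifier pair", {
  co <- small_cohort(n = 80, seed = 55)
  pp <- preprocess_cohort(co, seed = 55)
  fx <- transform_cohort(pp)
  labs <- cohort_labels(co)
  base <- fit_base_layer(fx, labs, light_ei(seed = 55))
  expect_equal(colnames(base$oof),
               c("ERK|lr", "ERK|dt", "Akt|lr", "Akt|dt"))
  expect_true(all(base$oof >= 0 & base$oof <= 1))
  expect_false(anyNA(base$oof))
  expect_equal(nrow(base$oof), 80L)
})

test_that("no test-fold cell ever enters a base training set (leakage canary)", {
  co <- small_cohort(n = 60, seed = 66)
  pp <- preprocess_cohort(co, seed = 66)
  fx <- transform_cohort(pp)
  base <- fit_base_layer(fx, cohort_labels(co), light_ei(seed = 66))
  for (key in names(base$train_index_record)) {
    f <- as.integer(sub(".*\\|", "", key))
    test_idx <- which(base$folds == f)
    expect_length(intersect(base$train_index_record[[key]], test_idx), 0)
  }
})

test_that("base columns stay at chance on a zero-effect cohort", {
  co <- generate_cohort(generator_config(n_cells = 200, erk_effect = 0,
                                         akt_effect = 0, seed = 19))
  pp <- preprocess_cohort(co, seed = 19)
  fx <- transform_cohort(pp)
  labs <- cohort_labels(co)
  base <- fit_base_layer(fx, labs, light_ei(seed = 19))
  for (j in seq_len(ncol(base$oof)))
    expect_true(auc(labs, base$oof[, j]) > 0.4 &&
                  auc(labs, base$oof[, j]) < 0.6,
                label = paste("chance-level AUC for", colnames(base$oof)[j]))
})

test_that("the mean stacker is exactly the row mean of base columns", {
  set.seed(1)
  P <- matrix(runif(60), 20, 3,
              dimnames = list(NULL, c("ERK|lr", "ERK|dt", "Akt|lr")))
  labs <- rep(c("divided", "undivided"), 10)
  m <- fit_stacker(P, labs, ei_config(base_roster = "lr",
                                      stacker_roster = "mean",
                                      inner_folds = 2, seed = 1))
  expect_equal(m$train_scores, rowMeans(P), tolerance = 1e-12)
  expect_equal(m$stacker$name, "mean")
})

test_that("a perfectly separating base column gives training F_max of 1", {
  labs <- rep(c("divided", "undivided"), c(12, 28))
  P <- cbind("M|lr" = ifelse(labs == "divided", 0.9, 0.1) +
               runif(40, -0.05, 0.05))
  m <- fit_stacker(P, labs, ei_config(base_roster = "lr",
                                      stacker_roster = c("mean", "lr"),
                                      inner_folds = 2, seed = 3))
  expect_equal(m$f_max_train, 1.0)
})

test_that("stacker selection never falls below mean aggregation", {
  co <- small_cohort(n = 100, seed = 77)
  pp <- preprocess_cohort(co, seed = 77)
  fx <- transform_cohort(pp)
  m <- train_ei(fx, cohort_labels(co), light_ei(seed = 77))
  sel <- m$stacker_selection
  best <- sel$f_max[sel$stacker == m$stacker$name]
  expect_gte(best, sel$f_max[sel$stacker == "mean"])
})

test_that("prediction is consistent, deterministic, and validated", {
  co <- small_cohort(n = 80, seed = 88)
  pp <- preprocess_cohort(co, seed = 88)
  fx <- transform_cohort(pp)
  labs <- cohort_labels(co)
  cfg <- light_ei(seed = 88)
  m <- train_ei(fx, labs, cfg)
  # resubstitution consistency of the stored threshold
  expect_equal(f_measure(labs, m$train_scores, m$threshold), m$f_max_train,
               tolerance = 1e-12)
  s <- predict(m, fx)
  expect_true(all(s >= 0 & s <= 1))
  # identical feature rows produce identical scores
  fx_same <- lapply(fx, function(M) {
    M2 <- M
    M2[] <- rep(M[1, ], each = nrow(M))
    M2
  })
  s_same <- predict(m, fx_same)
  expect_equal(max(abs(s_same - s_same[1])), 0, tolerance = 1e-12)
  # full retrain under the same config and seed reproduces scores
  m2 <- train_ei(fx, labs, cfg)
  expect_equal(predict(m2, fx), s, tolerance = 1e-12)
  # class predictions use the stored threshold
  cls <- predict(m, fx, type = "class")
  expect_identical(as.character(cls), ifelse(s >= m$threshold,
                                             "divided", "undivided"))
  # feature-name mismatch is rejected
  fx_bad <- fx
  colnames(fx_bad$ERK)[1] <- "wrong"
  expect_error(predict(m, fx_bad), "feature names")
})

test_that("stacker weights are exposed for linear stackers only", {
  co <- small_cohort(n = 80, seed = 99)
  pp <- preprocess_cohort(co, seed = 99)
  fx <- transform_cohort(pp)
  labs <- cohort_labels(co)
  m_lr <- train_ei(fx, labs, light_ei(seed = 99, stacker_roster = "lr"))
  w <- stacker_weights(m_lr)
  expect_named(w, m_lr$base_colnames)
  expect_true(all(w >= 0))
  m_mean <- train_ei(fx, labs, light_ei(seed = 99, stacker_roster = "mean"))
  expect_true(all(stacker_weights(m_mean) == 1))
  m_rf <- train_ei(fx, labs, light_ei(seed = 99, stacker_roster = "rf"))
  expect_error(stacker_weights(m_rf), "not linear")
})

test_that("every base learner in the default roster trains and predicts", {
  co <- small_cohort(n = 60, seed = 111)
  pp <- preprocess_cohort(co, seed = 111)
  fx <- transform_cohort(pp)["ERK"]
  labs <- cohort_labels(co)
  cfg <- ei_config(inner_folds = 3, num_trees = 50, seed = 111)
  m <- train_ei(fx, labs, cfg)
  expect_setequal(names(m$base_models$ERK),
                  c("lr", "knn", "svm", "rf", "nb", "dt", "gb"))
  s <- predict(m, fx)
  expect_length(s, 60L)
  expect_true(all(is.finite(s) & s >= 0 & s <= 1))
})

test_that("invalid EI configurations are rejected", {
  expect_error(ei_config(base_roster = character(0)), "base_roster")
  expect_error(ei_config(base_roster = "mystery"), "base_roster")
  expect_error(ei_config(stacker_roster = "boost"), "stacker_roster")
  expect_error(ei_config(inner_folds = 1), "inner_folds")
})
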