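# derive a reproducible child seed from a parent seed and a string context
child_seed <- function(seed, ...) {
  k <- sum(utf8ToInt(paste(..., collapse = "|")))
  as.integer((as.numeric(seed) * 1009 + k) %% 2147483647)
}

# labels normalized to factor with the minority/positive class second
as_fate_factor <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.numeric(labels) || is.logical(labels))
    labels <- ifelse(as.logical(labels), "divided", "undivided")
  if (!all(labels %in% c("divided", "undivided")))
    stop("labels must be 'divided' or 'undivided'")
  factor(labels, levels = c("undivided", "divided"))
}

#' Configuration of an Ensemble Integration (EI) model
#'
#' EI trains a roster of heterogeneous base classifiers separately on each
#' data modality (here: per-kinase feature matrices), collects their
#' out-of-fold probability predictions, and combines them with a stacker
#' (meta-classifier) selected by nested cross-validation using the
#' minority-class F-max as the selection metric.
#'
#' @param base_roster Character vector of base classifiers, any of
#'   `"lr"` (L2-regularized logistic regression), `"knn"` (k-nearest
#'   neighbors), `"svm"`
#'   (radial SVM with probability calibration), `"rf"` (random forest),
#'   `"nb"` (naive Bayes), `"dt"` (decision tree), `"gb"` (gradient
#'   boosting; requires the xgboost package).
#' @param stacker_roster Subset of `"mean"` (probability averaging),
#'   `"lr"` (logistic-regression stacking), `"rf"` (random-forest
#'   stacking), in preference order for ties.
#' @param inner_folds Folds for out-of-fold base predictions and stacker
#'   selection (default 5).
#' @param undersample Balance training folds by undersampling the majority
#'   class (default `TRUE`), the standard remedy for the divided-class
#'   imbalance.
#' @param num_trees Trees for random-forest learners (default 300).
#' @param knn_k Neighbors for `"knn"` (default 5).
#' @param seed Integer seed controlling fold assignment, undersampling and
#'   stochastic learners.
#' @return An `ei_config`.
#' @export
ei_config <- function(base_roster = c("lr", "knn", "svm", "rf", "nb", "dt", "gb"),
                      stacker_roster = c("mean", "lr", "rf"),
                      inner_folds = 5L, undersample = TRUE,
                      num_trees = 300L, knn_k = 5L, seed = 1L) {
  known_b <- c("lr", "knn", "svm", "rf", "nb", "dt", "gb")
  known_s <- c("mean", "lr", "rf")
  if (length(base_roster) == 0L || !all(base_roster %in% known_b))
    stop("base_roster must be a non-empty subset of: ",
         paste(known_b, collapse = ", "))
  if (length(stacker_roster) == 0L || !all(stacker_roster %in% known_s))
    stop("stacker_roster must be a non-empty subset of: ",
         paste(known_s, collapse = ", "))
  if (inner_folds < 2L) stop("inner_folds must be >= 2")
  if ("gb" %in% base_roster && !requireNamespace("xgboost", quietly = TRUE))
    stop("base learner 'gb' requires the xgboost package")
  structure(list(base_roster = base_roster, stacker_roster = stacker_roster,
                 inner_folds = as.integer(inner_folds),
                 undersample = isTRUE(undersample),
                 num_trees = as.integer(num_trees), knn_k = as.integer(knn_k),
                 seed = as.integer(seed)),
            class = "ei_config")
}

#' Balance classes by undersampling the majority class
#'
#' Keeps every minority-class index and a seeded uniform random subset of
#' majority-class indices of equal size.
#'
#' @param labels Fate labels (`divided` is the minority/positive class by
#'   convention; the actual minority class is detected from counts).
#' @param seed Integer seed.
#' @return Sorted integer index vector into `labels`.
#' @export
undersample_majority <- function(labels, seed = 1L) {
  y <- as_fate_factor(labels)
  tab <- table(y)
  if (any(tab == 0L)) stop("both classes must be present")
  minority <- names(tab)[which.min(tab)]
  min_idx <- which(y == minority)
  maj_idx <- which(y != minority)
  if (length(min_idx) == length(maj_idx)) return(sort(c(min_idx, maj_idx)))
  set.seed(seed)
  sort(c(min_idx, sample(maj_idx, length(min_idx))))
}

#' Stratified fold assignment
#'
#' Assigns each observation to one of `k` folds so that every fold's class
#' ratio matches the global ratio to within one cell per class.
#'
#' @param labels Fate labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in 1..k.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  y <- as_fate_factor(labels)
  if (any(table(y) < k)) stop("a class has fewer than k members")
  fold <- integer(length(y))
  set.seed(seed)
  offset <- 0L
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    # rotate the dealing start between classes so total fold sizes differ
    # by at most one even when each class's count is not a multiple of k
    fold[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
    offset <- offset + length(idx)
  }
  fold
}

# --- ridge logistic regression helpers -------------------------------------
# L2 regularization keeps coefficients stable on the strongly collinear DWT
# coefficient features (unpenalized ML fits drift to level-cancelling
# contrasts there, which also wrecks permutation importance). The penalty is
# fixed at lambda = 1/n, the glmnet-scale equivalent of the standard default
# unit-C ridge logistic regression, which keeps the fit deterministic.
# glmnet needs >= 2 informative columns, so degenerate inputs are padded
# with a constant dummy column (coefficient necessarily 0) or, when every
# column is constant, replaced by a base-rate predictor.

fit_ridge_logistic <- function(X, y, seed) {
  X <- as.matrix(X)
  keep <- which(apply(X, 2, function(v) max(v) - min(v)) > 0)
  if (length(keep) == 0L)
    return(list(type = "const", p = mean(y == "divided"),
                n_col = ncol(X), col_names = colnames(X)))
  Xk <- X[, keep, drop = FALSE]
  pad <- ncol(Xk) < 2L
  if (pad) Xk <- cbind(Xk, `..const..` = 0)
  lam <- 1 / nrow(Xk)
  lambda_path <- sort(unique(c(1000, 100, 10, 1, 0.1, 0.01, lam)),
                      decreasing = TRUE)
  # suppress the small-sample class-count warning: undersampled inner folds
  # are legitimately small in nested CV
  fit <- suppressWarnings(
    glmnet::glmnet(Xk, y, family = "binomial", alpha = 0,
                   lambda = lambda_path, standardize = TRUE))
  list(type = "glmnet", fit = fit, lambda = lam, keep = keep, pad = pad,
       n_col = ncol(X), col_names = colnames(X))
}

predict_ridge_logistic <- function(model, X) {
  X <- as.matrix(X)
  if (identical(model$type, "const")) return(rep(model$p, nrow(X)))
  Xk <- X[, model$keep, drop = FALSE]
  if (model$pad) Xk <- cbind(Xk, `..const..` = 0)
  p <- stats::predict(model$fit, newx = Xk, s = model$lambda,
                      type = "response", exact = FALSE)
  pmin(pmax(as.numeric(p), 0), 1)
}

ridge_coefficients <- function(model) {
  out <- stats::setNames(numeric(model$n_col), model$col_names)
  if (identical(model$type, "const")) return(out)
  cf <- as.matrix(stats::coef(model$fit, s = model$lambda))[, 1]
  cf <- cf[setdiff(names(cf), c("(Intercept)", "..const.."))]
  out[names(cf)] <- cf
  out
}

# --- base learner registry -------------------------------------------------
# each entry: fit(X, y, cfg, seed) -> model; predict(model, X) -> P(divided)

.base_learners <- list(
  lr = list(
    fit = function(X, y, cfg, seed) fit_ridge_logistic(X, y, seed),
    predict = predict_ridge_logistic),
  knn = list(
    fit = function(X, y, cfg, seed) list(X = X, y = y, k = cfg$knn_k, seed = seed),
    predict = function(model, X) {
      set.seed(model$seed)  # tie-breaking in knn is randomized
      pr <- class::knn(model$X, X, model$y, k = model$k, prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == "divided", p, 1 - p)
    }),
  svm = list(
    fit = function(X, y, cfg, seed) {
      set.seed(seed)  # internal CV of the probability model
      e1071::svm(x = X, y = y, kernel = "radial", probability = TRUE)
    },
    predict = function(model, X) {
      pr <- stats::predict(model, X, probability = TRUE)
      unname(attr(pr, "probabilities")[, "divided"])
    }),
  rf = list(
    fit = function(X, y, cfg, seed) {
      ranger::ranger(x = X, y = y, probability = TRUE,
                     num.trees = cfg$num_trees, seed = seed, num.threads = 1L)
    },
    predict = function(model, X) {
      unname(stats::predict(model, data = X,
                            num.threads = 1L)$predictions[, "divided"])
    }),
  nb = list(
    fit = function(X, y, cfg, seed)
      e1071::naiveBayes(x = data.frame(X, check.names = FALSE), y = y),
    predict = function(model, X) {
      p <- stats::predict(model, data.frame(X, check.names = FALSE), type = "raw")
      unname(p[, "divided"])
    }),
  dt = list(
    fit = function(X, y, cfg, seed) {
      d <- data.frame(X, check.names = FALSE)
      d$.y <- y
      rpart::rpart(.y ~ ., data = d, method = "class")
    },
    predict = function(model, X) {
      p <- stats::predict(model, newdata = data.frame(X, check.names = FALSE),
                          type = "prob")
      unname(p[, "divided"])
    }),
  gb = list(
    fit = function(X, y, cfg, seed) {
      set.seed(seed)
      # factor response: xgboost models P(second level) = P(divided)
      xgboost::xgboost(x = X, y = y, nrounds = 50L, max_depth = 3L,
                       learning_rate = 0.3, nthreads = 1L, verbosity = 0L)
    },
    predict = function(model, X) unname(stats::predict(model, X)))
)

#' Fit the per-modality base layer of an EI model
#'
#' For every (modality, base classifier) pair, produces out-of-fold
#' probability predictions for every training cell via stratified
#' `inner_folds`-fold cross-validation, with majority-class undersampling
#' applied strictly inside each training fold, and refits a final model on
#' the full (undersampled) training set. The out-of-fold matrix is the
#' stacker's training input; using out-of-fold rather than resubstitution
#' predictions is what keeps the stacker honest.
#'
#' @param features Named list of feature matrices (one per modality, equal
#'   row order matching `labels`).
#' @param labels Fate labels, one per row.
#' @param config An [ei_config()].
#' @return List with `base_models` (nested modality -> base name), `oof`
#'   (cells x (modalities x bases) probability matrix, columns named
#'   `"modality|base"`), `feature_names` per modality, `folds` (the
#'   stratified fold assignment), and `train_index_record` (the training
#'   row indices actually used for every (modality, base, fold) fit, for
#'   leakage auditing).
#' @export
fit_base_layer <- function(features, labels, config = ei_config()) {
  stopifnot(is.list(features), length(features) >= 1L, !is.null(names(features)))
  y <- as_fate_factor(labels)
  n <- length(y)
  for (m in names(features))
    if (nrow(features[[m]]) != n)
      stop("modality '", m, "' row count does not match labels")
  folds <- stratified_folds(y, config$inner_folds,
                            seed = child_seed(config$seed, "base-folds"))
  cols <- list()
  base_models <- list()
  train_index_record <- list()
  for (m in names(features)) {
    X <- unclass(features[[m]])
    base_models[[m]] <- list()
    for (b in config$base_roster) {
      learner <- .base_learners[[b]]
      oof <- rep(NA_real_, n)
      for (f in seq_len(config$inner_folds)) {
        tr <- which(folds != f); te <- which(folds == f)
        if (config$undersample)
          tr <- tr[undersample_majority(y[tr],
                                        seed = child_seed(config$seed, m, b, f))]
        train_index_record[[paste(m, b, f, sep = "|")]] <- tr
        fit <- learner$fit(X[tr, , drop = FALSE], y[tr], config,
                           seed = child_seed(config$seed, m, b, f, "fit"))
        oof[te] <- learner$predict(fit, X[te, , drop = FALSE])
      }
      cols[[paste(m, b, sep = "|")]] <- pmin(pmax(oof, 0), 1)
      tr_full <- if (config$undersample)
        undersample_majority(y, seed = child_seed(config$seed, m, b, "final"))
      else seq_len(n)
      base_models[[m]][[b]] <-
        learner$fit(X[tr_full, , drop = FALSE], y[tr_full], config,
                    seed = child_seed(config$seed, m, b, "final-fit"))
    }
  }
  oof <- do.call(cbind, cols)
  rownames(oof) <- rownames(features[[1L]])
  list(base_models = base_models, oof = oof,
       feature_names = lapply(features, colnames),
       folds = folds, train_index_record = train_index_record)
}

# --- stacker registry ------------------------------------------------------

.stackers <- list(
  mean = list(
    fit = function(P, y, cfg, seed) list(),
    predict = function(model, P) rowMeans(P)),
  lr = list(
    fit = function(P, y, cfg, seed) fit_ridge_logistic(P, y, seed),
    predict = predict_ridge_logistic),
  rf = list(
    fit = function(P, y, cfg, seed)
      ranger::ranger(x = P, y = y, probability = TRUE,
                     num.trees = cfg$num_trees, seed = seed, num.threads = 1L),
    predict = function(model, P)
      unname(stats::predict(model, data = P,
                            num.threads = 1L)$predictions[, "divided"]))
)

#' Select and fit the EI stacker on out-of-fold base predictions
#'
#' Scores every stacker in the roster by inner cross-validated minority
#' class F-max on the out-of-fold base-prediction matrix, retains the best
#' (ties broken by roster order), refits it on all rows, and stores the
#' decision threshold that maximizes the F-measure on the training
#' predictions — the threshold later transferred to test data. The selected
#' stacker's out-of-fold scores are kept in the model (`oof_scores`), giving
#' a nested cross-validated performance estimate without refitting.
#'
#' @param base A [fit_base_layer()] result (or a bare out-of-fold matrix).
#' @param labels Fate labels, one per row.
#' @param config An [ei_config()].
#' @return An `ei_model` (without feature metadata if given a bare matrix);
#'   prefer [train_ei()] for end-to-end fitting.
#' @export
fit_stacker <- function(base, labels, config = ei_config()) {
  if (is.matrix(base)) base <- list(base_models = NULL, oof = base,
                                    feature_names = NULL)
  P <- base$oof
  y <- as_fate_factor(labels)
  folds <- stratified_folds(y, config$inner_folds,
                            seed = child_seed(config$seed, "stacker-folds"))
  sel <- data.frame(stacker = config$stacker_roster, f_max = NA_real_)
  oof_by_stacker <- list()
  for (si in seq_along(config$stacker_roster)) {
    s <- config$stacker_roster[si]
    st <- .stackers[[s]]
    oof <- rep(NA_real_, length(y))
    for (f in seq_len(config$inner_folds)) {
      tr <- which(folds != f); te <- which(folds == f)
      fit <- st$fit(P[tr, , drop = FALSE], y[tr], config,
                    seed = child_seed(config$seed, "stk", s, f))
      oof[te] <- st$predict(fit, P[te, , drop = FALSE])
    }
    oof_by_stacker[[s]] <- oof
    sel$f_max[si] <- f_max(y, oof)$f_max
  }
  best <- sel$stacker[which.max(sel$f_max)]
  st <- .stackers[[best]]
  final <- st$fit(P, y, config, seed = child_seed(config$seed, "stk", best, "final"))
  train_scores <- st$predict(final, P)
  fm <- f_max(y, train_scores)
  structure(list(base_models = base$base_models,
                 base_colnames = colnames(P),
                 feature_names = base$feature_names,
                 stacker = list(name = best, model = final),
                 stacker_selection = sel,
                 threshold = fm$threshold,
                 f_max_train = fm$f_max,
                 train_scores = train_scores,
                 oof_scores = oof_by_stacker[[best]],
                 config = config),
            class = "ei_model")
}

#' Train a full Ensemble Integration model
#'
#' Convenience wrapper: [fit_base_layer()] followed by [fit_stacker()].
#'
#' @inheritParams fit_base_layer
#' @return An `ei_model` with base models, selected stacker, and the
#'   training F-max threshold.
#' @examples
#' \donttest{
#' co <- generate_cohort(generator_config(n_cells = 120, seed = 3))
#' pp <- preprocess_cohort(co, seed = 3)
#' fx <- transform_cohort(pp)
#' m <- train_ei(fx, cohort_labels(pp$cohort),
#'               ei_config(base_roster = c("lr", "rf"), inner_folds = 3))
#' }
#' @export
train_ei <- function(features, labels, config = ei_config()) {
  base <- fit_base_layer(features, labels, config)
  fit_stacker(base, labels, config)
}

#' @export
print.ei_model <- function(x, ...) {
  cat("<ei_model> ", length(x$base_models), " modalities x ",
      length(x$config$base_roster), " base classifiers; stacker: ",
      x$stacker$name, "\n  training F_max = ", round(x$f_max_train, 3),
      " at threshold ", round(x$threshold, 3), "\n", sep = "")
  invisible(x)
}

#' Predict division scores (or calls) with an EI model
#'
#' Base models score each modality's features; the stacker maps the base
#' probability columns to a final score in \[0, 1\]. Binary calls use the
#' F-max threshold learned on the training data (threshold transfer).
#'
#' @param object An `ei_model`.
#' @param features Named list of feature matrices whose column names match
#'   the training-time feature names.
#' @param type `"score"` (default) or `"class"`.
#' @param ... Ignored.
#' @return Numeric scores in \[0, 1\], or a factor of fate calls.
#' @export
predict.ei_model <- function(object, features, type = c("score", "class"), ...) {
  type <- match.arg(type)
  if (is.null(object$base_models))
    stop("model was fit on a bare prediction matrix; no base layer to apply")
  cols <- list()
  for (m in names(object$base_models)) {
    if (is.null(features[[m]]))
      stop("features for modality '", m, "' missing")
    X <- unclass(features[[m]])
    if (!identical(colnames(X), object$feature_names[[m]]))
      stop("feature names of modality '", m, "' do not match training")
    for (b in names(object$base_models[[m]])) {
      p <- .base_learners[[b]]$predict(object$base_models[[m]][[b]], X)
      cols[[paste(m, b, sep = "|")]] <- pmin(pmax(p, 0), 1)
    }
  }
  P <- do.call(cbind, cols)[, object$base_colnames, drop = FALSE]
  s <- .stackers[[object$stacker$name]]$predict(object$stacker$model, P)
  s <- pmin(pmax(s, 0), 1)
  if (type == "score") return(s)
  factor(ifelse(s >= object$threshold, "divided", "undivided"),
         levels = c("undivided", "divided"))
}

#' Absolute stacker weights of a linear EI model
#'
#' For the interpretation algorithm: the reliance of the stacker on each
#' base column. Defined for the logistic-regression stacker (absolute
#' coefficients) and the mean stacker (equal weights); random-forest
#' stacking has no linear weights and is rejected.
#'
#' @param model An `ei_model`.
#' @return Named non-negative numeric vector, one entry per base column.
#' @export
stacker_weights <- function(model) {
  stopifnot(inherits(model, "ei_model"))
  if (model$stacker$name == "mean") {
    w <- rep(1, length(model$base_colnames))
    names(w) <- model$base_colnames
    return(w)
  }
  if (model$stacker$name == "lr") {
    cf <- ridge_coefficients(model$stacker$model)
    cf[is.na(cf)] <- 0
    return(abs(cf)[model$base_colnames])
  }
  stop("stacker '", model$stacker$name,
       "' is not linear; interpretation requires 'lr' or 'mean'")
}
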