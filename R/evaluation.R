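#' F-measure of the divided (minority) class at a threshold
#'
#' Harmonic mean of precision and recall of the positive (divided) class
#' when scores at or above `threshold` are called divided. Returns 0 when
#' no positives are predicted.
#'
#' @param labels Fate labels.
#' @param scores Numeric classification scores (higher = more likely
#'   divided).
#' @param threshold Decision threshold; predictions are `scores >=
#'   threshold`.
#' @return F-measure in \[0, 1\].
#' @export
f_measure <- function(labels, scores, threshold) {
  y <- as_fate_factor(labels) == "divided"
  if (any(!is.finite(scores))) stop("non-finite scores")
  stopifnot(length(y) == length(scores))
  pred <- scores >= threshold
  tp <- sum(pred & y)
  if (tp == 0) return(0)
  prec <- tp / sum(pred)
  rec <- tp / sum(y)
  2 * prec * rec / (prec + rec)
}

#' Maximum F-measure over all thresholds (F-max)
#'
#' The primary metric for the imbalanced division-fate problem: the
#' maximum of the minority-class F-measure across all classification-score
#' thresholds. Candidate thresholds are the observed unique scores (the
#' F-measure is piecewise constant between them) plus an all-negative
#' sentinel; ties are broken toward the lowest threshold. The argmax
#' threshold is returned for transfer to test data.
#'
#' @inheritParams f_measure
#' @return List with `f_max` and `threshold`.
#' @examples
#' f_max(c(1, 0, 1, 0, 0), c(0.9, 0.8, 0.7, 0.3, 0.2))  # 0.8 at 0.7
#' @export
f_max <- function(labels, scores) {
  y <- as_fate_factor(labels)
  if (any(table(y) == 0L)) stop("both classes must be present")
  if (any(!is.finite(scores))) stop("non-finite scores")
  thr <- c(sort(unique(scores)), Inf)
  f <- vapply(thr, function(t) f_measure(y, scores, t), numeric(1))
  i <- which.max(f)  # first maximum = lowest threshold among ties
  list(f_max = f[i], threshold = thr[i])
}

#' Area under the ROC curve (rank / Mann-Whitney formulation)
#'
#' The probability that a randomly chosen divided cell receives a higher
#' score than a randomly chosen undivided cell, with ties counted as 1/2.
#'
#' @inheritParams f_measure
#' @return AUC in \[0, 1\].
#' @export
auc <- function(labels, scores) {
  y <- as_fate_factor(labels) == "divided"
  if (all(y) || !any(y)) stop("both classes must be present")
  if (any(!is.finite(scores))) stop("non-finite scores")
  r <- rank(scores)
  n1 <- sum(y); n0 <- sum(!y)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Specify a classification pipeline for evaluation
#'
#' Bundles the feature transform, the modality set, and the EI
#' configuration evaluated by [cross_validate()] and [comparison_grid()].
#'
#' @param transform A [transform_spec()].
#' @param modalities Character vector of modality names to use (a single
#'   kinase, or both for the multi-modal model).
#' @param ei An [ei_config()].
#' @return A `pipeline_spec`.
#' @export
pipeline_spec <- function(transform = transform_spec(),
                          modalities = c("ERK", "Akt"),
                          ei = ei_config()) {
  stopifnot(inherits(transform, "transform_spec"), inherits(ei, "ei_config"),
            length(modalities) >= 1L)
  structure(list(transform = transform, modalities = modalities, ei = ei),
            class = "pipeline_spec")
}

#' Stratified k-fold cross-validation of a pipeline
#'
#' For each stratified fold: the EI model (undersampling inside) is fit on
#' the other k-1 folds, the F-max threshold is learned on that training
#' portion only, and the held-out fold is scored with the transferred
#' threshold (F-measure) and ranked (AUC). Test labels never touch
#' threshold selection.
#'
#' @param method A [pipeline_spec()].
#' @param pp A [preprocess_cohort()] result.
#' @param k Number of folds (default 10).
#' @param seed Integer seed for fold assignment and model fitting.
#' @return An `evaluation_report`: list with `per_fold` (data.frame: fold,
#'   n_test, f_max_train, threshold, f_measure, auc), `summary` (median
#'   and quartiles per metric), `pooled_auc` (AUC of pooled out-of-fold
#'   scores), `scores` (pooled out-of-fold score per cell), `folds`, and
#'   `seed`.
#' @export
cross_validate <- function(method, pp, k = 10L, seed = 1L) {
  stopifnot(inherits(method, "pipeline_spec"),
            inherits(pp, "preprocessed_cohort"), k >= 2L)
  x <- pp$cohort
  missing_m <- setdiff(method$modalities, x$modalities)
  if (length(missing_m) > 0)
    stop("cohort lacks modalities: ", paste(missing_m, collapse = ", "))
  labels <- cohort_labels(x)
  y <- as_fate_factor(labels)
  features <- transform_cohort(pp, method$transform)[method$modalities]
  folds <- stratified_folds(y, k, seed = child_seed(seed, "cv-folds"))
  per_fold <- data.frame(fold = seq_len(k), n_test = NA_integer_,
                         f_max_train = NA_real_, threshold = NA_real_,
                         f_measure = NA_real_, auc = NA_real_)
  oof_scores <- rep(NA_real_, length(y))
  for (f in seq_len(k)) {
    tr <- which(folds != f); te <- which(folds == f)
    cfg <- method$ei
    cfg$seed <- child_seed(seed, "cv-fit", f)
    ftr <- lapply(features, function(M) M[tr, , drop = FALSE])
    fte <- lapply(features, function(M) M[te, , drop = FALSE])
    model <- train_ei(ftr, y[tr], cfg)
    s <- predict(model, fte)
    oof_scores[te] <- s
    per_fold$n_test[f] <- length(te)
    per_fold$f_max_train[f] <- model$f_max_train
    per_fold$threshold[f] <- model$threshold
    per_fold$f_measure[f] <- f_measure(y[te], s, model$threshold)
    per_fold$auc[f] <- auc(y[te], s)
  }
  summ <- do.call(rbind, lapply(c("f_max_train", "f_measure", "auc"), function(mname) {
    v <- per_fold[[mname]]
    data.frame(metric = mname, median = stats::median(v),
               q1 = unname(stats::quantile(v, 0.25)),
               q3 = unname(stats::quantile(v, 0.75)))
  }))
  structure(list(per_fold = per_fold, summary = summ,
                 pooled_auc = auc(y, oof_scores), scores = oof_scores,
                 folds = folds, seed = as.integer(seed)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> ", nrow(x$per_fold), "-fold CV; median F-measure = ",
      round(stats::median(x$per_fold$f_measure), 3), ", median AUC = ",
      round(stats::median(x$per_fold$auc), 3), ", pooled AUC = ",
      round(x$pooled_auc, 3), "\n", sep = "")
  invisible(x)
}

#' Factorial comparison of transforms, EI methods and modality sets
#'
#' Cross-validates every combination of feature transform, EI
#' configuration and modality set (single kinases and their multi-modal
#' combination), reporting median fold metrics — the grid from which the
#' best transform + method combination per modality set is selected for
#' final model building. A failing grid cell is flagged (its `error`
#' column set) rather than aborting the grid.
#'
#' @param transforms Named list of [transform_spec()]s.
#' @param methods Named list of [ei_config()]s.
#' @param pp A [preprocess_cohort()] result.
#' @param modality_sets Named list of character vectors.
#' @param k Folds (default 10).
#' @param seed Integer seed.
#' @return Data frame with one row per combination: `transform`, `method`,
#'   `modalities`, `median_f_max_train`, `median_f_measure`, `median_auc`,
#'   `error` (NA unless the cell failed).
#' @export
comparison_grid <- function(transforms, methods, pp, modality_sets,
                            k = 10L, seed = 1L) {
  stopifnot(length(transforms) > 0, length(methods) > 0,
            length(modality_sets) > 0)
  rows <- list()
  for (tn in names(transforms)) for (mn in names(methods))
    for (sn in names(modality_sets)) {
      res <- tryCatch({
        rep_ <- cross_validate(pipeline_spec(transforms[[tn]],
                                             modality_sets[[sn]],
                                             methods[[mn]]),
                               pp, k = k, seed = seed)
        data.frame(transform = tn, method = mn, modalities = sn,
                   median_f_max_train = stats::median(rep_$per_fold$f_max_train),
                   median_f_measure = stats::median(rep_$per_fold$f_measure),
                   median_auc = stats::median(rep_$per_fold$auc),
                   error = NA_character_)
      }, error = function(e)
        data.frame(transform = tn, method = mn, modalities = sn,
                   median_f_max_train = NA_real_, median_f_measure = NA_real_,
                   median_auc = NA_real_, error = conditionMessage(e)))
      rows[[length(rows) + 1L]] <- res
    }
  do.call(rbind, rows)
}
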