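time_col_names <- function(start_h, n, interval_min) {
  sprintf("t%.2fh", start_h + (seq_len(n) - 1L) * interval_min / 60)
}

#' Write a cohort to plain-text files
#'
#' Writes, under `dir`: one wide CSV per modality (`<modality>_wide.csv`;
#' rows = cells, columns = `cell_id` then time-in-hours headers, empty
#' fields beyond a truncated cell's retained length), a long TSV
#' (`cohort_long.tsv`: cell_id, modality, time_h, value), a labels CSV
#' (`labels.csv`: cell_id, label, division_time_h), and a provenance JSON
#' carrying the grid conventions and generator config/seed.
#'
#' @param x A [cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tc <- time_col_names(x$start_h, x$grid_length, x$sampling_interval)
  for (m in x$modalities) {
    mat <- t(vapply(x$cells, function(c) {
      v <- c$series[[m]]
      c(v, rep(NA_real_, x$grid_length - length(v)))
    }, numeric(x$grid_length)))
    df <- data.frame(cell_id = cohort_ids(x), mat, check.names = FALSE)
    colnames(df) <- c("cell_id", tc)
    utils::write.csv(df, file.path(dir, paste0(m, "_wide.csv")),
                     row.names = FALSE, na = "")
  }
  long <- do.call(rbind, lapply(x$cells, function(c) {
    t_h <- cell_times(c)
    do.call(rbind, lapply(names(c$series), function(m)
      data.frame(cell_id = c$cell_id, modality = m, time_h = t_h,
                 value = c$series[[m]])))
  }))
  utils::write.table(long, file.path(dir, "cohort_long.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  labs <- data.frame(cell_id = cohort_ids(x), label = cohort_labels(x),
                     division_time_h = vapply(x$cells,
                                              function(c) c$division_time,
                                              numeric(1)))
  utils::write.csv(labs, file.path(dir, "labels.csv"), row.names = FALSE,
                   na = "")
  prov <- list(modalities = x$modalities, grid_length = x$grid_length,
               sampling_interval = x$sampling_interval, start_h = x$start_h,
               provenance = x$provenance)
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a cohort from files written by [write_cohort()]
#'
#' Reconstructs and validates the cohort from either the wide per-modality
#' CSVs or the long TSV (both carry identical information). Malformed
#' input — an irregular time grid, duplicate cell ids, a label outside
#' divided/undivided, or a missing value in the middle of a series — is
#' rejected with the offending cell named.
#'
#' @param dir Directory containing the cohort files.
#' @param format `"wide"` (default) or `"long"`.
#' @return A validated [cohort()].
#' @export
read_cohort <- function(dir, format = c("wide", "long")) {
  format <- match.arg(format)
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"),
                              simplifyVector = TRUE)
  mods <- prov$modalities
  labs <- utils::read.csv(file.path(dir, "labels.csv"),
                          colClasses = c("character", "character", "numeric"))
  if (anyDuplicated(labs$cell_id))
    stop("duplicate cell_ids in labels.csv")
  bad <- !(labs$label %in% c("divided", "undivided") | is.na(labs$label))
  if (any(bad))
    stop("invalid label for cell(s): ",
         paste(labs$cell_id[bad], collapse = ", "))

  series_by_cell <- list()
  if (format == "wide") {
    for (m in mods) {
      df <- utils::read.csv(file.path(dir, paste0(m, "_wide.csv")),
                            check.names = FALSE,
                            colClasses = c("character",
                                           rep("numeric", prov$grid_length)))
      t_h <- as.numeric(sub("h$", "", sub("^t", "", colnames(df)[-1])))
      if (max(abs(diff(t_h) - prov$sampling_interval / 60)) > 1e-6)
        stop("irregular time grid in ", m, "_wide.csv")
      for (r in seq_len(nrow(df))) {
        v <- as.numeric(df[r, -1])
        obs <- !is.na(v)
        n_obs <- sum(obs)
        if (n_obs == 0L) stop("cell '", df$cell_id[r], "' has no values (",
                              m, "_wide.csv row ", r, ")")
        if (any(which(obs) != seq_len(n_obs)))
          stop("missing value inside series of cell '", df$cell_id[r],
               "' (", m, "_wide.csv row ", r, ")")
        series_by_cell[[df$cell_id[r]]][[m]] <- v[seq_len(n_obs)]
      }
    }
  } else {
    long <- utils::read.table(file.path(dir, "cohort_long.tsv"), sep = "\t",
                              header = TRUE,
                              colClasses = c("character", "character",
                                             "numeric", "numeric"))
    for (id in unique(long$cell_id)) {
      sub <- long[long$cell_id == id, ]
      for (m in mods) {
        sm <- sub[sub$modality == m, ]
        sm <- sm[order(sm$time_h), ]
        if (nrow(sm) == 0L) stop("cell '", id, "' lacks modality '", m, "'")
        if (nrow(sm) > 1L &&
            max(abs(diff(sm$time_h) - prov$sampling_interval / 60)) > 1e-6)
          stop("irregular time grid for cell '", id, "', modality '", m, "'")
        if (anyNA(sm$value))
          stop("missing value inside series of cell '", id, "'")
        series_by_cell[[id]][[m]] <- sm$value
      }
    }
  }
  ids <- labs$cell_id
  cells <- lapply(seq_along(ids), function(i) {
    s <- series_by_cell[[ids[i]]]
    if (is.null(s)) stop("cell '", ids[i], "' in labels.csv has no series")
    cell_timecourse(ids[i], s[mods], prov$sampling_interval,
                    start_h = prov$start_h, label = labs$label[i],
                    division_time = labs$division_time_h[i])
  })
  cohort(cells, mods, prov$grid_length, prov$sampling_interval,
         start_h = prov$start_h,
         provenance = c(prov$provenance, list(source_dir = dir)))
}

#' Write a feature matrix (or list of them) as CSV
#'
#' @param features A `feature_matrix` or named list of them.
#' @param path File path (single matrix) or directory (list).
#' @return The path(s), invisibly.
#' @export
write_features <- function(features, path) {
  if (is.list(features) && !is.matrix(features)) {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    for (m in names(features))
      write_features(features[[m]], file.path(path, paste0(m, "_features.csv")))
    return(invisible(path))
  }
  df <- data.frame(cell_id = rownames(features), unclass(features),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline end to end
#'
#' Simulate (or read) a cohort, preprocess it, extract features, train the
#' multi-modal EI model, cross-validate it, and compute the interpretation
#' profile, writing every artifact with its provenance under `out_dir`.
#' Identical configuration and seeds reproduce identical artifacts.
#'
#' @param generator A [generator_config()], or `NULL` to read a cohort
#'   from `cohort_dir`.
#' @param cohort_dir Directory with a written cohort (used when
#'   `generator` is `NULL`).
#' @param out_dir Output directory.
#' @param transform A [transform_spec()].
#' @param ei An [ei_config()].
#' @param modalities Modalities for the final model (default both).
#' @param k Cross-validation folds (default 10).
#' @param n_repeats Permutations per feature for interpretation.
#' @param seed Master seed for preprocessing, CV and interpretation.
#' @param verbose Log stage progress (default `TRUE`).
#' @return Invisible list with `cohort`, `preprocessed`, `features`,
#'   `model`, `evaluation`, `importance`, `concordance` and the artifact
#'   paths.
#' @export
run_pipeline <- function(generator = generator_config(n_cells = 300L),
                         cohort_dir = NULL,
                         out_dir = tempfile("kinfate_run_"),
                         transform = transform_spec(),
                         ei = ei_config(),
                         modalities = NULL,
                         k = 10L, n_repeats = 10L, seed = 1L,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message("[kinfate] ", ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(generator)) {
    say("simulate: n_cells = ", generator$n_cells, ", seed = ", generator$seed)
    co <- generate_cohort(generator)
  } else {
    if (is.null(cohort_dir)) stop("either generator or cohort_dir is required")
    say("read cohort from ", cohort_dir)
    co <- read_cohort(cohort_dir)
  }
  write_cohort(co, file.path(out_dir, "cohort"))
  if (is.null(modalities)) modalities <- co$modalities
  labs <- cohort_labels(co)
  say("classes: ", sum(labs == "divided"), " divided / ",
      sum(labs == "undivided"), " undivided")

  pp <- preprocess_cohort(co, seed = child_seed(seed, "preprocess"))
  say("preprocess: class length KS = ", signif(pp$length_ks, 3))
  jsonlite::write_json(
    list(seed = pp$seed, length_ks = pp$length_ks,
         truncation_record = as.list(pp$truncation_record)),
    file.path(out_dir, "preprocessing_report.json"),
    auto_unbox = TRUE, digits = NA)

  features <- transform_cohort(pp, transform)[modalities]
  write_features(features, file.path(out_dir, "features"))

  say("evaluate: ", k, "-fold stratified CV")
  method <- pipeline_spec(transform, modalities, ei)
  ev <- cross_validate(method, pp, k = k, seed = child_seed(seed, "cv"))
  utils::write.csv(ev$per_fold, file.path(out_dir, "cv_per_fold.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(summary = ev$summary, pooled_auc = ev$pooled_auc, seed = ev$seed),
    file.path(out_dir, "cv_report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")

  say("train final model on full cohort")
  ei_final <- ei
  ei_final$seed <- child_seed(seed, "final-model")
  model <- train_ei(features, labs, ei_final)
  say("selected stacker: ", model$stacker$name,
      "; training F_max = ", round(model$f_max_train, 3),
      " at threshold ", round(model$threshold, 3))
  jsonlite::write_json(
    list(stacker = model$stacker$name,
         stacker_selection = model$stacker_selection,
         threshold = model$threshold, f_max_train = model$f_max_train),
    file.path(out_dir, "model_summary.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")

  imp <- NULL; conc <- NULL
  if (model$stacker$name %in% c("lr", "mean")) {
    say("interpret: permutation importance, ", n_repeats, " repeats")
    imp <- ei_importance(model, features, labs, n_repeats = n_repeats,
                         seed = child_seed(seed, "interpret"))
    utils::write.csv(imp, file.path(out_dir, "importance_profile.csv"),
                     row.names = FALSE)
    diffs <- median_class_difference(pp, transform)
    conc <- importance_concordance(imp, diffs[modalities])
    say("importance-vs-median-difference Spearman: ",
        paste(names(conc), round(conc, 3), sep = " = ", collapse = ", "))
  } else {
    say("interpret: skipped (non-linear stacker '", model$stacker$name, "')")
  }
  jsonlite::write_json(
    list(seed = seed, k = k, n_repeats = n_repeats,
         modalities = modalities, transform = transform[c("kind", "level",
                                                          "wavelet", "boundary")],
         ei = unclass(ei), generator = if (!is.null(generator)) unclass(generator),
         concordance = as.list(conc)),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(list(cohort = co, preprocessed = pp, features = features,
                 model = model, evaluation = ev, importance = imp,
                 concordance = conc, out_dir = out_dir))
}
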