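#' Single-cell kinase activity time course
#'
#' Constructs a `cell_timecourse`, the package's unit record: one cell's
#' kinase-activity series (cytoplasmic-to-nuclear reporter ratio, C/N) for
#' one or more modalities (e.g. ERK, Akt) on a regular sampling grid,
#' together with its division-fate label and, for divided cells, the
#' division time.
#'
#' All modalities of one cell must have equal length, and C/N values must be
#' finite and strictly positive (they are ratios of fluorescence
#' intensities). A divided cell's series ends at the grid point at or just
#' before its division time, because imaging of the mother cell stops there.
#'
#' @param cell_id Character scalar identifier, unique within a cohort.
#' @param series Named list of numeric vectors, one per modality, equal
#'   lengths, finite and positive.
#' @param sampling_interval Sampling interval in minutes.
#' @param start_h Time (hours) of the first grid point, relative to
#'   treatment at 0 h (e.g. -1 for a 1-h pre-treatment baseline).
#' @param label `"divided"`, `"undivided"`, or `NA` (unlabeled, e.g. before
#'   window-based relabeling).
#' @param division_time Division time in hours, required when
#'   `label == "divided"`, otherwise `NA`.
#' @param metadata Optional named list (condition, replicate, recorded
#'   division events, ...).
#' @return An object of class `cell_timecourse`.
#' @seealso [cohort()], [generate_cohort()]
#' @export
cell_timecourse <- function(cell_id, series, sampling_interval, start_h = -1,
                            label = NA_character_, division_time = NA_real_,
                            metadata = list()) {
  stopifnot(is.character(cell_id), length(cell_id) == 1L,
            is.list(series), length(series) >= 1L, !is.null(names(series)),
            is.numeric(sampling_interval), sampling_interval > 0)
  lens <- vapply(series, length, integer(1))
  if (length(unique(lens)) != 1L)
    stop("all modalities of cell '", cell_id, "' must have equal length")
  for (m in names(series)) {
    v <- series[[m]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)) || any(v <= 0))
      stop("series values of cell '", cell_id, "', modality '", m,
           "' must be finite and > 0")
  }
  if (!is.na(label) && !label %in% c("divided", "undivided"))
    stop("label must be 'divided', 'undivided' or NA")
  if (identical(label, "divided") && is.na(division_time))
    stop("divided cell '", cell_id, "' requires a division_time")
  structure(list(cell_id = cell_id,
                 series = lapply(series, as.numeric),
                 sampling_interval = as.numeric(sampling_interval),
                 start_h = as.numeric(start_h),
                 label = label,
                 division_time = as.numeric(division_time),
                 metadata = metadata),
            class = "cell_timecourse")
}

#' Grid time points (hours) of a cell's series
#'
#' @param cell A `cell_timecourse`.
#' @return Numeric vector of times in hours, one per observed grid point.
#' @export
cell_times <- function(cell) {
  n <- length(cell$series[[1L]])
  cell$start_h + (seq_len(n) - 1L) * cell$sampling_interval / 60
}

#' Retained series length of a cell
#' @param cell A `cell_timecourse`.
#' @return Integer number of observed grid points.
#' @export
cell_length <- function(cell) length(cell$series[[1L]])

#' @export
print.cell_timecourse <- function(x, ...) {
  cat("<cell_timecourse> ", x$cell_id, ": ", cell_length(x), " points x ",
      length(x$series), " modalities (", paste(names(x$series), collapse = ", "),
      "), label = ", ifelse(is.na(x$label), "<NA>", x$label),
      if (!is.na(x$division_time)) paste0(", division at ", x$division_time, " h"),
      "\n", sep = "")
  invisible(x)
}

#' A cohort of single-cell time courses
#'
#' A `cohort` bundles `cell_timecourse` records sharing grid conventions
#' (modalities, sampling interval, grid start, full-length grid size) plus
#' provenance (generator configuration or source-file record). The
#' full-length grid is the length an untruncated series has; divided cells'
#' series are shorter.
#'
#' @param cells List of [cell_timecourse()] objects.
#' @param modalities Character vector of modality names; every cell must
#'   carry exactly these.
#' @param grid_length Full-length grid size in points (e.g. 197 for 49 h at
#'   15-min intervals).
#' @param sampling_interval Minutes between grid points.
#' @param start_h First grid time in hours.
#' @param provenance Named list recording how the cohort was produced.
#' @return An object of class `cohort`.
#' @export
cohort <- function(cells, modalities, grid_length, sampling_interval,
                   start_h = -1, provenance = list()) {
  stopifnot(is.list(cells), length(cells) >= 1L)
  ids <- vapply(cells, function(c) c$cell_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate cell_ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  for (c in cells) {
    if (!identical(names(c$series), as.character(modalities)))
      stop("cell '", c$cell_id, "' modalities do not match cohort modalities")
    if (cell_length(c) > grid_length)
      stop("cell '", c$cell_id, "' longer than grid_length")
  }
  structure(list(cells = cells, modalities = as.character(modalities),
                 grid_length = as.integer(grid_length),
                 sampling_interval = as.numeric(sampling_interval),
                 start_h = as.numeric(start_h),
                 provenance = provenance),
            class = "cohort")
}

#' Cell-fate labels of a cohort
#' @param x A `cohort`.
#' @return Character vector of labels in cell order.
#' @export
cohort_labels <- function(x) vapply(x$cells, function(c) c$label, character(1))

#' Cell identifiers of a cohort
#' @param x A `cohort`.
#' @return Character vector of cell ids in cell order.
#' @export
cohort_ids <- function(x) vapply(x$cells, function(c) c$cell_id, character(1))

#' Retained series lengths of a cohort
#' @param x A `cohort`.
#' @return Integer vector of observed lengths in cell order.
#' @export
cohort_lengths <- function(x) vapply(x$cells, cell_length, integer(1))

#' Subset a cohort by cell index
#' @param x A `cohort`.
#' @param i Integer or logical index over cells.
#' @param ... Ignored.
#' @return A `cohort` containing the selected cells.
#' @export
`[.cohort` <- function(x, i, ...) {
  cohort(x$cells[i], x$modalities, x$grid_length, x$sampling_interval,
         x$start_h, x$provenance)
}

#' @export
length.cohort <- function(x) length(x$cells)

#' @export
print.cohort <- function(x, ...) {
  lb <- cohort_labels(x)
  cat("<cohort> ", length(x$cells), " cells, modalities: ",
      paste(x$modalities, collapse = ", "),
      ", grid ", x$grid_length, " points @ ", x$sampling_interval,
      " min from ", x$start_h, " h\n", sep = "")
  cat("  divided: ", sum(lb == "divided", na.rm = TRUE),
      ", undivided: ", sum(lb == "undivided", na.rm = TRUE),
      ", unlabeled: ", sum(is.na(lb)), "\n", sep = "")
  invisible(x)
}

#' Split a cohort into train and test subsets
#'
#' Randomly partitions cells in a given ratio, the standard design for
#' held-out evaluation (e.g. an 80:20 train/test split). The split is
#' seeded and reproducible; `floor(frac * n)` cells go to the training set.
#'
#' @param x A `cohort`.
#' @param frac Training fraction in (0, 1); default 0.8.
#' @param seed Integer seed.
#' @return List with `cohort` elements `train` and `test`.
#' @export
split_cohort <- function(x, frac = 0.8, seed = 1L) {
  stopifnot(frac > 0, frac < 1)
  n <- length(x$cells)
  set.seed(seed)
  idx <- sample.int(n, floor(frac * n))
  list(train = x[sort(idx)], test = x[sort(setdiff(seq_len(n), idx))])
}
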