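#' Truncate a divided cell's series at its division time
#'
#' Imaging of a mother cell stops at division, so a divided cell's series
#' must end at the last grid point at or before `division_time`. Undivided
#' or unlabeled cells are returned unchanged; the operation is idempotent.
#'
#' @param cell A [cell_timecourse()].
#' @return The cell, truncated if divided.
#' @export
truncate_at_division <- function(cell) {
  stopifnot(inherits(cell, "cell_timecourse"))
  if (!identical(cell$label, "divided")) return(cell)
  if (cell$division_time < max(cell$start_h, 0))
    stop("division_time of '", cell$cell_id,
         "' precedes the end of the pre-treatment baseline")
  t_h <- cell_times(cell)
  keep <- sum(t_h <= cell$division_time + 1e-9)
  if (keep == cell_length(cell)) return(cell)
  cell$series <- lapply(cell$series, function(v) v[seq_len(keep)])
  cell
}

#' Match undivided-cell length distribution to the divided class
#'
#' Divided cells have shorter series (they end at division), so series
#' length alone would let a classifier trivially predict fate. This
#' operation removes that artifact: each undivided cell is truncated to a
#' length drawn, with replacement and seeded, from the empirical
#' distribution of divided-cell lengths, making the two classes' length
#' distributions statistically indistinguishable. Divided cells are
#' unchanged.
#'
#' @param x A [cohort()] whose divided cells are already truncated.
#' @param seed Integer seed for the length draws.
#' @return The cohort with undivided series truncated.
#' @export
match_length_distributions <- function(x, seed = 1L) {
  stopifnot(inherits(x, "cohort"))
  labs <- cohort_labels(x)
  div_idx <- which(labs == "divided")
  if (length(div_idx) == 0L) stop("no divided cells: cannot match lengths")
  div_lens <- vapply(x$cells[div_idx], cell_length, integer(1))
  und_idx <- which(labs == "undivided")
  set.seed(seed)
  draw <- sample(div_lens, length(und_idx), replace = TRUE)
  for (j in seq_along(und_idx)) {
    i <- und_idx[j]
    L <- min(draw[j], cell_length(x$cells[[i]]))
    x$cells[[i]]$series <- lapply(x$cells[[i]]$series,
                                  function(v) v[seq_len(L)])
  }
  x
}

#' Pad a series to a target length with its own mean
#'
#' Appends, to each modality of a truncated cell, the mean of that
#' modality's retained points until the series reaches `target_length`.
#' Padding with the mean leaves the series mean unchanged and adds no
#' spurious frequency content beyond the step at the pad boundary.
#'
#' @param cell A [cell_timecourse()].
#' @param target_length Grid length to pad to; must be >= the retained
#'   length.
#' @return The padded cell.
#' @export
pad_with_mean <- function(cell, target_length) {
  stopifnot(inherits(cell, "cell_timecourse"))
  n <- cell_length(cell)
  if (n > target_length)
    stop("cell '", cell$cell_id, "' is longer (", n,
         ") than target_length (", target_length, ")")
  if (n == target_length) return(cell)
  cell$series <- lapply(cell$series, function(v) {
    c(v, rep(mean(v), target_length - n))
  })
  cell
}

#' Run the full anti-artifact preprocessing pipeline on a cohort
#'
#' Applies, in order: [truncate_at_division()] to every divided cell,
#' [match_length_distributions()] to the undivided class, and
#' [pad_with_mean()] to bring every series back to the full grid length.
#' Records, per cell, the retained length and per-modality padding value,
#' plus the two-sample Kolmogorov-Smirnov statistic between the classes'
#' retained-length distributions (small after matching).
#'
#' @param x A [cohort()] with labeled cells.
#' @param seed Integer seed passed to the length matching.
#' @return A `preprocessed_cohort`: list with elements `cohort` (all series
#'   at `grid_length`), `truncation_record` (named integer vector of
#'   retained lengths), `pad_value_record` (per-cell named list of
#'   per-modality padding values), `length_ks` (KS statistic), `seed`.
#' @export
preprocess_cohort <- function(x, seed = 1L) {
  stopifnot(inherits(x, "cohort"))
  x$cells <- lapply(x$cells, truncate_at_division)
  x <- match_length_distributions(x, seed = seed)
  retained <- vapply(x$cells, cell_length, integer(1))
  names(retained) <- cohort_ids(x)
  pad_vals <- lapply(x$cells, function(c) vapply(c$series, mean, numeric(1)))
  names(pad_vals) <- cohort_ids(x)
  x$cells <- lapply(x$cells, pad_with_mean, target_length = x$grid_length)
  labs <- cohort_labels(x)
  ks <- suppressWarnings(stats::ks.test(retained[labs == "divided"],
                                        retained[labs == "undivided"])$statistic)
  structure(list(cohort = x,
                 truncation_record = retained,
                 pad_value_record = pad_vals,
                 length_ks = unname(ks),
                 seed = as.integer(seed)),
            class = "preprocessed_cohort")
}

#' @export
print.preprocessed_cohort <- function(x, ...) {
  cat("<preprocessed_cohort> grid", x$cohort$grid_length,
      "points; retained lengths", min(x$truncation_record), "-",
      max(x$truncation_record), "; class length KS =",
      signif(x$length_ks, 3), "\n")
  invisible(x)
}

#' Linearly resample a cell's series onto a coarser or finer grid
#'
#' Interpolates each modality at grid points spaced `target_interval`
#' minutes apart, starting at the first observed time and never
#' extrapolating beyond the observed span. Used to bring, e.g., a 10-min
#' FRET course onto the 15-min grid of a KTR-trained model.
#'
#' @param cell A [cell_timecourse()] with at least 2 observed points.
#' @param target_interval Target sampling interval in minutes.
#' @return A resampled [cell_timecourse()].
#' @export
resample_to_grid <- function(cell, target_interval) {
  stopifnot(inherits(cell, "cell_timecourse"), target_interval > 0)
  n <- cell_length(cell)
  if (n < 2L) stop("cell '", cell$cell_id, "' has fewer than 2 points")
  t_src <- cell_times(cell)
  t_new <- seq(t_src[1], t_src[n], by = target_interval / 60)
  cell$series <- lapply(cell$series, function(v) {
    stats::approx(t_src, v, xout = t_new, method = "linear")$y
  })
  cell$sampling_interval <- target_interval
  cell
}

#' Derive a fate label from division events in the last observation window
#'
#' For asynchronously cycling cells whose fate label is not pre-assigned,
#' labels a cell `divided` if any recorded division event falls within the
#' final `window` hours of its course, `undivided` if it has no events, and
#' `excluded` if it divided only before the window (such cells were
#' committed to division before the treatment under study and would
#' confound the analysis).
#'
#' @param cell A [cell_timecourse()] with `metadata$division_events`
#'   (numeric vector of hours, possibly empty).
#' @param window Window length in hours (must not exceed the course span).
#' @return One of `"divided"`, `"undivided"`, `"excluded"`.
#' @export
relabel_last_window <- function(cell, window = 49) {
  stopifnot(inherits(cell, "cell_timecourse"))
  ev <- cell$metadata$division_events
  if (is.null(ev)) stop("cell '", cell$cell_id, "' has no division_events record")
  t_h <- cell_times(cell)
  span <- t_h[length(t_h)] - t_h[1]
  if (window > span + 1e-9) stop("window (", window,
                                 " h) exceeds course span (", span, " h)")
  t_end <- t_h[length(t_h)]
  if (length(ev) == 0L) return("undivided")
  if (any(ev > t_end - window & ev <= t_end + 1e-9)) return("divided")
  "excluded"
}

#' Apply last-window relabeling across a cohort
#'
#' Convenience wrapper over [relabel_last_window()]: labels each cell,
#' drops `excluded` cells, and returns the labeled cohort.
#'
#' @param x A [cohort()] of cells carrying `metadata$division_events`.
#' @param window Window length in hours.
#' @return A labeled [cohort()] with excluded cells removed; the number
#'   excluded is recorded in provenance.
#' @export
relabel_cohort_last_window <- function(x, window = 49) {
  labs <- vapply(x$cells, relabel_last_window, character(1), window = window)
  keep <- labs != "excluded"
  x$cells <- x$cells[keep]
  for (i in seq_along(x$cells)) x$cells[[i]]$label <- labs[keep][i]
  x$provenance$relabel_window_h <- window
  x$provenance$n_excluded <- sum(!keep)
  x
}

#' Pooled location/spread statistics of a reference cohort
#'
#' Computes, per modality, the median and interquartile range of all
#' observed values in a (training) cohort, for use as the target of
#' [rescale_to_reference()].
#'
#' @param x A [cohort()].
#' @return A `reference_stats` object: per-modality list of
#'   `median` and `iqr` (both > 0 required of `iqr`).
#' @export
reference_stats <- function(x) {
  stopifnot(inherits(x, "cohort"))
  out <- lapply(x$modalities, function(m) {
    v <- unlist(lapply(x$cells, function(c) c$series[[m]]), use.names = FALSE)
    s <- list(median = stats::median(v), iqr = stats::IQR(v))
    if (s$iqr <= 0) stop("modality '", m, "' has zero spread")
    s
  })
  names(out) <- x$modalities
  structure(out, class = "reference_stats")
}

#' Affinely rescale a cohort's reporter values to a reference scale
#'
#' Different reporters (e.g. a FRET sensor vs a translocation reporter)
#' read kinase activity on different scales. This maps each modality of
#' `x` through the affine transform that sends its pooled median and IQR
#' onto the reference's, making cross-reporter data as consistent as a
#' robust location/scale match can.
#'
#' @param x A [cohort()] to rescale.
#' @param ref A [reference_stats()] from the training cohort.
#' @return The rescaled cohort; the fitted per-modality `(scale, offset)`
#'   is stored in provenance.
#' @export
rescale_to_reference <- function(x, ref) {
  stopifnot(inherits(x, "cohort"), inherits(ref, "reference_stats"))
  maps <- list()
  for (m in x$modalities) {
    if (is.null(ref[[m]])) stop("reference lacks modality '", m, "'")
    v <- unlist(lapply(x$cells, function(c) c$series[[m]]), use.names = FALSE)
    med <- stats::median(v); iqr <- stats::IQR(v)
    if (iqr <= 0) stop("modality '", m, "' in cohort has zero spread")
    a <- ref[[m]]$iqr / iqr
    b <- ref[[m]]$median - a * med
    maps[[m]] <- c(scale = a, offset = b)
    for (i in seq_along(x$cells))
      x$cells[[i]]$series[[m]] <- a * x$cells[[i]]$series[[m]] + b
  }
  x$provenance$rescale_maps <- maps
  x
}
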