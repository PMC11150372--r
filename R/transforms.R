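#' Specification of a time-course feature transform
#'
#' @param kind One of `"dwt_approx"` (Haar discrete-wavelet approximation
#'   coefficients at `level`), `"dft_amplitude"` (half-spectrum discrete
#'   Fourier amplitudes), `"identity"` (raw grid values), or
#'   `"external_adapter"` (a user-supplied function, e.g. a wrapper around
#'   an installed MiniRocket/tsfresh implementation).
#' @param level Cascade depth for `dwt_approx` (default 3; level-3
#'   coefficients of a 15-min grid summarize ~2-h windows).
#' @param wavelet Wavelet name; only `"haar"` is implemented.
#' @param boundary Extension mode for odd lengths: `"symmetric"`
#'   (half-point edge replication, the common toolkit default), `"zero"`,
#'   or `"periodic"`.
#' @param fn For `external_adapter`: function mapping a numeric series to a
#'   numeric feature vector of fixed length.
#' @return A `transform_spec`.
#' @export
transform_spec <- function(kind = c("dwt_approx", "dft_amplitude",
                                    "identity", "external_adapter"),
                           level = 3L, wavelet = "haar",
                           boundary = c("symmetric", "zero", "periodic"),
                           fn = NULL) {
  kind <- match.arg(kind)
  boundary <- match.arg(boundary)
  if (kind == "dwt_approx") {
    if (level < 1L) stop("level must be >= 1 for dwt_approx")
    if (!identical(wavelet, "haar"))
      stop("only the haar wavelet is implemented")
  }
  if (kind == "external_adapter" && !is.function(fn))
    stop("external_adapter requires a function in `fn`")
  structure(list(kind = kind, level = as.integer(level), wavelet = wavelet,
                 boundary = boundary, fn = fn),
            class = "transform_spec")
}

#' Haar DWT approximation coefficients (analysis cascade)
#'
#' Applies `level` single-level Haar analysis steps, keeping only the
#' approximation (low-pass) branch at each step. The orthonormal Haar
#' low-pass filter replaces each adjacent pair (a, b) by (a + b) / sqrt(2);
#' odd-length inputs are extended by one point according to `boundary`
#' before pairing, so each step halves the length with ceiling. A 197-point
#' course (49 h at 15-min intervals) yields 99, then 50, then 25
#' coefficients at levels 1-3; the level-3 coefficients form a denoised
#' low-frequency summary with one value per ~2-h window.
#'
#' @param x Numeric series, length at least `2^level` effective points.
#' @param level Number of cascade levels (default 3).
#' @param boundary `"symmetric"`, `"zero"`, or `"periodic"` extension for
#'   odd lengths.
#' @return Numeric vector of approximation coefficients, length
#'   `ceiling(length(x) / 2^level)` under repeated ceiling-halving.
#' @examples
#' length(haar_dwt_approx(rnorm(197), level = 3))  # 25
#' @export
haar_dwt_approx <- function(x, level = 3L,
                            boundary = c("symmetric", "zero", "periodic")) {
  boundary <- match.arg(boundary)
  stopifnot(is.numeric(x), level >= 1L)
  if (anyNA(x) || any(!is.finite(x))) stop("non-finite values in series")
  if (length(x) < 2^level)
    stop("series of length ", length(x), " too short for level ", level)
  for (l in seq_len(level)) {
    n <- length(x)
    if (n %% 2L == 1L) {
      ext <- switch(boundary,
                    symmetric = x[n],
                    zero = 0,
                    periodic = x[1])
      x <- c(x, ext)
      n <- n + 1L
    }
    odd <- x[seq(1L, n, by = 2L)]
    even <- x[seq(2L, n, by = 2L)]
    x <- (odd + even) / sqrt(2)
  }
  x
}

#' Discrete Fourier amplitudes (non-redundant half-spectrum)
#'
#' Returns the modulus of the DFT coefficients at indices 0..floor(n/2),
#' the non-redundant half of the spectrum for a real series. The DC
#' amplitude of a constant series c of length n is n * c.
#'
#' @param x Non-empty numeric series.
#' @return Numeric vector of length `floor(length(x) / 2) + 1`.
#' @export
dft_amplitude <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1L)
  if (anyNA(x) || any(!is.finite(x))) stop("non-finite values in series")
  Mod(stats::fft(x))[seq_len(floor(length(x) / 2) + 1L)]
}

#' Extract a per-modality feature matrix from a preprocessed cohort
#'
#' Applies a [transform_spec()] to every padded series and assembles one
#' cells-by-features matrix per modality. Column names encode
#' (modality, transform, index); for DWT features the matrix carries a
#' `time_h` attribute anchoring coefficient i to the center of its input
#' window (width `sampling_interval * 2^level`), so importance scores can
#' be mapped back to time.
#'
#' @param pp A [preprocess_cohort()] result (all series at `grid_length`),
#'   or a [cohort()] whose series all have full grid length.
#' @param spec A [transform_spec()].
#' @return Named list (one element per modality) of `feature_matrix`
#'   objects: numeric matrices with `cell_id` rownames and attributes
#'   `modality`, `spec`, `time_h` (DWT/identity only).
#' @export
transform_cohort <- function(pp, spec = transform_spec()) {
  x <- if (inherits(pp, "preprocessed_cohort")) pp$cohort else pp
  stopifnot(inherits(x, "cohort"), inherits(spec, "transform_spec"))
  if (any(cohort_lengths(x) != x$grid_length))
    stop("all series must be padded to grid_length before transforming")
  tf <- switch(spec$kind,
               dwt_approx = function(v) haar_dwt_approx(v, spec$level, spec$boundary),
               dft_amplitude = dft_amplitude,
               identity = identity,
               external_adapter = spec$fn)
  tag <- switch(spec$kind,
                dwt_approx = paste0("dwt", spec$level),
                dft_amplitude = "dft",
                identity = "raw",
                external_adapter = "ext")
  dt_h <- x$sampling_interval / 60
  out <- lapply(x$modalities, function(m) {
    rows <- lapply(x$cells, function(c) tf(c$series[[m]]))
    p <- unique(vapply(rows, length, integer(1)))
    if (length(p) != 1L) stop("transform produced unequal feature lengths")
    mat <- do.call(rbind, rows)
    if (any(!is.finite(mat))) stop("non-finite feature values produced")
    rownames(mat) <- cohort_ids(x)
    colnames(mat) <- sprintf("%s|%s|c%02d", m, tag, seq_len(p))
    attr(mat, "modality") <- m
    attr(mat, "spec") <- spec
    if (spec$kind == "dwt_approx") {
      # coefficient i summarizes input window ((i-1)*2^L, i*2^L]
      attr(mat, "time_h") <- x$start_h + (seq_len(p) - 0.5) * dt_h * 2^spec$level
    } else if (spec$kind == "identity") {
      attr(mat, "time_h") <- x$start_h + (seq_len(p) - 1L) * dt_h
    }
    class(mat) <- c("feature_matrix", class(mat))
    mat
  })
  names(out) <- x$modalities
  out
}
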