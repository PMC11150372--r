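mk_cell <- function(values, label = "undivided", division_time = NA_real_,
                    interval = 15, start_h = -1, id = "c1", ...) {
  cell_timecourse(id, list(ERK = values), interval, start_h = start_h,
                  label = label, division_time = division_time, ...)
}

test_that("truncation keeps exactly the grid points up to division", {
  full <- exp(rnorm(197, 0, 0.1))
  # division at 40.0 h on a grid from -1 h: (40 + 1) * 4 + 1 = 165 points
  c40 <- truncate_at_division(mk_cell(full, "divided", 40.0))
  expect_equal(cell_length(c40), 165L)
  # division at 47.9 h: last grid point <= 47.9 is 47.75 h -> 196 points
  c479 <- truncate_at_division(mk_cell(full, "divided", 47.9))
  expect_equal(cell_length(c479), 196L)
  # idempotent
  expect_identical(truncate_at_division(c40)$series, c40$series)
  # undivided untouched
  und <- mk_cell(full, "undivided")
  expect_identical(truncate_at_division(und), und)
  # division during the baseline hour is malformed
  expect_error(truncate_at_division(mk_cell(full, "divided", -0.5)),
               "baseline")
})

test_that("length matching equalizes the class length distributions", {
  co <- small_cohort(n = 500, seed = 44)
  co$cells <- lapply(co$cells, truncate_at_division)
  matched <- match_length_distributions(co, seed = 9)
  labs <- cohort_labels(matched)
  lens <- cohort_lengths(matched)
  ks <- suppressWarnings(ks.test(lens[labs == "divided"],
                                 lens[labs == "undivided"]))$statistic
  expect_lte(unname(ks), 0.15)
  # divided cells untouched
  expect_identical(lens[labs == "divided"],
                   cohort_lengths(co)[labs == "divided"])
  # determinism
  again <- match_length_distributions(co, seed = 9)
  expect_identical(cohort_lengths(again), lens)
})

test_that("degenerate divided length distribution truncates all undivided to it", {
  cells <- c(
    lapply(1:3, function(i)
      mk_cell(exp(rnorm(120, 0, 0.1)), "divided", 28.75, id = paste0("d", i))),
    lapply(1:5, function(i)
      mk_cell(exp(rnorm(197, 0, 0.1)), id = paste0("u", i)))
  )
  co <- cohort(cells, "ERK", 197, 15)
  matched <- match_length_distributions(co, seed = 1)
  expect_true(all(cohort_lengths(matched) == 120L))
  co_nodiv <- cohort(cells[4:8], "ERK", 197, 15)
  expect_error(match_length_distributions(co_nodiv), "no divided cells")
})

test_that("mean padding appends the retained mean and preserves it", {
  cell <- mk_cell(c(1, 2, 3))
  padded <- pad_with_mean(cell, 5)
  expect_equal(padded$series$ERK, c(1, 2, 3, 2, 2))
  expect_identical(pad_with_mean(cell, 3), cell)
  expect_error(pad_with_mean(cell, 2), "longer")
  for (s in 1:20) {
    set.seed(s)
    v <- exp(rnorm(sample(10:50, 1)))
    tgt <- length(v) + sample(0:30, 1)
    out <- pad_with_mean(mk_cell(v), tgt)$series$ERK
    expect_equal(mean(out), mean(v), tolerance = 1e-12)
    expect_length(out, tgt)
  }
})

test_that("full preprocessing pads every cell to the grid with its own mean", {
  co <- small_cohort(n = 120, seed = 31)
  pp <- preprocess_cohort(co, seed = 31)
  expect_s3_class(pp, "preprocessed_cohort")
  expect_true(all(cohort_lengths(pp$cohort) == co$grid_length))
  for (id in sample(cohort_ids(co), 5)) {
    i <- which(cohort_ids(co) == id)
    L <- pp$truncation_record[[id]]
    cell <- pp$cohort$cells[[i]]
    for (m in co$modalities) {
      v <- cell$series[[m]]
      expect_equal(unname(pp$pad_value_record[[id]][m]), mean(v[seq_len(L)]))
      if (L < co$grid_length)
        expect_true(all(v[(L + 1):co$grid_length] == mean(v[seq_len(L)])))
    }
  }
  pp2 <- preprocess_cohort(co, seed = 31)
  expect_identical(pp$truncation_record, pp2$truncation_record)
})

test_that("linear resampling hits interior grid points without extrapolating", {
  cell <- mk_cell(c(1, 2, 3), interval = 10, start_h = 0)
  out <- resample_to_grid(cell, 15)
  expect_equal(cell_times(out), c(0, 0.25))
  expect_equal(out$series$ERK, c(1, 2.5))
  # identity when already on the target grid
  cell15 <- mk_cell(c(1, 2, 3, 4), interval = 15, start_h = 0)
  expect_equal(resample_to_grid(cell15, 15)$series$ERK, cell15$series$ERK)
  expect_error(resample_to_grid(mk_cell(c(2, 2)[1], interval = 10), 15),
               "fewer than 2")
})

test_that("resampling error respects the linear-interpolation bound", {
  # sine of period 4 h sampled at 10 min: |f''| max = (2*pi/4)^2, h = 1/6 h
  t_src <- seq(0, 8, by = 10 / 60)
  f <- function(t) 2 + sin(2 * pi * t / 4)
  cell <- mk_cell(f(t_src), interval = 10, start_h = 0)
  out <- resample_to_grid(cell, 15)
  err <- abs(out$series$ERK - f(cell_times(out)))
  bound <- (10 / 60)^2 * (2 * pi / 4)^2 / 8
  expect_lte(max(err), bound + 1e-12)
})

test_that("last-window relabeling follows the division-event record", {
  mk_ev <- function(events) mk_cell(exp(rnorm(577, 0, 0.05)), label = NA,
                                    interval = 10, start_h = 0,
                                    metadata = list(division_events = events))
  expect_equal(relabel_last_window(mk_ev(c(20, 60)), 49), "divided")
  expect_equal(relabel_last_window(mk_ev(c(95)), 49), "divided")
  expect_equal(relabel_last_window(mk_ev(numeric(0)), 49), "undivided")
  expect_equal(relabel_last_window(mk_ev(c(10)), 49), "excluded")
  expect_error(relabel_last_window(mk_ev(c(10)), 200), "span")
})

test_that("cohort-level relabeling drops excluded cells and labels the rest", {
  cfg <- generator_config(n_cells = 80, sampling_interval = 10, duration = 96,
                          baseline_hours = 0, seed = 13)
  co <- generate_rpe_like(cfg)
  lab <- relabel_cohort_last_window(co, window = 49)
  labs <- cohort_labels(lab)
  expect_true(all(labs %in% c("divided", "undivided")))
  expect_equal(length(lab) + lab$provenance$n_excluded, length(co))
  # spot-check agreement with the per-cell rule
  for (cell in lab$cells[1:10]) {
    ev <- cell$metadata$division_events
    expect_equal(cell$label,
                 if (length(ev) > 0 && any(ev > 96 - 49)) "divided" else "undivided")
  }
})

test_that("robust affine rescaling matches reference median and IQR", {
  ref_co <- small_cohort(n = 40, seed = 61)
  ref <- reference_stats(ref_co)
  # affine-shifted copy: values * 2 + 1 must map back with scale 0.5, offset -0.5
  shifted <- ref_co
  shifted$cells <- lapply(shifted$cells, function(c) {
    c$series <- lapply(c$series, function(v) 2 * v + 1); c
  })
  back <- rescale_to_reference(shifted, ref)
  expect_equal(unname(back$provenance$rescale_maps$ERK["scale"]), 0.5,
               tolerance = 1e-9)
  expect_equal(unname(back$provenance$rescale_maps$ERK["offset"]), -0.5,
               tolerance = 1e-9)
  pooled <- unlist(lapply(back$cells, function(c) c$series$ERK))
  expect_equal(median(pooled), ref$ERK$median, tolerance = 1e-9)
  expect_equal(IQR(pooled), ref$ERK$iqr, tolerance = 1e-9)
  # identity when already matching
  same <- rescale_to_reference(ref_co, ref)
  expect_equal(unname(same$provenance$rescale_maps$ERK["scale"]), 1,
               tolerance = 1e-9)
})

test_that("an RPE-like cohort rescales onto a KTR reference scale", {
  ref_co <- small_cohort(n = 60, seed = 71)
  ref <- reference_stats(ref_co)
  cfg <- generator_config(n_cells = 60, sampling_interval = 10, duration = 96,
                          baseline_hours = 0, seed = 72)
  rpe <- generate_rpe_like(cfg, scale = 2, offset = 1)
  rescaled <- rescale_to_reference(rpe, reference_stats(ref_co))
  pooled <- unlist(lapply(rescaled$cells, function(c) c$series$ERK))
  expect_equal(median(pooled), ref$ERK$median, tolerance = 0.02 * ref$ERK$median)
})
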