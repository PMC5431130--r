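mk_trace <- function(v, dt = 3, id = 1)
  ratio_trace(id, "nfkb_nuc_cyt", (seq_along(v) - 1) * dt, v)

test_that("noise level is zero for flat curves and matches a square wave's envelope", {
  flat <- lapply(1:5, function(i) mk_trace(rep(0.8, 40), id = i))
  nm <- estimate_noise_level(flat)
  expect_equal(nm$threshold, 0)
  expect_identical(nm$n_cells, 5L)

  sq <- lapply(1:8, function(i) mk_trace(0.8 + rep(c(0.1, -0.1), 20), id = i))
  expect_equal(estimate_noise_level(sq)$threshold, 0.1)

  single <- estimate_noise_level(list(mk_trace(rep(1, 10))))
  expect_identical(single$n_cells, 1L)
  expect_error(estimate_noise_level(list()), "unstimulated")
})

test_that("peak calling finds pulses above noise and nothing on flat curves", {
  nm <- structure(list(threshold = 0.05), class = "noise_model")
  expect_identical(nrow(detect_peaks(mk_trace(rep(1, 50)), nm)), 0L)

  p <- pulse_train_params(n_pulses = 3, first_peak_time_sd = 0, interval_sd = 0)
  tr <- simulate_nfkb_trace(p, 120, 3)
  pk <- detect_peaks(mk_trace(tr$values), nm)
  expect_identical(nrow(pk), 3L)
  expect_true(all(abs(pk$peak_time - tr$pulses$time) <= 6))
  expect_true(all(pk$height > median(tr$values) + nm$threshold))
  expect_equal(pk$duration, pk$peak_time - pk$initiation_time)
  expect_true(all(pk$initiation_time <= pk$peak_time))
})

test_that("near-coincident maxima merge to the higher one, ties to the earlier", {
  nm <- structure(list(threshold = 0.0), class = "noise_model")
  v <- rep(1, 30)
  v[10] <- 2; v[12] <- 2.4           # two maxima 2 frames apart
  pk <- detect_peaks(mk_trace(v), nm, min_separation_frames = 5, margin = 1)
  expect_identical(nrow(pk), 1L)
  expect_equal(pk$peak_time, 11 * 3)  # frame 12, 0-based time
  v2 <- rep(1, 30)
  v2[10] <- 2; v2[12] <- 2            # exact tie: keep the earlier
  pk2 <- detect_peaks(mk_trace(v2), nm, min_separation_frames = 5, margin = 1)
  expect_equal(pk2$peak_time, 9 * 3)
})

test_that("peak caller matches the exhaustive oracle on fuzzed curves", {
  set.seed(99)
  grid <- seq(0.6, 2.2, by = 0.2)
  for (i in 1:300) {
    n <- sample(5:40, 1)
    v <- sample(grid, n, TRUE)
    thr <- sample(c(0, 0.1, 0.3), 1)
    ms <- sample(2:6, 1)
    pk <- detect_peaks(mk_trace(v), structure(list(threshold = thr),
                                              class = "noise_model"),
                       min_separation_frames = ms, margin = 1.25)
    oracle <- oracle_peak_indices(v, thr, ms, 1.25)
    expect_identical(round(pk$peak_time / 3) + 1, as.numeric(oracle))
  }
})

test_that("raising the noise threshold never increases the peak count", {
  set.seed(7)
  for (i in 1:40) {
    v <- cumsum(rnorm(60, 0, 0.2)) + 1.5
    v <- v - min(v) + 0.5
    counts <- vapply(c(0, 0.05, 0.1, 0.2, 0.4), function(thr)
      nrow(detect_peaks(mk_trace(v), structure(list(threshold = thr),
                                               class = "noise_model"))),
      numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("damping rates are relative height drops, defined only between existing peaks", {
  pk <- data.frame(height = c(2, 1, 0.5))
  expect_equal(unname(compute_damping(pk)), c(0.5, 0.5))
  expect_equal(unname(compute_damping(data.frame(height = c(1.4, 1.4)))), 0)
  expect_equal(unname(compute_damping(data.frame(height = c(1, 1.2)))), -0.2)
  expect_length(compute_damping(data.frame(height = 2)), 0)
  expect_equal(unname(compute_damping(pk, mode = "absolute")), c(1, 0.5))
})

test_that("fold increase is max over baseline, exactly 1 for constant traces", {
  const <- ratio_trace(1, "mcherry_cell_bg", (0:29) * 3, rep(1.3, 30))
  expect_equal(compute_fold_increase(const), 1)
  prof <- simulate_mcherry_profile(reporter_params(fold = 2.1), 170, 3)
  tr <- ratio_trace(1, "mcherry_cell_bg", prof$times, prof$values)
  expect_equal(compute_fold_increase(tr), 2.1, tolerance = 0.03)
  expect_error(compute_fold_increase(ratio_trace(1, "mcherry_cell_bg",
                                                 0:5 * 3, rep(1, 6))),
               "shorter")
})

test_that("per-cell summary assembles peaks, intervals, damping and fold", {
  nm <- structure(list(threshold = 0.05), class = "noise_model")
  p <- pulse_train_params(first_peak_time_mean = 9, first_peak_time_sd = 0,
                          interval_mean = 90, interval_sd = 0, n_pulses = 3)
  tr <- simulate_nfkb_trace(p, 120, 3)
  nf_curve <- mk_trace(tr$values)
  prof <- simulate_mcherry_profile(reporter_params(fold = 1.8), 120, 3)
  mc_curve <- ratio_trace(1, "mcherry_cell_bg", prof$times, prof$values)
  cm <- summarize_cell(nf_curve, mc_curve, nm, "WT")
  expect_identical(cm$n_peaks, 3L)
  expect_equal(cm$intervals, c(90, 90), tolerance = 0.05)
  expect_length(cm$damping, 2)

  # single-peak cell: no intervals, no damping
  p1 <- pulse_train_params(n_pulses = 1, first_peak_time_sd = 0)
  cm1 <- summarize_cell(mk_trace(simulate_nfkb_trace(p1, 120, 3)$values),
                        NULL, nm, "WT")
  expect_identical(cm1$n_peaks, 1L)
  expect_length(cm1$intervals, 0)
  expect_length(cm1$damping, 0)
  expect_true(is.na(cm1$fold_increase))

  # flat cell: nothing called
  cm0 <- summarize_cell(mk_trace(rep(0.8, 120)), const_mc <- ratio_trace(
    1, "mcherry_cell_bg", (0:119) * 3, rep(1, 120)), nm, "DKO")
  expect_identical(cm0$n_peaks, 0L)
  expect_equal(cm0$fold_increase, 1)
  tab <- metrics_table(list(cm, cm1, cm0))
  expect_identical(nrow(tab), 3L)
  expect_true(is.na(tab$damp_12[2]) && is.na(tab$interval_12[3]))
})
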