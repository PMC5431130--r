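test_that("pulse train without pulses is flat at baseline", {
  p <- pulse_train_params(baseline_ratio = 0.9, n_pulses = 0)
  tr <- simulate_nfkb_trace(p, 50, 3)
  expect_equal(tr$values, rep(0.9, 50))
  expect_identical(nrow(tr$pulses), 0L)
})

test_that("pulse heights follow the geometric damping sequence", {
  p <- pulse_train_params(first_peak_amplitude = 1, damping_factor = 0.5,
                          n_pulses = 3, first_peak_time_sd = 0,
                          interval_sd = 0)
  tr <- simulate_nfkb_trace(p, 120, 3, seed = 1)
  expect_equal(tr$pulses$height, c(1, 0.5, 0.25))
  expect_equal(tr$pulses$time, c(33, 123, 213))
  expect_true(all(diff(tr$pulses$time) > 0))
  expect_true(all(tr$values >= p$baseline_ratio))
})

test_that("sampled trace matches the closed-form pulse train on the grid", {
  p <- pulse_train_params(first_peak_time_mean = 9, first_peak_time_sd = 2,
                          interval_mean = 90, pulse_width_sd = 8,
                          n_pulses = 3)
  tr <- simulate_nfkb_trace(p, 100, 3, seed = 42)
  ref <- oracle_pulse_train(tr$times, p$baseline_ratio,
                            p$first_peak_amplitude, p$damping_factor,
                            tr$pulses$time, p$pulse_width_sd)
  expect_equal(tr$values, ref, tolerance = 1e-12)
  expect_lt(abs(tr$times[which.max(tr$values)] - tr$pulses$time[1]), 3)
})

test_that("invalid pulse parameters are rejected", {
  expect_error(pulse_train_params(first_peak_amplitude = -1), "amplitude")
  expect_error(pulse_train_params(pulse_width_sd = 0), "pulse_width_sd")
  expect_error(pulse_train_params(first_peak_time_sd = -2), "deviations")
  expect_error(pulse_train_params(damping_factor = 1.7), "damping_factor")
})

test_that("reporter profile is 1 at t=0, peaks at fold near peak_time, and rises monotonically", {
  flat <- simulate_mcherry_profile(reporter_params(fold = 1), 100, 3)
  expect_equal(flat$values, rep(1, 100))

  rp <- reporter_params(fold = 2.1, peak_time = 450)
  mc <- simulate_mcherry_profile(rp, 300, 3)
  expect_equal(mc$values[1], 1, tolerance = 0.01)
  expect_equal(max(mc$values), 2.1, tolerance = 0.01)
  expect_lte(abs(mc$times[which.max(mc$values)] - 450), 3)
  pre <- mc$values[mc$times <= 450]
  expect_true(all(diff(pre) >= -1e-12))

  expect_error(reporter_params(fold = 0.5), "fold")
})

test_that("DKO preset yields no pulses and unit folds", {
  opt <- optics_params(image_size = 150, n_frames = 20)
  coh <- generate_cohort("DKO", 5, opt, seed = 9)
  expect_identical(nrow(coh$truth$pulses), 0L)
  expect_true(all(coh$truth$cells$fold == 1))
  expect_true(all(coh$truth$cells$n_pulses == 0))
})

test_that("WT preset reproduces its target pulse-count and interval structure", {
  # ground-truth level: 250 cells drawn at trace scale only
  opt <- optics_params(image_size = 512, n_frames = 2)
  pre <- genotype_preset("WT")
  set.seed(303)
  counts <- sample(pre$n_pulses_values, 250, TRUE, pre$n_pulses_probs)
  expect_identical(median(counts), 3)

  gaps <- c()
  for (s in 1:250) {
    p <- pulse_train_params(n_pulses = 4)
    tr <- simulate_nfkb_trace(p, 2, 3, seed = 7000 + s)
    gaps <- c(gaps, diff(tr$pulses$time))
  }
  expect_lt(abs(mean(gaps) - 90), 5)
})

test_that("cohort generation is reproducible and records every drawn parameter", {
  opt <- optics_params(image_size = 150, n_frames = 10)
  a <- generate_cohort("WT", 4, opt, seed = 5)
  b <- generate_cohort("WT", 4, opt, seed = 5)
  expect_identical(a$movie$data, b$movie$data)
  expect_identical(a$truth$cells, b$truth$cells)
  expect_true(all(c("baseline_ratio", "first_peak_amplitude",
                    "damping_factor", "pulse_width_sd", "n_pulses", "fold")
                  %in% names(a$truth$cells)))
  # pulse times strictly increasing within every cell
  for (cid in unique(a$truth$pulses$cell_id))
    expect_true(all(diff(a$truth$pulses$time[a$truth$pulses$cell_id == cid]) > 0))
  expect_error(generate_cohort("XX", 4, opt, seed = 5))
  expect_error(generate_cohort("WT", 5000, opt, seed = 5), "layout")
})
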