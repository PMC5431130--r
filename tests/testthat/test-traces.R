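test_that("noiseless extraction reproduces the simulated ratio traces pointwise", {
  fx <- noiseless_cohort()
  for (r in seq_len(nrow(fx$match))) {
    key <- fx$match$key[r]; gi <- fx$match$truth_row[r]
    nf_err <- abs(fx$traces$nfkb_raw[[key]]$values - fx$truth$nfkb_traces[, gi]) /
      fx$truth$nfkb_traces[, gi]
    mc_err <- abs(fx$traces$mcherry[[key]]$values - fx$truth$mcherry_traces[, gi]) /
      fx$truth$mcherry_traces[, gi]
    expect_lt(max(nf_err), 0.02)
    expect_lt(max(mc_err), 0.02)
  }
})

test_that("a uniform cell gives a Nuc/Cyt ratio of exactly 1", {
  nf <- 3
  opt <- optics_params(image_size = 96, n_frames = nf, psf_sigma = 0,
                       shot_noise = FALSE, read_noise_sd = 0)
  cells <- list(list(cell_id = 1, center = c(47, 47), radius = 11,
                     nucleus_center = c(47, 47), nucleus_radius = 5,
                     nfkb_trace = rep(1, nf), mcherry_trace = rep(1, nf)))
  mv <- render_movie(cells, opt)
  masks <- segment_movie(mv)
  tk <- track_cells(masks)
  tr <- extract_nfkb_raw(mv, tk$tracks[[1]], masks,
                         list(center = c(47, 47), radius = 5))
  expect_equal(tr$values, rep(1, nf))
  mc <- extract_mcherry(mv, tk$tracks[[1]], masks)
  expect_equal(mc$values, rep(1, nf), tolerance = 1e-12)
})

test_that("noiseless responder recovers its reporter fold at the peak", {
  nf <- 170
  opt <- optics_params(image_size = 96, n_frames = nf, psf_sigma = 0,
                       shot_noise = FALSE, read_noise_sd = 0)
  prof <- simulate_mcherry_profile(reporter_params(fold = 2.1), nf, 3)
  cells <- list(list(cell_id = 1, center = c(47, 47), radius = 11,
                     nucleus_center = c(47, 47), nucleus_radius = 5,
                     nfkb_trace = rep(0.8, nf), mcherry_trace = prof$values))
  mv <- render_movie(cells, opt)
  masks <- segment_movie(mv)
  tk <- track_cells(masks)
  mc <- extract_mcherry(mv, tk$tracks[[1]], masks)
  expect_equal(max(mc$values) / mc$values[1], 2.1, tolerance = 0.03)
})

test_that("sliding smoothing averages with edge truncation", {
  tr <- ratio_trace(1, "nfkb_nuc_cyt", (0:4) * 3, c(0, 0, 10, 0, 0) + 1)
  sm <- smooth_trace(tr, window_frames = 10)
  expect_equal(sm$values, rep(3, 5))  # window spans the whole 5-point trace
  expect_true(sm$smoothed)

  const <- ratio_trace(1, "nfkb_nuc_cyt", (0:9) * 3, rep(2.5, 10))
  expect_equal(smooth_trace(const, 10)$values, rep(2.5, 10))
  ident <- ratio_trace(1, "nfkb_nuc_cyt", (0:9) * 3, runif(10) + 1)
  expect_equal(smooth_trace(ident, 1)$values, ident$values)
  expect_error(smooth_trace(ident, 0), "window")
})

test_that("smoothing is mean-preserving in the interior and never raises the max", {
  set.seed(20)
  for (i in 1:10) {
    v <- runif(60, 0.5, 3)
    tr <- ratio_trace(1, "nfkb_nuc_cyt", (0:59) * 3, v)
    sm <- smooth_trace(tr, 10)
    expect_lte(max(sm$values), max(v) + 1e-12)
    # interior point = plain mean of its window (left 4, right 5)
    i0 <- 30
    expect_equal(sm$values[i0], mean(v[(i0 - 4):(i0 + 5)]))
  }
  # block mode averages disjoint ten-frame blocks
  v <- rep(c(1, 3), each = 10)
  sm <- smooth_trace(ratio_trace(1, "nfkb_nuc_cyt", (0:19) * 3, v),
                     10, mode = "block")
  expect_equal(sm$values, rep(c(1, 3), each = 10))
})

test_that("empty cytosol and confluent frames raise extraction errors", {
  nf <- 3
  opt <- optics_params(image_size = 64, n_frames = nf, psf_sigma = 0,
                       shot_noise = FALSE, read_noise_sd = 0)
  cells <- list(list(cell_id = 1, center = c(31, 31), radius = 10,
                     nucleus_center = c(31, 31), nucleus_radius = 5,
                     nfkb_trace = rep(0.8, nf), mcherry_trace = rep(1, nf)))
  mv <- render_movie(cells, opt)
  masks <- segment_movie(mv)
  tk <- track_cells(masks)
  expect_error(extract_nfkb_raw(mv, tk$tracks[[1]], masks,
                                list(center = c(31, 31), radius = 40)),
               "cytosolic")
  # background comes up empty when every pixel is claimed by the dilated mask
  full <- list(matrix(1L, 64, 64))
  tk1 <- tk$tracks[[1]]
  tk1$frames <- 1L; tk1$labels <- 1L
  expect_error(extract_mcherry(mv, tk1, full), "background|confluent")
})
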