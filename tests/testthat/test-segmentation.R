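test_that("blank frames segment to an empty mask", {
  bf <- matrix(1000, 64, 64)
  eg <- matrix(100, 64, 64)
  expect_true(all(segment_frame(bf, eg) == 0))
  # noisy but cell-free frame
  set.seed(1)
  expect_true(all(segment_frame(bf + rnorm(64 * 64, 0, 3),
                                matrix(rpois(64 * 64, 100), 64, 64)) == 0))
})

test_that("isolated rendered cells give one label each with high overlap", {
  fx <- noiseless_cohort()
  m <- fx$masks[[1]]
  expect_identical(max(m), nrow(fx$truth$cells))
  h <- nrow(m)
  for (gi in seq_len(nrow(fx$truth$cells))) {
    true_px <- nfkbtrace:::disk_pixels(fx$truth$cells$cx[gi],
                                       fx$truth$cells$cy[gi],
                                       fx$truth$cells$radius[gi], h, h)
    ious <- vapply(seq_len(max(m)), function(L) {
      px <- which(m == L)
      length(intersect(px, true_px)) / length(union(px, true_px))
    }, numeric(1))
    expect_gte(max(ious), 0.8)
  }
})

test_that("stationary cells yield one full-length track each, without identity swaps", {
  fx <- noiseless_cohort()
  nf <- dim(fx$movie$data)[4]
  expect_identical(length(fx$tracking$tracks), nrow(fx$truth$cells))
  for (tr in fx$tracking$tracks) {
    expect_identical(tr$frames, seq_len(nf))
    drift <- max(abs(tr$centroids[, 1] - tr$centroids[1, 1]),
                 abs(tr$centroids[, 2] - tr$centroids[1, 2]))
    expect_lt(drift, 2)
  }
})

test_that("a cell vanishing mid-movie is marked lost", {
  nf <- 20
  opt <- optics_params(image_size = 96, n_frames = nf, psf_sigma = 0,
                       shot_noise = FALSE, read_noise_sd = 0)
  cells <- list(list(cell_id = 1, center = c(47, 47), radius = 10,
                     nucleus_center = c(47, 47), nucleus_radius = 5,
                     nfkb_trace = rep(0.8, nf), mcherry_trace = rep(1, nf)))
  mv <- render_movie(cells, opt)
  # blank the cell out of the second half of the movie
  mv$data[, , , 11:nf] <- opt$background_offset
  mv$data[, , 3, 11:nf] <- opt$bf_level
  masks <- segment_movie(mv)
  ex <- apply_exclusions(track_cells(masks), masks)
  expect_identical(ex$exclusion_reason, "lost")
})

test_that("nucleus is located on the EGFP-dark spot of a resting cell", {
  fx <- noiseless_cohort()
  for (r in seq_len(nrow(fx$match))) {
    key <- fx$match$key[r]; gi <- fx$match$truth_row[r]
    err <- sqrt(sum((fx$traces$nuclei[[key]]$center -
                     c(fx$truth$cells$nucleus_cx[gi],
                       fx$truth$cells$nucleus_cy[gi]))^2))
    expect_lte(err, 2)
  }
})

test_that("degenerate nucleus placements are handled", {
  nf <- 4
  opt <- optics_params(image_size = 96, n_frames = nf, psf_sigma = 0,
                       shot_noise = FALSE, read_noise_sd = 0)
  # uniform EGFP over the cell: any interior centre is acceptable
  cells <- list(list(cell_id = 1, center = c(47, 47), radius = 11,
                     nucleus_center = c(47, 47), nucleus_radius = 5,
                     nfkb_trace = rep(1, nf), mcherry_trace = rep(1, nf)))
  mv <- render_movie(cells, opt)
  masks <- segment_movie(mv)
  tk <- track_cells(masks)
  nuc <- locate_nucleus(mv, tk$tracks[[1]], masks, diameter = 10)
  expect_false(is.null(nuc))
  d <- sqrt(sum((nuc$center - c(47, 47))^2))
  expect_lt(d, 11 - 5)  # circle inside the cell disk
  # a circle as large as the cell cannot be placed
  expect_null(locate_nucleus(mv, tk$tracks[[1]], masks, diameter = 24))
})

test_that("touching and dividing cells are excluded with the correct reason", {
  opt <- optics_params(image_size = 96, n_frames = 40)
  mv <- render_movie(synthetic_touching_pair(opt), opt, seed = 5)
  masks <- segment_movie(mv)
  ex <- apply_exclusions(track_cells(masks), masks)
  expect_true(all(!ex$included))
  expect_true(all(ex$exclusion_reason == "touching"))

  mv2 <- render_movie(synthetic_dividing_cell(opt), opt, seed = 6)
  m2 <- segment_movie(mv2)
  ex2 <- apply_exclusions(track_cells(m2), m2)
  expect_true(all(!ex2$included))
  expect_true(all(ex2$exclusion_reason == "dividing"))
})

test_that("border contact excludes a cell; isolated interior cells stay included", {
  nf <- 10
  opt <- optics_params(image_size = 96, n_frames = nf)
  cells <- list(
    list(cell_id = 1, center = c(10, 30), radius = 10,
         nucleus_center = c(10, 30), nucleus_radius = 5,
         nfkb_trace = rep(0.8, nf), mcherry_trace = rep(1, nf)),
    list(cell_id = 2, center = c(60, 60), radius = 10,
         nucleus_center = c(60, 60), nucleus_radius = 5,
         nfkb_trace = rep(0.8, nf), mcherry_trace = rep(1, nf)))
  mv <- render_movie(cells, opt, seed = 8)
  masks <- segment_movie(mv)
  tk <- track_cells(masks)
  ex <- apply_exclusions(tk, masks)
  by_x <- order(vapply(tk$tracks, function(tr) tr$centroids[1, 1], numeric(1)))
  expect_identical(ex$exclusion_reason[by_x], c("border", "none"))
})

test_that("exclusion is monotone: adding a touching neighbour never re-includes a cell", {
  nf <- 30
  opt <- optics_params(image_size = 160, n_frames = nf)
  mk_cell <- function(id, x, y, drift = NULL) {
    c(list(cell_id = id, center = c(x, y), radius = 10,
           nucleus_center = c(x, y), nucleus_radius = 5,
           nfkb_trace = rep(0.8, nf), mcherry_trace = rep(1, nf)),
      if (!is.null(drift)) list(drift = drift))
  }
  status_at <- function(cells, centers) {
    mv <- render_movie(cells, opt, seed = 4)
    masks <- segment_movie(mv)
    tk <- track_cells(masks)
    ex <- apply_exclusions(tk, masks)
    vapply(seq_len(nrow(centers)), function(i) {
      d <- vapply(tk$tracks, function(tr)
        sum((tr$centroids[1, ] - centers[i, ])^2), numeric(1))
      ex$included[which.min(d)]
    }, logical(1))
  }
  # scene A: one interior cell (included) and one border cell (excluded)
  a_cells <- list(mk_cell(1, 80, 80), mk_cell(2, 10, 40))
  centers <- rbind(c(80, 80), c(10, 40))
  st_a <- status_at(a_cells, centers)
  expect_identical(st_a, c(TRUE, FALSE))
  # scene B: a neighbour drifts into the interior cell
  drift <- cbind(-pmin((seq_len(nf) - 1) * 1.0, 26), 0)
  b_cells <- c(a_cells, list(mk_cell(3, 128, 80, drift = drift)))
  st_b <- status_at(b_cells, centers)
  # every cell excluded in A stays excluded in B; the contacted cell flips out
  expect_false(st_b[2])
  expect_false(st_b[1])
})
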