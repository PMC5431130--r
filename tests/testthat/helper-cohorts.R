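# Shared rendered fixtures, built once per test run and memoised. Sizes are
# chosen so the whole suite stays well inside a desktop run: 240-384 px
# frames, 3-min intervals, 150-180 frames (450-540 min of imaging).

.cohort_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .cohort_cache)) {
    assign(key, builder(), envir = .cohort_cache)
  }
  get(key, envir = .cohort_cache)
}

# match each extracted cell to its ground-truth record by first centroid
match_truth <- function(tracking, trx, truth) {
  keys <- names(trx$nfkb)
  gi <- vapply(keys, function(key) {
    ctr <- tracking$tracks[[as.integer(key)]]$centroids[1, ]
    which.min((truth$cells$cx - ctr[1])^2 + (truth$cells$cy - ctr[2])^2)
  }, integer(1))
  data.frame(key = keys, truth_row = gi, stringsAsFactors = FALSE)
}

# segment/track/exclude/extract one rendered cohort
process_cohort <- function(coh, nucleus_diameter = 10, window_frames = 10) {
  masks <- segment_movie(coh$movie)
  tracking <- track_cells(masks)
  excl <- apply_exclusions(tracking, masks)
  trx <- extract_traces(coh$movie, tracking, masks, excl,
                        nucleus_diameter = nucleus_diameter,
                        window_frames = window_frames)
  # only the first mask frame is needed downstream (IoU checks); dropping
  # the rest keeps the memoised fixtures small
  list(masks = masks[1], tracking = tracking, exclusions = excl, traces = trx,
       match = match_truth(tracking, trx, coh$truth))
}

# small noiseless cohort for exact round-trip checks
noiseless_cohort <- function() memo("noiseless", function() {
  opt <- optics_params(image_size = 150, n_frames = 60, psf_sigma = 0,
                       shot_noise = FALSE, read_noise_sd = 0)
  coh <- generate_cohort("WT", 6, opt, seed = 71)
  c(coh, process_cohort(coh, window_frames = 1))
})

# default-noise WT recovery cohort: 200 cells over two rendered movies,
# plus an unstimulated cohort for the noise model
recovery_fixture <- function() memo("recovery", function() {
  opt <- optics_params(image_size = 384, n_frames = 180)
  cohs <- lapply(1:2, function(k) generate_cohort("WT", 100, opt, seed = 500 + k))
  procs <- lapply(cohs, process_cohort)
  for (k in seq_along(cohs)) cohs[[k]]$movie <- NULL  # truth is all that is used
  unstim <- generate_cohort("UNSTIM", 20, optics_params(image_size = 240,
                                                        n_frames = 180),
                            seed = 599)
  punstim <- process_cohort(unstim)
  noise <- estimate_noise_level(punstim$traces$nfkb)
  list(cohorts = cohs, procs = procs, noise = noise)
})

# full four-genotype experiment at n = 30 per group
endtoend_fixture <- function() memo("endtoend", function() {
  cfg <- run_config(simulate = list(genotypes = c("WT", "TKO", "MKO", "DKO"),
                                    n_per_group = 30, n_unstimulated = 20,
                                    optics = optics_params(image_size = 288,
                                                           n_frames = 180)),
                    seed = 2026)
  suppressMessages(run_experiment(cfg))
})

# per-cell recovery table for the recovery fixture: called vs true peak
# counts/times, damping and fold
recovery_table <- function(fix) {
  rows <- list()
  for (k in seq_along(fix$procs)) {
    coh <- fix$cohorts[[k]]
    pr <- fix$procs[[k]]
    t_max <- max(coh$truth$times)
    for (r in seq_len(nrow(pr$match))) {
      key <- pr$match$key[r]
      gi <- pr$match$truth_row[r]
      cid <- coh$truth$cells$cell_id[gi]
      tp <- coh$truth$pulses[coh$truth$pulses$cell_id == cid, ]
      tp <- tp[tp$time <= t_max - 10, , drop = FALSE]  # visible pulses only
      pk <- detect_peaks(pr$traces$nfkb[[key]], fix$noise)
      dt_match <- rep(NA_real_, nrow(tp))
      if (nrow(tp) && nrow(pk)) {
        for (i in seq_len(nrow(tp))) {
          d <- abs(pk$peak_time - tp$time[i])
          if (min(d) <= 15) dt_match[i] <- min(d)
        }
      }
      true_damp <- if (nrow(tp) >= 2) (tp$value[1] - tp$value[2]) / tp$value[1]
                   else NA_real_
      called_damp <- if (nrow(pk) >= 2)
        (pk$height[1] - pk$height[2]) / pk$height[1] else NA_real_
      fold <- compute_fold_increase(pr$traces$mcherry[[key]])
      rows[[paste(k, key)]] <- data.frame(
        n_true = nrow(tp), n_called = nrow(pk),
        mean_dt = if (all(is.na(dt_match))) NA_real_ else
          mean(dt_match, na.rm = TRUE),
        matched = sum(!is.na(dt_match)),
        true_damp = true_damp, called_damp = called_damp,
        true_fold = coh$truth$cells$fold[gi], called_fold = fold)
    }
  }
  do.call(rbind, rows)
}
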