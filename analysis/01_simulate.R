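#!/usr/bin/env Rscript
# Stage 1: simulate the study's five cohorts (WT, TKO, MKO, DKO and an
# unstimulated noise-reference cohort), 30 cells each, 288 x 288 px frames
# every 3 min for 540 min. Movies are written as 16-bit multi-page TIFFs
# under scratch/movies/ (large, regenerable); ground truth goes to
# results/ground_truth/ as JSON.

suppressMessages(library(nfkbtrace))

seed <- 1L
out_movies <- "scratch/movies"
out_truth <- "results/ground_truth"
dir.create(out_movies, recursive = TRUE, showWarnings = FALSE)
dir.create(out_truth, recursive = TRUE, showWarnings = FALSE)

optics <- optics_params(image_size = 288, n_frames = 180)
cohorts <- c("UNSTIM", "WT", "TKO", "MKO", "DKO")

for (k in seq_along(cohorts)) {
  gt <- cohorts[k]
  n <- if (gt == "UNSTIM") 20 else 30
  message("simulating ", gt, " (n = ", n, ") ...")
  coh <- generate_cohort(gt, n, optics, seed = seed * 101 + k)
  write_movie(coh$movie, file.path(out_movies, gt))
  jsonlite::write_json(
    list(cells = coh$truth$cells, pulses = coh$truth$pulses,
         times = coh$truth$times, label = gt, seed = coh$truth$seed),
    file.path(out_truth, paste0(gt, ".json")), digits = NA, auto_unbox = TRUE)
  message("  ", nrow(coh$truth$cells), " cells, ",
          nrow(coh$truth$pulses), " true pulses")
}
message("done: movies in ", out_movies, ", ground truth in ", out_truth)
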