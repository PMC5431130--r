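# Noise-thresholded peak calling and the per-cell oscillation metric panel.

#' Estimate the peak-calling noise level from unstimulated cells
#'
#' Per unstimulated cell, the baseline is the median of its (smoothed)
#' Nuc/Cyt curve; the cell's fluctuation envelope is the maximum absolute
#' deviation from that baseline. The noise threshold is the `percentile`-th
#' percentile of these per-cell envelopes, i.e. an estimate of how far a
#' non-translocating cell's curve ever strays from baseline. Flat curves
#' give a threshold of exactly 0.
#'
#' @param unstimulated_curves non-empty list of `ratio_trace` objects.
#' @param percentile percentile of per-cell maximum deviations (default 95).
#' @return an object of class `noise_model`: `threshold`,
#'   `baseline_estimator` (`"median"`), `percentile`, `n_cells`.
#' @export
estimate_noise_level <- function(unstimulated_curves, percentile = 95) {
  if (!length(unstimulated_curves))
    stop("at least one unstimulated curve is required")
  envelopes <- vapply(unstimulated_curves, function(tr) {
    v <- tr$values
    max(abs(v - stats::median(v)))
  }, numeric(1))
  structure(list(threshold = unname(stats::quantile(envelopes, percentile / 100)),
                 baseline_estimator = "median",
                 percentile = percentile,
                 n_cells = length(unstimulated_curves)),
            class = "noise_model")
}

#' Call NF-kB translocation peaks above the noise level
#'
#' Local maxima of the smoothed curve are clustered transitively when closer
#' than `min_separation_frames`; each cluster keeps its highest maximum
#' (ties towards the earlier frame). A representative is a peak when its
#' value exceeds `baseline + margin * threshold`, where the baseline is the
#' curve's median and the threshold comes from the [estimate_noise_level()]
#' model (`margin`, default 1.25, keeps fluctuations of the same magnitude
#' as unstimulated cells from being called). Clustering precedes
#' thresholding so that raising the threshold can never increase the number
#' of called peaks. Each peak's initiation time is the latest upward
#' crossing of the detection level at or before the peak (linearly
#' interpolated between frames); duration = peak time - initiation time.
#'
#' @param curve a smoothed `ratio_trace` (Nuc/Cyt).
#' @param noise a `noise_model`.
#' @param min_separation_frames merge window in frames (default 5 = 15 min).
#' @param margin multiplicative safety factor on the threshold.
#' @return data.frame of peaks ordered by time: `index`, `initiation_time`,
#'   `peak_time`, `height` (ratio value at the maximum), `duration`
#'   (minutes). Zero rows when no peaks (e.g. a flat curve).
#' @export
detect_peaks <- function(curve, noise, min_separation_frames = 5,
                         margin = 1.25) {
  v <- curve$values
  t <- curve$times
  n <- length(v)
  empty <- data.frame(index = integer(0), initiation_time = numeric(0),
                      peak_time = numeric(0), height = numeric(0),
                      duration = numeric(0))
  if (n < 3) return(empty)
  cand <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  if (!length(cand)) return(empty)
  # transitive clustering by frame distance, then one representative each
  cl <- cumsum(c(1L, diff(cand) >= min_separation_frames))
  reps <- vapply(split(cand, cl), function(idx)
    idx[which.max(v[idx])], integer(1))  # which.max ties -> earlier
  baseline <- stats::median(v)
  level <- baseline + margin * noise$threshold
  reps <- sort(unname(reps[v[reps] > level]))
  if (!length(reps)) return(empty)
  init <- vapply(reps, function(p) {
    up <- which(v[seq_len(p)[-1]] >= level & v[seq_len(p - 1)] < level)
    if (!length(up)) return(t[1])
    j <- max(up) + 1L  # crossing between j-1 and j
    t[j - 1] + (level - v[j - 1]) / (v[j] - v[j - 1]) * (t[j] - t[j - 1])
  }, numeric(1))
  data.frame(index = seq_along(reps),
             initiation_time = init,
             peak_time = t[reps],
             height = v[reps],
             duration = t[reps] - init)
}

#' Damping rates between successive translocation peaks
#'
#' `rate(k -> k+1) = (h_k - h_{k+1}) / h_k` by default (relative decrease);
#' `mode = "absolute"` returns `h_k - h_{k+1}`. Defined only when both peaks
#' exist (fewer than two peaks gives a zero-length result, not zeros);
#' negative rates mean the later peak is higher.
#'
#' @param peaks data.frame from [detect_peaks()] (or any with a `height`
#'   column of positive values).
#' @param mode `"relative"` (default) or `"absolute"`.
#' @return named numeric vector (`damp_12`, `damp_23`, ...).
#' @export
compute_damping <- function(peaks, mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  h <- peaks$height
  if (length(h) < 2) return(stats::setNames(numeric(0), character(0)))
  stopifnot(all(h > 0))
  k <- seq_len(length(h) - 1)
  drop <- h[k] - h[k + 1]
  out <- if (mode == "relative") drop / h[k] else drop
  stats::setNames(out, paste0("damp_", k, k + 1))
}

#' Fold increase of the mCherry reporter
#'
#' Maximum of the Cell/BG curve divided by its mean over the first
#' `baseline_frames` frames; a constant curve gives exactly 1 (no increase).
#'
#' @param mcherry a `ratio_trace` of kind `mcherry_cell_bg`.
#' @param baseline_frames frames defining the pre-induction baseline
#'   (default 10).
#' @return dimensionless fold increase.
#' @export
compute_fold_increase <- function(mcherry, baseline_frames = 10) {
  v <- mcherry$values
  if (length(v) <= baseline_frames)
    stop("trace shorter than the baseline window")
  base <- mean(v[seq_len(baseline_frames)])
  if (base <= 0) stop("non-positive mCherry baseline")
  max(v) / base
}

#' Full per-cell metric panel
#'
#' Calls peaks on the NF-kB curve and assembles the metrics reported per
#' cell: peak list, peak count, intervals between successive peak times,
#' damping rates, and the mCherry fold increase.
#'
#' @param nfkb_curve smoothed Nuc/Cyt `ratio_trace`.
#' @param mcherry_curve Cell/BG `ratio_trace` (or `NULL`).
#' @param noise a `noise_model`.
#' @param genotype label attached to the cell.
#' @param min_separation_frames,margin passed to [detect_peaks()].
#' @param damping_mode passed to [compute_damping()].
#' @param baseline_frames passed to [compute_fold_increase()].
#' @return an object of class `cell_metrics`: `cell_id`, `genotype`,
#'   `peaks`, `n_peaks`, `intervals` (minutes), `damping`, `fold_increase`
#'   (NA when no mCherry curve given).
#' @export
summarize_cell <- function(nfkb_curve, mcherry_curve, noise, genotype,
                           min_separation_frames = 5, margin = 1.25,
                           damping_mode = "relative", baseline_frames = 10) {
  if (!is.null(mcherry_curve) &&
      !identical(nfkb_curve$cell_id, mcherry_curve$cell_id))
    stop("curves belong to different cells")
  peaks <- detect_peaks(nfkb_curve, noise, min_separation_frames, margin)
  structure(list(cell_id = nfkb_curve$cell_id,
                 genotype = genotype,
                 peaks = peaks,
                 n_peaks = nrow(peaks),
                 intervals = if (nrow(peaks) >= 2) diff(peaks$peak_time)
                             else numeric(0),
                 damping = compute_damping(peaks, damping_mode),
                 fold_increase = if (is.null(mcherry_curve)) NA_real_ else
                   compute_fold_increase(mcherry_curve, baseline_frames)),
            class = "cell_metrics")
}

#' Flatten cell metrics into the wide per-cell table
#'
#' One row per cell: genotype, peak count, first-peak initiation time,
#' peak times and heights of the first three peaks, first-peak duration,
#' the first two inter-peak intervals, the two damping rates, and the
#' reporter fold increase. Metrics whose defining peaks are absent are NA.
#'
#' @param metrics_list list of `cell_metrics`.
#' @return data.frame, one row per cell.
#' @export
metrics_table <- function(metrics_list) {
  pick <- function(x, i) if (length(x) >= i) x[[i]] else NA_real_
  rows <- lapply(metrics_list, function(m) {
    p <- m$peaks
    data.frame(cell_id = m$cell_id, genotype = m$genotype,
               n_peaks = m$n_peaks,
               t_init_1 = pick(p$initiation_time, 1),
               t_peak_1 = pick(p$peak_time, 1),
               t_peak_2 = pick(p$peak_time, 2),
               t_peak_3 = pick(p$peak_time, 3),
               h_1 = pick(p$height, 1),
               h_2 = pick(p$height, 2),
               h_3 = pick(p$height, 3),
               duration_1 = pick(p$duration, 1),
               interval_12 = pick(m$intervals, 1),
               interval_23 = pick(m$intervals, 2),
               damp_12 = pick(m$damping, 1),
               damp_23 = pick(m$damping, 2),
               fold = m$fold_increase,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
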