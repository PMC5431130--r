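# Per-cell ratio time series: Nuc/Cyt EGFP and Cell/BG mCherry.

#' Ratio trace container
#'
#' @param cell_id integer id.
#' @param kind `"nfkb_nuc_cyt"` or `"mcherry_cell_bg"`.
#' @param times minutes post-stimulation (frame index times frame interval).
#' @param values dimensionless ratios (finite, > 0).
#' @param smoothed logical flag.
#' @param window_frames averaging window used, if smoothed.
#' @return an object of class `ratio_trace`.
#' @export
ratio_trace <- function(cell_id, kind, times, values,
                        smoothed = FALSE, window_frames = NA_integer_) {
  stopifnot(length(times) == length(values))
  kind <- match.arg(kind, c("nfkb_nuc_cyt", "mcherry_cell_bg"))
  if (any(!is.finite(values)))
    stop("ratio trace contains non-finite values")
  structure(list(cell_id = cell_id, kind = kind, times = times,
                 values = values, smoothed = smoothed,
                 window_frames = window_frames),
            class = "ratio_trace")
}

# per-frame pixel lists for every label in one pass
label_pixel_lists <- function(mask) {
  idx <- which(mask > 0)
  if (!length(idx)) return(list())
  split(idx, mask[idx])
}

#' Extract the raw per-frame Nuc/Cyt EGFP ratio of one cell
#'
#' The EGFP intensity of all pixels in the nuclear circle and in the cytosol
#' (cell-body region minus the circle) is averaged per frame, and the ratio
#' of the nuclear mean to the cytosolic mean is returned, one value per
#' tracked frame.
#'
#' @param movie an [nfkb_movie()].
#' @param track one track from [track_cells()].
#' @param masks per-frame label masks.
#' @param nucleus list(center, radius) from [locate_nucleus()].
#' @return a `ratio_trace` of kind `nfkb_nuc_cyt`.
#' @export
extract_nfkb_raw <- function(movie, track, masks, nucleus) {
  h <- dim(movie$data)[1]
  nuc_idx <- disk_pixels(nucleus$center[1], nucleus$center[2],
                         nucleus$radius, h, dim(movie$data)[2])
  vals <- numeric(length(track$frames))
  for (j in seq_along(track$frames)) {
    f <- track$frames[j]
    region <- which(masks[[f]] == track$labels[j])
    cyto <- setdiff(region, nuc_idx)
    if (!length(cyto)) stop("empty cytosolic area for cell ", track$cell_id)
    eg <- get_frame(movie, "EGFP", f)
    vals[j] <- mean(eg[nuc_idx]) / mean(eg[cyto])
  }
  ratio_trace(track$cell_id, "nfkb_nuc_cyt",
              (track$frames - movie$stimulation_frame) * movie$frame_interval,
              vals)
}

#' Smooth a ratio trace by a centred moving average
#'
#' Width `window_frames` (default 10, the ten-frame averaging used to build
#' translocation curves); at the edges the window truncates to the available
#' frames, so output length equals input length. `mode = "block"` averages
#' non-overlapping blocks instead, assigning each frame its block mean.
#'
#' @param raw a `ratio_trace`.
#' @param window_frames window width in frames (>= 1).
#' @param mode `"sliding"` (default) or `"block"`.
#' @return the smoothed `ratio_trace`.
#' @export
smooth_trace <- function(raw, window_frames = 10, mode = c("sliding", "block")) {
  mode <- match.arg(mode)
  if (window_frames < 1) stop("window_frames must be >= 1")
  v <- raw$values
  n <- length(v)
  w <- as.integer(window_frames)
  if (mode == "sliding") {
    left <- (w - 1) %/% 2
    right <- w - 1 - left
    cs <- cumsum(c(0, v))
    lo <- pmax(seq_len(n) - left, 1)
    hi <- pmin(seq_len(n) + right, n)
    out <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  } else {
    blk <- (seq_len(n) - 1) %/% w
    out <- stats::ave(v, blk)
  }
  tr <- raw
  tr$values <- out
  tr$smoothed <- TRUE
  tr$window_frames <- w
  tr
}

#' Extract the per-frame Cell/BG mCherry ratio of one cell
#'
#' mCherry is averaged over the cell-body region and divided by the mean
#' over the background: all pixels outside every cell region after dilating
#' the regions by `bg_margin` pixels (to avoid halo contamination).
#'
#' @param movie an [nfkb_movie()].
#' @param track one track from [track_cells()].
#' @param masks per-frame label masks.
#' @param bg_margin dilation margin in pixels (default 5).
#' @param bg_idx optional list of per-frame background pixel indices, as
#'   computed by [background_pixels()]; computed on the fly if missing.
#' @return a `ratio_trace` of kind `mcherry_cell_bg`.
#' @export
extract_mcherry <- function(movie, track, masks, bg_margin = 5, bg_idx = NULL) {
  if (is.null(bg_idx)) bg_idx <- background_pixels(masks, bg_margin)
  vals <- numeric(length(track$frames))
  for (j in seq_along(track$frames)) {
    f <- track$frames[j]
    region <- which(masks[[f]] == track$labels[j])
    bgp <- bg_idx[[f]]
    if (!length(bgp)) stop("no background area in frame ", f,
                           " (confluent field)")
    mc <- get_frame(movie, "mCherry", f)
    vals[j] <- mean(mc[region]) / mean(mc[bgp])
  }
  ratio_trace(track$cell_id, "mcherry_cell_bg",
              (track$frames - movie$stimulation_frame) * movie$frame_interval,
              vals)
}

#' Per-frame background pixel indices
#' @param masks per-frame label masks.
#' @param bg_margin dilation margin in pixels.
#' @return list of integer index vectors, one per frame.
#' @export
background_pixels <- function(masks, bg_margin = 5) {
  brush <- EBImage::makeBrush(2 * bg_margin + 1, "disc")
  lapply(masks, function(m) {
    if (max(m) == 0) return(which(m == 0))
    which(EBImage::dilate(m > 0, brush) == 0)
  })
}

#' Extract smoothed NF-kB and mCherry traces for all included cells
#'
#' Batch driver over [locate_nucleus()], [extract_nfkb_raw()],
#' [smooth_trace()] and [extract_mcherry()], sharing the per-frame
#' background computation. Cells for which no valid nuclear placement exists
#' are dropped and reported in `failed`.
#'
#' @param movie an [nfkb_movie()].
#' @param tracking result of [track_cells()].
#' @param masks per-frame label masks.
#' @param exclusions data.frame from [apply_exclusions()].
#' @param nucleus_diameter circle diameter in pixels.
#' @param window_frames smoothing window (default 10).
#' @param smoothing_mode `"sliding"` or `"block"`.
#' @param baseline_frames frames used for nucleus placement.
#' @param bg_margin background dilation margin in pixels.
#' @return list with `nfkb` (list of smoothed `ratio_trace`), `nfkb_raw`,
#'   `mcherry`, `nuclei` (per-cell circle), and `failed` (cell ids without a
#'   nuclear placement).
#' @export
extract_traces <- function(movie, tracking, masks, exclusions,
                           nucleus_diameter, window_frames = 10,
                           smoothing_mode = "sliding",
                           baseline_frames = 3, bg_margin = 5) {
  keep <- exclusions$cell_id[exclusions$included]
  bg_idx <- background_pixels(masks, bg_margin)
  nfkb <- nfkb_raw <- mcherry <- nuclei <- list()
  failed <- integer(0)
  for (cid in keep) {
    track <- tracking$tracks[[cid]]
    nuc <- locate_nucleus(movie, track, masks, nucleus_diameter,
                          baseline_frames = baseline_frames)
    if (is.null(nuc)) { failed <- c(failed, cid); next }
    raw <- extract_nfkb_raw(movie, track, masks, nuc)
    key <- as.character(cid)
    nuclei[[key]] <- nuc
    nfkb_raw[[key]] <- raw
    nfkb[[key]] <- smooth_trace(raw, window_frames, smoothing_mode)
    mcherry[[key]] <- extract_mcherry(movie, track, masks, bg_margin, bg_idx)
  }
  list(nfkb = nfkb, nfkb_raw = nfkb_raw, mcherry = mcherry,
       nuclei = nuclei, failed = failed)
}
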