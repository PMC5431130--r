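#' Multi-channel time-lapse movie container
#'
#' @param data numeric array of dimension (height, width, channels, frames),
#'   intensities in arbitrary units on a 16-bit scale.
#' @param frame_interval minutes between frames (> 0).
#' @param channel_names ordered channel labels; the analysis expects
#'   `"EGFP"`, `"mCherry"` and `"BF"` (bright-field) where present.
#' @param stimulation_frame index (1-based) of the stimulation frame;
#'   imaging starts immediately after stimulation, so the default is 1 and
#'   frame `i` is at `t = (i - stimulation_frame) * frame_interval` minutes.
#' @return an object of class `nfkb_movie`.
#' @export
nfkb_movie <- function(data, frame_interval = 3,
                       channel_names = c("EGFP", "mCherry", "BF"),
                       stimulation_frame = 1L) {
  if (length(dim(data)) != 4)
    stop("data must be a 4-d array (height, width, channels, frames)")
  if (dim(data)[3] != length(channel_names))
    stop("channel_names must match the number of channels")
  if (dim(data)[4] < 1) stop("a movie needs at least one frame")
  if (frame_interval <= 0) stop("frame_interval must be positive")
  if (!any(channel_names %in% c("EGFP", "mCherry", "BF")))
    stop("channels must include at least one of EGFP, mCherry, BF")
  structure(list(data = data,
                 frame_interval = frame_interval,
                 channel_names = channel_names,
                 stimulation_frame = as.integer(stimulation_frame)),
            class = "nfkb_movie")
}

#' @export
print.nfkb_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("nfkb_movie: %d x %d px, %d channel(s) [%s], %d frames @ %g min\n",
              d[1], d[2], d[3], paste(x$channel_names, collapse = ", "),
              d[4], x$frame_interval))
  invisible(x)
}

#' Frame times in minutes post-stimulation
#' @param movie an `nfkb_movie`.
#' @return numeric vector, one entry per frame.
#' @export
frame_times <- function(movie) {
  (seq_len(dim(movie$data)[4]) - movie$stimulation_frame) * movie$frame_interval
}

#' Pull one channel plane
#' @param movie an `nfkb_movie`.
#' @param channel channel name.
#' @param frame frame index (1-based).
#' @return numeric matrix (height x width).
#' @export
get_frame <- function(movie, channel, frame) {
  ci <- match(channel, movie$channel_names)
  if (is.na(ci)) stop("unknown channel: ", channel)
  movie$data[, , ci, frame]
}

#' Write a movie as multi-page 16-bit TIFFs plus a JSON sidecar
#'
#' One multi-page TIFF per channel (`<prefix>_<channel>.tif`) and a sidecar
#' `<prefix>.json` recording channel order, frame interval and stimulation
#' frame. Intensities are rounded and clipped to the 16-bit range
#' \[0, 65535\] with a warning if clipping occurred.
#'
#' @param movie an `nfkb_movie`.
#' @param prefix output path prefix (directory must exist).
#' @return invisibly, the vector of files written.
#' @export
write_movie <- function(movie, prefix) {
  d <- dim(movie$data)
  vals <- round(movie$data)
  if (any(vals < 0) || any(vals > 65535)) {
    warning("intensities outside [0, 65535] were clipped to the 16-bit range")
    vals <- pmin(pmax(vals, 0), 65535)
  }
  files <- character(0)
  for (ci in seq_len(d[3])) {
    pages <- lapply(seq_len(d[4]), function(f) vals[, , ci, f] / 65535)
    path <- paste0(prefix, "_", gsub("[^A-Za-z0-9]+", "", movie$channel_names[ci]), ".tif")
    tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
    files <- c(files, path)
  }
  sidecar <- paste0(prefix, ".json")
  jsonlite::write_json(list(channel_names = movie$channel_names,
                            frame_interval_min = movie$frame_interval,
                            stimulation_frame = movie$stimulation_frame,
                            height = d[1], width = d[2], n_frames = d[4]),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(files, sidecar))
}

#' Read a movie written by [write_movie()]
#'
#' @param prefix path prefix used when writing; the sidecar
#'   `<prefix>.json` supplies the channel mapping and time metadata.
#' @return an `nfkb_movie`; 16-bit values are recovered losslessly.
#' @export
read_movie <- function(prefix) {
  sidecar <- paste0(prefix, ".json")
  if (!file.exists(sidecar))
    stop("missing sidecar JSON (channel mapping): ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  chans <- meta$channel_names
  arr <- NULL
  for (ci in seq_along(chans)) {
    path <- paste0(prefix, "_", gsub("[^A-Za-z0-9]+", "", chans[ci]), ".tif")
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop("TIFF pages disagree in size: ", path)
    if (is.null(arr))
      arr <- array(0, dim = c(dims[1, 1], dims[2, 1], length(chans), length(pages)))
    if (dim(arr)[4] != length(pages))
      stop("channel stacks disagree in page count")
    for (f in seq_along(pages)) arr[, , ci, f] <- pages[[f]]
  }
  nfkb_movie(arr, frame_interval = meta$frame_interval_min,
             channel_names = chans,
             stimulation_frame = meta$stimulation_frame)
}

#' Write / read per-cell ratio trace tables
#'
#' Long-format CSV with columns `cell_id, genotype, time_minutes,
#' nuc_cyt_ratio, mcherry_cell_bg_ratio`; round trips are lossless at full
#' double precision.
#'
#' @param table data.frame with the columns above.
#' @param path CSV path.
#' @return `write_traces` returns `path` invisibly; `read_traces` the
#'   data.frame.
#' @export
write_traces <- function(table, path) {
  required <- c("cell_id", "genotype", "time_minutes",
                "nuc_cyt_ratio", "mcherry_cell_bg_ratio")
  missing <- setdiff(required, names(table))
  if (length(missing))
    stop("trace table lacks columns: ", paste(missing, collapse = ", "))
  utils::write.csv(format_full(table), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  required <- c("cell_id", "genotype", "time_minutes",
                "nuc_cyt_ratio", "mcherry_cell_bg_ratio")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("malformed trace CSV, lacks columns: ", paste(missing, collapse = ", "))
  tab
}

# full-precision formatting for CSV round trips (17 significant digits)
format_full <- function(df) {
  as.data.frame(lapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else col
  }), stringsAsFactors = FALSE, check.names = FALSE, optional = TRUE) |>
    stats::setNames(names(df))
}
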