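# Cell-body segmentation, tracking, nucleus placement and exclusion rules.

#' Segment one frame into labelled cell bodies
#'
#' Combines evidence from both channels: an Otsu threshold on the EGFP image
#' (cells carry the fluorescent fusion protein) and the dark boundary ring in
#' the bright-field image (absolute deviation from the median grey,
#' thresholded by Otsu, closed and hole-filled). The union is closed,
#' hole-filled, opened to drop speckles, connected-component labelled, and
#' regions below `min_area` pixels are discarded. A contrast guard returns an
#' empty mask on blank or constant frames instead of thresholding noise.
#'
#' @param bright_field,egfp numeric matrices of identical shape.
#' @param config list; `min_area` (pixels, default 120) and
#'   `contrast_ratio` (default 1.5): a channel only contributes if its
#'   maximum exceeds `contrast_ratio` times its median.
#' @return integer label matrix; 0 is background, labels are 1..n.
#' @export
segment_frame <- function(bright_field, egfp, config = list()) {
  stopifnot(all(dim(bright_field) == dim(egfp)))
  min_area <- config$min_area %||% 120
  contrast <- config$contrast_ratio %||% 1.5
  h <- nrow(egfp); w <- ncol(egfp)
  mask <- matrix(FALSE, h, w)

  med_e <- stats::median(egfp)
  if (max(egfp) > contrast * max(med_e, 1e-12)) {
    # Otsu can collapse into the background mode when cells cover only a few
    # percent of the frame; a median + 6*mad noise floor guards against that
    thr <- max(EBImage::otsu(egfp / max(egfp), range = c(0, 1)) * max(egfp),
               med_e + 6 * max(stats::mad(egfp), 1))
    mask <- mask | (egfp > thr)
  }
  dev_bf <- abs(bright_field - stats::median(bright_field))
  if (max(dev_bf) > 0.15 * max(stats::median(bright_field), 1e-12)) {
    thr_b <- max(EBImage::otsu(dev_bf / max(dev_bf), range = c(0, 1)) * max(dev_bf),
                 stats::median(dev_bf) + 6 * max(stats::mad(dev_bf), 1))
    ring <- EBImage::closing(dev_bf > thr_b, EBImage::makeBrush(5, "disc"))
    mask <- mask | (EBImage::fillHull(ring) > 0)
  }
  if (!any(mask)) return(matrix(0L, h, w))
  mask <- EBImage::closing(mask, EBImage::makeBrush(5, "disc"))
  mask <- EBImage::fillHull(mask)
  mask <- EBImage::opening(mask, EBImage::makeBrush(3, "disc"))
  lab <- EBImage::bwlabel(mask)
  counts <- tabulate(lab[lab > 0])
  keep <- which(counts >= min_area)
  if (!length(keep)) return(matrix(0L, h, w))
  remap <- integer(length(counts))
  remap[keep] <- seq_along(keep)
  out <- matrix(0L, h, w)
  pos <- lab > 0
  out[pos] <- remap[lab[pos]]
  out
}

#' Segment every frame of a movie
#' @param movie an [nfkb_movie()] with EGFP and BF channels.
#' @param config passed to [segment_frame()].
#' @return list of per-frame integer label matrices.
#' @export
segment_movie <- function(movie, config = list()) {
  nf <- dim(movie$data)[4]
  lapply(seq_len(nf), function(f)
    segment_frame(get_frame(movie, "BF", f), get_frame(movie, "EGFP", f), config))
}

region_centroids <- function(mask) {
  n <- max(mask)
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  idx <- which(mask > 0)
  lab <- mask[idx]
  # 0-based (x, y) centroids
  y <- (idx - 1) %% nrow(mask)
  x <- (idx - 1) %/% nrow(mask)
  cbind(x = tapply(x, lab, mean)[as.character(seq_len(n))],
        y = tapply(y, lab, mean)[as.character(seq_len(n))])
}

#' Track cells across frames by nearest centroid
#'
#' Regions are linked frame-to-frame by nearest centroid within a
#' `max_displacement` gate. A region with no link starts a new track; a track
#' unmatched for more than `gap_frames` consecutive frames ends (it is marked
#' lost unless the movie ended). Merge events (two tracks claiming one
#' region) and split candidates (several regions nearest to one track) are
#' recorded for [apply_exclusions()].
#'
#' @param masks list of per-frame label matrices from [segment_movie()].
#' @param max_displacement gate in pixels per frame (default 10; the
#'   macrophages are near-stationary).
#' @param gap_frames frames a track may go unmatched before ending.
#' @return list with `tracks` (each: `cell_id`, `frames`, `labels`,
#'   `centroids`, `ended_early`) and `events` (data.frame of merge/split
#'   candidates with frame and track ids).
#' @export
track_cells <- function(masks, max_displacement = 10, gap_frames = 2) {
  stopifnot(length(masks) >= 1)
  nf <- length(masks)
  tracks <- list()
  active <- integer(0)        # indices into tracks
  miss <- integer(0)          # consecutive misses per active track
  events <- list()
  new_track <- function(f, lab, ctr) {
    list(cell_id = NA_integer_, frames = f, labels = lab,
         centroids = matrix(ctr, ncol = 2), ended_early = FALSE)
  }
  for (f in seq_len(nf)) {
    cent <- region_centroids(masks[[f]])
    nr <- nrow(cent)
    assigned_track <- rep(NA_integer_, nr)
    if (length(active) && nr) {
      last <- t(vapply(tracks[active], function(tr)
        tr$centroids[nrow(tr$centroids), ], numeric(2)))
      d <- sqrt(outer(last[, 1], cent[, 1], "-")^2 +
                outer(last[, 2], cent[, 2], "-")^2)
      # greedy matching by increasing distance
      dd <- d
      repeat {
        m <- which.min(dd)
        if (!length(m) || !is.finite(dd[m]) || dd[m] > max_displacement) break
        ti <- (m - 1) %% nrow(dd) + 1
        ri <- (m - 1) %/% nrow(dd) + 1
        assigned_track[ri] <- active[ti]
        # merge candidates: other tracks whose nearest region is this one
        others <- which(is.finite(dd[, ri]) & dd[, ri] <= max_displacement)
        others <- setdiff(others, ti)
        for (o in others)
          events[[length(events) + 1]] <- data.frame(
            frame = f, type = "merge", track = active[o],
            other = active[ti], region = ri)
        dd[ti, ] <- Inf
        dd[, ri] <- Inf
      }
      # unassigned regions: near >= 2 tracks -> merge of those tracks into
      # one blob; otherwise group by the single near track: a split if that
      # track kept its own region or sheds >= 2 regions at once
      un <- which(is.na(assigned_track))
      near_list <- lapply(un, function(ri)
        which(d[, ri] <= 1.5 * max_displacement))
      single <- integer(0); single_ri <- integer(0)
      for (k in seq_along(un)) {
        near <- near_list[[k]]
        if (length(near) >= 2) {
          prs <- utils::combn(active[near], 2)
          for (q in seq_len(ncol(prs)))
            events[[length(events) + 1]] <- data.frame(
              frame = f, type = "merge", track = prs[1, q],
              other = prs[2, q], region = un[k])
        } else if (length(near) == 1) {
          single <- c(single, near); single_ri <- c(single_ri, un[k])
        }
      }
      for (ti in unique(single)) {
        ris <- single_ri[single == ti]
        if (active[ti] %in% assigned_track || length(ris) >= 2)
          for (ri in ris)
            events[[length(events) + 1]] <- data.frame(
              frame = f, type = "split", track = active[ti],
              other = NA_integer_, region = ri)
      }
    }
    matched <- active[active %in% assigned_track]
    miss[match(matched, active)] <- 0L
    unmatched <- setdiff(active, matched)
    miss[match(unmatched, active)] <- miss[match(unmatched, active)] + 1L
    drop <- active[miss > gap_frames]
    for (tid in drop) tracks[[tid]]$ended_early <- TRUE
    keepi <- miss <= gap_frames
    active <- active[keepi]; miss <- miss[keepi]
    for (ri in seq_len(nr)) {
      tid <- assigned_track[ri]
      if (is.na(tid)) {
        tracks[[length(tracks) + 1]] <- new_track(f, ri, cent[ri, ])
        active <- c(active, length(tracks))
        miss <- c(miss, 0L)
      } else {
        tr <- tracks[[tid]]
        tr$frames <- c(tr$frames, f)
        tr$labels <- c(tr$labels, ri)
        tr$centroids <- rbind(tr$centroids, cent[ri, ])
        tracks[[tid]] <- tr
      }
    }
  }
  for (i in seq_along(tracks)) {
    tracks[[i]]$cell_id <- i
    if (tracks[[i]]$frames[length(tracks[[i]]$frames)] < nf - gap_frames)
      tracks[[i]]$ended_early <- TRUE
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(frame = integer(0), type = character(0), track = integer(0),
               other = integer(0), region = integer(0))
  list(tracks = tracks, events = ev)
}

# pairs of distinct labels that are 8-adjacent anywhere in a label matrix
adjacent_label_pairs <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pairs <- list()
  shifts <- list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
  for (s in shifts) {
    dy <- s[1]; dx <- s[2]
    ys <- seq_len(h - abs(dy)); xs <- seq_len(w - abs(dx))
    a <- mask[ys + max(dy, 0), xs + max(dx, 0)]
    b <- mask[ys - min(dy, 0), xs - min(dx, 0)]
    sel <- a > 0 & b > 0 & a != b
    if (any(sel)) pairs[[length(pairs) + 1]] <-
        unique(cbind(pmin(a[sel], b[sel]), pmax(a[sel], b[sel])))
  }
  if (!length(pairs)) return(matrix(integer(0), ncol = 2))
  unique(do.call(rbind, pairs))
}

#' Apply the exclusion rules to tracked cells
#'
#' The automated analysis only works for single cells isolated for the whole
#' movie, so: cells whose regions are 8-adjacent (or that merge into one
#' region) in any frame are excluded as `touching`; a cell whose region
#' splits into two or more is excluded as `dividing`; a region touching the
#' image border in any frame is excluded as `border`; a track that ends (or
#' starts) away from the movie boundaries is `lost`. Flags are permanent for
#' the movie.
#'
#' @param tracking result of [track_cells()].
#' @param masks the per-frame label masks used for tracking.
#' @return data.frame with one row per track: `cell_id`, `included`,
#'   `exclusion_reason` in `none, touching, dividing, border, lost`.
#' @export
apply_exclusions <- function(tracking, masks) {
  tracks <- tracking$tracks
  nf <- length(masks)
  n <- length(tracks)
  reason <- rep("none", n)
  track_at <- function(f) {
    m <- masks[[f]]
    track_of <- rep(NA_integer_, max(max(m), 1))
    for (i in seq_len(n)) {
      j <- match(f, tracks[[i]]$frames)
      if (!is.na(j)) track_of[tracks[[i]]$labels[j]] <- i
    }
    track_of
  }
  # chronological event list: splits (dividing) get priority 0 within a
  # frame so daughters are classified before their mutual adjacency shows up
  ev <- tracking$events
  events <- data.frame(frame = integer(0), prio = integer(0),
                       type = character(0), a = integer(0), b = integer(0))
  if (nrow(ev)) {
    mg <- ev[ev$type == "merge", ]
    sp <- ev[ev$type == "split", ]
    if (nrow(sp)) {
      kid <- vapply(seq_len(nrow(sp)), function(r) {
        k <- which(vapply(tracks, function(tr)
          tr$frames[1] == sp$frame[r] && tr$labels[1] == sp$region[r],
          logical(1)))
        if (length(k)) k[1] else NA_integer_
      }, integer(1))
      events <- rbind(events, data.frame(frame = sp$frame, prio = 0L,
                                         type = "split", a = sp$track, b = kid))
    }
    if (nrow(mg)) {
      events <- rbind(events, data.frame(frame = mg$frame, prio = 1L,
                                         type = "touch", a = mg$track,
                                         b = mg$other))
      # a track born from the merged blob is part of the touching event
      kid <- vapply(seq_len(nrow(mg)), function(r) {
        k <- which(vapply(tracks, function(tr)
          tr$frames[1] == mg$frame[r] && tr$labels[1] == mg$region[r],
          logical(1)))
        if (length(k)) k[1] else NA_integer_
      }, integer(1))
      if (any(!is.na(kid)))
        events <- rbind(events, data.frame(frame = mg$frame[!is.na(kid)],
                                           prio = 1L, type = "touch",
                                           a = kid[!is.na(kid)],
                                           b = mg$track[!is.na(kid)]))
    }
  }
  for (f in seq_len(nf)) {
    pr <- adjacent_label_pairs(masks[[f]])
    if (nrow(pr)) {
      track_of <- track_at(f)
      events <- rbind(events, data.frame(frame = f, prio = 1L, type = "touch",
                                         a = track_of[pr[, 1]],
                                         b = track_of[pr[, 2]]))
    }
  }
  if (nrow(events)) {
    events <- events[order(events$frame, events$prio), ]
    for (r in seq_len(nrow(events))) {
      a <- events$a[r]; b <- events$b[r]
      if (events$type[r] == "split") {
        why <- if (!is.na(a) && reason[a] != "none") reason[a] else "dividing"
        if (!is.na(a) && reason[a] == "none") reason[a] <- why
        if (!is.na(b) && reason[b] == "none") reason[b] <- why
      } else {
        for (i in c(a, b))
          if (!is.na(i) && reason[i] == "none") reason[i] <- "touching"
      }
    }
  }
  # border contact, then incomplete tracks
  for (f in seq_len(nf)) {
    m <- masks[[f]]
    edge <- unique(c(m[1, ], m[nrow(m), ], m[, 1], m[, ncol(m)]))
    edge <- edge[edge > 0]
    if (length(edge)) {
      track_of <- track_at(f)
      for (i in track_of[edge])
        if (!is.na(i) && reason[i] == "none") reason[i] <- "border"
    }
  }
  incomplete <- vapply(tracks, function(tr)
    tr$ended_early || tr$frames[1] > 1 ||
      tr$frames[length(tr$frames)] < nf, logical(1))
  reason[incomplete & reason == "none"] <- "lost"
  data.frame(cell_id = vapply(tracks, `[[`, integer(1), "cell_id"),
             included = reason == "none",
             exclusion_reason = reason,
             stringsAsFactors = FALSE)
}

#' Place the nuclear circle inside a tracked cell
#'
#' The nuclear region is a circle of the configured diameter. Before
#' stimulation p65 is cytoplasmic, so the nucleus is the EGFP-dark part of
#' the cell: the centre is chosen to minimise mean EGFP within the circle
#' averaged over the first `baseline_frames` frames, constrained so the
#' circle lies fully inside the cell region. Ties break towards the smallest
#' pixel index. A manual centre/diameter can be supplied instead via
#' `override`.
#'
#' @param movie an [nfkb_movie()].
#' @param track one track from [track_cells()].
#' @param masks per-frame label masks.
#' @param diameter circle diameter in pixels (required; no biological
#'   default exists).
#' @param baseline_frames frames to average (default 3).
#' @param override optional list(cx, cy) manual 0-based centre.
#' @return list(center = c(x, y) 0-based, radius) or `NULL` when no valid
#'   placement exists (the cell should then be excluded as lost).
#' @export
locate_nucleus <- function(movie, track, masks, diameter,
                           baseline_frames = 3, override = NULL) {
  stopifnot(diameter > 0)
  r <- diameter / 2
  f0 <- track$frames[1]
  m <- masks[[f0]]
  region <- m == track$labels[1]
  if (!is.null(override))
    return(list(center = c(override$cx, override$cy), radius = r))
  dm <- EBImage::distmap(region)
  valid <- dm >= r + 1
  if (!any(valid)) return(NULL)
  use <- track$frames[seq_len(min(baseline_frames, length(track$frames)))]
  acc <- 0
  for (f in use) acc <- acc + get_frame(movie, "EGFP", f)
  acc <- acc / length(use)
  k <- 2 * floor(r) + 1
  kern <- matrix(0, k, k)
  cc <- floor(r) + 1
  for (i in seq_len(k)) for (j in seq_len(k))
    if ((i - cc)^2 + (j - cc)^2 <= r^2) kern[i, j] <- 1
  kern <- kern / sum(kern)
  means <- EBImage::filter2(acc, kern)
  means[!valid] <- Inf
  best <- which.min(means)
  cy <- (best - 1) %% nrow(m)
  cx <- (best - 1) %/% nrow(m)
  list(center = c(cx, cy), radius = r)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
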