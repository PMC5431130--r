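# Synthetic ground-truth dynamics and forward rendering into noisy movies.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

rnorm_clamped <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

# pixel membership of a disk, 0-based coordinates, distance <= radius inclusive
disk_pixels <- function(cx, cy, r, h, w, annulus_inner = NULL) {
  x0 <- max(0, floor(cx - r)); x1 <- min(w - 1, ceiling(cx + r))
  y0 <- max(0, floor(cy - r)); y1 <- min(h - 1, ceiling(cy + r))
  if (x0 > x1 || y0 > y1) return(integer(0))
  xs <- x0:x1; ys <- y0:y1
  dx2 <- (xs - cx)^2; dy2 <- (ys - cy)^2
  d2 <- outer(dy2, dx2, "+")
  keep <- d2 <= r^2
  if (!is.null(annulus_inner)) keep <- keep & d2 > annulus_inner^2
  ij <- which(keep, arr.ind = TRUE)
  (x0 + ij[, 2] - 1) * h + (y0 + ij[, 1])  # linear index into h x w matrix
}

#' Simulate one cell's nuclear NF-kB translocation trace
#'
#' Evaluates the damped Gaussian pulse-train model of
#' [pulse_train_params()] on the frame grid `t = 0, dt, ..., (n_frames-1)*dt`
#' and returns both the sampled Nuc/Cyt ratio trace and the true pulse list.
#' Pulses are additive, so the trace is never below baseline.
#'
#' @param params a [pulse_train_params()] object.
#' @param n_frames number of frames (>= 1).
#' @param dt frame interval in minutes (> 0).
#' @param seed optional integer; pulse times are drawn reproducibly.
#' @return list with `times` (minutes), `values` (ratio), and `pulses`, a
#'   data.frame of true (time, height-above-baseline) sorted by time.
#' @export
simulate_nfkb_trace <- function(params, n_frames, dt, seed = NULL) {
  stopifnot(inherits(params, "pulse_train_params"), n_frames >= 1, dt > 0)
  times <- (seq_len(n_frames) - 1) * dt
  K <- params$n_pulses
  pulses <- with_seed(seed, {
    if (K == 0) data.frame(time = numeric(0), height = numeric(0))
    else {
      tau <- numeric(K)
      tau[1] <- stats::rnorm(1, params$first_peak_time_mean, params$first_peak_time_sd)
      if (K > 1) {
        gaps <- pmax(stats::rnorm(K - 1, params$interval_mean, params$interval_sd),
                     2 * dt)  # keep pulse times strictly increasing
        tau[-1] <- tau[1] + cumsum(gaps)
      }
      data.frame(time = tau,
                 height = params$first_peak_amplitude *
                   params$damping_factor^(seq_len(K) - 1))
    }
  })
  values <- rep(params$baseline_ratio, n_frames)
  if (nrow(pulses)) {
    s2 <- 2 * params$pulse_width_sd^2
    for (k in seq_len(nrow(pulses)))
      values <- values + pulses$height[k] * exp(-(times - pulses$time[k])^2 / s2)
  }
  list(times = times, values = values, pulses = pulses)
}

#' Simulate a TNFa-promoter mCherry cell/background profile
#'
#' Deterministic logistic rise from 1, rescaled so the value at
#' `params$peak_time` equals `params$fold` exactly, followed by exponential
#' relaxation towards 1. `fold = 1` gives a flat non-responder profile.
#'
#' @param params a [reporter_params()] object.
#' @param n_frames number of frames (>= 1).
#' @param dt frame interval in minutes.
#' @return list with `times` and `values` (Cell/BG ratio).
#' @export
simulate_mcherry_profile <- function(params, n_frames, dt) {
  stopifnot(inherits(params, "reporter_params"), n_frames >= 1, dt > 0)
  times <- (seq_len(n_frames) - 1) * dt
  if (params$fold == 1) return(list(times = times, values = rep(1, n_frames)))
  logis <- function(t) 1 / (1 + exp(-params$rise_steepness * (t - params$rise_midpoint)))
  l0 <- logis(0); lp <- logis(params$peak_time)
  # affine rescale: value 1 at t = 0 and exactly `fold` at the peak time
  rise <- 1 + (params$fold - 1) * (logis(times) - l0) / (lp - l0)
  post <- times > params$peak_time
  vals <- rise
  vals[post] <- 1 + (params$fold - 1) *
    exp(-params$decay_rate * (times[post] - params$peak_time))
  list(times = times, values = vals)
}

# slow bounded baseline fluctuation: sum of 3 random-phase sinusoids scaled
# to a target sd; emulates focus/biological drift in resting cells
baseline_wiggle <- function(times, sd_target) {
  if (sd_target <= 0) return(numeric(length(times)))
  periods <- stats::runif(3, 60, 200)
  phases <- stats::runif(3, 0, 2 * pi)
  amps <- stats::rnorm(3)
  w <- rowSums(sapply(1:3, function(j) amps[j] * sin(2 * pi * times / periods[j] + phases[j])))
  s <- stats::sd(w)
  if (s < 1e-12) return(numeric(length(times)))
  w / s * sd_target
}

#' Render ground-truth cells into a noisy 3-channel movie
#'
#' Forward model: per cell, total EGFP is conserved over time and split
#' between the nuclear circle and the remaining cell-body pixels so that the
#' mean-intensity Nuc/Cyt ratio of the rendered pixels equals the input trace
#' exactly (before optics). mCherry is uniform over the cell body at
#' `background_offset * trace`, so the rendered Cell/BG ratio equals the
#' reporter trace. Bright-field is a uniform grey with a dark ring at the
#' cell boundary. Optics: Gaussian PSF blur, then Poisson shot noise, then
#' additive Gaussian read noise.
#'
#' @param cells list of cell records; each a list with `cell_id`, `center`
#'   (x, y in 0-based pixels), `radius`, `nucleus_center`, `nucleus_radius`,
#'   `nfkb_trace` and `mcherry_trace` (numeric, one value per frame), and
#'   optionally `drift` (n_frames x 2 cumulative pixel offsets) and
#'   `divide_frame` (frame index at which the cell splits in two).
#' @param optics an [optics_params()] object.
#' @param seed optional integer controlling the noise draws.
#' @return an [nfkb_movie()] with channels EGFP, mCherry, BF.
#' @export
render_movie <- function(cells, optics, seed = NULL) {
  stopifnot(inherits(optics, "optics_params"))
  h <- w <- optics$image_size
  nf <- optics$n_frames
  for (cell in cells) {
    ctr <- cell$center
    if (ctr[1] - cell$radius < 0 || ctr[1] + cell$radius > w - 1 ||
        ctr[2] - cell$radius < 0 || ctr[2] + cell$radius > h - 1)
      stop("cell ", cell$cell_id, " placed outside image bounds")
  }
  arr <- array(0, dim = c(h, w, 3, nf))
  bg <- optics$background_offset
  # static geometry cache for non-drifting, non-dividing cells
  static <- lapply(cells, function(cell) {
    if (!is.null(cell$drift) || !is.null(cell$divide_frame)) return(NULL)
    cell_px <- disk_pixels(cell$center[1], cell$center[2], cell$radius, h, w)
    nuc_px <- disk_pixels(cell$nucleus_center[1], cell$nucleus_center[2],
                          cell$nucleus_radius, h, w)
    ring_px <- disk_pixels(cell$center[1], cell$center[2], cell$radius, h, w,
                           annulus_inner = cell$radius - 1.5)
    list(cell = cell_px, nuc = nuc_px, cyto = setdiff(cell_px, nuc_px),
         ring = ring_px)
  })
  egfp_total <- rep(NA_real_, length(cells))
  with_seed(seed, {
    for (f in seq_len(nf)) {
      egfp <- matrix(bg, h, w)
      mch <- matrix(bg, h, w)
      bf <- matrix(optics$bf_level, h, w)
      for (ci in seq_along(cells)) {
        cell <- cells[[ci]]
        geom <- static[[ci]]
        divided <- !is.null(cell$divide_frame) && f >= cell$divide_frame
        if (is.null(geom) && !divided) {
          off <- if (is.null(cell$drift)) c(0, 0) else cell$drift[f, ]
          ctr <- cell$center + off
          nctr <- cell$nucleus_center + off
          cell_px <- disk_pixels(ctr[1], ctr[2], cell$radius, h, w)
          nuc_px <- disk_pixels(nctr[1], nctr[2], cell$nucleus_radius, h, w)
          geom <- list(cell = cell_px, nuc = nuc_px,
                       cyto = setdiff(cell_px, nuc_px),
                       ring = disk_pixels(ctr[1], ctr[2], cell$radius, h, w,
                                          annulus_inner = cell$radius - 1.5))
        }
        if (divided) {
          # two daughter disks separating along x; uniform EGFP, no nucleus
          sep <- (f - cell$divide_frame + 1) * 1.0
          r2 <- cell$radius * 0.75
          off <- if (is.null(cell$drift)) c(0, 0) else cell$drift[f, ]
          ctr <- cell$center + off
          for (sgn in c(-1, 1)) {
            px <- disk_pixels(ctr[1] + sgn * sep, ctr[2], r2, h, w)
            egfp[px] <- optics$egfp_cyto_baseline
            mch[px] <- bg * cell$mcherry_trace[f]
            rg <- disk_pixels(ctr[1] + sgn * sep, ctr[2], r2, h, w,
                              annulus_inner = r2 - 1.5)
            bf[rg] <- optics$bf_ring_level
          }
          next
        }
        An <- length(geom$nuc); Ac <- length(geom$cyto)
        r_f <- cell$nfkb_trace[f]
        if (is.na(egfp_total[ci]))
          egfp_total[ci] <- optics$egfp_cyto_baseline *
            (An * cell$nfkb_trace[1] + Ac)
        Ic <- egfp_total[ci] / (An * r_f + Ac)
        egfp[geom$cyto] <- Ic
        egfp[geom$nuc] <- r_f * Ic
        mch[geom$cell] <- bg * cell$mcherry_trace[f]
        bf[geom$ring] <- optics$bf_ring_level
      }
      planes <- list(egfp, mch, bf)
      for (k in 1:3) {
        p <- planes[[k]]
        if (optics$psf_sigma > 0) p <- EBImage::gblur(p, sigma = optics$psf_sigma)
        if (optics$shot_noise) p <- matrix(stats::rpois(length(p), pmax(p, 0)), h, w)
        if (optics$read_noise_sd > 0)
          p <- p + stats::rnorm(length(p), 0, optics$read_noise_sd)
        arr[, , k, f] <- pmax(p, 0)
      }
    }
  })
  nfkb_movie(arr, frame_interval = optics$frame_interval,
             channel_names = c("EGFP", "mCherry", "BF"))
}

#' Generate a rendered cohort of one genotype with full ground truth
#'
#' Draws per-cell pulse-train and reporter parameters from a
#' [genotype_preset()], simulates the traces, adds the slow baseline
#' fluctuation, lays the cells out on a jittered grid with guaranteed
#' separation, and renders the movie. Identical seeds give bit-identical
#' movies and ground truth.
#'
#' @param preset a [genotype_preset()] (or a label accepted by it).
#' @param n_cells number of cells (>= 1).
#' @param optics an [optics_params()] object.
#' @param seed integer seed.
#' @param layout_margin minimum pixel gap between cell disks.
#' @return list with `movie` (an [nfkb_movie()]) and `truth`: `cells`
#'   (one row per cell with every drawn parameter), `pulses` (true pulse
#'   times/heights), `nfkb_traces` and `mcherry_traces` (frames x cells
#'   matrices of the rendered input traces), `times`.
#' @export
generate_cohort <- function(preset, n_cells, optics = optics_params(),
                            seed = 1, layout_margin = 8) {
  if (is.character(preset)) preset <- genotype_preset(preset)
  stopifnot(n_cells >= 1, inherits(optics, "optics_params"))
  h <- w <- optics$image_size
  nf <- optics$n_frames
  dt <- optics$frame_interval
  rmax <- max(optics$cell_radius_range)
  spacing <- 2 * rmax + layout_margin
  border <- rmax + 3
  gx <- seq(border, w - 1 - border, by = spacing)
  gy <- seq(border, h - 1 - border, by = spacing)
  if (length(gx) * length(gy) < n_cells)
    stop("layout error: ", n_cells, " cells do not fit in a ",
         w, "x", h, " frame at spacing ", spacing)
  with_seed(seed, {
    sites <- expand.grid(x = gx, y = gy)
    sites <- sites[sample.int(nrow(sites), n_cells), , drop = FALSE]
    times <- (seq_len(nf) - 1) * dt
    cells <- vector("list", n_cells)
    rows <- vector("list", n_cells)
    pulse_rows <- vector("list", n_cells)
    nfkb_mat <- matrix(NA_real_, nf, n_cells)
    mch_mat <- matrix(NA_real_, nf, n_cells)
    for (i in seq_len(n_cells)) {
      radius <- stats::runif(1, optics$cell_radius_range[1], optics$cell_radius_range[2])
      cx <- sites$x[i] + stats::runif(1, -2, 2)
      cy <- sites$y[i] + stats::runif(1, -2, 2)
      max_off <- max(0, radius - optics$nucleus_radius - 1)
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- stats::runif(1, 0, min(2, max_off))
      # nucleus centres sit on the pixel grid, like the manual circles they
      # stand in for
      nucleus_center <- round(c(cx + rad * cos(ang), cy + rad * sin(ang)))
      n_pulses <- if (stats::runif(1) < preset$zero_pulse_prob) 0L else
        sample(preset$n_pulses_values, 1, prob = preset$n_pulses_probs)
      pp <- pulse_train_params(
        baseline_ratio = rnorm_clamped(1, preset$baseline_mean, preset$baseline_sd, lo = 0.3),
        first_peak_amplitude = rnorm_clamped(1, preset$amplitude_mean,
                                             preset$amplitude_sd, lo = preset$amplitude_min),
        damping_factor = rnorm_clamped(1, preset$damping_mean, preset$damping_sd,
                                       lo = preset$damping_range[1],
                                       hi = preset$damping_range[2]),
        n_pulses = n_pulses,
        first_peak_time_mean = preset$tau1_mean,
        first_peak_time_sd = preset$tau1_sd,
        interval_mean = preset$interval_mean,
        interval_sd = preset$interval_sd,
        pulse_width_sd = rnorm_clamped(1, preset$width_mean, preset$width_sd,
                                       lo = preset$width_min))
      tr <- simulate_nfkb_trace(pp, nf, dt)
      if (nrow(tr$pulses) && tr$pulses$time[1] < preset$tau1_min) {
        shift <- preset$tau1_min - tr$pulses$time[1]
        tr$pulses$time <- tr$pulses$time + shift
        tr <- utils::modifyList(tr, list(values = {
          v <- rep(pp$baseline_ratio, nf)
          for (k in seq_len(nrow(tr$pulses)))
            v <- v + tr$pulses$height[k] *
              exp(-(times - tr$pulses$time[k])^2 / (2 * pp$pulse_width_sd^2))
          v
        }))
      }
      fold <- if (preset$fold_sd == 0) preset$fold_mean else
        max(1, stats::rnorm(1, preset$fold_mean, preset$fold_sd))
      rp <- reporter_params(fold = fold,
                            rise_midpoint = rnorm_clamped(1, preset$rise_midpoint_mean,
                                                          preset$rise_midpoint_sd, lo = 100),
                            rise_steepness = preset$rise_steepness,
                            peak_time = rnorm_clamped(1, preset$peak_time_mean,
                                                      preset$peak_time_sd, lo = 200),
                            decay_rate = preset$decay_rate)
      mc <- simulate_mcherry_profile(rp, nf, dt)
      wig <- baseline_wiggle(times, preset$wiggle_sd)
      nfkb_vals <- pmax(tr$values + wig, 0.2 * pp$baseline_ratio)
      cells[[i]] <- list(cell_id = i, center = c(cx, cy), radius = radius,
                         nucleus_center = nucleus_center,
                         nucleus_radius = optics$nucleus_radius,
                         nfkb_trace = nfkb_vals, mcherry_trace = mc$values)
      nfkb_mat[, i] <- nfkb_vals
      mch_mat[, i] <- mc$values
      rows[[i]] <- data.frame(
        cell_id = i, genotype = preset$label, cx = cx, cy = cy, radius = radius,
        nucleus_cx = nucleus_center[1], nucleus_cy = nucleus_center[2],
        nucleus_radius = optics$nucleus_radius,
        baseline_ratio = pp$baseline_ratio,
        first_peak_amplitude = pp$first_peak_amplitude,
        damping_factor = pp$damping_factor,
        pulse_width_sd = pp$pulse_width_sd,
        n_pulses = nrow(tr$pulses), fold = fold,
        reporter_peak_time = rp$peak_time)
      pulse_rows[[i]] <- if (nrow(tr$pulses))
        data.frame(cell_id = i, k = seq_len(nrow(tr$pulses)),
                   time = tr$pulses$time, height = tr$pulses$height,
                   value = pp$baseline_ratio + tr$pulses$height)
      else NULL
    }
    movie <- render_movie(cells, optics,
                          seed = sample.int(.Machine$integer.max, 1))
    list(movie = movie,
         truth = list(cells = do.call(rbind, rows),
                      pulses = if (length(pr <- Filter(Negate(is.null), pulse_rows)))
                        do.call(rbind, pr)
                      else data.frame(cell_id = integer(0), k = integer(0),
                                      time = numeric(0), height = numeric(0),
                                      value = numeric(0)),
                      nfkb_traces = nfkb_mat, mcherry_traces = mch_mat,
                      times = times, label = preset$label, seed = seed))
  })
}

#' Synthetic exclusion fixtures: a touching pair and a dividing cell
#'
#' `synthetic_touching_pair` builds two cells that start separated and drift
#' into contact mid-movie; `synthetic_dividing_cell` builds one cell that
#' splits into two separating daughters at `divide_frame`. Both return cell
#' lists ready for [render_movie()], placed around an isolated control cell
#' so inclusion logic can be checked in the same scene.
#'
#' @param optics an [optics_params()] object (small frames are enough).
#' @param contact_frame,divide_frame frame at which contact/division starts.
#' @return list of cell records for [render_movie()].
#' @export
synthetic_touching_pair <- function(optics, contact_frame = 12) {
  nf <- optics$n_frames
  r <- min(optics$cell_radius_range)
  gap0 <- 14
  step <- gap0 / (2 * contact_frame)  # each cell covers half the gap
  drift_right <- cbind(pmin((seq_len(nf) - 1) * step, gap0 / 2 + 2), 0)
  drift_left <- -drift_right
  mid <- (optics$image_size - 1) / 2
  flat <- rep(0.8, nf); one <- rep(1, nf)
  list(
    list(cell_id = 1, center = c(mid - r - gap0 / 2, mid), radius = r,
         nucleus_center = c(mid - r - gap0 / 2, mid),
         nucleus_radius = optics$nucleus_radius,
         nfkb_trace = flat, mcherry_trace = one, drift = drift_right),
    list(cell_id = 2, center = c(mid + r + gap0 / 2, mid), radius = r,
         nucleus_center = c(mid + r + gap0 / 2, mid),
         nucleus_radius = optics$nucleus_radius,
         nfkb_trace = flat, mcherry_trace = one, drift = drift_left)
  )
}

#' @rdname synthetic_touching_pair
#' @export
synthetic_dividing_cell <- function(optics, divide_frame = 15) {
  nf <- optics$n_frames
  r <- max(optics$cell_radius_range)
  mid <- (optics$image_size - 1) / 2
  list(list(cell_id = 1, center = c(mid, mid), radius = r,
            nucleus_center = c(mid, mid),
            nucleus_radius = optics$nucleus_radius,
            nfkb_trace = rep(0.8, nf), mcherry_trace = rep(1, nf),
            divide_frame = divide_frame))
}
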