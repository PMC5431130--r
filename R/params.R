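#' Pulse-train parameters for the nuclear NF-kB fraction
#'
#' Describes one cell's damped train of nuclear-translocation pulses on top of
#' a resting nuclear-to-cytoplasmic (Nuc/Cyt) ratio. The trace model is
#' \deqn{r(t) = b + \sum_{k=1}^{K} A\,d^{\,k-1}
#'   \exp\{-(t-\tau_k)^2 / (2\sigma^2)\}}
#' with \eqn{\tau_1 \sim N(\mu_1, s_1)} and
#' \eqn{\tau_{k+1} = \tau_k + N(\mu_\Delta, s_\Delta)}.
#'
#' @param baseline_ratio resting Nuc/Cyt ratio (dimensionless, > 0). Below 1
#'   pre-stimulation: p65 is cytoplasmic at rest, so the nucleus is EGFP-dark.
#' @param first_peak_amplitude height of the first pulse above baseline.
#' @param damping_factor per-peak multiplier `d` in (0, 1.5]; values > 1 are
#'   allowed so degenerate growing trains can be exercised.
#' @param n_pulses number of pulses `K` (>= 0).
#' @param first_peak_time_mean,first_peak_time_sd minutes; centre and spread
#'   of the first pulse time.
#' @param interval_mean,interval_sd minutes; centre and spread of successive
#'   pulse intervals (about 90 min in wild-type macrophages).
#' @param pulse_width_sd Gaussian pulse sigma in minutes.
#' @return an object of class `pulse_train_params`.
#' @export
pulse_train_params <- function(baseline_ratio = 0.8,
                               first_peak_amplitude = 1.8,
                               damping_factor = 0.55,
                               n_pulses = 3,
                               first_peak_time_mean = 33,
                               first_peak_time_sd = 6,
                               interval_mean = 90,
                               interval_sd = 10,
                               pulse_width_sd = 8) {
  stopifnot(is.numeric(baseline_ratio), baseline_ratio > 0)
  if (first_peak_amplitude < 0)
    stop("first_peak_amplitude must be non-negative")
  if (pulse_width_sd <= 0) stop("pulse_width_sd must be positive")
  if (first_peak_time_sd < 0 || interval_sd < 0)
    stop("timing standard deviations must be non-negative")
  if (n_pulses < 0) stop("n_pulses must be >= 0")
  if (interval_mean <= 0) stop("interval_mean must be positive")
  if (damping_factor <= 0 || damping_factor > 1.5)
    stop("damping_factor must lie in (0, 1.5]")
  structure(list(baseline_ratio = baseline_ratio,
                 first_peak_amplitude = first_peak_amplitude,
                 damping_factor = damping_factor,
                 n_pulses = as.integer(n_pulses),
                 first_peak_time_mean = first_peak_time_mean,
                 first_peak_time_sd = first_peak_time_sd,
                 interval_mean = interval_mean,
                 interval_sd = interval_sd,
                 pulse_width_sd = pulse_width_sd),
            class = "pulse_train_params")
}

#' TNFa-promoter reporter (mCherry) accumulation parameters
#'
#' Cell/background mCherry ratio profile: a logistic rise from 1 towards
#' `fold`, rescaled so the value at `peak_time` equals `fold` exactly, then an
#' exponential relaxation back towards 1 after the peak. `fold = 1` encodes a
#' non-responder (flat profile at 1, "no increase").
#'
#' @param fold peak fold-increase (>= 1; 1 = non-responder).
#' @param rise_midpoint minutes; logistic midpoint of the rise.
#' @param rise_steepness per-minute logistic slope.
#' @param peak_time minutes at which the profile attains `fold` (about
#'   450 min post-stimulation in responding wild-type cells).
#' @param decay_rate per-minute exponential relaxation rate after the peak.
#' @return an object of class `reporter_params`.
#' @export
reporter_params <- function(fold = 2.1,
                            rise_midpoint = 250,
                            rise_steepness = 0.03,
                            peak_time = 450,
                            decay_rate = 0.002) {
  if (fold < 1) stop("fold must be >= 1 (1 means no increase)")
  if (peak_time <= 0) stop("peak_time must be positive")
  if (rise_steepness <= 0) stop("rise_steepness must be positive")
  if (decay_rate < 0) stop("decay_rate must be non-negative")
  structure(list(fold = fold, rise_midpoint = rise_midpoint,
                 rise_steepness = rise_steepness, peak_time = peak_time,
                 decay_rate = decay_rate),
            class = "reporter_params")
}

#' Genotype presets for cohort simulation
#'
#' Per-genotype distributions of pulse-train and reporter parameters that
#' emulate the four macrophage lines:
#' \describe{
#'   \item{WT}{wild type: synchronous early first peak, median 3 pulses
#'     (range 1-5), strong damping, mCherry responder (fold about 2).}
#'   \item{TKO}{TRIF-/-: NF-kB dynamics like WT (median 4 pulses, slightly
#'     longer first interval) but minimal reporter induction (fold about 1.2).}
#'   \item{MKO}{MyD88-/-: delayed, heterogeneous initiation, fewer and lower
#'     peaks (30% of cells show none), little damping, no reporter induction.}
#'   \item{DKO}{double knockout: no pulses, no reporter induction.}
#'   \item{UNSTIM}{unstimulated cells: no pulses, no induction; used to
#'     estimate the noise level for peak calling.}
#' }
#' Every cell additionally carries a slow bounded baseline fluctuation
#' (`wiggle_sd`, ratio units), identical across genotypes, standing in for
#' the biological and focus drift seen in resting cells.
#'
#' @param label one of `"WT"`, `"TKO"`, `"MKO"`, `"DKO"`, `"UNSTIM"`.
#' @return an object of class `genotype_preset`: a list of distribution
#'   hyper-parameters consumed by [generate_cohort()].
#' @export
genotype_preset <- function(label = c("WT", "TKO", "MKO", "DKO", "UNSTIM")) {
  label <- match.arg(label)
  base <- list(
    label = label,
    baseline_mean = 0.8, baseline_sd = 0.05,
    amplitude_mean = 1.8, amplitude_sd = 0.3, amplitude_min = 0.5,
    damping_mean = 0.55, damping_sd = 0.08,
    damping_range = c(0.3, 0.9),
    n_pulses_values = 1:5,
    n_pulses_probs = c(0.05, 0.20, 0.50, 0.20, 0.05),
    zero_pulse_prob = 0,
    tau1_mean = 33, tau1_sd = 6, tau1_min = 15,
    interval_mean = 90, interval_sd = 10,
    width_mean = 8, width_sd = 1, width_min = 5,
    fold_mean = 2.1, fold_sd = 1.5,
    peak_time_mean = 450, peak_time_sd = 40,
    rise_midpoint_mean = 250, rise_midpoint_sd = 30,
    rise_steepness = 0.03, decay_rate = 0.002,
    wiggle_sd = 0.02
  )
  switch(label,
    WT = base,
    TKO = utils::modifyList(base, list(
      n_pulses_values = 2:6,
      n_pulses_probs = c(0.10, 0.25, 0.35, 0.20, 0.10),
      interval_mean = 100,
      fold_mean = 1.2, fold_sd = 0.4)),
    MKO = utils::modifyList(base, list(
      amplitude_mean = 1.0, amplitude_sd = 0.25, amplitude_min = 0.3,
      damping_mean = 0.90, damping_sd = 0.10,
      damping_range = c(0.5, 1.2),
      n_pulses_values = 1:3, n_pulses_probs = c(0.25, 0.50, 0.25),
      zero_pulse_prob = 0.30,
      tau1_mean = 150, tau1_sd = 60, tau1_min = 30,
      interval_mean = 100, interval_sd = 25,
      fold_mean = 1, fold_sd = 0)),
    DKO = utils::modifyList(base, list(
      zero_pulse_prob = 1, fold_mean = 1, fold_sd = 0)),
    UNSTIM = utils::modifyList(base, list(
      zero_pulse_prob = 1, fold_mean = 1, fold_sd = 0))
  )
}

#' Optical / rendering parameters of the synthetic microscope
#'
#' Defaults follow the acquisition settings of the experiments being
#' emulated: 512 x 512 px frames every 3 minutes for 15 h (300 frames),
#' 16-bit intensities in arbitrary units. Intensities are uncalibrated
#' (counts per molecule unknown), so the scales below are arbitrary but fixed.
#'
#' @param image_size frame side length in pixels (square frames).
#' @param cell_radius_range min/max cell disk radius in pixels.
#' @param nucleus_radius nuclear circle radius in pixels (must be smaller
#'   than the minimum cell radius).
#' @param psf_sigma Gaussian point-spread sigma in pixels (0 disables blur).
#' @param background_offset camera background level (a.u.).
#' @param egfp_cyto_baseline cytosolic EGFP level at the first frame (a.u.).
#' @param bf_level,bf_ring_level bright-field interior grey and the dark ring
#'   level rendered at the cell boundary.
#' @param shot_noise logical; Poisson shot noise on expected intensities.
#' @param read_noise_sd additive Gaussian read noise sd (a.u.).
#' @param frame_interval minutes between frames.
#' @param n_frames number of frames (>= 1).
#' @return an object of class `optics_params`.
#' @export
optics_params <- function(image_size = 512,
                          cell_radius_range = c(10, 13),
                          nucleus_radius = 5,
                          psf_sigma = 1,
                          background_offset = 100,
                          egfp_cyto_baseline = 300,
                          bf_level = 1000,
                          bf_ring_level = 600,
                          shot_noise = TRUE,
                          read_noise_sd = 3,
                          frame_interval = 3,
                          n_frames = 300) {
  stopifnot(n_frames >= 1, frame_interval > 0, image_size >= 16,
            background_offset > 0)
  if (nucleus_radius >= min(cell_radius_range))
    stop("nucleus_radius must be smaller than the minimum cell radius")
  structure(list(image_size = as.integer(image_size),
                 cell_radius_range = cell_radius_range,
                 nucleus_radius = nucleus_radius,
                 psf_sigma = psf_sigma,
                 background_offset = background_offset,
                 egfp_cyto_baseline = egfp_cyto_baseline,
                 bf_level = bf_level, bf_ring_level = bf_ring_level,
                 shot_noise = isTRUE(shot_noise),
                 read_noise_sd = read_noise_sd,
                 frame_interval = frame_interval,
                 n_frames = as.integer(n_frames)),
            class = "optics_params")
}
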