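#' Cardiac waveform specification
#'
#' Defines the quasi-periodic cardiac drive shared by all phantoms: an
#' asymmetric pulse (fast systolic upstroke, slow diastolic decay, a
#' beta-shaped pulse `phi^a (1-phi)^b`) repeated at the murine heart rate
#' with beat-to-beat period jitter. Modulation depths are expressed directly
#' as target pulsatility indexes of the noiseless waveform, the ground truth
#' the pipeline is asked to recover.
#'
#' @param rate_hz mean heart rate, Hz (default 10; awake mice run ~8-11 Hz).
#' @param jitter fractional SD of the beat period (default 0.03).
#' @param pi_bfi target pulsatility index of the blood-flow-index waveform.
#' @param pi_d target pulsatility index of the vessel diameter waveform.
#' @param shape pulse shape exponents `c(a, b)`; the peak sits at
#'   `a/(a + b)` of the cycle (default `c(2, 6)`, peak at 25%).
#' @param corrupted_frac fraction of beats corrupted by an artifact
#'   (amplitude scaled by `corrupt_gain`), default 0.
#' @param corrupt_gain amplitude gain of corrupted beats (default 2.5).
#' @return A `cardiac_waveform_spec` list.
#' @export
cardiac_waveform_spec <- function(rate_hz = 10, jitter = 0.03, pi_bfi = 0.15,
                                  pi_d = 0, shape = c(2, 6),
                                  corrupted_frac = 0, corrupt_gain = 2.5) {
  if (jitter < 0 || jitter >= 0.2) stop("`jitter` must lie in [0, 0.2)")
  if (pi_bfi < 0 || pi_d < 0) stop("modulation depths must be >= 0")
  structure(list(rate_hz = rate_hz, jitter = jitter, pi_bfi = pi_bfi,
                 pi_d = pi_d, shape = shape, corrupted_frac = corrupted_frac,
                 corrupt_gain = corrupt_gain),
            class = "cardiac_waveform_spec")
}

# Normalized pulse shape on phase [0, 1]: 0 at both ends, max 1. The beta
# pulse phi^a (1-phi)^b gives the fast systolic upstroke; the parabolic term
# (weight = shape[3]) adds a dicrotic-like mid-cycle hump so the diastolic
# foot keeps a finite slope (a perfectly flat foot would make cycle-onset
# minima ill-localized, which real waveforms are not).
pulse_shape <- function(phi, shape) {
  a <- shape[1]; b <- shape[2]
  foot <- if (length(shape) >= 3L) shape[3] else 0.2
  peak <- (a / (a + b))^a * (b / (a + b))^b
  raw <- function(x) x^a * (1 - x)^b / peak + foot * 4 * x * (1 - x)
  raw(phi) / max(raw(seq(0, 1, length.out = 2001)))
}

# modulation depth m such that (max-min)/mean of 1 + m*p equals pi_target
modulation_depth <- function(pi_target, shape) {
  if (pi_target <= 0) return(0)
  q <- mean(pulse_shape(seq(0, 1, length.out = 4096), shape))
  if (pi_target * q >= 1) stop("PI target too large for this pulse shape")
  pi_target / (1 - pi_target * q)
}

#' Generate a jittered cardiac trace with known ground truth
#'
#' Concatenates beats of jittered period, each carrying the asymmetric
#' pulse, into a sampled waveform `1 + m * p(phi)` whose noiseless
#' pulsatility index equals the spec target. Beats flagged as corrupted get
#' their amplitude scaled by the corruption gain.
#'
#' @param spec a [cardiac_waveform_spec()].
#' @param fps sampling rate, Hz (must exceed twice the heart rate).
#' @param duration_s trace length, seconds.
#' @param pi_target which modulation target drives the trace (default the
#'   spec's `pi_bfi`).
#' @param seed optional RNG seed for the beat-period jitter and corruption
#'   draws.
#' @return List: `signal` (length `fps * duration_s`), `time_s`,
#'   `onset_times` (beat starts, s), `onset_index` (nearest sample, 1-based),
#'   `beat` (beat number per sample), `corrupted` (per beat), `pi_true`
#'   (PI of the clean noiseless waveform), `fps`.
#' @export
make_cardiac_trace <- function(spec, fps, duration_s,
                               pi_target = spec$pi_bfi, seed = NULL) {
  stopifnot(inherits(spec, "cardiac_waveform_spec"))
  if (fps <= 2 * spec$rate_hz) stop("`fps` must exceed twice the heart rate")
  if (!is.null(seed)) set.seed(seed)
  T0 <- 1 / spec$rate_hz
  n_beats <- ceiling(duration_s / T0 * (1 + 4 * spec$jitter)) + 2L
  z <- pmin(pmax(rnorm(n_beats), -3), 3)
  periods <- T0 * (1 + spec$jitter * z)
  if (any(periods <= 0)) stop("jitter too large: non-positive beat period")
  onsets <- c(0, cumsum(periods))
  corrupted <- runif(n_beats) < spec$corrupted_frac

  n <- round(fps * duration_s)
  t <- (seq_len(n) - 1) / fps
  beat <- findInterval(t, onsets)
  phi <- (t - onsets[beat]) / periods[beat]
  m <- modulation_depth(pi_target, spec$shape)
  gain <- ifelse(corrupted[beat], spec$corrupt_gain, 1)
  pulse <- pulse_shape(phi, spec$shape)
  signal <- 1 + gain * m * pulse

  dense <- 1 + m * pulse_shape(seq(0, 1, length.out = 4096), spec$shape)
  keep <- onsets <= max(t)
  list(signal = signal, pulse = pulse, gain = gain, time_s = t,
       onset_times = onsets[keep],
       onset_index = round(onsets[keep] * fps) + 1L,
       beat = beat, corrupted = corrupted[seq_len(max(beat))],
       pi_true = (max(dense) - min(dense)) / mean(dense), fps = fps)
}

#' Speckle phantom specification
#'
#' Geometry and noise model for a synthetic LSCI recording: a straight
#' vessel of given width crossing a uniform parenchymal background, each
#' with a prescribed baseline speckle contrast. The intensity model is
#' `I = I0 * (1 + K_target * Z)` with `Z` white unit-variance noise, clamped
#' to the 16-bit camera range: its local 5x5 contrast equals `K_target` in
#' expectation. This is deliberately an estimator-faithful noise model, not
#' a coherent speckle simulation - it reproduces the local contrast
#' statistics the pipeline consumes and nothing else about speckle optics.
#'
#' @param size `c(rows, cols)` in px (default 128 x 128).
#' @param fps frame rate, Hz (default 194).
#' @param duration_s recording length, seconds (default 60).
#' @param vessel_width_px baseline vessel width (default 12).
#' @param vessel_angle_deg vessel orientation in the image plane (default 25).
#' @param k_vessel,k_background baseline contrast inside / outside the
#'   vessel (defaults 0.2, 0.35; lower contrast = faster flow).
#' @param i0 mean camera intensity in counts (default 10000, ~35% of the
#'   16-bit range as in typical LSCI practice).
#' @param bg_pulses logical: does the parenchymal background pulse with the
#'   same PI as the vessel (default `TRUE`; the capillary bed is perfused
#'   and the whole-field time course owes its cardiac modulation to it).
#' @param edge_sigma width of the soft vessel edge, px (default 0.5).
#' @param seed RNG seed.
#' @return A `speckle_phantom_spec` list.
#' @export
speckle_phantom_spec <- function(size = c(128L, 128L), fps = 194,
                                 duration_s = 60, vessel_width_px = 12,
                                 vessel_angle_deg = 25, k_vessel = 0.2,
                                 k_background = 0.35, i0 = 10000,
                                 bg_pulses = TRUE, edge_sigma = 0.5,
                                 seed = 1L) {
  if (k_vessel <= 0 || k_vessel >= 1 || k_background <= 0 || k_background >= 1)
    stop("baseline contrasts must lie in (0, 1)")
  if (vessel_width_px < 2) stop("vessel width must be >= 2 px")
  structure(list(size = size, fps = fps, duration_s = duration_s,
                 vessel_width_px = vessel_width_px,
                 vessel_angle_deg = vessel_angle_deg, k_vessel = k_vessel,
                 k_background = k_background, i0 = i0, bg_pulses = bg_pulses,
                 edge_sigma = edge_sigma, seed = seed),
            class = "speckle_phantom_spec")
}

#' Render a ground-truthed synthetic LSCI recording
#'
#' Builds, frame by frame, a target-contrast map in which the vessel
#' interior BFI (`1/K^2`) follows the cardiac waveform at the requested
#' `pi_bfi`, the vessel width follows it at `pi_d`, and (optionally) the
#' background pulses too; then draws camera intensities from the
#' estimator-faithful noise model of [speckle_phantom_spec()]. The returned
#' truth sidecar carries everything needed to score the pipeline.
#'
#' @param phantom a [speckle_phantom_spec()].
#' @param waveform a [cardiac_waveform_spec()].
#' @return List with `stack` (a [frame_stack()], 16-bit integer counts) and
#'   `truth` (per-frame true width and interior/background BFI, beat onsets,
#'   corrupted-beat labels, `pi_bfi_true`, `pi_d_true`, the distance field
#'   and vessel geometry).
#' @export
render_speckle_video <- function(phantom, waveform) {
  stopifnot(inherits(phantom, "speckle_phantom_spec"),
            inherits(waveform, "cardiac_waveform_spec"))
  set.seed(phantom$seed)
  nr <- phantom$size[1]; nc <- phantom$size[2]
  n <- round(phantom$fps * phantom$duration_s)

  # cardiac drive (shared phase for flow and diameter)
  tr <- make_cardiac_trace(waveform, phantom$fps, phantom$duration_s,
                           pi_target = waveform$pi_bfi)
  m_b <- modulation_depth(waveform$pi_bfi, waveform$shape)
  m_d <- modulation_depth(waveform$pi_d, waveform$shape)
  pulse <- tr$pulse
  gain <- tr$gain

  bfi_in <- (1 / phantom$k_vessel^2) * (1 + gain * m_b * pulse)
  bfi_bg0 <- 1 / phantom$k_background^2
  bfi_bg <- if (phantom$bg_pulses)
    bfi_bg0 * (1 + gain * m_b * pulse) else rep(bfi_bg0, n)
  width <- phantom$vessel_width_px * (1 + gain * m_d * pulse)
  k_in <- 1 / sqrt(bfi_in)
  k_bg <- 1 / sqrt(bfi_bg)

  # signed distance to the vessel axis (straight line through the centre)
  th <- phantom$vessel_angle_deg * pi / 180
  rr <- rep(seq_len(nr), times = nc) - (nr + 1) / 2
  cc <- rep(seq_len(nc), each = nr) - (nc + 1) / 2
  dist <- abs(-sin(th) * cc + cos(th) * rr)

  frames <- array(0L, dim = c(nr, nc, n))
  const_width <- m_d == 0 && all(gain == 1)
  if (const_width)
    mask0 <- 1 / (1 + exp((dist - width[1] / 2) / phantom$edge_sigma))
  npx <- nr * nc
  for (i in seq_len(n)) {
    mask <- if (const_width) mask0 else
      1 / (1 + exp((dist - width[i] / 2) / phantom$edge_sigma))
    kmap <- k_bg[i] + (k_in[i] - k_bg[i]) * mask
    I <- phantom$i0 * (1 + kmap * rnorm(npx))
    frames[, , i] <- as.integer(pmin(pmax(round(I), 0), 65535L))
  }

  clean <- !tr$corrupted[tr$beat]
  truth <- list(width = width, bfi_in = bfi_in, bfi_bg = bfi_bg,
                onset_times = tr$onset_times, onset_index = tr$onset_index,
                corrupted_beats = tr$corrupted, beat = tr$beat,
                pi_bfi_true = if (m_b > 0)
                  (max(bfi_in[clean]) - min(bfi_in[clean])) /
                    mean(bfi_in[clean]) else 0,
                pi_d_true = if (m_d > 0)
                  (max(width[clean]) - min(width[clean])) /
                    mean(width[clean]) else 0,
                dist = dist, angle_deg = phantom$vessel_angle_deg,
                width0 = phantom$vessel_width_px)
  list(stack = frame_stack(frames, fps = phantom$fps,
                           exposure_us = 5000, pixel_size_um = NA_real_),
       truth = truth)
}

#' Line-scan phantom specification
#'
#' A bright capillary lumen (smoothed top-hat cross-section) on a dark
#' background, sampled once per scan line. The lumen width and its centre
#' can each oscillate sinusoidally, emulating diameter pulsatility and
#' rigid wall displacement respectively; shot-like (Poisson) noise and
#' saturated artifact columns complete the picture.
#'
#' @param n_space_px rows along the scan line (default 40).
#' @param mean_width_px baseline lumen width (default 8).
#' @param width_amp_px,width_freq_hz diameter oscillation (default 0 px,
#'   10 Hz).
#' @param trans_amp_px,trans_freq_hz rigid translation of the lumen
#'   (default 0 px, 10 Hz).
#' @param line_period_s scan line period, s (default 0.001).
#' @param duration_s recording length, s (default 30).
#' @param i_fg,i_bg lumen / background mean photon counts (default 200, 10).
#' @param edge_sigma lumen edge softness, px (default 0.7).
#' @param artifact_frac fraction of saturated artifact columns (default 0).
#' @param orientation_deg vessel orientation tag carried to the outputs.
#' @param seed RNG seed.
#' @return A `linescan_phantom_spec` list.
#' @export
linescan_phantom_spec <- function(n_space_px = 40L, mean_width_px = 8,
                                  width_amp_px = 0, width_freq_hz = 10,
                                  trans_amp_px = 0, trans_freq_hz = 10,
                                  line_period_s = 0.001, duration_s = 30,
                                  i_fg = 200, i_bg = 10, edge_sigma = 0.7,
                                  artifact_frac = 0, orientation_deg = 45,
                                  seed = 1L) {
  if (width_amp_px >= mean_width_px / 2)
    stop("width oscillation amplitude must be < mean width / 2")
  structure(list(n_space_px = n_space_px, mean_width_px = mean_width_px,
                 width_amp_px = width_amp_px, width_freq_hz = width_freq_hz,
                 trans_amp_px = trans_amp_px, trans_freq_hz = trans_freq_hz,
                 line_period_s = line_period_s, duration_s = duration_s,
                 i_fg = i_fg, i_bg = i_bg, edge_sigma = edge_sigma,
                 artifact_frac = artifact_frac,
                 orientation_deg = orientation_deg, seed = seed),
            class = "linescan_phantom_spec")
}

#' Render a ground-truthed synthetic line scan
#'
#' @param phantom a [linescan_phantom_spec()].
#' @param id capillary identifier for the emitted scan.
#' @return List with `scan` (a [line_scan()]) and `truth` (per-column true
#'   `width`, `center`, wall positions, and `artifact_cols`).
#' @export
render_linescan <- function(phantom, id = "cap1") {
  stopifnot(inherits(phantom, "linescan_phantom_spec"))
  set.seed(phantom$seed)
  n <- round(phantom$duration_s / phantom$line_period_s)
  t <- (seq_len(n) - 1) * phantom$line_period_s
  width <- phantom$mean_width_px +
    phantom$width_amp_px * sin(2 * pi * phantom$width_freq_hz * t)
  center <- (phantom$n_space_px + 1) / 2 +
    phantom$trans_amp_px * sin(2 * pi * phantom$trans_freq_hz * t)
  lo <- center - width / 2
  hi <- center + width / 2
  r <- seq_len(phantom$n_space_px)
  es <- phantom$edge_sigma
  shape <- stats::plogis(outer(r, lo, "-") / es) *
    stats::plogis(outer(-r, -hi, "-") / es)
  lambda <- phantom$i_bg + (phantom$i_fg - phantom$i_bg) * shape
  img <- matrix(rpois(length(lambda), as.vector(lambda)),
                nrow = phantom$n_space_px)
  art <- integer(0)
  if (phantom$artifact_frac > 0) {
    art <- sort(sample.int(n, max(1L, round(phantom$artifact_frac * n))))
    img[, art] <- 4095L                     # railed detector, no noise
  }
  scan <- line_scan(img, phantom$line_period_s,
                    orientation_deg = phantom$orientation_deg, id = id)
  list(scan = scan,
       truth = list(width = width, center = center, lower = lo, upper = hi,
                    artifact_cols = art))
}
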