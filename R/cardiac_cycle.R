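#' Dominant cardiac frequency of a contrast time course
#'
#' Identifies the heart rate as the frequency of maximum discrete Fourier
#' magnitude of the mean-detrended time course within a physiological band
#' (default 5-15 Hz, bracketing the murine heart rate).
#'
#' @param tc a [contrast_timecourse()] (or any numeric vector plus `fps`).
#' @param band_hz numeric length-2, search band `(lo, hi)` in Hz.
#' @param fps frame rate, only needed when `tc` is a bare vector.
#' @return Frequency in Hz of the strongest spectral component in the band.
#' @export
dominant_frequency <- function(tc, band_hz = c(5, 15), fps = NULL) {
  v <- if (inherits(tc, "contrast_timecourse")) tc$values else as.numeric(tc)
  fs <- if (inherits(tc, "contrast_timecourse")) tc$fps else fps
  if (is.null(fs)) stop("`fps` required when `tc` is a bare vector")
  lo <- band_hz[1]; hi <- band_hz[2]
  if (!(lo > 0 && hi > lo && hi < fs / 2))
    stop("need 0 < lo < hi < fps/2")
  n <- length(v)
  if (n < 2 * fs / lo)
    stop("time course too short to resolve the lower band edge")
  spec <- Mod(fft(v - mean(v)))[seq_len(floor(n / 2) + 1)]
  freq <- (seq_len(floor(n / 2) + 1) - 1) * fs / n
  in_band <- which(freq >= lo & freq <= hi)
  if (length(in_band) == 0L) stop("band empty after discretization")
  freq[in_band[which.max(spec[in_band])]]
}

#' Cardiac spectral peak significance
#'
#' Ratio of the maximum to the median discrete-spectrum power within the
#' cardiac band. A genuine heartbeat concentrates power in a narrow line
#' (ratios in the thousands on 60-s recordings); a recording with no
#' cardiac component behaves like flat noise, whose max/median ratio over
#' the band stays near `log(n_bins)/log(2)` (single digits). Used to
#' refuse to gate on noise when nothing periodic is present.
#'
#' @param tc a [contrast_timecourse()].
#' @param band_hz search band in Hz (default 5-15).
#' @return The peak-to-median power ratio (scalar).
#' @export
cardiac_peak_ratio <- function(tc, band_hz = c(5, 15)) {
  stopifnot(inherits(tc, "contrast_timecourse"))
  v <- tc$values
  n <- length(v)
  p <- Mod(fft(v - mean(v)))[seq_len(floor(n / 2) + 1)]^2
  freq <- (seq_len(floor(n / 2) + 1) - 1) * tc$fps / n
  inb <- freq >= band_hz[1] & freq <= band_hz[2]
  if (!any(inb)) stop("band empty after discretization")
  max(p[inb]) / median(p[inb])
}

#' Detect individual cardiac cycles from a contrast time course
#'
#' Cycle boundaries are local minima of the time course. Candidate minima
#' come from a sliding window of width `0.5 * fps / f0`; candidates closer
#' together than the shortest admissible period are merged (keeping the
#' deeper one), and consecutive minima whose separation lies within
#' `(1 +/- variability_frac) * fps / f0` delimit a cycle. Leading/trailing
#' partial cycles are discarded by construction.
#'
#' @param tc a [contrast_timecourse()].
#' @param f0 dominant cardiac frequency in Hz (see [dominant_frequency()]).
#' @param variability_frac admissible fractional heart-rate variability
#'   (default 0.3).
#' @return A `cycle_set`: list with `cycles` (data.frame: `start`, `end`
#'   1-based frame indices, `duration_frames`, feature columns once
#'   [cycle_features()] has run, `accepted`), `f0`, `fps`, `status`.
#' @export
detect_cycles <- function(tc, f0, variability_frac = 0.3) {
  stopifnot(inherits(tc, "contrast_timecourse"))
  v <- tc$values; fs <- tc$fps
  if (!(f0 > 0 && f0 < fs / 2)) stop("`f0` must lie in (0, fps/2)")
  if (!(variability_frac > 0 && variability_frac < 1))
    stop("`variability_frac` must lie in (0, 1)")
  period <- fs / f0
  wmin <- round(period * (1 - variability_frac))
  wmax <- round(period * (1 + variability_frac))

  # light moving-average smoothing (quarter period) for minima localization
  # only; everything downstream (features, averaging) uses the raw trace
  ws <- max(3L, round(0.25 * period))
  if (ws %% 2 == 0) ws <- ws + 1L
  vs <- as.numeric(stats::filter(v, rep(1 / ws, ws), sides = 2))
  vs[is.na(vs)] <- v[is.na(vs)]

  w <- max(3L, round(0.5 * period))
  if (w %% 2 == 0) w <- w + 1L
  h <- (w - 1L) %/% 2L
  n <- length(v)
  cand <- integer(0)
  if (n >= w) {
    win <- embed(vs, w)                  # row i = v[(i+w-1):(i)] reversed
    winmin <- apply(win, 1L, min)
    winmax <- apply(win, 1L, max)
    centre <- seq_len(n - w + 1L) + h   # centre index of each window
    is_min <- vs[centre] <= winmin & winmax > winmin
    # keep only the first sample of a plateau of equal minima
    cand <- centre[is_min]
    if (length(cand) > 1L)
      cand <- cand[c(TRUE, !(diff(cand) == 1L & diff(vs[cand]) == 0))]
  }
  empty <- function(status) {
    structure(list(cycles = data.frame(start = integer(0), end = integer(0),
                                       duration_frames = integer(0)),
                   f0 = f0, fps = fs, status = status), class = "cycle_set")
  }
  if (length(cand) < 3L) {
    warning("fewer than 3 local minima found; no cycles detected")
    return(empty("warning_too_few_minima"))
  }
  # merge minima closer than the shortest admissible period, keep the deeper
  kept <- cand[1]
  for (i in cand[-1]) {
    last <- kept[length(kept)]
    if (i - last < wmin) {
      if (vs[i] < vs[last]) kept[length(kept)] <- i
    } else kept <- c(kept, i)
  }
  if (length(kept) < 2L) return(empty("warning_too_few_minima"))
  # sub-sample refinement of each minimum (parabola through 3 points of the
  # smoothed trace); gives fractional boundaries so that phase alignment is
  # not quantized to the frame clock
  frac <- vapply(kept, function(b) {
    if (b < 2L || b > n - 1L) return(0)
    den <- vs[b - 1L] - 2 * vs[b] + vs[b + 1L]
    if (den <= 0) return(0)
    max(-0.5, min(0.5, 0.5 * (vs[b - 1L] - vs[b + 1L]) / den))
  }, 0)
  keptf <- kept + frac
  dur <- diff(kept)
  ok <- dur >= wmin & dur <= wmax
  cycles <- data.frame(start = kept[-length(kept)][ok], end = kept[-1][ok],
                       duration_frames = dur[ok],
                       start_frac = keptf[-length(keptf)][ok],
                       end_frac = keptf[-1][ok])
  structure(list(cycles = cycles, f0 = f0, fps = fs,
                 status = if (nrow(cycles)) "ok" else "warning_no_cycles"),
            class = "cycle_set")
}

#' @export
print.cycle_set <- function(x, ...) {
  acc <- if ("accepted" %in% names(x$cycles)) sum(x$cycles$accepted)
         else NA_integer_
  cat(sprintf("<cycle_set> %d cycles (f0 = %.4g Hz, status %s)",
              nrow(x$cycles), x$f0, x$status))
  if (!is.na(acc)) cat(sprintf(", %d accepted", acc))
  cat("\n"); invisible(x)
}

#' Per-cycle quality features
#'
#' Characterizes each detected cycle by its mean, standard deviation,
#' magnitude (max - min), duration in frames, absolute start-to-end contrast
#' difference, and number of noise spikes. A noise spike is a
#' counter-directional step on a monotone limb (an increase during the
#' descent or a decrease during the ascent) larger than `spike_frac` of the
#' cycle magnitude; limbs are split at the cycle's global maximum.
#'
#' @param tc the [contrast_timecourse()] the cycles were detected on.
#' @param cycles a `cycle_set` from [detect_cycles()].
#' @param spike_frac spike threshold as a fraction of cycle magnitude
#'   (default 0.2).
#' @return The `cycle_set` with feature columns filled.
#' @export
cycle_features <- function(tc, cycles, spike_frac = 0.2) {
  stopifnot(inherits(tc, "contrast_timecourse"), inherits(cycles, "cycle_set"))
  v <- tc$values
  cy <- cycles$cycles
  n <- nrow(cy)
  feat <- data.frame(mean = numeric(n), sd = numeric(n),
                     magnitude = numeric(n), start_end_diff = numeric(n),
                     n_noise_spikes = integer(n))
  for (i in seq_len(n)) {
    seg <- v[cy$start[i]:cy$end[i]]
    mag <- max(seg) - min(seg)
    feat$mean[i] <- mean(seg)
    feat$sd[i] <- sd(seg)
    feat$magnitude[i] <- mag
    feat$start_end_diff[i] <- abs(seg[length(seg)] - seg[1])
    imax <- which.max(seg)
    thr <- spike_frac * mag
    up <- diff(seg[seq_len(imax)])          # ascending limb
    down <- diff(seg[imax:length(seg)])     # descending limb
    feat$n_noise_spikes[i] <- sum(up < -thr) + sum(down > thr)
  }
  keep <- intersect(c("start", "end", "duration_frames", "start_frac",
                      "end_frac"), names(cy))
  cycles$cycles <- cbind(cy[keep], feat)
  cycles
}

#' Reject low-quality cardiac cycles
#'
#' A cycle is rejected when any screened feature (mean, sd, magnitude,
#' duration, start-end difference) deviates from the feature's median by more
#' than `k_sd` standard deviations, or when its noise-spike count exceeds
#' `max_spikes` (an absolute cap: the +/- SD rule degenerates for small
#' counts). Screening is single-pass: statistics are computed once over all
#' cycles, not re-estimated after rejection.
#'
#' @param cycles a `cycle_set` with features (see [cycle_features()]).
#' @param k_sd rejection threshold in standard deviations (default 2).
#' @param max_spikes maximum tolerated noise spikes per cycle (default 2).
#' @return The `cycle_set` with `accepted` and `rejection_reasons` columns;
#'   `status` is `"error_all_rejected"` if nothing survives.
#' @export
reject_cycles <- function(cycles, k_sd = 2, max_spikes = 2L) {
  stopifnot(inherits(cycles, "cycle_set"))
  cy <- cycles$cycles
  if (nrow(cy) < 3L) {
    cycles$status <- "error_insufficient_cycles"
    warning("insufficient cycles (< 3) for quality screening")
    return(cycles)
  }
  if (!"magnitude" %in% names(cy)) stop("run cycle_features() first")
  screened <- c("mean", "sd", "magnitude", "duration_frames",
                "start_end_diff")
  reasons <- vector("list", nrow(cy))
  for (f in screened) {
    x <- cy[[f]]
    dev <- abs(x - median(x))
    bad <- dev > k_sd * sd(x)
    for (i in which(bad)) reasons[[i]] <- c(reasons[[i]], f)
  }
  for (i in which(cy$n_noise_spikes > max_spikes))
    reasons[[i]] <- c(reasons[[i]], "n_noise_spikes")
  cy$accepted <- vapply(reasons, length, 1L) == 0L
  cy$rejection_reasons <- vapply(reasons, paste, "", collapse = ";")
  cycles$cycles <- cy
  if (!any(cy$accepted)) {
    cycles$status <- "error_all_rejected"
    warning("all cycles rejected by quality screening")
  } else cycles$status <- "ok"
  cycles
}

#' Ensemble-average accepted cycles into a representative cardiac cycle
#'
#' Each accepted cycle is linearly resampled on its own time base
#' (phase-normalized 0 to 1) to `n_phase = round(median duration *
#' interpolation_factor)` samples and the resampled cycles are averaged
#' pointwise. Because cycle durations differ, the pooled samples form an
#' irregular grid denser than the frame clock, so an interpolation factor
#' > 1 yields genuine temporal super-resolution. Works per pixel when given
#' a `contrast_stack`, or on a scalar time course.
#'
#' @param x a `contrast_stack` or [contrast_timecourse()].
#' @param cycles a screened `cycle_set` (see [reject_cycles()]); if no
#'   `accepted` column is present, all cycles are used.
#' @param interpolation_factor temporal oversampling factor >= 1 (default 4).
#' @return A `representative_cycle`: list with `k_cycle` (vector `n_phase`,
#'   or array `(row, col, n_phase)`), `phase` in `[0, 1]`, `n_phase`, `fps`,
#'   `f0`, `n_cycles_used`, `interpolation_factor`.
#' @export
representative_cycle <- function(x, cycles, interpolation_factor = 4) {
  stopifnot(inherits(cycles, "cycle_set"))
  if (interpolation_factor < 1) stop("`interpolation_factor` must be >= 1")
  cy <- cycles$cycles
  if ("accepted" %in% names(cy)) cy <- cy[cy$accepted, , drop = FALSE]
  if (nrow(cy) == 0L) stop("no accepted cycles to average")
  n_phase <- max(4L, as.integer(round(median(cy$duration_frames) *
                                        interpolation_factor)))
  phase <- seq(0, 1, length.out = n_phase)
  n_frames_total <- if (inherits(x, "contrast_timecourse"))
    length(x$values) else dim(x$contrast)[3]
  # fractional (sub-sample) boundaries when available
  sf <- if ("start_frac" %in% names(cy)) cy$start_frac else cy$start
  ef <- if ("end_frac" %in% names(cy)) cy$end_frac else cy$end
  s0 <- pmax(1L, floor(sf))
  e0 <- pmin(n_frames_total, ceiling(ef))

  if (inherits(x, "contrast_timecourse")) {
    v <- x$values
    acc <- numeric(n_phase)
    for (i in seq_len(nrow(cy))) {
      seg <- v[s0[i]:e0[i]]
      pos <- sf[i] + phase * (ef[i] - sf[i]) - s0[i] + 1
      acc <- acc + approx(seq_along(seg), seg, xout = pos, rule = 2)$y
    }
    k_cycle <- acc / nrow(cy)
  } else if (inherits(x, "contrast_stack")) {
    k <- x$contrast
    d <- dim(k)
    npx <- d[1] * d[2]
    acc <- matrix(0, npx, n_phase)
    for (i in seq_len(nrow(cy))) {
      block <- k[, , s0[i]:e0[i], drop = FALSE]
      dim(block) <- c(npx, e0[i] - s0[i] + 1L)
      pos <- sf[i] + phase * (ef[i] - sf[i]) - s0[i]   # 0-based columns
      accumulate_cycle_cpp(block, pos, acc)
    }
    k_cycle <- array(acc / nrow(cy), dim = c(d[1], d[2], n_phase))
  } else stop("`x` must be a contrast_stack or contrast_timecourse")

  structure(list(k_cycle = k_cycle, phase = phase, n_phase = n_phase,
                 fps = cycles$fps, f0 = cycles$f0,
                 n_cycles_used = nrow(cy),
                 interpolation_factor = interpolation_factor),
            class = "representative_cycle")
}

#' @export
print.representative_cycle <- function(x, ...) {
  kind <- if (is.null(dim(x$k_cycle))) "scalar" else
    paste(dim(x$k_cycle)[1:2], collapse = " x ")
  cat(sprintf("<representative_cycle> %s, n_phase = %d (interp %.3g), %d cycles\n",
              kind, x$n_phase, x$interpolation_factor, x$n_cycles_used))
  invisible(x)
}

#' Pulsatility index of a phase-resolved trace
#'
#' `PI = (max - min) / mean`, evaluated over the valid (non-`NA`) samples of
#' one cardiac cycle. Dimensionless and invariant under positive scaling.
#'
#' @param cycle_values numeric vector of phase-resolved values (e.g. BFI or
#'   diameter over the representative cycle).
#' @return The pulsatility index (scalar, >= 0).
#' @export
pulsatility_index <- function(cycle_values) {
  v <- cycle_values[!is.na(cycle_values)]
  if (length(v) < 2L) stop("need at least 2 valid samples")
  m <- mean(v)
  if (m <= 0) stop("pulsatility index undefined for non-positive mean")
  (max(v) - min(v)) / m
}

#' Per-pixel pulsatility and mean-BFI maps
#'
#' Converts the per-pixel representative contrast cycle to BFI
#' (`BFI = 1/K_cycle^2`) and computes, per pixel, the pulsatility index and
#' the cycle-mean BFI. Pixels undefined in the contrast (border band, mask)
#' stay `NA`.
#'
#' @param rep a per-pixel `representative_cycle` (from a `contrast_stack`).
#' @return A `pulsatility_map`: list with matrices `pi` and `mean_bfi`.
#' @export
pi_map <- function(rep) {
  stopifnot(inherits(rep, "representative_cycle"))
  k <- rep$k_cycle
  if (is.null(dim(k)) || length(dim(k)) != 3L)
    stop("`rep` must hold a per-pixel cycle; got a scalar trace")
  d <- dim(k)
  bfi <- 1 / (k * k)
  bfi[!is.finite(bfi)] <- NA_real_
  mx <- bfi[, , 1]; mn <- bfi[, , 1]; sm <- bfi[, , 1]
  for (p in seq_len(d[3])[-1]) {
    sl <- bfi[, , p]
    mx <- pmax(mx, sl); mn <- pmin(mn, sl); sm <- sm + sl
  }
  mean_bfi <- sm / d[3]
  structure(list(pi = (mx - mn) / mean_bfi, mean_bfi = mean_bfi),
            class = "pulsatility_map")
}
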