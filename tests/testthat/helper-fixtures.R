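# Small deterministic fixtures shared across test files. Everything is
# generated in code; no binary data ships with the package.

# constant-intensity stack
const_stack <- function(value = 100, nr = 9, nc = 9, nt = 3, fps = 194) {
  frame_stack(array(value, dim = c(nr, nc, nt)), fps = fps)
}

# scalar contrast time course carrying a pulsatile waveform (positive)
waveform_tc <- function(duration_s = 30, fps = 194, rate_hz = 10,
                        jitter = 0.03, pi_bfi = 0.15, noise_sd = 0,
                        seed = 42) {
  spec <- cardiac_waveform_spec(rate_hz = rate_hz, jitter = jitter,
                                pi_bfi = pi_bfi)
  tr <- make_cardiac_trace(spec, fps, duration_s, seed = seed)
  v <- tr$signal
  if (noise_sd > 0) v <- v + rnorm(length(v), sd = noise_sd)
  list(tc = contrast_timecourse(v, fps), truth = tr)
}

# straight synthetic vessel image: Gaussian cross-section of width sigma_g
# centred on a line through (r0, c0) at `angle_deg` to the column axis
vessel_image <- function(nr = 48, nc = 48, r0 = nr / 2, c0 = nc / 2,
                         angle_deg = 0, sigma_g = 3, amp = 10, base = 1) {
  th <- angle_deg * pi / 180
  rr <- matrix(seq_len(nr), nr, nc) - r0
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - c0
  dist <- -sin(th) * cc + cos(th) * rr
  base + amp * exp(-dist^2 / (2 * sigma_g^2))
}

# smoothed top-hat vessel image (plateau lumen) of full width `width`
tophat_vessel_image <- function(nr = 48, nc = 48, width = 10, angle_deg = 0,
                                edge = 1, amp = 10, base = 1,
                                r0 = nr / 2, c0 = nc / 2) {
  th <- angle_deg * pi / 180
  rr <- matrix(seq_len(nr), nr, nc) - r0
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - c0
  dist <- abs(-sin(th) * cc + cos(th) * rr)
  base + amp * stats::plogis((width / 2 - dist) / edge)
}

# wrap a per-phase stack of images into a representative_cycle object
fake_rep_cycle <- function(k_cycle, fps = 194, f0 = 10, interp = 4) {
  np <- dim(k_cycle)[3]
  structure(list(k_cycle = k_cycle, phase = seq(0, 1, length.out = np),
                 n_phase = np, fps = fps, f0 = f0, n_cycles_used = 1L,
                 interpolation_factor = interp),
            class = "representative_cycle")
}

# brute-force minimum within-class variance threshold (independent oracle)
brute_force_threshold <- function(x) {
  x <- x[is.finite(x)]
  ux <- sort(unique(x))
  best_thr <- NA_real_; best_wcv <- Inf
  for (thr in ux[-length(ux)]) {
    lo <- x[x <= thr]; hi <- x[x > thr]
    pv <- function(v) if (length(v) > 0) mean((v - mean(v))^2) else 0
    wcv <- (length(lo) * pv(lo) + length(hi) * pv(hi)) / length(x)
    if (wcv < best_wcv - 1e-15) { best_wcv <- wcv; best_thr <- thr }
  }
  list(threshold = best_thr, wcv = best_wcv)
}

# brute-force optimal two-class 1-D split minimising within-class SS
# (scan over sorted order; the optimal 1-D 2-means partition is an interval
# split of the sorted values)
brute_force_split <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  best <- Inf; cut <- NA_real_
  for (k in seq_len(n - 1)) {
    lo <- xs[1:k]; hi <- xs[(k + 1):n]
    ss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (ss < best - 1e-12) { best <- ss; cut <- (xs[k] + xs[k + 1]) / 2 }
  }
  list(cut = cut, ss = best)
}
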