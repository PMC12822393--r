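test_that("dominant frequency finds a pure tone to one bin", {
  fps <- 194; dur <- 60
  t <- seq(0, dur - 1 / fps, by = 1 / fps)
  tc <- contrast_timecourse(0.3 + 0.01 * sin(2 * pi * 10 * t), fps)
  expect_lt(abs(dominant_frequency(tc) - 10), 1 / dur + 1e-9)
})

test_that("dominant frequency ignores strong out-of-band components", {
  fps <- 194; dur <- 30
  t <- seq(0, dur - 1 / fps, by = 1 / fps)
  v <- 1 + 1 * sin(2 * pi * 10 * t) + 0.5 * sin(2 * pi * 2 * t)
  # oracle: argmax over a dense zero-padded spectrum restricted to the band
  n <- length(v); pad <- 8 * n
  sp <- Mod(fft(c(v - mean(v), numeric(pad - n))))[seq_len(pad / 2)]
  fr <- (seq_len(pad / 2) - 1) * fps / pad
  oracle <- fr[fr >= 5 & fr <= 15][which.max(sp[fr >= 5 & fr <= 15])]
  est <- dominant_frequency(contrast_timecourse(v, fps), c(5, 15))
  expect_lt(abs(est - oracle), 1 / dur + 1e-9)
  expect_lt(abs(est - 10), 1 / dur + 1e-9)
})

test_that("dominant frequency recovers a jittered cardiac rate", {
  w <- waveform_tc(duration_s = 60, rate_hz = 9.5, jitter = 0.03, seed = 21)
  expect_lt(abs(dominant_frequency(w$tc) - 9.5), 0.2)
})

test_that("cycle detection counts the beats of a sinusoid", {
  fps <- 194; dur <- 60
  t <- seq(0, dur - 1 / fps, by = 1 / fps)
  tc <- contrast_timecourse(1 + 0.1 * sin(2 * pi * 10 * t), fps)
  cs <- detect_cycles(tc, 10)
  expect_true(abs(nrow(cs$cycles) - 599) <= 1)
  expect_true(all(diff(cs$cycles$start) > 0))
  expect_true(all(cs$cycles$end > cs$cycles$start))
})

test_that("a constant signal yields an empty cycle set with a warning", {
  tc <- contrast_timecourse(rep(0.3, 2000), 194)
  expect_warning(cs <- detect_cycles(tc, 10), "minima")
  expect_equal(nrow(cs$cycles), 0)
})

test_that("detected boundaries land on generator beat onsets", {
  w <- waveform_tc(duration_s = 40, pi_bfi = 0.15, noise_sd = 0.003,
                   seed = 33)
  cs <- detect_cycles(w$tc, 10)
  expect_gt(nrow(cs$cycles), 300)
  bounds <- unique(c(cs$cycles$start, cs$cycles$end))
  nearest <- vapply(bounds, function(b)
    min(abs(b - w$truth$onset_index)), 0)
  expect_gte(mean(nearest <= 2), 0.95)
})

test_that("cycle features match a literal per-cycle computation", {
  set.seed(4)
  v <- abs(cumsum(rnorm(600))) + 5
  tc <- contrast_timecourse(v, 100)
  cs <- structure(list(cycles = data.frame(start = c(1L, 101L, 340L),
                                           end = c(100L, 339L, 520L),
                                           duration_frames = c(99L, 239L, 180L)),
                       f0 = 10, fps = 100, status = "ok"),
                  class = "cycle_set")
  cs <- cycle_features(tc, cs)
  for (i in 1:3) {
    seg <- v[cs$cycles$start[i]:cs$cycles$end[i]]
    expect_equal(cs$cycles$mean[i], mean(seg))
    expect_equal(cs$cycles$sd[i], sd(seg))
    expect_equal(cs$cycles$magnitude[i], max(seg) - min(seg))
    expect_equal(cs$cycles$start_end_diff[i], abs(seg[length(seg)] - seg[1]))
  }
})

test_that("one period of a sinusoid has the expected features and no spikes", {
  t <- seq(0, 1, length.out = 101)
  v <- 2 + 0.5 * (-cos(2 * pi * t))   # one cycle, minima at both ends
  tc <- contrast_timecourse(v, 101)
  cs <- structure(list(cycles = data.frame(start = 1L, end = 101L,
                                           duration_frames = 100L),
                       f0 = 1, fps = 101, status = "ok"),
                  class = "cycle_set")
  cs <- cycle_features(tc, cs)
  expect_equal(cs$cycles$mean, 2, tolerance = 0.01)
  expect_equal(cs$cycles$magnitude, 1, tolerance = 1e-3)
  expect_equal(cs$cycles$n_noise_spikes, 0L)
})

test_that("an injected outlier on the descending limb counts as one spike", {
  t <- seq(0, 1, length.out = 101)
  v <- 2 + 0.5 * (-cos(2 * pi * t))
  v[75] <- v[75] + 0.4            # upward step on the descent, > 20% of mag
  tc <- contrast_timecourse(v, 101)
  cs <- structure(list(cycles = data.frame(start = 1L, end = 101L,
                                           duration_frames = 100L),
                       f0 = 1, fps = 101, status = "ok"),
                  class = "cycle_set")
  cs <- cycle_features(tc, cs)
  expect_gte(cs$cycles$n_noise_spikes, 1L)
})

test_that("identical cycles are all accepted; a doubled one is rejected", {
  one <- 1 + 0.3 * pulsemap:::pulse_shape(seq(0, 1, length.out = 20),
                                          c(2, 6, 0.2))[-20]
  v <- rep(one, 50)
  tc <- contrast_timecourse(v, 194)
  starts <- seq(1L, by = 19L, length.out = 50)
  cs <- structure(list(cycles = data.frame(start = starts[-50],
                                           end = starts[-1],
                                           duration_frames = 19L),
                       f0 = 10, fps = 194, status = "ok"),
                  class = "cycle_set")
  cs <- reject_cycles(cycle_features(tc, cs))
  expect_true(all(cs$cycles$accepted))

  # double the magnitude of cycle 25 only
  v2 <- v
  idx <- starts[25]:(starts[26] - 1L)
  v2[idx] <- 1 + 2 * (v2[idx] - 1)
  cs2 <- structure(list(cycles = data.frame(start = starts[-50],
                                            end = starts[-1],
                                            duration_frames = 19L),
                        f0 = 10, fps = 194, status = "ok"),
                   class = "cycle_set")
  cs2 <- reject_cycles(cycle_features(contrast_timecourse(v2, 194), cs2))
  expect_false(cs2$cycles$accepted[25])
  expect_equal(sum(!cs2$cycles$accepted), 1)
})

test_that("rejection errors on too few cycles and flags all-rejected", {
  cs <- structure(list(cycles = data.frame(start = c(1L, 10L),
                                           end = c(10L, 20L),
                                           duration_frames = c(9L, 10L)),
                       f0 = 10, fps = 100, status = "ok"),
                  class = "cycle_set")
  expect_warning(out <- reject_cycles(cs), "insufficient")
  expect_match(out$status, "insufficient")
})

test_that("single accepted cycle reproduces itself resampled", {
  set.seed(8)
  v <- 1 + abs(rnorm(40, sd = 0.1))
  tc <- contrast_timecourse(v, 100)
  cs <- structure(list(cycles = data.frame(start = 5L, end = 25L,
                                           duration_frames = 20L,
                                           accepted = TRUE),
                       f0 = 5, fps = 100, status = "ok"),
                  class = "cycle_set")
  rep1 <- representative_cycle(tc, cs, interpolation_factor = 1)
  expect_equal(rep1$n_cycles_used, 1)
  expect_equal(rep1$n_phase, 20)
  expect_equal(rep1$k_cycle,
               approx(seq(0, 1, length.out = 21), v[5:25],
                      xout = seq(0, 1, length.out = 20))$y)
})

test_that("ensemble averaging suppresses additive noise as 1/sqrt(n)", {
  fps <- 194; n_cyc <- 100; per <- 20
  base <- 1 + 0.2 * pulsemap:::pulse_shape(seq(0, 1, length.out = per + 1),
                                           c(2, 6, 0.2))[-(per + 1)]
  sigma <- 0.05
  set.seed(9)
  v <- rep(base, n_cyc + 2) + rnorm(per * (n_cyc + 2), sd = sigma)
  tc <- contrast_timecourse(v, fps)
  starts <- seq(1L, by = per, length.out = n_cyc + 1)
  cs <- structure(list(cycles = data.frame(start = starts[-(n_cyc + 1)],
                                           end = starts[-1],
                                           duration_frames = per,
                                           accepted = TRUE),
                       f0 = fps / per, fps = fps, status = "ok"),
                  class = "cycle_set")
  rep1 <- representative_cycle(tc, cs, interpolation_factor = 1)
  truth <- c(base, base[1])[seq_len(per)]
  resid <- rep1$k_cycle - approx(seq(0, 1, length.out = per + 1),
                                 c(base, base[1]),
                                 xout = rep1$phase)$y
  expect_lte(sd(resid), 1.5 * sigma / sqrt(n_cyc))
})

test_that("n_phase expands with the interpolation factor", {
  w <- waveform_tc(duration_s = 20, seed = 13)
  cs <- detect_cycles(w$tc, 10)
  cs <- reject_cycles(cycle_features(w$tc, cs))
  r1 <- representative_cycle(w$tc, cs, interpolation_factor = 1)
  r4 <- representative_cycle(w$tc, cs, interpolation_factor = 4)
  med <- median(cs$cycles$duration_frames[cs$cycles$accepted])
  expect_equal(r1$n_phase, round(med))
  expect_equal(r4$n_phase, round(4 * med))
  expect_gt(r4$n_phase, med)
})

test_that("a noiseless periodic signal is reproduced up to interpolation", {
  w <- waveform_tc(duration_s = 30, jitter = 0, pi_bfi = 0.2, seed = 1)
  cs <- detect_cycles(w$tc, 10)
  cs <- reject_cycles(cycle_features(w$tc, cs))
  r <- representative_cycle(w$tc, cs, interpolation_factor = 2)
  # reference: one cycle resampled at its own (sub-sample) boundaries; the
  # 19.4-frame period is incommensurate with the frame clock, so residuals
  # are pure linear-interpolation error
  cy <- cs$cycles[cs$cycles$accepted, ]
  pos <- cy$start_frac[5] + r$phase * (cy$end_frac[5] - cy$start_frac[5])
  ref <- approx(seq_along(w$tc$values), w$tc$values, xout = pos)$y
  expect_lt(max(abs(r$k_cycle - ref)), 0.02 * diff(range(ref)))
})

test_that("waveform peak phase is recovered under beat-to-beat jitter", {
  w <- waveform_tc(duration_s = 30, jitter = 0.05, pi_bfi = 0.2, seed = 17)
  cs <- detect_cycles(w$tc, 10)
  cs <- reject_cycles(cycle_features(w$tc, cs))
  r <- representative_cycle(w$tc, cs, interpolation_factor = 4)
  # boundaries sit at waveform minima, so the ensemble peak should sit at
  # the pulse peak phase measured on a single noiseless beat
  one <- w$tc$values[cs$cycles$start[3]:cs$cycles$end[3]]
  ref_peak <- (which.max(one) - 1) / (length(one) - 1)
  est_peak <- r$phase[which.max(r$k_cycle)]
  expect_lt(abs(est_peak - ref_peak), 1 / r$n_phase + 0.02)
})

test_that("pulsatility index obeys its closed forms and invariances", {
  expect_equal(pulsatility_index(rep(2, 10)), 0)
  expect_equal(pulsatility_index(c(0.8, 1.2)), 0.4)
  set.seed(5)
  for (i in 1:20) {
    x <- runif(30, 0.5, 2)
    c0 <- runif(1, 0.1, 10)
    expect_equal(pulsatility_index(c0 * x), pulsatility_index(x),
                 tolerance = 1e-12)
    expect_equal(pulsatility_index(x), (max(x) - min(x)) / mean(x))
  }
  expect_error(pulsatility_index(c(-2, -1)), "mean")
  expect_error(pulsatility_index(2), "2 valid")
})

test_that("pi_map equals a per-pixel loop oracle", {
  set.seed(6)
  k <- array(runif(16 * 16 * 10, 0.2, 0.5), dim = c(16, 16, 10))
  k[1, 1, ] <- NA
  pm <- pi_map(fake_rep_cycle(k))
  for (i in c(1, 5, 16)) for (j in c(1, 7, 16)) {
    kb <- k[i, j, ]
    if (all(is.na(kb))) {
      expect_true(is.na(pm$pi[i, j]))
    } else {
      b <- 1 / kb^2
      expect_equal(pm$pi[i, j], (max(b) - min(b)) / mean(b),
                   tolerance = 1e-12)
      expect_equal(pm$mean_bfi[i, j], mean(b), tolerance = 1e-12)
    }
  }
})

test_that("uniform field with modulated K gives a spatially constant PI map", {
  np <- 24
  kt <- 0.3 * (1 + 0.05 * sin(2 * pi * seq(0, 1, length.out = np)))
  k <- array(rep(kt, each = 8 * 8), dim = c(8, 8, np))
  pm <- pi_map(fake_rep_cycle(k))
  scalar <- pulsatility_index(1 / kt^2)
  expect_equal(as.vector(pm$pi), rep(scalar, 64), tolerance = 1e-10)
})
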