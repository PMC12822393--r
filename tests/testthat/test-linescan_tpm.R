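test_that("rough stats find half-maximum boundaries on a top-hat lumen", {
  sim <- render_linescan(linescan_phantom_spec(duration_s = 2, seed = 2))
  st <- rough_scan_stats(sim$scan)
  truth_lo <- mean(sim$truth$lower); truth_hi <- mean(sim$truth$upper)
  expect_lt(abs(st$boundaries[1] - truth_lo), 1.5)
  expect_lt(abs(st$boundaries[2] - truth_hi), 1.5)
  expect_gt(st$snr, 3)
})

test_that("rough stats agree with a hand computation on a printed profile", {
  profile <- c(10, 11, 10, 12, 60, 100, 98, 55, 11, 10)
  img <- matrix(rep(profile, 8), nrow = 10)
  img <- img + matrix(c(0.2, -0.2), 10, 8)   # break zero variance
  sc <- line_scan(img, 0.001)
  st <- rough_scan_stats(sc)
  # by hand: bg = median = 11.5ish; half-max crossings at rows 5..7
  prof <- rowMeans(img)
  half <- median(prof) + (max(prof) - median(prof)) / 2
  expect_equal(st$boundaries, range(which(prof >= half)))
})

test_that("a flat scan has no capillary signal", {
  img <- matrix(rpois(40 * 50, 10), 40, 50)
  expect_error(rough_scan_stats(line_scan(img, 0.001)), "no capillary")
})

test_that("k-means separates a two-valued column exactly", {
  img <- matrix(10, 30, 20)
  img[12:18, ] <- 200
  img[1, 1] <- 11                      # avoid pathological exact ties
  sc <- line_scan(img, 0.001)
  seg <- kmeans_segment(sc)
  expect_false(any(seg$excluded))
  expect_true(all(seg$foreground[12:18, ]))
  expect_true(all(!seg$foreground[c(1:11, 19:30), ]))
})

test_that("zero-variance columns are excluded as background", {
  img <- matrix(10, 30, 10)
  img[12:18, ] <- 200
  img[, 4] <- 50                        # railed column
  seg <- kmeans_segment(line_scan(img, 0.001))
  expect_true(seg$excluded[4])
  expect_false(any(seg$foreground[, 4]))
})

test_that("k-means matches the optimal 1-D split under noise", {
  set.seed(19)
  sim <- render_linescan(linescan_phantom_spec(duration_s = 0.2, i_fg = 200,
                                               i_bg = 10, seed = 19))
  seg <- kmeans_segment(sim$scan)
  img <- sim$scan$intensity
  for (j in seq(1, ncol(img), by = 13)) {
    if (seg$excluded[j]) next
    bf <- brute_force_split(img[, j])
    expect_equal(seg$foreground[, j], img[, j] > bf$cut)
  }
  # pixelwise agreement with ground truth on a noisy phantom
  truth_fg <- outer(seq_len(nrow(img)), seq_len(ncol(img)),
                    function(r, j) r > sim$truth$lower[j] &
                                   r < sim$truth$upper[j])
  agree <- mean(seg$foreground == truth_fg)
  expect_gt(agree, 0.95)
})

test_that("boundary extraction recovers a constant diameter", {
  sim <- render_linescan(linescan_phantom_spec(duration_s = 3,
                                               mean_width_px = 8, seed = 3))
  ds <- extract_boundaries(kmeans_segment(sim$scan))
  expect_true(ds$usable)
  expect_lt(abs(mean(ds$d_px) - 8), 0.5)
  expect_lt(sd(ds$d_px), 0.8)
})

test_that("saturated artifact columns are excluded", {
  sim <- render_linescan(linescan_phantom_spec(duration_s = 1,
                                               artifact_frac = 0.01,
                                               seed = 4))
  ds <- extract_boundaries(kmeans_segment(sim$scan))
  n <- ds$n_total
  kept <- round(ds$time_s / sim$scan$line_period_s) + 1L
  expect_true(length(intersect(kept, sim$truth$artifact_cols)) == 0)
})

test_that("a rigidly translating lumen keeps its width but moves its walls", {
  sim <- render_linescan(linescan_phantom_spec(duration_s = 5,
                                               trans_amp_px = 1.5,
                                               trans_freq_hz = 10,
                                               i_fg = 500, i_bg = 5,
                                               seed = 5))
  ds <- extract_boundaries(kmeans_segment(sim$scan))
  expect_lt(sd(ds$d_px), 0.5)
  expect_gt(sd(ds$lower), 0.7)        # walls trace the 1.5 px translation
  expect_gt(cor(ds$lower, ds$upper), 0.8)
})

test_that("Lomb-Scargle matches the classical periodogram on regular data", {
  fs <- 200; n <- 1000
  t <- (0:(n - 1)) / fs
  y <- sin(2 * pi * 10 * t) + 0.3 * sin(2 * pi * 17 * t)
  freq <- seq(1, 30, by = 0.2)
  P <- lomb_scargle(t, y, freq)
  # classical (Schuster) periodogram at matching FFT bins
  sp <- Mod(fft(y - mean(y)))^2 / n
  fft_freq <- (0:(n - 1)) * fs / n
  for (f in c(10, 17)) {
    i_ls <- which.min(abs(freq - f))
    i_ff <- which.min(abs(fft_freq - f))
    expect_equal(P[i_ls], sp[i_ff], tolerance = 0.01)
  }
  expect_equal(freq[which.max(P)], 10)
})

test_that("the spectral peak survives 30% random gaps", {
  fs <- 500; n <- 5000
  t <- (0:(n - 1)) / fs
  y <- sin(2 * pi * 10 * t)
  set.seed(23)
  keep <- sort(sample.int(n, round(0.7 * n)))
  psd <- lombscargle_psd(list(time_s = t[keep], values = y[keep]),
                         window_s = 5)
  expect_lte(abs(psd$freq_hz[which.max(psd$power)] - 10), 0.1 + 1e-9)
})

test_that("windowed averaging shrinks the white-noise floor like 1/w", {
  fs <- 200
  set.seed(31)
  one_run <- function(n_win) {
    n <- n_win * 5 * fs
    t <- (0:(n - 1)) / fs
    psd <- lombscargle_psd(list(time_s = t, values = rnorm(n)),
                           window_s = 5)
    stopifnot(psd$n_windows == n_win)
    var(psd$power)
  }
  v1 <- mean(replicate(6, one_run(1)))
  v8 <- mean(replicate(6, one_run(8)))
  expect_lt(v8 / v1, 1 / 4)           # ~1/8 expected; generous band
})

test_that("white noise rarely produces large spectral excursions", {
  # on a window-averaged spectrum (6 x 5 s), a >5x-median bin is rare
  fs <- 200
  set.seed(37)
  hits <- replicate(50, {
    t <- (0:(30 * fs - 1)) / fs
    psd <- lombscargle_psd(list(time_s = t, values = rnorm(length(t))),
                           window_s = 5)
    any(psd$power > 5 * median(psd$power))
  })
  expect_lte(mean(hits), 0.05)
})

test_that("SNR semantics: peak height twice the pedestal gives SNR 1", {
  freq <- seq(1, 30, by = 0.1)
  p0 <- 2
  power <- rep(p0, length(freq))
  power[freq == 10] <- 2 * p0
  snr <- cardiac_snr(list(freq_hz = freq, power = power))
  expect_equal(snr$snr, 1)
  expect_equal(snr$peak_freq_hz, 10)
  expect_equal(snr$p_c, p0)
  expect_equal(snr$p_n, p0)
})

test_that("hand-built prominences: height 9 on pedestal 3 gives SNR 2", {
  freq <- seq(1, 30, by = 0.1)
  power <- rep(3, length(freq))
  i <- which(freq == 11)
  power[(i - 2):(i + 2)] <- c(4, 6, 9, 6, 4)
  snr <- cardiac_snr(list(freq_hz = freq, power = power))
  expect_equal(snr$p_c, 6)
  expect_equal(snr$p_n, 3)
  expect_equal(snr$snr, 2)
})

test_that("flat spectra and out-of-band peaks give SNR 0", {
  freq <- seq(1, 30, by = 0.1)
  flat <- cardiac_snr(list(freq_hz = freq, power = rep(1, length(freq))))
  expect_equal(flat$snr, 0)
  expect_equal(flat$flag, "no_peak")
  power <- rep(1, length(freq)); power[freq == 5] <- 10
  out <- cardiac_snr(list(freq_hz = freq, power = power))
  expect_equal(out$snr, 0)
})

test_that("an isolated peak on zero background is capped, not infinite", {
  freq <- seq(1, 30, by = 0.1)
  power <- rep(0, length(freq)); power[freq == 10] <- 5
  snr <- cardiac_snr(list(freq_hz = freq, power = power))
  expect_equal(snr$flag, "infinite")
  expect_true(is.finite(snr$snr))
})

test_that("orientation binning averages within 20-degree bins", {
  rec <- data.frame(orientation_deg = c(45, 45, 45), snr = c(1, 2, 3))
  out <- orientation_summary(rec)
  expect_equal(sum(out$n), 3)
  expect_equal(out$n[out$bin_lo == 40], 3)
  expect_equal(out$mean_snr[out$bin_lo == 40], 2)
  expect_true(all(is.na(out$mean_snr[out$bin_lo != 40])))

  set.seed(41)
  th <- runif(1000, 0, 180)
  rec2 <- data.frame(orientation_deg = th, snr = abs(cos(th * pi / 180)))
  out2 <- orientation_summary(rec2)
  # analytic bin means of |cos(theta)| over each 20-degree bin
  analytic <- vapply(seq_len(nrow(out2)), function(b) {
    f <- function(x) abs(cos(x * pi / 180))
    stats::integrate(f, out2$bin_lo[b], out2$bin_hi[b])$value / 20
  }, 0)
  expect_lt(max(abs(out2$mean_snr - analytic) / analytic), 0.12)
  # normalized variant has grand mean 1 over records
  expect_equal(sum(out2$mean_snr_norm * out2$n) / sum(out2$n), 1,
               tolerance = 1e-10)
})
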