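#' Construct a two-photon line scan
#'
#' A line scan is a space x time intensity image: each column is one fast
#' sweep of the scan line across a capillary (bright lumen on dark
#' background), repeated every `line_period_s` seconds for ~30 s.
#'
#' @param intensity numeric matrix, rows = position along the scan line,
#'   columns = time.
#' @param line_period_s scan line period in seconds (typically 1-2 ms).
#' @param pixel_size_um pixel size along the line, or `NA`.
#' @param orientation_deg vessel angle relative to the coronal plane, in
#'   `[0, 180)`, or `NA`.
#' @param id capillary identifier (cross-sections of one capillary share it).
#' @return A `line_scan` object.
#' @export
line_scan <- function(intensity, line_period_s, pixel_size_um = NA_real_,
                      orientation_deg = NA_real_, id = "cap1") {
  intensity <- as.matrix(intensity)
  if (!is.numeric(line_period_s) || line_period_s <= 0)
    stop("`line_period_s` must be positive")
  structure(list(intensity = intensity, line_period_s = line_period_s,
                 pixel_size_um = pixel_size_um,
                 orientation_deg = orientation_deg, id = id,
                 duration_s = ncol(intensity) * line_period_s),
            class = "line_scan")
}

#' @export
print.line_scan <- function(x, ...) {
  cat(sprintf("<line_scan> %s: %d px x %d lines @ %.3g ms (%.3g s)\n",
              x$id, nrow(x$intensity), ncol(x$intensity),
              1e3 * x$line_period_s, x$duration_s))
  invisible(x)
}

#' Rough whole-scan statistics of a line scan
#'
#' Collapses the scan over time into a mean spatial profile and estimates:
#' initial capillary boundaries at the half-maximum of that profile, the
#' foreground/background mean intensities (k-means initialization), and an
#' intensity SNR `(peak - background)/sd(background)`. A scan whose profile
#' never rises meaningfully above background has no capillary signal.
#'
#' @param scan a [line_scan()].
#' @param min_snr minimum intensity SNR to accept a signal (default 5; the
#'   maximum of a flat noise profile over ~10-200 rows stays below ~3.5
#'   robust SDs, while a real lumen sits tens of SDs above background).
#' @return List with `boundaries` (1-based rows of the half-maximum
#'   crossings), `bg_level`, `bg_sd`, `fg_mean`, `bg_mean`, `snr`,
#'   `profile`.
#' @export
rough_scan_stats <- function(scan, min_snr = 5) {
  stopifnot(inherits(scan, "line_scan"))
  profile <- rowMeans(scan$intensity)
  bg_level <- median(profile)
  bg_sd <- stats::mad(profile)
  peak <- max(profile)
  if (!is.finite(bg_sd)) bg_sd <- 0
  if (peak - bg_level <= 0 ||
      (bg_sd > 0 && (peak - bg_level) / bg_sd < min_snr))
    stop("no capillary signal: profile is flat")
  half <- bg_level + (peak - bg_level) / 2
  above <- which(profile >= half)
  fg <- profile >= half
  list(boundaries = range(above), bg_level = bg_level, bg_sd = bg_sd,
       fg_mean = mean(profile[fg]), bg_mean = mean(profile[!fg]),
       snr = if (bg_sd > 0) (peak - bg_level) / bg_sd else Inf,
       profile = profile)
}

#' Per-column k-means segmentation of a line scan
#'
#' Classifies every time point (column) into foreground (capillary lumen)
#' and background by two-class 1-D k-means on the column intensities,
#' deterministically initialized from the rough whole-scan foreground and
#' background means. Columns with zero variance carry no signal: they are
#' classified all-background and excluded.
#'
#' @param scan a [line_scan()].
#' @param stats output of [rough_scan_stats()]; computed if missing.
#' @return A `segmented_line_scan`: list with logical `foreground` matrix,
#'   `excluded` (per column), and `centroids` (2 x n matrix, background and
#'   foreground class means per column).
#' @export
kmeans_segment <- function(scan, stats = NULL) {
  stopifnot(inherits(scan, "line_scan"))
  if (is.null(stats)) stats <- rough_scan_stats(scan)
  img <- scan$intensity
  n <- ncol(img)
  fg <- matrix(FALSE, nrow(img), n)
  excluded <- logical(n)
  centroids <- matrix(NA_real_, 2, n)
  init <- rbind(stats$bg_mean, stats$fg_mean)
  for (j in seq_len(n)) {
    x <- img[, j]
    if (var(x) == 0) { excluded[j] <- TRUE; next }
    km <- tryCatch(
      kmeans(x, centers = init, algorithm = "Lloyd", iter.max = 100L),
      error = function(e) NULL, warning = function(w) {
        suppressWarnings(kmeans(x, centers = init, algorithm = "Lloyd",
                                iter.max = 100L))
      })
    if (is.null(km)) {                      # degenerate column: midpoint split
      thr <- mean(init)
      cl <- ifelse(x > thr, 2L, 1L)
      if (all(cl == cl[1])) { excluded[j] <- TRUE; next }
      cen <- c(mean(x[cl == 1L]), mean(x[cl == 2L]))
    } else {
      cl <- km$cluster
      cen <- as.numeric(km$centers)
    }
    hi <- which.max(cen)
    fg[, j] <- cl == hi
    centroids[, j] <- sort(cen)
  }
  structure(list(foreground = fg, excluded = excluded,
                 centroids = centroids, scan = scan),
            class = "segmented_line_scan")
}

#' Extract gapped diameter and wall-coordinate series
#'
#' For every non-excluded column, the longest foreground run gives the
#' lumen; its walls are refined to sub-pixel coordinates by linearly
#' interpolating the intensity to the midpoint of the two class centroids.
#' Columns likely containing artifacts are excluded: no usable run, run
#' touching the scan edge (covers saturated/whole-bright columns), or a
#' diameter jumping by more than `jump_frac` of the local (0.5 s block)
#' median. The result is an irregularly sampled (gapped) series, which is
#' exactly what the Lomb-Scargle periodogram is for.
#'
#' @param seg a `segmented_line_scan` from [kmeans_segment()].
#' @param jump_frac artifact threshold on diameter jumps (default 0.5).
#' @param block_s block length for the local median, seconds (default 0.5).
#' @param max_excluded_frac above this exclusion fraction the series is
#'   flagged unusable (default 0.5).
#' @return A `diameter_series`: list with `time_s`, `d_px`, `d_um`,
#'   `lower`, `upper` (sub-pixel wall rows), `n_total`, `frac_excluded`,
#'   `usable`, plus scan metadata.
#' @export
extract_boundaries <- function(seg, jump_frac = 0.5, block_s = 0.5,
                               max_excluded_frac = 0.5) {
  stopifnot(inherits(seg, "segmented_line_scan"))
  scan <- seg$scan
  img <- scan$intensity
  ns <- nrow(img); n <- ncol(img)
  lower <- upper <- rep(NA_real_, n)
  for (j in which(!seg$excluded)) {
    fgc <- seg$foreground[, j]
    r <- rle(fgc)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    if (length(runs) == 0L) next
    best <- runs[which.max(r$lengths[runs])]
    i0 <- starts[best]; i1 <- ends[best]
    if (i1 - i0 + 1L < 2L) next
    if (i0 == 1L || i1 == ns) next          # edge contact / saturation
    mid <- mean(seg$centroids[, j])
    lo <- i0
    if (img[i0, j] > img[i0 - 1L, j])
      lo <- i0 - (img[i0, j] - mid) / (img[i0, j] - img[i0 - 1L, j])
    up <- i1
    if (img[i1, j] > img[i1 + 1L, j])
      up <- i1 + (img[i1, j] - mid) / (img[i1, j] - img[i1 + 1L, j])
    if (up > lo) { lower[j] <- lo; upper[j] <- up }
  }
  d <- upper - lower
  # block-median jump screening
  block <- pmax(1L, round(block_s / scan$line_period_s))
  grp <- (seq_len(n) - 1L) %/% block
  for (g in unique(grp)) {
    sel <- which(grp == g & is.finite(d))
    if (length(sel) < 3L) next
    med <- median(d[sel])
    bad <- sel[abs(d[sel] - med) > jump_frac * med]
    d[bad] <- NA_real_; lower[bad] <- NA_real_; upper[bad] <- NA_real_
  }
  ok <- is.finite(d)
  frac_excl <- 1 - sum(ok) / n
  if (frac_excl > max_excluded_frac)
    warning(sprintf("%.0f%% of columns excluded; series flagged unusable",
                    100 * frac_excl))
  t_s <- (seq_len(n) - 1L) * scan$line_period_s
  psz <- scan$pixel_size_um
  structure(list(time_s = t_s[ok], d_px = d[ok],
                 d_um = if (is.na(psz)) NULL else d[ok] * psz,
                 lower = lower[ok], upper = upper[ok],
                 n_total = n, frac_excluded = frac_excl,
                 usable = frac_excl <= max_excluded_frac,
                 line_period_s = scan$line_period_s,
                 orientation_deg = scan$orientation_deg, id = scan$id),
            class = "diameter_series")
}

#' @export
print.diameter_series <- function(x, ...) {
  cat(sprintf("<diameter_series> %s: %d/%d samples (%.1f%% excluded), mean d = %.3g px\n",
              x$id, length(x$d_px), x$n_total, 100 * x$frac_excluded,
              mean(x$d_px)))
  invisible(x)
}

#' Lomb-Scargle periodogram of a gapped series
#'
#' Standard (Press) Lomb-Scargle periodogram of the mean-subtracted values,
#' reducing to the classical periodogram for regular sampling. Power is in
#' the unnormalized convention (units of variance halves).
#'
#' @param t sample times, seconds.
#' @param y sample values.
#' @param freq_hz frequencies at which to evaluate, Hz.
#' @return Numeric vector of power values, one per frequency.
#' @export
lomb_scargle <- function(t, y, freq_hz) {
  y <- y - mean(y)
  vapply(freq_hz, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    arg <- w * (t - tau)
    ct <- cos(arg); st <- sin(arg)
    0.5 * (sum(y * ct)^2 / sum(ct * ct) + sum(y * st)^2 / sum(st * st))
  }, 0)
}

#' Windowed, averaged Lomb-Scargle power spectrum
#'
#' Splits a gapped series into consecutive non-overlapping windows (default
#' 5 s), computes the Lomb-Scargle periodogram of each sufficiently sampled
#' window on a fixed 1-30 Hz grid, and averages over all windows - and over
#' multiple cross-sections of the same capillary when a list of series is
#' given. Windowed averaging trades frequency resolution for a stable noise
#' floor (variance shrinks like 1/n_windows).
#'
#' @param series a `diameter_series`, a `list(time_s=, values=)`, or a list
#'   of either (cross-sections averaged together).
#' @param values for `diameter_series` input: which series to analyze -
#'   `"diameter"` (wall separation: caliber pulsatility), `"center"` (wall
#'   midpoint: common-mode displacement of the vessel by surrounding
#'   tissue), or a single `"lower"`/`"upper"` wall coordinate (which mixes
#'   both effects).
#' @param window_s window length in seconds (default 5).
#' @param f_lo,f_hi,df frequency grid, Hz (defaults 1-30 by 0.1).
#' @param min_frac minimum fraction of nominal samples a window must retain
#'   (default 0.2).
#' @return A `lomb_psd`: list with `freq_hz`, `power`, `n_windows`.
#' @export
lombscargle_psd <- function(series,
                            values = c("diameter", "center", "lower",
                                       "upper"),
                            window_s = 5, f_lo = 1, f_hi = 30, df = 0.1,
                            min_frac = 0.2) {
  values <- match.arg(values)
  freq <- seq(f_lo, f_hi, by = df)
  one <- function(s) {
    if (inherits(s, "diameter_series")) {
      t <- s$time_s
      y <- switch(values, diameter = s$d_px,
                  center = (s$lower + s$upper) / 2, lower = s$lower,
                  upper = s$upper)
      nominal <- window_s / s$line_period_s
    } else {
      t <- s$time_s; y <- s$values
      nominal <- window_s / median(diff(sort(t)))
    }
    ok <- is.finite(y)
    t <- t[ok]; y <- y[ok]
    acc <- numeric(length(freq)); nw <- 0L
    for (k in seq_len(ceiling(max(t) / window_s))) {
      sel <- t >= (k - 1) * window_s & t < k * window_s
      if (sum(sel) < min_frac * nominal || sum(sel) < 8L) next
      acc <- acc + lomb_scargle(t[sel], y[sel], freq)
      nw <- nw + 1L
    }
    list(acc = acc, nw = nw)
  }
  slist <- if (inherits(series, c("diameter_series")) ||
               (is.list(series) && !is.null(series$time_s)))
    list(series) else series
  acc <- numeric(length(freq)); nw <- 0L
  for (s in slist) {
    r <- one(s)
    acc <- acc + r$acc; nw <- nw + r$nw
  }
  if (nw == 0L) stop("all windows under-sampled; no spectrum computed")
  structure(list(freq_hz = freq, power = acc / nw, n_windows = nw),
            class = "lomb_psd")
}

#' Topographic prominence of local spectral maxima
#'
#' For each interior local maximum, scan outward on both sides until a
#' higher point (or the spectrum edge) is reached; the higher of the two
#' intervening minima is the peak's base, and prominence = height - base.
#'
#' @param power numeric vector.
#' @return data.frame with `index`, `height`, `prominence`.
#' @keywords internal
peak_prominences <- function(power) {
  n <- length(power)
  idx <- which(diff(sign(diff(power))) < 0) + 1L
  idx <- idx[power[idx] > power[idx - 1L] & power[idx] >= power[idx + 1L]]
  if (length(idx) == 0L)
    return(data.frame(index = integer(0), height = numeric(0),
                      prominence = numeric(0)))
  prom <- vapply(idx, function(i) {
    h <- power[i]
    left <- power[seq_len(i - 1L)]
    higher_l <- which(left > h)
    lbase <- min(left[seq.int(from = if (length(higher_l))
      max(higher_l) + 1L else 1L, to = i - 1L)])
    right <- power[seq.int(i + 1L, n)]
    higher_r <- which(right > h)
    rbase <- min(right[seq_len(if (length(higher_r))
      min(higher_r) - 1L else length(right))])
    h - max(lbase, rbase)
  }, 0)
  data.frame(index = idx, height = power[idx], prominence = prom)
}

#' Cardiac-band spectral signal-to-noise ratio
#'
#' Finds the most prominent local maximum of the power spectrum within the
#' cardiac band (default 9-13 Hz; prominences are computed over the full
#' grid). The SNR is `P_c / P_n`, where `P_c` is the peak's prominence and
#' `P_n` the noise pedestal, defined as peak height minus prominence.
#' `SNR > 1` therefore means the peak's power is at least twice the noise
#' level at that frequency. A spectrum with no local maximum in the band
#' reports `snr = 0`; an isolated peak on a zero pedestal is capped.
#'
#' @param psd a `lomb_psd` (or list with `freq_hz`, `power`).
#' @param band cardiac frequency band, Hz (default `c(9, 13)`).
#' @param cap sentinel value reported when the pedestal is zero
#'   (default 1e6).
#' @return A `cardiac_snr`: list with `snr`, `peak_freq_hz`, `p_c`, `p_n`,
#'   `flag` (`"ok"`, `"no_peak"`, or `"infinite"`).
#' @export
cardiac_snr <- function(psd, band = c(9, 13), cap = 1e6) {
  freq <- psd$freq_hz; power <- psd$power
  if (band[1] < min(freq) || band[2] > max(freq))
    stop("`band` must lie within the frequency grid")
  pk <- peak_prominences(power)
  pk <- pk[freq[pk$index] >= band[1] & freq[pk$index] <= band[2], ,
           drop = FALSE]
  if (nrow(pk) == 0L)
    return(structure(list(snr = 0, peak_freq_hz = NA_real_, p_c = NA_real_,
                          p_n = NA_real_, flag = "no_peak"),
                     class = "cardiac_snr"))
  best <- pk[which.max(pk$prominence), ]
  p_c <- best$prominence
  p_n <- best$height - p_c
  if (p_n <= 0)
    return(structure(list(snr = cap, peak_freq_hz = freq[best$index],
                          p_c = p_c, p_n = 0, flag = "infinite"),
                     class = "cardiac_snr"))
  structure(list(snr = p_c / p_n, peak_freq_hz = freq[best$index],
                 p_c = p_c, p_n = p_n, flag = "ok"),
            class = "cardiac_snr")
}

#' @export
print.cardiac_snr <- function(x, ...) {
  cat(sprintf("<cardiac_snr> SNR = %.4g at %.3g Hz (Pc = %.3g, Pn = %.3g, %s)\n",
              x$snr, x$peak_freq_hz, x$p_c, x$p_n, x$flag))
  invisible(x)
}

#' Bin SNR records by vessel orientation
#'
#' Groups per-capillary SNR records into fixed-width orientation bins
#' (default 20 degrees over `[0, 180)`) and reports per-bin means and
#' counts. The mean-normalized variant divides each record by the grand
#' mean before binning, so a flat profile sits at 1.
#'
#' @param records data.frame with columns `orientation_deg` and `snr`.
#' @param bin_width bin width in degrees (default 20).
#' @return data.frame with `bin_lo`, `bin_hi`, `n`, `mean_snr`,
#'   `mean_snr_norm`; empty bins have `NA` means.
#' @export
orientation_summary <- function(records, bin_width = 20) {
  ori <- records$orientation_deg
  if (any(ori < 0 | ori >= 180, na.rm = TRUE))
    stop("orientations must lie in [0, 180)")
  edges <- seq(0, 180, by = bin_width)
  bin <- findInterval(ori, edges, rightmost.closed = FALSE)
  grand <- mean(records$snr)
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1])
  out$n <- vapply(seq_len(nrow(out)), function(b) sum(bin == b), 0L)
  out$mean_snr <- vapply(seq_len(nrow(out)), function(b)
    if (out$n[b]) mean(records$snr[bin == b]) else NA_real_, 0)
  out$mean_snr_norm <- out$mean_snr / grand
  out
}
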