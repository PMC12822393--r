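#' Define a region of interest
#'
#' ROIs are labeled polygons in pixel coordinates. Following common imaging
#' conventions the external representation is 0-based with `x` = column and
#' `y` = row and pixel centers at integer coordinates; internally all
#' geometry runs in 1-based `(row, col)` matrix coordinates.
#'
#' @param id identifier (character or integer).
#' @param label one of `"artery"`, `"vein"`, `"parenchyma"`.
#' @param polygon n x 2 matrix of `(x, y)` vertices (0-based).
#' @return An `roi` object.
#' @export
roi <- function(id, label, polygon) {
  label <- match.arg(label, c("artery", "vein", "parenchyma"))
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2L || nrow(polygon) < 3L)
    stop("`polygon` must be an n x 2 (x, y) matrix with n >= 3")
  structure(list(id = id, label = label, polygon = polygon), class = "roi")
}

#' Axis-aligned rectangular ROI
#'
#' @param id,label see [roi()].
#' @param x0,y0 top-left corner (0-based, inclusive).
#' @param width,height extent in pixels.
#' @return An `roi` object.
#' @export
roi_rect <- function(id, label, x0, y0, width, height) {
  roi(id, label, cbind(x = c(x0, x0 + width - 1, x0 + width - 1, x0),
                       y = c(y0, y0, y0 + height - 1, y0 + height - 1)))
}

#' Rasterize an ROI to a logical pixel mask
#'
#' Even-odd ray casting over pixel centers; pixel centers lying exactly on
#' the polygon outline count as inside, so a rectangle from `(x0, y0)` of
#' size `w x h` covers exactly `w * h` pixels.
#'
#' @param roi an [roi()].
#' @param dim_rc `c(nrow, ncol)` of the target image.
#' @return Logical matrix, `TRUE` inside the polygon.
#' @export
roi_mask <- function(roi, dim_rc) {
  px <- roi$polygon[, 1]; py <- roi$polygon[, 2]
  nr <- dim_rc[1]; nc <- dim_rc[2]
  x <- rep(seq_len(nc) - 1, each = nr)     # pixel-center coords, 0-based
  y <- rep(seq_len(nr) - 1, times = nc)
  inside <- logical(nr * nc)
  on_edge <- logical(nr * nc)
  j <- length(px)
  for (i in seq_along(px)) {
    crosses <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses)
    # point-on-segment test (cross product ~ 0 and inside the segment box)
    ex <- px[j] - px[i]; ey <- py[j] - py[i]
    cross <- (x - px[i]) * ey - (y - py[i]) * ex
    inseg <- x >= pmin(px[i], px[j]) - 1e-9 & x <= pmax(px[i], px[j]) + 1e-9 &
             y >= pmin(py[i], py[j]) - 1e-9 & y <= pmax(py[i], py[j]) + 1e-9
    on_edge <- on_edge | (abs(cross) < 1e-9 * max(1, abs(ex), abs(ey)) & inseg)
    j <- i
  }
  matrix(inside | on_edge, nr, nc)
}

#' Estimate a vessel centerline from a mean-BFI image
#'
#' The image is Gaussian-smoothed (`sigma` px), pixels brighter than the
#' median are weighted by their excess intensity, and the weighted
#' second-moment tensor gives the vessel's principal axis. The ROI is then
#' swept in 1-px bins along that axis; each bin's intensity-weighted centroid
#' across the axis gives a sub-pixel centerline point, smoothed with a
#' spline. An anisotropy score (eigenvalue ratio of the moment tensor) below
#' `anisotropy_min` means no elongated structure is present.
#'
#' @param mean_bfi_roi 2-D numeric matrix (ROI crop of the phase-mean BFI
#'   image); `NA` pixels (outside the ROI polygon) are ignored.
#' @param sigma Gaussian smoothing scale in px (default 2).
#' @param anisotropy_min minimum eigenvalue ratio to accept a vessel
#'   (default 2).
#' @param spacing arc-length spacing of emitted centerline points in px
#'   (default 0.5).
#' @return A `centerline` object: data.frame `points` with continuous
#'   1-based `(r, c)` coordinates and local tangent angle `theta` (radians,
#'   relative to the column axis), plus the anisotropy score.
#' @export
estimate_centerline <- function(mean_bfi_roi, sigma = 2, anisotropy_min = 2,
                                spacing = 0.5) {
  img <- as.matrix(mean_bfi_roi)
  if (min(dim(img)) < 5L) stop("ROI too small for centerline estimation")
  valid <- is.finite(img)
  if (!any(valid)) stop("no vessel found: ROI has no defined pixels")
  imgf <- img; imgf[!valid] <- median(img[valid])
  size <- 2L * ceiling(3 * sigma) + 1L
  size <- min(size, 2L * (min(dim(img)) %/% 2L) - 1L)
  sm <- EBImage::filter2(imgf,
                         EBImage::makeBrush(size, "Gaussian", sigma = sigma),
                         boundary = "replicate")
  sm <- as.matrix(sm)
  w <- pmax(sm - median(sm[valid]), 0)
  w[!valid] <- 0
  if (sum(w) <= 0) stop("no vessel found: no supra-median structure")

  nr <- nrow(img); nc <- ncol(img)
  rr <- rep(seq_len(nr), times = nc); cc <- rep(seq_len(nc), each = nr)
  wt <- as.vector(w)
  mu_r <- sum(wt * rr) / sum(wt); mu_c <- sum(wt * cc) / sum(wt)
  dr <- rr - mu_r; dc <- cc - mu_c
  C <- matrix(c(sum(wt * dc * dc), sum(wt * dc * dr),
                sum(wt * dc * dr), sum(wt * dr * dr)) / sum(wt), 2, 2)
  eg <- eigen(C, symmetric = TRUE)
  aniso <- eg$values[1] / max(eg$values[2], .Machine$double.eps)
  if (!is.finite(aniso) || aniso < anisotropy_min)
    stop("no vessel found: anisotropy score ", format(aniso, digits = 3),
         " below threshold")
  u <- eg$vectors[, 1]                       # principal axis, (dc, dr)
  if (u[1] < 0 || (u[1] == 0 && u[2] < 0)) u <- -u   # deterministic direction
  v <- c(-u[2], u[1])                        # normal
  s <- dc * u[1] + dr * u[2]                 # along-axis coordinate
  t <- dc * v[1] + dr * v[2]                 # across-axis coordinate

  keep <- wt > 0
  bin <- round(s[keep])
  tb <- tapply(t[keep] * wt[keep], bin, sum) / tapply(wt[keep], bin, sum)
  sb <- as.numeric(names(tb))
  ord <- order(sb); sb <- sb[ord]; tb <- as.numeric(tb)[ord]
  if (length(sb) < 4L) stop("no vessel found: vessel support too short")
  fit <- if (length(sb) >= 8L) {
    sp <- smooth.spline(sb, tb, spar = 0.6)
    function(s) predict(sp, s)$y
  } else {
    cf <- stats::coef(stats::lm(tb ~ sb))
    function(s) cf[1] + cf[2] * s
  }
  sg <- seq(min(sb), max(sb), by = spacing)
  tg <- fit(sg)
  eps <- 0.01
  slope <- (fit(sg + eps) - fit(sg - eps)) / (2 * eps)
  # tangent in (dc, dr): u + t'(s) * v
  tan_c <- u[1] + slope * v[1]
  tan_r <- u[2] + slope * v[2]
  theta <- atan2(tan_r, tan_c)
  pts <- data.frame(r = mu_r + sg * u[2] + tg * v[2],
                    c = mu_c + sg * u[1] + tg * v[1],
                    theta = theta)
  inside <- pts$r >= 1 & pts$r <= nr & pts$c >= 1 & pts$c <= nc
  structure(list(points = pts[inside, , drop = FALSE], anisotropy = aniso),
            class = "centerline")
}

#' Bilinear interpolation on a matrix
#'
#' @param img numeric matrix.
#' @param r,c continuous 1-based row/column coordinates (vectors).
#' @return Interpolated values; `NA` outside the matrix.
#' @keywords internal
bilinear_interp <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  out <- rep(NA_real_, length(r))
  ok <- r >= 1 & r <= nr & c >= 1 & c <= nc & is.finite(r) & is.finite(c)
  r0 <- pmin(floor(r[ok]), nr - 1L); c0 <- pmin(floor(c[ok]), nc - 1L)
  fr <- r[ok] - r0; fc <- c[ok] - c0
  i00 <- (c0 - 1L) * nr + r0
  out[ok] <- img[i00] * (1 - fr) * (1 - fc) +
    img[i00 + 1L] * fr * (1 - fc) +
    img[i00 + nr] * (1 - fr) * fc +
    img[i00 + nr + 1L] * fr * fc
  out
}

#' Averaged sub-pixel cross-sectional profile
#'
#' Samples the image along the perpendicular of every centerline point at
#' sub-pixel spacing `step` (bilinear interpolation) and averages the
#' per-point profiles into one mean cross-section. Because the centerline is
#' not pixel-aligned, the pooled samples form an irregular grid across the
#' vessel: averaging them retains sub-pixel (spatially super-resolved)
#' information about the wall position.
#'
#' @param bfi_frame 2-D numeric matrix.
#' @param centerline a `centerline` from [estimate_centerline()].
#' @param step perpendicular sample spacing in px (<= 1; default 0.25).
#' @param half_width profile half-extent in px.
#' @return List with `profile` (mean across centerline points), `offsets`
#'   (signed px along the normal), `step`, and `n_valid` (contributing
#'   points per offset). Offsets sampling outside the frame are dropped from
#'   the average and flagged by reduced `n_valid`.
#' @export
cross_profile <- function(bfi_frame, centerline, step = 0.25, half_width) {
  if (step > 1) stop("`step` must be <= 1 px for sub-pixel sampling")
  pts <- centerline$points
  offsets <- seq(-half_width, half_width, by = step)
  nrm_r <- cos(pts$theta)                    # normal = tangent rotated 90deg
  nrm_c <- -sin(pts$theta)
  rs <- outer(pts$r, offsets, function(p, o) p) +
    outer(nrm_r, offsets)
  cs <- outer(pts$c, offsets, function(p, o) p) +
    outer(nrm_c, offsets)
  vals <- matrix(bilinear_interp(bfi_frame, as.vector(rs), as.vector(cs)),
                 nrow = nrow(pts))
  n_valid <- colSums(!is.na(vals))
  profile <- colMeans(vals, na.rm = TRUE)
  profile[n_valid == 0L] <- NA_real_
  list(profile = profile, offsets = offsets, step = step, n_valid = n_valid)
}

#' Classify a profile into vessel and background
#'
#' Exhaustive minimum within-class variance thresholding (Otsu's criterion
#' evaluated at every observed value): the threshold minimizing the weighted
#' sum of the two class variances is selected, ties broken toward the lower
#' threshold, and samples strictly above it form the foreground.
#'
#' @param profile numeric vector (length >= 4 after `NA` removal).
#' @return List with `threshold`, `foreground` (logical, `NA` where the
#'   profile is `NA`), and `within_class_var`.
#' @export
classify_profile <- function(profile) {
  x <- profile[is.finite(profile)]
  if (length(x) < 4L) stop("profile too short to classify")
  ux <- sort(unique(x))
  if (length(ux) < 2L) stop("degenerate profile: constant values")
  xs <- sort(x); n <- length(xs)
  cs <- cumsum(xs); cs2 <- cumsum(xs * xs)
  # split after the last occurrence of each candidate value (all but max)
  idx <- findInterval(ux[-length(ux)], xs)
  n1 <- idx; n2 <- n - idx
  v1 <- cs2[idx] / n1 - (cs[idx] / n1)^2
  v2 <- (cs2[n] - cs2[idx]) / n2 - ((cs[n] - cs[idx]) / n2)^2
  wcv <- (n1 * pmax(v1, 0) + n2 * pmax(v2, 0)) / n
  best <- which.min(wcv)                     # first minimum = lowest threshold
  thr <- ux[best]
  fg <- profile > thr
  list(threshold = thr, foreground = fg, within_class_var = wcv[best],
       class_means = c(bg = mean(x[x <= thr]), fg = mean(x[x > thr])))
}

#' Vessel diameter from a classified profile
#'
#' The diameter is the length of the longest contiguous foreground run times
#' the sample spacing (robust to side-branch bleed-in at the profile ends);
#' runs shorter than 2 samples are invalid. With `refine = TRUE` and the
#' profile supplied, the run edges are refined by linear interpolation to
#' the sub-sample position where the profile crosses `level` - by default
#' the classification threshold, but the midpoint of the two class means
#' (half-maximum convention, as in the line-scan wall refinement) gives an
#' edge estimate that does not inherit the threshold's class-imbalance
#' bias.
#'
#' @param foreground logical vector from [classify_profile()].
#' @param step sample spacing in px.
#' @param profile,threshold optional, enable sub-sample edge refinement.
#' @param level crossing level for edge refinement (default `threshold`).
#' @param refine logical (default `FALSE`).
#' @return List with `valid`, `d` (px), `run` (index range of the selected
#'   run), and `d_refined` when requested.
#' @export
diameter_from_mask <- function(foreground, step, profile = NULL,
                               threshold = NULL, level = threshold,
                               refine = FALSE) {
  fg <- !is.na(foreground) & foreground
  r <- rle(fg)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (length(runs) == 0L || max(r$lengths[runs]) < 2L)
    return(list(valid = FALSE, d = NA_real_, run = c(NA, NA)))
  best <- runs[which.max(r$lengths[runs])]
  i0 <- starts[best]; i1 <- ends[best]
  d <- (i1 - i0 + 1L) * step
  out <- list(valid = TRUE, d = d, run = c(i0, i1))
  if (refine) {
    if (is.null(profile) || is.null(level))
      stop("refinement needs `profile` and a crossing `level`")
    # supra-level sub-run nested in the supra-threshold run (level >=
    # threshold for the class-mean midpoint), edges interpolated to the
    # exact level crossings
    in_run <- i0:i1
    sup <- in_run[!is.na(profile[in_run]) & profile[in_run] >= level]
    if (length(sup) >= 2L) {
      j0 <- min(sup); j1 <- max(sup)
      xL <- (j0 - 1) * step
      if (j0 > 1L && is.finite(profile[j0 - 1L]) && profile[j0 - 1L] < level)
        xL <- xL - step * (profile[j0] - level) /
          (profile[j0] - profile[j0 - 1L])
      xR <- (j1 - 1) * step
      if (j1 < length(profile) && is.finite(profile[j1 + 1L]) &&
          profile[j1 + 1L] < level)
        xR <- xR + step * (profile[j1] - level) /
          (profile[j1] - profile[j1 + 1L])
      out$d_refined <- max(xR - xL, step)
    } else out$d_refined <- out$d
  }
  out
}

#' Fit a double-logistic vessel cross-section model to a profile
#'
#' Least-squares fit of
#' `P(x) = B + A * (plogis((x - c + w/2)/s) + plogis((c + w/2 - x)/s) - 1)`
#' - a lumen of width `w` centred at `c` with edge scale `s` on background
#' `B`. For vessels whose width is comparable to the imaging point-spread
#' function, threshold-crossing widths under-respond to true width changes
#' (the two edge spreads overlap, so the profile peak itself moves with
#' width); the model fit absorbs the edge spread into `s` and keeps `w`
#' amplitude-faithful.
#'
#' @param profile numeric vector (averaged cross-profile).
#' @param step sample spacing in px.
#' @param init list with starting values `c`, `w` (px; e.g. from
#'   [diameter_from_mask()]).
#' @return List with `w`, `center`, `s`, `B`, `A`, `converged`.
#' @export
fit_profile_width <- function(profile, step, init) {
  ok <- which(is.finite(profile))
  if (length(ok) < 8L) return(list(converged = FALSE))
  x <- (ok - 1) * step
  y <- profile[ok]
  model <- function(p) {
    p["B"] + p["A"] * (stats::plogis((x - p["c"] + p["w"] / 2) / p["s"]) +
                         stats::plogis((p["c"] + p["w"] / 2 - x) / p["s"]) - 1)
  }
  start <- c(B = min(y), A = diff(range(y)), c = init$c, w = init$w, s = 1)
  fit <- tryCatch(
    stats::optim(start, function(p) {
      if (p["w"] <= step || p["s"] <= 0.05) return(1e12)
      sum((y - model(p))^2)
    }, method = "Nelder-Mead",
    control = list(maxit = 2000, reltol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit) || fit$convergence != 0) return(list(converged = FALSE))
  p <- fit$par
  list(w = unname(p["w"]), center = unname(p["c"]), s = unname(p["s"]),
       B = unname(p["B"]), A = unname(p["A"]), converged = TRUE)
}

#' Trace a vessel's diameter and intra-vessel BFI over the cardiac cycle
#'
#' The centerline is estimated once from the phase-mean BFI image of the ROI
#' and held fixed; at every phase of the representative cycle the averaged
#' cross-sectional profile is re-evaluated, classified into vessel and
#' background, and reduced to a diameter and an intra-vessel mean BFI. The
#' diameter is the edge-model fit of [fit_profile_width()] (initialized
#' from the classified run), falling back to the sub-sample refined run
#' width when the fit does not converge.
#'
#' @param rep a per-pixel `representative_cycle`.
#' @param roi an [roi()] with label `"artery"` or `"vein"`.
#' @param step profile sampling step in px (default 0.25).
#' @param half_width profile half-extent in px; default 1.5 x the rough
#'   vessel width measured on the phase-mean image.
#' @param pixel_size_um optional calibration for `d_um`.
#' @param margin crop margin around the ROI bounding box in px (default 3).
#' @return A `vessel_trace`: data.frame `trace` (`phase`, `d_px`, `d_um`,
#'   `bfi`, `threshold`, `valid`) plus the centerline and ROI metadata.
#' @export
trace_vessel <- function(rep, roi, step = 0.25, half_width = NULL,
                         pixel_size_um = NA_real_, margin = 3L) {
  stopifnot(inherits(rep, "representative_cycle"), inherits(roi, "roi"))
  if (!roi$label %in% c("artery", "vein"))
    stop("trace_vessel() needs an artery or vein ROI")
  k <- rep$k_cycle
  if (is.null(dim(k)) || length(dim(k)) != 3L)
    stop("`rep` must hold a per-pixel cycle")
  d <- dim(k)
  mask <- roi_mask(roi, d[1:2])
  if (sum(mask) < 25L) stop("vessel ROI smaller than 25 px")
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  r0 <- max(1L, rows[1] - margin); r1 <- min(d[1], rows[2] + margin)
  c0 <- max(1L, cols[1] - margin); c1 <- min(d[2], cols[2] + margin)
  kc <- k[r0:r1, c0:c1, , drop = FALSE]
  bfi <- 1 / (kc * kc)
  bfi[!is.finite(bfi)] <- NA_real_
  mean_img <- apply(bfi, c(1, 2), mean)
  cl_img <- mean_img
  cl_img[!mask[r0:r1, c0:c1]] <- NA_real_   # centerline only from ROI pixels
  cl <- estimate_centerline(cl_img)

  if (is.null(half_width)) {
    pr0 <- cross_profile(mean_img, cl, step = step,
                         half_width = min(dim(mean_img)) / 2)
    cls0 <- classify_profile(pr0$profile)
    dm0 <- diameter_from_mask(cls0$foreground, step)
    rough <- if (isTRUE(dm0$valid)) dm0$d else min(dim(mean_img)) / 4
    half_width <- max(3, 1.5 * rough)      # half-extent = 1.5x rough width
  }

  np <- rep$n_phase
  tr <- data.frame(phase = rep$phase, d_px = NA_real_, d_um = NA_real_,
                   bfi = NA_real_, threshold = NA_real_, valid = FALSE)
  for (p in seq_len(np)) {
    pr <- cross_profile(bfi[, , p], cl, step = step, half_width = half_width)
    cls <- try(classify_profile(pr$profile), silent = TRUE)
    if (inherits(cls, "try-error")) next
    dm <- diameter_from_mask(cls$foreground, step, profile = pr$profile,
                             threshold = cls$threshold,
                             level = mean(cls$class_means), refine = TRUE)
    if (!isTRUE(dm$valid)) next
    # fit in contrast space (-K so the lumen is the bright phase): the
    # vessel edge is a smoothed logistic in K, whereas BFI = 1/K^2 skews it
    ft <- fit_profile_width(-1 / sqrt(pr$profile), step,
                            init = list(c = mean(dm$run - 1) * step,
                                        w = dm$d_refined))
    fit_ok <- isTRUE(ft$converged) &&
      abs(ft$w - dm$d_refined) < 0.5 * dm$d_refined
    tr$d_px[p] <- if (fit_ok) ft$w else dm$d_refined
    # intra-vessel BFI from the lumen core (central half of the width):
    # edge samples are partial-volume mixtures with the background and
    # would dilute the flow modulation
    ctr <- if (fit_ok) ft$center else mean(dm$run - 1) * step
    wd <- if (fit_ok) ft$w else dm$d_refined
    xs <- (seq_along(pr$profile) - 1) * step
    core <- which(abs(xs - ctr) <= wd / 4)
    if (length(core) < 2L) core <- dm$run[1]:dm$run[2]
    tr$bfi[p] <- mean(pr$profile[core], na.rm = TRUE)
    tr$threshold[p] <- cls$threshold
    tr$valid[p] <- TRUE
  }
  if (!is.na(pixel_size_um)) tr$d_um <- tr$d_px * pixel_size_um
  structure(list(trace = tr, centerline = cl, id = roi$id,
                 label = roi$label, step = step, half_width = half_width,
                 pixel_size_um = pixel_size_um),
            class = "vessel_trace")
}

#' Per-structure pulsatility summary
#'
#' Reduces a vessel trace (or a parenchymal ROI on the representative cycle)
#' to the four reported parameters: cycle-mean BFI, cycle-mean diameter
#' (vessels only), `PI_BFI = (BFI_max - BFI_min)/<BFI>`, and
#' `PI_D = (d_max - d_min)/<d>`. Parenchymal ROIs (vessel-free ~5000 px
#' regions) have no diameter: their per-phase BFI is the pixel mean over the
#' ROI.
#'
#' @param x a `vessel_trace`, or a per-pixel `representative_cycle` when
#'   summarizing a parenchyma ROI.
#' @param roi the parenchyma [roi()] (ignored for vessel traces).
#' @param area_tol fractional tolerance on the nominal 5000-px parenchyma
#'   area (default 0.1); violations warn, they do not error.
#' @return A one-row data.frame: `id`, `label`, `mean_bfi`, `mean_d_px`,
#'   `mean_d_um`, `pi_bfi`, `pi_d`, `n_valid_phases`.
#' @export
summarize_structure <- function(x, roi = NULL, area_tol = 0.1) {
  if (inherits(x, "vessel_trace")) {
    tr <- x$trace[x$trace$valid, , drop = FALSE]
    if (nrow(tr) < 2L) stop("fewer than 2 valid phases")
    return(data.frame(
      id = as.character(x$id), label = x$label,
      mean_bfi = mean(tr$bfi), mean_d_px = mean(tr$d_px),
      mean_d_um = if (is.na(x$pixel_size_um)) NA_real_ else mean(tr$d_um),
      pi_bfi = pulsatility_index(tr$bfi),
      pi_d = pulsatility_index(tr$d_px),
      n_valid_phases = nrow(tr), stringsAsFactors = FALSE))
  }
  if (inherits(x, "representative_cycle")) {
    stopifnot(inherits(roi, "roi"))
    if (roi$label != "parenchyma")
      stop("representative-cycle summaries are for parenchyma ROIs; ",
           "use trace_vessel() for vessels")
    k <- x$k_cycle
    d <- dim(k)
    mask <- roi_mask(roi, d[1:2])
    area <- sum(mask)
    if (abs(area - 5000) > area_tol * 5000)
      warning(sprintf("parenchyma ROI area %d px outside 5000 +/- %.0f%%",
                      area, 100 * area_tol))
    km <- matrix(k, nrow = d[1] * d[2])[as.vector(mask), , drop = FALSE]
    bfi <- 1 / (km * km)
    bfi[!is.finite(bfi)] <- NA_real_
    trace <- colMeans(bfi, na.rm = TRUE)
    if (sum(is.finite(trace)) < 2L) stop("fewer than 2 valid phases")
    return(data.frame(
      id = as.character(roi$id), label = "parenchyma",
      mean_bfi = mean(trace, na.rm = TRUE),
      mean_d_px = NA_real_, mean_d_um = NA_real_,
      pi_bfi = pulsatility_index(trace), pi_d = NA_real_,
      n_valid_phases = sum(is.finite(trace)), stringsAsFactors = FALSE))
  }
  stop("`x` must be a vessel_trace or representative_cycle")
}
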