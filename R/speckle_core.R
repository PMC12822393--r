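#' Construct an LSCI frame stack
#'
#' Bundles an intensity video with its acquisition metadata. Frames are held
#' as a 3-D array with dimensions `(row, col, frame)`; integer storage is
#' kept as-is (camera counts), which halves memory for long recordings.
#'
#' @param frames 3-D numeric or integer array `(row, col, frame)` of
#'   non-negative intensities, at least 2 frames.
#' @param fps acquisition frame rate in Hz (> 0).
#' @param exposure_us exposure time in microseconds, or `NA`.
#' @param pixel_size_um physical pixel size in micrometres, or `NA` when the
#'   magnification is uncalibrated.
#' @return A `frame_stack` object (list with `frames`, `fps`, `exposure_us`,
#'   `pixel_size_um`).
#' @export
frame_stack <- function(frames, fps, exposure_us = NA_real_,
                        pixel_size_um = NA_real_) {
  if (length(dim(frames)) != 3L)
    stop("`frames` must be a 3-D (row, col, frame) array")
  if (dim(frames)[3] < 2L) stop("a frame stack needs at least 2 frames")
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    stop("`fps` must be a single positive number")
  rng <- suppressWarnings(range(frames))
  if (!all(is.finite(rng)) || rng[1] < 0)
    stop("intensities must be finite and non-negative")
  structure(list(frames = frames, fps = fps,
                 exposure_us = as.numeric(exposure_us),
                 pixel_size_um = as.numeric(pixel_size_um)),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d x %d px, %d frames @ %.6g fps (%.3g s)\n",
              d[1], d[2], d[3], x$fps, d[3] / x$fps))
  invisible(x)
}

#' Spatial speckle contrast of a frame stack
#'
#' Computes the per-pixel spatial speckle contrast `K = sd(I)/mean(I)` over a
#' square sliding neighborhood (default 5 x 5) on every frame. The standard
#' deviation is the population (1/N) form, the convention in the LSCI
#' literature; the choice is fixed and documented, not configurable.
#'
#' `K` is computed only where the full window fits inside the frame; the
#' border band is `NA`. Windows with non-positive mean (e.g. all-zero
#' neighborhoods) give `NA`, never an error or an infinite value. When a
#' `mask` is supplied, pixels outside it are additionally set to `NA` (the
#' neighborhood statistics themselves always use the raw intensities).
#'
#' @param stack a [frame_stack()], or a bare 3-D `(row, col, frame)` array.
#' @param window odd integer neighborhood side, >= 3 (default 5).
#' @param mask optional logical matrix `(row, col)`; `TRUE` = analyzable.
#' @return A `contrast_stack`: list with `contrast` (3-D array of `K`, `NA`
#'   where undefined), `window`, and `fps`.
#' @export
spatial_contrast <- function(stack, window = 5L, mask = NULL) {
  frames <- if (inherits(stack, "frame_stack")) stack$frames else stack
  fps <- if (inherits(stack, "frame_stack")) stack$fps else NA_real_
  if (length(window) != 1L || is.na(window) || window %% 2 == 0 || window < 3)
    stop("`window` must be an odd integer >= 3")
  d <- dim(frames)
  if (window > min(d[1:2])) stop("`window` exceeds the image dimensions")
  k <- spatial_contrast_cpp(frames, as.integer(window))
  if (!is.null(mask)) {
    mask <- check_mask(mask, d[1:2])
    out_idx <- which(!mask)
    npx <- d[1] * d[2]
    for (i in seq_len(d[3])) k[out_idx + (i - 1) * npx] <- NA_real_
  }
  structure(list(contrast = k, window = as.integer(window), fps = fps),
            class = "contrast_stack")
}

check_mask <- function(mask, dim_rc) {
  if (is.null(dim(mask)) || !all(dim(mask) == dim_rc))
    stop("`mask` shape must match the frame shape")
  mask <- array(as.logical(mask), dim = dim_rc)
  if (!any(mask, na.rm = TRUE)) stop("`mask` selects no pixels")
  mask & !is.na(mask)
}

#' Convert speckle contrast to blood flow index
#'
#' `BFI = 1/K^2`, a relative perfusion index: faster flow blurs the speckle
#' pattern, lowering `K` and raising `BFI`. Undefined (`NA`) contrast
#' propagates; `K = 0` maps to `NA` (an infinite flow index is never emitted
#' as a finite number).
#'
#' @param contrast array (any shape) of contrast values `K`, or a
#'   `contrast_stack`.
#' @return Numeric array of the same shape with `BFI` values.
#' @export
contrast_to_bfi <- function(contrast) {
  k <- if (inherits(contrast, "contrast_stack")) contrast$contrast else contrast
  if (any(k < 0, na.rm = TRUE)) stop("contrast values must be >= 0")
  bfi <- 1 / (k * k)
  bfi[!is.finite(bfi)] <- NA_real_
  bfi
}

#' Whole-field mean contrast time course
#'
#' Averages the defined contrast values inside the mask for every frame,
#' producing the single refined time course on which cardiac cycles are
#' detected. A 600 s recording at 194 fps yields 116,400 points.
#'
#' @param contrast a `contrast_stack` from [spatial_contrast()].
#' @param mask optional logical matrix; defaults to all pixels.
#' @return A `contrast_timecourse`: list with `values` (one mean `K` per
#'   frame), `fps`, and `time_s`.
#' @export
field_mean_timecourse <- function(contrast, mask = NULL) {
  stopifnot(inherits(contrast, "contrast_stack"))
  k <- contrast$contrast
  d <- dim(k)
  idx <- if (!is.null(mask)) which(as.vector(check_mask(mask, d[1:2])))
         else NULL
  # frame-by-frame to avoid materializing a full reshaped copy of the stack
  values <- vapply(seq_len(d[3]), function(i) {
    f <- k[, , i]
    mean(if (is.null(idx)) f else f[idx], na.rm = TRUE)
  }, 0)
  if (anyNA(values) || any(!is.finite(values)))
    stop("some frames have no defined contrast inside the mask")
  contrast_timecourse(values, contrast$fps)
}

#' Construct a contrast time course
#'
#' @param values numeric vector of per-frame mask-averaged contrast.
#' @param fps frame rate in Hz.
#' @return A `contrast_timecourse` object.
#' @export
contrast_timecourse <- function(values, fps) {
  if (!is.numeric(values) || length(values) < 2L)
    stop("`values` must be a numeric vector of length >= 2")
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    stop("`fps` must be a single positive number")
  structure(list(values = as.numeric(values), fps = fps,
                 time_s = (seq_along(values) - 1) / fps),
            class = "contrast_timecourse")
}

#' @export
print.contrast_timecourse <- function(x, ...) {
  cat(sprintf("<contrast_timecourse> %d points @ %.6g fps (%.4g s), mean K = %.4g\n",
              length(x$values), x$fps, length(x$values) / x$fps,
              mean(x$values)))
  invisible(x)
}
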