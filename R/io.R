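#' Read an LSCI recording from disk
#'
#' Supports multi-page grayscale TIFF (8/16-bit or float) and raw binary
#' frame sequences with a sidecar JSON metadata file. Acquisition metadata
#' (`fps` above all) is never guessed: TIFF input requires it as an
#' argument or sidecar, raw input requires the sidecar fields
#' `{fps, width, height, dtype}` (`dtype` one of `"uint8"`, `"uint16"`,
#' `"float32"`, `"float64"`).
#'
#' @param path TIFF or raw binary file.
#' @param meta named list of metadata, or path to a sidecar JSON file;
#'   defaults to `<path>.json` when that file exists.
#' @param fps,exposure_us,pixel_size_um override/supply metadata directly.
#' @return A [frame_stack()].
#' @export
read_stack <- function(path, meta = NULL, fps = NULL, exposure_us = NULL,
                       pixel_size_um = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  meta <- resolve_meta(path, meta)
  fps <- fps %||% meta$fps
  if (is.null(fps)) stop("`fps` missing: supply it or a sidecar JSON")
  exposure_us <- exposure_us %||% meta$exposure_us %||% NA_real_
  pixel_size_um <- pixel_size_um %||% meta$pixel_size_um %||% NA_real_

  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    d <- dim(pages[[1]])
    frames <- array(0, dim = c(d[1], d[2], length(pages)))
    for (i in seq_along(pages)) frames[, , i] <- pages[[i]]
  } else {
    need <- c("width", "height", "dtype")
    if (!all(need %in% names(meta)))
      stop("raw input needs sidecar fields: ", paste(need, collapse = ", "))
    sz <- switch(meta$dtype, uint8 = 1L, uint16 = 2L, float32 = 4L,
                 float64 = 8L, stop("unknown dtype: ", meta$dtype))
    npx <- meta$width * meta$height
    nbytes <- file.size(path)
    n_frames <- nbytes / (npx * sz)
    expected <- meta$n_frames %||% NULL
    if (n_frames != round(n_frames) ||
        (!is.null(expected) && n_frames != expected) || n_frames < 2)
      stop(sprintf(
        "truncated file: %d bytes holds %.2f frames of %dx%d (expected %s)",
        nbytes, n_frames, meta$height, meta$width,
        if (is.null(expected)) "a whole number >= 2" else expected))
    con <- file(path, "rb"); on.exit(close(con))
    raw_v <- if (sz <= 2L)
      readBin(con, "integer", n = npx * n_frames, size = sz, signed = FALSE,
              endian = "little")
    else readBin(con, "double", n = npx * n_frames, size = sz,
                 endian = "little")
    # row-major frames (row scans) as written by write_stack
    frames <- aperm(array(raw_v, dim = c(meta$width, meta$height, n_frames)),
                    c(2, 1, 3))
  }
  frame_stack(frames, fps = fps, exposure_us = exposure_us,
              pixel_size_um = pixel_size_um)
}

resolve_meta <- function(path, meta) {
  if (is.character(meta)) return(jsonlite::read_json(meta, simplifyVector = TRUE))
  if (is.list(meta)) return(meta)
  side <- paste0(path, ".json")
  if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
  else list()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a frame stack to disk
#'
#' Integer stacks go to raw binary (`uint16`, row-major per frame) plus a
#' `<path>.json` sidecar; float data (e.g. contrast or BFI stacks) go to
#' multi-page 32-bit TIFF when `path` ends in `.tif`/`.tiff`.
#'
#' @param stack a [frame_stack()] or `contrast_stack`, or a bare 3-D array
#'   (then `fps` must be given).
#' @param path output file.
#' @param fps frame rate recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, fps = NULL) {
  frames <- if (inherits(stack, "frame_stack")) stack$frames
            else if (inherits(stack, "contrast_stack")) stack$contrast
            else stack
  fps <- fps %||% (if (is.list(stack)) stack$fps else NULL)
  d <- dim(frames)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    mx <- max(frames, na.rm = TRUE)
    pages <- lapply(seq_len(d[3]), function(i) {
      f <- frames[, , i]
      f[!is.finite(f)] <- 0
      f / max(mx, 1e-12)                  # writeTIFF expects [0,1]
    })
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
    meta <- list(fps = fps, width = d[2], height = d[1], n_frames = d[3],
                 dtype = "float32", scale = mx,
                 exposure_us = if (is.list(stack)) stack$exposure_us else NULL,
                 pixel_size_um = if (is.list(stack)) stack$pixel_size_um else NULL)
  } else {
    con <- file(path, "wb")
    v <- as.integer(aperm(frames, c(2, 1, 3)))
    writeBin(v, con, size = 2L, endian = "little")
    close(con)
    meta <- list(fps = fps, width = d[2], height = d[1], n_frames = d[3],
                 dtype = "uint16",
                 exposure_us = if (is.list(stack)) stack$exposure_us else NULL,
                 pixel_size_um = if (is.list(stack)) stack$pixel_size_um else NULL)
  }
  drop <- vapply(meta, function(x)
    is.null(x) || (length(x) == 1 && is.na(x)), TRUE)
  jsonlite::write_json(meta[!drop], paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a field mask from a PNG file
#'
#' Nonzero pixels are analyzable (`TRUE`).
#'
#' @param path PNG file (grayscale or RGB; first channel used).
#' @return Logical matrix.
#' @export
read_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img > 0
}

#' Write a field mask to a PNG file
#' @param mask logical matrix.
#' @param path output PNG.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask)), path)
  invisible(path)
}

#' Read ROIs from a JSON file
#'
#' The file holds a list of `{id, label, polygon: [[x, y], ...]}` objects,
#' 0-based with `x` = column (see [roi()]).
#'
#' @param path JSON file.
#' @return List of [roi()] objects.
#' @export
read_rois <- function(path) {
  raw_l <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw_l, function(r) {
    poly <- do.call(rbind, lapply(r$polygon, function(p)
      c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
    roi(r$id, r$label, poly)
  })
}

#' Write ROIs to a JSON file
#' @param rois list of [roi()] objects.
#' @param path output JSON.
#' @return `path`, invisibly.
#' @export
write_rois <- function(rois, path) {
  jsonlite::write_json(lapply(rois, function(r)
    list(id = r$id, label = r$label,
         polygon = lapply(seq_len(nrow(r$polygon)), function(i)
           as.numeric(r$polygon[i, ])))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a contrast time course to CSV
#'
#' Columns: `frame_index` (1-based), `time_s`, `mean_contrast`.
#'
#' @param tc a [contrast_timecourse()].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(tc, path) {
  write.csv(data.frame(frame_index = seq_along(tc$values),
                       time_s = tc$time_s, mean_contrast = tc$values),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a line scan from TIFF plus sidecar JSON
#'
#' @param path TIFF file (single page, space x time).
#' @param meta sidecar list or JSON path with `line_period_s` and optional
#'   `pixel_size_um`, `orientation_deg`, `id`; defaults to `<path>.json`.
#' @return A [line_scan()].
#' @export
read_linescan <- function(path, meta = NULL) {
  meta <- resolve_meta(path, meta)
  if (is.null(meta$line_period_s)) stop("`line_period_s` missing from sidecar")
  img <- tiff::readTIFF(path, as.is = TRUE)
  line_scan(img, meta$line_period_s,
            pixel_size_um = meta$pixel_size_um %||% NA_real_,
            orientation_deg = meta$orientation_deg %||% NA_real_,
            id = meta$id %||% basename(path))
}
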