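#' Assemble and validate a pipeline configuration
#'
#' Collects every stage parameter of the LSCI pulsatility pipeline in one
#' validated object. All parameters are checked here, before any
#' computation starts.
#'
#' @param input a [frame_stack()], or path to a recording readable by
#'   [read_stack()].
#' @param meta optional metadata (list or sidecar path) for [read_stack()].
#' @param mask logical matrix, path to a PNG mask, or `NULL` (whole field).
#' @param rois list of [roi()] objects or path to an ROI JSON file.
#' @param window contrast neighborhood side (odd, default 5).
#' @param interp_factor representative-cycle interpolation factor
#'   (default 4).
#' @param band_hz cardiac search band, Hz (default `c(5, 15)`).
#' @param variability_frac admissible heart-rate variability (default 0.3).
#' @param k_sd cycle rejection threshold in SD units (default 2).
#' @param max_spikes absolute noise-spike cap per cycle (default 2).
#' @param step profile sampling step, px (default 0.25).
#' @param pixel_size_um optional calibration.
#' @param min_cardiac_ratio minimum [cardiac_peak_ratio()] to accept that a
#'   cardiac component is present (default 50; genuine heartbeats score in
#'   the thousands, pure noise in single digits). Below it the recording is
#'   treated as having no measurable pulsatility: PI values are reported as
#'   0 and no cycle gating is attempted.
#' @param out_dir output directory, or `NULL` for in-memory results only.
#' @param seed optional RNG seed recorded in the provenance block (the
#'   analysis itself is deterministic).
#' @return A `run_config` list.
#' @export
run_config <- function(input, meta = NULL, mask = NULL, rois = NULL,
                       window = 5L, interp_factor = 4, band_hz = c(5, 15),
                       variability_frac = 0.3, k_sd = 2, max_spikes = 2L,
                       step = 0.25, pixel_size_um = NA_real_,
                       min_cardiac_ratio = 50, out_dir = NULL, seed = NULL) {
  if (window %% 2 == 0 || window < 3) stop("`window` must be odd, >= 3")
  if (interp_factor < 1) stop("`interp_factor` must be >= 1")
  if (!(band_hz[1] > 0 && band_hz[2] > band_hz[1]))
    stop("`band_hz` must be an increasing positive pair")
  if (!(variability_frac > 0 && variability_frac < 1))
    stop("`variability_frac` must lie in (0, 1)")
  if (step <= 0 || step > 1) stop("`step` must lie in (0, 1]")
  structure(list(input = input, meta = meta, mask = mask, rois = rois,
                 window = as.integer(window), interp_factor = interp_factor,
                 band_hz = band_hz, variability_frac = variability_frac,
                 k_sd = k_sd, max_spikes = as.integer(max_spikes),
                 step = step, pixel_size_um = pixel_size_um,
                 min_cardiac_ratio = min_cardiac_ratio,
                 out_dir = out_dir, seed = seed),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' YAML keys mirror the [run_config()] arguments; `input`, `mask` and
#' `rois` are file paths resolved relative to the YAML file.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(path)
  rel <- function(p) if (!is.null(p) && !file.exists(p) &&
                         file.exists(file.path(base, p)))
    file.path(base, p) else p
  args <- y
  for (f in c("input", "mask", "rois", "meta"))
    if (is.character(args[[f]])) args[[f]] <- rel(args[[f]])
  if (!is.null(args$band_hz)) args$band_hz <- as.numeric(args$band_hz)
  do.call(run_config, args)
}

#' Run the full LSCI pulsatility pipeline
#'
#' Executes, in order: spatial contrast, whole-field time course, dominant
#' cardiac frequency, cycle detection / feature screening, per-pixel
#' representative cycle, PI and mean-BFI maps, and per-ROI structure
#' summaries. Any stage failure aborts with a stage-named error. Identical
#' inputs and configuration produce identical outputs.
#'
#' @param config a [run_config()].
#' @return A `result_bundle`: list with `timecourse`, `f0_hz`, `cycles`,
#'   `rep_cycle`, `maps`, `structures` (data.frame), `qc`, and `provenance`.
#'   When `config$out_dir` is set, CSV/TIFF/JSON artifacts are also written
#'   there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  stack <- stage("read_stack",
                 if (inherits(config$input, "frame_stack")) config$input
                 else read_stack(config$input, meta = config$meta))
  mask <- config$mask
  if (is.character(mask)) mask <- stage("read_mask", read_mask(mask))
  rois <- config$rois
  if (is.character(rois)) rois <- stage("read_rois", read_rois(rois))

  contrast <- stage("spatial_contrast",
                    spatial_contrast(stack, config$window, mask))
  tc <- stage("field_mean_timecourse", field_mean_timecourse(contrast, mask))
  peak_ratio <- stage("cardiac_peak_ratio",
                      cardiac_peak_ratio(tc, config$band_hz))
  cardiac_detected <- peak_ratio >= config$min_cardiac_ratio

  if (cardiac_detected) {
    f0 <- stage("dominant_frequency", dominant_frequency(tc, config$band_hz))
    cycles <- stage("detect_cycles",
                    detect_cycles(tc, f0, config$variability_frac))
    cycles <- stage("cycle_features", cycle_features(tc, cycles))
    cycles <- stage("reject_cycles",
                    reject_cycles(cycles, config$k_sd, config$max_spikes))
    if (!any(cycles$cycles$accepted))
      stop("[reject_cycles] no cycles survived quality screening")
    rep <- stage("representative_cycle",
                 representative_cycle(contrast, cycles, config$interp_factor))
  } else {
    # no cardiac component: pulsatility is zero by measurement; summaries
    # and diameters come from a constant phase-mean "cycle"
    warning(sprintf(
      "no cardiac component detected (peak ratio %.1f < %.1f); PI = 0",
      peak_ratio, config$min_cardiac_ratio))
    f0 <- NA_real_
    cycles <- structure(list(cycles = data.frame(), f0 = NA_real_,
                             fps = tc$fps, status = "no_cardiac_component"),
                        class = "cycle_set")
    d <- dim(contrast$contrast)
    k_mean <- contrast$contrast[, , 1] * 0
    for (i in seq_len(d[3])) k_mean <- k_mean + contrast$contrast[, , i]
    k_mean <- k_mean / d[3]
    rep <- structure(list(k_cycle = array(rep(k_mean, 4),
                                          dim = c(d[1], d[2], 4)),
                          phase = seq(0, 1, length.out = 4), n_phase = 4L,
                          fps = tc$fps, f0 = NA_real_, n_cycles_used = 0L,
                          interpolation_factor = config$interp_factor),
                     class = "representative_cycle")
  }
  maps <- stage("pi_map", pi_map(rep))

  structures <- NULL
  if (!is.null(rois)) {
    rows <- lapply(rois, function(r) {
      stage(paste0("roi_", r$id),
            if (r$label == "parenchyma") summarize_structure(rep, r)
            else summarize_structure(
              trace_vessel(rep, r, step = config$step,
                           pixel_size_um = config$pixel_size_um)))
    })
    structures <- do.call(rbind, rows)
  }

  qc <- list(
    heart_rate_hz = f0,
    cardiac_peak_ratio = peak_ratio,
    cardiac_detected = cardiac_detected,
    n_frames = length(tc$values),
    n_cycles_detected = nrow(cycles$cycles),
    n_cycles_accepted = if (cardiac_detected) sum(cycles$cycles$accepted)
                        else 0L,
    acceptance_rate = if (cardiac_detected) mean(cycles$cycles$accepted)
                      else NA_real_,
    n_phase = rep$n_phase,
    interpolation_factor = config$interp_factor)

  prov <- list(package_version = as.character(utils::packageVersion("pulsemap")),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               seed = config$seed)

  bundle <- structure(list(timecourse = tc, f0_hz = f0, cycles = cycles,
                           rep_cycle = rep, maps = maps,
                           structures = structures, qc = qc,
                           provenance = prov),
                      class = "result_bundle")
  if (!is.null(config$out_dir)) write_bundle(bundle, config)
  bundle
}

#' @export
print.result_bundle <- function(x, ...) {
  cat(sprintf("<result_bundle> HR %.3g Hz, %d/%d cycles accepted, n_phase %d\n",
              x$f0_hz, x$qc$n_cycles_accepted, x$qc$n_cycles_detected,
              x$qc$n_phase))
  if (!is.null(x$structures)) print(x$structures)
  invisible(x)
}

write_bundle <- function(bundle, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  # config + hash for provenance cross-referencing
  cfg <- config[setdiff(names(config), c("input", "mask", "rois", "meta"))]
  jsonlite::write_json(cfg, p("config.json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  hash <- unname(tools::md5sum(p("config.json")))
  bundle$provenance$config_md5 <- hash

  write_timecourse(bundle$timecourse, p("timecourse.csv"))
  qc_tab <- bundle$cycles$cycles
  if (nrow(qc_tab)) {
    qc_tab$config_md5 <- hash
    write.csv(qc_tab, p("cycles_qc.csv"), row.names = FALSE)
  }
  for (nm in c("pi", "mean_bfi")) {
    img <- bundle$maps[[nm]]
    img[!is.finite(img)] <- 0
    tiff::writeTIFF(img / max(img, 1e-12), p(paste0(nm, ".tif")),
                    bits.per.sample = 32L)
  }
  if (!is.null(bundle$structures)) {
    st <- bundle$structures
    st$config_md5 <- hash
    write.csv(st, p("structures.csv"), row.names = FALSE)
  }
  jsonlite::write_json(c(bundle$provenance, bundle$qc), p("provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(bundle)
}
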