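#' Run the full analysis on a synthetic scene
#'
#' Convenience pipeline from a [synth_scene()] to the PV activation flow
#' metric: ground-truth activation times, normalised-derivative movie
#' rendered at the optical-flow lattice of one analysis window, optional
#' contact dropout, valve-spline duplication (9x8 arrangement), refinement
#' to the interpolated grid, Horn-Schunck flow, wavefront detection,
#' window averaging and PV-vector tagging.
#'
#' @param scene a [synth_scene()].
#' @param cfg an [analysis_config()].
#' @param duplicate_valve_spline use the 9x8 grid (default) or the plain
#'   8x8 grid.
#' @param dropout `NULL` or a list of arguments for [apply_dropout()]
#'   (e.g. `list(fraction = 0.25, seed = 7)`).
#' @param window_start_s start of the analysis window within the scene (s).
#' @param times optional precomputed [activation_times()] for the scene.
#' @param keep_fields also return the averaged field, wavefront mask and
#'   movie (for streamlines or inspection).
#' @return A `pv_flow_result`; with `keep_fields = TRUE`, a list
#'   `(result, avg, wavefronts, movie, raw_valid_mask)`.
#' @export
pv_flow_from_scene <- function(scene, cfg = analysis_config(),
                               duplicate_valve_spline = TRUE,
                               dropout = NULL, window_start_s = 0,
                               times = NULL, keep_fields = FALSE) {
  stopifnot(inherits(scene, "synth_scene"))
  cfg <- as_af_config(cfg)
  n_window <- round(cfg$window_s * scene$fs)
  start <- round(window_start_s * scene$fs)
  n_total <- round(scene$fs * scene$duration)
  if (n_window > n_total)
    stop("analysis window exceeds scene duration")
  # sub-sample rounding slack at the very end of the recording
  start <- min(start, n_total - n_window)
  lat <- flow_lattice(n_window, cfg$frame_increment_samples)
  # lattice frames plus the sample after each (leading-edge derivative)
  samp <- sort(unique(c(lat, lat + 1L)))
  samp <- samp[samp <= n_total - start]
  if (is.null(times)) times <- activation_times(scene)
  gm <- render_movie(times, scene, sample_idx = start + samp)
  gm$sample_idx <- gm$sample_idx - start
  if (!is.null(dropout)) gm <- do.call(apply_dropout, c(list(gm), dropout))
  raw_mask <- gm$valid_mask
  if (duplicate_valve_spline) gm <- duplicate_valve_row(gm, 1L)
  gmi <- interpolate_grid(gm)
  fields <- flow_sequence(gmi, cfg, n_samples = n_window)
  wf <- detect_wavefronts(gmi, cfg, n_samples = n_window)
  avg <- average_flow(fields, wf, cfg)
  res <- tag_pv_vectors(avg, cfg = cfg)
  if (!keep_fields) return(res)
  list(result = res, avg = avg, wavefronts = wf, movie = gmi,
       raw_valid_mask = gm$valid_mask, raw_mask_predup = raw_mask)
}

#' Run the full analysis on an electrogram recording
#'
#' Pipeline from raw unipolar electrograms to the PV activation flow metric:
#' QRS subtraction (when QRS times are available), derivative chain, grid
#' arrangement with optional valve-spline duplication, interpolation,
#' optical flow, wavefront averaging and PV-vector tagging. The first
#' `window_s` seconds (after `window_start_s`) are analysed.
#'
#' @param rec a [recording()].
#' @param cfg an [analysis_config()].
#' @param duplicate_valve_spline use the 9x8 grid (default).
#' @param window_start_s start of the analysis window (s).
#' @param keep_fields also return intermediate products.
#' @return A `pv_flow_result` (or a list when `keep_fields = TRUE`).
#' @export
pv_flow_from_recording <- function(rec, cfg = analysis_config(),
                                   duplicate_valve_spline = TRUE,
                                   window_start_s = 0, keep_fields = FALSE) {
  stopifnot(inherits(rec, "recording"))
  cfg <- as_af_config(cfg)
  n_window <- round(cfg$window_s * rec$fs)
  start <- round(window_start_s * rec$fs)
  if (start + n_window > ncol(rec$voltages))
    stop("analysis window exceeds recording duration")
  rec <- subtract_qrs(rec)
  win <- recording(rec$voltages[, (start + 1):(start + n_window),
                                drop = FALSE],
                   fs = rec$fs, chamber = rec$chamber, layout = rec$layout,
                   contact_mask = rec$contact_mask)
  ps <- derivative_chain(win, cfg)
  gm <- arrange_grid(ps, rec$layout, duplicate_valve_spline)
  gmi <- interpolate_grid(gm)
  fields <- flow_sequence(gmi, cfg, n_samples = n_window)
  wf <- detect_wavefronts(gmi, cfg, n_samples = n_window)
  avg <- average_flow(fields, wf, cfg)
  res <- tag_pv_vectors(avg, cfg = cfg)
  if (!keep_fields) return(res)
  list(result = res, avg = avg, wavefronts = wf, movie = gmi,
       raw_valid_mask = gm$valid_mask, processed = ps)
}
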