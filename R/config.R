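#' Analysis configuration
#'
#' Bundles every tunable threshold of the wavefront-analysis pipeline in one
#' place, with defaults matching the published methodology: optical flow at
#' an increment of 40 samples (about 20 ms at 2034.5 Hz), vector averaging
#' over 10 s windows, wavefronts as isolines of 0.9 normalised filtered
#' derivative with more than three connected pixels, a streamline angular
#' stopping criterion of 0.7 radians and minimum streamline spacing of
#' 0.5 pixels, and a 90-degree acceptance cone for PV-to-body flow.
#'
#' @param frame_increment_samples samples between the two frames of each
#'   optical-flow pair (default 40).
#' @param window_s length of the averaging window in seconds (default 10).
#' @param isoline_level normalised-derivative level defining wavefronts
#'   (default 0.9).
#' @param min_isoline_pixels minimum connected-component size kept as a
#'   wavefront; components smaller than this are discarded, so the default 4
#'   keeps components with strictly more than three pixels.
#' @param hs_alpha Horn-Schunck regularisation weight (default 1).
#' @param hs_iters Horn-Schunck Jacobi iteration count (default 100).
#' @param angular_stop_rad streamline tracing stops when consecutive step
#'   directions turn by more than this angle (default 0.7 rad).
#' @param min_streamline_spacing_px minimum distance between retained
#'   streamlines (default 0.5 px).
#' @param pv_cone_deg full width of the direction cone, centred on the
#'   inward grid axis, within which a vector counts as PV-to-body flow
#'   (default 90).
#' @param magnitude_rule rule for the magnitude threshold when tagging PV
#'   flow vectors; currently only `"mean_over_array"` (magnitude must exceed
#'   the mean over all valid pixels of the array).
#' @param bp_low,bp_high band-pass corner frequencies (Hz) applied to the
#'   differentiated electrogram (defaults 40 and 250).
#' @param lp_cut low-pass corner (Hz) applied after rectification
#'   (default 20).
#' @param min_peak_separation_ms minimum distance between detected
#'   activation peaks (default 50 ms).
#' @param min_peak_height minimum normalised-derivative height of a peak
#'   (default 0.5).
#' @param qrs_window_ms half-width of the QRS template window (default 60).
#' @param streamline_step_px Euler integration step for streamline tracing
#'   (default 0.25 px).
#' @param pv_box_col_frac,pv_box_row_frac fraction of columns (per side) and
#'   of central rows covered by each PV box (defaults 0.2 and 0.6).
#' @param pooled_box_denominator if `TRUE`, both PV box percentages use the
#'   pooled valid-pixel count of the two boxes as denominator instead of each
#'   box's own count.
#'
#' @return An object of class `af_config` (a named list).
#' @export
analysis_config <- function(frame_increment_samples = 40,
                            window_s = 10,
                            isoline_level = 0.9,
                            min_isoline_pixels = 4,
                            hs_alpha = 1,
                            hs_iters = 100,
                            angular_stop_rad = 0.7,
                            min_streamline_spacing_px = 0.5,
                            pv_cone_deg = 90,
                            magnitude_rule = "mean_over_array",
                            bp_low = 40,
                            bp_high = 250,
                            lp_cut = 20,
                            min_peak_separation_ms = 50,
                            min_peak_height = 0.5,
                            qrs_window_ms = 60,
                            streamline_step_px = 0.25,
                            pv_box_col_frac = 0.2,
                            pv_box_row_frac = 0.6,
                            pooled_box_denominator = FALSE) {
  cfg <- list(
    frame_increment_samples = frame_increment_samples,
    window_s = window_s,
    isoline_level = isoline_level,
    min_isoline_pixels = min_isoline_pixels,
    hs_alpha = hs_alpha,
    hs_iters = hs_iters,
    angular_stop_rad = angular_stop_rad,
    min_streamline_spacing_px = min_streamline_spacing_px,
    pv_cone_deg = pv_cone_deg,
    magnitude_rule = magnitude_rule,
    bp_low = bp_low,
    bp_high = bp_high,
    lp_cut = lp_cut,
    min_peak_separation_ms = min_peak_separation_ms,
    min_peak_height = min_peak_height,
    qrs_window_ms = qrs_window_ms,
    streamline_step_px = streamline_step_px,
    pv_box_col_frac = pv_box_col_frac,
    pv_box_row_frac = pv_box_row_frac,
    pooled_box_denominator = pooled_box_denominator
  )
  stopifnot(
    frame_increment_samples >= 1, window_s > 0,
    isoline_level > 0, isoline_level < 1,
    min_isoline_pixels >= 1, hs_alpha > 0, hs_iters >= 1,
    angular_stop_rad > 0, min_streamline_spacing_px > 0,
    pv_cone_deg > 0, pv_cone_deg <= 180,
    magnitude_rule == "mean_over_array",
    streamline_step_px > 0,
    pv_box_col_frac > 0, pv_box_col_frac <= 0.5,
    pv_box_row_frac > 0, pv_box_row_frac <= 1
  )
  structure(cfg, class = "af_config")
}

as_af_config <- function(cfg) {
  if (inherits(cfg, "af_config")) return(cfg)
  if (is.null(cfg)) return(analysis_config())
  do.call(analysis_config, cfg)
}

#' @export
print.af_config <- function(x, ...) {
  cat("<af_config>\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
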