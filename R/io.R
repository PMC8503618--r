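#' Read a recording from delimited text plus JSON metadata
#'
#' The interchange format is a plain-text numeric matrix (electrodes x
#' samples, whitespace- or comma-delimited) together with a JSON metadata
#' document containing at least `fs_hz`; optional fields are `chamber`,
#' `layout` (`spline_order`, `valve_spline`), `contact_mask` and
#' `qrs_times` (1-based sample indices).
#'
#' @param path path to the voltage matrix.
#' @param meta_path path to the JSON metadata (default: `path` with a
#'   `.json` extension appended).
#' @return A [recording()].
#' @export
read_recording <- function(path, meta_path = paste0(path, ".json")) {
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$fs_hz)) stop("metadata missing required field: fs_hz")
  volt <- as.matrix(read.table(path, sep = "", header = FALSE))
  dimnames(volt) <- NULL
  if (any(!is.finite(volt))) {
    badch <- which(apply(volt, 1, function(x) any(!is.finite(x))))
    stop("NaN/Inf voltages in channel(s): ", paste(badch, collapse = ", "))
  }
  layout <- if (!is.null(meta$layout))
    basket_layout(spline_order = meta$layout$spline_order %||% 1:8,
                  valve_spline = meta$layout$valve_spline %||% 1L,
                  chamber = meta$chamber %||% "LA")
  else basket_layout(chamber = meta$chamber %||% "LA")
  cm <- meta$contact_mask %||% rep(TRUE, nrow(volt))
  if (length(cm) != nrow(volt))
    stop("metadata field contact_mask has length ", length(cm),
         " but there are ", nrow(volt), " channels")
  recording(volt, fs = meta$fs_hz, chamber = meta$chamber %||% "LA",
            layout = layout, contact_mask = as.logical(cm),
            qrs_times = meta$qrs_times)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a recording to delimited text plus JSON metadata
#'
#' @param rec a [recording()].
#' @param path output path for the voltage matrix.
#' @param meta_path output path for the metadata JSON.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, meta_path = paste0(path, ".json")) {
  stopifnot(inherits(rec, "recording"))
  write.table(rec$voltages, path, row.names = FALSE, col.names = FALSE)
  meta <- list(fs_hz = rec$fs, chamber = rec$chamber,
               layout = list(spline_order = rec$layout$spline_order,
                             valve_spline = rec$layout$valve_spline),
               contact_mask = rec$contact_mask)
  if (!is.null(rec$qrs_times)) meta$qrs_times <- rec$qrs_times
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a scene description from JSON or YAML
#'
#' The document mirrors the fields of [synth_scene()] and [driver_spec()]:
#' `grid_shape`, `fs`, `duration`, `conduction_speed`, `noise_sd`,
#' `pulse_sd_ms`, `seed`, optional `qrs_artifact {period_ms, amplitude}`,
#' and `drivers`, a list of objects with `kind` and the driver fields.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` document.
#' @return A [synth_scene()].
#' @export
read_scene <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  drivers <- lapply(doc$drivers, function(d) {
    d <- as.list(d)
    do.call(driver_spec, d[!vapply(d, function(x) all(is.na(x)), TRUE)])
  })
  synth_scene(grid_shape = doc$grid_shape %||% c(8, 8),
              fs = doc$fs %||% 2034.5,
              duration = doc$duration %||% 12,
              drivers = drivers,
              conduction_speed = doc$conduction_speed %||% 0.1,
              noise_sd = doc$noise_sd %||% 0.05,
              qrs_artifact = doc$qrs_artifact,
              pulse_sd_ms = doc$pulse_sd_ms %||% 10,
              seed = doc$seed %||% 1L)
}

#' Write a PV flow result (with full configuration echo) as JSON
#'
#' Every output artifact embeds the resolved configuration so a run can be
#' audited and reproduced.
#'
#' @param res a `pv_flow_result`.
#' @param path output path.
#' @param cfg the [analysis_config()] used.
#' @return `path`, invisibly.
#' @export
write_pv_result <- function(res, path, cfg = analysis_config()) {
  stopifnot(inherits(res, "pv_flow_result"))
  out <- list(left_pct = res$left_pct, right_pct = res$right_pct,
              metric_pct = res$metric_pct,
              mean_magnitude = res$mean_magnitude,
              boxes = list(left = res$boxes$left[c("rows", "cols")],
                           right = res$boxes$right[c("rows", "cols")]),
              config = unclass(as_af_config(cfg)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write streamlines as JSON polylines
#'
#' @param ss a `streamline_set`.
#' @param path output path.
#' @param cfg the [analysis_config()] used.
#' @return `path`, invisibly.
#' @export
write_streamlines <- function(ss, path, cfg = analysis_config()) {
  stopifnot(inherits(ss, "streamline_set"))
  out <- list(
    spacing = ss$spacing,
    streamlines = lapply(ss$streamlines, function(sl)
      list(seed_id = sl$seed_id,
           points = unname(apply(sl$points, 1, function(p) c(p[1], p[2]),
                                 simplify = FALSE)),
           magnitudes = sl$mags)),
    config = unclass(as_af_config(cfg)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
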