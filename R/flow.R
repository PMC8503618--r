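#' Horn-Schunck optical flow between two frames
#'
#' Classical Horn-Schunck estimation of the dense displacement field that
#' carries `frame_a` into `frame_b`: spatial and temporal intensity
#' derivatives from the 4-point cube stencils, a global smoothness prior
#' weighted by `hs_alpha`, and `hs_iters` Jacobi iterations from a zero
#' initial field. Invalid pixels carry zero flow and are excluded from the
#' smoothness neighbourhood averages (the weights of missing neighbours are
#' renormalised, a Neumann condition that also applies at grid borders).
#'
#' @param frame_a,frame_b numeric matrices of the same shape with values in
#'   `[0, 1]`.
#' @param cfg an [analysis_config()] (uses `hs_alpha`, `hs_iters`).
#' @param valid_mask logical matrix; defaults to all valid.
#' @return A `flow_field` object with `u` (displacement along columns,
#'   +right) and `v` (along rows, +down) in pixels, plus the mask.
#' @export
horn_schunck <- function(frame_a, frame_b, cfg = analysis_config(),
                         valid_mask = NULL) {
  cfg <- as_af_config(cfg)
  if (!all(dim(frame_a) == dim(frame_b))) stop("frame shape mismatch")
  if (is.null(valid_mask)) valid_mask <- matrix(TRUE, nrow(frame_a),
                                                ncol(frame_a))
  res <- .hs_flow_cpp(frame_a, frame_b, cfg$hs_alpha,
                      as.integer(cfg$hs_iters), valid_mask)
  structure(list(u = res$u, v = res$v, valid_mask = valid_mask,
                 frame_time = NA_real_),
            class = "flow_field")
}

# 1-based sample indices of the optical-flow lattice for a window of
# n_samples at the configured increment: frames at inc, 2*inc, ...,
# floor(n/inc)*inc; flow is computed between consecutive lattice frames,
# giving floor(n/inc) - 1 fields.
flow_lattice <- function(n_samples, increment) {
  seq.int(increment, n_samples, by = increment)
}

#' Optical flow along a grid movie
#'
#' Computes Horn-Schunck flow between consecutive frames of the analysis
#' lattice: frames at sample indices `k * frame_increment_samples` within
#' the window. At the default 40-sample increment and 2034.5 Hz this is one
#' flow field per ~20 ms; a 10 s window yields
#' `floor(10 * 2034.5 / 40) - 1 = 507` fields.
#'
#' @param gm an interpolated `grid_movie`. The movie may store only the
#'   lattice frames (see `sample_idx`), as produced by windowed rendering.
#' @param cfg an [analysis_config()].
#' @param n_samples total samples in the analysis window (defaults to the
#'   largest stored sample index).
#' @return A list of `flow_field` objects, each with `frame_time` (s) of its
#'   first frame, plus attribute `lattice` (the sample indices used).
#' @export
flow_sequence <- function(gm, cfg = analysis_config(), n_samples = NULL) {
  stopifnot(inherits(gm, "grid_movie"))
  cfg <- as_af_config(cfg)
  if (gm$grid_kind != "interpolated")
    warning("flow is normally computed on the interpolated grid")
  if (is.null(n_samples)) n_samples <- max(gm$sample_idx)
  lat <- flow_lattice(n_samples, cfg$frame_increment_samples)
  if (length(lat) < 2)
    stop("window shorter than one frame increment; no flow pairs")
  pos <- match(lat, gm$sample_idx)
  if (any(is.na(pos)))
    stop("movie does not contain all lattice frames; render with sample_idx ",
         "covering the flow lattice")
  fields <- vector("list", length(lat) - 1)
  for (k in seq_len(length(lat) - 1)) {
    fa <- gm$frames[pos[k], , ]
    fb <- gm$frames[pos[k + 1], , ]
    ff <- horn_schunck(fa, fb, cfg, gm$valid_mask)
    ff$frame_time <- (lat[k] - 1) / gm$fs
    fields[[k]] <- ff
  }
  attr(fields, "lattice") <- lat
  fields
}
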