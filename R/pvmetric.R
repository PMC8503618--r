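#' Default PV assessment boxes on the interpolated LA grid
#'
#' Each pulmonary-vein box spans the outermost fraction of columns on its
#' side of the grid (default 20%) and the central fraction of rows (default
#' 60%); the inward direction points towards the grid centre along the
#' column axis.
#'
#' @param grid_shape `(rows, cols)` of the interpolated grid.
#' @param cfg an [analysis_config()] (`pv_box_col_frac`, `pv_box_row_frac`).
#' @return A `pv_boxes` object: for each of `left` and `right`, the
#'   inclusive `rows`/`cols` index ranges and the inward unit direction
#'   `(u, v)` (column/row components).
#' @export
default_pv_boxes <- function(grid_shape, cfg = analysis_config()) {
  cfg <- as_af_config(cfg)
  R <- grid_shape[1]; C <- grid_shape[2]
  nbc <- floor(cfg$pv_box_col_frac * C)
  nbr <- floor(cfg$pv_box_row_frac * R)
  if (nbc < 1 || nbr < 1) stop("grid too small for nonempty PV boxes")
  r0 <- floor((R - nbr) / 2) + 1
  rows <- r0:(r0 + nbr - 1)
  structure(list(
    left = list(rows = rows, cols = 1:nbc, inward = c(1, 0)),
    right = list(rows = rows, cols = (C - nbc + 1):C, inward = c(-1, 0)),
    grid_shape = grid_shape), class = "pv_boxes")
}

# tag vectors of one box; returns list(pct, tagged, n_valid)
tag_box <- function(avg, box, mean_mag, cos_half) {
  u <- avg$u_avg[box$rows, box$cols, drop = FALSE]
  v <- avg$v_avg[box$rows, box$cols, drop = FALSE]
  ok <- avg$valid_mask[box$rows, box$cols, drop = FALSE]
  mag <- sqrt(u^2 + v^2)
  # angle between vector and inward axis within half-cone
  dot <- u * box$inward[1] + v * box$inward[2]
  aligned <- dot >= cos_half * mag & mag > 0
  tagged <- ok & (mag > mean_mag) & aligned
  n_valid <- sum(ok)
  list(pct = if (n_valid) 100 * sum(tagged) / n_valid else NA_real_,
       tagged = tagged, n_valid = n_valid, n_tagged = sum(tagged))
}

#' PV activation flow metric
#'
#' Tags vectors inside the left and right PV boxes as PV-antra-to-LA-body
#' activation flow when (a) their magnitude exceeds the mean magnitude over
#' all valid pixels of the array (a repeatability threshold) and (b) their
#' direction lies within a 90-degree cone centred on the inward direction of
#' the box. Each box's percentage is the tagged fraction of its valid
#' pixels, and the headline PV activation flow metric is the maximum of the
#' left and right percentages.
#'
#' @param avg an `averaged_flow` field on the interpolated LA grid.
#' @param boxes a `pv_boxes` object (default boxes for the field's shape).
#' @param cfg an [analysis_config()].
#' @return A `pv_flow_result`: `left_pct`, `right_pct`, `metric_pct`,
#'   per-box tag masks, `mean_magnitude`, and the boxes used.
#' @export
tag_pv_vectors <- function(avg, boxes = NULL, cfg = analysis_config()) {
  stopifnot(inherits(avg, "averaged_flow"))
  cfg <- as_af_config(cfg)
  if (is.null(boxes)) boxes <- default_pv_boxes(dim(avg$u_avg), cfg)
  mag <- sqrt(avg$u_avg^2 + avg$v_avg^2)
  mean_mag <- mean(mag[avg$valid_mask])
  cos_half <- cos(cfg$pv_cone_deg / 2 * pi / 180)
  left <- tag_box(avg, boxes$left, mean_mag, cos_half)
  right <- tag_box(avg, boxes$right, mean_mag, cos_half)
  if (left$n_valid == 0 && right$n_valid == 0)
    stop("both PV boxes contain zero valid pixels")
  if (cfg$pooled_box_denominator) {
    pooled <- left$n_valid + right$n_valid
    left$pct <- if (left$n_valid) 100 * left$n_tagged / pooled else NA_real_
    right$pct <- if (right$n_valid) 100 * right$n_tagged / pooled else NA_real_
  }
  metric <- max(c(left$pct, right$pct), na.rm = TRUE)
  structure(list(left_pct = left$pct, right_pct = right$pct,
                 metric_pct = metric,
                 tagged = list(left = left$tagged, right = right$tagged),
                 mean_magnitude = mean_mag, boxes = boxes),
            class = "pv_flow_result")
}

#' @export
print.pv_flow_result <- function(x, ...) {
  cat(sprintf("<pv_flow_result> left %.1f%%, right %.1f%%, metric %.1f%%\n",
              x$left_pct, x$right_pct, x$metric_pct))
  invisible(x)
}
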