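#' Detect activation wavefronts on the analysis lattice
#'
#' For every analysed frame pair, the wavefront is the leading edge of the
#' super-level set of the normalised filtered derivative: pixels at or above
#' `isoline_level` (default 0.9) that border the set (at least one 4-neighbour
#' below level, invalid, or off-grid) and whose temporal derivative is
#' positive (leading edge, as opposed to the wave back; the derivative is
#' taken over one sample, at the first frame of the pair). 8-connected
#' components with fewer than `min_isoline_pixels` pixels (default:
#' components of three or fewer pixels) are discarded. The movie must
#' therefore contain, for every analysed lattice frame, also the frame one
#' sample later.
#'
#' @param gm an interpolated `grid_movie`.
#' @param cfg an [analysis_config()].
#' @param n_samples total samples in the analysis window (defaults to the
#'   largest stored sample index).
#' @return A `wavefront_mask` object: `mask` is a logical array
#'   `pairs x rows x cols`, `labels` an integer array of component labels.
#' @export
detect_wavefronts <- function(gm, cfg = analysis_config(), n_samples = NULL) {
  stopifnot(inherits(gm, "grid_movie"))
  cfg <- as_af_config(cfg)
  if (is.null(n_samples)) n_samples <- max(gm$sample_idx)
  lat <- flow_lattice(n_samples, cfg$frame_increment_samples)
  pos <- match(lat, gm$sample_idx)
  posd <- match(lat + 1L, gm$sample_idx)
  n_pairs <- length(lat) - 1
  if (any(is.na(pos[seq_len(n_pairs)])))
    stop("movie does not contain all lattice frames")
  if (any(is.na(posd[seq_len(n_pairs)])))
    stop("movie must also contain the sample after each lattice frame ",
         "(for the leading-edge temporal derivative)")
  d <- dim(gm$frames)[2:3]
  mask <- array(FALSE, dim = c(n_pairs, d[1], d[2]))
  labels <- array(0L, dim = c(n_pairs, d[1], d[2]))
  vm <- gm$valid_mask
  for (k in seq_len(n_pairs)) {
    a <- gm$frames[pos[k], , ]
    b <- gm$frames[posd[k], , ]
    s <- (a >= cfg$isoline_level) & vm
    if (!any(s)) next
    inner <- shift_and(s, vm)   # pixels whose 4-neighbourhood is fully in set
    boundary <- s & !inner
    leading <- (b - a) > 0
    m <- boundary & leading
    if (!any(m)) next
    lab <- .label8_cpp(m)
    sizes <- tabulate(lab)
    small <- which(sizes < cfg$min_isoline_pixels)
    if (length(small)) {
      m[lab %in% small] <- FALSE
      lab[lab %in% small] <- 0L
    }
    mask[k, , ] <- m
    labels[k, , ] <- lab
  }
  structure(list(mask = mask, labels = labels, lattice = lat),
            class = "wavefront_mask")
}

# TRUE where all four 4-neighbours exist, are valid and are in the set.
shift_and <- function(s, vm) {
  R <- nrow(s); C <- ncol(s)
  inset <- s & vm
  up <- rbind(matrix(FALSE, 1, C), inset[-R, , drop = FALSE])
  dn <- rbind(inset[-1, , drop = FALSE], matrix(FALSE, 1, C))
  lf <- cbind(matrix(FALSE, R, 1), inset[, -C, drop = FALSE])
  rt <- cbind(inset[, -1, drop = FALSE], matrix(FALSE, R, 1))
  up & dn & lf & rt
}

#' Average optical flow vectors at wavefront pixels over a window
#'
#' Per pixel, the vector sum of the flow vectors over all analysed frames in
#' which the pixel belongs to a wavefront, divided by the number of analysed
#' frames in the window. The magnitude of the averaged vector therefore
#' encodes both directional repeatability and how often the pixel is
#' activated: coherent repeated directions accumulate, incoherent ones
#' cancel.
#'
#' @param fields list of `flow_field` objects from [flow_sequence()].
#' @param wf a `wavefront_mask` from [detect_wavefronts()], frame-aligned
#'   with `fields`.
#' @param cfg an [analysis_config()].
#' @return An `averaged_flow` object with `u_avg`, `v_avg`,
#'   `contribution_count`, `n_frames`, `valid_mask`.
#' @export
average_flow <- function(fields, wf, cfg = analysis_config()) {
  stopifnot(inherits(wf, "wavefront_mask"))
  n <- length(fields)
  if (n == 0) stop("window contains zero analysed frames")
  if (dim(wf$mask)[1] != n)
    stop("wavefront mask and flow fields are not frame-aligned")
  d <- dim(fields[[1]]$u)
  u <- matrix(0, d[1], d[2])
  v <- matrix(0, d[1], d[2])
  cnt <- matrix(0L, d[1], d[2])
  for (k in seq_len(n)) {
    m <- wf$mask[k, , ]
    u <- u + fields[[k]]$u * m
    v <- v + fields[[k]]$v * m
    cnt <- cnt + m
  }
  structure(list(u_avg = u / n, v_avg = v / n, contribution_count = cnt,
                 n_frames = n, valid_mask = fields[[1]]$valid_mask),
            class = "averaged_flow")
}

#' @export
print.averaged_flow <- function(x, ...) {
  mag <- sqrt(x$u_avg^2 + x$v_avg^2)
  cat(sprintf("<averaged_flow> %dx%d over %d frames, mean |v| = %.4g px\n",
              nrow(x$u_avg), ncol(x$u_avg), x$n_frames,
              mean(mag[x$valid_mask])))
  invisible(x)
}
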