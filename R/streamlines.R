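#' Triangulate recording points and return seed centroids
#'
#' Builds a triangular mesh over the recording points (raw grid nodes) and
#' returns one streamline seed per mesh element (the triangle centroid). On
#' the regular electrode lattice each unit cell splits into two triangles
#' along its main diagonal; because the four corners of a lattice cell are
#' cocircular this split is a valid Delaunay triangulation of the points.
#' Cells with an invalid corner contribute at most the triangle of their
#' three valid corners.
#'
#' @param points numeric matrix `n x 2` of `(row, col)` node positions on
#'   the integer lattice, or a raw `grid_movie` (its valid nodes are used).
#' @return A list with `triangles` (list of 3x2 vertex matrices) and `seeds`
#'   (matrix of centroids, one row per element).
#' @export
triangulate_seeds <- function(points) {
  if (inherits(points, "grid_movie")) {
    vm <- points$valid_mask
  } else {
    points <- as.matrix(points)
    if (nrow(points) < 3) stop("need at least 3 points to triangulate")
    if (length(unique(points[, 1])) == 1 || length(unique(points[, 2])) == 1)
      stop("points are collinear")
    if (any(abs(points - round(points)) > 1e-9))
      stop("recording points must lie on the integer grid lattice")
    R <- max(points[, 1]); C <- max(points[, 2])
    vm <- matrix(FALSE, R, C)
    vm[cbind(round(points[, 1]), round(points[, 2]))] <- TRUE
  }
  tri <- triangulate_valid_nodes(vm)
  if (!length(tri)) stop("no complete cells to triangulate")
  seeds <- t(vapply(tri, colMeans, numeric(2)))
  colnames(seeds) <- c("row", "col")
  list(triangles = tri, seeds = seeds)
}

# Bilinear interpolation of the averaged field at continuous (row, col);
# returns c(u, v) or NULL if the 2x2 support is not fully valid / in grid.
field_at <- function(avg, p) {
  R <- nrow(avg$u_avg); C <- ncol(avg$u_avg)
  i <- floor(p[1]); j <- floor(p[2])
  if (i < 1 || j < 1 || i + 1 > R || j + 1 > C) {
    # allow points exactly on the far border
    if (p[1] >= 1 && p[1] <= R && p[2] >= 1 && p[2] <= C) {
      i <- min(i, R - 1); j <- min(j, C - 1)
    } else return(NULL)
  }
  if (!(avg$valid_mask[i, j] && avg$valid_mask[i + 1, j] &&
        avg$valid_mask[i, j + 1] && avg$valid_mask[i + 1, j + 1]))
    return(NULL)
  fy <- p[1] - i; fx <- p[2] - j
  w <- c((1 - fy) * (1 - fx), fy * (1 - fx), (1 - fy) * fx, fy * fx)
  idx <- cbind(c(i, i + 1, i, i + 1), c(j, j, j + 1, j + 1))
  c(sum(w * avg$u_avg[idx]), sum(w * avg$v_avg[idx]))
}

# One branch of a streamline from p0 in direction sign s (+1/-1). The
# angular stopping criterion compares the current step direction with the
# direction one pixel of arc length earlier (a lagged step pair): with small
# Euler steps on a bilinearly interpolated field a sharp corner unfolds over
# about one pixel, so a strictly consecutive-step comparison could never
# reach the stopping angle; for steps >= 1 px the lag reduces to the plain
# consecutive-step comparison.
trace_branch <- function(p0, avg, cfg, s, eps_mag, max_len) {
  h <- cfg$streamline_step_px
  lag <- max(1L, round(1 / h))
  n_max <- ceiling(max_len / h) + 1
  pts <- matrix(NA_real_, n_max, 2)
  mags <- numeric(n_max)
  dirs <- matrix(NA_real_, n_max + 1, 2)
  p <- p0
  k <- 0
  len <- 0
  repeat {
    f <- field_at(avg, p)
    if (is.null(f)) break
    m <- sqrt(sum(f^2))
    if (m < eps_mag) break
    dir <- s * f / m
    nd <- k + 1
    dirs[nd, ] <- dir
    if (nd > lag) {
      cosang <- sum(dir * dirs[nd - lag, ])
      if (acos(max(-1, min(1, cosang))) > cfg$angular_stop_rad) break
    }
    # step: dir is (u, v) = (dcol, drow)
    p_new <- c(p[1] + h * dir[2], p[2] + h * dir[1])
    k <- k + 1
    pts[k, ] <- p_new
    mags[k] <- m
    len <- len + h
    if (len >= max_len) break
    p <- p_new
  }
  list(pts = pts[seq_len(k), , drop = FALSE], mags = mags[seq_len(k)])
}

#' Trace one streamline through the averaged flow field
#'
#' Fixed-step Euler integration of the normalised field direction from the
#' seed, forward then backward, concatenated. A branch stops when it leaves
#' the valid region, when the local field magnitude falls below 1e-6 of the
#' field maximum, when the turn of the step direction over one pixel of arc
#' length exceeds the angular stopping criterion (default 0.7 rad; for steps
#' of 1 px or more this is the turn between consecutive steps), or at a
#' length cap of four grid diagonals.
#'
#' @param seed numeric `(row, col)` in interpolated-grid coordinates.
#' @param avg an `averaged_flow` field.
#' @param cfg an [analysis_config()].
#' @return A `streamline`: list with `points` (n x 2, row/col), `mags`
#'   (field magnitude at each point), or an empty polyline if the field
#'   vanishes at the seed.
#' @export
trace_streamline <- function(seed, avg, cfg = analysis_config()) {
  cfg <- as_af_config(cfg)
  mag <- sqrt(avg$u_avg^2 + avg$v_avg^2)
  eps_mag <- 1e-6 * max(mag)
  f0 <- field_at(avg, seed)
  if (is.null(f0) || sqrt(sum(f0^2)) < eps_mag || max(mag) == 0)
    return(structure(list(points = matrix(numeric(0), 0, 2),
                          mags = numeric(0)), class = "streamline"))
  diag_len <- sqrt(nrow(avg$u_avg)^2 + ncol(avg$u_avg)^2)
  max_len <- 4 * diag_len
  fwd <- trace_branch(seed, avg, cfg, +1, eps_mag, max_len)
  bwd <- trace_branch(seed, avg, cfg, -1, eps_mag, max_len)
  m0 <- sqrt(sum(f0^2))
  pts <- rbind(bwd$pts[rev(seq_len(nrow(bwd$pts))), , drop = FALSE],
               matrix(seed, 1, 2), fwd$pts)
  mags <- c(rev(bwd$mags), m0, fwd$mags)
  structure(list(points = pts, mags = mags), class = "streamline")
}

streamline_length <- function(sl) {
  n <- nrow(sl$points)
  if (n < 2) return(0)
  sum(sqrt(rowSums((sl$points[-1, , drop = FALSE] -
                      sl$points[-n, , drop = FALSE])^2)))
}

#' Select streamlines by length with a minimum spacing criterion
#'
#' Sorts candidate streamlines by decreasing arc length (ties broken by
#' ascending seed id) and greedily retains a streamline only if every one of
#' its points is at least `min_streamline_spacing_px` (default 0.5 px) from
#' all previously retained streamlines.
#'
#' @param traces list of `streamline` objects.
#' @param cfg an [analysis_config()].
#' @return A `streamline_set`: retained streamlines, each with `seed_id`,
#'   plus the spacing used.
#' @export
select_streamlines <- function(traces, cfg = analysis_config()) {
  cfg <- as_af_config(cfg)
  spacing <- cfg$min_streamline_spacing_px
  lens <- vapply(traces, streamline_length, 0)
  ord <- order(-lens, seq_along(traces))
  cell <- spacing
  hash <- new.env(hash = TRUE, parent = emptyenv())
  key <- function(cy, cx) paste0(cy, ",", cx)
  add_points <- function(pts) {
    for (i in seq_len(nrow(pts))) {
      cy <- floor(pts[i, 1] / cell); cx <- floor(pts[i, 2] / cell)
      k <- key(cy, cx)
      hash[[k]] <- rbind(if (!is.null(hash[[k]])) hash[[k]], pts[i, ])
    }
  }
  far_enough <- function(pts) {
    for (i in seq_len(nrow(pts))) {
      cy <- floor(pts[i, 1] / cell); cx <- floor(pts[i, 2] / cell)
      for (dy in -1:1) for (dx in -1:1) {
        q <- hash[[key(cy + dy, cx + dx)]]
        if (is.null(q)) next
        d2 <- (q[, 1] - pts[i, 1])^2 + (q[, 2] - pts[i, 2])^2
        if (any(d2 < spacing^2)) return(FALSE)
      }
    }
    TRUE
  }
  kept <- list()
  for (id in ord) {
    sl <- traces[[id]]
    if (nrow(sl$points) < 2) next
    if (far_enough(sl$points)) {
      sl$seed_id <- id
      kept[[length(kept) + 1]] <- sl
      add_points(sl$points)
    }
  }
  structure(list(streamlines = kept, spacing = spacing), class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  cat(sprintf("<streamline_set> %d streamlines (spacing %.2f px)\n",
              length(x$streamlines), x$spacing))
  invisible(x)
}

#' Build the preferential-pathway streamline set for an averaged field
#'
#' Seeds one streamline per element of the triangulated recording-point
#' mesh, traces all of them, and applies the length-ordered spacing
#' selection.
#'
#' @param avg an `averaged_flow` field on the interpolated grid.
#' @param raw_valid_mask logical matrix of valid raw nodes (splines x
#'   electrodes) used to build the seeding mesh.
#' @param cfg an [analysis_config()].
#' @return A `streamline_set`.
#' @export
build_streamlines <- function(avg, raw_valid_mask, cfg = analysis_config()) {
  cfg <- as_af_config(cfg)
  ts <- triangulate_seeds_mask(raw_valid_mask)
  # raw node (i, j) sits at interpolated coordinate (3i - 2, 3j - 2)
  seeds <- 3 * ts$seeds - 2
  traces <- lapply(seq_len(nrow(seeds)), function(k)
    trace_streamline(seeds[k, ], avg, cfg))
  select_streamlines(traces, cfg)
}

# triangulate directly from a validity mask (internal variant)
triangulate_seeds_mask <- function(vm) {
  tri <- triangulate_valid_nodes(vm)
  if (!length(tri)) stop("no complete cells to triangulate")
  seeds <- t(vapply(tri, colMeans, numeric(2)))
  colnames(seeds) <- c("row", "col")
  list(triangles = tri, seeds = seeds)
}

#' Plot a streamline set
#'
#' Thin rendering helper: draws each retained streamline with line width
#' proportional to the mean underlying field magnitude and an arrowhead at
#' its centre point.
#'
#' @param x a `streamline_set`.
#' @param grid_shape `(rows, cols)` of the field, for axis limits.
#' @param ... passed to [graphics::plot()].
#' @export
plot_streamlines <- function(x, grid_shape, ...) {
  graphics::plot(NA, xlim = c(1, grid_shape[2]), ylim = c(grid_shape[1], 1),
                 xlab = "col", ylab = "row", asp = 1, ...)
  if (!length(x$streamlines)) return(invisible(x))
  mmax <- max(vapply(x$streamlines, function(s) max(s$mags), 0))
  for (sl in x$streamlines) {
    w <- 0.5 + 2.5 * mean(sl$mags) / mmax
    graphics::lines(sl$points[, 2], sl$points[, 1], lwd = w)
    n <- nrow(sl$points)
    if (n >= 2) {
      mid <- max(2, round(n / 2))
      graphics::arrows(sl$points[mid - 1, 2], sl$points[mid - 1, 1],
                       sl$points[mid, 2], sl$points[mid, 1],
                       length = 0.05, lwd = w)
    }
  }
  invisible(x)
}
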