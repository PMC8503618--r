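#' Basket-catheter layout
#'
#' Describes how the 64 electrodes of an 8-spline x 8-electrode basket map
#' onto the 2D anatomical grid. Grid rows are splines (top row = anterior
#' mitral-valve spline for the LA) and grid columns are electrode positions
#' along each spline (left = lateral / left-PV side, right = septal /
#' right-PV side). The spline arrangement is case-by-case clinically, so it
#' is carried here as an explicit permutation.
#'
#' @param spline_order integer permutation of `1:8`; `spline_order[r]` is the
#'   spline occupying grid row `r` (top to bottom).
#' @param valve_spline index (1-8) of the anterior MV (LA) or septal TV (RA)
#'   spline, the one duplicated at the opposite grid edge in the 9x8
#'   arrangement.
#' @param edge_labels named list of anatomical edge names.
#' @param chamber `"LA"` or `"RA"`.
#' @return A `basket_layout` object.
#' @export
basket_layout <- function(spline_order = 1:8, valve_spline = 1L,
                          edge_labels = list(top = "anterior MV",
                                             bottom = "posterior MV",
                                             left = "lateral / left PV",
                                             right = "septal / right PV"),
                          chamber = "LA") {
  stopifnot(length(spline_order) == 8, all(sort(spline_order) == 1:8),
            valve_spline %in% 1:8, chamber %in% c("LA", "RA"))
  structure(list(spline_count = 8L, electrodes_per_spline = 8L,
                 spline_order = as.integer(spline_order),
                 valve_spline = as.integer(valve_spline),
                 edge_labels = edge_labels, chamber = chamber),
            class = "basket_layout")
}

# Grid position of every electrode channel. Channels are numbered
# (spline - 1) * 8 + electrode, i.e. spline-major. Row = grid row of the
# spline under the layout permutation, col = electrode index along spline.
electrode_positions <- function(layout) {
  ch <- seq_len(64)
  spl <- (ch - 1) %/% 8 + 1
  ele <- (ch - 1) %% 8 + 1
  row <- match(spl, layout$spline_order)
  data.frame(channel = ch, spline = spl, electrode = ele,
             row = row, col = ele)
}

#' Construct a grid movie
#'
#' Time-ordered frames of normalised filtered derivative values on the 2D
#' anatomical grid. Values lie in `[0, 1]` where valid.
#'
#' @param frames numeric array `time x rows x cols`.
#' @param fs sampling rate (Hz) of the underlying recording.
#' @param sample_idx 1-based sample indices (into the underlying recording)
#'   of the stored frames; defaults to `1:T`.
#' @param grid_kind one of `"raw_9x8"`, `"raw_8x8"`, `"raw"`,
#'   `"interpolated"`.
#' @param valid_mask logical `rows x cols`; `FALSE` marks out-of-contact or
#'   unsupported pixels.
#' @param edge_labels anatomical edge names.
#' @param node_electrode optional integer `rows x cols` matrix giving the
#'   electrode channel behind each raw node (used by [apply_dropout()]).
#' @return A `grid_movie` object.
#' @export
grid_movie <- function(frames, fs, sample_idx = NULL, grid_kind = "raw",
                       valid_mask = NULL, edge_labels = NULL,
                       node_electrode = NULL) {
  stopifnot(length(dim(frames)) == 3, fs > 0)
  d <- dim(frames)
  if (is.null(sample_idx)) sample_idx <- seq_len(d[1])
  stopifnot(length(sample_idx) == d[1])
  if (is.null(valid_mask)) valid_mask <- matrix(TRUE, d[2], d[3])
  stopifnot(all(dim(valid_mask) == d[2:3]))
  structure(list(frames = frames, fs = fs, sample_idx = as.integer(sample_idx),
                 grid_kind = grid_kind, valid_mask = valid_mask,
                 edge_labels = edge_labels, node_electrode = node_electrode),
            class = "grid_movie")
}

#' @export
print.grid_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<grid_movie> %d frames of %dx%d (%s), fs = %g Hz, %d/%d valid\n",
              d[1], d[2], d[3], x$grid_kind, x$fs, sum(x$valid_mask),
              length(x$valid_mask)))
  invisible(x)
}

#' Arrange processed electrode signals on the anatomical grid
#'
#' Places the 64 per-electrode normalised-derivative traces on the 8x8
#' spline-by-electrode grid following the layout permutation and, when
#' `duplicate_valve_spline` is set, copies the valve spline's row to the
#' opposite edge of the grid, giving the 9x8 arrangement in which
#' propagation across the valve orifice stays contiguous.
#'
#' @param ps a `processed_signals` object (see [derivative_chain()]).
#' @param layout a [basket_layout()].
#' @param duplicate_valve_spline copy the valve-spline row to the opposite
#'   edge (default `TRUE`, the 9x8 grid).
#' @return A raw `grid_movie`.
#' @export
arrange_grid <- function(ps, layout = basket_layout(),
                         duplicate_valve_spline = TRUE) {
  stopifnot(inherits(ps, "processed_signals"))
  nd <- ps$nd
  if (nrow(nd) != 64) stop("expected 64 channels, got ", nrow(nd))
  pos <- electrode_positions(layout)
  n_t <- ncol(nd)
  frames <- array(0, dim = c(n_t, 8, 8))
  vmask <- matrix(TRUE, 8, 8)
  nodes <- matrix(NA_integer_, 8, 8)
  for (e in seq_len(64)) {
    frames[, pos$row[e], pos$col[e]] <- nd[e, ]
    vmask[pos$row[e], pos$col[e]] <- ps$contact_mask[e] && !ps$flat[e]
    nodes[pos$row[e], pos$col[e]] <- e
  }
  gm <- grid_movie(frames, fs = ps$fs, grid_kind = "raw_8x8",
                   valid_mask = vmask, edge_labels = layout$edge_labels,
                   node_electrode = nodes)
  if (duplicate_valve_spline)
    gm <- duplicate_valve_row(gm, match(layout$valve_spline,
                                        layout$spline_order))
  gm
}

#' Duplicate one grid row at the opposite edge (9x8 arrangement)
#'
#' Copies the given raw grid row to the far edge of the grid: the anterior
#' MV spline reappears at the posterior MV side, so that wavefronts crossing
#' the valve orifice remain contiguous on the grid.
#'
#' @param gm a raw `grid_movie`.
#' @param valve_row row index to duplicate (default 1, the top row).
#' @return A raw `grid_movie` with one extra row.
#' @export
duplicate_valve_row <- function(gm, valve_row = 1L) {
  stopifnot(inherits(gm, "grid_movie"), gm$grid_kind != "interpolated")
  d <- dim(gm$frames)
  frames <- array(0, dim = c(d[1], d[2] + 1, d[3]))
  frames[, seq_len(d[2]), ] <- gm$frames
  frames[, d[2] + 1, ] <- gm$frames[, valve_row, ]
  vmask <- rbind(gm$valid_mask, gm$valid_mask[valve_row, ])
  nodes <- if (!is.null(gm$node_electrode))
    rbind(gm$node_electrode, gm$node_electrode[valve_row, ]) else NULL
  grid_movie(frames, fs = gm$fs, sample_idx = gm$sample_idx,
             grid_kind = if (d[2] + 1 == 9 && d[3] == 8) "raw_9x8" else "raw",
             valid_mask = vmask, edge_labels = gm$edge_labels,
             node_electrode = nodes)
}

# Triangulation of the valid raw-grid nodes: each unit cell with all four
# corners valid is split into two triangles along its main diagonal (for
# square lattice cells the split is a valid Delaunay triangulation, since
# the four corners are cocircular); cells with exactly three valid corners
# contribute that single triangle. Returns a data.frame of triangle vertex
# coordinates (rows r1..c3).
triangulate_valid_nodes <- function(valid_mask) {
  R <- nrow(valid_mask); C <- ncol(valid_mask)
  tri <- list()
  k <- 0
  for (j in seq_len(C - 1)) {
    for (i in seq_len(R - 1)) {
      v <- c(valid_mask[i, j], valid_mask[i, j + 1],
             valid_mask[i + 1, j + 1], valid_mask[i + 1, j])
      pts <- rbind(c(i, j), c(i, j + 1), c(i + 1, j + 1), c(i + 1, j))
      if (all(v)) {
        k <- k + 1; tri[[k]] <- rbind(pts[1, ], pts[2, ], pts[3, ])
        k <- k + 1; tri[[k]] <- rbind(pts[1, ], pts[3, ], pts[4, ])
      } else if (sum(v) == 3) {
        k <- k + 1; tri[[k]] <- pts[v, ]
      }
    }
  }
  tri
}

# Interpolation weights from valid raw nodes to the refined lattice.
# Refinement inserts two points per gap: raw node i maps to refined index
# 3i - 2. Full cells use bilinear weights; cells with three valid corners
# use barycentric weights inside that triangle; everything else is invalid.
# Returns list(W = npix_out x (R*C) matrix, valid = logical matrix out).
interp_weights <- function(valid_mask) {
  R <- nrow(valid_mask); C <- ncol(valid_mask)
  Ro <- 3 * R - 2; Co <- 3 * C - 2
  W <- matrix(0, Ro * Co, R * C)
  vout <- matrix(FALSE, Ro, Co)
  node <- function(i, j) (j - 1) * R + i
  for (jo in seq_len(Co)) {
    for (io in seq_len(Ro)) {
      # continuous raw coordinates of this refined pixel
      rr <- (io - 1) / 3 + 1
      cc <- (jo - 1) / 3 + 1
      i <- min(floor(rr), R - 1); j <- min(floor(cc), C - 1)
      fy <- rr - i; fx <- cc - j
      corners <- c(node(i, j), node(i, j + 1),
                   node(i + 1, j + 1), node(i + 1, j))
      v <- valid_mask[corners]
      out_row <- (jo - 1) * Ro + io
      wts <- NULL
      if (all(v)) {
        wts <- c((1 - fy) * (1 - fx), (1 - fy) * fx, fy * fx, fy * (1 - fx))
      } else {
        # local corner coordinates (y, x): TL (0,0), TR (0,1),
        # BR (1,1), BL (1,0)
        py <- c(0, 0, 1, 1); px <- c(0, 1, 1, 0)
        if (sum(v) == 3) {
          idx <- which(v)
          b <- barycentric(fy, fx, py[idx], px[idx])
          if (!is.null(b)) { wts <- numeric(4); wts[idx] <- b }
        }
        if (is.null(wts) && sum(v) >= 2) {
          # on a valid edge or node?
          edges <- list(c(1, 2), c(2, 3), c(3, 4), c(4, 1))
          for (ed in edges) {
            if (!all(v[ed])) next
            ay <- py[ed[1]]; ax <- px[ed[1]]
            by <- py[ed[2]]; bx <- px[ed[2]]
            # pixel on segment a-b?
            t_num <- (fy - ay) * (by - ay) + (fx - ax) * (bx - ax)
            seg2 <- (by - ay)^2 + (bx - ax)^2
            tt <- t_num / seg2
            d2 <- (fy - (ay + tt * (by - ay)))^2 +
              (fx - (ax + tt * (bx - ax)))^2
            if (d2 < 1e-12 && tt >= -1e-9 && tt <= 1 + 1e-9) {
              wts <- numeric(4)
              wts[ed[1]] <- 1 - tt; wts[ed[2]] <- tt
              break
            }
          }
        }
        if (is.null(wts)) {
          # exactly on a valid node?
          exact <- which(v & abs(py - fy) < 1e-12 & abs(px - fx) < 1e-12)
          if (length(exact)) { wts <- numeric(4); wts[exact[1]] <- 1 }
        }
      }
      if (!is.null(wts)) {
        W[out_row, corners] <- wts
        vout[io, jo] <- TRUE
      }
    }
  }
  list(W = W, valid = vout)
}

# Barycentric coordinates of point (fy, fx) in the triangle with vertices
# (py, px); NULL if outside (tolerance 1e-9).
barycentric <- function(fy, fx, py, px) {
  d <- (py[2] - py[3]) * (px[1] - px[3]) + (px[3] - px[2]) * (py[1] - py[3])
  if (abs(d) < 1e-12) return(NULL)
  l1 <- ((py[2] - py[3]) * (fx - px[3]) + (px[3] - px[2]) * (fy - py[3])) / d
  l2 <- ((py[3] - py[1]) * (fx - px[3]) + (px[1] - px[3]) * (fy - py[3])) / d
  l3 <- 1 - l1 - l2
  b <- c(l1, l2, l3)
  if (any(b < -1e-9)) return(NULL)
  b[b < 0] <- 0
  b / sum(b)
}

#' Interpolate a raw grid movie to the refined lattice
#'
#' Linear interpolation inserting two points between every two original grid
#' points, so a 9x8 grid becomes 25x22 (and 8x8 becomes 22x22). Values at
#' the original node positions are preserved exactly. Invalid nodes are
#' excluded from the interpolation support: full cells interpolate
#' bilinearly, cells with three valid corners linearly over that triangle,
#' and refined pixels without valid support are marked invalid.
#'
#' @param gm a raw `grid_movie`.
#' @return An interpolated `grid_movie`.
#' @export
interpolate_grid <- function(gm) {
  stopifnot(inherits(gm, "grid_movie"))
  if (gm$grid_kind == "interpolated") stop("movie is already interpolated")
  if (!any(gm$valid_mask)) stop("all grid nodes invalid")
  d <- dim(gm$frames)
  iw <- interp_weights(gm$valid_mask)
  flat <- matrix(gm$frames, nrow = d[1])  # time x (R*C), column-major pixels
  out <- flat %*% t(iw$W)                 # time x (Ro*Co)
  Ro <- 3 * d[2] - 2; Co <- 3 * d[3] - 2
  frames <- array(out, dim = c(d[1], Ro, Co))
  grid_movie(frames, fs = gm$fs, sample_idx = gm$sample_idx,
             grid_kind = "interpolated", valid_mask = iw$valid,
             edge_labels = gm$edge_labels)
}

#' Mark electrodes or splines as out of contact
#'
#' Emulates poor basket contact by invalidating grid nodes before
#' interpolation, either as a random fraction of electrodes (deterministic
#' given `seed`), an explicit electrode index set, or whole splines. On a
#' 9x8 grid, dropping an electrode of the duplicated valve spline
#' invalidates both row copies.
#'
#' @param gm a raw `grid_movie` with electrode-to-node bookkeeping (as built
#'   by [arrange_grid()], [render_movie()] or [duplicate_valve_row()]).
#' @param fraction fraction of distinct electrodes to drop (in `[0, 0.9]`).
#' @param electrodes explicit electrode channel indices to drop.
#' @param splines spline row indices (1-8, pre-duplication) to drop whole.
#' @param seed integer seed for random selection.
#' @return The movie with an updated `valid_mask`.
#' @export
apply_dropout <- function(gm, fraction = NULL, electrodes = NULL,
                          splines = NULL, seed = 1L) {
  stopifnot(inherits(gm, "grid_movie"), !is.null(gm$node_electrode))
  ids <- unique(as.vector(gm$node_electrode))
  ids <- ids[!is.na(ids)]
  drop_ids <- integer(0)
  if (!is.null(fraction)) {
    stopifnot(fraction >= 0, fraction <= 0.9)
    n_drop <- round(fraction * length(ids))
    drop_ids <- local_seed(seed, sample(ids, n_drop))
  }
  if (!is.null(electrodes)) drop_ids <- c(drop_ids, electrodes)
  if (!is.null(splines)) {
    # splines are grid rows of the pre-duplication grid; the duplicated
    # valve row shares its electrode ids, so dropping it invalidates both
    # copies
    for (s in splines)
      drop_ids <- c(drop_ids, gm$node_electrode[s, ])
  }
  drop_ids <- unique(drop_ids)
  if (length(drop_ids) >= length(ids)) stop("cannot drop all grid nodes")
  vmask <- gm$valid_mask
  vmask[gm$node_electrode %in% drop_ids] <- FALSE
  if (!any(vmask)) stop("cannot drop all grid nodes")
  gm$valid_mask <- vmask
  gm
}
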