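# Independent oracles used by the unit and acceptance tests. These are
# written directly from the algorithm definitions, with plain loops, and are
# kept independent of the package's implementation paths.

# Direct-iteration Horn-Schunck reference: 4-point cube derivative stencils
# with replicate handling at the last row/column, Jacobi updates from zero
# with the 1/6 (edge) / 1/12 (diagonal) neighbour weights renormalised over
# in-bounds valid neighbours.
hs_reference <- function(a, b, alpha, iters, valid = NULL) {
  nr <- nrow(a); nc <- ncol(a)
  if (is.null(valid)) valid <- matrix(TRUE, nr, nc)
  cl <- function(i, n) min(i, n)
  Ex <- matrix(0, nr, nc); Ey <- matrix(0, nr, nc); Et <- matrix(0, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    i1 <- cl(i + 1, nr); j1 <- cl(j + 1, nc)
    Ex[i, j] <- ((a[i, j1] - a[i, j]) + (a[i1, j1] - a[i1, j]) +
                   (b[i, j1] - b[i, j]) + (b[i1, j1] - b[i1, j])) / 4
    Ey[i, j] <- ((a[i1, j] - a[i, j]) + (a[i1, j1] - a[i, j1]) +
                   (b[i1, j] - b[i, j]) + (b[i1, j1] - b[i, j1])) / 4
    Et[i, j] <- ((b[i, j] - a[i, j]) + (b[i1, j] - a[i1, j]) +
                   (b[i, j1] - a[i, j1]) + (b[i1, j1] - a[i1, j1])) / 4
  }
  nbr <- rbind(c(-1, 0, 1 / 6), c(1, 0, 1 / 6), c(0, -1, 1 / 6),
               c(0, 1, 1 / 6), c(-1, -1, 1 / 12), c(-1, 1, 1 / 12),
               c(1, -1, 1 / 12), c(1, 1, 1 / 12))
  u <- matrix(0, nr, nc); v <- matrix(0, nr, nc)
  for (it in seq_len(iters)) {
    un <- matrix(0, nr, nc); vn <- matrix(0, nr, nc)
    for (i in 1:nr) for (j in 1:nc) {
      if (!valid[i, j]) next
      su <- 0; sv <- 0; sw <- 0
      for (k in 1:8) {
        ii <- i + nbr[k, 1]; jj <- j + nbr[k, 2]
        if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
        if (!valid[ii, jj]) next
        su <- su + nbr[k, 3] * u[ii, jj]
        sv <- sv + nbr[k, 3] * v[ii, jj]
        sw <- sw + nbr[k, 3]
      }
      ubar <- if (sw > 0) su / sw else 0
      vbar <- if (sw > 0) sv / sw else 0
      num <- Ex[i, j] * ubar + Ey[i, j] * vbar + Et[i, j]
      den <- alpha^2 + Ex[i, j]^2 + Ey[i, j]^2
      un[i, j] <- ubar - Ex[i, j] * num / den
      vn[i, j] <- vbar - Ey[i, j] * num / den
    }
    u <- un; v <- vn
  }
  list(u = u, v = v)
}

# Brute-force AUC: fraction of responder/non-responder pairs won, ties half.
auc_bruteforce <- function(x, y) {
  wins <- 0
  for (xi in x) for (yi in y)
    wins <- wins + (xi > yi) + 0.5 * (xi == yi)
  wins / (length(x) * length(y))
}

# Brute-force PV tagging on explicit vectors: per-vector enumeration.
tag_bruteforce <- function(u, v, inward, mean_mag, cone_deg = 90) {
  tagged <- logical(length(u))
  for (i in seq_along(u)) {
    m <- sqrt(u[i]^2 + v[i]^2)
    if (m <= mean_mag || m == 0) next
    ang <- acos(max(-1, min(1, (u[i] * inward[1] + v[i] * inward[2]) / m)))
    tagged[i] <- ang <= cone_deg / 2 * pi / 180
  }
  tagged
}

# Mean circulation (tangential component) of an averaged field on a ring
# around `centre` (row, col); positive for anticlockwise flow in (col, row)
# axes, matching rotor chirality +1.
ring_circulation <- function(avg, centre, radius = 3, n = 72) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  s <- 0
  for (t in th) {
    p <- centre + radius * c(sin(t), cos(t))
    i <- round(p[1]); j <- round(p[2])
    s <- s + avg$u_avg[i, j] * (-sin(t)) + avg$v_avg[i, j] * cos(t)
  }
  s / n
}

# Mean radial alignment of streamline step directions w.r.t. a centre.
mean_radial_component <- function(ss, centre) {
  comps <- c()
  for (sl in ss$streamlines) {
    n <- nrow(sl$points)
    if (n < 2) next
    dirs <- sl$points[-1, , drop = FALSE] - sl$points[-n, , drop = FALSE]
    mid <- (sl$points[-1, , drop = FALSE] + sl$points[-n, , drop = FALSE]) / 2
    rv <- cbind(mid[, 1] - centre[1], mid[, 2] - centre[2])
    rn <- sqrt(rowSums(rv^2)); dn <- sqrt(rowSums(dirs^2))
    ok <- rn > 1e-6 & dn > 1e-6
    comps <- c(comps, (rowSums(rv * dirs) / (rn * dn))[ok])
  }
  mean(comps)
}

# A hand-built averaged_flow object for structural tests.
make_avg <- function(u, v, valid = NULL) {
  if (is.null(valid)) valid <- matrix(TRUE, nrow(u), ncol(u))
  structure(list(u_avg = u, v_avg = v,
                 contribution_count = matrix(1L, nrow(u), ncol(u)),
                 n_frames = 1L, valid_mask = valid),
            class = "averaged_flow")
}

# Angular difference in degrees, wrapped to [0, 180].
ang_err_deg <- function(est, truth) {
  abs(((est - truth + pi) %% (2 * pi)) - pi) * 180 / pi
}

# Short analysis config for unit tests (2 s windows keep pipelines cheap).
short_cfg <- function(...) analysis_config(window_s = 2, ...)
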