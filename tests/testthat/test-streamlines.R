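test_that("triangulation of a 2x2 node square yields 2 triangles with
           interior seeds", {
  pts <- rbind(c(1, 1), c(1, 2), c(2, 1), c(2, 2))
  ts <- triangulate_seeds(pts)
  expect_length(ts$triangles, 2)
  expect_equal(nrow(ts$seeds), 2)
  expect_true(all(ts$seeds > 1 & ts$seeds < 2))
})

test_that("a full n x m grid triangulates into 2(n-1)(m-1) elements", {
  for (dims in list(c(3, 4), c(5, 5), c(9, 8))) {
    pts <- as.matrix(expand.grid(seq_len(dims[1]), seq_len(dims[2])))
    ts <- triangulate_seeds(pts)
    expect_length(ts$triangles, 2 * (dims[1] - 1) * (dims[2] - 1))
  }
})

test_that("degenerate point sets are rejected", {
  expect_error(triangulate_seeds(rbind(c(1, 1), c(1, 2))), "at least 3")
  expect_error(triangulate_seeds(rbind(c(1, 1), c(1, 2), c(1, 3))),
               "collinear")
})

test_that("a uniform field traces a straight spanning line", {
  u <- matrix(1, 15, 20); v <- matrix(0, 15, 20)
  avg <- make_avg(u, v)
  sl <- trace_streamline(c(8, 10), avg)
  expect_gt(nrow(sl$points), 10)
  expect_true(all(abs(sl$points[, 1] - 8) < 1e-9))
  expect_lt(min(sl$points[, 2]), 2.3)
  expect_gt(max(sl$points[, 2]), 18.7)
})

test_that("a 90-degree corner stops the trace; a gentle bend does not", {
  # rightward in the left half, downward in the right half
  u <- cbind(matrix(1, 20, 10), matrix(0, 20, 10))
  v <- cbind(matrix(0, 20, 10), matrix(1, 20, 10))
  avg <- make_avg(u, v)
  sl <- trace_streamline(c(5, 3), avg)
  # forward branch must not get far past the corner transition zone
  expect_lt(max(sl$points[, 1]), 8)
  # gentle circular arc (turn per 0.25 px step << 0.7 rad) keeps going
  n <- 40
  ang <- function(i, j) atan2(i - 20.5, j - 20.5)
  uu <- outer(1:n, 1:n, function(i, j) -sin(ang(i, j)))
  vv <- outer(1:n, 1:n, function(i, j) cos(ang(i, j)))
  avg2 <- make_avg(uu, vv)
  sl2 <- trace_streamline(c(20.5 - 10, 20.5), avg2)
  # winds at least 270 degrees around the centre before stopping
  th <- atan2(sl2$points[, 1] - 20.5, sl2$points[, 2] - 20.5)
  dth <- diff(th)
  dth <- (dth + pi) %% (2 * pi) - pi
  expect_gt(abs(sum(dth)), 1.5 * pi)
})

test_that("a zero field at the seed returns an empty polyline", {
  avg <- make_avg(matrix(0, 6, 6), matrix(0, 6, 6))
  sl <- trace_streamline(c(3, 3), avg)
  expect_equal(nrow(sl$points), 0)
})

test_that("selection enforces the minimum spacing with deterministic
           tie-breaks", {
  mk_line <- function(row, n = 30) {
    structure(list(points = cbind(rep(row, n), seq(1, 8, length.out = n)),
                   mags = rep(1, n)), class = "streamline")
  }
  # two identical traces: only one kept, the lower seed id
  ss <- select_streamlines(list(mk_line(3), mk_line(3)))
  expect_length(ss$streamlines, 1)
  expect_equal(ss$streamlines[[1]]$seed_id, 1)
  # parallel traces 1 px apart: both kept
  ss2 <- select_streamlines(list(mk_line(3), mk_line(4)))
  expect_length(ss2$streamlines, 2)
  # 0.4 px apart: second dropped
  ss3 <- select_streamlines(list(mk_line(3), mk_line(3.4)))
  expect_length(ss3$streamlines, 1)
})

test_that("retained sets are order-independent and respect pairwise
           spacing", {
  set.seed(19)
  traces <- lapply(1:12, function(k) {
    n <- sample(10:40, 1)
    row <- runif(1, 2, 18)
    structure(list(points = cbind(rep(row, n) + cumsum(rnorm(n, 0, 0.05)),
                                  seq(2, 2 + 0.25 * (n - 1), by = 0.25)),
                   mags = runif(n)), class = "streamline")
  })
  s1 <- select_streamlines(traces)
  # shuffling input order does not change the retained geometry because the
  # sort is by length with seed-id tie-break mapped back to original ids
  perm <- sample(12)
  s2 <- select_streamlines(traces[perm])
  pts1 <- lapply(s1$streamlines, function(s) s$points)
  pts2 <- lapply(s2$streamlines, function(s) s$points)
  expect_equal(length(pts1), length(pts2))
  # compare as sets
  key <- function(p) paste(round(p[1, 1], 6), round(p[1, 2], 6),
                           nrow(p))
  expect_setequal(vapply(pts1, key, ""), vapply(pts2, key, ""))
  # pairwise min distance between retained streamlines >= spacing
  if (length(pts1) >= 2) {
    for (i in 1:(length(pts1) - 1)) for (j in (i + 1):length(pts1)) {
      dmin <- min(as.matrix(stats::dist(rbind(pts1[[i]], pts1[[j]])))[
        seq_len(nrow(pts1[[i]])), nrow(pts1[[i]]) + seq_len(nrow(pts1[[j]]))])
      expect_gte(dmin, 0.5)
    }
  }
})

test_that("focal-source streamlines diverge radially from the origin", {
  sc <- synth_scene(grid_shape = c(8, 8), duration = 10.5,
                    drivers = driver_spec("focal", origin = c(4.5, 4.5),
                                          period = 180),
                    conduction_speed = 0.1, noise_sd = 0.05, seed = 13)
  parts <- pv_flow_from_scene(sc, keep_fields = TRUE)
  ss <- build_streamlines(parts$avg, parts$raw_valid_mask)
  expect_gt(length(ss$streamlines), 0)
  expect_gt(mean_radial_component(ss, c(11.5, 11.5)), 0.8)
})
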