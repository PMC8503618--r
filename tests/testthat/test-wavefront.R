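# movie with two frames per lattice point built from explicit matrices:
# lattice frames a_k and their +1-sample partners b_k
lattice_movie <- function(a_frames, b_frames, inc = 10, fs = 1000,
                          valid = NULL) {
  n <- length(a_frames)
  d <- dim(a_frames[[1]])
  frames <- array(0, c(2 * n, d[1], d[2]))
  idx <- integer(2 * n)
  for (k in seq_len(n)) {
    frames[2 * k - 1, , ] <- a_frames[[k]]
    frames[2 * k, , ] <- b_frames[[k]]
    idx[2 * k - 1] <- k * inc
    idx[2 * k] <- k * inc + 1
  }
  grid_movie(frames, fs = fs, sample_idx = idx, grid_kind = "interpolated",
             valid_mask = valid)
}

test_that("frames below the isoline level give an empty mask", {
  a <- matrix(0.5, 10, 10)
  gm <- lattice_movie(list(a, a, a), list(a, a, a))
  wf <- detect_wavefronts(gm, analysis_config(frame_increment_samples = 10),
                          n_samples = 30)
  expect_equal(sum(wf$mask), 0)
})

test_that("components of exactly 3 pixels are discarded, 4 kept", {
  a <- matrix(0, 12, 12)
  a[2, 2:4] <- 0.95          # 3-pixel component
  a[8, 4:7] <- 0.95          # 4-pixel component
  b <- a + 0.01              # everything rising
  gm <- lattice_movie(list(a, a), list(b, b), inc = 10)
  wf <- detect_wavefronts(gm, analysis_config(frame_increment_samples = 10),
                          n_samples = 20)
  m <- wf$mask[1, , ]
  expect_false(any(m[2, ]))
  expect_true(all(m[8, 4:7]))
  expect_equal(sum(m), 4)
})

test_that("only the rising (leading) edge is kept", {
  a <- matrix(0, 12, 12)
  a[4, 3:10] <- 0.95   # rising band
  a[9, 3:10] <- 0.95   # falling band
  b <- a
  b[4, ] <- b[4, ] + 0.02
  b[9, ] <- b[9, ] - 0.02
  gm <- lattice_movie(list(a, a), list(b, b), inc = 10)
  wf <- detect_wavefronts(gm, analysis_config(frame_increment_samples = 10),
                          n_samples = 20)
  m <- wf$mask[1, , ]
  expect_true(all(m[4, 3:10]))
  expect_false(any(m[9, ]))
})

test_that("a planar synthetic band yields one thin perpendicular component", {
  sc <- synth_scene(grid_shape = c(8, 8), duration = 2.5,
                    drivers = driver_spec("planar", direction = 0,
                                          period = 300),
                    conduction_speed = 0.1, noise_sd = 0, seed = 3)
  parts <- pv_flow_from_scene(sc, short_cfg(), keep_fields = TRUE)
  wf <- parts$wavefronts
  n_comp <- apply(wf$labels, 1, function(l) length(setdiff(unique(l), 0L)))
  with_wf <- which(n_comp > 0)
  expect_gt(length(with_wf), 10)
  expect_true(mean(n_comp[with_wf] == 1) > 0.9)
  # band is perpendicular to rightward propagation: spans rows, few cols
  k <- with_wf[which.max(apply(wf$mask, 1, sum)[with_wf])]
  m <- wf$mask[k, , ]
  expect_gt(length(unique(which(m, arr.ind = TRUE)[, 1])),
            2 * length(unique(which(m, arr.ind = TRUE)[, 2])))
})

test_that("vector averaging is coherent for repeats, cancels alternation", {
  d <- c(6, 6)
  mk_field <- function(u) structure(
    list(u = matrix(u, d[1], d[2]), v = matrix(0, d[1], d[2]),
         valid_mask = matrix(TRUE, d[1], d[2]), frame_time = 0),
    class = "flow_field")
  mask <- array(TRUE, c(4, d[1], d[2]))
  wf <- structure(list(mask = mask, labels = NULL, lattice = NULL),
                  class = "wavefront_mask")
  coh <- average_flow(list(mk_field(1), mk_field(1), mk_field(1),
                           mk_field(1)), wf)
  expect_true(all(abs(coh$u_avg - 1) < 1e-12))
  alt <- average_flow(list(mk_field(1), mk_field(-1), mk_field(1),
                           mk_field(-1)), wf)
  expect_true(all(alt$u_avg == 0))
  expect_true(all(coh$contribution_count == 4))
  expect_error(average_flow(list(), wf), "zero analysed frames")
})

test_that("averaged magnitude never exceeds the max per-frame magnitude", {
  sc <- synth_scene(grid_shape = c(8, 8), duration = 2.5,
                    drivers = driver_spec("rotor", origin = c(4.5, 4.5),
                                          period = 180),
                    conduction_speed = 0.1, noise_sd = 0.05, seed = 5)
  cfg <- short_cfg()
  n_win <- round(cfg$window_s * sc$fs)
  lat <- afpathways:::flow_lattice(n_win, cfg$frame_increment_samples)
  samp <- sort(unique(c(lat, lat + 1L)))
  gm <- render_movie(activation_times(sc), sc, sample_idx = samp)
  gmi <- interpolate_grid(gm)
  fields <- flow_sequence(gmi, cfg, n_samples = n_win)
  wf <- detect_wavefronts(gmi, cfg, n_samples = n_win)
  avg <- average_flow(fields, wf, cfg)
  mag_avg <- sqrt(avg$u_avg^2 + avg$v_avg^2)
  mag_max <- Reduce(pmax, lapply(fields, function(f) sqrt(f$u^2 + f$v^2)))
  expect_true(all(mag_avg <= mag_max + 1e-12))
})

test_that("rotor scenes produce circulation of the driver chirality", {
  for (ch in c(1L, -1L)) {
    sc <- synth_scene(grid_shape = c(8, 8), duration = 10.5,
                      drivers = driver_spec("rotor", origin = c(4.5, 4.5),
                                            period = 180, chirality = ch),
                      conduction_speed = 0.1, noise_sd = 0.05, seed = 7)
    parts <- pv_flow_from_scene(sc, keep_fields = TRUE)
    circ <- ring_circulation(parts$avg, c(11.5, 11.5), radius = 3)
    expect_true(sign(circ) == ch,
                label = paste("circulation sign, chirality", ch))
  }
})

test_that("incoherent equal-magnitude vectors cancel to under 25% of the
           coherent average", {
  # same per-frame magnitudes, same wavefront occupancy; only the direction
  # coherence differs
  set.seed(43)
  d <- c(8, 8); n <- 100
  mk_field <- function(theta) structure(
    list(u = matrix(cos(theta), d[1], d[2]),
         v = matrix(sin(theta), d[1], d[2]),
         valid_mask = matrix(TRUE, d[1], d[2]), frame_time = 0),
    class = "flow_field")
  mask <- array(TRUE, c(n, d[1], d[2]))
  wf <- structure(list(mask = mask, labels = NULL, lattice = NULL),
                  class = "wavefront_mask")
  coherent <- average_flow(lapply(rep(0.3, n), mk_field), wf)
  incoherent <- average_flow(lapply(runif(n, 0, 2 * pi), mk_field), wf)
  med_co <- median(sqrt(coherent$u_avg^2 + coherent$v_avg^2))
  med_in <- median(sqrt(incoherent$u_avg^2 + incoherent$v_avg^2))
  expect_lt(med_in, 0.25 * med_co)
})
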