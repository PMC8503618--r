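test_that("planar activation times follow distance / speed", {
  sc <- synth_scene(grid_shape = c(8, 12), duration = 1,
                    drivers = driver_spec("planar", direction = 0,
                                          period = 200),
                    conduction_speed = 1, noise_sd = 0, seed = 1)
  tt <- activation_times(sc)
  # rightward wave at 1 px/ms: col 1 activates at 0, col 11 at 10 ms
  expect_equal(tt[[1, 1]][1], 0)
  expect_equal(tt[[1, 11]][1], 10)
  expect_equal(tt[[5, 11]][1], 10)  # same column, same time
  # period spacing
  expect_equal(diff(tt[[3, 4]]), rep(200, length(tt[[3, 4]]) - 1))
})

test_that("focal activation is radially symmetric around the origin", {
  sc <- synth_scene(grid_shape = c(9, 9), duration = 1,
                    drivers = driver_spec("focal", origin = c(5, 5),
                                          period = 250),
                    conduction_speed = 0.5, noise_sd = 0, seed = 1)
  tt <- activation_times(sc)
  four <- c(tt[[5, 3]][1], tt[[5, 7]][1], tt[[3, 5]][1], tt[[7, 5]][1])
  expect_equal(max(four) - min(four), 0)
  expect_equal(tt[[5, 5]][1], 0)
  expect_equal(tt[[5, 7]][1], 2 / 0.5)
})

test_that("rotor inter-activation intervals equal the period", {
  sc <- synth_scene(grid_shape = c(8, 8), duration = 2,
                    drivers = driver_spec("rotor", origin = c(4.5, 4.5),
                                          period = 200, chirality = 1L),
                    conduction_speed = 0.5, noise_sd = 0, seed = 1)
  tt <- activation_times(sc)
  for (idx in list(c(1, 1), c(2, 7), c(8, 4))) {
    iv <- diff(tt[[idx[1], idx[2]]])
    expect_true(all(abs(iv - 200) < 1e-9))
  }
  # closed-form phase map: activation fraction within a cycle equals the
  # pixel's polar angle fraction plus radial delay
  th <- atan2(1 - 4.5, 1 - 4.5)
  frac <- (th / (2 * pi)) %% 1
  dl <- sqrt((1 - 4.5)^2 + (1 - 4.5)^2) / 0.5
  expect_equal(tt[[1, 1]][1] %% 200, (frac * 200 + dl) %% 200,
               tolerance = 1e-9)
})

test_that("per-pixel median inter-activation interval recovers the period", {
  for (kind in c("planar", "focal", "rotor")) {
    sc <- synth_scene(grid_shape = c(8, 8), duration = 3,
                      drivers = driver_spec(kind, origin = c(4.2, 5.1),
                                            period = 170, direction = 1),
                      conduction_speed = 0.2, noise_sd = 0, seed = 2)
    tt <- activation_times(sc)
    meds <- vapply(tt, function(ts) median(diff(ts)), 0)
    expect_true(all(abs(meds - 170) <= 1000 / sc$fs),
                label = paste(kind, "period recovery"))
  }
})

test_that("rotor phase map has one singularity at the core, focal none", {
  # winding number of the analytic activation-phase map on a loop
  winding <- function(sc, loop) {
    tt <- activation_times(sc)
    ph <- vapply(seq_len(nrow(loop)), function(k) {
      ts <- tt[[loop[k, 1], loop[k, 2]]]
      # phase at t = 500 ms relative to the activation cycle
      tprev <- max(ts[ts <= 500])
      2 * pi * (500 - tprev) / 200
    }, 0)
    d <- diff(c(ph, ph[1]))
    d <- (d + pi) %% (2 * pi) - pi
    round(sum(d) / (2 * pi))
  }
  loop <- rbind(c(3, 3), c(3, 4), c(3, 5), c(3, 6), c(4, 6), c(5, 6),
                c(6, 6), c(6, 5), c(6, 4), c(6, 3), c(5, 3), c(4, 3))
  rot <- synth_scene(grid_shape = c(8, 8), duration = 1,
                     drivers = driver_spec("rotor", origin = c(4.5, 4.5),
                                           period = 200, chirality = 1L),
                     conduction_speed = 10, noise_sd = 0, seed = 1)
  foc <- synth_scene(grid_shape = c(8, 8), duration = 1,
                     drivers = driver_spec("focal", origin = c(4.5, 4.5),
                                           period = 200),
                     conduction_speed = 10, noise_sd = 0, seed = 1)
  expect_equal(abs(winding(rot, loop)), 1)
  expect_equal(winding(foc, loop), 0)
})

test_that("movie rendering peaks at activation times and clips to [0,1]", {
  sc <- synth_scene(grid_shape = c(4, 4), fs = 1000, duration = 0.5,
                    drivers = driver_spec("focal", origin = c(2, 2),
                                          period = 400),
                    conduction_speed = 1, noise_sd = 0, seed = 1)
  tt <- activation_times(sc)
  expect_equal(tt[[2, 2]][1], 0)
  gm <- render_movie(tt, sc)
  # activation at t = 100 ms for a pixel 100 px away is out of this grid;
  # check the origin pixel peaks at value 1 at its activation sample
  expect_equal(gm$frames[1, 2, 2], 1)
  expect_true(all(gm$frames >= 0 & gm$frames <= 1))
  # argmax over time recovers activation time within one sample
  sc2 <- synth_scene(grid_shape = c(6, 6), fs = 1000, duration = 0.4,
                     drivers = driver_spec("planar", direction = 0,
                                           period = 500),
                     conduction_speed = 0.05, noise_sd = 0, seed = 1)
  tt2 <- activation_times(sc2)
  gm2 <- render_movie(tt2, sc2)
  for (j in 1:6) {
    est <- (which.max(gm2$frames[, 3, j]) - 1) / sc2$fs * 1000
    expect_lt(abs(est - tt2[[3, j]][1]), 1.5)
  }
})

test_that("a scene with no drivers renders an all-zero movie", {
  sc <- synth_scene(grid_shape = c(4, 4), fs = 500, duration = 0.5,
                    drivers = list(), noise_sd = 0, seed = 1)
  gm <- render_movie(activation_times(sc), sc)
  expect_true(all(gm$frames == 0))
})

test_that("unknown driver kinds and invalid pulse widths error", {
  expect_error(driver_spec("spiral"), "spiral")
  sc <- synth_scene(grid_shape = c(4, 4), fs = 500, duration = 0.5,
                    drivers = list(), noise_sd = 0, seed = 1, pulse_sd_ms = 0)
  expect_error(render_movie(activation_times(sc), sc), "pulse width")
})

test_that("electrogram rendering places one negative peak per activation", {
  sc <- synth_scene(grid_shape = c(8, 8), fs = 2000, duration = 0.6,
                    drivers = driver_spec("focal", origin = c(1, 1),
                                          period = 1000),
                    conduction_speed = 0.05, noise_sd = 0, seed = 1)
  tt <- activation_times(sc)
  rec <- render_electrograms(tt, sc)
  x <- rec$voltages[28, ]  # channel 28 = spline 4, electrode 4 = pixel (4,4)
  mins <- diff(sign(diff(x))) == 2 & x[2:(length(x) - 1)] < -0.2
  expect_equal(sum(mins), 1)
  tmin <- (which.min(x) - 1) / 2000 * 1000
  expect_lt(abs(tmin - tt[[4, 4]][1]), 8)  # within half the deflection width
})

test_that("common-mode QRS artifact appears on the cross-channel mean", {
  sc <- synth_scene(grid_shape = c(8, 8), fs = 2000, duration = 2,
                    drivers = list(), noise_sd = 0.02,
                    qrs_artifact = list(period_ms = 800, amplitude = 2),
                    seed = 4)
  rec <- render_electrograms(activation_times(sc), sc)
  expect_false(is.null(rec$qrs_times))
  m <- colMeans(rec$voltages)
  expect_true(all(m[rec$qrs_times] > 0.9 * 2))
})

test_that("identical scenes (including seed) render bit-identical outputs", {
  mk <- function() synth_scene(grid_shape = c(8, 8), fs = 1000, duration = 1,
                               drivers = driver_spec("multiwavelet",
                                                     wavelet_count = 3L,
                                                     period = 180),
                               conduction_speed = 0.1, noise_sd = 0.05,
                               seed = 9)
  s1 <- mk(); s2 <- mk()
  t1 <- activation_times(s1); t2 <- activation_times(s2)
  expect_identical(t1, t2)
  expect_identical(render_movie(t1, s1), render_movie(t2, s2))
  expect_identical(render_electrograms(t1, s1)$voltages,
                   render_electrograms(t2, s2)$voltages)
})

test_that("electrodes mapped outside the scene grid are reported", {
  sc <- synth_scene(grid_shape = c(4, 4), fs = 500, duration = 0.5,
                    drivers = list(), noise_sd = 0, seed = 1)
  expect_error(render_electrograms(activation_times(sc), sc),
               "outside grid")
})
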