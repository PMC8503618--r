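#' Describe a synthetic activation driver
#'
#' A kinematic description of one arrhythmia driver on the 2D grid. Four
#' archetypes are supported: a planar wave sweeping the grid, an anchored
#' rotor (spiral arm rotating about a core), a repetitive focal source, and
#' a multi-wavelet regime built from short-lived pseudo-random focal bursts.
#'
#' @param kind one of `"planar"`, `"rotor"`, `"focal"`, `"multiwavelet"`.
#' @param origin numeric `(row, col)` grid coordinates (continuous,
#'   1-based) of the driver core / focus. Ignored for planar waves.
#' @param period activation period in ms.
#' @param direction propagation direction in radians for planar waves;
#'   0 points towards increasing column (rightward), `pi/2` towards
#'   increasing row.
#' @param chirality rotor rotation sense, `+1` or `-1`. With `+1` the
#'   activated angle advances anticlockwise in (col, row) coordinates.
#' @param core_radius radius (pixels) of the circular obstacle a rotor
#'   circulates around. 0 (default) is a functional point rotor, whose phase
#'   arm sweeps the neighbourhood like a beacon; a positive radius emulates
#'   anatomical re-entry around an orifice such as a PV ostium, whose far
#'   field radiates outward like a rotating focal source.
#' @param wavelet_count mean number of concurrently active wavelets for the
#'   multiwavelet regime (integer >= 1).
#' @param drift_speed optional core drift speed in pixels/s (rotor and
#'   focal drivers); drift direction is drawn from the scene seed.
#' @param active_ms optional `(start, end)` in ms restricting the driver to
#'   part of the recording (e.g. to build driver-switch scenes); default:
#'   active throughout.
#' @return A `driver_spec` object.
#' @export
driver_spec <- function(kind, origin = c(4.5, 4.5), period = 180,
                        direction = 0, chirality = 1L, wavelet_count = 4L,
                        drift_speed = 0, active_ms = NULL, core_radius = 0) {
  kinds <- c("planar", "rotor", "focal", "multiwavelet")
  if (!kind %in% kinds)
    stop("unknown driver kind: '", kind, "'")
  stopifnot(period > 0, length(origin) == 2, wavelet_count >= 1,
            chirality %in% c(-1L, 1L), drift_speed >= 0, core_radius >= 0)
  if (!is.null(active_ms))
    stopifnot(length(active_ms) == 2, active_ms[1] < active_ms[2])
  structure(list(kind = kind, origin = as.numeric(origin), period = period,
                 direction = direction, chirality = as.integer(chirality),
                 wavelet_count = as.integer(wavelet_count),
                 drift_speed = drift_speed, active_ms = active_ms,
                 core_radius = core_radius),
            class = "driver_spec")
}

#' Define a synthetic activation scene
#'
#' A scene bundles the grid geometry, sampling, drivers, wave speed, noise
#' and artifact settings that together define a ground-truth activation
#' "movie". Defaults emulate a basket-catheter recording: an 8x8 electrode
#' grid sampled at 2034.5 Hz, atrial-fibrillation cycle lengths near 180 ms,
#' and a conduction speed of 0.1 pixels/ms (about 0.7 m/s at a 7 mm
#' electrode pitch).
#'
#' @param grid_shape integer `(rows, cols)`, each at least 4.
#' @param fs sampling rate in Hz.
#' @param duration recording duration in seconds.
#' @param drivers a `driver_spec` or list of them.
#' @param conduction_speed wave speed in raw-grid pixels per ms.
#' @param noise_sd additive Gaussian noise, as a fraction of unit signal
#'   amplitude.
#' @param qrs_artifact `NULL`, or `list(period_ms=, amplitude=)` describing
#'   a periodic far-field deflection added identically to all channels when
#'   electrograms are rendered.
#' @param pulse_sd_ms temporal SD of the Gaussian activation pulse used when
#'   rendering normalised-derivative movies (default 10 ms).
#' @param seed integer seed governing all randomness attached to the scene.
#' @return A `synth_scene` object.
#' @export
synth_scene <- function(grid_shape = c(8, 8), fs = 2034.5, duration = 12,
                        drivers = driver_spec("planar"),
                        conduction_speed = 0.1, noise_sd = 0.05,
                        qrs_artifact = NULL, pulse_sd_ms = 10, seed = 1L) {
  if (inherits(drivers, "driver_spec")) drivers <- list(drivers)
  stopifnot(fs > 0, duration > 0, length(grid_shape) == 2,
            all(grid_shape >= 4), conduction_speed > 0, noise_sd >= 0)
  for (d in drivers) {
    stopifnot(inherits(d, "driver_spec"))
    # drivers may sit just beyond the mapped field (the basket does not
    # cover the PV ostia), but not arbitrarily far from it
    margin <- 6
    if (d$kind != "planar" &&
        (d$origin[1] < 1 - margin || d$origin[1] > grid_shape[1] + margin ||
         d$origin[2] < 1 - margin || d$origin[2] > grid_shape[2] + margin))
      stop("driver origin too far outside grid bounds")
  }
  if (!is.null(qrs_artifact))
    stopifnot(is.list(qrs_artifact), qrs_artifact$period_ms > 0,
              qrs_artifact$amplitude > 0)
  structure(list(grid_shape = as.integer(grid_shape), fs = fs,
                 duration = duration, drivers = drivers,
                 conduction_speed = conduction_speed, noise_sd = noise_sd,
                 qrs_artifact = qrs_artifact, pulse_sd_ms = pulse_sd_ms,
                 seed = as.integer(seed)),
            class = "synth_scene")
}

# Activation times for a single driver at pixel coordinates (r, c),
# vectorised over pixels. Returns a list (one sorted vector per pixel).
driver_times <- function(d, r, c, t_max, v, seed) {
  n <- length(r)
  out <- vector("list", n)
  per <- d$period
  drift_dir <- local_seed(derive_seed(seed, 11), runif(1, 0, 2 * pi))
  origin_at <- function(t_ms) {
    if (d$drift_speed <= 0) return(d$origin)
    d$origin + d$drift_speed / 1000 * t_ms *
      c(sin(drift_dir), cos(drift_dir))
  }
  if (d$kind == "planar") {
    # Phase distance along the propagation direction; earliest pixel
    # activates at t = 0 of each cycle.
    s <- c * cos(d$direction) + r * sin(d$direction)
    s <- (s - min(s)) / v
    ks <- seq(0, ceiling(t_max / per))
    for (i in seq_len(n))
      out[[i]] <- s[i] + ks * per
  } else if (d$kind == "focal") {
    ks <- seq(0, ceiling(t_max / per))
    for (k in ks) {
      o <- origin_at(k * per)
      dl <- sqrt((r - o[1])^2 + (c - o[2])^2) / v
      for (i in seq_len(n))
        out[[i]] <- c(out[[i]], k * per + dl[i])
    }
  } else if (d$kind == "rotor") {
    # The spiral arm sweeps angle chirality * 2*pi*t/period; a pixel
    # activates when the arm passes its polar angle, delayed radially.
    ks <- seq(0, ceiling(t_max / per))
    for (k in ks) {
      o <- origin_at(k * per)
      th <- atan2(r - o[1], c - o[2])
      frac <- ((d$chirality * th) / (2 * pi)) %% 1
      dl <- pmax(0, sqrt((r - o[1])^2 + (c - o[2])^2) - d$core_radius) / v
      for (i in seq_len(n))
        out[[i]] <- c(out[[i]], (k + frac[i]) * per + dl[i])
    }
  } else if (d$kind == "multiwavelet") {
    # Poisson-seeded short-lived focal bursts: each burst fires twice
    # (lifetime ~ 2 periods) from a uniform random site, and its waves
    # reach only pixels within 2 periods of travel.
    lifetime <- 2 * per
    n_bursts <- local_seed(derive_seed(seed, 13), {
      nb <- max(1, rpois(1, d$wavelet_count * (t_max + lifetime) / lifetime))
      nb
    })
    bursts <- local_seed(derive_seed(seed, 17), {
      data.frame(
        t0 = runif(n_bursts, -lifetime, t_max),
        br = runif(n_bursts, 1, max(r)),
        bc = runif(n_bursts, 1, max(c))
      )
    })
    for (b in seq_len(n_bursts)) {
      dl <- sqrt((r - bursts$br[b])^2 + (c - bursts$bc[b])^2) / v
      reach <- dl <= lifetime
      for (j in 0:1) {
        tb <- bursts$t0[b] + j * per + dl
        keep <- reach & tb >= 0 & tb <= t_max
        idx <- which(keep)
        for (i in idx)
          out[[i]] <- c(out[[i]], tb[i])
      }
    }
  }
  out
}

#' Compute per-pixel activation times for a scene
#'
#' Evaluates the closed-form kinematic activation model of each driver on
#' every grid pixel and superposes drivers. Times within half a period of a
#' kept earlier activation at the same pixel are dropped (refractoriness),
#' and each pixel's list is sorted ascending. Times are in ms from the start
#' of the recording.
#'
#' @param scene a [synth_scene()].
#' @return A `rows x cols` matrix-of-lists: `times[[r, c]]` is a sorted
#'   numeric vector of activation times (ms).
#' @export
activation_times <- function(scene) {
  stopifnot(inherits(scene, "synth_scene"))
  R <- scene$grid_shape[1]; C <- scene$grid_shape[2]
  t_max <- scene$duration * 1000
  rr <- rep(seq_len(R), times = C)
  cc <- rep(seq_len(C), each = R)
  all_t <- vector("list", R * C)
  for (d in scene$drivers) {
    dt <- driver_times(d, rr, cc, t_max, scene$conduction_speed, scene$seed)
    if (!is.null(d$active_ms))
      dt <- lapply(dt, function(ts) ts[ts >= d$active_ms[1] &
                                         ts <= d$active_ms[2]])
    for (i in seq_len(R * C)) all_t[[i]] <- c(all_t[[i]], dt[[i]])
  }
  refr <- if (length(scene$drivers)) min(vapply(scene$drivers,
                                                function(d) d$period,
                                                0)) / 2 else Inf
  for (i in seq_len(R * C)) {
    ts <- sort(all_t[[i]])
    ts <- ts[ts >= 0 & ts <= t_max]
    if (length(ts) > 1) {
      keep <- rep(TRUE, length(ts))
      last <- ts[1]
      for (k in seq_along(ts)[-1]) {
        if (ts[k] - last < refr) keep[k] <- FALSE else last <- ts[k]
      }
      ts <- ts[keep]
    }
    all_t[i] <- list(ts)   # [[<- would drop the element when ts is empty
  }
  dim(all_t) <- c(R, C)
  all_t
}

#' Render a normalised-derivative movie from activation times
#'
#' Each activation contributes a unit-amplitude Gaussian pulse in time at
#' its pixel; frames are clipped to `[0, 1]`, Gaussian noise of
#' `scene$noise_sd` is added, and frames are re-clipped. This emulates the
#' normalised filtered derivative signal that the electrogram processing
#' chain produces from real recordings.
#'
#' @param times output of [activation_times()].
#' @param scene the [synth_scene()] the times came from.
#' @param sample_idx optional integer vector of 1-based sample indices to
#'   render (default: all `round(fs * duration)` samples). Rendering only
#'   the optical-flow lattice keeps long scenes cheap.
#' @return A `grid_movie` object (see [grid_movie()]).
#' @export
render_movie <- function(times, scene, sample_idx = NULL) {
  stopifnot(inherits(scene, "synth_scene"))
  if (scene$pulse_sd_ms <= 0) stop("pulse width must be positive")
  R <- scene$grid_shape[1]; C <- scene$grid_shape[2]
  n_total <- round(scene$fs * scene$duration)
  if (is.null(sample_idx)) sample_idx <- seq_len(n_total)
  stopifnot(all(sample_idx >= 1), all(sample_idx <= n_total))
  t_ms <- (sample_idx - 1) / scene$fs * 1000
  sdp <- scene$pulse_sd_ms
  frames <- array(0, dim = c(length(sample_idx), R, C))
  for (cidx in seq_len(C)) {
    for (ridx in seq_len(R)) {
      ts <- times[[ridx, cidx]]
      if (!length(ts)) next
      # evaluate only near each pulse (+-5 SD)
      sig <- numeric(length(t_ms))
      for (ta in ts) {
        sel <- which(abs(t_ms - ta) <= 5 * sdp)
        if (length(sel))
          sig[sel] <- sig[sel] + exp(-(t_ms[sel] - ta)^2 / (2 * sdp^2))
      }
      frames[, ridx, cidx] <- sig
    }
  }
  frames[frames > 1] <- 1
  if (scene$noise_sd > 0) {
    # Band-limited noise, emulating what survives the 20 Hz low-pass of the
    # electrogram chain: Gaussian knots every 25 ms per pixel, linearly
    # interpolated in time. Deterministic for any sample subset because the
    # knot table depends only on the scene.
    knot_ms <- 25
    n_knots <- ceiling(scene$duration * 1000 / knot_ms) + 2L
    knots <- local_seed(derive_seed(scene$seed, 23),
                        matrix(rnorm(R * C * n_knots, sd = scene$noise_sd),
                               n_knots, R * C))
    kf <- t_ms / knot_ms + 1
    k0 <- pmin(floor(kf), n_knots - 1L)
    w1 <- kf - k0
    noise <- knots[k0, , drop = FALSE] * (1 - w1) +
      knots[k0 + 1L, , drop = FALSE] * w1
    frames <- frames + array(noise, dim = dim(frames))
    frames[frames > 1] <- 1
    frames[frames < 0] <- 0
  }
  grid_movie(frames, fs = scene$fs, sample_idx = sample_idx,
             grid_kind = if (all(c(R, C) == c(9, 8))) "raw_9x8"
                         else if (all(c(R, C) == c(8, 8))) "raw_8x8"
                         else "raw",
             valid_mask = matrix(TRUE, R, C),
             node_electrode = matrix(seq_len(R * C), R, C))
}

# Biphasic unipolar deflection: a positive lobe followed by a larger
# negative lobe (difference of two Gaussians), negative peak at tau = 0.
biphasic_deflection <- function(tau, sd_pos = 5, sd_neg = 8, lead_ms = 6) {
  0.9 * exp(-(tau + lead_ms)^2 / (2 * sd_pos^2)) -
    1.4 * exp(-tau^2 / (2 * sd_neg^2))
}

#' Render synthetic unipolar electrograms at basket electrodes
#'
#' Each activation at an electrode's grid pixel contributes a biphasic
#' deflection (positive lobe then a larger negative lobe). An optional
#' periodic far-field artifact ("QRS") is added identically to all channels,
#' then Gaussian noise. Output is deterministic given the scene seed.
#'
#' @param times output of [activation_times()] on the scene grid.
#' @param scene the [synth_scene()].
#' @param layout a [basket_layout()] mapping electrodes to grid positions;
#'   the scene grid must cover all electrode positions.
#' @return A `recording` object (see [recording()]).
#' @export
render_electrograms <- function(times, scene, layout = basket_layout()) {
  stopifnot(inherits(scene, "synth_scene"), inherits(layout, "basket_layout"))
  pos <- electrode_positions(layout)
  bad <- which(pos$row > scene$grid_shape[1] | pos$col > scene$grid_shape[2] |
               pos$row < 1 | pos$col < 1)
  if (length(bad))
    stop("electrodes mapped outside grid: ", paste(bad, collapse = ", "))
  n <- round(scene$fs * scene$duration)
  t_ms <- (seq_len(n) - 1) / scene$fs * 1000
  n_el <- nrow(pos)
  volt <- matrix(0, n_el, n)
  for (e in seq_len(n_el)) {
    ts <- times[[pos$row[e], pos$col[e]]]
    sig <- numeric(n)
    for (ta in ts) {
      sel <- which(t_ms >= ta - 60 & t_ms <= ta + 60)
      if (length(sel))
        sig[sel] <- sig[sel] + biphasic_deflection(t_ms[sel] - ta)
    }
    volt[e, ] <- sig
  }
  qrs_idx <- NULL
  if (!is.null(scene$qrs_artifact)) {
    qa <- scene$qrs_artifact
    qrs_ms <- seq(qa$period_ms / 2, scene$duration * 1000, by = qa$period_ms)
    art <- numeric(n)
    for (tq in qrs_ms) {
      sel <- which(abs(t_ms - tq) <= 60)
      art[sel] <- art[sel] + qa$amplitude * exp(-(t_ms[sel] - tq)^2 /
                                                  (2 * 12^2))
    }
    volt <- volt + matrix(art, n_el, n, byrow = TRUE)
    qrs_idx <- round(qrs_ms / 1000 * scene$fs) + 1L
    qrs_idx <- qrs_idx[qrs_idx >= 1 & qrs_idx <= n]
  }
  if (scene$noise_sd > 0) {
    noise <- local_seed(derive_seed(scene$seed, 29),
                        rnorm(length(volt), sd = scene$noise_sd))
    volt <- volt + matrix(noise, n_el, n)
  }
  recording(volt, fs = scene$fs, chamber = "LA", layout = layout,
            contact_mask = rep(TRUE, n_el), qrs_times = qrs_idx)
}

#' Generate a paired synthetic cohort of responder and non-responder scenes
#'
#' Responder-like scenes host a driver at a PV of the grid: either a
#' repetitive focal source (PV trigger) just beyond the lateral or septal
#' column edge, or anatomical re-entry around a PV ostium, modelled as a
#' rotor with a 2-pixel core sitting deeper behind the edge so that the
#' mapped field sees its radiating far field — mirroring that the basket
#' does not cover the veins themselves. The two archetypes are placed so
#' that they produce comparable PV activation flow, consistent with the
#' physiology that LA-body recordings cannot distinguish PV triggers from
#' PV rotational drivers. Non-responder-like scenes host a functional point
#' rotor in the atrial body or a multi-wavelet regime. Driver kinds, sides
#' and jittered origins are drawn deterministically from `seed`.
#'
#' @param n_per_group scenes per group.
#' @param seed integer seed.
#' @param duration scene duration in seconds.
#' @param noise_sd noise level passed to each scene.
#' @return A list with `responder` and `nonresponder` lists of scenes.
#' @export
synthetic_cohort <- function(n_per_group = 20, seed = 1L, duration = 11,
                             noise_sd = 0.05) {
  draw <- local_seed(derive_seed(seed, 31), {
    list(
      side = sample(c("left", "right"), n_per_group, replace = TRUE),
      rkind = sample(c("rotor", "focal"), n_per_group, replace = TRUE),
      nkind = sample(c("rotor", "multiwavelet"), n_per_group, replace = TRUE),
      jit_r = runif(2 * n_per_group, -0.8, 0.8),
      jit_c = runif(2 * n_per_group, 0, 1),
      per = runif(2 * n_per_group, 165, 195),
      chir = sample(c(-1L, 1L), 2 * n_per_group, replace = TRUE)
    )
  })
  resp <- vector("list", n_per_group)
  nonr <- vector("list", n_per_group)
  for (i in seq_len(n_per_group)) {
    # PV triggers just beyond the edge (cols 0..1 / 8..9); PV re-entry
    # deeper behind the ostium (cols -5..-4 / 13..14) with a 2 px core
    depth <- if (draw$rkind[i] == "focal") draw$jit_c[i]
             else 4 + draw$jit_c[i]
    col <- if (draw$side[i] == "left") 1 - depth else 8 + depth
    resp[[i]] <- synth_scene(
      grid_shape = c(8, 8), duration = duration,
      drivers = driver_spec(draw$rkind[i],
                            origin = c(4.5 + draw$jit_r[i], col),
                            period = draw$per[i], chirality = draw$chir[i],
                            core_radius = if (draw$rkind[i] == "rotor") 2
                                          else 0),
      noise_sd = noise_sd, seed = derive_seed(seed, 100 + i))
    nonr[[i]] <- synth_scene(
      grid_shape = c(8, 8), duration = duration,
      drivers = driver_spec(draw$nkind[i],
                            origin = c(4.5 + draw$jit_r[n_per_group + i],
                                       4 + draw$jit_c[n_per_group + i]),
                            period = draw$per[n_per_group + i],
                            chirality = draw$chir[n_per_group + i],
                            wavelet_count = 4L),
      noise_sd = noise_sd, seed = derive_seed(seed, 500 + i))
  }
  list(responder = resp, nonresponder = nonr)
}
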