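#' Construct a recording of unipolar electrograms
#'
#' @param voltages numeric matrix, electrodes x samples (mV or arbitrary
#'   units).
#' @param fs sampling rate in Hz.
#' @param chamber `"LA"` or `"RA"`.
#' @param layout a [basket_layout()].
#' @param contact_mask logical per electrode; `FALSE` marks electrodes out
#'   of tissue contact.
#' @param qrs_times optional 1-based sample indices of ventricular (QRS)
#'   far-field complexes, used for template subtraction.
#' @return A `recording` object.
#' @export
recording <- function(voltages, fs, chamber = "LA",
                      layout = basket_layout(), contact_mask = NULL,
                      qrs_times = NULL) {
  voltages <- as.matrix(voltages)
  stopifnot(fs > 0, chamber %in% c("LA", "RA"))
  if (!all(is.finite(voltages))) {
    badch <- which(apply(voltages, 1, function(x) any(!is.finite(x))))
    stop("non-finite voltages in channel(s): ", paste(badch, collapse = ", "))
  }
  if (is.null(contact_mask)) contact_mask <- rep(TRUE, nrow(voltages))
  stopifnot(length(contact_mask) == nrow(voltages))
  structure(list(voltages = voltages, fs = fs, chamber = chamber,
                 layout = layout, contact_mask = contact_mask,
                 qrs_times = qrs_times),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples at %g Hz (%s), %d in contact\n",
              nrow(x$voltages), ncol(x$voltages), x$fs, x$chamber,
              sum(x$contact_mask)))
  invisible(x)
}

#' Subtract the ventricular far-field (QRS) template
#'
#' For each channel, an average beat template is estimated over windows
#' centred on the QRS times and subtracted at each occurrence. Samples
#' outside the QRS windows are untouched. With fewer than two QRS times the
#' input is returned unchanged with a warning; with `qrs_times = NULL` and
#' the detector disabled the input is returned unchanged silently (no-op).
#'
#' @param rec a [recording()].
#' @param window_ms half-width of the template window (default 60 ms).
#' @param detect if `TRUE` and `rec$qrs_times` is absent, QRS times are
#'   detected as peaks of the cross-channel mean signal (far-field artifact
#'   is common-mode). Default `FALSE`.
#' @return A new [recording()] with the template removed.
#' @export
subtract_qrs <- function(rec, window_ms = 60, detect = FALSE) {
  stopifnot(inherits(rec, "recording"))
  qt <- rec$qrs_times
  if (is.null(qt) && detect) {
    m <- colMeans(rec$voltages)
    thr <- stats::quantile(abs(m - stats::median(m)), 0.999)
    qt <- find_peaks(abs(m - stats::median(m)),
                     min_sep = round(0.3 * rec$fs), min_height = 0.5 * thr)
  }
  if (is.null(qt)) return(rec)
  if (length(qt) < 2) {
    warning("fewer than 2 QRS times; returning recording unchanged")
    return(rec)
  }
  half <- round(window_ms / 1000 * rec$fs)
  n <- ncol(rec$voltages)
  offs <- -half:half
  volt <- rec$voltages
  for (ch in seq_len(nrow(volt))) {
    segs <- vapply(qt, function(t0) {
      idx <- t0 + offs
      out <- rep(NA_real_, length(offs))
      ok <- idx >= 1 & idx <= n
      out[ok] <- volt[ch, idx[ok]]
      out
    }, numeric(length(offs)))
    template <- rowMeans(segs, na.rm = TRUE)
    for (t0 in qt) {
      idx <- t0 + offs
      ok <- idx >= 1 & idx <= n
      volt[ch, idx[ok]] <- volt[ch, idx[ok]] - template[ok]
    }
  }
  recording(volt, fs = rec$fs, chamber = rec$chamber, layout = rec$layout,
            contact_mask = rec$contact_mask, qrs_times = qt)
}

# Local maxima with a minimum separation (samples) and minimum height;
# greedy by decreasing height.
find_peaks <- function(x, min_sep, min_height = -Inf) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- cand[x[cand] >= min_height]
  if (!length(cand)) return(integer(0))
  cand <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (p in cand) {
    if (!length(kept) || all(abs(kept - p) >= min_sep)) kept <- c(kept, p)
  }
  sort(kept)
}

# Analytic-signal phase via FFT Hilbert transform.
analytic_phase <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(X * h, inverse = TRUE) / n
  ph <- Arg(z)
  ph[ph <= -pi] <- pi
  ph
}

#' Compute normalised filtered derivative, phase and activation peaks
#'
#' The derivative-based activation signal used throughout the pipeline.
#' Per channel: first difference, zero-phase band-pass (default 40-250 Hz,
#' the chain conventionally applied before dominant-frequency analysis),
#' full-wave rectification, zero-phase low-pass (default 20 Hz) to make the
#' signal near-sinusoidal, then min-max normalisation to `[0, 1]` over the
#' analysis window. Channels whose filtered derivative has negligible range
#' (< 1e-9) are flagged flat and set to zero. The unipolar phase is the
#' analytic-signal angle of the mean-subtracted normalised derivative.
#' Activation peaks are local maxima of the normalised derivative subject to
#' a minimum separation and height.
#'
#' @param rec a [recording()] (QRS-subtracted if artifacts are present).
#' @param cfg an [analysis_config()].
#' @return A `processed_signals` object with fields `nd` (electrodes x
#'   samples in `[0,1]`), `phase` (radians in `(-pi, pi]`), `peak_times`
#'   (list of per-electrode sample indices), `flat`, `contact_mask`, `fs`.
#' @export
derivative_chain <- function(rec, cfg = analysis_config()) {
  stopifnot(inherits(rec, "recording"))
  cfg <- as_af_config(cfg)
  n <- ncol(rec$voltages)
  if (n < rec$fs) stop("analysis window shorter than filter warm-up (1 s)")
  nyq <- rec$fs / 2
  hi <- min(cfg$bp_high, 0.9 * nyq)
  bp <- signal::butter(2, c(cfg$bp_low, hi) / nyq, type = "pass")
  lp <- signal::butter(2, cfg$lp_cut / nyq, type = "low")
  n_ch <- nrow(rec$voltages)
  nd <- matrix(0, n_ch, n)
  phase <- matrix(0, n_ch, n)
  flat <- logical(n_ch)
  peaks <- vector("list", n_ch)
  min_sep <- round(cfg$min_peak_separation_ms / 1000 * rec$fs)
  for (ch in seq_len(n_ch)) {
    d <- c(0, diff(rec$voltages[ch, ]))
    f <- signal::filtfilt(bp, d)
    f <- abs(f)
    f <- signal::filtfilt(lp, f)
    rng <- range(f)
    if (diff(rng) < 1e-9) {
      flat[ch] <- TRUE
      peaks[[ch]] <- integer(0)
      next
    }
    v <- (f - rng[1]) / diff(rng)
    nd[ch, ] <- v
    phase[ch, ] <- analytic_phase(v - mean(v))
    peaks[[ch]] <- find_peaks(v, min_sep = min_sep,
                              min_height = cfg$min_peak_height)
  }
  structure(list(nd = nd, phase = phase, peak_times = peaks, flat = flat,
                 contact_mask = rec$contact_mask, fs = rec$fs,
                 chamber = rec$chamber),
            class = "processed_signals")
}

#' Per-electrode and chamber-mean cycle lengths
#'
#' The cycle length (CL) of an electrode is the mean of all time intervals
#' between successive peaks of its normalised filtered derivative. The
#' chamber mean is the mean CL over in-contact electrodes with a defined CL.
#'
#' @param ps a `processed_signals` object.
#' @param fs sampling rate in Hz (defaults to the one stored in `ps`).
#' @return A list with `per_electrode_cl` (ms, `NA` where undefined) and
#'   `chamber_mean_cl` (ms).
#' @export
cycle_lengths <- function(ps, fs = ps$fs) {
  stopifnot(inherits(ps, "processed_signals"))
  cl <- vapply(ps$peak_times, function(p) {
    if (length(p) < 2) return(NA_real_)
    mean(diff(p)) / fs * 1000
  }, 0)
  ok <- !is.na(cl) & ps$contact_mask
  if (!any(ok)) stop("no in-contact electrode with at least 2 peaks")
  list(per_electrode_cl = cl, chamber_mean_cl = mean(cl[ok]))
}
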