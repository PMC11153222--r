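#' Band-pass filter specification
#'
#' Defaults follow the pipeline's denoising stage: order-6 Butterworth
#' band-pass from 1 to 60 Hz, applied zero-phase (forward-backward, so the
#' effective magnitude response is squared and net phase is zero).
#'
#' "Order 6" follows the filter-design convention of `butter(n, [lo hi])`:
#' the low-pass prototype has `n` poles and the band-pass transform doubles
#' them, giving a 12-pole filter realized as 6 second-order sections.
#'
#' @param order prototype order (even, >= 2); default 6.
#' @param band numeric length-2, `(low_hz, high_hz)`; default `c(1, 60)`.
#' @param fs sampling rate in Hz.
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(order = 6, band = c(1, 60), fs = 256) {
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1] ||
      band[2] >= fs / 2) {
    stopf("band must satisfy 0 < low < high < fs/2 (got %s at fs=%g)",
          paste(band, collapse = "-"), fs)
  }
  if (order < 2 || order %% 2 != 0) stopf("order must be even and >= 2")
  structure(list(order = order, band = as.numeric(band), fs = fs),
            class = "filter_spec")
}

#' Design a Butterworth band-pass filter as second-order sections
#'
#' Closed-form design: analog Butterworth prototype poles, low-pass to
#' band-pass transform with bilinear prewarping of the band edges, bilinear
#' transform to the z-domain, and conjugate-pair grouping into second-order
#' sections. Gain is normalized to exactly 1 at the (geometric) center
#' frequency, as for an analog Butterworth band-pass.
#'
#' @param spec a [filter_spec()].
#' @return object of class `sos_filter`: list with `sos` (n_sections x 6
#'   matrix, columns b0 b1 b2 a0 a1 a2), plus the design's digital zeros,
#'   poles and gain, and the originating `spec`.
#' @export
design_bandpass <- function(spec) {
  n <- spec$order
  fs <- spec$fs
  # prewarped analog band edges (rad/s)
  w1 <- 2 * fs * tan(pi * spec$band[1] / fs)
  w2 <- 2 * fs * tan(pi * spec$band[2] / fs)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1

  k <- seq_len(n)
  proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n))   # LHP Butterworth poles
  # lp->bp: each prototype pole p solves s^2 - (bw p) s + w0^2 = 0
  b2 <- bw * proto / 2
  disc <- sqrt(b2^2 - w0^2)
  s_poles <- c(b2 + disc, b2 - disc)
  # bilinear transform
  z_poles <- (2 * fs + s_poles) / (2 * fs - s_poles)
  z_zeros <- c(rep(1 + 0i, n), rep(-1 + 0i, n))

  # group poles into conjugate pairs; each section gets zeros (+1, -1)
  pos <- z_poles[Im(z_poles) > 1e-12]
  pos <- pos[order(Mod(pos))]
  reals <- sort(Re(z_poles[abs(Im(z_poles)) <= 1e-12]))
  sec_a <- matrix(0, 0, 3)
  for (p in pos) {
    sec_a <- rbind(sec_a, c(1, -2 * Re(p), Mod(p)^2))
  }
  if (length(reals)) {
    for (i in seq(1, length(reals), by = 2)) {
      r1 <- reals[i]; r2 <- reals[i + 1]
      sec_a <- rbind(sec_a, c(1, -(r1 + r2), r1 * r2))
    }
  }
  nsec <- nrow(sec_a)
  sos <- cbind(1, 0, -1, sec_a)               # b = (1, 0, -1) per section
  colnames(sos) <- c("b0", "b1", "b2", "a0", "a1", "a2")

  # normalize overall gain to 1 at the digital center frequency
  f0 <- fs / pi * atan(w0 / (2 * fs))
  g <- abs(sos_response(list(sos = sos), f0, fs))
  sos[, 1:3] <- sos[, 1:3] * (1 / g)^(1 / nsec)

  structure(list(sos = sos, zeros = z_zeros, poles = z_poles,
                 spec = spec), class = "sos_filter")
}

#' Complex frequency response of a second-order-section filter
#'
#' @param filt an `sos_filter` (or any list with an `sos` matrix).
#' @param f frequencies in Hz.
#' @param fs sampling rate (taken from `filt$spec$fs` when omitted).
#' @return complex vector `H(e^{i 2 pi f / fs})`.
#' @export
sos_response <- function(filt, f, fs = NULL) {
  fs <- fs %||% filt$spec$fs
  z1 <- exp(-1i * 2 * pi * f / fs)
  h <- rep(1 + 0i, length(f))
  s <- filt$sos
  for (i in seq_len(nrow(s))) {
    h <- h * (s[i, 1] + s[i, 2] * z1 + s[i, 3] * z1^2) /
      (s[i, 4] + s[i, 5] * z1 + s[i, 6] * z1^2)
  }
  h
}

#' Analytic Butterworth band-pass magnitude
#'
#' Closed-form magnitude of the designed filter at digital frequency `f`,
#' evaluated through the bilinear prewarp:
#' `|H|^2 = 1 / (1 + W(f)^(2n))` with
#' `W = (omega^2 - omega_l omega_h) / (omega (omega_h - omega_l))` on the
#' prewarped axis. Independent of the pole/section machinery; used to verify
#' the design.
#'
#' @param spec a [filter_spec()].
#' @param f frequencies in Hz.
#' @return magnitude response (single forward pass).
#' @export
butterworth_magnitude <- function(spec, f) {
  fs <- spec$fs
  w <- 2 * fs * tan(pi * f / fs)
  w1 <- 2 * fs * tan(pi * spec$band[1] / fs)
  w2 <- 2 * fs * tan(pi * spec$band[2] / fs)
  W <- (w^2 - w1 * w2) / (w * (w2 - w1))
  ifelse(f == 0, 0, 1 / sqrt(1 + W^(2 * spec$order)))
}

# one second-order section, direct form, vectorized via stats::filter;
# pre-history is treated as constant x[1] (edges are protected by padding).
sos_section_filter <- function(x, b, a) {
  n <- length(x)
  x1 <- c(x[1], x[-n])
  x2 <- c(x[1], x1[-n])
  v <- b[1] * x + b[2] * x1 + b[3] * x2
  y0 <- x[1] * sum(b) / sum(c(1, a))
  as.numeric(stats::filter(v, -a, method = "recursive", init = c(y0, y0)))
}

sos_filter_once <- function(x, sos) {
  for (i in seq_len(nrow(sos))) {
    x <- sos_section_filter(x, sos[i, 1:3], sos[i, 5:6])
  }
  x
}

#' Zero-phase filtering of one signal
#'
#' Forward-backward second-order-section filtering with odd-reflection edge
#' padding. The net phase response is zero and the magnitude response is the
#' square of the single-pass response.
#'
#' @param x numeric vector.
#' @param filt an `sos_filter` from [design_bandpass()].
#' @param padlen padding length in samples; the default is adaptive — long
#'   enough for the slowest filter pole to decay below 1e-9 — capped at
#'   `length(x) - 1`.
#' @return filtered vector, same length as `x`.
#' @export
filtfilt_sos <- function(x, filt, padlen = NULL) {
  n <- length(x)
  if (is.null(padlen)) {
    maxp <- max(Mod(filt$poles))
    padlen <- min(n - 1, ceiling(log(1e-9) / log(min(maxp, 1 - 1e-12))))
  }
  if (n <= 2 * nrow(filt$sos) + 1 || padlen < 1) {
    stopf("signal too short (%d samples) for zero-phase filtering", n)
  }
  ext <- c(2 * x[1] - x[(padlen + 1):2],
           x,
           2 * x[n] - x[(n - 1):(n - padlen)])
  y <- sos_filter_once(ext, filt$sos)
  y <- rev(sos_filter_once(rev(y), filt$sos))
  y[(padlen + 1):(padlen + n)]
}

#' Zero-phase band-pass filtering of a recording
#'
#' Applies [filtfilt_sos()] to every channel. The whole recording is filtered
#' before any windowing, so short analysis windows never see filter edges.
#'
#' @param rec an `eeg_recording`.
#' @param spec a [filter_spec()]; its `fs` must match the recording.
#' @return filtered `eeg_recording` of identical shape.
#' @export
apply_zero_phase <- function(rec, spec = filter_spec(fs = rec$fs)) {
  if (!isTRUE(all.equal(rec$fs, spec$fs))) {
    stopf("filter fs (%g) does not match recording fs (%g)", spec$fs, rec$fs)
  }
  filt <- design_bandpass(spec)
  out <- rec
  for (i in seq_len(nrow(rec$signals))) {
    out$signals[i, ] <- filtfilt_sos(rec$signals[i, ], filt)
  }
  out
}
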