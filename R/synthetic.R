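#' Synthetic EEG configuration
#'
#' Describes a seeded multichannel recording: 1/f ("pink") background with a
#' 10 Hz posterior rhythm, plus annotated seizure episodes that combine
#' periodic sharp transients (a spike-and-wave caricature at 3-5 Hz) with
#' band-limited 20-60 Hz noise calibrated to raise in-band power by a
#' configured amount. Amplitude-depression onsets are deliberately not
#' generated by default (the detection method does not target them); set
#' `depression = TRUE` on a seizure row for negative testing.
#'
#' @param fs sampling rate (default 256 Hz).
#' @param n_channels number of channels (default 6, labeled with
#'   [default_channels()]).
#' @param duration_s recording length in seconds.
#' @param onef_exponent 1/f^a background exponent (default 1).
#' @param alpha_uv 10 Hz rhythm amplitude in microvolts (default 10).
#' @param sigma_uv background RMS in microvolts (default 15).
#' @param seizures data.frame with columns `onset_s`, `duration_s` and
#'   optionally `spike_rate_hz` (3-5, default 4), `band_boost_db`
#'   (default 20), `amplitude_uv` (spike amplitude, default 40),
#'   `depression` (default `FALSE`).
#' @param seed RNG seed.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(fs = 256, n_channels = 6, duration_s = 480,
                         onef_exponent = 1, alpha_uv = 10, sigma_uv = 15,
                         seizures = data.frame(onset_s = c(70, 210, 350),
                                               duration_s = c(35, 35, 35)),
                         seed = 1) {
  sz <- as.data.frame(seizures)
  if (nrow(sz)) {
    if (is.null(sz$spike_rate_hz)) sz$spike_rate_hz <- 4
    if (is.null(sz$band_boost_db)) sz$band_boost_db <- 20
    if (is.null(sz$amplitude_uv)) sz$amplitude_uv <- 40
    if (is.null(sz$depression)) sz$depression <- FALSE
    if (any(sz$onset_s < 0) ||
        any(sz$onset_s + sz$duration_s > duration_s)) {
      stopf("seizure intervals must lie within the recording")
    }
    o <- order(sz$onset_s)
    sz <- sz[o, , drop = FALSE]
    if (nrow(sz) > 1 &&
        any(sz$onset_s[-1] < (sz$onset_s + sz$duration_s)[-nrow(sz)])) {
      stopf("seizure intervals overlap")
    }
    if (any(sz$spike_rate_hz < 3 | sz$spike_rate_hz > 5)) {
      stopf("spike_rate_hz must be within 3-5 Hz")
    }
  }
  structure(list(fs = fs, n_channels = n_channels, duration_s = duration_s,
                 onef_exponent = onef_exponent, alpha_uv = alpha_uv,
                 sigma_uv = sigma_uv, seizures = sz, seed = seed),
            class = "synth_config")
}

# seeded 1/f^a noise of length n, unit variance, via spectral shaping
pink_noise <- function(n, a) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- c(1, seq_len(n - 1))                 # avoid f = 0 blowup
  f <- pmin(f, n - f + 1)                   # mirror for negative freqs
  X <- X * f^(-a / 2)
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  as.numeric(scale(x))
}

# band-limited noise via the package's own band-pass, unit variance
band_noise <- function(n, fs, band) {
  x <- stats::rnorm(n + 2 * fs)
  filt <- design_bandpass(filter_spec(6, band, fs))
  y <- filtfilt_sos(x, filt)[(fs + 1):(fs + n)]
  y / stats::sd(y)
}

# spike-and-wave caricature kernel: sharp biphasic transient + slow wave
spike_kernel <- function(fs) {
  t <- seq(0, 0.25, by = 1 / fs)
  sharp <- (1 - (t / 0.025 - 1)^2) * exp(-((t - 0.025) / 0.02)^2)
  wave <- -0.5 * sin(pi * pmin(t / 0.25, 1))
  sharp + wave
}

#' Generate a synthetic annotated EEG recording
#'
#' Background: per-channel independent 1/f noise scaled to `sigma_uv` RMS
#' plus a 10 Hz rhythm with a random phase per channel. During each seizure
#' interval, all channels receive (with per-channel gains in [0.5, 1]) a
#' periodic sharp-transient train at `spike_rate_hz`, and per-channel
#' band-limited 20-60 Hz noise whose variance is calibrated, channel by
#' channel, so that total in-band power during the seizure exceeds the
#' channel's background in-band power by `band_boost_db` (the spike train's
#' own in-band contribution is measured and subtracted first). Fully
#' reproducible from `cfg$seed`.
#'
#' @param cfg a [synth_config()].
#' @return list with `recording` (an `eeg_recording`) and `annotation`
#'   (a [seizure_annotation()]).
#' @export
generate_recording <- function(cfg) {
  fs <- cfg$fs
  n <- round(cfg$duration_s * fs)
  nch <- cfg$n_channels
  labels <- if (nch == 6) default_channels() else paste0("CH", seq_len(nch))
  band <- c(20, 60)

  with_seed(cfg$seed, {
    bg_filt <- design_bandpass(filter_spec(6, band, fs))
    sig <- matrix(0, nch, n)
    for (ch in seq_len(nch)) {
      bg <- cfg$sigma_uv * pink_noise(n, cfg$onef_exponent)
      ph <- stats::runif(1, 0, 2 * pi)
      bg <- bg + cfg$alpha_uv * sin(2 * pi * 10 * seq_len(n) / fs + ph)
      sig[ch, ] <- bg
    }
    # per-channel background in-band power (for boost calibration)
    p_bg <- vapply(seq_len(nch), function(ch) {
      stats::var(filtfilt_sos(sig[ch, ], bg_filt))
    }, numeric(1))

    sz <- cfg$seizures
    kern <- spike_kernel(fs)
    for (i in seq_len(nrow(sz))) {
      i0 <- round(sz$onset_s[i] * fs) + 1L
      i1 <- min(n, i0 + round(sz$duration_s[i] * fs) - 1L)
      len <- i1 - i0 + 1L
      gains <- stats::runif(nch, 0.5, 1)
      # periodic sharp transients
      train <- numeric(len)
      step <- round(fs / sz$spike_rate_hz[i])
      train[seq(1L, len, by = step)] <- 1
      spikes <- stats::convolve(train, rev(kern), type = "open")[seq_len(len)]
      spikes <- sz$amplitude_uv[i] * spikes
      sp_band <- filtfilt_sos(spikes, bg_filt)
      p_spike <- stats::var(sp_band)
      if (isTRUE(sz$depression[i])) {
        # amplitude-depression onset: attenuate background, no band boost
        ramp <- pmin(seq_len(len) / (2 * fs), 1)
        for (ch in seq_len(nch)) {
          sig[ch, i0:i1] <- sig[ch, i0:i1] * (1 - 0.7 * ramp)
        }
        next
      }
      target <- 10^(sz$band_boost_db[i] / 10)
      for (ch in seq_len(nch)) {
        p_add <- max(p_bg[ch] * target - p_bg[ch] - gains[ch]^2 * p_spike, 0)
        bn <- sqrt(p_add) * band_noise(len, fs, band)
        sig[ch, i0:i1] <- sig[ch, i0:i1] + gains[ch] * spikes + bn
      }
    }
    ann <- if (nrow(sz)) {
      seizure_annotation(sz$onset_s, sz$onset_s + sz$duration_s)
    } else seizure_annotation()
    list(recording = eeg_recording(sig, fs = fs, channel_labels = labels),
         annotation = ann)
  })
}

#' Generate a multi-subject synthetic dataset
#'
#' Subjects share the template configuration but differ in seed and in
#' slightly jittered background parameters (RMS and rhythm amplitude within
#' +/-20%), each with the template's seizures.
#'
#' @param n_subjects number of subjects (>= 2 for cross-validation).
#' @param template a [synth_config()]; per-subject seeds are
#'   `template$seed + 1000 * (subject index)`.
#' @return named list (`subject1`, ...) of lists with `recording` and
#'   `annotation`.
#' @export
generate_dataset <- function(n_subjects = 3, template = synth_config()) {
  if (n_subjects < 1) stopf("need at least one subject")
  out <- list()
  for (s in seq_len(n_subjects)) {
    cfg <- template
    cfg$seed <- template$seed + 1000L * s
    jit <- with_seed(cfg$seed + 1L, stats::runif(2, 0.8, 1.2))
    cfg$sigma_uv <- template$sigma_uv * jit[1]
    cfg$alpha_uv <- template$alpha_uv * jit[2]
    out[[sprintf("subject%d", s)]] <- generate_recording(cfg)
  }
  out
}

#' Write a synthetic recording as EDF plus annotation files
#'
#' Produces `<name>.edf`, a CHB-MIT-style `<name>-summary.txt`, and a
#' `<name>-seizures.csv`, all of which round-trip through the package's
#' readers.
#'
#' @param rec an `eeg_recording`.
#' @param ann a [seizure_annotation()].
#' @param dir output directory (created if missing).
#' @param name file stem (default `"synthetic"`).
#' @return named character vector of the written paths.
#' @export
write_synthetic_edf <- function(rec, ann, dir, name = "synthetic") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  edf <- file.path(dir, paste0(name, ".edf"))
  write_edf(rec, edf)
  summ <- file.path(dir, paste0(name, "-summary.txt"))
  lines <- c(sprintf("File Name: %s.edf", name),
             sprintf("Number of Seizures in File: %d", nrow(ann)))
  for (i in seq_len(nrow(ann))) {
    lines <- c(lines,
               sprintf("Seizure %d Start Time: %g seconds", i, ann$onset_s[i]),
               sprintf("Seizure %d End Time: %g seconds", i, ann$offset_s[i]))
  }
  writeLines(lines, summ)
  csv <- file.path(dir, paste0(name, "-seizures.csv"))
  utils::write.csv(data.frame(recording = paste0(name, ".edf"),
                              onset_s = ann$onset_s,
                              offset_s = ann$offset_s),
                   csv, row.names = FALSE, quote = FALSE)
  c(edf = edf, summary = summ, csv = csv)
}
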