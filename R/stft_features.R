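#' Sliding-window configuration
#'
#' The real-time analysis unit: a 1.35-s window (345 samples at 256 Hz)
#' advanced with 1-s overlap. The hop is computed in samples:
#' `345 - round(1.0 * 256) = 89` samples (~0.348 s).
#'
#' @param window_s window length in seconds (default 1.35).
#' @param overlap_s overlap between consecutive windows in seconds (default 1).
#' @param fs sampling rate in Hz.
#' @return object of class `window_config` with derived `window_samples` and
#'   `hop_samples`.
#' @export
window_config <- function(window_s = 1.35, overlap_s = 1.0, fs = 256) {
  if (overlap_s < 0 || overlap_s >= window_s) {
    stopf("need 0 <= overlap_s < window_s")
  }
  ws <- as.integer(floor(window_s * fs))
  hop <- as.integer(ws - round(overlap_s * fs))
  if (hop < 1) stopf("hop must be >= 1 sample")
  structure(list(window_s = window_s, overlap_s = overlap_s, fs = fs,
                 window_samples = ws, hop_samples = hop),
            class = "window_config")
}

#' STFT parameters
#'
#' Defaults produce the 20 x 344 per-channel image: a 2-sample Hamming
#' window (both taps 0.08) hopped by 1 sample, zero-padded to a 128-point
#' transform (2 Hz bin spacing at 256 Hz), band-limited to 20-60 Hz.
#' Values are log power in dB, floored so silent input stays finite.
#'
#' @param win_len analysis window length in samples (default 2).
#' @param hop hop between frames in samples (default 1).
#' @param nfft transform length; frames are zero-padded to this (default 128).
#' @param fs sampling rate in Hz.
#' @param band `(low_hz, high_hz)`; bins with center frequency in the
#'   half-open interval `[low, high)` are kept (20 bins at defaults).
#' @param floor_db log-power floor in dB (default -120).
#' @return object of class `stft_params` (includes the Hamming `window`).
#' @export
stft_params <- function(win_len = 2, hop = 1, nfft = 128, fs = 256,
                        band = c(20, 60), floor_db = -120) {
  if (win_len < 1 || hop < 1 || nfft < win_len) {
    stopf("need win_len >= 1, hop >= 1, nfft >= win_len")
  }
  if (length(band) != 2 || band[1] < 0 || band[2] <= band[1] ||
      band[1] > fs / 2) {
    stopf("band must lie within [0, fs/2]")
  }
  w <- if (win_len == 1) 1 else {
    nn <- 0:(win_len - 1)
    0.54 - 0.46 * cos(2 * pi * nn / (win_len - 1))
  }
  structure(list(win_len = win_len, hop = hop, nfft = nfft, fs = fs,
                 band = as.numeric(band), floor_db = floor_db, window = w),
            class = "stft_params")
}

#' Named rhythm bands
#'
#' Standard EEG rhythm bands plus the pipeline's selected band:
#' delta 1-4, theta 4-8, alpha 8-12, beta 12-30, gamma 30-60, and
#' selected 20-60 Hz.
#'
#' @param name one of `"delta"`, `"theta"`, `"alpha"`, `"beta"`, `"gamma"`,
#'   `"selected"`.
#' @return numeric `(low_hz, high_hz)`.
#' @export
rhythm_band <- function(name) {
  bands <- list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 12),
                beta = c(12, 30), gamma = c(30, 60), selected = c(20, 60))
  if (!name %in% names(bands)) {
    stopf("unknown band '%s' (know: %s)", name,
          paste(names(bands), collapse = ", "))
  }
  bands[[name]]
}

#' Frequency bins selected by the band
#'
#' @param p an [stft_params()].
#' @return list with `index` (1-based FFT bin indices) and `freq_hz`
#'   (bin center frequencies, spacing `fs/nfft`).
#' @export
band_bins <- function(p) {
  k <- 0:(p$nfft %/% 2)
  f <- k * p$fs / p$nfft
  sel <- f >= p$band[1] & f < p$band[2]
  if (!any(sel)) stopf("band [%g, %g) selects zero bins", p$band[1], p$band[2])
  list(index = k[sel] + 1L, freq_hz = f[sel])
}

#' Number of STFT frames for a signal length
#' @param n signal length in samples.
#' @param p an [stft_params()].
#' @return `floor((n - win_len)/hop) + 1` (0 when `n < win_len`).
#' @export
n_frames <- function(n, p) {
  if (n < p$win_len) return(0L)
  as.integer((n - p$win_len) %/% p$hop + 1L)
}

# Complex band-limited STFT, vectorized over frames: for each window tap n,
# S[k, f] += w[n] * x[start_f + n] * exp(-2i pi k n / nfft).
stft_band_complex <- function(x, p) {
  bb <- band_bins(p)
  nf <- n_frames(length(x), p)
  if (nf == 0) {
    return(matrix(complex(real = 0), length(bb$index), 0))
  }
  starts <- seq.int(1L, by = p$hop, length.out = nf)
  kk <- bb$index - 1L
  S <- matrix(0 + 0i, length(kk), nf)
  for (n in seq_len(p$win_len) - 1L) {
    cn <- p$window[n + 1L] * exp(-2i * pi * kk * n / p$nfft)
    S <- S + cn %o% x[starts + n]
  }
  S
}

#' Band-limited log-power STFT of one channel window
#'
#' Frames of `win_len` samples, Hamming-weighted, hopped by `hop`, are
#' zero-padded to `nfft` points and transformed; squared magnitudes of the
#' bins inside the band are converted to dB and floored at `floor_db`.
#'
#' @param x numeric vector (one channel of a window segment).
#' @param p an [stft_params()].
#' @return matrix `n_band_bins x n_frames` of log power (dB), with attribute
#'   `freq_hz` (bin centers). 345 samples at defaults give 20 x 344.
#' @export
stft_channel <- function(x, p = stft_params()) {
  if (length(x) < p$win_len) {
    stopf("signal (%d samples) shorter than win_len (%d)",
          length(x), p$win_len)
  }
  S <- stft_band_complex(x, p)
  out <- pmax(10 * log10(Mod(S)^2), p$floor_db)
  attr(out, "freq_hz") <- band_bins(p)$freq_hz
  out
}

#' Enumerate sliding windows over a recording
#'
#' Windows start at sample offsets 0, hop, 2 hop, ...; the last window lies
#' fully inside the recording (no padding). A recording shorter than one
#' window yields zero windows.
#'
#' @param rec an `eeg_recording`.
#' @param cfg a [window_config()].
#' @param materialize if `TRUE` (default) return segments with sample data;
#'   otherwise only start times/offsets.
#' @return data.frame with `start_s` and 0-based `offset` columns; when
#'   materialized, a list-column `samples` of channels x window matrices.
#' @export
sliding_windows <- function(rec, cfg = window_config(fs = rec$fs),
                            materialize = TRUE) {
  offs <- window_offsets(ncol(rec$signals), cfg)
  out <- data.frame(start_s = offs / cfg$fs, offset = offs)
  if (materialize && length(offs)) {
    out$samples <- lapply(offs, function(o) {
      rec$signals[, (o + 1):(o + cfg$window_samples), drop = FALSE]
    })
  }
  out
}

#' 0-based sample offsets of all complete windows
#' @param n_samples total samples available.
#' @param cfg a [window_config()].
#' @return integer vector (possibly empty).
#' @export
window_offsets <- function(n_samples, cfg) {
  n_samples <- as.integer(n_samples)
  if (n_samples < cfg$window_samples) return(integer())
  seq.int(0L, n_samples - cfg$window_samples, by = cfg$hop_samples)
}

#' Stack per-channel spectrogram blocks into one epoch image
#'
#' Vertical concatenation in channel order: rows `(i-1)*B + 1 .. i*B` belong
#' to channel `i`, where `B` is the per-channel bin count. Six 20 x 344
#' blocks give the 120 x 344 epoch (41,280 values).
#'
#' @param per_channel list of equally shaped log-power matrices.
#' @param start_s window start time in seconds.
#' @param channel_labels labels in block order.
#' @return matrix of class `spectrogram_epoch` with attributes `start_s`,
#'   `channel_labels`, `freq_hz`.
#' @export
stack_channels <- function(per_channel, start_s = 0, channel_labels = NULL) {
  dims <- vapply(per_channel, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stopf("channel spectrogram shapes differ")
  }
  ep <- do.call(rbind, per_channel)
  attr(ep, "start_s") <- start_s
  attr(ep, "channel_labels") <- channel_labels %||%
    paste0("CH", seq_along(per_channel))
  attr(ep, "freq_hz") <- attr(per_channel[[1]], "freq_hz")
  class(ep) <- c("spectrogram_epoch", class(ep))
  ep
}

#' Label a window against seizure annotations
#'
#' A window `[start, start + window_s)` is `"seizure-active"` iff its overlap
#' with any annotated interval reaches `min_overlap_frac * window_s`
#' (default half the window), else `"seizure-free"`.
#'
#' @param start_s window start(s), seconds (vectorized).
#' @param window_s window length in seconds.
#' @param ann a [seizure_annotation()].
#' @param min_overlap_frac fraction of the window that must be ictal.
#' @return character vector of labels.
#' @export
label_window <- function(start_s, window_s, ann, min_overlap_frac = 0.5) {
  if (nrow(ann) == 0) {
    return(rep("seizure-free", length(start_s)))
  }
  need <- min_overlap_frac * window_s
  lab <- vapply(start_s, function(s) {
    ov <- pmax(0, pmin(s + window_s, ann$offset_s) - pmax(s, ann$onset_s))
    if (sum(ov) >= need) "seizure-active" else "seizure-free"
  }, character(1))
  lab
}

#' Extract all spectrogram epochs of a recording
#'
#' The pipeline path from a (filtered) recording to CNN inputs. With the
#' default 1-sample STFT hop, the per-channel spectrogram is computed once
#' over the full signal and sliced per window (identical to running
#' [stft_channel()] on each window, but far cheaper). Otherwise each window
#' is transformed individually.
#'
#' @param rec an `eeg_recording` (already band-pass filtered).
#' @param wcfg a [window_config()].
#' @param p an [stft_params()].
#' @param ann optional [seizure_annotation()]; adds labels.
#' @param offsets optional integer vector of 0-based window offsets to use
#'   (default: all complete windows).
#' @param min_overlap_frac labeling rule threshold, see [label_window()].
#' @return list with `epochs` (array rows x frames x n), `start_s`, `labels`
#'   (or `NULL`), `freq_hz`, `channel_labels`.
#' @export
extract_epochs <- function(rec, wcfg = window_config(fs = rec$fs),
                           p = stft_params(fs = rec$fs), ann = NULL,
                           offsets = NULL, min_overlap_frac = 0.5) {
  offs <- offsets %||% window_offsets(ncol(rec$signals), wcfg)
  nch <- nrow(rec$signals)
  bb <- band_bins(p)
  fpw <- n_frames(wcfg$window_samples, p)
  n <- length(offs)
  epochs <- array(p$floor_db, dim = c(nch * length(bb$index), fpw, n))
  if (n > 0) {
    if (p$hop == 1L) {
      for (ch in seq_len(nch)) {
        G <- stft_channel(rec$signals[ch, ], p)
        rows <- ((ch - 1) * length(bb$index) + 1):(ch * length(bb$index))
        for (i in seq_len(n)) {
          epochs[rows, , i] <- G[, (offs[i] + 1):(offs[i] + fpw)]
        }
      }
    } else {
      for (i in seq_len(n)) {
        per_ch <- lapply(seq_len(nch), function(ch) {
          stft_channel(rec$signals[ch, (offs[i] + 1):
                                     (offs[i] + wcfg$window_samples)], p)
        })
        epochs[, , i] <- do.call(rbind, per_ch)
      }
    }
  }
  start_s <- offs / wcfg$fs
  labels <- if (!is.null(ann)) {
    label_window(start_s, wcfg$window_s, ann, min_overlap_frac)
  }
  list(epochs = epochs, start_s = start_s, labels = labels,
       freq_hz = bb$freq_hz, channel_labels = rec$channel_labels)
}

#' Persist / load labeled epoch sets
#'
#' Epoch tensors with labels and the generating parameters, stored as a
#' single RDS file.
#'
#' @param epoch_set a list as returned by [extract_epochs()].
#' @param path file path.
#' @return `save_epochs`: `path` invisibly; `load_epochs`: the list.
#' @export
save_epochs <- function(epoch_set, path) {
  saveRDS(epoch_set, path)
  invisible(path)
}

#' @rdname save_epochs
#' @export
load_epochs <- function(path) readRDS(path)
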