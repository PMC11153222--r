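# shared in-code fixtures

# small multichannel recording with named channels
toy_recording <- function(seconds = 10, fs = 256, nch = 6, seed = 1,
                          labels = default_channels()) {
  withr::with_seed(seed, {
    eeg_recording(matrix(rnorm(nch * seconds * fs), nch), fs = fs,
                  channel_labels = labels[seq_len(nch)])
  })
}

# linearly separable spectrogram epochs: seizure-active epochs carry a
# +20 dB offset in the second channel block
toy_epochs <- function(n = 40, seed = 9, sd = 2, offset_db = 20) {
  lab <- rep(detector_classes(), length.out = n)
  eps <- withr::with_seed(seed, {
    e <- array(-60 + rnorm(120 * 344 * n, sd = sd), c(120, 344, n))
    e[21:40, , lab == "seizure-active"] <-
      e[21:40, , lab == "seizure-active"] + offset_db
    e
  })
  list(epochs = eps, labels = lab)
}

# decisions data.frame on a regular 1-s grid
toy_decisions <- function(positive_at, t_max = 500, window_s = 1.35,
                          step = 1) {
  st <- seq(0, t_max, by = step)
  lab <- ifelse(st %in% positive_at, "seizure-active", "seizure-free")
  d <- data.frame(start_s = st, label = lab,
                  probability = ifelse(lab == "seizure-active", 0.9, 0.1),
                  stringsAsFactors = FALSE)
  attr(d, "window_s") <- window_s
  d
}

# independent brute-force event scorer (exhaustive interval scan)
oracle_events <- function(decisions, ann, pre_tol = 0, k = 1) {
  st <- decisions$start_s
  pos <- decisions$label == "seizure-active"
  asserted <- logical(length(pos))
  for (i in seq_along(pos)) {
    if (i >= k) asserted[i] <- all(pos[(i - k + 1):i])
  }
  kind <- character(); anni <- integer(); det <- numeric(); del <- numeric()
  matched <- logical(length(st))
  for (j in seq_len(nrow(ann))) {
    hit <- NA_integer_
    for (i in seq_along(st)) {
      if (asserted[i] && st[i] >= ann$onset_s[j] - pre_tol &&
          st[i] < ann$offset_s[j]) { hit <- i; break }
    }
    if (!is.na(hit)) {
      kind <- c(kind, "TP"); anni <- c(anni, j)
      det <- c(det, st[hit]); del <- c(del, st[hit] - ann$onset_s[j])
      for (i in seq_along(st)) {
        if (st[i] >= ann$onset_s[j] - pre_tol && st[i] < ann$offset_s[j]) {
          matched[i] <- TRUE
        }
      }
    } else {
      kind <- c(kind, "missed"); anni <- c(anni, j)
      det <- c(det, NA_real_); del <- c(del, NA_real_)
    }
  }
  fp <- asserted & !matched
  i <- 1
  while (i <= length(fp)) {
    if (fp[i]) {
      kind <- c(kind, "FP_event"); anni <- c(anni, NA_integer_)
      det <- c(det, st[i]); del <- c(del, NA_real_)
      while (i <= length(fp) && fp[i]) i <- i + 1
    } else i <- i + 1
  }
  data.frame(kind = kind, annotation_index = anni, detection_time_s = det,
             delay_s = del)
}

# random decision/annotation configuration for property fuzzing
random_case <- function(seed) {
  withr::with_seed(seed, {
    n <- sample(10:60, 1)
    st <- cumsum(runif(n, 0.2, 2))
    lab <- sample(detector_classes(), n, replace = TRUE, prob = c(0.7, 0.3))
    d <- data.frame(start_s = st, label = lab,
                    probability = runif(n), stringsAsFactors = FALSE)
    attr(d, "window_s") <- 1.35
    nint <- sample(0:3, 1)
    if (nint > 0) {
      bounds <- sort(runif(2 * nint, 0, max(st) + 2))
      ann <- seizure_annotation(bounds[seq(1, 2 * nint, 2)],
                                bounds[seq(2, 2 * nint, 2)])
    } else ann <- seizure_annotation()
    list(decisions = d, ann = ann,
         pre_tol = sample(c(0, 0.5, 2), 1), k = sample(1:3, 1))
  })
}
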