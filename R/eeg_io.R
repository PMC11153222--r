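#' Multichannel EEG recording container
#'
#' Bundles a channels-by-samples signal matrix (microvolts) with its sampling
#' rate and channel labels. All pipeline stages consume this object.
#'
#' @param signals numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz (CHB-MIT recordings use 256).
#' @param channel_labels character vector, one unique label per row.
#' @param start_time offset of the first sample in seconds (default 0).
#' @return An object of class `eeg_recording` with fields `signals`, `fs`,
#'   `channel_labels`, `start_time`.
#' @export
eeg_recording <- function(signals, fs = 256, channel_labels = NULL,
                          start_time = 0) {
  if (!is.matrix(signals)) signals <- matrix(signals, nrow = 1)
  storage.mode(signals) <- "double"
  if (is.null(channel_labels)) {
    channel_labels <- paste0("CH", seq_len(nrow(signals)))
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stopf("fs must be a single positive number, got %s", format(fs))
  }
  if (length(channel_labels) != nrow(signals)) {
    stopf("%d channel labels for %d signal rows",
          length(channel_labels), nrow(signals))
  }
  if (anyDuplicated(channel_labels)) {
    stopf("duplicate channel labels: %s",
          paste(unique(channel_labels[duplicated(channel_labels)]),
                collapse = ", "))
  }
  structure(list(signals = signals, fs = fs,
                 channel_labels = as.character(channel_labels),
                 start_time = start_time),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channel(s) x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$signals), ncol(x$signals), x$fs, duration_s(x)))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an `eeg_recording`.
#' @return length in seconds (`n_samples / fs`).
#' @export
duration_s <- function(rec) ncol(rec$signals) / rec$fs

#' Seizure annotation: onset/offset intervals
#'
#' Intervals are seconds from recording start, closed at onset and open at
#' offset: `[onset, offset)`. The constructor sorts intervals by onset so
#' parsing is insensitive to input order.
#'
#' @param onset_s,offset_s numeric vectors of equal length (may be empty).
#' @return Object of class `seizure_annotation`: a data.frame with columns
#'   `onset_s`, `offset_s`, sorted, validated non-overlapping.
#' @export
seizure_annotation <- function(onset_s = numeric(), offset_s = numeric()) {
  onset_s <- as.numeric(onset_s %||% numeric())
  offset_s <- as.numeric(offset_s %||% numeric())
  if (length(onset_s) != length(offset_s)) {
    stopf("onset_s and offset_s lengths differ")
  }
  if (any(!is.finite(onset_s)) || any(!is.finite(offset_s))) {
    stopf("non-finite annotation times")
  }
  if (any(offset_s <= onset_s)) {
    bad <- which(offset_s <= onset_s)[1]
    stopf("interval %d has offset (%g) <= onset (%g)",
          bad, offset_s[bad], onset_s[bad])
  }
  o <- order(onset_s)
  df <- data.frame(onset_s = as.numeric(onset_s[o]),
                   offset_s = as.numeric(offset_s[o]))
  if (nrow(df) > 1 && any(df$onset_s[-1] < df$offset_s[-nrow(df)])) {
    stopf("annotation intervals overlap")
  }
  class(df) <- c("seizure_annotation", "data.frame")
  df
}

#' @export
print.seizure_annotation <- function(x, ...) {
  cat(sprintf("<seizure_annotation> %d interval(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(x)
  invisible(x)
}

n_seizures <- function(ann) nrow(ann)

#' Default six-channel analysis montage
#'
#' The six bipolar channels used for detection, chosen near the frontal,
#' temporal and occipital seizure-onset zones: P3-O1, FP2-F8, P8-O2, P7-T7,
#' T7-FT9, FT10-T8 (in this fixed order).
#'
#' @return character vector of six channel labels.
#' @export
default_channels <- function() {
  c("P3-O1", "FP2-F8", "P8-O2", "P7-T7", "T7-FT9", "FT10-T8")
}

# Canonical form for channel-label comparison: uppercase, all dash variants
# (en/em dash, spaced hyphen) collapsed to "-", whitespace stripped.
canonical_label <- function(x) {
  x <- toupper(x)
  x <- gsub("–|—", "-", x)
  x <- gsub("[[:space:]]*-[[:space:]]*", "-", x)
  gsub("^[[:space:]]+|[[:space:]]+$", "", x)
}

#' Select and order analysis channels
#'
#' Reduces a recording to the requested channels, in the requested order.
#' Labels are compared after canonicalization (case and dash style are
#' ignored), so "P3 - O1" in a file header matches "P3-O1".
#'
#' @param rec an `eeg_recording`.
#' @param labels channel labels to keep, default [default_channels()].
#' @return `eeg_recording` with `length(labels)` rows in the given order.
#' @export
select_channels <- function(rec, labels = default_channels()) {
  have <- canonical_label(rec$channel_labels)
  want <- canonical_label(labels)
  idx <- match(want, have)
  if (anyNA(idx)) {
    stopf("channel(s) not found in recording: %s",
          paste(labels[is.na(idx)], collapse = ", "))
  }
  eeg_recording(rec$signals[idx, , drop = FALSE], fs = rec$fs,
                channel_labels = labels, start_time = rec$start_time)
}

# ---------------------------------------------------------------------------
# EDF reader / writer (16-bit integer records, ASCII header)

edf_pad <- function(x, n) {
  s <- substr(as.character(x), 1, n)
  formatC(s, width = -n, flag = " ")
}

#' Write a recording to an EDF file
#'
#' Writes a plain EDF (16-bit samples, one-second data records). The physical
#' range is set per channel to cover the data symmetrically, so values
#' round-trip within one 16-bit quantization step. The recording is truncated
#' to a whole number of seconds if needed (with a warning).
#'
#' @param rec an `eeg_recording`.
#' @param path output file path.
#' @param phys_dim physical dimension string (default "uV").
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, phys_dim = "uV") {
  fs <- rec$fs
  if (fs != round(fs)) stopf("EDF writer requires an integer sampling rate")
  ns <- nrow(rec$signals)
  n_rec <- floor(ncol(rec$signals) / fs)
  if (n_rec < 1) stopf("recording shorter than one 1-s EDF data record")
  if (n_rec * fs < ncol(rec$signals)) {
    warning(sprintf("truncating %d trailing samples to whole EDF records",
                    ncol(rec$signals) - n_rec * fs))
  }
  sig <- rec$signals[, seq_len(n_rec * fs), drop = FALSE]

  pmax_ <- apply(abs(sig), 1, max)
  pmax_ <- ifelse(pmax_ > 0, ceiling(pmax_ * 1.01), 1)
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad("1", 8), edf_pad(ns, 4))
  sig_hdr <- paste0(
    paste(edf_pad(rec$channel_labels, 16), collapse = ""),
    paste(edf_pad(rep("", ns), 80), collapse = ""),
    paste(edf_pad(rep(phys_dim, ns), 8), collapse = ""),
    paste(edf_pad(-pmax_, 8), collapse = ""),
    paste(edf_pad(pmax_, 8), collapse = ""),
    paste(edf_pad(rep(dmin, ns), 8), collapse = ""),
    paste(edf_pad(rep(dmax, ns), 8), collapse = ""),
    paste(edf_pad(rep("", ns), 80), collapse = ""),
    paste(edf_pad(rep(fs, ns), 8), collapse = ""),
    paste(edf_pad(rep("", ns), 32), collapse = ""))
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL, useBytes = TRUE)

  scale <- (dmax - dmin) / (2 * pmax_)
  dig <- round((sig + pmax_) * scale + dmin)
  dig <- pmin(pmax(dig, dmin), dmax)
  # records: for each second, all channels sequentially
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con,
             size = 2, endian = "little")
  }
  invisible(path)
}

read_ascii <- function(con, n) {
  rawToChar(readBin(con, "raw", n))
}

trimws_ <- function(x) gsub("^[[:space:]]+|[[:space:]]+$", "", x)

#' Read an EDF/EDF+ recording
#'
#' Parses the EDF header and 16-bit data records, rescaling to physical units.
#' Labels and the sampling rate are taken from the header as stored; no
#' resampling is performed. Signals whose sampling rate differs from the
#' majority rate are dropped with a warning (EDF+ annotation channels).
#'
#' @param path EDF file path.
#' @param fs_expected if given, an error is raised when the header sampling
#'   rate differs (configuration guard).
#' @return an `eeg_recording`.
#' @export
read_edf_recording <- function(path, fs_expected = NULL) {
  if (!file.exists(path)) stopf("EDF file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  read_ascii(con, 8)                      # version
  read_ascii(con, 80); read_ascii(con, 80)
  read_ascii(con, 8);  read_ascii(con, 8)
  hdr_bytes <- as.integer(read_ascii(con, 8))
  read_ascii(con, 44)
  n_rec <- as.integer(read_ascii(con, 8))
  rec_dur <- as.numeric(read_ascii(con, 8))
  ns <- as.integer(read_ascii(con, 4))
  if (is.na(ns) || ns < 1 || is.na(n_rec) || n_rec < 1 ||
      is.na(rec_dur) || rec_dur <= 0) {
    stopf("malformed EDF header in %s", path)
  }
  field <- function(w) trimws_(substring(read_ascii(con, w * ns),
                                         (seq_len(ns) - 1) * w + 1,
                                         seq_len(ns) * w))
  labels <- field(16); field(80)
  field(8)                                 # phys dim
  pmin_ <- as.numeric(field(8)); pmax_ <- as.numeric(field(8))
  dmin <- as.numeric(field(8)); dmax <- as.numeric(field(8))
  field(80)
  spr <- as.integer(field(8)); field(32)
  if (anyNA(c(pmin_, pmax_, dmin, dmax, spr))) {
    stopf("malformed EDF signal headers in %s", path)
  }
  if (hdr_bytes != 256 * (1 + ns)) {
    stopf("EDF header size field inconsistent in %s", path)
  }

  raw_all <- readBin(con, "integer", n_rec * sum(spr), size = 2,
                     signed = TRUE, endian = "little")
  if (length(raw_all) < n_rec * sum(spr)) stopf("EDF data truncated in %s", path)

  fs_all <- spr / rec_dur
  fs <- as.numeric(names(sort(table(fs_all), decreasing = TRUE))[1])
  keep <- which(fs_all == fs & labels != "EDF Annotations")
  if (length(keep) < ns) {
    warning(sprintf("dropping %d channel(s) with non-majority sampling rate",
                    ns - length(keep)))
  }
  if (!is.null(fs_expected) && fs != fs_expected) {
    stopf("EDF sampling rate %g Hz does not match expected %g Hz",
          fs, fs_expected)
  }

  sig <- matrix(0, length(keep), n_rec * spr[keep[1]])
  offs <- c(0, cumsum(spr))
  per_rec <- sum(spr)
  for (i in seq_along(keep)) {
    ch <- keep[i]
    idx <- as.vector(outer(offs[ch] + seq_len(spr[ch]),
                           (seq_len(n_rec) - 1) * per_rec, `+`))
    g <- (pmax_[ch] - pmin_[ch]) / (dmax[ch] - dmin[ch])
    sig[i, ] <- (raw_all[idx] - dmin[ch]) * g + pmin_[ch]
  }
  eeg_recording(sig, fs = fs, channel_labels = labels[keep])
}

# ---------------------------------------------------------------------------
# Annotation readers

parse_chbmit_summary <- function(lines) {
  out <- list()
  cur <- NULL; onsets <- numeric(); offsets <- numeric()
  flush <- function() {
    if (!is.null(cur)) out[[cur]] <<- seizure_annotation(onsets, offsets)
  }
  for (ln in lines) {
    if (grepl("^File Name:", ln)) {
      flush()
      cur <- trimws_(sub("^File Name:", "", ln))
      onsets <- numeric(); offsets <- numeric()
    } else if (grepl("^Seizure( [0-9]+)? Start Time:", ln)) {
      onsets <- c(onsets, as.numeric(gsub("[^0-9.]", "", sub(".*Time:", "", ln))))
    } else if (grepl("^Seizure( [0-9]+)? End Time:", ln)) {
      offsets <- c(offsets, as.numeric(gsub("[^0-9.]", "", sub(".*Time:", "", ln))))
    }
  }
  flush()
  out
}

#' Read seizure annotations
#'
#' Supported dialects:
#' \describe{
#'   \item{chbmit_summary}{plain text with `File Name:`,
#'     `Seizure [k] Start Time: N seconds`, `Seizure [k] End Time: N seconds`
#'     lines (the CHB-MIT summary style).}
#'   \item{csv}{columns `onset_s`, `offset_s` and optionally `recording`.}
#'   \item{json}{object mapping recording name to a list of
#'     `{"onset_s": ..., "offset_s": ...}` entries.}
#' }
#'
#' @param path annotation file.
#' @param dialect one of `"chbmit_summary"`, `"csv"`, `"json"`.
#' @return named list: recording name -> [seizure_annotation()]. CSV files
#'   without a `recording` column yield one element named `""`.
#' @export
read_annotations <- function(path,
                             dialect = c("chbmit_summary", "csv", "json")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  if (dialect == "chbmit_summary") {
    ann <- parse_chbmit_summary(readLines(path, warn = FALSE))
  } else if (dialect == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("onset_s", "offset_s") %in% names(df))) {
      stopf("CSV annotations need onset_s and offset_s columns")
    }
    key <- if ("recording" %in% names(df)) df$recording else rep("", nrow(df))
    ann <- lapply(split(df, key), function(d) {
      seizure_annotation(d$onset_s, d$offset_s)
    })
  } else {
    js <- jsonlite::read_json(path, simplifyVector = TRUE)
    ann <- lapply(js, function(d) {
      if (length(d) == 0) return(seizure_annotation())
      seizure_annotation(d$onset_s, d$offset_s)
    })
  }
  ann
}

#' Write / read detection events as CSV
#'
#' @param events data.frame with columns `time_s`, `label`, `probability`.
#' @param path CSV path.
#' @return `write_events`: `path` invisibly; `read_events`: the data.frame.
#' @export
write_events <- function(events, path) {
  if (is.null(events) || nrow(events) == 0) {
    events <- data.frame(time_s = numeric(), label = character(),
                         probability = numeric())
  }
  utils::write.csv(events[, c("time_s", "label", "probability")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("numeric", "character", "numeric"))
  df
}
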