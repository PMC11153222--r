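#' Run the detector over a recording as a causal sliding-window stream
#'
#' Emits one decision per sliding window. Each decision uses only the
#' samples inside its own window (the per-window spectrogram is a function
#' of those samples alone), so truncating the recording reproduces exactly
#' the decisions of the windows that still fit.
#'
#' @param model a trained `cnn_model`.
#' @param rec an `eeg_recording` (already band-pass filtered, or pass
#'   `fspec` to filter inline).
#' @param wcfg a [window_config()].
#' @param p an [stft_params()].
#' @param fspec optional [filter_spec()] applied before windowing.
#' @param batch windows per inference batch.
#' @param timing if `TRUE`, record per-window processing time (attribute
#'   `timing_s`, seconds, averaged within each inference batch).
#' @return data.frame of class `window_decisions` with columns `start_s`,
#'   `label`, `probability`; attributes `window_s` and optionally
#'   `timing_s`.
#' @export
stream_detect <- function(model, rec, wcfg = window_config(fs = rec$fs),
                          p = stft_params(fs = rec$fs), fspec = NULL,
                          batch = 128L, timing = FALSE) {
  if (!is.null(fspec)) rec <- apply_zero_phase(rec, fspec)
  offs <- window_offsets(ncol(rec$signals), wcfg)
  n <- length(offs)
  if (n == 0) {
    out <- data.frame(start_s = numeric(), label = character(),
                      probability = numeric())
    attr(out, "window_s") <- wcfg$window_s
    class(out) <- c("window_decisions", "data.frame")
    return(out)
  }
  labs <- character(n)
  prob <- numeric(n)
  times <- if (timing) numeric(n) else NULL
  i <- 1L
  while (i <= n) {
    j <- min(i + batch - 1L, n)
    t0 <- proc.time()[["elapsed"]]
    es <- extract_epochs(rec, wcfg, p, offsets = offs[i:j])
    pr <- predict_epoch(model, es$epochs, batch = batch)
    if (timing) times[i:j] <- (proc.time()[["elapsed"]] - t0) / (j - i + 1L)
    labs[i:j] <- pr$label
    prob[i:j] <- pr$probability
    i <- j + 1L
  }
  out <- data.frame(start_s = offs / wcfg$fs, label = labs,
                    probability = prob, stringsAsFactors = FALSE)
  attr(out, "window_s") <- wcfg$window_s
  if (timing) attr(out, "timing_s") <- times
  class(out) <- c("window_decisions", "data.frame")
  out
}

#' Convert window decisions into detection events
#'
#' A positive is asserted at window `i` when `smoothing_k` consecutive
#' windows ending at `i` are positive (`k = 1` means raw decisions). Each
#' annotated seizure is matched to the first asserted-positive window whose
#' start lies in `[onset - pre_tolerance_s, offset)`; that window's start
#' time is the detection time and `delay_s = detection_time - onset`.
#' Seizures with no such window become `missed` events. Runs of asserted
#' positives entirely outside every (tolerance-extended) annotated interval
#' are grouped into `FP_event` rows; extra positives inside an already
#' matched interval are neither TPs nor FPs.
#'
#' @param decisions a `window_decisions` data.frame from [stream_detect()].
#' @param ann a [seizure_annotation()].
#' @param pre_tolerance_s seconds before onset in which a detection still
#'   counts as the seizure's true positive (default 0).
#' @param smoothing_k consecutive positive windows required (default 1).
#' @return data.frame with columns `kind` (`TP`/`missed`/`FP_event`),
#'   `annotation_index`, `detection_time_s`, `delay_s`.
#' @export
extract_events <- function(decisions, ann, pre_tolerance_s = 0,
                           smoothing_k = 1L) {
  pos <- decisions$label == "seizure-active"
  k <- max(1L, as.integer(smoothing_k))
  asserted <- pos
  if (k > 1L && length(pos)) {
    run <- 0L
    for (i in seq_along(pos)) {
      run <- if (pos[i]) run + 1L else 0L
      asserted[i] <- run >= k
    }
  }
  st <- decisions$start_s
  ev <- list()
  in_matched <- rep(FALSE, length(st))
  for (j in seq_len(nrow(ann))) {
    lo <- ann$onset_s[j] - pre_tolerance_s
    hi <- ann$offset_s[j]
    inside <- st >= lo & st < hi
    hit <- which(asserted & inside)
    if (length(hit)) {
      ev[[length(ev) + 1]] <- data.frame(
        kind = "TP", annotation_index = j,
        detection_time_s = st[hit[1]],
        delay_s = st[hit[1]] - ann$onset_s[j])
      in_matched <- in_matched | inside
    } else {
      ev[[length(ev) + 1]] <- data.frame(
        kind = "missed", annotation_index = j,
        detection_time_s = NA_real_, delay_s = NA_real_)
    }
  }
  fp <- asserted & !in_matched
  if (any(fp)) {
    r <- rle(fp)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      ev[[length(ev) + 1]] <- data.frame(
        kind = "FP_event", annotation_index = NA_integer_,
        detection_time_s = st[starts[i]], delay_s = NA_real_)
    }
  }
  if (!length(ev)) {
    return(data.frame(kind = character(), annotation_index = integer(),
                      detection_time_s = numeric(), delay_s = numeric()))
  }
  do.call(rbind, ev)
}

#' Per-window processing-time report
#'
#' Informational only (hardware dependent); requires [stream_detect()] to
#' have been run with `timing = TRUE`.
#'
#' @param decisions a `window_decisions` data.frame.
#' @return data.frame with one row per window (`start_s`, `elapsed_s`), or
#'   zero rows when timing was not enabled.
#' @export
measure_latency <- function(decisions) {
  t <- attr(decisions, "timing_s")
  if (is.null(t)) {
    return(data.frame(start_s = numeric(), elapsed_s = numeric()))
  }
  data.frame(start_s = decisions$start_s, elapsed_s = t)
}

#' Decisions as an events table
#'
#' @param decisions a `window_decisions` data.frame.
#' @return data.frame suitable for [write_events()] (`time_s`, `label`,
#'   `probability`).
#' @export
decisions_to_events <- function(decisions) {
  data.frame(time_s = decisions$start_s, label = decisions$label,
             probability = decisions$probability)
}
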