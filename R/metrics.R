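#' Window-level confusion counts
#'
#' @param TP,TN,FP,FN nonnegative window counts.
#' @return object of class `confusion`.
#' @export
confusion <- function(TP = 0, TN = 0, FP = 0, FN = 0) {
  if (any(c(TP, TN, FP, FN) < 0)) stopf("confusion counts must be >= 0")
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN), class = "confusion")
}

#' Score window decisions against annotations
#'
#' Each window's ground truth comes from the same overlap rule used for
#' training labels ([label_window()]): seizure-active iff at least
#' `min_overlap_frac` of the window lies inside an annotated interval.
#'
#' @param decisions a `window_decisions` data.frame ([stream_detect()]).
#' @param ann a [seizure_annotation()].
#' @param window_s window length in seconds (default: the decisions'
#'   `window_s` attribute).
#' @param min_overlap_frac labeling threshold (default 0.5).
#' @return a [confusion()].
#' @export
window_confusion <- function(decisions, ann, window_s = NULL,
                             min_overlap_frac = 0.5) {
  window_s <- window_s %||% attr(decisions, "window_s")
  if (is.null(window_s)) stopf("window_s not given and not an attribute")
  truth <- label_window(decisions$start_s, window_s, ann, min_overlap_frac)
  pos <- decisions$label == "seizure-active"
  tru <- truth == "seizure-active"
  confusion(TP = sum(pos & tru), TN = sum(!pos & !tru),
            FP = sum(pos & !tru), FN = sum(!pos & tru))
}

#' Window accuracy in percent
#'
#' `100 (TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param c a [confusion()].
#' @return percentage in `[0, 100]` (unrounded).
#' @export
accuracy <- function(c) {
  tot <- c$TP + c$TN + c$FP + c$FN
  if (tot == 0) stopf("empty confusion")
  100 * (c$TP + c$TN) / tot
}

#' Event-based sensitivity in percent
#'
#' `100 * detected / seizures`, reported to two decimals (half-up): the
#' fraction of annotated seizures with at least one true-positive
#' detection.
#'
#' @param n_detected detected seizure count.
#' @param n_seizures annotated seizure count (> 0).
#' @return percentage, rounded to two decimals.
#' @export
event_sensitivity <- function(n_detected, n_seizures) {
  if (n_seizures <= 0) stopf("sensitivity undefined for zero seizures")
  if (n_detected > n_seizures) stopf("detected > seizures")
  round_half_up(100 * n_detected / n_seizures, 2)
}

#' Window false-positive rate in percent
#'
#' `100 FP / (FP + TN)`: the fraction of truly seizure-free windows flagged
#' seizure-active.
#'
#' @param c a [confusion()].
#' @return percentage in `[0, 100]` (unrounded).
#' @export
fp_rate <- function(c) {
  if (c$FP + c$TN == 0) stopf("no seizure-free windows; FP rate undefined")
  100 * c$FP / (c$FP + c$TN)
}

#' Evaluate one recording (case)
#'
#' Combines event extraction and window scoring into one per-case row.
#'
#' @param decisions a `window_decisions` data.frame.
#' @param ann a [seizure_annotation()].
#' @param case case identifier.
#' @param pre_tolerance_s,smoothing_k see [extract_events()].
#' @param min_overlap_frac see [window_confusion()].
#' @return one-row data.frame: `case`, `n_seizures`, `n_detected`,
#'   `fp_rate_pct`, `sensitivity_pct`, `mean_delay_s`, `accuracy_pct`.
#' @export
evaluate_case <- function(decisions, ann, case = "case",
                          pre_tolerance_s = 0, smoothing_k = 1L,
                          min_overlap_frac = 0.5) {
  ev <- extract_events(decisions, ann, pre_tolerance_s, smoothing_k)
  cf <- window_confusion(decisions, ann, min_overlap_frac = min_overlap_frac)
  nd <- sum(ev$kind == "TP")
  ns <- nrow(ann)
  data.frame(case = case, n_seizures = ns, n_detected = nd,
             fp_rate_pct = fp_rate(cf),
             sensitivity_pct = if (ns > 0) event_sensitivity(nd, ns)
                               else NA_real_,
             mean_delay_s = if (nd > 0) mean(ev$delay_s[ev$kind == "TP"])
                            else NA_real_,
             accuracy_pct = accuracy(cf),
             stringsAsFactors = FALSE)
}

#' Pool per-case results into an evaluation report
#'
#' Pooled sensitivity uses summed counts
#' (`100 sum(detected) / sum(seizures)`); FP rate, accuracy and delay are
#' averaged over cases (delay over cases with at least one detection), as
#' in per-patient evaluation tables.
#'
#' @param per_case data.frame of rows from [evaluate_case()].
#' @return object of class `eval_report`: list with `per_case` and `pooled`
#'   (one-row data.frame).
#' @export
aggregate_cases <- function(per_case) {
  if (is.null(per_case) || nrow(per_case) == 0) stopf("no cases to pool")
  tot_s <- sum(per_case$n_seizures)
  tot_d <- sum(per_case$n_detected)
  pooled <- data.frame(
    n_cases = nrow(per_case),
    total_seizures = tot_s,
    total_detected = tot_d,
    mean_fp_rate_pct = mean(per_case$fp_rate_pct),
    pooled_sensitivity_pct = if (tot_s > 0) event_sensitivity(tot_d, tot_s)
                             else NA_real_,
    mean_delay_s = if (any(per_case$n_detected > 0))
      mean(per_case$mean_delay_s[per_case$n_detected > 0]) else NA_real_,
    mean_accuracy_pct = mean(per_case$accuracy_pct))
  structure(list(per_case = per_case, pooled = pooled),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  pc <- x$per_case
  num <- vapply(pc, is.numeric, logical(1))
  pc[num] <- lapply(pc[num], round_half_up, 2)
  print.data.frame(pc, row.names = FALSE)
  cat("pooled:\n")
  pl <- x$pooled
  pl[] <- lapply(pl, function(v) if (is.numeric(v)) round_half_up(v, 2) else v)
  print.data.frame(pl, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report
#'
#' CSV mirrors the per-case table columns (case, number of seizures, true
#' positives, FP rate %, sensitivity %, delay s, accuracy %) with the
#' pooled row appended; JSON carries both tables verbatim.
#'
#' @param report an `eval_report`.
#' @param path output path; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(per_case = report$per_case,
                              pooled = report$pooled),
                         path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    pc <- report$per_case
    pooled <- report$pooled
    pooled_row <- data.frame(
      case = "pooled", n_seizures = pooled$total_seizures,
      n_detected = pooled$total_detected,
      fp_rate_pct = pooled$mean_fp_rate_pct,
      sensitivity_pct = pooled$pooled_sensitivity_pct,
      mean_delay_s = pooled$mean_delay_s,
      accuracy_pct = pooled$mean_accuracy_pct, stringsAsFactors = FALSE)
    out <- rbind(pc, pooled_row)
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], round_half_up, 2)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
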