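#' Bin event onsets into fixed-width time bins
#'
#' Counts events whose onset falls in each half-open bin `[k*w, (k+1)*w)`
#' covering `[0, total_span]`. The default 4-h bin width matches the
#' longitudinal seizure-burden plots.
#'
#' @param events data.frame with an `onset_s` column (seconds), e.g. from
#'   [detect_ictal()].
#' @param bin_width_h bin width in hours (default 4).
#' @param total_span_h total span covered, in hours.
#' @return data.frame with `bin_start_h`, `bin_mid_h`, `count`.
#' @export
bin_events <- function(events, bin_width_h = 4, total_span_h) {
  if (bin_width_h <= 0) stop("bin width must be positive")
  if (total_span_h <= 0) stop("total span must be positive")
  onset_h <- events$onset_s / 3600
  if (nrow(events) > 0 && any(onset_h < 0 | onset_h > total_span_h))
    stop("event onsets outside the span")
  n_bins <- ceiling(total_span_h / bin_width_h)
  edges <- (0:n_bins) * bin_width_h
  counts <- vapply(seq_len(n_bins), function(k)
    sum(onset_h >= edges[k] & onset_h < edges[k + 1]), integer(1))
  data.frame(bin_start_h = edges[-length(edges)],
             bin_mid_h = edges[-length(edges)] + bin_width_h / 2,
             count = counts)
}

#' Seizure-burden summary
#'
#' Summarises a detected event table over a recording span: counts per
#' 4-h bin, the trapezoidal area under the binned count curve (over bin
#' midpoints, in events x hours), mean event duration, and onset latency
#' (time of the earliest event; `NA` when no events occurred).
#'
#' @param events data.frame with `onset_s` and `duration_s` columns.
#' @param total_span_h span of the recording in hours (> 0).
#' @param bin_width_h bin width in hours (default 4).
#' @return list of class `burden_summary`: `bins`, `auc_event_hours`,
#'   `n_events`, `mean_duration_s` (NA when empty), `onset_latency_h`
#'   (NA when empty).
#' @export
burden_summary <- function(events, total_span_h, bin_width_h = 4) {
  if (total_span_h <= 0) stop("total span must be positive")
  bins <- bin_events(events, bin_width_h, total_span_h)
  auc <- if (nrow(bins) >= 2)
    pracma::trapz(bins$bin_mid_h, bins$count) else 0
  n_ev <- nrow(events)
  structure(list(
    bins = bins,
    auc_event_hours = auc,
    n_events = n_ev,
    mean_duration_s = if (n_ev > 0) mean(events$duration_s) else NA_real_,
    onset_latency_h = if (n_ev > 0) min(events$onset_s) / 3600 else
      NA_real_), class = "burden_summary")
}

#' @export
print.burden_summary <- function(x, ...) {
  cat(sprintf(
    "<burden_summary> %d event(s); AUC %.2f event-hours; mean duration %s s; onset latency %s h\n",
    x$n_events, x$auc_event_hours,
    if (is.na(x$mean_duration_s)) "NA" else sprintf("%.1f", x$mean_duration_s),
    if (is.na(x$onset_latency_h)) "NA" else sprintf("%.2f", x$onset_latency_h)))
  invisible(x)
}
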