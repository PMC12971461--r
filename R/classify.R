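#' Classifier thresholds for the five-criterion majority vote
#'
#' Bundles the numeric cut-points and baseline feature references used to
#' label an event generalized versus focal. The published cut-points are a
#' delta/fast-gamma power ratio of 1.5 (above favors generalized) and an
#' alpha/beta ratio of 1.2 (above is the focal signature); entropy,
#' coherence and Hurst criteria compare against the baseline-window means.
#' An event is called generalized when at least `min_generalized_votes` of
#' the five generalized-favoring criteria are met.
#'
#' @param delta_fastgamma_cut cut on the delta/fast-gamma ratio (default 1.5).
#' @param alpha_beta_cut cut on the alpha/beta ratio (default 1.2).
#' @param entropy_reference,coherence_reference,hurst_reference baseline
#'   means, typically filled from [estimate_baseline()].
#' @param min_generalized_votes votes needed for a generalized call
#'   (default 3, of 5).
#' @param count_alpha_beta_negation if TRUE (default) the absence of the
#'   focal alpha/beta signature counts as a generalized-favoring vote, so
#'   that five comparable votes exist; if FALSE vote 2 is always FALSE and
#'   only four criteria can favor generalized.
#' @return list of class `classifier_thresholds`.
#' @export
classifier_thresholds <- function(delta_fastgamma_cut = 1.5,
                                  alpha_beta_cut = 1.2,
                                  entropy_reference = NA_real_,
                                  coherence_reference = NA_real_,
                                  hurst_reference = NA_real_,
                                  min_generalized_votes = 3L,
                                  count_alpha_beta_negation = TRUE) {
  if (delta_fastgamma_cut <= 0 || alpha_beta_cut <= 0)
    stop("cut-points must be positive")
  if (!min_generalized_votes %in% 1:5)
    stop("min_generalized_votes must be in 1..5")
  structure(list(delta_fastgamma_cut = delta_fastgamma_cut,
                 alpha_beta_cut = alpha_beta_cut,
                 entropy_reference = entropy_reference,
                 coherence_reference = coherence_reference,
                 hurst_reference = hurst_reference,
                 min_generalized_votes = as.integer(min_generalized_votes),
                 count_alpha_beta_negation = count_alpha_beta_negation),
            class = "classifier_thresholds")
}

#' Build thresholds from baseline statistics
#' @param baseline a `baseline_stats` from [estimate_baseline()].
#' @param ... overrides passed to [classifier_thresholds()].
#' @return a `classifier_thresholds`.
#' @export
thresholds_from_baseline <- function(baseline, ...) {
  stopifnot(inherits(baseline, "baseline_stats"))
  classifier_thresholds(entropy_reference = baseline$entropy,
                        coherence_reference = baseline$coherence,
                        hurst_reference = baseline$hurst, ...)
}

#' The five criterion votes for one feature vector
#'
#' Each vote is TRUE when the criterion favors a generalized seizure:
#' 1. delta/fast-gamma ratio > cut (low-frequency dominance);
#' 2. NOT(alpha/beta ratio > cut) — absence of the focal signature;
#' 3. spectral entropy > baseline reference (greater unpredictability);
#' 4. mean coherence > baseline reference (network synchrony);
#' 5. Hurst exponent < baseline reference (less temporal persistence).
#' All comparisons are strict; ties favor the focal (less severe) label.
#'
#' @param features a `feature_vector` from [extract_features()], or a named
#'   list with `delta_fastgamma_ratio`, `alpha_beta_ratio`,
#'   `spectral_entropy`, `mean_coherence`, `hurst`.
#' @param thresholds a `classifier_thresholds`.
#' @return named logical vector of length 5.
#' @export
criterion_votes <- function(features, thresholds) {
  stopifnot(inherits(thresholds, "classifier_thresholds"))
  need <- c("delta_fastgamma_ratio", "alpha_beta_ratio",
            "spectral_entropy", "mean_coherence", "hurst")
  ref <- c(delta_fastgamma_ratio = NA, alpha_beta_ratio = NA,
           spectral_entropy = thresholds$entropy_reference,
           mean_coherence = thresholds$coherence_reference,
           hurst = thresholds$hurst_reference)
  for (f in need) {
    v <- features[[f]]
    if (is.null(v) || !is.finite(v))
      stop("missing or non-finite feature: ", f)
  }
  for (f in c("spectral_entropy", "mean_coherence", "hurst"))
    if (!is.finite(ref[[f]]))
      stop("missing baseline reference for feature: ", f)
  v2 <- if (thresholds$count_alpha_beta_negation)
    !(features$alpha_beta_ratio > thresholds$alpha_beta_cut) else FALSE
  c(delta_fastgamma = features$delta_fastgamma_ratio >
      thresholds$delta_fastgamma_cut,
    alpha_beta = v2,
    entropy = features$spectral_entropy > thresholds$entropy_reference,
    coherence = features$mean_coherence > thresholds$coherence_reference,
    hurst = features$hurst < thresholds$hurst_reference)
}

#' Majority-vote feature call
#'
#' @param votes logical vector of exactly 5 criterion votes.
#' @param thresholds a `classifier_thresholds` (supplies
#'   `min_generalized_votes`).
#' @return `"generalized"` when the number of TRUE votes meets the minimum,
#'   otherwise `"focal"`.
#' @export
classify_event <- function(votes, thresholds = classifier_thresholds()) {
  if (length(votes) != 5 || !is.logical(votes) || any(is.na(votes)))
    stop("exactly 5 non-missing logical votes required")
  if (sum(votes) >= thresholds$min_generalized_votes) "generalized"
  else "focal"
}

#' Channel-extent call for a spike-wave event
#'
#' Focal spike-wave events are confined to a single channel; generalized
#' events are detected simultaneously across multiple channels.
#'
#' @param channels character vector of channel labels, or a single
#'   ";"-separated string as emitted by [detect_ictal()].
#' @return `"focal"` or `"generalized"`.
#' @export
channel_extent <- function(channels) {
  if (length(channels) == 1 && is.character(channels))
    channels <- strsplit(channels, ";", fixed = TRUE)[[1]]
  channels <- channels[nzchar(channels)]
  if (length(channels) == 0) stop("event has an empty channel set")
  if (length(channels) == 1) "focal" else "generalized"
}

#' Detect, featurize and classify every event in a recording
#'
#' Runs the full per-recording pipeline: RMS-threshold detection against the
#' baseline, per-event feature extraction over the event window (extended
#' symmetrically to at least 1024 samples so the Hurst estimator is
#' defined), the five-criterion majority vote, and the channel-extent rule.
#'
#' @param rec an `eeg_recording` (already band-pass filtered).
#' @param baseline a `baseline_stats` for the same channels.
#' @param thresholds optional `classifier_thresholds`; defaults to
#'   [thresholds_from_baseline()] of `baseline`.
#' @param ... passed to [detect_ictal()].
#' @return data.frame with one row per event: detection columns plus the
#'   five votes, `vote_count`, `feature_call`, `extent_call`.
#' @export
classify_recording <- function(rec, baseline, thresholds = NULL, ...) {
  stopifnot(inherits(rec, "eeg_recording"),
            inherits(baseline, "baseline_stats"))
  if (is.null(thresholds)) thresholds <- thresholds_from_baseline(baseline)
  events <- detect_ictal(rec, baseline, ...)
  empty <- data.frame(onset_s = numeric(), duration_s = numeric(),
                      channels = character(), n_channels = integer(),
                      peak_rms_ratio = numeric(),
                      vote_delta_fastgamma = logical(),
                      vote_alpha_beta = logical(), vote_entropy = logical(),
                      vote_coherence = logical(), vote_hurst = logical(),
                      vote_count = integer(), feature_call = character(),
                      extent_call = character(), stringsAsFactors = FALSE)
  if (nrow(events) == 0) return(empty)
  fs <- rec$sampling_rate
  n <- ncol(rec$signal)
  rows <- lapply(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    i0 <- round(ev$onset_s * fs) + 1L
    i1 <- round((ev$onset_s + ev$duration_s) * fs)
    # extend the window to >= 1024 samples for the Hurst estimator
    short <- 1024L - (i1 - i0 + 1L)
    if (short > 0) {
      i0 <- max(1L, i0 - ceiling(short / 2))
      i1 <- min(n, i0 + 1023L)
      i0 <- max(1L, i1 - 1023L)
    }
    chans <- strsplit(ev$channels, ";", fixed = TRUE)[[1]]
    ch_idx <- match(chans, rec$channel_labels)
    fv <- tryCatch(
      extract_features(rec$signal[, i0:i1, drop = FALSE], fs,
                       channels = ch_idx),
      error = function(e)
        stop("feature extraction failed for event ", i, ": ",
             conditionMessage(e)))
    votes <- criterion_votes(fv, thresholds)
    cbind(ev,
          data.frame(vote_delta_fastgamma = votes[["delta_fastgamma"]],
                     vote_alpha_beta = votes[["alpha_beta"]],
                     vote_entropy = votes[["entropy"]],
                     vote_coherence = votes[["coherence"]],
                     vote_hurst = votes[["hurst"]],
                     vote_count = sum(votes),
                     feature_call = classify_event(votes, thresholds),
                     extent_call = channel_extent(ev$channels),
                     stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}
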