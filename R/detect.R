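#' Root-mean-square amplitude of an epoch
#'
#' @param x numeric vector of samples.
#' @return `sqrt(mean(x^2))` in the signal's unit.
#' @export
compute_rms <- function(x) {
  if (length(x) == 0) stop("empty epoch")
  sqrt(mean(x^2))
}

#' Estimate baseline statistics over a designated window
#'
#' Computes per-channel baseline RMS and the baseline feature references the
#' classifier compares events against (spectral entropy, mean pairwise
#' coherence, Hurst exponent, and mean band powers). RMS, entropy and band
#' powers are averaged over non-overlapping 4-s epochs in the window; the
#' Hurst exponent uses 8-s epochs (the estimator needs >= 1024 samples);
#' coherence is estimated once over the whole window.
#'
#' @param rec an `eeg_recording`.
#' @param window numeric length-2 `(start, end)` in seconds; must lie inside
#'   the recording and span at least 60 s.
#' @return list of class `baseline_stats`: `rms` (per channel, named),
#'   `band_power` (named, mean over channels and epochs), `entropy`,
#'   `coherence`, `hurst`, `window`.
#' @export
estimate_baseline <- function(rec, window) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate
  if (length(window) != 2 || window[1] < 0 ||
      window[2] > ncol(rec$signal) / fs)
    stop("baseline window outside the recording")
  if (diff(window) < 60)
    stop("baseline window must span at least 60 s")
  i0 <- round(window[1] * fs) + 1L
  i1 <- round(window[2] * fs)
  seg <- rec$signal[, i0:i1, drop = FALSE]
  nch <- nrow(seg)
  win4 <- round(4 * fs)
  starts4 <- seq(1L, ncol(seg) - win4 + 1L, by = win4)
  rms <- vapply(seq_len(nch), function(ch)
    mean(vapply(starts4, function(s)
      compute_rms(seg[ch, s:(s + win4 - 1L)]), numeric(1))), numeric(1))
  pw <- Reduce(`+`, lapply(seq_len(nch), function(ch) {
    Reduce(`+`, lapply(starts4, function(s)
      band_powers(seg[ch, s:(s + win4 - 1L)], fs))) / length(starts4)
  })) / nch
  ent <- mean(vapply(seq_len(nch), function(ch)
    mean(vapply(starts4, function(s)
      spectral_entropy(welch_psd(seg[ch, s:(s + win4 - 1L)], fs)),
      numeric(1))), numeric(1)))
  coh <- if (nch >= 2) {
    prs <- utils::combn(nch, 2)
    mean(vapply(seq_len(ncol(prs)), function(j)
      coherence(seg[prs[1, j], ], seg[prs[2, j], ], fs)$mean_msc,
      numeric(1)))
  } else NA_real_
  win8 <- round(8 * fs)
  starts8 <- seq(1L, ncol(seg) - win8 + 1L, by = win8)
  hur <- mean(vapply(seq_len(nch), function(ch)
    mean(vapply(starts8, function(s)
      hurst_rs(seg[ch, s:(s + win8 - 1L)]), numeric(1))), numeric(1)))
  structure(list(
    rms = stats::setNames(rms, rec$channel_labels),
    band_power = pw, entropy = ent, coherence = coh, hurst = hur,
    window = window), class = "baseline_stats")
}

#' Detect ictal-like events by RMS threshold against baseline
#'
#' Slides a short RMS window along each channel and flags epochs whose RMS
#' is strictly greater than `ratio` times that channel's baseline RMS.
#' Contiguous flagged epochs (gaps up to `merge_gap_s`) are merged into
#' events; events shorter than `min_duration_s` are discarded; events that
#' are simultaneous across channels (onset-interval intersection over union
#' >= 0.5) are merged into one multichannel event.
#'
#' @param rec an `eeg_recording`.
#' @param baseline a `baseline_stats` from [estimate_baseline()] estimated
#'   on the same channels.
#' @param ratio detection threshold as a multiple of baseline RMS
#'   (default 3; flagging requires RMS strictly greater than
#'   `ratio * baseline`).
#' @param min_duration_s discard events shorter than this (default 2 s).
#' @param merge_gap_s merge flagged runs separated by gaps up to this
#'   (default 2 s).
#' @param window_s,hop_s RMS sliding window and hop (defaults 2 s and 1 s).
#' @param exclude_baseline drop detections inside the baseline window
#'   (default TRUE).
#' @return data.frame with one row per event: `onset_s`, `duration_s`,
#'   `channels` (";"-separated labels), `n_channels`, `peak_rms_ratio`.
#' @export
detect_ictal <- function(rec, baseline, ratio = 3, min_duration_s = 2,
                         merge_gap_s = 2, window_s = 2, hop_s = 1,
                         exclude_baseline = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"),
            inherits(baseline, "baseline_stats"))
  if (ratio <= 0) stop("ratio must be positive")
  if (!identical(names(baseline$rms), rec$channel_labels))
    stop("baseline was estimated on different channels")
  fs <- rec$sampling_rate
  win <- round(window_s * fs)
  hop <- round(hop_s * fs)
  n <- ncol(rec$signal)
  starts <- seq(1L, n - win + 1L, by = hop)
  per_ch <- list()
  for (ch in seq_len(nrow(rec$signal))) {
    rms <- vapply(starts, function(s)
      compute_rms(rec$signal[ch, s:(s + win - 1L)]), numeric(1))
    rr <- rms / baseline$rms[ch]
    flag <- rr > ratio
    if (exclude_baseline) {
      t0 <- (starts - 1L) / fs
      t1 <- t0 + window_s
      flag[t1 > baseline$window[1] & t0 < baseline$window[2]] <- FALSE
    }
    per_ch[[ch]] <- .runs_to_events(flag, rr, starts, win, fs,
                                    merge_gap_s, min_duration_s)
    if (nrow(per_ch[[ch]]) > 0)
      per_ch[[ch]]$channel <- rec$channel_labels[ch]
  }
  evs <- do.call(rbind, Filter(function(d) nrow(d) > 0, per_ch))
  if (is.null(evs) || nrow(evs) == 0)
    return(data.frame(onset_s = numeric(), duration_s = numeric(),
                      channels = character(), n_channels = integer(),
                      peak_rms_ratio = numeric(), stringsAsFactors = FALSE))
  .merge_simultaneous(evs)
}

# turn a logical flag sequence over sliding epochs into merged events
.runs_to_events <- function(flag, rr, starts, win, fs, merge_gap_s,
                            min_duration_s) {
  out <- data.frame(onset_s = numeric(), duration_s = numeric(),
                    peak_rms_ratio = numeric())
  if (!any(flag)) return(out)
  idx <- which(flag)
  t0 <- (starts[idx] - 1L) / fs
  t1 <- t0 + win / fs
  # merge flagged epochs whose gaps are <= merge_gap_s
  grp <- cumsum(c(1, diff(t0) > (win / fs + merge_gap_s)))
  for (g in unique(grp)) {
    sel <- idx[grp == g]
    onset <- (starts[sel[1]] - 1L) / fs
    end <- (starts[sel[length(sel)]] - 1L + win) / fs
    if (end - onset >= min_duration_s)
      out <- rbind(out, data.frame(onset_s = onset,
                                   duration_s = end - onset,
                                   peak_rms_ratio = max(rr[sel])))
  }
  out
}

# merge per-channel events that are simultaneous (interval IoU >= 0.5)
.merge_simultaneous <- function(evs) {
  evs <- evs[order(evs$onset_s), , drop = FALSE]
  k <- nrow(evs)
  group <- seq_len(k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    a0 <- evs$onset_s[i]; a1 <- a0 + evs$duration_s[i]
    b0 <- evs$onset_s[j]; b1 <- b0 + evs$duration_s[j]
    inter <- max(0, min(a1, b1) - max(a0, b0))
    uni <- max(a1, b1) - min(a0, b0)
    if (uni > 0 && inter / uni >= 0.5)
      group[group == group[j]] <- group[i]
  }
  rows <- lapply(unique(group), function(g) {
    sub <- evs[group == g, , drop = FALSE]
    on <- min(sub$onset_s)
    off <- max(sub$onset_s + sub$duration_s)
    data.frame(onset_s = on, duration_s = off - on,
               channels = paste(sort(unique(sub$channel)), collapse = ";"),
               n_channels = length(unique(sub$channel)),
               peak_rms_ratio = max(sub$peak_rms_ratio),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$onset_s), , drop = FALSE]
}
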