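#' Multichannel EEG recording container
#'
#' Bundles a channels-by-samples signal matrix (microvolts) with its sampling
#' rate, channel labels, electrode montage and acquisition metadata. All
#' analysis functions in the package operate on this container.
#'
#' @param signal numeric matrix, channels in rows, samples in columns, in uV.
#' @param sampling_rate sampling frequency in Hz.
#' @param channel_labels character vector, one label per row of `signal`.
#' @param montage optional named list mapping each label to a 2-D position
#'   (numeric length-2). Defaults to the package's 4-lead epidural montage
#'   when the labels match it.
#' @param meta named list of free-form metadata (subject id, group, start
#'   time, ...).
#'
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(signal, sampling_rate, channel_labels = NULL,
                      montage = NULL, meta = list()) {
  if (!is.matrix(signal) || !is.numeric(signal))
    stop("`signal` must be a numeric matrix (channels x samples)")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0)
    stop("`sampling_rate` must be a single positive number")
  if (any(!is.finite(signal)))
    stop("signal contains non-finite samples")
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(nrow(signal)))
  if (length(channel_labels) != nrow(signal))
    stop("one channel label per signal row is required")
  structure(
    list(signal = signal,
         sampling_rate = sampling_rate,
         channel_labels = as.character(channel_labels),
         montage = montage,
         meta = meta),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$signal), ncol(x$signal), x$sampling_rate,
              ncol(x$signal) / x$sampling_rate))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples and duration helpers
#' @param x an `eeg_recording`.
#' @return `n_samples()` the number of samples per channel; `duration()` the
#'   recording length in seconds.
#' @export
n_samples <- function(x) ncol(x$signal)

#' @rdname n_samples
#' @export
duration <- function(x) ncol(x$signal) / x$sampling_rate
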