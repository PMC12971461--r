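# Minimal European Data Format (EDF) reader/writer covering the subset the
# pipeline emits: continuous 16-bit signals, one sampling rate for all
# channels, 1-second data records. Physical unit is uV.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Stores the signal as 16-bit integers in 1-second data records with a
#' symmetric physical range spanning the data, so quantization error is at
#' most (physical range) / 2^16 per sample. The number of samples per
#' channel must be a multiple of the sampling rate (whole seconds).
#'
#' @param rec an `eeg_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate
  if (abs(fs - round(fs)) > 1e-9)
    stop("write_edf requires an integer sampling rate")
  fs <- as.integer(round(fs))
  ns <- ncol(rec$signal)
  if (ns %% fs != 0)
    stop("samples per channel must be a whole number of seconds")
  n_rec <- ns %/% fs
  n_ch <- nrow(rec$signal)
  phys_max <- max(abs(rec$signal), 1e-6)
  dig_min <- -32768L; dig_max <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8),
    .edf_pad(if (!is.null(rec$meta$subject)) rec$meta$subject else "X", 80),
    .edf_pad("ictalkit recording", 80),
    .edf_pad("01.01.26", 8), .edf_pad("00.00.00", 8),
    .edf_pad(256L * (1L + n_ch), 8),
    .edf_pad("", 44),
    .edf_pad(n_rec, 8),
    .edf_pad("1", 8),
    .edf_pad(n_ch, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste0(vapply(vals, .edf_pad, "", width = width),
                     collapse = ""), con, eos = NULL)
  field(rec$channel_labels, 16)
  field(rep("", n_ch), 80)                       # transducer
  field(rep("uV", n_ch), 8)                      # physical dimension
  field(rep(sprintf("%g", -phys_max), n_ch), 8)  # physical min
  field(rep(sprintf("%g", phys_max), n_ch), 8)   # physical max
  field(rep(dig_min, n_ch), 8)
  field(rep(dig_max, n_ch), 8)
  field(rep("BP:1-120Hz", n_ch), 80)             # prefiltering note
  field(rep(fs, n_ch), 8)                        # samples per record
  field(rep("", n_ch), 32)
  scale <- (dig_max - dig_min) / (2 * phys_max)
  dig <- round((rec$signal + phys_max) * scale) + dig_min
  dig <- pmin(pmax(dig, dig_min), dig_max)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con, size = 2,
             endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Supports continuous EDF with a common sampling rate across channels (the
#' format this package writes). Mixed per-channel sampling rates raise an
#' unsupported-format error.
#'
#' @param path EDF file path.
#' @return an `eeg_recording` with samples in the file's physical unit.
#' @export
read_edf <- function(path) {
  if (!file.exists(path))
    stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8)
  subject <- rd(80); rec_id <- rd(80)
  rd(8); rd(8)                                  # date, time
  hdr_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  n_ch <- as.integer(rd(4))
  if (is.na(n_ch) || n_ch < 1 || is.na(n_rec))
    stop("corrupt EDF header in ", path)
  labels <- vapply(seq_len(n_ch), function(i) rd(16), "")
  invisible(vapply(seq_len(n_ch), function(i) rd(80), ""))  # transducer
  units <- vapply(seq_len(n_ch), function(i) rd(8), "")
  pmin_ <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), ""))
  invisible(vapply(seq_len(n_ch), function(i) rd(80), ""))  # prefilter
  spr <- as.integer(vapply(seq_len(n_ch), function(i) rd(8), ""))
  invisible(vapply(seq_len(n_ch), function(i) rd(32), ""))
  if (length(unique(spr)) != 1L)
    stop("unsupported EDF: mixed sampling rates across channels in ", path)
  fs <- spr[1] / rec_dur
  sig <- matrix(0, n_ch, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    blk <- readBin(con, integer(), n = n_ch * spr[1], size = 2,
                   endian = "little", signed = TRUE)
    if (length(blk) < n_ch * spr[1])
      stop("corrupt EDF: truncated data records in ", path)
    m <- matrix(blk, nrow = spr[1], ncol = n_ch)
    for (ch in seq_len(n_ch)) {
      gain <- (pmax_[ch] - pmin_[ch]) / (dmax_[ch] - dmin_[ch])
      sig[ch, ((r - 1L) * spr[1] + 1L):(r * spr[1])] <-
        (m[, ch] - dmin_[ch]) * gain + pmin_[ch]
    }
  }
  recording(sig, fs, channel_labels = labels,
            meta = list(subject = subject, recording_id = rec_id,
                        unit = units[1]))
}
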