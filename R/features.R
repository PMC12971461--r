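#' The six-band analysis scheme
#'
#' The canonical EEG frequency bands used throughout the pipeline:
#' Delta (1-4 Hz), Theta (4-8), Alpha (8-12), Beta (12-30),
#' Slow Gamma (30-60) and Fast Gamma (70-120). Note the deliberate
#' 60-70 Hz inter-band gap between the gamma bands; band powers omit it,
#' while spectral entropy uses the full 1-120 Hz range.
#'
#' @return data.frame with columns `band`, `low`, `high` (Hz).
#' @export
band_scheme <- function() {
  data.frame(
    band = c("Delta", "Theta", "Alpha", "Beta", "SlowGamma", "FastGamma"),
    low  = c(1, 4, 8, 12, 30, 70),
    high = c(4, 8, 12, 30, 60, 120),
    stringsAsFactors = FALSE)
}

#' Welch power spectral density estimate
#'
#' One-sided averaged-periodogram PSD: the signal is split into Hann-
#' windowed segments with 50% overlap, each segment's periodogram is
#' density-scaled, and the segments are averaged. With this scaling the
#' integral of the PSD over frequency approximates the signal variance
#' (Parseval).
#'
#' @param x numeric vector (one channel of one epoch).
#' @param fs sampling rate in Hz.
#' @param nperseg segment length in samples; default 2 s worth, shrunk when
#'   the epoch is short so that at least one full segment fits.
#' @param demean subtract the segment mean before windowing (default TRUE).
#' @return list with `freq` (Hz) and `psd` (power per Hz), class `eeg_psd`.
#' @export
welch_psd <- function(x, fs, nperseg = NULL, demean = TRUE) {
  n <- length(x)
  if (n < 2 * fs)
    stop("epoch too short for PSD: need at least 2 s of samples")
  if (is.null(nperseg)) nperseg <- min(round(2 * fs), n)
  nperseg <- min(nperseg, n)
  step <- max(1L, floor(nperseg / 2))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nperseg) / (nperseg + 1)))  # Hann
  scale <- fs * sum(w^2)
  nfreq <- floor(nperseg / 2) + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    if (demean) seg <- seg - mean(seg)
    X <- stats::fft(seg * w)[seq_len(nfreq)]
    acc <- acc + (Mod(X)^2) / scale
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when nperseg even)
  dbl <- rep(2, nfreq)
  dbl[1] <- 1
  if (nperseg %% 2 == 0) dbl[nfreq] <- 1
  psd <- psd * dbl
  structure(list(freq = (seq_len(nfreq) - 1) * fs / nperseg, psd = psd),
            class = "eeg_psd")
}

#' Integrated band power from a PSD
#'
#' Trapezoidal integral of the PSD over `[low, high)` Hz, in uV^2.
#'
#' @param psd an `eeg_psd` from [welch_psd()].
#' @param band numeric length-2 `(low, high)` in Hz, or a band name from
#'   [band_scheme()].
#' @return power in uV^2.
#' @export
band_power <- function(psd, band) {
  stopifnot(inherits(psd, "eeg_psd"))
  if (is.character(band)) {
    scheme <- band_scheme()
    if (!band %in% scheme$band) stop("unknown band name: ", band)
    band <- as.numeric(scheme[scheme$band == band, c("low", "high")])
  }
  if (band[1] >= band[2]) stop("band low edge must be below high edge")
  if (band[1] < min(psd$freq) || band[2] > max(psd$freq))
    stop("band [", band[1], ", ", band[2], "] outside PSD frequency range")
  keep <- psd$freq >= band[1] & psd$freq < band[2]
  if (sum(keep) < 2) return(0)
  pracma::trapz(psd$freq[keep], psd$psd[keep])
}

#' All six band powers of an epoch
#' @param x numeric vector; @param fs Hz; @param ... passed to [welch_psd()].
#' @return named numeric vector, one entry per band of [band_scheme()].
#' @export
band_powers <- function(x, fs, ...) {
  p <- welch_psd(x, fs, ...)
  scheme <- band_scheme()
  stats::setNames(
    vapply(seq_len(nrow(scheme)), function(i)
      band_power(p, c(scheme$low[i], scheme$high[i])), numeric(1)),
    scheme$band)
}

#' Ratio of two band powers
#'
#' @param powers named numeric vector of band powers (from [band_powers()]).
#' @param numerator,denominator band names.
#' @return numerator power / denominator power.
#' @export
band_ratio <- function(powers, numerator, denominator) {
  for (b in c(numerator, denominator))
    if (!b %in% names(powers)) stop("band not present in powers: ", b)
  if (powers[[denominator]] <= 0)
    stop("undefined band ratio: zero power in denominator band ",
         denominator)
  unname(powers[[numerator]] / powers[[denominator]])
}

#' Normalized spectral (Shannon) entropy of a PSD
#'
#' The PSD over 1-120 Hz is normalized to a probability distribution over
#' frequency bins; its Shannon entropy (base 2) is divided by log2 of the
#' bin count so the result lies in [0, 1]: 0 for power confined to one bin,
#' 1 for an exactly flat spectrum.
#'
#' @param psd an `eeg_psd`.
#' @param range frequency range used, default `c(1, 120)` Hz.
#' @return entropy in [0, 1].
#' @export
spectral_entropy <- function(psd, range = c(1, 120)) {
  stopifnot(inherits(psd, "eeg_psd"))
  keep <- psd$freq >= range[1] & psd$freq <= range[2]
  p <- psd$psd[keep]
  if (length(p) < 2) stop("need at least 2 PSD bins in range")
  if (any(p < 0)) stop("negative PSD values")
  tot <- sum(p)
  if (tot == 0) stop("undefined spectral entropy: all-zero PSD in range")
  p <- p / tot
  nz <- p > 0
  h <- -sum(p[nz] * log2(p[nz]))
  h / log2(length(p))
}

#' Magnitude-squared coherence between two epochs
#'
#' Welch cross-spectral estimate: MSC(f) = |Pxy|^2 / (Pxx Pyy) with Hann-
#' windowed, 50%-overlapping segments, then averaged over the analysis band
#' (1-120 Hz by default). The estimate is biased upward by roughly
#' 1/(number of segments); the default segment length adapts so that at
#' least 8 segments are averaged.
#'
#' @param x,y equal-length numeric vectors.
#' @param fs sampling rate in Hz.
#' @param nperseg segment length; default the largest power of two giving
#'   >= 8 half-overlapping segments (capped at 2 s).
#' @param range frequency band to average over, default `c(1, 120)` Hz.
#' @return list with `freq`, `msc` (per-frequency), `mean_msc`.
#' @export
coherence <- function(x, y, fs, nperseg = NULL, range = c(1, 120)) {
  if (length(x) != length(y)) stop("epochs must have equal length")
  n <- length(x)
  if (is.null(nperseg)) {
    # k segments at 50% overlap need n >= (k+1)/2 * nperseg
    nperseg <- min(round(2 * fs), 2^floor(log2(2 * n / 9)))
  }
  if (nperseg < 8) stop("epoch too short for coherence estimation")
  step <- max(1L, floor(nperseg / 2))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  if (length(starts) < 8)
    stop("need at least 8 Welch segments; shorten nperseg or lengthen epoch")
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nperseg) / (nperseg + 1)))
  nfreq <- floor(nperseg / 2) + 1L
  pxx <- pyy <- numeric(nfreq)
  pxy <- complex(nfreq)
  for (s in starts) {
    sx <- x[s:(s + nperseg - 1L)]; sx <- (sx - mean(sx)) * w
    sy <- y[s:(s + nperseg - 1L)]; sy <- (sy - mean(sy)) * w
    X <- stats::fft(sx)[seq_len(nfreq)]
    Y <- stats::fft(sy)[seq_len(nfreq)]
    pxx <- pxx + Mod(X)^2
    pyy <- pyy + Mod(Y)^2
    pxy <- pxy + X * Conj(Y)
  }
  msc <- Mod(pxy)^2 / (pxx * pyy)
  msc[pxx == 0 | pyy == 0] <- 0
  freq <- (seq_len(nfreq) - 1) * fs / nperseg
  keep <- freq >= range[1] & freq <= range[2]
  list(freq = freq, msc = msc, mean_msc = mean(msc[keep]))
}

# Anis-Lloyd expected R/S for a block of length m under the null
.expected_rs <- function(m) {
  i <- seq_len(m - 1)
  s <- sum(sqrt((m - i) / i))
  if (m <= 340) {
    exp(lgamma((m - 1) / 2) - lgamma(m / 2) - 0.5 * log(pi)) *
      (m - 0.5) / m * s
  } else {
    (m - 0.5) / m * s / sqrt(m * pi / 2)
  }
}

#' Hurst exponent by corrected rescaled-range (R/S) analysis
#'
#' Classical R/S analysis over logarithmically spaced block sizes from 16 to
#' n/4, with the Anis-Lloyd small-sample correction: the fitted exponent is
#' 0.5 plus the slope of log(R/S) minus the slope of the expected log(R/S)
#' of a memoryless process, which removes the well-known upward bias of the
#' raw R/S statistic at finite n.
#'
#' @param x numeric vector, length >= 1024.
#' @param corrected apply the Anis-Lloyd correction (default TRUE).
#' @return Hurst exponent estimate (typically in (0, 1)).
#' @export
hurst_rs <- function(x, corrected = TRUE) {
  n <- length(x)
  if (n < 1024) stop("hurst_rs needs at least 1024 samples")
  if (stats::sd(x) == 0) stop("undefined Hurst exponent: constant signal")
  sizes <- unique(round(exp(seq(log(16), log(n / 4), length.out = 12))))
  rs <- vapply(sizes, function(m) {
    nb <- floor(n / m)
    vals <- vapply(seq_len(nb), function(b) {
      seg <- x[((b - 1) * m + 1):(b * m)]
      d <- seg - mean(seg)
      z <- cumsum(d)
      r <- max(z) - min(z)
      s <- sqrt(mean(d^2))
      if (s == 0) NA_real_ else r / s
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  ok <- is.finite(rs) & rs > 0
  fit <- stats::lm(log(rs[ok]) ~ log(sizes[ok]))
  h_raw <- unname(stats::coef(fit)[2])
  if (!corrected) return(h_raw)
  ers <- vapply(sizes[ok], .expected_rs, numeric(1))
  efit <- stats::lm(log(ers) ~ log(sizes[ok]))
  0.5 + h_raw - unname(stats::coef(efit)[2])
}

#' Per-band PSD normalized against a baseline
#'
#' Divides each of the six band powers of an epoch by the corresponding
#' baseline mean band power, giving the ratio-to-baseline PSD used for
#' burden spectral summaries.
#'
#' @param x numeric vector (epoch samples) or a named band-power vector.
#' @param baseline_powers named numeric vector of baseline mean band powers
#'   (all strictly positive), e.g. from [estimate_baseline()].
#' @param fs sampling rate (needed when `x` is a raw epoch).
#' @return named numeric vector of per-band ratios.
#' @export
normalized_psd <- function(x, baseline_powers, fs = NULL) {
  scheme <- band_scheme()
  if (is.null(names(baseline_powers)) ||
      !all(scheme$band %in% names(baseline_powers)))
    stop("baseline_powers must be named with all six canonical bands")
  bad <- scheme$band[baseline_powers[scheme$band] <= 0]
  if (length(bad))
    stop("zero baseline power in band ", paste(bad, collapse = ", "))
  pw <- if (is.null(names(x))) {
    if (is.null(fs)) stop("fs required when x is a raw epoch")
    band_powers(x, fs)
  } else x
  pw[scheme$band] / baseline_powers[scheme$band]
}

#' Extract the full biomarker vector for a multichannel window
#'
#' Computes, over a channels-by-samples window: six band powers (averaged
#' across the given channels), the delta/fast-gamma and alpha/beta ratios,
#' normalized spectral entropy, RMS amplitude, mean pairwise magnitude-
#' squared coherence (all channel pairs of the recording) and the Hurst
#' exponent (averaged across channels; windows shorter than 1024 samples
#' are rejected).
#'
#' @param sig numeric matrix, channels x samples.
#' @param fs sampling rate in Hz.
#' @param channels integer indices of the channels carrying the activity of
#'   interest (band powers/entropy/RMS/Hurst are computed on these);
#'   coherence always uses all rows of `sig`. Default: all channels.
#' @return named list of class `feature_vector`.
#' @export
extract_features <- function(sig, fs, channels = seq_len(nrow(sig))) {
  stopifnot(is.matrix(sig), length(channels) >= 1)
  pw <- Reduce(`+`, lapply(channels, function(ch)
    band_powers(sig[ch, ], fs))) / length(channels)
  psd_main <- welch_psd(colMeans(sig[channels, , drop = FALSE]), fs)
  ent <- spectral_entropy(psd_main)
  rms <- mean(vapply(channels, function(ch)
    compute_rms(sig[ch, ]), numeric(1)))
  nch <- nrow(sig)
  mean_coh <- if (nch >= 2) {
    prs <- utils::combn(nch, 2)
    mean(vapply(seq_len(ncol(prs)), function(j)
      coherence(sig[prs[1, j], ], sig[prs[2, j], ], fs)$mean_msc,
      numeric(1)))
  } else NA_real_
  hur <- mean(vapply(channels, function(ch)
    hurst_rs(sig[ch, ]), numeric(1)))
  structure(list(
    band_power = pw,
    delta_fastgamma_ratio = band_ratio(pw, "Delta", "FastGamma"),
    alpha_beta_ratio = band_ratio(pw, "Alpha", "Beta"),
    spectral_entropy = ent,
    rms = rms,
    mean_coherence = mean_coh,
    hurst = hur), class = "feature_vector")
}
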