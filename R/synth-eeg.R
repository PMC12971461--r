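#' Specification for a synthetic multichannel EEG recording
#'
#' Describes a 4-channel, 250 Hz epidural-style recording: independent
#' 1/f^slope Gaussian baseline activity on each channel, plus optional
#' scheduled ictal bursts (see [scheduled_event()]). Identical spec + seed
#' reproduces identical output bit-for-bit.
#'
#' @param n_channels number of channels (default 4).
#' @param sampling_rate Hz; must exceed 240 Hz (twice the highest analysis
#'   band edge, 120 Hz). Default 250.
#' @param duration recording length in seconds (> 0).
#' @param seed integer seed driving all randomness for this spec.
#' @param baseline_amplitude target per-channel baseline RMS in uV.
#' @param spectral_slope exponent of the 1/f^slope baseline spectrum.
#' @param event_schedule list of [scheduled_event()] objects.
#' @return list of class `eeg_spec`.
#' @export
eeg_spec <- function(n_channels = 4, sampling_rate = 250, duration = 120,
                     seed = 1L, baseline_amplitude = 20,
                     spectral_slope = 1, event_schedule = list()) {
  if (duration <= 0) stop("duration must be positive")
  if (baseline_amplitude <= 0) stop("baseline_amplitude must be positive")
  if (sampling_rate <= 2 * 120)
    stop("sampling_rate must exceed 240 Hz (Nyquist for the 120 Hz band edge)")
  if (n_channels < 1) stop("need at least one channel")
  spec <- structure(
    list(n_channels = as.integer(n_channels),
         sampling_rate = sampling_rate, duration = duration,
         seed = as.integer(seed),
         baseline_amplitude = baseline_amplitude,
         spectral_slope = spectral_slope,
         event_schedule = event_schedule),
    class = "eeg_spec")
  validate_schedule(spec)
  spec
}

#' A scheduled ictal burst for the synthetic EEG generator
#'
#' Encodes the two electrographic archetypes the classifier distinguishes:
#' `focal` — a rhythmic 3 Hz spike-wave train confined to one channel;
#' `generalized` — a common source mixed into every channel at a requested
#' pairwise coherence, with adjustable band emphasis and temporal
#' persistence (Hurst target) of the source.
#'
#' @param kind "focal" or "generalized".
#' @param onset seconds from recording start.
#' @param duration seconds (> 0).
#' @param target_channel channel index carrying a focal burst (ignored for
#'   generalized bursts).
#' @param amplitude_ratio burst RMS as a multiple of the baseline RMS (> 0).
#' @param dominant_band name of the band carrying the burst's power
#'   emphasis (one of the six canonical bands, see [band_scheme()]).
#' @param coherence_level target pairwise magnitude-squared coherence of a
#'   generalized burst, in (0, 1).
#' @param hurst_target Hurst exponent of the generalized source's
#'   fractional-Gaussian-noise component, in (0, 1).
#' @return list of class `scheduled_event`.
#' @export
scheduled_event <- function(kind = c("focal", "generalized"),
                            onset, duration, target_channel = 1L,
                            amplitude_ratio = 5, dominant_band = "Delta",
                            coherence_level = 0.9, hurst_target = 0.3) {
  kind <- match.arg(kind)
  if (duration <= 0) stop("event duration must be positive")
  if (amplitude_ratio <= 0) stop("amplitude_ratio must be positive")
  if (!dominant_band %in% band_scheme()$band)
    stop("unknown dominant_band: ", dominant_band)
  if (coherence_level <= 0 || coherence_level >= 1)
    stop("coherence_level must lie in (0, 1)")
  if (hurst_target <= 0 || hurst_target >= 1)
    stop("hurst_target must lie in (0, 1)")
  structure(list(kind = kind, onset = onset, duration = duration,
                 target_channel = as.integer(target_channel),
                 amplitude_ratio = amplitude_ratio,
                 dominant_band = dominant_band,
                 coherence_level = coherence_level,
                 hurst_target = hurst_target),
            class = "scheduled_event")
}

validate_schedule <- function(spec) {
  ev <- spec$event_schedule
  if (length(ev) == 0L) return(invisible(TRUE))
  for (e in ev) {
    if (!inherits(e, "scheduled_event"))
      stop("event_schedule entries must be scheduled_event objects")
    if (e$onset < 0 || e$onset + e$duration > spec$duration)
      stop("event at ", e$onset, " s extends outside the recording")
    if (e$kind == "focal" &&
        (e$target_channel < 1 || e$target_channel > spec$n_channels))
      stop("focal target_channel out of range")
  }
  # events must not overlap within any channel; generalized bursts occupy
  # all channels
  for (ch in seq_len(spec$n_channels)) {
    own <- Filter(function(e) e$kind == "generalized" ||
                    e$target_channel == ch, ev)
    if (length(own) < 2L) next
    iv <- t(vapply(own, function(e) c(e$onset, e$onset + e$duration),
                   numeric(2)))
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (any(iv[-1, 1] < iv[-nrow(iv), 2]))
      stop("overlapping events within channel ", ch)
  }
  invisible(TRUE)
}

# 1/f^slope Gaussian noise of length n, unit RMS, via frequency-domain
# shaping of white noise. Components below 0.5 Hz are removed so the
# baseline process is stationary at the analysis window scale (the pipeline
# band-passes at 1 Hz anyway). Deterministic given the current RNG state.
.one_over_f <- function(n, slope, fs) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- c(0, seq_len(n - 1)) * fs / n
  # two-sided frequency axis: mirror above Nyquist
  f <- pmin(f, fs - f)
  shape <- numeric(n)
  nz <- f >= 0.5
  shape[nz] <- if (slope == 0) 1 else f[nz]^(-slope / 2)
  x <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

#' Generate a baseline (event-free) synthetic recording
#'
#' Each channel is independent 1/f^slope Gaussian noise scaled to the
#' requested RMS amplitude. Used as the null process for detector
#' false-positive checks and as the substrate for burst injection.
#'
#' @param spec an [eeg_spec()] with an empty `event_schedule`.
#' @return an `eeg_recording`.
#' @export
gen_baseline <- function(spec) {
  stopifnot(inherits(spec, "eeg_spec"))
  if (length(spec$event_schedule) > 0L)
    stop("gen_baseline expects an empty event_schedule; use assemble_recording")
  n <- round(spec$duration * spec$sampling_rate)
  sig <- withr::with_seed(spec$seed, {
    t(vapply(seq_len(spec$n_channels), function(ch) {
      spec$baseline_amplitude *
        .one_over_f(n, spec$spectral_slope, spec$sampling_rate)
    }, numeric(n)))
  })
  recording(sig, spec$sampling_rate,
            channel_labels = names(default_montage())[seq_len(spec$n_channels)],
            montage = default_montage(),
            meta = list(generator = "gen_baseline", seed = spec$seed))
}

#' Fractional Gaussian noise by circulant embedding (Davies-Harte)
#'
#' Exact synthesis of stationary fractional Gaussian noise with Hurst
#' parameter `hurst` and unit variance. The circulant embedding of the fGn
#' autocovariance gamma(k) = 0.5(|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H}) is
#' diagonalized by FFT; its eigenvalues are non-negative for all H in (0,1),
#' so the synthesis is exact (no approximation, no estimator circularity).
#'
#' @param hurst Hurst parameter, strictly inside (0, 1).
#' @param n number of samples; a power of two.
#' @param seed integer seed.
#' @return numeric vector of length `n`.
#' @export
gen_fgn <- function(hurst, n, seed = 1L) {
  if (hurst <= 0 || hurst >= 1) stop("hurst must lie strictly in (0, 1)")
  if (n < 2 || bitwAnd(n, n - 1L) != 0L)
    stop("n must be a power of two")
  k <- 0:(n - 1)
  g <- 0.5 * (abs(k + 1)^(2 * hurst) - 2 * abs(k)^(2 * hurst) +
                abs(k - 1)^(2 * hurst))
  # circulant row of length 2n: gamma(0..n), gamma(n-1..1)
  row <- c(g, 0.5 * (abs(n + 1)^(2 * hurst) - 2 * n^(2 * hurst) +
                       (n - 1)^(2 * hurst)), rev(g[-1]))
  lambda <- Re(stats::fft(row))
  lambda[lambda < 0] <- 0  # numerical guard; theoretically non-negative
  m <- 2L * n
  x <- withr::with_seed(as.integer(seed), {
    z <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m))
    Re(stats::fft(sqrt(lambda / (2 * m)) * z)) * sqrt(2)
  })
  x[seq_len(n)] / 1  # unit variance by construction
}

# one cycle of a biphasic spike-wave at `rate` Hz: a sharp spike followed by
# a slow half-sine wave, zero-mean. Returns `cycle_n` samples.
.spike_wave_cycle <- function(cycle_n) {
  t <- seq(0, 1, length.out = cycle_n + 1)[-(cycle_n + 1)]
  spike <- exp(-((t - 0.08) / 0.025)^2) - 0.6 * exp(-((t - 0.14) / 0.035)^2)
  wave <- 0.5 * sin(pi * pmax(0, pmin(1, (t - 0.25) / 0.65)))
  w <- spike + wave
  w - mean(w)
}

# cosine on/off ramp over ramp_n samples at each end
.ramp <- function(n, ramp_n) {
  r <- rep(1, n)
  k <- min(ramp_n, floor(n / 2))
  if (k > 0) {
    up <- 0.5 * (1 - cos(pi * seq_len(k) / k))
    r[seq_len(k)] <- up
    r[n + 1 - seq_len(k)] <- up
  }
  r
}

# band-limited Gaussian noise: white noise bandpassed to `band` Hz, unit RMS
.band_noise <- function(n, band, fs) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)
  keep <- f >= band[1] & f <= band[2]
  X[!keep] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y / sqrt(mean(y^2))
}

#' Assemble a recording with scheduled ictal bursts and its ground truth
#'
#' Generates the baseline process and injects each scheduled event
#' additively. Focal bursts are a rhythmic 3 Hz biphasic spike-wave train on
#' the target channel, with its residual power emphasis in the event's
#' dominant band; generalized bursts mix one shared source (fractional
#' Gaussian noise at the requested Hurst target plus dominant-band noise)
#' into all channels, with per-channel independent noise balanced so the
#' pairwise magnitude-squared coherence equals `coherence_level`
#' (MSC = (SNR/(1+SNR))^2). Burst amplitude is scaled so the event-window
#' RMS of an affected channel is `amplitude_ratio` times the baseline RMS.
#' Amplitude ramps over the first and last 0.5 s to avoid edge ringing.
#'
#' @param spec an [eeg_spec()]; its schedule may be empty.
#' @return list with `recording` (an `eeg_recording`) and `ground_truth`, a
#'   data.frame with one row per injected event (kind, onset_s, duration_s,
#'   channels, amplitude_ratio).
#' @export
assemble_recording <- function(spec) {
  stopifnot(inherits(spec, "eeg_spec"))
  validate_schedule(spec)
  base_spec <- spec
  base_spec$event_schedule <- list()
  rec <- gen_baseline(base_spec)
  fs <- spec$sampling_rate
  scheme <- band_scheme()
  gt <- list()
  for (i in seq_along(spec$event_schedule)) {
    e <- spec$event_schedule[[i]]
    i0 <- round(e$onset * fs) + 1L
    n_ev <- round(e$duration * fs)
    idx <- i0:(i0 + n_ev - 1L)
    ramp <- .ramp(n_ev, round(0.5 * fs))
    target_rms <- e$amplitude_ratio * spec$baseline_amplitude
    band <- as.numeric(scheme[scheme$band == e$dominant_band,
                              c("low", "high")])
    ev_seed <- (spec$seed + 7919L * i) %% .Machine$integer.max
    if (e$kind == "focal") {
      burst <- withr::with_seed(ev_seed, {
        cyc <- .spike_wave_cycle(round(fs / 3))
        w <- rep_len(cyc, n_ev)
        w <- w + 0.15 * .band_noise(n_ev, band, fs)
        w
      })
      burst <- burst * ramp
      burst <- burst * target_rms / sqrt(mean(burst^2))
      rec$signal[e$target_channel, idx] <-
        rec$signal[e$target_channel, idx] + burst
      chans <- rec$channel_labels[e$target_channel]
    } else {
      # MSC = (SNR/(1+SNR))^2  =>  source fraction p = sqrt(MSC)
      p <- sqrt(e$coherence_level)
      nfft <- 2^ceiling(log2(n_ev))
      mixed <- withr::with_seed(ev_seed, {
        src_fgn <- gen_fgn(e$hurst_target, nfft,
                           seed = (ev_seed + 104729L) %%
                             .Machine$integer.max)[seq_len(n_ev)]
        src_fgn <- src_fgn / sqrt(mean(src_fgn^2))
        src_band <- .band_noise(n_ev, band, fs)
        src <- sqrt(0.45) * src_fgn + sqrt(0.55) * src_band
        src <- src / sqrt(mean(src^2))
        vapply(seq_len(spec$n_channels), function(ch) {
          nz <- stats::rnorm(n_ev)
          nz <- nz / sqrt(mean(nz^2))
          sqrt(p) * src + sqrt(1 - p) * nz
        }, numeric(n_ev))
      })
      for (ch in seq_len(spec$n_channels)) {
        burst <- mixed[, ch] * ramp
        burst <- burst * target_rms / sqrt(mean(burst^2))
        rec$signal[ch, idx] <- rec$signal[ch, idx] + burst
      }
      chans <- paste(rec$channel_labels, collapse = ";")
    }
    gt[[i]] <- data.frame(kind = e$kind, onset_s = e$onset,
                          duration_s = e$duration, channels = chans,
                          amplitude_ratio = e$amplitude_ratio,
                          stringsAsFactors = FALSE)
  }
  ground_truth <- if (length(gt)) do.call(rbind, gt) else
    data.frame(kind = character(), onset_s = numeric(),
               duration_s = numeric(), channels = character(),
               amplitude_ratio = numeric(), stringsAsFactors = FALSE)
  rec$meta$generator <- "assemble_recording"
  list(recording = rec, ground_truth = ground_truth)
}
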