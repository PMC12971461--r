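# shared fixtures built in code

# deterministic multichannel sine recording: RMS is exactly A/sqrt(2) per
# channel (10 Hz at 250 Hz sampling gives integer cycles in every analysis
# window used by the tests)
sine_recording <- function(amplitude = 10, duration_s = 120, fs = 250,
                           n_ch = 4, freq = 10) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  sig <- matrix(rep(amplitude * sin(2 * pi * freq * t), n_ch),
                nrow = n_ch, byrow = TRUE)
  recording(sig, fs, channel_labels = names(default_montage())[1:n_ch])
}

# recording with a single amplified segment at an exact RMS ratio r
ratio_recording <- function(r, amplitude = 10, duration_s = 120,
                            event = c(80, 90), fs = 250) {
  rec <- sine_recording(amplitude, duration_s, fs)
  idx <- (round(event[1] * fs) + 1):round(event[2] * fs)
  rec$signal[, idx] <- rec$signal[, idx] * r
  rec
}

# a feature list with controllable values for classifier tests
feature_fixture <- function(dfg = 2, ab = 1.0, ent = 0.9, coh = 0.5,
                            hur = 0.4) {
  list(delta_fastgamma_ratio = dfg, alpha_beta_ratio = ab,
       spectral_entropy = ent, mean_coherence = coh, hurst = hur)
}

# thresholds with fixed baseline references for constructed features
fixture_thresholds <- function(...) {
  classifier_thresholds(entropy_reference = 0.8,
                        coherence_reference = 0.3,
                        hurst_reference = 0.6, ...)
}

# archetype recording with n events of one kind; returns recording,
# ground truth and baseline stats (baseline window 0-75 s)
archetype_recording <- function(seed, kind, n_events = 2,
                                amplitude_ratio = 5) {
  evs <- lapply(seq_len(n_events) - 1, function(k)
    scheduled_event(kind, onset = 80 + 20 * k, duration = 10,
                    target_channel = 1 + (k %% 4),
                    amplitude_ratio = amplitude_ratio,
                    dominant_band = "Delta", coherence_level = 0.9,
                    hurst_target = 0.3))
  spec <- eeg_spec(duration = 80 + 20 * n_events + 10, seed = seed,
                   event_schedule = evs)
  out <- assemble_recording(spec)
  out$baseline <- estimate_baseline(out$recording, c(0, 75))
  out
}
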