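test_that("Welch PSD satisfies Parseval and localizes narrowband power", {
  set.seed(5)
  x <- rnorm(15000)
  p <- welch_psd(x, 250)
  expect_lt(abs(pracma::trapz(p$freq, p$psd) - var(x)) / var(x), 0.10)

  t <- seq(0, 60 - 1 / 250, by = 1 / 250)
  s <- sin(2 * pi * 2 * t)
  ps <- welch_psd(s, 250)
  total <- pracma::trapz(ps$freq, ps$psd)
  expect_gte(band_power(ps, c(1, 4)) / total, 0.95)

  pz <- welch_psd(rep(0, 1000), 250, demean = FALSE)
  expect_true(all(pz$psd == 0))
  expect_error(welch_psd(rnorm(100), 250), "too short")
})

test_that("band powers are bandwidth-proportional on white noise and omit 60-70 Hz", {
  set.seed(6)
  x <- rnorm(30000)
  p <- welch_psd(x, 250)
  total <- band_power(p, c(1, 120))
  delta <- band_power(p, "Delta")
  expect_lt(abs(delta / total - 3 / 119), 0.15 * 3 / 119)
  pw <- band_powers(x, 250)
  expect_lt(sum(pw), total)  # the six bands leave the 60-70 Hz gap out
  expect_error(band_power(p, c(100, 130)), "outside")
  expect_error(band_power(p, "Sigma"), "unknown band")
})

test_that("band ratios divide correctly and refuse a zero denominator", {
  pw <- c(Delta = 3, Theta = 1, Alpha = 2, Beta = 2, SlowGamma = 1,
          FastGamma = 1.5)
  expect_equal(band_ratio(pw, "Delta", "FastGamma"), 2)
  expect_gt(band_ratio(pw, "Delta", "FastGamma"), 1.5)
  expect_equal(band_ratio(pw, "Alpha", "Beta"), 1)
  pw["FastGamma"] <- 0
  expect_error(band_ratio(pw, "Delta", "FastGamma"), "FastGamma")
})

test_that("spectral entropy hits its bounds and matches the direct Shannon sum", {
  freq <- seq(0, 125, by = 0.5)
  single <- structure(list(freq = freq, psd = replace(numeric(251), 60, 7)),
                      class = "eeg_psd")
  expect_equal(spectral_entropy(single), 0)
  flat <- structure(list(freq = freq, psd = rep(2, 251)),
                    class = "eeg_psd")
  expect_equal(spectral_entropy(flat), 1)

  pink <- welch_psd(gen_baseline(eeg_spec(duration = 60, seed = 2,
                                          n_channels = 1))$signal[1, ], 250)
  keep <- pink$freq >= 1 & pink$freq <= 120
  q <- pink$psd[keep] / sum(pink$psd[keep])
  oracle <- -sum(q[q > 0] * log2(q[q > 0])) / log2(length(q))
  expect_equal(spectral_entropy(pink), oracle, tolerance = 1e-9)

  zero <- structure(list(freq = freq, psd = numeric(251)),
                    class = "eeg_psd")
  expect_error(spectral_entropy(zero), "all-zero")
})

test_that("coherence is 1 for self, near-zero for independent, and matches the common-source closed form", {
  set.seed(7)
  x <- rnorm(5000)
  expect_equal(coherence(x, x, 250)$mean_msc, 1, tolerance = 1e-9)
  ind <- coherence(rnorm(5000), rnorm(5000), 250,
                   nperseg = 512)$mean_msc  # >= 16 segments
  expect_lt(ind, 0.2)
  s <- rnorm(8000)
  cs <- coherence(s + rnorm(8000), s + rnorm(8000), 250)$mean_msc
  expect_lt(abs(cs - 0.25), 0.1)  # MSC = (SNR/(1+SNR))^2 with SNR = 1
  expect_error(coherence(rnorm(100), rnorm(101), 250), "equal length")
})

test_that("the Hurst estimator recovers known exponents on fGn", {
  est <- function(h) mean(vapply(1:20, function(s)
    hurst_rs(gen_fgn(h, 8192, seed = s)), numeric(1)))
  expect_lt(abs(est(0.5) - 0.5), 0.1)  # white noise
  expect_lt(abs(est(0.8) - 0.8), 0.1)
  expect_lt(abs(est(0.3) - 0.3), 0.1)
  expect_error(hurst_rs(rep(1, 2048)), "constant")
  expect_error(hurst_rs(rnorm(512)), "1024")
})

test_that("R/S estimates agree with an independent implementation", {
  x <- gen_fgn(0.7, 4096, seed = 41)
  ours <- hurst_rs(x)
  ref <- pracma::hurstexp(x, display = FALSE)$Hal
  expect_lt(abs(ours - ref), 0.1)
})

test_that("normalized PSD is near 1 on baseline draws and scales with amplitude squared", {
  rec <- gen_baseline(eeg_spec(duration = 240, seed = 19))
  bl <- estimate_baseline(rec, c(0, 120))
  epoch <- rec$signal[1, (150 * 250 + 1):(154 * 250)]
  ratios <- normalized_psd(epoch, bl$band_power, fs = 250)
  expect_equal(sort(names(ratios)), sort(band_scheme()$band))
  expect_true(all(abs(ratios - 1) < 0.5))
  doubled <- normalized_psd(2 * epoch, bl$band_power, fs = 250)
  expect_equal(unname(doubled / ratios), rep(4, 6), tolerance = 1e-9)
  bad <- bl$band_power; bad["Theta"] <- 0
  expect_error(normalized_psd(epoch, bad), "Theta")
})

test_that("features are amplitude-equivariant", {
  out <- archetype_recording(43, "generalized", n_events = 1)
  fs <- 250
  win <- out$recording$signal[, (80 * fs + 1):(90 * fs)]
  f1 <- extract_features(win, fs)
  f2 <- extract_features(3 * win, fs)
  expect_equal(f2$band_power, 9 * f1$band_power, tolerance = 1e-6)
  expect_equal(f2$rms, 3 * f1$rms, tolerance = 1e-9)
  for (nm in c("delta_fastgamma_ratio", "alpha_beta_ratio",
               "spectral_entropy", "mean_coherence", "hurst"))
    expect_equal(f2[[nm]], f1[[nm]], tolerance = 1e-6)
  expect_gte(f1$spectral_entropy, 0); expect_lte(f1$spectral_entropy, 1)
  expect_gte(f1$mean_coherence, 0); expect_lte(f1$mean_coherence, 1)
})

test_that("archetype spectra point the directions the classifier expects", {
  fs <- 250
  foc <- archetype_recording(47, "focal", n_events = 1)
  win <- foc$recording$signal[, (80 * fs + 1):(90 * fs)]
  pw <- band_powers(win[1, ], fs)
  expect_gt(pw[["Delta"]] + pw[["Theta"]],
            pw[["Beta"]] + pw[["SlowGamma"]])
  gen <- archetype_recording(48, "generalized", n_events = 1)
  gwin <- gen$recording$signal[, (80 * fs + 1):(90 * fs)]
  fv <- extract_features(gwin, fs)
  expect_gt(fv$mean_coherence, gen$baseline$coherence)
})
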