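test_that("baseline generator produces the requested shape, RMS and seed determinism", {
  spec <- eeg_spec(duration = 60, seed = 3, baseline_amplitude = 20)
  rec <- gen_baseline(spec)
  expect_equal(dim(rec$signal), c(4, 15000))
  expect_equal(sqrt(rowMeans(rec$signal^2)), rep(20, 4), tolerance = 1e-9,
               ignore_attr = TRUE)
  rec2 <- gen_baseline(eeg_spec(duration = 60, seed = 3,
                                baseline_amplitude = 20))
  expect_identical(rec$signal, rec2$signal)
  expect_error(eeg_spec(duration = 0), "positive")
  expect_error(eeg_spec(baseline_amplitude = -1), "positive")
})

test_that("baseline spectrum follows the requested 1/f slope", {
  spec <- eeg_spec(duration = 120, seed = 8, spectral_slope = 1)
  rec <- gen_baseline(spec)
  # independent oracle: periodogram regression in log-log space
  p <- stats::spec.pgram(rec$signal[1, ], taper = 0, plot = FALSE,
                         spans = 11)
  f <- p$freq * 250
  keep <- f >= 2 & f <= 80
  slope <- unname(coef(lm(log(p$spec[keep]) ~ log(f[keep])))[2])
  expect_lt(abs(slope - (-1)), 0.2)
})

test_that("fGn generator matches the closed-form autocovariance and is deterministic", {
  x <- gen_fgn(0.5, 16384, seed = 2)
  r1 <- cor(x[-1], x[-length(x)])
  expect_lt(abs(r1), 0.05)  # H = 0.5 is white noise

  h <- 0.8; n <- 8192
  y <- gen_fgn(h, n, seed = 3)
  gam <- function(k) 0.5 * (abs(k + 1)^(2 * h) - 2 * k^(2 * h) +
                              abs(k - 1)^(2 * h))
  for (k in 1:10) {
    emp <- mean((y[-(1:k)] - mean(y)) * (y[1:(n - k)] - mean(y)))
    # sampling SE of the autocovariance of a strongly persistent process;
    # conservative long-run-variance bound
    se <- sqrt(2 / n) * (1 + 2 * sum(gam(1:50)^2))^0.5
    expect_lt(abs(emp - gam(k)), 3 * se)
  }
  expect_identical(gen_fgn(0.7, 1024, seed = 5), gen_fgn(0.7, 1024, seed = 5))
  expect_error(gen_fgn(1.2, 1024), "hurst")
  expect_error(gen_fgn(0.5, 1000), "power of two")
})

test_that("assemble_recording injects bursts at the scheduled RMS ratio and records ground truth", {
  spec <- eeg_spec(duration = 120, seed = 11, event_schedule = list(
    scheduled_event("focal", onset = 80, duration = 20,
                    target_channel = 1, amplitude_ratio = 5)))
  out <- assemble_recording(spec)
  expect_equal(nrow(out$ground_truth), 1)
  expect_equal(out$ground_truth$kind, "focal")
  fs <- 250
  rms_win <- function(ch, a, b)
    sqrt(mean(out$recording$signal[ch, (a * fs + 1):(b * fs)]^2))
  # inside the event (away from ramps) the target channel is >= 4x baseline
  expect_gte(rms_win(1, 85, 95) / rms_win(1, 10, 70), 4)
  # untouched channels stay near baseline
  for (ch in 2:4)
    expect_lt(rms_win(ch, 85, 95) / rms_win(ch, 10, 70), 1.2)
})

test_that("generalized bursts raise pairwise coherence above baseline", {
  spec <- eeg_spec(duration = 120, seed = 13, event_schedule = list(
    scheduled_event("generalized", onset = 80, duration = 20,
                    amplitude_ratio = 5, coherence_level = 0.9)))
  out <- assemble_recording(spec)
  fs <- 250
  ev <- out$recording$signal[, (82 * fs + 1):(98 * fs)]
  bl <- out$recording$signal[, (10 * fs + 1):(26 * fs)]
  msc_ev <- coherence(ev[1, ], ev[2, ], fs)$mean_msc
  msc_bl <- coherence(bl[1, ], bl[2, ], fs)$mean_msc
  expect_gt(msc_ev, msc_bl)
  expect_gt(msc_ev, 0.5)
})

test_that("empty schedules and overlap violations behave per contract", {
  out <- assemble_recording(eeg_spec(duration = 60, seed = 1))
  expect_equal(nrow(out$ground_truth), 0)
  expect_error(
    eeg_spec(duration = 100, seed = 1, event_schedule = list(
      scheduled_event("focal", onset = 10, duration = 20,
                      target_channel = 1),
      scheduled_event("focal", onset = 25, duration = 20,
                      target_channel = 1))),
    "overlap")
  expect_error(
    eeg_spec(duration = 50, seed = 1, event_schedule = list(
      scheduled_event("focal", onset = 45, duration = 20))),
    "outside")
})

test_that("puncta image generator honors counts, areas and determinism", {
  sp <- image_spec(field_size = c(60, 60), pixel_size = 0.1,
                   layer_bands = list(A = c(0, 60)),
                   puncta_per_layer = c(A = 50),
                   area_mean = 0.785, area_sd = 0,
                   area_range = c(0.785, 0.785),
                   circularity_range = c(1, 1), seed = 6)
  out <- gen_puncta_image(sp)
  # disks of radius 0.5 um: analytic area pi r^2 = 0.785 um^2
  expect_equal(out$ground_truth$area_um2, rep(pi * 0.5^2, 50),
               tolerance = 1e-3)
  out2 <- gen_puncta_image(sp)
  expect_identical(out$image, out2$image)

  sp3 <- image_spec(seed = 5)  # 30 puncta x 3 layers
  gt <- gen_puncta_image(sp3)$ground_truth
  expect_equal(nrow(gt), 90)
  expect_equal(unname(table(gt$layer)[c("I", "II", "III")]),
               rep(30L, 3), ignore_attr = TRUE)
  # ground truth is exhaustive and within the field
  expect_true(all(gt$cx_um > 0 & gt$cx_um < 100))
  expect_true(all(gt$cy_um > 0 & gt$cy_um < 90))

  blank <- gen_puncta_image(image_spec(puncta_per_layer = c(I = 0, II = 0,
                                                            III = 0)))
  expect_equal(nrow(blank$ground_truth), 0)
})

test_that("cohort generator follows the specified line and seeds", {
  noiseless <- gen_cohort(cohort_spec(n_animals = 6, slope = 2,
                                      intercept = 1, noise_sd = 0))
  expect_equal(noiseless$response, 2 * noiseless$predictor + 1)
  # OLS sampling-error bound: slope 0, sd 1, n 200; with predictors over
  # [0, 10], 3 x SE(slope) = 3 / sqrt(n * var(x)) ~ 0.07, so +-0.2 is a
  # conservative bound
  big <- gen_cohort(cohort_spec(n_animals = 200, slope = 0, intercept = 0,
                                noise_sd = 1, predictor_range = c(0, 10),
                                seed = 7))
  se3 <- 3 / sqrt(200 * var(big$predictor))
  sl <- abs(linfit(big$predictor, big$response)$slope)
  expect_lt(sl, se3)
  expect_lt(sl, 0.2)
  expect_identical(gen_cohort(cohort_spec(seed = 4)),
                   gen_cohort(cohort_spec(seed = 4)))
  expect_error(cohort_spec(n_animals = 2), "at least 3")
  expect_error(cohort_spec(noise_sd = -1), "non-negative")
})
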