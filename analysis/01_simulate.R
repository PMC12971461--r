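#!/usr/bin/env Rscript
# Simulate a small synthetic cohort: 4-channel, 250 Hz recordings with
# scheduled ictal bursts for four "animals" in two treatment-like groups
# (high-burden: frequent, long, high-amplitude events; low-burden: fewer,
# brief, delayed events), plus laminar puncta images and a linked
# per-animal table. Everything is written under results/simulated/ with
# full ground truth; downstream drivers (02-05) consume these files.

suppressMessages(library(ictalkit))
out_dir <- "results/simulated"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

animals <- data.frame(
  animal = c("A1", "A2", "A3", "A4"),
  group = c("high_burden", "high_burden", "low_burden", "low_burden"),
  seed = c(101, 102, 103, 104),
  stringsAsFactors = FALSE)

make_schedule <- function(group, seed) {
  if (group == "high_burden") {
    onsets <- seq(90, 380, by = 45)        # 7 events after the baseline
    durs <- rep(c(15, 20), length.out = length(onsets))
    amp <- 5
  } else {
    onsets <- c(200, 330)                  # delayed, sparse
    durs <- c(6, 8)
    amp <- 4
  }
  lapply(seq_along(onsets), function(k)
    scheduled_event(if (k %% 2 == 0) "generalized" else "focal",
                    onset = onsets[k], duration = durs[k],
                    target_channel = 1 + (k %% 4),
                    amplitude_ratio = amp, dominant_band = "Delta",
                    coherence_level = 0.9, hurst_target = 0.3))
}

for (i in seq_len(nrow(animals))) {
  a <- animals[i, ]
  spec <- eeg_spec(duration = 420, seed = a$seed,
                   event_schedule = make_schedule(a$group, a$seed))
  out <- assemble_recording(spec)
  out$recording$meta$subject <- a$animal
  write_edf(out$recording, file.path(out_dir, paste0(a$animal, ".edf")))
  write.csv(out$ground_truth,
            file.path(out_dir, paste0(a$animal, "_ground_truth.csv")),
            row.names = FALSE)
  img <- gen_puncta_image(image_spec(seed = a$seed + 500,
    puncta_per_layer = c(I = if (a$group == "high_burden") 40 else 25,
                         II = 30, III = 20)))
  write_puncta_tiff(img, file.path(out_dir, paste0(a$animal, ".tif")))
  write.csv(img$ground_truth,
            file.path(out_dir, paste0(a$animal, "_puncta_truth.csv")),
            row.names = FALSE)
  message(sprintf("%s (%s): %d scheduled events, %d puncta",
                  a$animal, a$group, nrow(out$ground_truth),
                  nrow(img$ground_truth)))
}
write.csv(animals, file.path(out_dir, "animals.csv"), row.names = FALSE)
message("simulation written to ", out_dir)
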