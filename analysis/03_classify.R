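#!/usr/bin/env Rscript
# Classify every detected event focal vs generalized by the five-criterion
# majority vote and the channel-extent rule, then score agreement with the
# injected ground truth.

suppressMessages(library(ictalkit))
sim <- "results/simulated"
animals <- read.csv(file.path(sim, "animals.csv"))

labels <- list(); hits <- 0; total <- 0
for (i in seq_len(nrow(animals))) {
  a <- animals[i, ]
  rec <- bandpass(read_edf(file.path(sim, paste0(a$animal, ".edf"))))
  bl <- estimate_baseline(rec, c(0, 75))
  lab <- classify_recording(rec, bl)
  gt <- read.csv(file.path(sim, paste0(a$animal, "_ground_truth.csv")))
  lab$animal <- a$animal
  lab$truth <- NA_character_
  for (j in seq_len(nrow(gt))) {
    total <- total + 1
    g0 <- gt$onset_s[j]; g1 <- g0 + gt$duration_s[j]
    hit <- which(lab$onset_s < g1 & lab$onset_s + lab$duration_s > g0)
    if (!length(hit)) next
    lab$truth[hit[1]] <- gt$kind[j]
    call <- if (gt$kind[j] == "focal") lab$extent_call[hit[1]] else
      lab$feature_call[hit[1]]
    if (call == gt$kind[j]) hits <- hits + 1
  }
  labels[[i]] <- lab
}
all_lab <- do.call(rbind, labels)
write.csv(all_lab, "results/classification.csv", row.names = FALSE)
message(sprintf("classification agreement with ground truth: %d/%d (%.0f%%)",
                hits, total, 100 * hits / total))
print(table(truth = all_lab$truth, extent_call = all_lab$extent_call))
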