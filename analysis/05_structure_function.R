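#!/usr/bin/env Rscript
# Structure-function regression: per cortical layer, regress the simulated
# seizure-burden metrics on the laminar puncta metrics and tabulate the
# R-squared grid (the heatmap input). With four animals these fits are
# descriptive, exactly as in small-cohort laminar studies.

suppressMessages(library(ictalkit))
burden <- read.csv("results/burden.csv")
metrics <- read.csv("results/layer_metrics.csv")

cohort <- merge(metrics, burden[, c("animal", "n_detected",
                                    "mean_duration_s",
                                    "auc_event_hours")], by = "animal")
grid <- r2_matrix(cohort,
                  predictors = c("mean_area_um2", "coverage_pct",
                                 "density_per_1000um2"),
                  responses = c("n_detected", "auc_event_hours"),
                  layers = c("I-1", "I-2", "I-3", "II", "III"))
write.csv(grid, "results/r2_matrix.csv", row.names = FALSE)
message("R-squared grid (", nrow(grid), " cells):")
print(grid[order(-grid$r_squared), ][1:8, ])

best <- grid[which.max(grid$r_squared), ]
sub <- cohort[cohort$layer == best$layer, ]
fit <- linfit(sub[[best$predictor]], sub[[best$response]],
              best$predictor, best$response, best$layer)
print(fit)
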