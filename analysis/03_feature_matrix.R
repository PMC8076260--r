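#!/usr/bin/env Rscript

# Step 3 — sliding-window variability indices and the feature matrix.
#
# Turns the per-beat indices into 40-dimensional per-window rows
# (C1-C10, CV1-CV10, P1-P10, P1_SD-P10_SD over 15-beat windows) and
# writes results/features.csv. Normalization is deliberately NOT
# applied here: the classification step fits Z-score parameters on
# training subjects only.

suppressPackageStartupMessages(library(pulsespec))

beat_df <- read.csv("results/beat_indices.csv", check.names = FALSE)

feats <- lapply(split(beat_df, beat_df$subject_id), function(b) {
  b <- b[order(b$beat_index), ]
  assemble_features(b)
})
feature_df <- do.call(rbind, c(feats, list(make.row.names = FALSE)))

write.csv(feature_df, "results/features.csv", row.names = FALSE)
cat(sprintf("%d windows x %d features from %d subjects\n",
            nrow(feature_df), length(feature_columns()),
            length(unique(feature_df$subject_id))))
cat(sprintf("windows per subject: %s\n",
            paste(range(table(feature_df$subject_id)), collapse = "-")))
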