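#!/usr/bin/env Rscript

# Step 5 — MLP classification protocol.
#
# Splits subjects 2:1 into training and hold-out sets, runs three
# 80/20 subject-level cross-validation folds inside the training set,
# then fits the final 40-20-20-20-1 network on all training subjects
# and evaluates it once on the held-out subjects. Writes
# results/mlp_report.json (metrics + seeds) and
# results/mlp_history.csv (per-epoch learning curves of the folds).

suppressPackageStartupMessages(library(pulsespec))

feature_df <- read.csv("results/features.csv", check.names = FALSE)
seed <- 42

split <- make_split(unique(feature_df[, c("subject_id", "label")]),
                    seed = seed)
print(split)
report <- run_protocol(feature_df, split, mlp_config(seed = seed))
print(report)

jsonlite::write_json(
  list(summary = report$summary, seeds = as.list(report$seeds),
       confusion_holdout = as.list(report$holdout$confusion),
       level = report$level),
  "results/mlp_report.json", auto_unbox = TRUE, digits = NA)

# subject-level view of the same hold-out model for comparison
cat("\nhold-out confusion (pulse level): ",
    paste(names(report$holdout$confusion), report$holdout$confusion,
          collapse = "  "), "\n")
cat("written: results/mlp_report.json\n")
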