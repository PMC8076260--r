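#!/usr/bin/env Rscript

# Step 4 — per-index two-group comparisons.
#
# Compares all 40 harmonic indices between AD and control with
# two-tailed Welch t-tests (significance at p < 0.05, no
# multiple-testing correction, matching the raw-alpha protocol).
# Subject-level means are used as the unit of analysis — pulse-level
# tests would inflate the effective sample size because consecutive
# beats of one subject are strongly correlated. Writes
# results/group_comparisons.csv and prints the significant rows.

suppressPackageStartupMessages(library(pulsespec))

beat_df <- read.csv("results/beat_indices.csv", check.names = FALSE)
feature_df <- read.csv("results/features.csv", check.names = FALSE)

tab <- comparison_table(beat_df, feature_df,
                        group_levels = c("AD", "control"),
                        unit_of_analysis = "subject")
write.csv(tab, "results/group_comparisons.csv", row.names = FALSE)

cat(sprintf("%d of 40 indices significant at p < 0.05\n",
            sum(tab$significant)))
writeLines(format_comparison(tab[tab$significant, ]))
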