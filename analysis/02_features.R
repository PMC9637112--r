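#!/usr/bin/env Rscript
# Stage 2: derive the model covariates from the raw tables.
#
# Recomputes, from the files written by stage 1 alone: the CMR and
# environmental hazard scores from the notification fractions, log10 tonnage
# (largest-entry rule, sentinel handling) and square-root country counts from
# the registry entries, and the grouped publication rank from corpus name
# matching. Writes the raw feature table and the per-list mean
# comparison.

suppressPackageStartupMessages(library(svhcdrivers))

indir <- "results/synthetic_bundle"
bundle <- read_bundle(indir)

features <- build_features(bundle$registry, bundle$notifications,
                           bundle$substances, bundle$corpus,
                           model = "aggregate")
features_dis <- build_features(bundle$registry, bundle$notifications,
                               bundle$substances, bundle$corpus,
                               model = "disaggregated")

utils::write.csv(features, "results/features_aggregate.csv", row.names = FALSE)
utils::write.csv(features_dis, "results/features_disaggregated.csv", row.names = FALSE)

cat(sprintf("features for %d substances\n", nrow(features)))
cat(sprintf("complete cases: %d (%.1f%%)\n",
            sum(stats::complete.cases(features[-1])),
            100 * mean(stats::complete.cases(features[-1]))))
cat(sprintf("mean CMR score %.3f, mean env score %.3f, mean tonnage %.2f, mean sqrt-countries %.2f\n",
            mean(features$cmr_score, na.rm = TRUE),
            mean(features$env_score, na.rm = TRUE),
            mean(features$tonnage_log, na.rm = TRUE),
            mean(features$countries_sqrt, na.rm = TRUE)))

tab1 <- mean_comparison_table(features, bundle$membership, focal = "cl")
utils::write.csv(tab1, "results/mean_comparisons.csv", row.names = FALSE)
cat("\nper-list means (CMR score):\n")
print(tab1[tab1$variable == "cmr_score", c("list", "mean", "sd", "n", "p_vs_focal", "stars")],
      row.names = FALSE)
cat("wrote results/features_*.csv and results/mean_comparisons.csv\n")
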