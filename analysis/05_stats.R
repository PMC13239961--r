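#!/usr/bin/env Rscript
# Stage 5: direction-stratified correlation statistics and the DVH link.
#
# Per rotation direction (UP/RO/CW, plus the multi-axis group and the
# pooled two-phase analysis with direction count as a predictor):
# Pearson correlations of every dose metric against rotation angle, and
# the proportion of records passing the 95% clinical gamma threshold.
# Also the SSIM vs delta-V100 correlation. Writes
# results/direction_correlations.csv and results/pass_proportions.csv.

suppressPackageStartupMessages(library(rotqa))

dir.create("results", showWarnings = FALSE)
metrics <- read_feature_table("results/metrics.csv")

res <- direction_analysis(metrics)
write_feature_table(res$correlations, "results/direction_correlations.csv")
write_feature_table(res$pass_proportions, "results/pass_proportions.csv")

cat("SSIM vs total rotation angle by direction:\n")
ssim_rows <- subset(res$correlations,
                    metric == "ssim" & predictor == "angle_total_deg")
print(ssim_rows, row.names = FALSE)

dvh <- pearson_cor(metrics$ssim, metrics$delta_v100)
cat(sprintf("\nSSIM vs delta-V100: r = %.3f (p = %.2g, n = %d)\n",
            dvh$r, dvh$p, dvh$n))

cat("\nProportion of records with gamma(2%/2mm) pass rate > 95%:\n")
print(res$pass_proportions, row.names = FALSE)
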