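#!/usr/bin/env Rscript
# Stage 2: score every (reference, perturbed) pair.
#
# Planes are standardized (45 x 45, 70% low-dose threshold), then scored
# with SSIM, gamma passing rates at 2%/2mm, 1.5%/1.5mm and 1%/1mm in both
# relative-dose and absolute-dose modes, and the 2% dose-difference-only
# passing rates. Writes results/metrics.csv.

suppressPackageStartupMessages(library(rotqa))

seed <- 1
dir.create("results", showWarnings = FALSE)

cohort <- simulate_cohort(cohort_protocol(n_plans = 40, seed = seed),
                          keep_volumes = FALSE)
metrics <- cohort_metrics(cohort, include_gamma = TRUE, include_dd = TRUE)
write_feature_table(metrics, "results/metrics.csv")

cat(sprintf("Scored %d records.\n", nrow(metrics)))
cat(sprintf("SSIM range: %.3f to %.3f (mean %.3f).\n",
            min(metrics$ssim), max(metrics$ssim), mean(metrics$ssim)))
cat(sprintf("Gamma 2%%/2mm (RD) pass rate: mean %.1f%%; %.1f%% of records above 95%%.\n",
            mean(metrics$gamma_rd_2_2),
            100 * mean(metrics$gamma_rd_2_2 > 95)))
cat("Metric table written to results/metrics.csv\n")
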