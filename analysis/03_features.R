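#!/usr/bin/env Rscript
# Stage 3: radiomic and dosiomic feature extraction.
#
# Per plan, 32 radiomic features (18 first-order + 14 shape, target mask)
# and 837 dosiomic features (18 first-order + 75 texture + 744 wavelet,
# whole dose field) from the reference volume. Writes
# results/features.csv.

suppressPackageStartupMessages(library(rotqa))

seed <- 1
dir.create("results", showWarnings = FALSE)

cohort <- simulate_cohort(cohort_protocol(n_plans = 40, seed = seed))
features <- cohort_features(cohort)
write_feature_table(features, "results/features.csv")

cat(sprintf("Extracted %d features for %d plans.\n",
            ncol(features) - 1, nrow(features)))
cat(sprintf("  radiomics: %d, dosiomics: %d (of which wavelet: %d)\n",
            length(grep("^radiomics_", names(features))),
            length(grep("^dosiomics_", names(features))),
            length(grep("^dosiomics_wavelet-", names(features)))))
cat("Feature table written to results/features.csv\n")
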