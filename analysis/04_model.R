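#!/usr/bin/env Rscript
# Stage 4: feature selection and the three-scenario SSIM prediction model.
#
# Grouped 70/30 split at the plan level; two-stage attribution-based
# selection (top-17 per feature group, importance-floor re-ranking);
# model search by grouped 10-fold CV over a fixed candidate family; the
# full (features + angles), rotation-only and features-only scenarios are
# evaluated on the same held-out plans. Writes results/model_reports.csv
# and results/selection.csv.

suppressPackageStartupMessages(library(rotqa))

seed <- 1
dir.create("results", showWarnings = FALSE)

metrics <- read_feature_table("results/metrics.csv")
features <- read_feature_table("results/features.csv")

cmp <- scenario_compare(metrics, features, k = 17, cv_folds = 10,
                        seed = seed)

reports <- do.call(rbind, lapply(
  Filter(Negate(is.null), cmp[c("full", "rotation_only", "features_only")]),
  function(rep) data.frame(scenario = rep$scenario, model = rep$model,
                           r2 = rep$r2, mae = rep$mae, rmse = rep$rmse,
                           medae = rep$medae, n_train = rep$n_train,
                           n_test = rep$n_test)))
write_feature_table(reports, "results/model_reports.csv")

sel <- cmp$selection
write_feature_table(
  data.frame(feature = sel$stage2$feature,
             importance = sel$stage2$importance,
             retained = sel$stage2$feature %in% sel$retained),
  "results/selection.csv")

cat("Scenario comparison on held-out plans:\n")
print(cmp)
cat(sprintf("Selection retained %d of %d merged features.\n",
            length(sel$retained), nrow(sel$stage2)))
cat(sprintf("Top features: %s\n",
            paste(head(sel$stage2$feature, 3), collapse = ", ")))
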