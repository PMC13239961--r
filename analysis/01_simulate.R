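#!/usr/bin/env Rscript
# Stage 1: simulate the two-stage measurement cohort.
#
# 40 synthetic SBRT-like plans; per plan one error-free reference plane,
# 15 stage-1 single-direction measurements (5 magnitudes x UP/RO/CW) and
# one stage-2 multi-axis measurement (2-3 axes, angles drawn from
# [1.5, 4.5] degrees), with 1% measurement noise. Writes a record
# manifest and the per-record planes under results/cohort/.

suppressPackageStartupMessages(library(rotqa))

seed <- 1
out <- "results/cohort"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

protocol <- cohort_protocol(n_plans = 40, seed = seed)
cohort <- simulate_cohort(protocol)

manifest <- do.call(rbind, lapply(seq_along(cohort$records), function(i) {
  rec <- cohort$records[[i]]
  rot <- rec$rotation
  ref_path <- file.path(out, sprintf("%s_ref", rec$plan_id))
  pert_path <- file.path(out, sprintf("rec%03d", i))
  if (!file.exists(paste0(ref_path, ".csv"))) {
    write_plane(rec$reference_plane, ref_path)
  }
  write_plane(rec$perturbed_plane, pert_path)
  data.frame(record = i, plan_id = rec$plan_id, stage = rec$stage,
             pitch_deg = rot$pitch_deg, roll_deg = rot$roll_deg,
             yaw_deg = rot$yaw_deg,
             delta_v100 = rec$delta_v100,
             reference = paste0(ref_path, ".csv"),
             perturbed = paste0(pert_path, ".csv"))
}))
write_feature_table(manifest, file.path(out, "manifest.csv"))

st <- table(manifest$stage)
cat(sprintf("Simulated %d plans: %d stage-1 and %d stage-2 records.\n",
            protocol$n_plans, st[["1"]], st[["2"]]))
cat(sprintf("Delta-V100 spans %.1f to %.1f percentage points.\n",
            min(manifest$delta_v100), max(manifest$delta_v100)))
cat("Manifest written to", file.path(out, "manifest.csv"), "\n")
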