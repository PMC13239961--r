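#' Per-record dose-comparison metrics for a cohort
#'
#' Preprocesses each (reference, perturbed) plane pair with the standard
#' pipeline and computes SSIM, gamma passing rates at the requested
#' criteria in relative-dose (RD: each plane self-normalized) and
#' absolute-dose (AD: Gy scale) modes, dose-difference-only passing rates,
#' and carries the per-record delta-V100.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param ssim_pars an [ssim_params()].
#' @param criteria named list of [gamma_criteria()] (names become column
#'   suffixes); `NULL` uses 2%/2mm, 1.5%/1.5mm, 1%/1mm.
#' @param include_gamma,include_dd compute gamma / DD columns (gamma is
#'   the slow part; SSIM-only studies can disable it).
#' @param n,fraction preprocessing grid size and low-dose threshold.
#' @return data.frame with one row per measurement record.
#' @export
cohort_metrics <- function(cohort, ssim_pars = ssim_params(),
                           criteria = NULL, include_gamma = TRUE,
                           include_dd = TRUE, n = 45, fraction = 0.70) {
  if (is.null(criteria)) {
    criteria <- list(
      "2_2" = gamma_criteria(2, 2),
      "1.5_1.5" = gamma_criteria(1.5, 1.5),
      "1_1" = gamma_criteria(1, 1))
  }
  rows <- lapply(cohort$records, function(rec) {
    ref_ad <- preprocess_plane(rec$reference_plane, n, fraction, "absolute")
    ev_ad <- preprocess_plane(rec$perturbed_plane, n, fraction, "absolute")
    ref_rd <- normalize_plane(ref_ad, "relative")
    ev_rd <- normalize_plane(ev_ad, "relative")
    rot <- rec$rotation
    out <- list(
      plan_id = rec$plan_id, stage = rec$stage,
      pitch_deg = rot$pitch_deg, roll_deg = rot$roll_deg,
      yaw_deg = rot$yaw_deg,
      angle_total_deg = rotation_total(rot),
      n_directions = rotation_ndir(rot),
      direction = if (rotation_ndir(rot) == 1) rot$direction_labels else
        if (rotation_ndir(rot) == 0) "NONE" else "MULTI",
      ssim = ssim(ref_rd, ev_rd, ssim_pars)$value,
      delta_v100 = rec$delta_v100)
    if (include_gamma) {
      for (nm in names(criteria)) {
        cr_g <- criteria[[nm]]
        out[[paste0("gamma_rd_", nm)]] <-
          gamma_pass_rate(gamma_map(ref_rd, ev_rd, cr_g), cr_g)
        out[[paste0("gamma_ad_", nm)]] <-
          gamma_pass_rate(gamma_map(ref_ad, ev_ad, cr_g), cr_g)
      }
    }
    if (include_dd) {
      out$dd_rd <- dose_difference_pass_rate(ref_rd, ev_rd, 2)
      out$dd_ad <- dose_difference_pass_rate(ref_ad, ev_ad, 2)
    }
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
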