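#' Gamma-analysis criteria
#'
#' @param dd_percent dose-difference criterion in percent (> 0).
#' @param dta_mm distance-to-agreement criterion in mm (> 0).
#' @param normalization `"global_reference_max"` (dose differences in
#'   percent of the reference plane maximum) or `"local"` (percent of the
#'   local reference dose).
#' @param pass_threshold_percent clinical passing-rate threshold
#'   (default 95, in (0, 100]).
#' @param search_radius_factor spatial search radius in multiples of
#'   `dta_mm` (default 3).
#' @param upsample_factor evaluation-grid refinement for the spatial
#'   search (default 10).
#' @return a list of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dd_percent = 2, dta_mm = 2,
                           normalization = c("global_reference_max", "local"),
                           pass_threshold_percent = 95,
                           search_radius_factor = 3, upsample_factor = 10) {
  check_number(dd_percent, "dd_percent", 0, strict = TRUE)
  check_number(dta_mm, "dta_mm", 0, strict = TRUE)
  if (pass_threshold_percent <= 0 || pass_threshold_percent > 100) {
    stop_rotqa("pass threshold must be in (0, 100]", "rotqa_invalid_spec")
  }
  structure(list(dd_percent = dd_percent, dta_mm = dta_mm,
                 normalization = match.arg(normalization),
                 pass_threshold_percent = pass_threshold_percent,
                 search_radius_factor = search_radius_factor,
                 upsample_factor = as.integer(upsample_factor)),
            class = "gamma_criteria")
}

# points scored by gamma / dose-difference analysis: entries surviving the
# low-dose preprocessing threshold in the reference
scored_points <- function(ref) ref$matrix > 0

#' Gamma index map between two dose planes
#'
#' For every scored reference point, the minimum over evaluated positions
#' within the search radius of
#' `sqrt(dist^2 / dta^2 + dDose^2 / dd^2)`, with the evaluation plane
#' bilinearly upsampled by `upsample_factor` for the spatial search.
#' Scored points are the entries surviving the low-dose preprocessing
#' threshold in the reference; other points are `NA`.
#'
#' @param ref,eval_plane [dose_plane()]s with equal shape and pixel pitch.
#' @param criteria a [gamma_criteria()].
#' @return matrix of gamma values (`NA` at unscored points).
#' @export
gamma_map <- function(ref, eval_plane, criteria = gamma_criteria()) {
  if (!all(dim(ref$matrix) == dim(eval_plane$matrix))) {
    stop_rotqa("planes must share shape", "rotqa_shape_mismatch")
  }
  if (abs(ref$spacing_mm - eval_plane$spacing_mm) > 1e-9) {
    stop_rotqa("planes must share pixel pitch", "rotqa_shape_mismatch")
  }
  if (ref$max_dose <= 0) {
    stop_rotqa("reference plane has zero maximum", "rotqa_degenerate_plane")
  }
  up <- criteria$upsample_factor
  fine <- if (up > 1) {
    resample_to_grid(eval_plane, (nrow(ref$matrix) - 1) * up + 1)$matrix
  } else {
    eval_plane$matrix
  }
  spacing_fine <- ref$spacing_mm * (nrow(ref$matrix) - 1) /
    (nrow(fine) - 1)
  scored <- scored_points(ref)
  dd_frac <- criteria$dd_percent / 100
  denom <- if (criteria$normalization == "global_reference_max") {
    matrix(dd_frac * ref$max_dose, nrow(ref$matrix), ncol(ref$matrix))
  } else {
    dd_frac * pmax(ref$matrix, 1e-12)
  }
  gamma_map_cpp(ref$matrix, fine, scored, denom, ref$spacing_mm,
                spacing_fine, criteria$dta_mm,
                criteria$search_radius_factor * criteria$dta_mm)
}

#' Gamma passing rate
#'
#' @param gmap gamma matrix from [gamma_map()].
#' @param criteria a [gamma_criteria()] (unused beyond validation; passing
#'   means gamma <= 1).
#' @return percent of scored points with gamma <= 1.
#' @export
gamma_pass_rate <- function(gmap, criteria = gamma_criteria()) {
  g <- gmap[!is.na(gmap)]
  if (length(g) == 0) stop_rotqa("no scored points", "rotqa_degenerate_plane")
  100 * mean(g <= 1)
}

#' Dose-difference passing rate
#'
#' Percent of scored points whose absolute dose difference is within
#' `dd_percent` of the normalization dose (no spatial search), i.e. the
#' DD-only analogue of the gamma criterion.
#'
#' @param ref,eval_plane [dose_plane()]s with equal shape.
#' @param dd_percent dose-difference criterion in percent.
#' @param normalization `"global_reference_max"` or `"local"`.
#' @return percent of scored points passing.
#' @export
dose_difference_pass_rate <- function(ref, eval_plane, dd_percent = 2,
                                      normalization = "global_reference_max") {
  if (!all(dim(ref$matrix) == dim(eval_plane$matrix))) {
    stop_rotqa("planes must share shape", "rotqa_shape_mismatch")
  }
  scored <- scored_points(ref)
  if (!any(scored)) stop_rotqa("no scored points", "rotqa_degenerate_plane")
  dd_frac <- dd_percent / 100
  tol <- if (normalization == "global_reference_max") {
    dd_frac * ref$max_dose
  } else {
    dd_frac * pmax(ref$matrix[scored], 1e-12)
  }
  diff <- abs(eval_plane$matrix[scored] - ref$matrix[scored])
  100 * mean(diff <= tol)
}
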