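#' Target V100: percent of the target receiving the prescription dose
#'
#' @param volume a [dose_volume()].
#' @param mask a [structure_mask()] aligned to `volume` (same shape,
#'   spacing and origin).
#' @param prescription prescription dose in Gy (> 0); defaults to the
#'   volume's prescription dose.
#' @return percent of masked voxels with dose >= prescription.
#' @export
v100 <- function(volume, mask, prescription = volume$prescription_dose) {
  if (!all(dim(volume$grid) == dim(mask$grid)) ||
      any(abs(volume$spacing - mask$spacing) > 1e-9) ||
      any(abs(volume$origin - mask$origin) > 1e-9)) {
    stop_rotqa("volume and mask are not aligned", "rotqa_shape_mismatch")
  }
  check_number(prescription, "prescription", 0, strict = TRUE)
  inmask <- volume$grid[mask$grid]
  if (length(inmask) == 0) stop_rotqa("mask is empty", "rotqa_empty_mask")
  100 * mean(inmask >= prescription)
}

#' Delta-V100: target coverage loss under rotation
#'
#' `v100(reference) - v100(rotated)` in percentage points; positive values
#' mean coverage loss under the rotation.
#'
#' @param ref reference (unrotated) [dose_volume()].
#' @param rot rotated [dose_volume()] on the same grid.
#' @param mask the target [structure_mask()].
#' @param prescription prescription dose in Gy.
#' @return difference in percentage points.
#' @export
delta_v100 <- function(ref, rot, mask,
                       prescription = ref$prescription_dose) {
  v100(ref, mask, prescription) - v100(rot, mask, prescription)
}
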