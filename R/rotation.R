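#' Rotational setup error
#'
#' Rigid rotation about the isocenter, expressed in the three clinical
#' directions: UP = upward pitch about the left-right (x) axis, RO = roll
#' about the anterior-posterior (y) axis, CW = clockwise yaw (viewed from
#' above) about the superior-inferior (z) axis.
#'
#' @param pitch_deg,roll_deg,yaw_deg angles in degrees, each within
#'   `[-10, 10]`.
#' @return an object of class `rotation_error` with fields `pitch_deg`,
#'   `roll_deg`, `yaw_deg` and `direction_labels` (a label is present iff
#'   its angle is nonzero).
#' @export
rotation_error <- function(pitch_deg = 0, roll_deg = 0, yaw_deg = 0) {
  ang <- c(pitch_deg = pitch_deg, roll_deg = roll_deg, yaw_deg = yaw_deg)
  if (any(!is.finite(ang)) || any(abs(ang) > 10)) {
    stop_rotqa("rotation angles must be finite and |angle| <= 10 degrees",
               "rotqa_invalid_rotation")
  }
  labels <- c("UP", "RO", "CW")[ang != 0]
  structure(list(pitch_deg = as.double(pitch_deg),
                 roll_deg = as.double(roll_deg),
                 yaw_deg = as.double(yaw_deg),
                 direction_labels = labels),
            class = "rotation_error")
}

#' @export
print.rotation_error <- function(x, ...) {
  cat(sprintf("<rotation_error> UP %.3g / RO %.3g / CW %.3g deg\n",
              x$pitch_deg, x$roll_deg, x$yaw_deg))
  invisible(x)
}

# total absolute angle and direction count of a rotation
rotation_total <- function(rot) abs(rot$pitch_deg) + abs(rot$roll_deg) +
  abs(rot$yaw_deg)
rotation_ndir <- function(rot) length(rot$direction_labels)

#' Rotation matrix for a rotational setup error
#'
#' Right-handed frame (x left-right, y anterior-posterior, z
#' superior-inferior). Positive pitch/roll follow the right-hand rule about
#' +x/+y; positive yaw is clockwise viewed from above, i.e. a negative
#' right-hand rotation about +z. Applied as `R = Rz %*% Ry %*% Rx`.
#'
#' @param rotation a [rotation_error()].
#' @return 3x3 rotation matrix.
#' @export
rotation_matrix <- function(rotation) {
  d2r <- pi / 180
  p <- rotation$pitch_deg * d2r
  r <- rotation$roll_deg * d2r
  y <- -rotation$yaw_deg * d2r  # CW viewed from above
  Rx <- matrix(c(1, 0, 0, 0, cos(p), sin(p), 0, -sin(p), cos(p)), 3, 3)
  Ry <- matrix(c(cos(r), 0, -sin(r), 0, 1, 0, sin(r), 0, cos(r)), 3, 3)
  Rz <- matrix(c(cos(y), sin(y), 0, -sin(y), cos(y), 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Apply a rigid rotation to a dose volume
#'
#' Emulates rotating the phantom while the detector stays fixed: the dose
#' field is resampled under the rigid rotation about `center`
#' (inverse-mapping trilinear interpolation; voxels that map outside the
#' original field are set to 0). The grid geometry is unchanged.
#'
#' @param volume a [dose_volume()].
#' @param rotation a [rotation_error()].
#' @param center rotation center (mm); defaults to the isocenter.
#' @return a new [dose_volume()] on the same grid.
#' @export
apply_rigid_rotation <- function(volume, rotation, center = NULL) {
  if (is.null(center)) center <- volume$isocenter
  center <- as.double(center)
  hi <- volume$origin + (dim(volume$grid) - 1) * volume$spacing
  if (any(center < volume$origin) || any(center > hi)) {
    stop_rotqa("rotation center must lie inside the grid",
               "rotqa_invalid_rotation")
  }
  if (rotation$pitch_deg == 0 && rotation$roll_deg == 0 &&
      rotation$yaw_deg == 0) {
    return(volume)
  }
  R <- rotation_matrix(rotation)
  dims <- dim(volume$grid)
  ax <- lapply(1:3, function(a) {
    volume$origin[a] + (seq_len(dims[a]) - 1) * volume$spacing[a]
  })
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  src <- sweep(sweep(pts, 2, center, "-") %*% R, 2, center, "+")
  vals <- sample_volume(volume, src, fill = 0)
  out <- volume
  out$grid <- array(vals, dim = dims)
  out
}
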