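#' Dose volume container
#'
#' A 3D dose grid on a regular axis-aligned lattice. Axis convention is a
#' patient-like right-handed frame: x = left-right, y = anterior-posterior,
#' z = superior-inferior. Voxel `(i, j, k)` sits at
#' `origin + (c(i, j, k) - 1) * spacing` (mm).
#'
#' @param grid 3D numeric array of dose values (Gy), all non-negative.
#' @param spacing per-axis voxel size in mm (length 1 or 3, strictly positive).
#' @param origin physical position of voxel `(1, 1, 1)` in mm (length 3).
#' @param isocenter 3D point (mm); must lie inside the grid bounding box.
#' @param prescription_dose prescription dose in Gy.
#' @return an object of class `dose_volume`.
#' @export
dose_volume <- function(grid, spacing, origin = c(0, 0, 0),
                        isocenter = NULL, prescription_dose = NA_real_) {
  if (!is.array(grid) || length(dim(grid)) != 3) {
    stop_rotqa("`grid` must be a 3D array", "rotqa_invalid_spec")
  }
  if (anyNA(grid) || any(grid < 0)) {
    stop_rotqa("dose values must be finite and >= 0", "rotqa_invalid_spec")
  }
  spacing <- rep(as.double(spacing), length.out = 3)
  if (any(spacing <= 0)) {
    stop_rotqa("spacing must be strictly positive", "rotqa_invalid_spec")
  }
  origin <- rep(as.double(origin), length.out = 3)
  hi <- origin + (dim(grid) - 1) * spacing
  if (is.null(isocenter)) isocenter <- (origin + hi) / 2
  isocenter <- as.double(isocenter)
  if (any(isocenter < origin - 1e-9) || any(isocenter > hi + 1e-9)) {
    stop_rotqa("isocenter must lie inside the grid bounding box",
               "rotqa_invalid_spec")
  }
  structure(list(grid = grid, spacing = spacing, origin = origin,
                 isocenter = isocenter,
                 prescription_dose = as.double(prescription_dose)),
            class = "dose_volume")
}

#' @export
print.dose_volume <- function(x, ...) {
  cat(sprintf(
    "<dose_volume> %s voxels, spacing %s mm, max %.2f Gy, prescription %.2f Gy\n",
    paste(dim(x$grid), collapse = "x"),
    paste(signif(x$spacing, 4), collapse = "x"),
    max(x$grid), x$prescription_dose))
  invisible(x)
}

#' Binary structure mask aligned to a dose volume
#'
#' @param grid 3D logical (or 0/1) array, same shape as its dose volume.
#' @param spacing,origin geometry copied from the parent volume.
#' @param label text label for the structure.
#' @return an object of class `structure_mask`.
#' @export
structure_mask <- function(grid, spacing, origin = c(0, 0, 0),
                           label = "target") {
  if (!is.array(grid) || length(dim(grid)) != 3) {
    stop_rotqa("`grid` must be a 3D array", "rotqa_invalid_spec")
  }
  grid <- array(as.logical(grid), dim = dim(grid))
  if (!any(grid)) stop_rotqa("mask is empty", "rotqa_empty_mask")
  spacing <- rep(as.double(spacing), length.out = 3)
  structure(list(grid = grid, spacing = spacing,
                 origin = rep(as.double(origin), length.out = 3),
                 label = label),
            class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask> '%s': %d of %s voxels\n", x$label,
              sum(x$grid), paste(dim(x$grid), collapse = "x")))
  invisible(x)
}

# physical mm point(s) -> continuous 0-based voxel index
mm_to_index <- function(volume, points) {
  points <- matrix(points, ncol = 3)
  sweep(sweep(points, 2, volume$origin, "-"), 2, volume$spacing, "/")
}

#' Sample a dose volume at arbitrary physical points
#'
#' Trilinear interpolation; points outside the grid return `fill`.
#'
#' @param volume a [dose_volume()].
#' @param points n x 3 matrix of positions (mm).
#' @param fill value for out-of-grid points.
#' @return numeric vector of length n.
#' @export
sample_volume <- function(volume, points, fill = 0) {
  idx <- mm_to_index(volume, points)
  trilinear_sample_cpp(as.double(volume$grid), dim(volume$grid), idx, fill)
}

#' Resample a dose volume onto a new regular grid
#'
#' Trilinear resampling onto a grid with the requested spacing covering the
#' same physical extent (the last node is the largest `origin + m * spacing`
#' not beyond the original extent).
#'
#' @param volume a [dose_volume()].
#' @param spacing target spacing in mm (length 1 for isotropic, or 3).
#' @return a new [dose_volume()].
#' @export
resample_volume <- function(volume, spacing) {
  spacing <- rep(as.double(spacing), length.out = 3)
  if (any(spacing <= 0)) stop_rotqa("spacing must be > 0", "rotqa_invalid_spec")
  if (anyNA(volume$grid) || any(!is.finite(volume$grid))) {
    stop_rotqa("volume contains non-finite values", "rotqa_invalid_input")
  }
  extent <- (dim(volume$grid) - 1) * volume$spacing
  nnew <- pmax(2L, as.integer(floor(extent / spacing + 1e-9)) + 1L)
  ax <- lapply(1:3, function(a) {
    volume$origin[a] + (seq_len(nnew[a]) - 1) * spacing[a]
  })
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  vals <- sample_volume(volume, pts)
  newgrid <- array(vals, dim = nnew)
  iso <- volume$isocenter
  # keep the isocenter only if it is still inside the shrunk extent
  hi <- volume$origin + (nnew - 1) * spacing
  iso <- pmin(pmax(iso, volume$origin), hi)
  dose_volume(newgrid, spacing, volume$origin, iso, volume$prescription_dose)
}

#' Write / read a dose volume as JSON header + flat CSV
#'
#' The header stores shape, spacing, origin, isocenter and prescription;
#' values are written flat in C order (last axis fastest).
#'
#' @param volume a [dose_volume()].
#' @param prefix file path prefix; writes `<prefix>.json` and `<prefix>.csv`.
#' @return `prefix`, invisibly (for `write_volume`); a [dose_volume()]
#'   (for `read_volume`).
#' @export
write_volume <- function(volume, prefix) {
  hdr <- list(shape = dim(volume$grid), spacing = volume$spacing,
              origin = volume$origin, isocenter = volume$isocenter,
              prescription_dose = volume$prescription_dose)
  jsonlite::write_json(hdr, paste0(prefix, ".json"), digits = NA,
                       auto_unbox = FALSE)
  vals <- as.vector(aperm(volume$grid, c(3, 2, 1)))
  write.csv(data.frame(dose_gy = vals), paste0(prefix, ".csv"),
            row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_volume
#' @export
read_volume <- function(prefix) {
  hdr <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  for (f in c("shape", "spacing", "origin", "isocenter")) {
    if (is.null(hdr[[f]]) || length(hdr[[f]]) != 3) {
      stop_rotqa(sprintf("volume header field `%s` missing or malformed", f),
                 "rotqa_parse_error")
    }
  }
  vals <- read.csv(paste0(prefix, ".csv"))$dose_gy
  if (length(vals) != prod(hdr$shape)) {
    stop_rotqa(sprintf("value count %d does not match header shape %s",
                       length(vals), paste(hdr$shape, collapse = "x")),
               "rotqa_parse_error")
  }
  grid <- aperm(array(vals, dim = rev(hdr$shape)), c(3, 2, 1))
  dose_volume(grid, hdr$spacing, hdr$origin, hdr$isocenter,
              hdr$prescription_dose)
}
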