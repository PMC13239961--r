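# 3D shape descriptors of a binary mask.
#
# The surface mesh is built by marching tetrahedra on a lightly
# Gaussian-smoothed indicator field (sigma = 1 voxel, iso-level 0.5):
# smoothing removes the voxelization staircase so that surface area and
# sphericity of digitized round objects are recovered to ~1%.

# separable Gaussian smoothing with zero padding
smooth3d <- function(arr, sigma_vox = 1) {
  if (sigma_vox <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-0.5 * ((-r:r) / sigma_vox)^2)
  k <- k / sum(k)
  d <- dim(arr)
  conv_axis <- function(a, axis) {
    perm <- c(axis, setdiff(1:3, axis))
    m <- aperm(a, perm)
    dm <- dim(m)
    m2 <- matrix(m, dm[1], dm[2] * dm[3])
    padded <- rbind(matrix(0, r, ncol(m2)), m2, matrix(0, r, ncol(m2)))
    out <- matrix(0, dm[1], ncol(m2))
    for (t in seq_along(k)) {
      out <- out + k[t] * padded[(t - 1) + seq_len(dm[1]), , drop = FALSE]
    }
    aperm(array(out, dm), order(perm))
  }
  for (axis in 1:3) arr <- conv_axis(arr, axis)
  arr
}

# boundary voxels: in-mask voxels with an out-of-mask 6-neighbour
boundary_voxels <- function(m) {
  d <- dim(m)
  shift <- function(a, axis, by) {
    idx <- lapply(d, seq_len)
    src <- idx
    src[[axis]] <- pmin(pmax(idx[[axis]] + by, 1), d[axis])
    out <- a[src[[1]], src[[2]], src[[3]], drop = FALSE]
    # out-of-range treated as background
    edge <- if (by > 0) d[axis] - seq_len(by) + 1 else seq_len(-by)
    slicer <- lapply(d, seq_len)
    slicer[[axis]] <- edge
    out[slicer[[1]], slicer[[2]], slicer[[3]]] <- FALSE
    out
  }
  nb_all <- array(TRUE, dim = d)
  for (axis in 1:3) {
    for (by in c(-1, 1)) {
      nb_all <- nb_all & shift(m, axis, by)
    }
  }
  m & !nb_all
}

max_pairwise_distance <- function(pts) {
  n <- nrow(pts)
  if (n < 2) return(0)
  if (n > 8000) {  # deterministic thinning for very large surfaces
    pts <- pts[round(seq(1, n, length.out = 8000)), , drop = FALSE]
    n <- nrow(pts)
  }
  best <- 0
  chunk <- 2000L
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1, n)
    block <- pts[s:e, , drop = FALSE]
    d2 <- outer(rowSums(block^2), rowSums(pts^2), "+") -
      2 * block %*% t(pts)
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}

#' 3D shape features of a structure mask
#'
#' The 14 standard mesh- and moment-based shape descriptors: mesh volume,
#' voxel volume, surface area, surface-to-volume ratio, sphericity, the
#' maximum 3D diameter and the three maximum in-plane diameters, the three
#' principal-axis lengths, elongation and flatness.
#'
#' @param mask a [structure_mask()] or logical 3D array.
#' @param spacing voxel spacing in mm (taken from the mask object if
#'   available).
#' @param prefix name prefix.
#' @return named numeric vector of length 14.
#' @export
shape_features <- function(mask, spacing = NULL, prefix = "original") {
  mgrid <- if (inherits(mask, "structure_mask")) mask$grid else mask
  if (is.null(spacing)) {
    spacing <- if (inherits(mask, "structure_mask")) mask$spacing else
      rep(1, 3)
  }
  spacing <- rep(as.double(spacing), length.out = 3)
  nvox <- sum(mgrid)
  if (nvox == 0) stop_rotqa("mask is empty", "rotqa_empty_mask")

  # mesh on the smoothed, zero-padded indicator (padding closes the surface)
  pad <- 4L
  d <- dim(mgrid)
  f <- array(0, d + 2 * pad)
  f[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <-
    as.double(mgrid)
  fs <- smooth3d(f, 1)
  av <- mesh_area_volume_cpp(as.double(fs), dim(fs), spacing, 0.5)
  if (av[2] <= 0) {
    # masks only a voxel or two wide vanish under smoothing; mesh the
    # raw indicator instead
    av <- mesh_area_volume_cpp(as.double(f), dim(f), spacing, 0.5)
  }
  area <- av[1]
  mesh_vol <- av[2]

  idx <- which(mgrid, arr.ind = TRUE)
  coords <- sweep(idx - 1, 2, spacing, "*")
  bnd <- which(boundary_voxels(mgrid), arr.ind = TRUE)
  bcoords <- sweep(bnd - 1, 2, spacing, "*")
  if (nrow(bcoords) == 0) bcoords <- coords
  # half-voxel surface extension so single-voxel-thick masks have extent
  d3 <- max_pairwise_distance(bcoords)
  d2_slice <- max_pairwise_distance(bcoords[, 1:2, drop = FALSE])   # x-y
  d2_col <- max_pairwise_distance(bcoords[, c(1, 3), drop = FALSE]) # x-z
  d2_row <- max_pairwise_distance(bcoords[, 2:3, drop = FALSE])     # y-z

  if (nvox > 1) {
    cv <- crossprod(sweep(coords, 2, colMeans(coords))) / nvox
    ev <- sort(pmax(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
                    0), decreasing = TRUE)
  } else {
    ev <- c(0, 0, 0)
  }
  axis_len <- 4 * sqrt(ev)

  out <- c(
    MeshVolume = mesh_vol,
    VoxelVolume = nvox * prod(spacing),
    SurfaceArea = area,
    SurfaceVolumeRatio = if (mesh_vol > 0) area / mesh_vol else Inf,
    Sphericity = if (area > 0) (36 * pi * mesh_vol^2)^(1 / 3) / area else 0,
    Maximum3DDiameter = d3,
    Maximum2DDiameterSlice = d2_slice,
    Maximum2DDiameterColumn = d2_col,
    Maximum2DDiameterRow = d2_row,
    MajorAxisLength = axis_len[1],
    MinorAxisLength = axis_len[2],
    LeastAxisLength = axis_len[3],
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0)
  setNames(out, paste0(prefix, "_shape_", names(out)))
}
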