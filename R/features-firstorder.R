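#' Feature-extraction configuration
#'
#' @param resample_spacing_mm isotropic target spacing in mm (1.0 matches
#'   typical imaging resolution); `NULL` skips resampling.
#' @param bin_width fixed discretization width (25 intensity units for
#'   images, 1 Gy for dose).
#' @param wavelet_name orthogonal wavelet id (only `"coif1"` is built in).
#' @param enabled_categories feature categories to extract.
#' @return a list of class `extraction_config`.
#' @export
extraction_config <- function(resample_spacing_mm = 1.0, bin_width = 25,
                              wavelet_name = "coif1",
                              enabled_categories = c("firstorder", "shape",
                                                     "glcm", "glrlm", "glszm",
                                                     "gldm", "ngtdm",
                                                     "wavelet")) {
  if (!is.null(resample_spacing_mm)) {
    check_number(resample_spacing_mm, "resample_spacing_mm", 0, strict = TRUE)
  }
  check_number(bin_width, "bin_width", 0, strict = TRUE)
  structure(list(resample_spacing_mm = resample_spacing_mm,
                 bin_width = bin_width, wavelet_name = wavelet_name,
                 enabled_categories = enabled_categories),
            class = "extraction_config")
}

#' Discretize intensities into fixed-width bins
#'
#' Gray level of an in-mask value v is `floor((v - min) / bin_width) + 1`,
#' anchored at the masked minimum, so levels start at 1. Outside-mask
#' voxels are level 0.
#'
#' @param values 3D array (or numeric vector) of intensities.
#' @param mask logical array of the same shape (`NULL` = all voxels).
#' @param bin_width bin width (> 0).
#' @return integer array of gray levels (0 outside the mask).
#' @export
discretize <- function(values, mask = NULL, bin_width = 1) {
  check_number(bin_width, "bin_width", 0, strict = TRUE)
  if (is.null(mask)) mask <- array(TRUE, dim = dim(values) %||% length(values))
  if (!any(mask)) stop_rotqa("mask is empty", "rotqa_empty_mask")
  v <- values[mask]
  lev <- array(0L, dim = dim(mask) %||% length(mask))
  lev[mask] <- as.integer(floor((v - min(v)) / bin_width)) + 1L
  lev
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# discrete probability distribution of masked values under fixed-width bins
bin_probs <- function(v, bin_width) {
  lev <- floor((v - min(v)) / bin_width)
  tabulate(lev + 1L) / length(v)
}

#' First-order statistical features
#'
#' The 18 standard first-order descriptors of the masked intensity
#' distribution. Entropy and uniformity use the fixed-bin-width
#' discretization; moments are population moments; percentiles use linear
#' interpolation.
#'
#' @param volume a [dose_volume()] or 3D array.
#' @param mask logical array / [structure_mask()] (`NULL` = all voxels).
#' @param config an [extraction_config()] (supplies `bin_width`).
#' @param prefix name prefix for the returned vector.
#' @return named numeric vector of length 18.
#' @export
first_order_features <- function(volume, mask = NULL,
                                 config = extraction_config(),
                                 prefix = "original") {
  arr <- if (inherits(volume, "dose_volume")) volume$grid else volume
  spacing <- if (inherits(volume, "dose_volume")) volume$spacing else
    rep(1, 3)
  mgrid <- if (inherits(mask, "structure_mask")) mask$grid else mask
  if (is.null(mgrid)) mgrid <- array(TRUE, dim = dim(arr))
  v <- arr[mgrid]
  if (length(v) == 0) stop_rotqa("mask is empty", "rotqa_empty_mask")

  p <- bin_probs(v, config$bin_width)
  p <- p[p > 0]
  n <- length(v)
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  m3 <- mean((v - mu)^3)
  m4 <- mean((v - mu)^4)
  q <- unname(quantile(v, c(0.10, 0.25, 0.50, 0.75, 0.90), type = 7))
  robust <- v[v >= q[1] & v <= q[5]]
  energy <- sum(v^2)

  out <- c(
    Energy = energy,
    TotalEnergy = prod(spacing) * energy,
    Entropy = -sum(p * log2(p)),
    Minimum = min(v),
    Percentile10 = q[1],
    Percentile90 = q[5],
    Maximum = max(v),
    Mean = mu,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(v) - min(v),
    MeanAbsoluteDeviation = mean(abs(v - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(robust - mean(robust))),
    RootMeanSquared = sqrt(mean(v^2)),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2))
  setNames(out, paste0(prefix, "_firstorder_", names(out)))
}
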