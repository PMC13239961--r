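#' Resample a dose plane to an n x n grid
#'
#' Bilinear (default) interpolation over the plane's physical extent; the
#' pixel pitch is rescaled so the extent is preserved.
#'
#' @param plane a [dose_plane()].
#' @param n output side length (>= 2; default 45, the standardized
#'   measurement matrix).
#' @param method `"bilinear"` (detector data are smooth) or `"cubic"`
#'   (Catmull-Rom, for completeness).
#' @return a resampled [dose_plane()].
#' @export
resample_to_grid <- function(plane, n = 45, method = c("bilinear", "cubic")) {
  method <- match.arg(method)
  m <- plane$matrix
  if (nrow(m) < 2 || ncol(m) < 2) stop_rotqa("input must be at least 2x2",
                                             "rotqa_invalid_input")
  if (n < 2) stop_rotqa("n must be >= 2", "rotqa_invalid_spec")
  if (anyNA(m) || any(!is.finite(m))) {
    stop_rotqa("plane contains non-finite values", "rotqa_invalid_input")
  }
  ri <- seq(0, nrow(m) - 1, length.out = n)
  ci <- seq(0, ncol(m) - 1, length.out = n)
  g <- expand.grid(r = ri, c = ci)
  vals <- if (method == "bilinear") {
    bilinear_sample_cpp(m, g$r, g$c, 0)
  } else {
    catmull_rom_sample(m, g$r, g$c)
  }
  vals[vals < 0] <- 0
  ext_r <- (nrow(m) - 1) * plane$spacing_mm
  dose_plane(matrix(vals, n, n), ext_r / (n - 1), plane$mode)
}

# Catmull-Rom bicubic sampling with edge clamping (R reference path; the
# standard pipeline uses the bilinear kernel).
catmull_rom_sample <- function(m, ri, ci) {
  cr <- function(t) {
    w0 <- -0.5 * t^3 + t^2 - 0.5 * t
    w1 <- 1.5 * t^3 - 2.5 * t^2 + 1
    w2 <- -1.5 * t^3 + 2 * t^2 + 0.5 * t
    w3 <- 0.5 * t^3 - 0.5 * t^2
    cbind(w0, w1, w2, w3)
  }
  nr <- nrow(m); nc <- ncol(m)
  r0 <- pmin(pmax(floor(ri), 0), nr - 2)
  c0 <- pmin(pmax(floor(ci), 0), nc - 2)
  wr <- cr(ri - r0)
  wc <- cr(ci - c0)
  out <- numeric(length(ri))
  for (a in 1:4) {
    rr <- pmin(pmax(r0 + a - 2, 0), nr - 1)
    for (b in 1:4) {
      cc <- pmin(pmax(c0 + b - 2, 0), nc - 1)
      out <- out + wr[, a] * wc[, b] * m[cbind(rr + 1, cc + 1)]
    }
  }
  out
}

#' Zero out the low-dose region of a plane
#'
#' Entries strictly below `fraction` of the plane maximum are set to zero
#' (ties at the threshold are kept); all other entries, including the
#' maximum, are unchanged.
#'
#' @param plane a [dose_plane()].
#' @param fraction threshold as a fraction of the plane maximum
#'   (default 0.70, the high-dose clinical region).
#' @return a thresholded [dose_plane()].
#' @export
threshold_low_dose <- function(plane, fraction = 0.70) {
  if (plane$max_dose <= 0) {
    stop_rotqa("cannot threshold an all-zero plane", "rotqa_degenerate_plane")
  }
  m <- plane$matrix
  m[m < fraction * plane$max_dose] <- 0
  dose_plane(m, plane$spacing_mm, plane$mode)
}

#' Normalize a dose plane
#'
#' Absolute mode returns the plane unchanged (Gy scale); relative mode
#' divides by `reference_max` (the plane's own maximum when unset) and
#' flips the mode flag.
#'
#' @param plane a [dose_plane()].
#' @param mode `"absolute"` or `"relative"`.
#' @param reference_max normalization dose in Gy (relative mode only).
#' @return a [dose_plane()].
#' @export
normalize_plane <- function(plane, mode = c("relative", "absolute"),
                            reference_max = NULL) {
  mode <- match.arg(mode)
  if (mode == "absolute") return(plane)
  if (is.null(reference_max)) reference_max <- plane$max_dose
  if (!is.finite(reference_max) || reference_max <= 0) {
    stop_rotqa("reference_max must be > 0", "rotqa_invalid_spec")
  }
  dose_plane(plane$matrix / reference_max, plane$spacing_mm,
             "relative_fraction")
}

#' Standard plane preprocessing pipeline
#'
#' Fixed order: resample to `n` x `n`, zero entries below `fraction` of the
#' maximum, then normalize. Applying the pipeline twice equals applying it
#' once. Set `threshold_first = TRUE` to threshold on the native grid
#' before interpolation instead.
#'
#' @param plane a [dose_plane()].
#' @param n standardized side length (default 45).
#' @param fraction low-dose threshold fraction (default 0.70).
#' @param mode `"relative"` or `"absolute"` normalization.
#' @param reference_max shared normalization dose (e.g. the reference
#'   plane's maximum) or `NULL` for the plane's own maximum.
#' @param threshold_first threshold before resampling (default `FALSE`:
#'   the text order of the measurement protocol, interpolate then
#'   threshold).
#' @return a standardized [dose_plane()].
#' @export
preprocess_plane <- function(plane, n = 45, fraction = 0.70,
                             mode = "relative", reference_max = NULL,
                             threshold_first = FALSE) {
  if (threshold_first) plane <- threshold_low_dose(plane, fraction)
  plane <- resample_to_grid(plane, n)
  if (!threshold_first) plane <- threshold_low_dose(plane, fraction)
  normalize_plane(plane, mode, reference_max)
}
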