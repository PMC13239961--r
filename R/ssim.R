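#' SSIM parameters
#'
#' Regularization and windowing parameters of the structural similarity
#' index. The derived constants are `C1 = (K1 L)^2`, `C2 = (K2 L)^2` and
#' `C3 = C2 / 2`.
#'
#' @param K1,K2 regularization coefficients (> 0; defaults 0.01 / 0.03,
#'   the standard image-library values).
#' @param L dynamic range of the data; `NULL` (default) uses the maximum
#'   of the two planes being compared.
#' @param alpha,beta,gamma_exp exponents of the luminance, contrast and
#'   structure components (defaults 1, giving the familiar combined form).
#' @param window odd side length of the local sliding window (default 7);
#'   0 computes a single global window.
#' @return a list of class `ssim_params`.
#' @export
ssim_params <- function(K1 = 0.01, K2 = 0.03, L = NULL, alpha = 1, beta = 1,
                        gamma_exp = 1, window = 7) {
  check_number(K1, "K1", 0, strict = TRUE)
  check_number(K2, "K2", 0, strict = TRUE)
  if (!is.null(L)) check_number(L, "L", 0, strict = TRUE)
  if (window != 0 && (window < 1 || window %% 2 != 1)) {
    stop_rotqa("window must be odd or 0 (global)", "rotqa_invalid_spec")
  }
  structure(list(K1 = K1, K2 = K2, L = L, alpha = alpha, beta = beta,
                 gamma_exp = gamma_exp, window = as.integer(window)),
            class = "ssim_params")
}

ssim_constants <- function(params, L) {
  C2 <- (params$K2 * L)^2
  list(C1 = (params$K1 * L)^2, C2 = C2, C3 = C2 / 2)
}

# sums over all w x w windows ("valid" positions only) via 2D cumsum
box_sums <- function(m, w) {
  S <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed cumulative sums
  S <- t(S)
  S <- rbind(0, cbind(0, S))
  nr <- nrow(m) - w + 1
  nc <- ncol(m) - w + 1
  i <- seq_len(nr)
  j <- seq_len(nc)
  S[i + w, j + w, drop = FALSE] - S[i, j + w, drop = FALSE] -
    S[i + w, j, drop = FALSE] + S[i, j, drop = FALSE]
}

#' SSIM component comparisons
#'
#' Luminance, contrast and structure comparisons from local window
#' statistics:
#' `l = (2 mu_x mu_y + C1) / (mu_x^2 + mu_y^2 + C1)`,
#' `c = (2 s_x s_y + C2) / (s_x^2 + s_y^2 + C2)`,
#' `s = (cov + C3) / (s_x s_y + C3)`, with `C3 = C2 / 2` so that
#' `l * c * s` equals the combined SSIM closed form when all exponents
#' are 1.
#'
#' @param stats list with numeric fields `mu_x`, `mu_y`, `var_x`, `var_y`,
#'   `cov_xy` (vectors allowed; variances >= 0).
#' @param params an [ssim_params()]; `L` must be set.
#' @return list with components `l`, `c`, `s`.
#' @export
ssim_components <- function(stats, params = ssim_params(L = 1)) {
  if (is.null(params$L)) {
    stop_rotqa("`L` must be fixed to evaluate components", "rotqa_invalid_spec")
  }
  cc <- ssim_constants(params, params$L)
  sx <- sqrt(pmax(stats$var_x, 0))
  sy <- sqrt(pmax(stats$var_y, 0))
  list(
    l = (2 * stats$mu_x * stats$mu_y + cc$C1) /
      (stats$mu_x^2 + stats$mu_y^2 + cc$C1),
    c = (2 * sx * sy + cc$C2) / (stats$var_x + stats$var_y + cc$C2),
    s = (stats$cov_xy + cc$C3) / (sx * sy + cc$C3))
}

#' Structural similarity index between two dose planes
#'
#' Computes local window statistics (uniform sliding window, population
#' variance/covariance, window fully inside the plane) and the SSIM
#' closed form
#' `(2 mu_x mu_y + C1)(2 cov + C2) / ((mu_x^2 + mu_y^2 + C1)(var_x + var_y + C2))`
#' per window when all exponents are 1, or the component product
#' `l^alpha c^beta s^gamma` otherwise. The scalar is the mean of the local
#' map (`window > 0`) or the single global value (`window = 0`).
#'
#' @param ref,eval_plane [dose_plane()]s with identical shape, both
#'   preprocessed identically.
#' @param params an [ssim_params()].
#' @return list with `value` (scalar) and `map` (local SSIM matrix; a
#'   1 x 1 matrix in global mode).
#' @export
ssim <- function(ref, eval_plane, params = ssim_params()) {
  x <- ref$matrix
  y <- eval_plane$matrix
  if (!all(dim(x) == dim(y))) {
    stop_rotqa("planes must share shape", "rotqa_shape_mismatch")
  }
  w <- params$window
  if (w > min(dim(x))) {
    stop_rotqa("window larger than plane", "rotqa_invalid_spec")
  }
  L <- if (is.null(params$L)) max(max(x), max(y)) else params$L
  if (L <= 0) L <- 1
  cc <- ssim_constants(params, L)

  if (w == 0) {
    n <- length(x)
    sx <- sum(x); sy <- sum(y)
    sxx <- sum(x * x); syy <- sum(y * y); sxy <- sum(x * y)
  } else {
    n <- w * w
    sx <- box_sums(x, w); sy <- box_sums(y, w)
    sxx <- box_sums(x * x, w); syy <- box_sums(y * y, w)
    sxy <- box_sums(x * y, w)
  }
  mux <- sx / n
  muy <- sy / n
  varx <- sxx / n - mux * mux
  vary <- syy / n - muy * muy
  covxy <- sxy / n - mux * muy

  default_exp <- params$alpha == 1 && params$beta == 1 && params$gamma_exp == 1
  if (default_exp) {
    map <- ((2 * mux * muy + cc$C1) * (2 * covxy + cc$C2)) /
      ((mux * mux + muy * muy + cc$C1) * (varx + vary + cc$C2))
  } else {
    comp <- ssim_components(
      list(mu_x = mux, mu_y = muy, var_x = varx, var_y = vary,
           cov_xy = covxy),
      ssim_params(params$K1, params$K2, L, window = max(w, 1)))
    map <- comp$l^params$alpha * comp$c^params$beta * comp$s^params$gamma_exp
  }
  map <- matrix(map, nrow = if (w == 0) 1 else nrow(x) - w + 1)
  list(value = mean(map), map = map)
}
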