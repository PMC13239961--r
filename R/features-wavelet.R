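# Single-level separable 3D wavelet decomposition with the orthonormal
# coiflet-1 filter bank (periodized). Each axis transform is the orthogonal
# circulant-downsampled analysis matrix, so the decomposition conserves
# energy exactly for even axis lengths; odd axes are replicate-padded by
# one slice and cropped after reconstruction.

# orthonormal coiflet-1 decomposition low-pass filter
coif1_lo <- c(-0.015655728135791993, -0.07273261951252645,
              0.38486484686485778, 0.85257202021160039,
              0.33789766245748182, -0.07273261951252645)

dwt_matrix <- function(n, lo = coif1_lo) {
  stopifnot(n %% 2 == 0, n >= length(lo))
  hi <- rev(lo) * (-1)^(seq_along(lo) - 1)  # quadrature mirror
  half <- n / 2
  W <- matrix(0, n, n)
  for (k in seq_len(half)) {
    idx <- ((seq_along(lo) - 1 + 2 * (k - 1)) %% n) + 1
    for (m in seq_along(lo)) {
      W[k, idx[m]] <- W[k, idx[m]] + lo[m]
      W[half + k, idx[m]] <- W[half + k, idx[m]] + hi[m]
    }
  }
  W
}

apply_axis <- function(arr, M, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  da <- dim(a)
  out <- M %*% matrix(a, da[1], da[2] * da[3])
  aperm(array(out, c(nrow(M), da[2], da[3])), order(perm))
}

#' Single-level 3D wavelet band decomposition
#'
#' Decomposes the volume with the orthonormal coiflet-1 wavelet and
#' reconstructs each of the 8 low/high subband combinations (LLL ... HHH,
#' letters ordered by axis) back to the input shape, i.e. each band is the
#' orthogonal projection of the input onto its subband. For even axis
#' lengths the band energies sum exactly to the input energy.
#'
#' @param volume a [dose_volume()] or 3D array (every axis at least the
#'   filter length, 6).
#' @return named list of 8 arrays of the input shape.
#' @export
wavelet_bands <- function(volume) {
  arr <- if (inherits(volume, "dose_volume")) volume$grid else volume
  d0 <- dim(arr)
  if (any(d0 < length(coif1_lo))) {
    stop_rotqa("volume too small for the wavelet filter",
               "rotqa_invalid_input")
  }
  # replicate-pad odd axes to even length
  padded <- d0 %% 2 == 1
  if (any(padded)) {
    for (axis in which(padded)) {
      idx <- lapply(dim(arr), seq_len)
      idx[[axis]] <- dim(arr)[axis]
      last <- arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
      arr <- abind_axis(arr, last, axis)
    }
  }
  d <- dim(arr)
  Ws <- lapply(d, dwt_matrix)
  coef <- arr
  for (axis in 1:3) coef <- apply_axis(coef, Ws[[axis]], axis)

  half <- d / 2
  sel <- list(L = lapply(half, seq_len),
              H = lapply(1:3, function(a) half[a] + seq_len(half[a])))
  bands <- list()
  for (b1 in c("L", "H")) for (b2 in c("L", "H")) for (b3 in c("L", "H")) {
    z <- array(0, d)
    z[sel[[b1]][[1]], sel[[b2]][[2]], sel[[b3]][[3]]] <-
      coef[sel[[b1]][[1]], sel[[b2]][[2]], sel[[b3]][[3]]]
    rec <- z
    for (axis in 1:3) rec <- apply_axis(rec, t(Ws[[axis]]), axis)
    if (any(padded)) {
      rec <- rec[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3]), drop = FALSE]
    }
    bands[[paste0(b1, b2, b3)]] <- rec
  }
  bands
}

# bind a slab onto `arr` along `axis`
abind_axis <- function(arr, slab, axis) {
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  s <- aperm(slab, perm)
  da <- dim(a)
  out <- array(0, c(da[1] + dim(s)[1], da[2], da[3]))
  out[seq_len(da[1]), , ] <- a
  out[da[1] + seq_len(dim(s)[1]), , ] <- s
  aperm(out, order(perm))
}
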