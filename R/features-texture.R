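# Texture-matrix features on a discretized volume (gray levels 1..ng,
# 0 outside the mask). Matrices use the 26-neighbourhood / the 13 unique
# distance-1 directions; per-direction features are averaged over
# directions (the common angle-aggregation default). Formula dialect
# follows the IBSI-aligned standard set.

texture_census <- c(glcm = 24, glrlm = 16, glszm = 16, gldm = 14, ngtdm = 5)

#' Texture features of one category
#'
#' @param level_volume integer array of gray levels (1..ng in-mask, 0
#'   outside), as returned by [discretize()].
#' @param category one of `"glcm"`, `"glrlm"`, `"glszm"`, `"gldm"`,
#'   `"ngtdm"`.
#' @param prefix name prefix.
#' @return named numeric vector (24/16/16/14/5 values by category).
#' @export
texture_features <- function(level_volume, category = c("glcm", "glrlm",
                                                        "glszm", "gldm",
                                                        "ngtdm"),
                             prefix = "original") {
  category <- match.arg(category)
  lev <- level_volume
  if (is.null(dim(lev)) || length(dim(lev)) != 3) {
    stop_rotqa("level volume must be a 3D array", "rotqa_invalid_input")
  }
  np <- sum(lev > 0)
  if (np < 2) stop_rotqa("texture needs at least two in-mask voxels",
                         "rotqa_degenerate_texture")
  ng <- max(lev)
  dims <- dim(lev)
  storage.mode(lev) <- "integer"
  vals <- switch(category,
                 glcm = glcm_features(lev, dims, ng),
                 glrlm = glrlm_features(lev, dims, ng, np),
                 glszm = glszm_features(lev, dims, ng, np),
                 gldm = gldm_features(lev, dims, ng, np),
                 ngtdm = ngtdm_features(lev, dims, ng, np))
  setNames(vals, paste0(prefix, "_", category, "_", names(vals)))
}

glcm_features <- function(lev, dims, ng) {
  counts <- glcm_counts_cpp(as.vector(lev), dims, ng)
  counts <- array(counts, c(ng, ng, 13))
  i <- matrix(1:ng, ng, ng)
  j <- t(i)
  per_dir <- vapply(1:13, function(d) {
    C <- counts[, , d]
    C <- C + t(C)  # symmetric co-occurrence
    if (sum(C) == 0) return(rep(NA_real_, 24))
    p <- C / sum(C)
    px <- rowSums(p)
    py <- colSums(p)
    mux <- sum((1:ng) * px)
    muy <- sum((1:ng) * py)
    sigx <- sqrt(sum((1:ng - mux)^2 * px))
    sigy <- sqrt(sum((1:ng - muy)^2 * py))
    # diagonal (difference) and cross-diagonal (sum) distributions
    k_diff <- 0:(ng - 1)
    p_diff <- vapply(k_diff, function(k) sum(p[abs(i - j) == k]), 0)
    k_sum <- 2:(2 * ng)
    p_sum <- vapply(k_sum, function(k) sum(p[(i + j) == k]), 0)
    da <- sum(k_diff * p_diff)
    eps <- .Machine$double.eps
    hxy <- -sum(p[p > 0] * log2(p[p > 0]))
    pxy <- outer(px, py)
    hxy1 <- -sum(p[pxy > 0] * log2(pxy[pxy > 0]))
    hxy2 <- -sum(pxy[pxy > 0] * log2(pxy[pxy > 0]))
    hx <- -sum(px[px > 0] * log2(px[px > 0]))
    hy <- -sum(py[py > 0] * log2(py[py > 0]))
    imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
    imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0))
    corr <- if (sigx > eps && sigy > eps) {
      (sum(i * j * p) - mux * muy) / (sigx * sigy)
    } else 1
    # MCC: sqrt of the second-largest eigenvalue of Q
    mcc <- if (ng > 1 && sigx > eps) {
      pos <- px > 0
      Q <- matrix(0, ng, ng)
      denom <- outer(px, py)
      for (kk in 1:ng) {
        if (py[kk] > 0) {
          Q <- Q + outer(p[, kk], p[, kk]) / outer(px, rep(py[kk], ng))
        }
      }
      Q[!pos, ] <- 0
      evq <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
      sqrt(max(evq[min(2, length(evq))], 0))
    } else 1
    c(Autocorrelation = sum(i * j * p),
      ClusterProminence = sum((i + j - mux - muy)^4 * p),
      ClusterShade = sum((i + j - mux - muy)^3 * p),
      ClusterTendency = sum((i + j - mux - muy)^2 * p),
      Contrast = sum((i - j)^2 * p),
      Correlation = corr,
      DifferenceAverage = da,
      DifferenceEntropy = -sum(p_diff[p_diff > 0] * log2(p_diff[p_diff > 0])),
      DifferenceVariance = sum((k_diff - da)^2 * p_diff),
      Id = sum(p / (1 + abs(i - j))),
      Idm = sum(p / (1 + (i - j)^2)),
      Idmn = sum(p / (1 + (i - j)^2 / ng^2)),
      Idn = sum(p / (1 + abs(i - j) / ng)),
      Imc1 = imc1,
      Imc2 = imc2,
      InverseVariance = sum(p[i != j] / (i - j)[i != j]^2),
      JointAverage = mux,
      JointEnergy = sum(p^2),
      JointEntropy = hxy,
      MCC = mcc,
      MaximumProbability = max(p),
      SumAverage = sum(k_sum * p_sum),
      SumEntropy = -sum(p_sum[p_sum > 0] * log2(p_sum[p_sum > 0])),
      SumSquares = sum((i - mux)^2 * p))
  }, numeric(24))
  rowMeans(per_dir, na.rm = TRUE)
}

# shared small/large + low/high emphasis formulas for distribution
# matrices P(gray level, size-like index)
sizezone_stats <- function(P, size_idx, np) {
  Nz <- sum(P)
  pg <- rowSums(P)
  ps <- colSums(P)
  i <- seq_len(nrow(P))
  s <- size_idx
  pnorm <- P / Nz
  mu_i <- sum(i * rowSums(pnorm))
  mu_s <- sum(s * colSums(pnorm))
  list(
    Nz = Nz, pg = pg, ps = ps, i = i, s = s, pnorm = pnorm,
    small = sum(t(t(P) / s^2)) / Nz,
    large = sum(t(t(P) * s^2)) / Nz,
    gln = sum(pg^2) / Nz,
    glnn = sum(pg^2) / Nz^2,
    sn = sum(ps^2) / Nz,
    snn = sum(ps^2) / Nz^2,
    pct = Nz / np,
    glvar = sum((matrix(i, nrow(P), ncol(P)) - mu_i)^2 * pnorm),
    svar = sum((matrix(s, nrow(P), ncol(P), byrow = TRUE) - mu_s)^2 * pnorm),
    entropy = -sum(pnorm[pnorm > 0] * log2(pnorm[pnorm > 0])),
    lowg = sum(pg / i^2) / Nz,
    highg = sum(pg * i^2) / Nz,
    smalllow = sum(P / outer(i^2, s^2)) / Nz,
    smallhigh = sum(P * outer(i^2, 1 / s^2)) / Nz,
    largelow = sum(P * outer(1 / i^2, s^2)) / Nz,
    largehigh = sum(P * outer(i^2, s^2)) / Nz)
}

glrlm_features <- function(lev, dims, ng, np) {
  maxlen <- max(dims)
  counts <- glrlm_counts_cpp(as.vector(lev), dims, ng, maxlen)
  counts <- array(counts, c(ng, maxlen, 13))
  per_dir <- vapply(1:13, function(d) {
    P <- counts[, , d, drop = TRUE]
    P <- matrix(P, ng, maxlen)
    if (sum(P) == 0) return(rep(NA_real_, 16))
    st <- sizezone_stats(P, seq_len(maxlen), np)
    c(ShortRunEmphasis = st$small,
      LongRunEmphasis = st$large,
      GrayLevelNonUniformity = st$gln,
      GrayLevelNonUniformityNormalized = st$glnn,
      RunLengthNonUniformity = st$sn,
      RunLengthNonUniformityNormalized = st$snn,
      RunPercentage = st$pct,
      GrayLevelVariance = st$glvar,
      RunVariance = st$svar,
      RunEntropy = st$entropy,
      LowGrayLevelRunEmphasis = st$lowg,
      HighGrayLevelRunEmphasis = st$highg,
      ShortRunLowGrayLevelEmphasis = st$smalllow,
      ShortRunHighGrayLevelEmphasis = st$smallhigh,
      LongRunLowGrayLevelEmphasis = st$largelow,
      LongRunHighGrayLevelEmphasis = st$largehigh)
  }, numeric(16))
  rowMeans(per_dir, na.rm = TRUE)
}

glszm_features <- function(lev, dims, ng, np) {
  zones <- glszm_zones_cpp(as.vector(lev), dims)
  maxsize <- max(zones[, 2])
  P <- matrix(0, ng, maxsize)
  for (r in seq_len(nrow(zones))) {
    P[zones[r, 1], zones[r, 2]] <- P[zones[r, 1], zones[r, 2]] + 1
  }
  st <- sizezone_stats(P, seq_len(maxsize), np)
  c(SmallAreaEmphasis = st$small,
    LargeAreaEmphasis = st$large,
    GrayLevelNonUniformity = st$gln,
    GrayLevelNonUniformityNormalized = st$glnn,
    SizeZoneNonUniformity = st$sn,
    SizeZoneNonUniformityNormalized = st$snn,
    ZonePercentage = st$pct,
    GrayLevelVariance = st$glvar,
    ZoneVariance = st$svar,
    ZoneEntropy = st$entropy,
    LowGrayLevelZoneEmphasis = st$lowg,
    HighGrayLevelZoneEmphasis = st$highg,
    SmallAreaLowGrayLevelEmphasis = st$smalllow,
    SmallAreaHighGrayLevelEmphasis = st$smallhigh,
    LargeAreaLowGrayLevelEmphasis = st$largelow,
    LargeAreaHighGrayLevelEmphasis = st$largehigh)
}

gldm_features <- function(lev, dims, ng, np, alpha = 0) {
  counts <- gldm_counts_cpp(as.vector(lev), dims, ng, alpha)
  # dependence size j = number of dependent neighbours + 1 (so j >= 1)
  P <- counts
  st <- sizezone_stats(P, seq_len(ncol(P)), np)
  c(SmallDependenceEmphasis = st$small,
    LargeDependenceEmphasis = st$large,
    GrayLevelNonUniformity = st$gln,
    DependenceNonUniformity = st$sn,
    DependenceNonUniformityNormalized = st$snn,
    GrayLevelVariance = st$glvar,
    DependenceVariance = st$svar,
    DependenceEntropy = st$entropy,
    LowGrayLevelEmphasis = st$lowg,
    HighGrayLevelEmphasis = st$highg,
    SmallDependenceLowGrayLevelEmphasis = st$smalllow,
    SmallDependenceHighGrayLevelEmphasis = st$smallhigh,
    LargeDependenceLowGrayLevelEmphasis = st$largelow,
    LargeDependenceHighGrayLevelEmphasis = st$largehigh)
}

ngtdm_features <- function(lev, dims, ng, np) {
  tab <- ngtdm_table_cpp(as.vector(lev), dims, ng)
  n_i <- tab[, 1]
  s_i <- tab[, 2]
  present <- which(n_i > 0)
  p_i <- n_i / np
  ngp <- length(present)
  ii <- present
  pp <- p_i[present]
  ss <- s_i[present]
  coarse_den <- sum(pp * ss)
  busy_den <- sum(abs(outer(ii * pp, ii * pp, "-")))
  strength_num <- sum(outer(pp, pp, "+") * outer(ii, ii, "-")^2)
  contrast <- if (ngp > 1) {
    sum(outer(pp, pp) * outer(ii, ii, "-")^2) / (ngp * (ngp - 1)) *
      sum(ss) / np
  } else 0
  cplx <- if (ngp > 0) {
    num <- outer(pp * ss, pp * ss, "+")
    den <- outer(pp, pp, "+")
    sum(abs(outer(ii, ii, "-")) * num / den) / np
  } else 0
  c(Coarseness = if (coarse_den > 0) 1 / coarse_den else 1e6,
    Contrast = contrast,
    Busyness = if (busy_den > 0) coarse_den / busy_den else 0,
    Complexity = cplx,
    Strength = if (sum(ss) > 0) strength_num / sum(ss) else 0)
}
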