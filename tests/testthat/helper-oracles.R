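# Shared fixtures and independent oracles for the test suite.

# small random dose plane (values >= 0)
random_plane <- function(n = 15, spacing = 1.75, seed = 1, base = 10) {
  with_seed(seed, {
    m <- matrix(base * runif(n * n), n, n)
    dose_plane(m, spacing)
  })
}

# a smooth nonconstant preprocessed plane for SSIM tests
smooth_plane <- function(seed = 1, noise = 0) {
  gen <- generate_plan(seed = seed)
  preprocess_plane(extract_plane(gen$volume,
                                 detector_spec(noise_sd_frac = noise),
                                 seed = seed))
}

# brute-force SSIM oracle: loops windows, computes stats directly and
# multiplies the l/c/s components (independent of the box-filter path)
ssim_oracle <- function(x, y, K1 = 0.01, K2 = 0.03, L = NULL, w = 7) {
  if (is.null(L)) L <- max(max(x), max(y))
  pars <- ssim_params(K1, K2, L, window = w)
  nr <- nrow(x) - w + 1
  nc <- ncol(x) - w + 1
  vals <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      wx <- as.vector(x[i:(i + w - 1), j:(j + w - 1)])
      wy <- as.vector(y[i:(i + w - 1), j:(j + w - 1)])
      n <- length(wx)
      st <- list(mu_x = mean(wx), mu_y = mean(wy),
                 var_x = sum((wx - mean(wx))^2) / n,
                 var_y = sum((wy - mean(wy))^2) / n,
                 cov_xy = sum((wx - mean(wx)) * (wy - mean(wy))) / n)
      comp <- ssim_components(st, pars)
      vals[i, j] <- comp$l * comp$c * comp$s
    }
  }
  list(value = mean(vals), map = vals)
}

# exhaustive gamma oracle: for every scored reference point, scans ALL
# upsampled evaluation positions inside the search radius (no early exit)
gamma_oracle <- function(ref, eval_plane, criteria) {
  up <- criteria$upsample_factor
  n <- nrow(ref$matrix)
  fine <- if (up > 1) {
    resample_to_grid(eval_plane, (n - 1) * up + 1)$matrix
  } else {
    eval_plane$matrix
  }
  sp_ref <- ref$spacing_mm
  sp_fine <- sp_ref * (n - 1) / (nrow(fine) - 1)
  radius <- criteria$search_radius_factor * criteria$dta_mm
  dd_frac <- criteria$dd_percent / 100
  out <- matrix(NA_real_, n, n)
  fi <- (seq_len(nrow(fine)) - 1) * sp_fine
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      dref <- ref$matrix[i, j]
      if (dref <= 0) next
      denom <- if (criteria$normalization == "global_reference_max") {
        dd_frac * ref$max_dose
      } else {
        dd_frac * max(dref, 1e-12)
      }
      ri <- (i - 1) * sp_ref
      rj <- (j - 1) * sp_ref
      di <- abs(fi - ri)
      dj <- abs(fi - rj)
      ii <- which(di <= radius)
      jj <- which(dj <= radius)
      d2 <- outer(di[ii]^2, dj[jj]^2, "+")
      keep <- d2 <= radius^2
      dd <- (fine[ii, jj, drop = FALSE] - dref) / denom
      g2 <- d2 / criteria$dta_mm^2 + dd * dd
      out[i, j] <- sqrt(min(g2[keep]))
    }
  }
  out
}

# tiny aligned volume/mask pair built by hand
toy_volume <- function(doses, spacing = 1) {
  dose_volume(array(doses, dim = c(length(doses), 1, 1)), spacing)
}
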