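test_that("fixed-bin-width discretization follows the binning rule", {
  v <- array(c(0, 24.9, 25, 50), dim = c(4, 1, 1))
  expect_identical(as.vector(discretize(v, bin_width = 25)),
                   c(1L, 1L, 2L, 3L))
  expect_true(all(discretize(array(7.3, dim = c(3, 3, 3)),
                             bin_width = 25) == 1L))
})

test_that("level count equals floor(range / width) + 1 on random volumes", {
  for (s in 1:10) {
    v <- with_seed(s, array(runif(60, 0, 40), dim = c(5, 4, 3)))
    for (w in c(1, 2.5, 10)) {
      lev <- discretize(v, bin_width = w)
      # brute force over every voxel
      expect_equal(max(lev), max(floor((v - min(v)) / w) + 1))
    }
  }
})

test_that("first-order features handle degenerate and tiny distributions", {
  const <- first_order_features(array(7, dim = c(3, 3, 3)),
                                config = extraction_config(bin_width = 25))
  expect_length(const, 18)
  expect_true(all(startsWith(names(const), "original_firstorder_")))
  expect_equal(unname(const["original_firstorder_Mean"]), 7)
  expect_equal(unname(const["original_firstorder_Median"]), 7)
  expect_equal(unname(const["original_firstorder_Minimum"]), 7)
  expect_equal(unname(const["original_firstorder_Maximum"]), 7)
  expect_equal(unname(const["original_firstorder_Variance"]), 0)
  expect_equal(unname(const["original_firstorder_Entropy"]), 0)
  expect_equal(unname(const["original_firstorder_Uniformity"]), 1)

  two <- array(0, dim = c(2, 1, 1))
  two[] <- c(2, 4)
  fo <- first_order_features(two, config = extraction_config(bin_width = 1))
  expect_equal(unname(fo["original_firstorder_Mean"]), 3)
  expect_equal(unname(fo["original_firstorder_Range"]), 2)
  expect_equal(unname(fo["original_firstorder_Variance"]), 1)  # population
  expect_equal(unname(fo["original_firstorder_Energy"]), 20)
  expect_equal(unname(fo["original_firstorder_RootMeanSquared"]), sqrt(10))
})

test_that("shape features recover the geometry of a digitized ball", {
  r <- 10
  n <- 27
  cc <- (n + 1) / 2
  idx <- expand.grid(1:n, 1:n, 1:n)
  ball <- array((idx[, 1] - cc)^2 + (idx[, 2] - cc)^2 + (idx[, 3] - cc)^2 <=
                  r^2, dim = c(n, n, n))
  sf <- shape_features(ball, spacing = 1)
  expect_length(sf, 14)
  expect_equal(unname(sf["original_shape_Sphericity"]), 1, tolerance = 0.02)
  expect_equal(unname(sf["original_shape_Elongation"]), 1, tolerance = 0.05)
  expect_equal(unname(sf["original_shape_Flatness"]), 1, tolerance = 0.05)
  expect_equal(unname(sf["original_shape_MeshVolume"]), 4 / 3 * pi * r^3,
               tolerance = 0.05 * 4 / 3 * pi * r^3)
  expect_equal(unname(sf["original_shape_Maximum3DDiameter"]), 2 * r,
               tolerance = 0.1 * 2 * r)
})

test_that("texture categories emit their standard feature counts", {
  lev <- discretize(with_seed(4, array(runif(5^3, 0, 30), dim = c(5, 5, 5))),
                    bin_width = 5)
  counts <- c(glcm = 24, glrlm = 16, glszm = 16, gldm = 14, ngtdm = 5)
  for (cat in names(counts)) {
    f <- texture_features(lev, cat)
    expect_length(f, counts[[cat]])
    expect_true(all(is.finite(f)))
    expect_true(all(startsWith(names(f), paste0("original_", cat))))
  }
})

test_that("a constant field gives trivial texture", {
  lev <- array(1L, dim = c(4, 4, 4))
  glcm <- texture_features(lev, "glcm")
  expect_equal(unname(glcm["original_glcm_MaximumProbability"]), 1)
  expect_equal(unname(glcm["original_glcm_JointEntropy"]), 0)
  szm <- texture_features(lev, "glszm")
  # a single zone spans the whole mask
  expect_equal(unname(szm["original_glszm_ZonePercentage"]), 1 / 64)
  expect_error(texture_features(array(c(1L, rep(0L, 7)), dim = c(2, 2, 2)),
                                "glcm"),
               class = "rotqa_degenerate_texture")
})

test_that("co-occurrence counts match hand enumeration on a 2x2x1 toy", {
  lev <- array(c(1L, 2L, 2L, 1L), dim = c(2, 2, 1))  # [[1,2],[2,1]] by row
  counts <- array(rotqa:::glcm_counts_cpp(as.vector(lev), dim(lev), 2L),
                  c(2, 2, 13))
  C <- counts[, , 1]          # direction (1, 0, 0)
  C <- C + t(C)
  expect_equal(C, matrix(c(0, 2, 2, 0), 2, 2))
  p <- C / sum(C)
  i <- matrix(1:2, 2, 2)
  expect_equal(sum((i - t(i))^2 * p), 1)  # GLCM contrast for this direction
})

test_that("wavelet decomposition yields 8 bands with exact energy split", {
  v <- with_seed(6, array(runif(16^3), dim = c(16, 16, 16)))
  bands <- wavelet_bands(v)
  expect_length(bands, 8)
  expect_identical(names(bands)[1], "LLL")
  expect_true(all(vapply(bands, function(b) all(dim(b) == 16), TRUE)))
  # Parseval: orthogonal subband projections partition the energy
  e <- sum(vapply(bands, function(b) sum(b^2), 0))
  expect_equal(e, sum(v^2), tolerance = 1e-8 * sum(v^2))
  # bands sum back to the input (projections onto complementary subspaces)
  expect_lt(max(abs(Reduce(`+`, bands) - v)), 1e-10)

  const <- wavelet_bands(array(3, dim = c(8, 8, 8)))
  for (nm in setdiff(names(const), "LLL")) {
    expect_lt(max(abs(const[[nm]])), 1e-10)
  }
  expect_equal(mean(const$LLL), 3, tolerance = 1e-10)
  expect_error(wavelet_bands(array(1, dim = c(4, 8, 8))),
               class = "rotqa_invalid_input")
})

test_that("the radiomic and dosiomic censuses match the feature contract", {
  gen <- generate_plan(plan_spec(grid_n = 16, spacing_mm = 4), seed = 2)
  cfgR <- extraction_config(resample_spacing_mm = NULL, bin_width = 25)
  cfgD <- extraction_config(resample_spacing_mm = NULL, bin_width = 1)
  rad <- extract_radiomics(gen$volume, gen$mask, cfgR)
  expect_length(rad, 32)
  expect_false(anyDuplicated(names(rad)) > 0)
  expect_true(all(grepl("^original_(firstorder|shape)_", names(rad))))
  rad2 <- extract_radiomics(gen$volume, gen$mask, cfgR)
  expect_identical(rad, rad2)

  dos <- extract_dosiomics(gen$volume, config = cfgD)
  expect_length(dos, 837)
  expect_false(anyDuplicated(names(dos)) > 0)
  expect_length(grep("^wavelet-", names(dos)), 744)
  expect_length(grep("^original_firstorder_", names(dos)), 18)

  cfg_nw <- cfgD
  cfg_nw$enabled_categories <- setdiff(cfg_nw$enabled_categories, "wavelet")
  expect_length(extract_dosiomics(gen$volume, config = cfg_nw), 93)
})

test_that("all features are finite on random valid inputs", {
  cfg <- extraction_config(resample_spacing_mm = NULL, bin_width = 1)
  for (s in 1:20) {
    v <- with_seed(s, {
      dose_volume(array(runif(12^3, 0, 50) *
                          rbinom(12^3, 1, 0.8), dim = c(12, 12, 12)),
                  spacing = 2)
    })
    f <- extract_dosiomics(v, config = cfg)
    expect_true(all(is.finite(f)))
  }
})
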