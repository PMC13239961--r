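test_that("resampling standardizes planes to 45 x 45 and reproduces bilinear fields", {
  pl <- random_plane(n = 30, spacing = 2, seed = 2)
  out <- resample_to_grid(pl)
  expect_equal(dim(out$matrix), c(45, 45))
  # physical extent preserved
  expect_equal(out$spacing_mm * 44, 29 * 2)

  # constant plane: interpolation of a constant
  const <- dose_plane(matrix(5, 10, 10), 1)
  expect_true(all(resample_to_grid(const, 17)$matrix == 5))

  # a bilinear ramp is reproduced exactly at the new nodes
  i <- matrix(seq_len(10), 10, 10)
  j <- t(i)
  ramp <- dose_plane(2 + 0.5 * i + 0.25 * j + 0.05 * i * j, 1.5)
  out <- resample_to_grid(ramp, 23)
  ri <- seq(1, 10, length.out = 23)  # original node coordinates
  expected <- outer(ri, ri, function(a, b) 2 + 0.5 * a + 0.25 * b +
                      0.05 * a * b)
  expect_lt(max(abs(out$matrix - expected)), 1e-9)
})

test_that("resampling validates its inputs", {
  expect_error(resample_to_grid(dose_plane(matrix(1, 5, 5), 1), n = 1),
               class = "rotqa_invalid_spec")
  bad <- dose_plane(matrix(1, 5, 5), 1)
  bad$matrix[2, 2] <- NaN
  expect_error(resample_to_grid(bad), class = "rotqa_invalid_input")
})

test_that("thresholding zeroes strictly-below entries and keeps ties", {
  m <- matrix(c(10, 7, 6.999, 0.5, 8, 3), 2, 3)
  out <- threshold_low_dose(dose_plane(m, 1), 0.70)
  expect_equal(out$matrix[1, 1], 10)
  expect_equal(out$matrix[2, 1], 7)    # tie at the threshold is kept
  expect_equal(out$matrix[1, 2], 0)    # 6.999 strictly below
  expect_equal(out$matrix[2, 2], 0)
  expect_equal(out$matrix[1, 3], 8)
  expect_equal(out$max_dose, 10)       # maximum unchanged

  pl <- random_plane(n = 12, seed = 3)
  expect_identical(threshold_low_dose(pl, 0)$matrix, pl$matrix)
  expect_error(threshold_low_dose(dose_plane(matrix(0, 4, 4), 1)),
               class = "rotqa_degenerate_plane")
})

test_that("surviving-entry count matches an exhaustive scan", {
  pl <- resample_to_grid(random_plane(n = 45, seed = 8))
  out <- threshold_low_dose(pl, 0.70)
  expect_equal(sum(out$matrix > 0), sum(pl$matrix >= 0.7 * pl$max_dose))
})

test_that("normalization modes behave as documented", {
  pl <- random_plane(n = 10, seed = 4, base = 20)
  rel <- normalize_plane(pl, "relative")
  expect_equal(max(rel$matrix), 1)
  expect_equal(rel$mode, "relative_fraction")
  expect_identical(normalize_plane(pl, "absolute")$matrix, pl$matrix)

  # pair-shared reference max: a plane scaled by 1.03 normalizes to 1.03
  scaled <- dose_plane(pl$matrix * 1.03, pl$spacing_mm)
  both <- normalize_plane(scaled, "relative", reference_max = pl$max_dose)
  expect_equal(max(both$matrix), 1.03)
  expect_error(normalize_plane(pl, "relative", reference_max = 0),
               class = "rotqa_invalid_spec")
})

test_that("the standard pipeline is idempotent and order-configurable", {
  pl <- random_plane(n = 30, seed = 5)
  once <- preprocess_plane(pl)
  twice <- preprocess_plane(once)
  expect_equal(dim(once$matrix), c(45, 45))
  expect_true(all(once$matrix[once$matrix > 0] >= 0.7 * max(once$matrix)))
  expect_equal(twice$matrix, once$matrix, tolerance = 1e-12)

  early <- preprocess_plane(pl, threshold_first = TRUE)
  expect_equal(dim(early$matrix), c(45, 45))
  expect_false(identical(early$matrix, once$matrix))
})

test_that("thresholding never increases entries and resampling keeps planes nonnegative", {
  for (s in 1:5) {
    pl <- random_plane(n = 17, seed = s)
    th <- threshold_low_dose(pl, 0.7)
    expect_true(all(th$matrix <= pl$matrix))
    rs <- resample_to_grid(pl, 31)
    expect_true(all(rs$matrix >= 0))
  }
})
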