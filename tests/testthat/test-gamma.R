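crit_fast <- function(dd = 2, dta = 2) {
  gamma_criteria(dd, dta, upsample_factor = 5)
}

test_that("self-comparison gives zero gamma at every scored point", {
  pl <- preprocess_plane(random_plane(n = 15, seed = 1), n = 15,
                         mode = "absolute")
  g <- gamma_map(pl, pl, crit_fast())
  expect_true(all(g[!is.na(g)] == 0))
  expect_equal(gamma_pass_rate(g), 100)
  expect_true(all(is.na(g[pl$matrix == 0])))
})

test_that("a uniform 1% scaling passes everywhere under 2%/2mm global normalization", {
  pl <- preprocess_plane(random_plane(n = 15, seed = 2), n = 15,
                         mode = "absolute")
  up <- dose_plane(pl$matrix * 1.01, pl$spacing_mm)
  g <- gamma_map(pl, up, crit_fast())
  # the zero-shift candidate already has dose term <= (1% / 2%)^2
  expect_true(all(g[!is.na(g)] < 1))
  expect_equal(gamma_pass_rate(g), 100)
})

test_that("gamma equals the exhaustive brute-force search on random pairs", {
  for (s in 1:6) {
    ref <- preprocess_plane(random_plane(n = 15, seed = s), n = 15,
                            mode = "absolute")
    ev <- with_seed(1000 + s, {
      dose_plane(pmax(ref$matrix + matrix(rnorm(225, sd = 0.4), 15, 15), 0),
                 ref$spacing_mm)
    })
    for (norm in c("global_reference_max", "local")) {
      cr <- gamma_criteria(2, 2, normalization = norm, upsample_factor = 5)
      g <- gamma_map(ref, ev, cr)
      expect_equal(g, gamma_oracle(ref, ev, cr), tolerance = 1e-9)
    }
  }
})

test_that("pass rates are monotone in the criteria", {
  for (s in 1:5) {
    ref <- preprocess_plane(random_plane(n = 15, seed = s + 50), n = 15,
                            mode = "absolute")
    ev <- dose_plane(pmax(ref$matrix * (1 + 0.05 * sin(s + row(ref$matrix))),
                          0), ref$spacing_mm)
    rates <- vapply(list(c(1, 1), c(1.5, 1.5), c(2, 2)), function(cd) {
      cr <- crit_fast(cd[1], cd[2])
      gamma_pass_rate(gamma_map(ref, ev, cr), cr)
    }, 0)
    expect_true(all(diff(rates) >= 0))
  }
})

test_that("gamma pass rate counts correctly", {
  g <- matrix(NA_real_, 2, 2)
  g[1, 1] <- 0.2; g[1, 2] <- 0.9; g[2, 1] <- 1.0; g[2, 2] <- 1.4
  expect_equal(gamma_pass_rate(g), 75)
  expect_error(gamma_pass_rate(matrix(NA_real_, 2, 2)),
               class = "rotqa_degenerate_plane")
})

test_that("dose-difference pass rate matches an exhaustive scan and is dominated by gamma", {
  ref <- preprocess_plane(random_plane(n = 15, seed = 9), n = 15,
                          mode = "absolute")
  expect_equal(dose_difference_pass_rate(ref, ref), 100)

  # uniform +3% offset under a 2% global criterion
  up <- dose_plane(ref$matrix * 1.03, ref$spacing_mm)
  got <- dose_difference_pass_rate(ref, up, 2)
  scored <- ref$matrix > 0
  manual <- 100 * mean(abs(up$matrix[scored] - ref$matrix[scored]) <=
                         0.02 * ref$max_dose)
  expect_equal(got, manual)
  expect_true(all(ref$matrix[scored][0.03 * ref$matrix[scored] >
                                       0.02 * ref$max_dose] >
                    (2 / 3) * ref$max_dose))

  # gamma adds a passing mechanism on top of DD
  for (s in 1:4) {
    ev <- with_seed(2000 + s, {
      dose_plane(pmax(ref$matrix + matrix(rnorm(225, sd = 0.3), 15, 15), 0),
                 ref$spacing_mm)
    })
    dd <- dose_difference_pass_rate(ref, ev, 2)
    cr <- crit_fast(2, 2)
    gm <- gamma_pass_rate(gamma_map(ref, ev, cr), cr)
    expect_gte(gm, dd)
  }
})

test_that("mismatched planes are rejected", {
  a <- random_plane(n = 15)
  b <- random_plane(n = 16)
  expect_error(gamma_map(a, b), class = "rotqa_shape_mismatch")
  d <- dose_plane(a$matrix, a$spacing_mm * 2)
  expect_error(gamma_map(a, d), class = "rotqa_shape_mismatch")
  expect_error(dose_difference_pass_rate(a, b),
               class = "rotqa_shape_mismatch")
})
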