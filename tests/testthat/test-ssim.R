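test_that("SSIM of a plane with itself is exactly 1", {
  pl <- smooth_plane(seed = 3)
  expect_false(sd(pl$matrix) == 0)
  res <- ssim(pl, pl)
  expect_identical(res$value, 1)
  expect_true(all(res$map == 1))
})

test_that("constant planes reproduce the global closed form", {
  a <- dose_plane(matrix(0.5, 9, 9), 1)
  b <- dose_plane(matrix(0.25, 9, 9), 1)
  pars <- ssim_params(L = 1, window = 0)
  # zero variances and covariance: combined form collapses to
  # (2 mu_x mu_y + C1) C2 / ((mu_x^2 + mu_y^2 + C1) C2)
  C1 <- (0.01 * 1)^2
  expected <- (2 * 0.5 * 0.25 + C1) / (0.5^2 + 0.25^2 + C1)
  expect_equal(ssim(a, b, pars)$value, expected, tolerance = 1e-10)
})

test_that("component product equals the combined closed form on random window stats", {
  pars <- ssim_params(L = 1)
  cc <- list(C1 = (0.01)^2, C2 = (0.03)^2)
  with_seed(42, {
    for (k in 1:1000) {
      sx <- runif(1, 0, 0.5)
      sy <- runif(1, 0, 0.5)
      rho <- runif(1, -1, 1)
      st <- list(mu_x = runif(1), mu_y = runif(1),
                 var_x = sx^2, var_y = sy^2, cov_xy = rho * sx * sy)
      comp <- ssim_components(st, pars)
      combined <- ((2 * st$mu_x * st$mu_y + cc$C1) *
                     (2 * st$cov_xy + cc$C2)) /
        ((st$mu_x^2 + st$mu_y^2 + cc$C1) * (st$var_x + st$var_y + cc$C2))
      expect_equal(comp$l * comp$c * comp$s, combined, tolerance = 1e-12)
    }
  })
})

test_that("windowed SSIM matches the per-window component oracle", {
  x <- smooth_plane(seed = 5)
  y <- smooth_plane(seed = 5, noise = 0.01)
  res <- ssim(x, y)
  orc <- ssim_oracle(x$matrix, y$matrix)
  expect_equal(res$value, orc$value, tolerance = 1e-10)
  expect_equal(res$map, orc$map, tolerance = 1e-10)
})

test_that("SSIM is symmetric and bounded", {
  for (s in 1:5) {
    a <- random_plane(n = 20, seed = s)
    b <- random_plane(n = 20, seed = s + 100)
    ab <- ssim(a, b)$value
    ba <- ssim(b, a)$value
    expect_equal(ab, ba, tolerance = 1e-12)
    expect_lte(abs(ab), 1)
  }
})

test_that("perfect anti-structure drives the structure component negative", {
  pars <- ssim_params(L = 1)
  st <- list(mu_x = 0.5, mu_y = 0.5, var_x = 0.2, var_y = 0.2,
             cov_xy = -0.2)  # cov = -sd_x sd_y
  comp <- ssim_components(st, pars)
  expect_lt(comp$s, 0)
  expect_lt(comp$l * comp$c * comp$s, 0)
})

test_that("identical window statistics give unit components", {
  comp <- ssim_components(list(mu_x = 0.3, mu_y = 0.3, var_x = 0.04,
                               var_y = 0.04, cov_xy = 0.04),
                          ssim_params(L = 1))
  expect_equal(comp$l, 1)
  expect_equal(comp$c, 1)
  expect_equal(comp$s, 1)
})

test_that("shape and window validation errors are raised", {
  a <- random_plane(n = 10)
  b <- random_plane(n = 12)
  expect_error(ssim(a, b), class = "rotqa_shape_mismatch")
  expect_error(ssim(a, a, ssim_params(window = 11)),
               class = "rotqa_invalid_spec")
  expect_error(ssim_params(window = 4), class = "rotqa_invalid_spec")
})
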