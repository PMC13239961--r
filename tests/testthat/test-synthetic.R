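test_that("plan generation is deterministic under a fixed seed", {
  a <- generate_plan(seed = 7)
  b <- generate_plan(seed = 7)
  expect_identical(a$volume$grid, b$volume$grid)
  expect_identical(a$mask$grid, b$mask$grid)
  c <- generate_plan(seed = 8)
  expect_false(identical(a$volume$grid, c$volume$grid))
})

test_that("a centered symmetric lobe is invariant under axis permutations", {
  spec <- plan_spec(grid_n = 33, ripple_amp = NULL, isocenter_z_mm = 0)
  gen <- generate_plan(spec, seed = 1,
                       lobes = list(list(center = c(0, 0, 0),
                                         sigma = c(6, 6, 6), amp = 1)),
                       peak_gy = 60)
  g <- gen$volume$grid
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(1, 3, 2))) {
    expect_lt(max(abs(g - aperm(g, perm))), 1e-9)
  }
})

test_that("the target mask is exactly the prescription isodose set", {
  spec <- plan_spec(prescription_fraction = 0.8)
  gen <- generate_plan(spec, seed = 3, peak_gy = 60)
  expect_equal(gen$volume$prescription_dose, 48)
  # exhaustive voxel scan against the stated rule
  expect_identical(gen$mask$grid, gen$volume$grid >= 48)
  expect_equal(max(gen$volume$grid), 60, tolerance = 1e-12)
})

test_that("degenerate plan specifications are rejected", {
  expect_error(plan_spec(grid_n = 1), class = "rotqa_invalid_spec")
  expect_error(plan_spec(sigma_range_mm = c(0, 5)),
               class = "rotqa_invalid_spec")
  expect_error(generate_plan(plan_spec(), seed = 1,
                             lobes = list(list(center = c(999, 0, 0),
                                               sigma = c(5, 5, 5), amp = 1))),
               class = "rotqa_invalid_spec")
})

test_that("zero rotation returns the input volume exactly", {
  gen <- generate_plan(seed = 2)
  out <- apply_rigid_rotation(gen$volume, rotation_error(0, 0, 0))
  expect_identical(out$grid, gen$volume$grid)
})

test_that("a spherical lobe at the rotation center is rotation invariant", {
  spec <- plan_spec(grid_n = 33, ripple_amp = NULL, isocenter_z_mm = 0)
  gen <- generate_plan(spec, seed = 1,
                       lobes = list(list(center = c(0, 0, 0),
                                         sigma = c(8, 8, 8), amp = 1)),
                       peak_gy = 50)
  rot <- rotation_error(pitch_deg = 4, roll_deg = -3, yaw_deg = 2)
  out <- apply_rigid_rotation(gen$volume, rot, center = c(0, 0, 0))
  # the field is exactly rotation invariant; the residual is trilinear
  # resampling error, which scales as spacing^2 / (8 sigma^2) ~ 1e-2 here
  expect_lt(max(abs(out$grid - gen$volume$grid)) / max(gen$volume$grid),
            2e-2)
})

test_that("yaw forward then backward recovers the field within the empirical interpolation bound", {
  spec <- plan_spec(grid_n = 33, ripple_amp = NULL, isocenter_z_mm = 0)
  lobes <- list(list(center = c(10, 6, 0), sigma = c(6, 9, 7), amp = 1))
  gen <- generate_plan(spec, seed = 1, lobes = lobes, peak_gy = 60)
  vol <- gen$volume
  theta <- 3
  fwd <- apply_rigid_rotation(vol, rotation_error(yaw_deg = theta),
                              center = c(0, 0, 0))
  back <- apply_rigid_rotation(fwd, rotation_error(yaw_deg = -theta),
                               center = c(0, 0, 0))
  # empirical single-rotation interpolation error against the analytic
  # closed form of the rotated Gaussian
  ang <- -(-theta) * pi / 180  # CW yaw is a negative rotation about +z
  Rz <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1),
               3, 3)
  dims <- dim(vol$grid)
  ax <- lapply(1:3, function(a) vol$origin[a] + (seq_len(dims[a]) - 1) *
                 vol$spacing[a])
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  src <- pts %*% Rz
  d <- sweep(src, 2, lobes[[1]]$center)
  analytic <- exp(-0.5 * ((d[, 1] / 6)^2 + (d[, 2] / 9)^2 + (d[, 3] / 7)^2))
  analytic <- analytic * max(vol$grid) / max(analytic)
  err1 <- max(abs(fwd$grid - array(analytic, dims)))
  expect_lt(max(abs(back$grid - vol$grid)), 2 * err1)
})

test_that("rotations beyond the allowed bound are rejected", {
  expect_error(rotation_error(pitch_deg = 11),
               class = "rotqa_invalid_rotation")
  gen <- generate_plan(seed = 1)
  expect_error(apply_rigid_rotation(gen$volume, rotation_error(1),
                                    center = c(999, 0, 0)),
               class = "rotqa_invalid_rotation")
})

test_that("direction labels follow the nonzero angles", {
  expect_identical(rotation_error(1, 0, 2)$direction_labels, c("UP", "CW"))
  expect_identical(rotation_error()$direction_labels, character(0))
})

test_that("plane extraction samples constant fields exactly and reports the detector pitch", {
  vol <- dose_volume(array(10, dim = c(40, 40, 40)), spacing = 2.75)
  spec <- detector_spec(plane_offset_mm = 0, noise_sd_frac = 0)
  pl <- extract_plane(vol, spec)
  expect_true(all(pl$matrix == 10))
  expect_equal(dim(pl$matrix), c(45, 45))
  expect_equal(pl$spacing_mm, 77 / 44)
})

test_that("plane extraction is deterministic and bounds-checked", {
  gen <- generate_plan(seed = 4)
  spec <- detector_spec(noise_sd_frac = 0.02)
  a <- extract_plane(gen$volume, spec, seed = 9)
  b <- extract_plane(gen$volume, spec, seed = 9)
  expect_identical(a$matrix, b$matrix)
  expect_error(extract_plane(gen$volume, detector_spec(plane_offset_mm = 500)),
               class = "rotqa_out_of_bounds")
})

test_that("stage-1 cohorts contain one record per angle-direction pair", {
  proto <- cohort_protocol(n_plans = 3, stage2_angle_range_deg = NULL,
                           seed = 5)
  coh <- simulate_cohort(proto, keep_volumes = FALSE)
  expect_length(coh$records, 45)  # 3 plans x 5 magnitudes x 3 directions
  refs <- unique(lapply(coh$records, function(r) r$reference_plane$matrix))
  expect_length(refs, 3)
  expect_true(all(vapply(coh$records, `[[`, 1L, "stage") == 1L))
})

test_that("stage-2-only cohorts emit one multi-axis record per plan", {
  proto <- cohort_protocol(n_plans = 4, stage1_angles_deg = numeric(0),
                           seed = 6)
  coh <- simulate_cohort(proto, keep_volumes = FALSE)
  expect_length(coh$records, 4)
  nd <- vapply(coh$records, function(r) length(r$rotation$direction_labels),
               1L)
  expect_true(all(nd %in% 2:3))
  ang <- unlist(lapply(coh$records, function(r) {
    rot <- r$rotation
    a <- c(rot$pitch_deg, rot$roll_deg, rot$yaw_deg)
    a[a != 0]
  }))
  expect_true(all(ang >= 1.5 & ang <= 4.5))
})

test_that("the default stage-1 magnitudes span 1.5 to 4.5 degrees", {
  proto <- cohort_protocol()
  expect_equal(range(proto$stage1_angles_deg), c(1.5, 4.5))
})

test_that("all records of a plan share the same reference plane", {
  coh <- simulate_cohort(cohort_protocol(n_plans = 2, seed = 11),
                         keep_volumes = FALSE)
  by_plan <- split(coh$records, vapply(coh$records, `[[`, "", "plan_id"))
  for (recs in by_plan) {
    ref <- recs[[1]]$reference_plane$matrix
    for (r in recs) expect_identical(r$reference_plane$matrix, ref)
  }
})

test_that("a noise-free zero-rotation measurement reproduces the reference exactly", {
  proto <- cohort_protocol(n_plans = 1, stage1_angles_deg = 0,
                           stage1_directions = "UP",
                           stage2_angle_range_deg = NULL,
                           detector = detector_spec(noise_sd_frac = 0),
                           seed = 2)
  coh <- simulate_cohort(proto, keep_volumes = FALSE)
  rec <- coh$records[[1]]
  ref <- preprocess_plane(rec$reference_plane)
  pert <- preprocess_plane(rec$perturbed_plane)
  expect_identical(ssim(ref, pert)$value, 1)
})

test_that("mean SSIM decreases monotonically with angle on noise-free single-lobe plans", {
  angles <- c(1.5, 2.25, 3.0, 3.75, 4.5)
  det <- detector_spec(plane_offset_mm = 0, noise_sd_frac = 0)
  spec <- plan_spec(grid_n = 33, ripple_amp = NULL, isocenter_z_mm = 0)
  curves <- sapply(1:20, function(s) {
    off <- with_seed(s, runif(2, 8, 16))
    gen <- generate_plan(spec, seed = s,
                         lobes = list(list(center = c(off, 2),
                                           sigma = c(5, 7, 6), amp = 1)),
                         peak_gy = 60)
    ref <- preprocess_plane(extract_plane(gen$volume, det))
    vapply(angles, function(a) {
      rot <- apply_rigid_rotation(gen$volume, rotation_error(yaw_deg = a))
      ssim(ref, preprocess_plane(extract_plane(rot, det)))$value
    }, 0)
  })
  mean_curve <- rowMeans(curves)
  expect_true(all(diff(mean_curve) <= 0))
})
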