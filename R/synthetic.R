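#' Synthetic SBRT plan specification
#'
#' Parameters of the multi-lobe Gaussian dose model used to emulate
#' steep-gradient SBRT dose fields. Lobes are mildly anisotropic Gaussians
#' arranged on a ring around the isocenter projection, modulated by a
#' crossfire ripple; plan-to-plan variation comes from the drawn lobe
#' sizes, amplitudes, off-plane offsets and ripple parameters.
#'
#' @param grid_n voxels per axis (length 1 or 3).
#' @param spacing_mm voxel size in mm.
#' @param n_lobes number of Gaussian lobes (>= 1; default 3).
#' @param sigma_range_mm per-axis Gaussian sigma range in mm.
#' @param peak_range_gy peak dose range in Gy.
#' @param offset_range_mm in-plane (x-y) radius range of the lobe centers
#'   from the isocenter (mm). The detector plane passes through the
#'   target region, so lobes sit near the plane but off the rotation
#'   axes - the geometry that gives rotations their lever arm. Lobes are
#'   spread evenly in azimuth (with jitter) so every plan has lever arms
#'   about both in-plane axes.
#' @param z_offset_mm maximum |z| offset of lobe centers from the
#'   detector plane (mm); each lobe sits off-plane by 2/3 to 1 of this,
#'   giving every plan through-plane structure that still survives the
#'   70% low-dose threshold.
#' @param satellite_amp relative amplitude range of the non-primary
#'   lobes.
#' @param sigma_scale_range plan-level multiplier range applied to every
#'   lobe sigma: plans differ in overall gradient steepness (small, steep
#'   targets vs larger, softer ones), the main geometry-independent
#'   driver of rotational sensitivity.
#' @param ripple_amp relative amplitude range of the multiplicative
#'   crossfire ripple (in-target dose heterogeneity from beam
#'   interference); 0 disables it.
#' @param ripple_wavelength_mm wavelength range of the ripple (mm); the
#'   wavevector is drawn obliquely with a substantial through-plane
#'   component.
#' @param isocenter_z_mm z position of the plan isocenter relative to the
#'   dose-cluster plane (mm). The rotation axis passes through the
#'   isocenter, which in phantom QA geometry need not lie in the
#'   measurement plane; the offset gives out-of-plane rotations a uniform
#'   in-plane lever arm, matching the strong measured pitch/roll response.
#' @param prescription_fraction prescription dose as a fraction of peak.
#' @return a list of class `plan_spec`.
#' @export
plan_spec <- function(grid_n = 32, spacing_mm = 2.75, n_lobes = 3,
                      sigma_range_mm = c(4, 10), peak_range_gy = c(40, 70),
                      offset_range_mm = c(19, 21), z_offset_mm = 5.5,
                      satellite_amp = c(0.9, 1.0),
                      sigma_scale_range = c(0.8, 1.3),
                      ripple_amp = c(0.02, 0.35),
                      ripple_wavelength_mm = c(12, 18),
                      isocenter_z_mm = -15,
                      prescription_fraction = 0.7) {
  grid_n <- rep(as.integer(grid_n), length.out = 3)
  if (any(grid_n < 2)) stop_rotqa("grid must have >= 2 voxels per axis",
                                  "rotqa_invalid_spec")
  check_number(spacing_mm, "spacing_mm", 0, strict = TRUE)
  if (!is.null(n_lobes) && n_lobes < 1) {
    stop_rotqa("lobe count must be >= 1", "rotqa_invalid_spec")
  }
  if (any(sigma_range_mm <= 0)) stop_rotqa("lobe sigma must be > 0",
                                           "rotqa_invalid_spec")
  if (any(peak_range_gy <= 0)) stop_rotqa("peak dose must be > 0",
                                          "rotqa_invalid_spec")
  check_number(prescription_fraction, "prescription_fraction", 0,
               strict = TRUE)
  structure(list(grid_n = grid_n, spacing_mm = as.double(spacing_mm),
                 n_lobes = n_lobes, sigma_range_mm = sigma_range_mm,
                 peak_range_gy = peak_range_gy,
                 offset_range_mm = offset_range_mm,
                 z_offset_mm = z_offset_mm,
                 satellite_amp = satellite_amp,
                 sigma_scale_range = sigma_scale_range,
                 ripple_amp = ripple_amp,
                 ripple_wavelength_mm = ripple_wavelength_mm,
                 isocenter_z_mm = isocenter_z_mm,
                 prescription_fraction = prescription_fraction),
            class = "plan_spec")
}

# random unit vector in 3D
runit3 <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# uniform-ish random 3D rotation (QR of a Gaussian matrix, det +1)
random_orientation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_d)
  Q * sign(det(Q))
}

draw_z <- function(spec) {
  sample(c(-1, 1), 1) * runif(1, 2 * spec$z_offset_mm / 3,
                              spec$z_offset_mm)
}

# mildly anisotropic per-lobe sigmas: a common base size with per-axis
# jitter, so the plan-level sigma scale (not lobe orientation) dominates
# gradient steepness
draw_sigma <- function(spec) {
  base <- runif(1, spec$sigma_range_mm[1] + 1, spec$sigma_range_mm[2] - 2)
  base * runif(3, 0.85, 1.15)
}

#' Generate a synthetic SBRT-like plan
#'
#' Builds a dose volume as a superposition of anisotropic Gaussian lobes
#' with steep fall-off, normalized so the maximum equals the drawn peak
#' dose, plus the target mask at the prescription isodose
#' (`dose >= prescription_fraction * peak`). Deterministic in
#' `(spec, seed)`.
#'
#' @param spec a [plan_spec()], or arguments overriding the default.
#' @param seed integer seed.
#' @param lobes optional explicit lobe list (each with `center` mm,
#'   `sigma` mm length 3, `amp` relative); overrides random placement.
#' @param peak_gy optional explicit peak dose.
#' @return a list with elements `volume` ([dose_volume()]) and `mask`
#'   ([structure_mask()]).
#' @export
generate_plan <- function(spec = plan_spec(), seed = 1, lobes = NULL,
                          peak_gy = NULL) {
  stopifnot(inherits(spec, "plan_spec"))
  with_seed(seed, {
    dims <- spec$grid_n
    sp <- rep(spec$spacing_mm, 3)
    extent <- (dims - 1) * sp
    origin <- -extent / 2          # dose cluster centered on the grid
    iso_z <- if (is.null(spec$isocenter_z_mm)) 0 else spec$isocenter_z_mm
    iso <- c(0, 0, max(min(iso_z, extent[3] / 2), -extent[3] / 2))
    if (is.null(peak_gy)) peak_gy <- runif(1, spec$peak_range_gy[1],
                                           spec$peak_range_gy[2])
    if (is.null(lobes)) {
      n_lobes <- if (is.null(spec$n_lobes)) 3L else spec$n_lobes
      # lobes on a ring around the isocenter, evenly spread in azimuth
      # with jitter, each moderately off-plane with near-equal amplitude
      phis <- runif(1, 0, 2 * pi) + (seq_len(n_lobes) - 1) * 2 * pi /
        n_lobes + runif(n_lobes, -pi / 6, pi / 6)
      sig_scale <- if (is.null(spec$sigma_scale_range)) 1 else
        runif(1, spec$sigma_scale_range[1], spec$sigma_scale_range[2])
      lobes <- lapply(seq_len(n_lobes), function(l) {
        r <- runif(1, spec$offset_range_mm[1], spec$offset_range_mm[2])
        list(center = c(r * cos(phis[l]), r * sin(phis[l]), draw_z(spec)),
             sigma = sig_scale * draw_sigma(spec),
             amp = if (l == 1) 1 else runif(1, spec$satellite_amp[1],
                                            spec$satellite_amp[2]),
             orientation = random_orientation())
      })
    }
    ax <- lapply(1:3, function(a) origin[a] + (seq_len(dims[a]) - 1) * sp[a])
    hi <- origin + (dims - 1) * sp
    pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
    grid <- array(0, dim = dims)
    for (lb in lobes) {
      if (any(lb$center < origin) || any(lb$center > hi)) {
        stop_rotqa("lobe center lies outside the grid", "rotqa_invalid_spec")
      }
      # anisotropic Gaussian with principal axes U (oblique-beam-like
      # orientation); axis-aligned when no orientation is given
      d <- sweep(pts, 2, lb$center)
      if (!is.null(lb$orientation)) d <- d %*% lb$orientation
      q <- (d[, 1] / lb$sigma[1])^2 + (d[, 2] / lb$sigma[2])^2 +
        (d[, 3] / lb$sigma[3])^2
      grid <- grid + lb$amp * exp(-0.5 * q)
    }
    dim(grid) <- dims
    # crossfire ripple: mild multiplicative in-target heterogeneity with
    # an oblique wavevector (strong through-plane component)
    if (!is.null(spec$ripple_amp) && max(spec$ripple_amp) > 0) {
      a <- runif(1, spec$ripple_amp[1], spec$ripple_amp[2])
      lambda <- runif(1, spec$ripple_wavelength_mm[1],
                      spec$ripple_wavelength_mm[2])
      u <- runit3()
      u[3] <- sign(u[3]) * max(abs(u[3]), 0.6)
      u <- u / sqrt(sum(u^2))
      kvec <- 2 * pi / lambda * u
      phase <- pts %*% kvec + runif(1, 0, 2 * pi)
      grid <- grid * (1 + a * array(sin(phase), dims))
    }
    grid <- grid * (peak_gy / max(grid))
    prescription <- spec$prescription_fraction * peak_gy
    vol <- dose_volume(grid, sp, origin, iso, prescription)
    mask <- structure_mask(grid >= prescription, sp, origin, "target")
    list(volume = vol, mask = mask)
  })
}

#' Planar detector specification
#'
#' Emulates a square diode-array detector (default geometry follows the
#' 77.00 x 77.00 mm effective area of an SRS-class planar array) sampled on
#' a regular grid centered on the isocenter projection.
#'
#' @param plane_normal axis id of the plane normal: 1 (x), 2 (y) or 3 (z).
#' @param plane_offset_mm signed distance of the plane from the isocenter
#'   along the normal (mm). The default matches the cohort geometry, where
#'   the measurement plane cuts the dose cluster 15 mm off the plan
#'   isocenter.
#' @param extent_mm side length of the square sampling area (mm).
#' @param n_samples detectors per side (>= 2).
#' @param noise_sd_frac Gaussian measurement-noise SD as a fraction of the
#'   plane maximum (0 disables noise).
#' @return a list of class `detector_spec`.
#' @export
detector_spec <- function(plane_normal = 3, plane_offset_mm = 15,
                          extent_mm = 77.0, n_samples = 45,
                          noise_sd_frac = 0.01) {
  check_number(extent_mm, "extent_mm", 0, strict = TRUE)
  if (n_samples < 2) stop_rotqa("n_samples must be >= 2", "rotqa_invalid_spec")
  check_number(noise_sd_frac, "noise_sd_frac", 0)
  if (!plane_normal %in% 1:3) stop_rotqa("plane_normal must be 1, 2 or 3",
                                         "rotqa_invalid_spec")
  structure(list(plane_normal = as.integer(plane_normal),
                 plane_offset_mm = as.double(plane_offset_mm),
                 extent_mm = as.double(extent_mm),
                 n_samples = as.integer(n_samples),
                 noise_sd_frac = as.double(noise_sd_frac)),
            class = "detector_spec")
}

#' Sample a planar detector measurement from a dose volume
#'
#' Interpolates the volume on an `n_samples` x `n_samples` grid spanning
#' `extent_mm`, centered on the isocenter projection, in the plane
#' orthogonal to `plane_normal` at `plane_offset_mm` from the isocenter.
#' Seeded Gaussian noise is added when `noise_sd_frac > 0`. Matrix rows
#' advance along the first in-plane axis.
#'
#' @param volume a [dose_volume()].
#' @param spec a [detector_spec()].
#' @param seed integer seed for the measurement noise.
#' @return a [dose_plane()] in absolute-dose mode.
#' @export
extract_plane <- function(volume, spec = detector_spec(), seed = 1) {
  iso <- volume$isocenter
  hi <- volume$origin + (dim(volume$grid) - 1) * volume$spacing
  nrm <- spec$plane_normal
  zpos <- iso[nrm] + spec$plane_offset_mm
  if (zpos < volume$origin[nrm] || zpos > hi[nrm]) {
    stop_rotqa("sampling plane lies outside the grid", "rotqa_out_of_bounds")
  }
  inplane <- setdiff(1:3, nrm)
  s <- seq(-spec$extent_mm / 2, spec$extent_mm / 2,
           length.out = spec$n_samples)
  g <- expand.grid(u = s, v = s)
  pts <- matrix(0, nrow(g), 3)
  pts[, inplane[1]] <- iso[inplane[1]] + g$u
  pts[, inplane[2]] <- iso[inplane[2]] + g$v
  pts[, nrm] <- zpos
  vals <- sample_volume(volume, pts, fill = 0)
  m <- matrix(vals, spec$n_samples, spec$n_samples)
  if (spec$noise_sd_frac > 0) {
    m <- with_seed(seed, {
      m + matrix(rnorm(length(m), sd = spec$noise_sd_frac * max(m)),
                 nrow(m), ncol(m))
    })
    m[m < 0] <- 0
  }
  dose_plane(m, spec$extent_mm / (spec$n_samples - 1), "absolute_Gy")
}

#' Two-stage acquisition protocol for a synthetic cohort
#'
#' Stage 1 measures each plan at a fixed grid of single-direction angles
#' (default 5 magnitudes x 3 directions = 15 records/plan); stage 2 adds
#' one multi-axis record per plan with angles drawn uniformly from a
#' continuous range in 2 or 3 randomly chosen axes (matching the
#' multidirectional second acquisition phase).
#'
#' @param n_plans number of plans (>= 1).
#' @param stage1_angles_deg stage-1 angle magnitudes (degrees); may be
#'   empty to skip stage 1.
#' @param stage1_directions subset of `c("UP", "RO", "CW")`.
#' @param stage2_angle_range_deg continuous angle interval for stage 2;
#'   `NULL` skips stage 2.
#' @param stage2_n_directions number of perturbed axes in stage 2 (1-3),
#'   or `NULL` to draw 2 or 3 at random per plan.
#' @param plan a [plan_spec()] shared by all plans.
#' @param detector a [detector_spec()].
#' @param seed master seed; every plan/measurement derives its own stream.
#' @return a list of class `cohort_protocol`.
#' @export
cohort_protocol <- function(n_plans = 40,
                            stage1_angles_deg = c(1.5, 2.25, 3.0, 3.75, 4.5),
                            stage1_directions = c("UP", "RO", "CW"),
                            stage2_angle_range_deg = c(1.5, 4.5),
                            stage2_n_directions = NULL,
                            plan = plan_spec(),
                            detector = detector_spec(),
                            seed = 1) {
  if (n_plans < 1) stop_rotqa("n_plans must be >= 1", "rotqa_invalid_spec")
  if (length(stage1_angles_deg) &&
      (any(stage1_angles_deg < 0) || any(stage1_angles_deg > 10))) {
    stop_rotqa("stage-1 angle magnitudes must lie in [0, 10]",
               "rotqa_invalid_spec")
  }
  if (!is.null(stage2_angle_range_deg) &&
      (any(stage2_angle_range_deg < 0) || any(stage2_angle_range_deg > 10))) {
    stop_rotqa("stage-2 angle range must lie in [0, 10]",
               "rotqa_invalid_spec")
  }
  if (!all(stage1_directions %in% c("UP", "RO", "CW"))) {
    stop_rotqa("directions must be in {UP, RO, CW}", "rotqa_invalid_spec")
  }
  if (!is.null(stage2_n_directions) && !stage2_n_directions %in% 1:3) {
    stop_rotqa("stage2_n_directions must be 1, 2 or 3", "rotqa_invalid_spec")
  }
  structure(list(n_plans = as.integer(n_plans),
                 stage1_angles_deg = stage1_angles_deg,
                 stage1_directions = stage1_directions,
                 stage2_angle_range_deg = stage2_angle_range_deg,
                 stage2_n_directions = stage2_n_directions,
                 plan = plan, detector = detector, seed = as.integer(seed)),
            class = "cohort_protocol")
}

direction_rotation <- function(direction, magnitude) {
  switch(direction,
         UP = rotation_error(pitch_deg = magnitude),
         RO = rotation_error(roll_deg = magnitude),
         CW = rotation_error(yaw_deg = magnitude))
}

#' Simulate a two-stage measurement cohort
#'
#' For each plan: generates the dose volume and target mask, records the
#' error-free (0 deg) reference plane, then one perturbed measurement per
#' stage-1 (magnitude x direction) combination and one multi-axis stage-2
#' measurement. Every record carries its plan id (for grouped splitting),
#' rotation, reference and perturbed planes, and the delta-V100 target
#' coverage loss computed from the 3D volumes.
#'
#' @param protocol a [cohort_protocol()].
#' @param keep_volumes keep each plan's reference volume and mask in the
#'   result (needed for feature extraction).
#' @return a list of class `rotqa_cohort` with elements `records` (list of
#'   measurement records) and `plans` (per-plan volume/mask, if kept).
#' @export
simulate_cohort <- function(protocol = cohort_protocol(),
                            keep_volumes = TRUE) {
  records <- list()
  plans <- list()
  for (p in seq_len(protocol$n_plans)) {
    plan_id <- sprintf("plan%03d", p)
    pseed <- derive_seed(protocol$seed, plan_id)
    gen <- generate_plan(protocol$plan, seed = pseed)
    vol <- gen$volume
    mask <- gen$mask
    ref_plane <- extract_plane(vol, protocol$detector,
                               seed = derive_seed(pseed, "ref"))
    v100_ref <- v100(vol, mask, vol$prescription_dose)
    if (keep_volumes) plans[[plan_id]] <- gen

    rotations <- list()
    stages <- integer(0)
    for (a in protocol$stage1_angles_deg) {
      for (d in protocol$stage1_directions) {
        rotations[[length(rotations) + 1]] <- direction_rotation(d, a)
        stages <- c(stages, 1L)
      }
    }
    if (!is.null(protocol$stage2_angle_range_deg)) {
      rot2 <- with_seed(derive_seed(pseed, "stage2"), {
        nd <- if (is.null(protocol$stage2_n_directions)) sample(2:3, 1) else
          protocol$stage2_n_directions
        axes <- sample(c("UP", "RO", "CW"), nd)
        ang <- runif(3, protocol$stage2_angle_range_deg[1],
                     protocol$stage2_angle_range_deg[2])
        rotation_error(
          pitch_deg = if ("UP" %in% axes) ang[1] else 0,
          roll_deg  = if ("RO" %in% axes) ang[2] else 0,
          yaw_deg   = if ("CW" %in% axes) ang[3] else 0)
      })
      rotations[[length(rotations) + 1]] <- rot2
      stages <- c(stages, 2L)
    }

    for (r in seq_along(rotations)) {
      rot <- rotations[[r]]
      vrot <- apply_rigid_rotation(vol, rot)
      pert <- extract_plane(vrot, protocol$detector,
                            seed = derive_seed(pseed, paste0("meas", r)))
      dv100 <- v100_ref - v100(vrot, mask, vol$prescription_dose)
      records[[length(records) + 1]] <- list(
        plan_id = plan_id, stage = stages[r], rotation = rot,
        reference_plane = ref_plane, perturbed_plane = pert,
        delta_v100 = dv100)
    }
  }
  structure(list(records = records, plans = plans, protocol = protocol),
            class = "rotqa_cohort")
}

#' @export
print.rotqa_cohort <- function(x, ...) {
  st <- vapply(x$records, `[[`, 1L, "stage")
  cat(sprintf("<rotqa_cohort> %d plans, %d records (%d stage 1, %d stage 2)\n",
              x$protocol$n_plans, length(x$records), sum(st == 1),
              sum(st == 2)))
  invisible(x)
}
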