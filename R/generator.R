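# Synthetic cohort generator: parametric torso surfaces plus ground-truth
# body composition, calibrated to the marginal statistics of an adult male
# cohort (height 177.9 (6.8) cm, body fat 21.02 (7.82) %, trunk:peripheral
# fat ratio 1.57 (0.22)).

# Sensitivity of the waist cross-section to the latent adiposity factor A
# and the central-distribution factor C (fractional change per 1 SD).
# These constants also define the standardized size index used in the
# structural equation for body-fat percentage.
.WAIST_SENS_A <- 0.060
.WAIST_SENS_C <- 0.022

#' Configuration for the synthetic cohort generator
#'
#' Bundles every tunable of the generative model. The defaults are the
#' study conditions the package emulates: cohort marginals of an adult male
#' sample (height, body-fat percentage, trunk:peripheral fat ratio), effect
#' sizes that couple body composition to a standardized size index and to
#' the two latent shape factors, and scanner noise of 2 mm.
#'
#' The structural equations are
#' \deqn{fat\% = \mu_f + \beta_{size} u + \beta_{L} s_L + \epsilon,\qquad
#'       \epsilon \sim N(0, \sigma_f^2)}
#' \deqn{TPFR = \mu_t + \gamma_{C} C + \gamma_{S} s_S + \epsilon',\qquad
#'       \epsilon' \sim N(0, \sigma_t^2)}
#' where `u` is the standardized (latent) waist-to-root-height index
#' WHT.5R, `s_L` drives low-frequency cross-section harmonics (aspect
#' ratio and the k = 2 harmonic) and `s_S` drives high-frequency harmonics
#' (k = 5--8). With the default effect sizes the implied marginal SDs are
#' sqrt(6.2^2 + 4^2 + 2.8^2) = 7.89 for fat% and
#' sqrt(0.13^2 + 0.14^2 + 0.10^2) = 0.216 for TPFR, within a few percent
#' of the calibration targets.
#'
#' @param n_subjects number of participants (default 93).
#' @param seed integer seed; together with the config it fully determines
#'   all generator output.
#' @param height_mean_cm,height_sd_cm stature distribution (cm).
#' @param fat_mean_pct,fat_sd_pct body-fat percentage calibration targets.
#' @param tpfr_mean,tpfr_sd trunk:peripheral fat ratio calibration targets.
#' @param beta_size effect (pct points per SD) of the standardized size
#'   index on fat%.
#' @param beta_largeshape effect of the large-scale shape factor on fat%.
#' @param sigma_fat residual SD of fat% (pct points).
#' @param gamma_central effect of the central-distribution factor on TPFR.
#' @param gamma_smallshape effect of the small-scale shape factor on TPFR.
#' @param sigma_tpfr residual SD of TPFR.
#' @param scanner_noise_sd_mm isotropic Gaussian noise added to every
#'   rendered surface point (mm).
#' @param latent_cor common correlation among the four latent factors
#'   (A, C, s_L, s_S); 0 by default, positive values stress collinearity
#'   handling downstream.
#' @param adp_noise_sd_l SD of a single plethysmography body-volume
#'   reading (L).
#' @param bia_noise_sd_kg SD of a single bioimpedance segmental fat-mass
#'   reading (kg).
#' @param include_limbs render limb proxy cylinders into the scan.
#' @param scan_z_step_mm vertical sampling pitch of the torso surface (mm).
#' @param scan_n_theta angular samples per torso ring.
#' @param n_reference size of the reference cohort used to fit the PCA
#'   shape basis when none is supplied.
#' @param retry_budget maximum redraws of the composition residuals when a
#'   draw leaves the physiologically plausible window.
#'
#' @return an object of class `generator_config` (a validated list).
#' @export
generator_config <- function(n_subjects = 93L,
                             seed = 1L,
                             height_mean_cm = 177.9,
                             height_sd_cm = 6.8,
                             fat_mean_pct = 21.02,
                             fat_sd_pct = 7.82,
                             tpfr_mean = 1.57,
                             tpfr_sd = 0.22,
                             beta_size = 6.2,
                             beta_largeshape = 4.0,
                             sigma_fat = 2.8,
                             gamma_central = 0.13,
                             gamma_smallshape = 0.14,
                             sigma_tpfr = 0.10,
                             scanner_noise_sd_mm = 2.0,
                             latent_cor = 0,
                             adp_noise_sd_l = 0.05,
                             bia_noise_sd_kg = 0.10,
                             include_limbs = TRUE,
                             scan_z_step_mm = 1.0,
                             scan_n_theta = 96L,
                             n_reference = 300L,
                             retry_budget = 20L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), seed = as.integer(seed),
    height_mean_cm = height_mean_cm, height_sd_cm = height_sd_cm,
    fat_mean_pct = fat_mean_pct, fat_sd_pct = fat_sd_pct,
    tpfr_mean = tpfr_mean, tpfr_sd = tpfr_sd,
    beta_size = beta_size, beta_largeshape = beta_largeshape,
    sigma_fat = sigma_fat,
    gamma_central = gamma_central, gamma_smallshape = gamma_smallshape,
    sigma_tpfr = sigma_tpfr,
    scanner_noise_sd_mm = scanner_noise_sd_mm,
    latent_cor = latent_cor,
    adp_noise_sd_l = adp_noise_sd_l, bia_noise_sd_kg = bia_noise_sd_kg,
    include_limbs = isTRUE(include_limbs),
    scan_z_step_mm = scan_z_step_mm, scan_n_theta = as.integer(scan_n_theta),
    n_reference = as.integer(n_reference),
    retry_budget = as.integer(retry_budget)
  )
  if (cfg$n_subjects < 1L) stop("n_subjects must be >= 1")
  sds <- c(height_sd_cm, sigma_fat, sigma_tpfr, scanner_noise_sd_mm,
           adp_noise_sd_l, bia_noise_sd_kg)
  if (any(sds < 0)) stop("all sd and noise parameters must be >= 0")
  if (latent_cor < 0 || latent_cor >= 1) stop("latent_cor must be in [0, 1)")
  if (cfg$scan_z_step_mm <= 0) stop("scan_z_step_mm must be > 0")
  class(cfg) <- "generator_config"
  cfg
}

# Draw the four latent factors, optionally with a common correlation.
.draw_latents <- function(rho) {
  z <- rnorm(4L)
  if (rho > 0) {
    sigma <- matrix(rho, 4L, 4L)
    diag(sigma) <- 1
    z <- drop(t(chol(sigma)) %*% z)
  }
  names(z) <- c("A", "C", "s_L", "s_S")
  z
}

#' Generate a single synthetic participant
#'
#' Draws the latent factors (adiposity A, central-distribution C,
#' large-scale shape s_L, small-scale shape s_S), builds the parametric
#' torso cross-section model (superellipse semi-axes at the hip, stomach,
#' waist and chest stations plus harmonic amplitudes for angular
#' frequencies 1--8), the limb measures, the landmark heights and the true
#' body composition. Uses the current RNG state; identical (config, id,
#' RNG state) yields identical output.
#'
#' Physiologically implausible composition draws (fat% outside (1, 59) or
#' TPFR outside (0.3, 3.5)) reject the whole draw and resample the
#' participant, up to `config$retry_budget` times; this truncates the
#' extreme tails of the latent factors very slightly.
#'
#' @param config a [generator_config()].
#' @param id integer subject identifier.
#' @return an object of class `synthetic_participant`.
#' @export
generate_participant <- function(config, id = 1L) {
  stopifnot(inherits(config, "generator_config"))
  for (attempt in seq_len(config$retry_budget + 1L)) {
    p <- .draw_participant(config, id)
    if (!is.null(p)) return(p)
  }
  stop("retry budget exhausted: could not draw a plausible participant")
}

.draw_participant <- function(config, id) {
  h_cm <- config$height_mean_cm + config$height_sd_cm * rnorm(1L)
  h_cm <- max(h_cm, 0.7 * config$height_mean_cm)
  h <- h_cm / config$height_mean_cm

  lat <- .draw_latents(config$latent_cor)
  A <- lat[["A"]]; C <- lat[["C"]]; s_L <- lat[["s_L"]]; s_S <- lat[["s_S"]]

  e_bmi <- rnorm(1L)
  e_se <- rnorm(1L)
  e_h <- rnorm(8L)     # harmonic amplitude noise
  e_limb <- rnorm(12L) # limb measure noise (2 sides x 6 measures)

  bmi <- max(26.2 + 3.2 * A + 0.8 * C + 1.2 * e_bmi, 16)
  weight_kg <- bmi * (h_cm / 100)^2

  # superellipse stations: t = 0 at the buttock (hip girth), 1 at the
  # xiphoid (chest girth); semi-axes in mm (a sagittal, b transverse)
  size_f <- h * (1 + 0.030 * A)
  aspect <- 0.022 * s_L
  station_t <- c(0, 0.22, 0.58, 1)
  base_a <- c(130, 122, 112, 128)
  base_b <- c(185, 170, 158, 182)
  extra <- c(1 + 0.006 * C,                     # hip
             1 + 0.020 * A + 0.020 * C,        # stomach
             1 + 0.030 * A + .WAIST_SENS_C * C, # waist
             1)                                 # chest
  a_mm <- base_a * size_f * extra * (1 - aspect)
  b_mm <- base_b * size_f * extra * (1 + aspect)
  if (any(a_mm <= 0) || any(b_mm <= 0)) stop("non-positive semi-axis drawn")

  se_exponent <- min(max(2.4 + 0.15 * e_se, 2.05), 2.9)

  harmonics <- c(
    0.050 + 0.010 * A   + 0.008 * e_h[1], # k = 1: anterior (belly) asymmetry
    0.012 + 0.012 * s_L + 0.004 * e_h[2], # k = 2: large-scale, driven by s_L
    0.008 +               0.003 * e_h[3],
    0.006 +               0.003 * e_h[4],
    0.005 + 0.012 * s_S + 0.003 * e_h[5], # k = 5..8: small-scale, driven by s_S
    0.004 + 0.004 * s_S + 0.002 * e_h[6],
    0.003 + 0.003 * s_S + 0.002 * e_h[7],
    0.002 + 0.002 * s_S + 0.001 * e_h[8]
  )
  names(harmonics) <- paste0("c", 1:8)

  # landmarks (mm, scan frame with the floor at z = 0)
  h_mm <- 10 * h_cm
  buttock <- 0.458 * h_mm
  neck <- 0.855 * h_mm
  xiphoid <- buttock + 0.60 * (neck - buttock)

  # standardized size index: the latent counterpart of WHT.5R
  s_lnh <- 0.5 * config$height_sd_cm / config$height_mean_cm
  u_sd <- sqrt(s_lnh^2 + .WAIST_SENS_A^2 + .WAIST_SENS_C^2)
  u <- (0.5 * log(h) + .WAIST_SENS_A * A + .WAIST_SENS_C * C) / u_sd

  fat_pct <- config$fat_mean_pct + config$beta_size * u +
    config$beta_largeshape * s_L + config$sigma_fat * rnorm(1L)
  tpfr <- config$tpfr_mean + config$gamma_central * C +
    config$gamma_smallshape * s_S + config$sigma_tpfr * rnorm(1L)
  if (fat_pct <= 1 || fat_pct >= 59 || tpfr <= 0.3 || tpfr >= 3.5) {
    # implausible composition draw: reject this whole participant draw
    return(NULL)
  }

  # true fat masses: 88% of total fat sits in the trunk + limbs, the
  # remainder in the head and neck; limb fat splits 72% legs / 28% arms
  total_fat_kg <- fat_pct / 100 * weight_kg
  appendicular <- 0.88 * total_fat_kg
  peripheral <- appendicular / (1 + tpfr)
  trunk_fat_kg <- tpfr * peripheral

  limb <- function(base, ca, cc, noise_sd, e1, e2, pow = 1) {
    base * h^pow * (1 + ca * A + cc * C) * (1 + noise_sd * c(e1, e2))
  }
  thigh <- limb(56, 0.035, -0.012, 0.008, e_limb[1], e_limb[2])
  bicep <- limb(33, 0.030, -0.010, 0.008, e_limb[3], e_limb[4])
  leg_vol <- limb(10.5, 0.080, -0.025, 0.02, e_limb[5], e_limb[6], pow = 2)
  arm_vol <- limb(3.8, 0.070, -0.022, 0.02, e_limb[7], e_limb[8], pow = 2)
  leg_sa <- limb(0.45, 0.030, -0.008, 0.01, e_limb[9], e_limb[10], pow = 2)
  arm_sa <- limb(0.22, 0.025, -0.008, 0.01, e_limb[11], e_limb[12], pow = 2)

  p <- list(
    id = as.integer(id),
    height_cm = h_cm, weight_kg = weight_kg, bmi = bmi,
    A = A, C = C, s_L = s_L, s_S = s_S,
    stations = data.frame(t = station_t, a_mm = a_mm, b_mm = b_mm),
    se_exponent = se_exponent,
    harmonics = harmonics,
    neck_height_mm = neck, buttock_height_mm = buttock,
    xiphoid_height_mm = xiphoid,
    torso_length_mm = xiphoid - buttock,
    thigh_girth_l_cm = thigh[1], thigh_girth_r_cm = thigh[2],
    bicep_girth_l_cm = bicep[1], bicep_girth_r_cm = bicep[2],
    leg_volume_l_l = leg_vol[1], leg_volume_r_l = leg_vol[2],
    arm_volume_l_l = arm_vol[1], arm_volume_r_l = arm_vol[2],
    leg_sa_l_m2 = leg_sa[1], leg_sa_r_m2 = leg_sa[2],
    arm_sa_l_m2 = arm_sa[1], arm_sa_r_m2 = arm_sa[2],
    true_fat_pct = fat_pct, true_tpfr = tpfr,
    trunk_fat_kg = trunk_fat_kg,
    leg_fat_l_kg = 0.36 * peripheral, leg_fat_r_kg = 0.36 * peripheral,
    arm_fat_l_kg = 0.14 * peripheral, arm_fat_r_kg = 0.14 * peripheral
  )
  stopifnot(p$xiphoid_height_mm > p$buttock_height_mm,
            p$xiphoid_height_mm < p$neck_height_mm,
            p$true_fat_pct > 0, p$true_fat_pct < 100,
            p$trunk_fat_kg > 0)
  class(p) <- "synthetic_participant"
  p
}

#' @export
print.synthetic_participant <- function(x, ...) {
  cat(sprintf(
    "<synthetic_participant #%d> height %.1f cm, weight %.1f kg, fat %.1f%%, TPFR %.2f\n",
    x$id, x$height_cm, x$weight_kg, x$true_fat_pct, x$true_tpfr))
  invisible(x)
}

# Interpolate the superellipse semi-axes along the torso (natural cubic
# through the four stations); t is the fraction of torso length, 0 at the
# buttock.
.semiaxes_at <- function(p, t) {
  list(
    a = spline(p$stations$t, p$stations$a_mm, xout = t, method = "natural")$y,
    b = spline(p$stations$t, p$stations$b_mm, xout = t, method = "natural")$y
  )
}

#' Cross-section radius of the parametric torso surface
#'
#' Radius (mm) of the torso cross-section at height fraction `t` (0 =
#' buttock, 1 = xiphoid) and polar angle `theta` (0 = anterior, measured
#' counter-clockwise in the transverse plane). The surface is a
#' superellipse of exponent `p$se_exponent` with semi-axes interpolated
#' between stations, modulated by cosine harmonics of angular frequency
#' 1--8.
#'
#' @param p a `synthetic_participant`.
#' @param t height fractions (vector).
#' @param theta polar angles in radians (vector).
#' @return a `length(t) x length(theta)` matrix of radii (mm).
#' @export
torso_radius <- function(p, t, theta) {
  ax <- .semiaxes_at(p, t)
  n <- p$se_exponent
  ct <- abs(cos(theta))^n
  st <- abs(sin(theta))^n
  r_se <- (outer(1 / ax$a^n, ct) + outer(1 / ax$b^n, st))^(-1 / n)
  harm <- rep(1, length(theta))
  for (k in 1:8) harm <- harm + p$harmonics[k] * cos(k * theta)
  sweep(r_se, 2L, harm, `*`)
}

#' Analytic ground-truth geometry of a synthetic torso
#'
#' Computes girths, cross-section areas, volume and lateral surface area
#' of the parametric torso by dense numerical quadrature of the analytic
#' surface, independent of the scan-based extraction pipeline. Used as the
#' oracle in validation tests.
#'
#' @param p a `synthetic_participant`.
#' @param n_t number of height stations for the axial quadrature.
#' @param n_theta number of polygon vertices for the angular quadrature.
#' @return a list with `girth_cm` (data frame t, girth_cm), `waist_girth_cm`,
#'   `hip_girth_cm`, `chest_girth_cm`, `stomach_girth_cm`,
#'   `torso_volume_l`, `torso_sa_m2`.
#' @export
torso_surface_truth <- function(p, n_t = 201L, n_theta = 1024L) {
  t <- seq(0, 1, length.out = n_t)
  theta <- 2 * pi * seq(0L, n_theta - 1L) / n_theta
  r <- torso_radius(p, t, theta)
  x <- r * matrix(cos(theta), n_t, n_theta, byrow = TRUE)
  y <- r * matrix(sin(theta), n_t, n_theta, byrow = TRUE)
  seg <- sqrt((x - x[, c(2:n_theta, 1L)])^2 + (y - y[, c(2:n_theta, 1L)])^2)
  perim_mm <- rowSums(seg)
  # polar area: 1/2 * integral r^2 dtheta
  area_mm2 <- 0.5 * rowSums(r^2) * (2 * pi / n_theta)
  dz <- p$torso_length_mm / (n_t - 1L)
  vol_mm3 <- sum((area_mm2[-1L] + area_mm2[-n_t]) / 2) * dz
  sa_mm2 <- sum((perim_mm[-1L] + perim_mm[-n_t]) / 2) * dz
  girth_cm <- perim_mm / 10
  i_waist <- which.min(girth_cm)
  i_stomach_region <- which(t < t[i_waist] & t > 0)
  list(
    girth_cm = data.frame(t = t, girth_cm = girth_cm),
    waist_girth_cm = girth_cm[i_waist],
    waist_t = t[i_waist],
    hip_girth_cm = girth_cm[1L],
    chest_girth_cm = max(girth_cm[t >= 0.7]),
    stomach_girth_cm = if (length(i_stomach_region))
      max(girth_cm[i_stomach_region]) else NA_real_,
    torso_volume_l = vol_mm3 / 1e6,
    torso_sa_m2 = sa_mm2 / 1e6
  )
}

#' Render a labeled 3D scan of a synthetic participant
#'
#' Samples the parametric torso surface on a vertical/angular grid between
#' the buttock and neck landmarks, optionally adds limb proxy cylinders
#' (legs below the buttock, arms hanging outward from the shoulders at 35
#' degrees), and corrupts every coordinate with isotropic Gaussian scanner
#' noise. Landmark heights are exact (they are software landmarks, not
#' surface points).
#'
#' @param p a `synthetic_participant`.
#' @param config a [generator_config()]; `scanner_noise_sd_mm`,
#'   `scan_z_step_mm`, `scan_n_theta` and `include_limbs` are honoured.
#' @return an object of class `labeled_scan`: list with `points`
#'   (n x 3 matrix, columns x, y, z in mm), `landmarks` (list with
#'   `neck_height_mm`, `buttock_height_mm`) and `subject_id`.
#' @export
render_scan <- function(p, config) {
  stopifnot(inherits(p, "synthetic_participant"),
            inherits(config, "generator_config"))
  h <- p$height_cm / config$height_mean_cm
  ntheta <- config$scan_n_theta
  theta <- 2 * pi * seq(0L, ntheta - 1L) / ntheta

  # torso: buttock -> xiphoid
  z_t <- seq(p$buttock_height_mm, p$xiphoid_height_mm, by = config$scan_z_step_mm)
  t_frac <- (z_t - p$buttock_height_mm) / p$torso_length_mm
  r <- torso_radius(p, t_frac, theta)
  ct <- matrix(cos(theta), length(z_t), ntheta, byrow = TRUE)
  st <- matrix(sin(theta), length(z_t), ntheta, byrow = TRUE)
  pts <- cbind(x = as.vector(r * ct), y = as.vector(r * st),
               z = rep(z_t, times = ntheta))

  # upper torso: xiphoid -> neck, tapering from the chest section to a
  # neck circle
  ntheta_u <- 64L
  theta_u <- 2 * pi * seq(0L, ntheta_u - 1L) / ntheta_u
  z_u <- seq(p$xiphoid_height_mm, p$neck_height_mm, by = 2)
  s <- (z_u - p$xiphoid_height_mm) / (p$neck_height_mm - p$xiphoid_height_mm)
  r_chest <- drop(torso_radius(p, 1, theta_u))
  r_neck <- 60 * h
  r_u <- outer(1 - s, r_chest) + outer(s, rep(r_neck, ntheta_u))
  pts_u <- cbind(x = as.vector(sweep(r_u, 2L, cos(theta_u), `*`)),
                 y = as.vector(sweep(r_u, 2L, sin(theta_u), `*`)),
                 z = rep(z_u, times = ntheta_u))
  pts <- rbind(pts, pts_u)

  if (config$include_limbs) {
    cyl <- function(center_fun, radius_top, radius_bot, z_lo, z_hi,
                    ntheta_l = 24L, step = 4) {
      zc <- seq(z_lo, z_hi, by = step)
      s <- (zc - z_lo) / max(z_hi - z_lo, 1)
      rad <- radius_bot + (radius_top - radius_bot) * s
      th <- 2 * pi * seq(0L, ntheta_l - 1L) / ntheta_l
      ctr <- center_fun(zc) # matrix length(zc) x 2
      cbind(x = as.vector(outer(rad, cos(th)) + ctr[, 1L]),
            y = as.vector(outer(rad, sin(th)) + ctr[, 2L]),
            z = rep(zc, times = ntheta_l))
    }
    r_thigh <- mean(c(p$thigh_girth_l_cm, p$thigh_girth_r_cm)) * 10 / (2 * pi)
    for (side in c(-1, 1)) {
      pts <- rbind(pts, cyl(function(z) cbind(0 * z, side * 90 * h),
                            r_thigh, 0.55 * r_thigh,
                            0.12 * 10 * p$height_cm, p$buttock_height_mm))
    }
    # arms: straight cylinders from the shoulder, 35 deg from vertical
    r_arm <- mean(c(p$bicep_girth_l_cm, p$bicep_girth_r_cm)) * 10 / (2 * pi)
    arm_len <- 0.34 * 10 * p$height_cm
    b_chest <- max(p$stations$b_mm)
    for (side in c(-1, 1)) {
      z_sh <- p$neck_height_mm - 30
      y_sh <- side * (b_chest + 40)
      axis_l <- seq(0, arm_len, by = 4)
      ctr_y <- y_sh + side * sin(35 * pi / 180) * axis_l
      ctr_z <- z_sh - cos(35 * pi / 180) * axis_l
      th <- 2 * pi * seq(0L, 23L) / 24L
      rad <- r_arm * (1 - 0.4 * axis_l / arm_len)
      ca <- cos(35 * pi / 180)
      pts <- rbind(pts, cbind(
        x = as.vector(outer(rad, cos(th))),
        y = as.vector(outer(rad, sin(th)) * ca + ctr_y),
        z = as.vector(outer(rad, sin(th)) * sin(35 * pi / 180) * side + ctr_z)))
    }
  }

  if (config$scanner_noise_sd_mm > 0) {
    pts <- pts + rnorm(length(pts), sd = config$scanner_noise_sd_mm)
  }
  scan <- list(points = pts,
               landmarks = list(neck_height_mm = p$neck_height_mm,
                                buttock_height_mm = p$buttock_height_mm),
               subject_id = p$id)
  class(scan) <- "labeled_scan"
  scan
}

#' @export
print.labeled_scan <- function(x, ...) {
  cat(sprintf("<labeled_scan #%s> %d points, z range [%.0f, %.0f] mm\n",
              x$subject_id, nrow(x$points), min(x$points[, "z"]),
              max(x$points[, "z"])))
  invisible(x)
}

#' Generate a full synthetic cohort
#'
#' Seeds the RNG from the config and generates `n_subjects` participants;
#' optionally renders one labeled scan per subject. The ground-truth table
#' carries the latent factors and the true composition targets for
#' recovery tests.
#'
#' @param config a [generator_config()].
#' @param render logical; also render scans (memory scales with
#'   `n_subjects`; use [simulate_study()] for streaming processing).
#' @return list with `participants` (list), `truth` (data frame), and
#'   `scans` (list of `labeled_scan`, or NULL).
#' @export
generate_cohort <- function(config, render = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  participants <- vector("list", config$n_subjects)
  scans <- if (render) vector("list", config$n_subjects) else NULL
  for (i in seq_len(config$n_subjects)) {
    participants[[i]] <- generate_participant(config, id = i)
    if (render) scans[[i]] <- render_scan(participants[[i]], config)
  }
  truth <- do.call(rbind, lapply(participants, function(p) {
    data.frame(id = p$id, height_cm = p$height_cm, weight_kg = p$weight_kg,
               bmi = p$bmi, A = p$A, C = p$C, s_L = p$s_L, s_S = p$s_S,
               true_fat_pct = p$true_fat_pct, true_tpfr = p$true_tpfr,
               trunk_fat_kg = p$trunk_fat_kg)
  }))
  list(participants = participants, truth = truth, scans = scans,
       config = config)
}
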