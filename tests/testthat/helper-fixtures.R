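# Shared fixtures: hand-built participants and analytic point clouds used
# as oracles across the geometry, feature and anthropometric tests.

# A participant with fully specified cross-section geometry (no random
# draws), for analytic-surface tests. Semi-axes are constant along the
# torso unless station values are given.
make_test_participant <- function(a_mm = 150, b_mm = 150, exponent = 2,
                                  harmonics = rep(0, 8), height_cm = 177.9,
                                  stations_a = rep(a_mm, 4),
                                  stations_b = rep(b_mm, 4)) {
  h_mm <- 10 * height_cm
  buttock <- 0.458 * h_mm
  neck <- 0.855 * h_mm
  xiphoid <- buttock + 0.60 * (neck - buttock)
  p <- list(
    id = 1L, height_cm = height_cm, weight_kg = 80, bmi = 25,
    A = 0, C = 0, s_L = 0, s_S = 0,
    stations = data.frame(t = c(0, 0.22, 0.58, 1),
                          a_mm = stations_a, b_mm = stations_b),
    se_exponent = exponent,
    harmonics = stats::setNames(harmonics, paste0("c", 1:8)),
    neck_height_mm = neck, buttock_height_mm = buttock,
    xiphoid_height_mm = xiphoid, torso_length_mm = xiphoid - buttock,
    thigh_girth_l_cm = 55, thigh_girth_r_cm = 57,
    bicep_girth_l_cm = 33, bicep_girth_r_cm = 33,
    leg_volume_l_l = 10, leg_volume_r_l = 10,
    arm_volume_l_l = 5, arm_volume_r_l = 5,
    leg_sa_l_m2 = 0.45, leg_sa_r_m2 = 0.45,
    arm_sa_l_m2 = 0.22, arm_sa_r_m2 = 0.22,
    true_fat_pct = 21, true_tpfr = 8 / 5.6, # trunk over summed limb fats
    trunk_fat_kg = 8, leg_fat_l_kg = 2, leg_fat_r_kg = 2,
    arm_fat_l_kg = 0.8, arm_fat_r_kg = 0.8
  )
  class(p) <- "synthetic_participant"
  p
}

# Dense analytic point cloud of an elliptic (or superelliptic) torso with
# one ring exactly at each of the 25 band centres, plus margin rings at
# the segment ends. With band-centred sampling the geometry chain is an
# exact continuum idealization (band membership is identical for scaled
# copies).
make_band_centred_scan <- function(a_mm = 120, b_mm = 170, n_theta = 180,
                                   height_cm = 177.9, c1 = 0.05,
                                   rings_per_band = 1) {
  p <- make_test_participant(a_mm, b_mm, exponent = 2,
                             harmonics = c(c1, rep(0, 7)),
                             height_cm = height_cm)
  L <- p$torso_length_mm
  centres <- (seq_len(25) - 0.5) / 25 * L
  offs <- if (rings_per_band > 1) {
    seq(-0.6, 0.6, length.out = rings_per_band)
  } else 0
  z <- as.vector(outer(offs, centres, `+`)) + p$buttock_height_mm
  # boundary rings so the landmark heights lie inside the cloud z-range
  z <- c(z, p$buttock_height_mm, p$xiphoid_height_mm, p$neck_height_mm)
  theta <- 2 * pi * seq(0L, n_theta - 1L) / n_theta
  r <- torso_radius(p, (z - p$buttock_height_mm) / L, theta)
  pts <- cbind(x = as.vector(r * matrix(cos(theta), length(z), n_theta,
                                        byrow = TRUE)),
               y = as.vector(r * matrix(sin(theta), length(z), n_theta,
                                        byrow = TRUE)),
               z = rep(z, times = n_theta))
  scan <- list(points = pts,
               landmarks = list(neck_height_mm = p$neck_height_mm,
                                buttock_height_mm = p$buttock_height_mm),
               subject_id = 1L)
  class(scan) <- "labeled_scan"
  list(scan = scan, participant = p)
}

# A profile_set built directly from analytic contours (bypassing scans),
# e.g. circular sections of given radii at given heights.
make_profile_set <- function(radii_mm, torso_length_mm = 480,
                             n_per_band = 120) {
  n_bands <- length(radii_mm)
  centres <- (seq_len(n_bands) - 0.5) / n_bands * torso_length_mm
  theta <- 2 * pi * seq(0L, n_per_band - 1L) / n_per_band
  bands <- lapply(radii_mm, function(r) {
    cbind(r * cos(theta), r * sin(theta))
  })
  ps <- list(bands = bands, centre_mm = centres,
             t = centres / torso_length_mm,
             torso_length_mm = torso_length_mm,
             n_bands = as.integer(n_bands), band_thickness_mm = 2)
  class(ps) <- "profile_set"
  ps
}

# Circle contour sampled at M uniform angles (exact, no smoothing).
circle_contour <- function(radius = 1, M = 128, centre = c(0, 0)) {
  th <- 2 * pi * seq(0L, M - 1L) / M
  cbind(x = centre[1] + radius * cos(th), y = centre[2] + radius * sin(th))
}

ellipse_contour <- function(a = 2, b = 1, M = 128, phase = 0) {
  th <- 2 * pi * seq(0L, M - 1L) / M + phase
  cbind(x = a * cos(th), y = b * sin(th))
}

rotate_about_z <- function(pts, angle_rad) {
  cbind(x = pts[, 1] * cos(angle_rad) - pts[, 2] * sin(angle_rad),
        y = pts[, 1] * sin(angle_rad) + pts[, 2] * cos(angle_rad),
        z = pts[, 3])
}
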