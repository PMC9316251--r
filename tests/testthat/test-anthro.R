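test_that("girths of a circular cylinder match 2 pi r, waist equals stomach", {
  ps <- make_profile_set(rep(150, 25))
  rec <- extract_anthropometrics(ps, height_cm = 177.9)
  expect_equal(rec$waist_girth_cm, 2 * pi * 15, tolerance = 5e-3)
  expect_equal(rec$hip_girth_cm, rec$waist_girth_cm, tolerance = 1e-6)
  expect_equal(rec$stomach_girth_cm, rec$waist_girth_cm, tolerance = 1e-6)
  expect_equal(rec$chest_girth_cm, rec$waist_girth_cm, tolerance = 1e-6)
})

test_that("extracted waist girth agrees with the superellipse quadrature oracle", {
  fx <- make_band_centred_scan(a_mm = 115, b_mm = 160, rings_per_band = 3)
  truth <- torso_surface_truth(fx$participant)
  profs <- extract_band_profiles(segment_and_align(fx$scan, min_points = 100))
  rec <- extract_anthropometrics(profs, height_cm = fx$participant$height_cm)
  expect_lt(abs(rec$waist_girth_cm - truth$waist_girth_cm) /
              truth$waist_girth_cm, 0.005)
  expect_lt(abs(rec$torso_volume_l - truth$torso_volume_l) /
              truth$torso_volume_l, 0.02)
})

test_that("an hourglass profile places the waist at the mid-torso minimum", {
  radii <- 150 - 30 * exp(-((1:25 - 13) / 4)^2)
  rec <- extract_anthropometrics(make_profile_set(radii), height_cm = 170)
  expect_equal(rec$waist_band, 13L)
  expect_equal(rec$waist_girth_cm, 2 * pi * min(radii) / 10, tolerance = 1e-3)
  expect_gt(rec$stomach_girth_cm, rec$waist_girth_cm)
})

test_that("waist search fails when no mid-torso bands exist", {
  ps <- make_profile_set(rep(150, 3)) # reduced-band mode
  ps$t <- c(0.05, 0.1, 0.95)
  expect_error(extract_anthropometrics(ps, height_cm = 170),
               "waist search region empty")
})

test_that("volume and surface of cylinder and cone match analytic values", {
  heights <- seq(0, 500, length.out = 26)
  circ <- lapply(heights, function(h) circle_contour(radius = 100, M = 256))
  vs <- compute_volume_surface(circ, heights)
  expect_lt(abs(vs$volume_l - 15.70796) / 15.70796, 0.01)
  expect_lt(abs(vs$surface_area_m2 - 0.3141593) / 0.3141593, 0.01)

  h_cone <- seq(0, 300, length.out = 31)
  cone <- lapply(h_cone, function(h) {
    circle_contour(radius = max(100 * (1 - h / 300), 1e-9), M = 256)
  })
  vc <- compute_volume_surface(cone, h_cone)
  expect_lt(abs(vc$volume_l - 3.141593) / 3.141593, 0.02)

  expect_error(compute_volume_surface(circ[1], heights[1]), "at least 2")
  expect_error(compute_volume_surface(circ[1:3], c(0, 2, 1)), "increasing")
})

test_that("allometric normalization removes height dependence", {
  expect_equal(allometric_normalize(100, 10, beta = 2), 1)
  expect_equal(allometric_normalize(42.5, 180, beta = 0), 42.5)
  # exact power law: identical normalized values
  H <- c(160, 170, 180, 190)
  y <- 3.2 * H^1.7
  expect_equal(var(allometric_normalize(y, H, beta = 1.7)), 0)
  # cohort with independent residual scatter: no residual height correlation
  set.seed(9)
  H <- rnorm(5000, 177.9, 6.8)
  y <- exp(rnorm(5000, sd = 0.05)) * H^1.4
  expect_lt(abs(cor(allometric_normalize(y, H, beta = 1.4), H)), 0.05)
  expect_error(allometric_normalize(-1, 170), "positive")
})

test_that("derived parameter subsets follow the averaging and ratio rules", {
  ps <- make_profile_set(c(seq(160, 140, length.out = 13),
                           seq(141, 155, length.out = 12)))
  limbs <- list(
    thigh_girth_l_cm = 55, thigh_girth_r_cm = 57,
    bicep_girth_l_cm = 33, bicep_girth_r_cm = 35,
    leg_volume_l_l = 10, leg_volume_r_l = 10,
    arm_volume_l_l = 5, arm_volume_r_l = 5,
    leg_sa_l_m2 = 0.4, leg_sa_r_m2 = 0.5,
    arm_sa_l_m2 = 0.2, arm_sa_r_m2 = 0.3)
  rec <- extract_anthropometrics(ps, height_cm = 177.9, limbs = limbs)
  rec$torso_volume_l <- 40 # closed-form ratio check
  par <- derive_model_parameters(rec, normalize = FALSE)
  expect_equal(unname(par$size5["avg_thigh_girth"]), 56)
  expect_equal(unname(par$size5["avg_bicep_girth"]), 34)
  expect_equal(unname(par$volume5["torso_limbs_volume_ratio"]), 40 / 30,
               tolerance = 1e-12)
  expect_equal(unname(par$volume5["legs_arms_volume_ratio"]), 2)
  expect_length(par$size5, 5)
  expect_length(par$volume5, 5)
  expect_length(par$sa5, 5)

  # WHT.5R closed form: waist 90 cm at height 177.9
  rec2 <- rec
  expect_equal(90 / sqrt(177.9), 6.7478, tolerance = 1e-4)
  expect_equal(rec$wht5r, rec$waist_girth_cm / sqrt(177.9))

  bad <- rec
  bad$arm_volume_l_l <- 0; bad$arm_volume_r_l <- 0
  expect_error(derive_model_parameters(bad, normalize = FALSE),
               "denominator")
})

test_that("normalization defaults divide girths and volumes by height", {
  ps <- make_profile_set(c(seq(160, 140, length.out = 13),
                           seq(141, 155, length.out = 12)))
  limbs <- list(
    thigh_girth_l_cm = 56, thigh_girth_r_cm = 56,
    bicep_girth_l_cm = 34, bicep_girth_r_cm = 34,
    leg_volume_l_l = 10, leg_volume_r_l = 10,
    arm_volume_l_l = 5, arm_volume_r_l = 5,
    leg_sa_l_m2 = 0.45, leg_sa_r_m2 = 0.45,
    arm_sa_l_m2 = 0.25, arm_sa_r_m2 = 0.25)
  rec <- extract_anthropometrics(ps, height_cm = 180, limbs = limbs)
  par_n <- derive_model_parameters(rec, normalize = TRUE)
  par_r <- derive_model_parameters(rec, normalize = FALSE)
  expect_equal(unname(par_n$size5["hip_girth"]),
               unname(par_r$size5["hip_girth"]) / 180)
  expect_equal(unname(par_n$volume5["torso_volume"]),
               unname(par_r$volume5["torso_volume"]) / 180)
  # ratios and WHT.5R are left untouched
  expect_equal(par_n$volume5["legs_arms_volume_ratio"],
               par_r$volume5["legs_arms_volume_ratio"])
  expect_equal(par_n$size5["wht5r"], par_r$size5["wht5r"])
})
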