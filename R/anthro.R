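# Anthropometrics: girths, volumes, surface areas, allometric height
# normalization and the derived 5-parameter model subsets.

.contour_perimeter_mm <- function(contour) {
  contour <- unclass(contour)
  nxt <- c(2:nrow(contour), 1L)
  sum(sqrt((contour[, 1L] - contour[nxt, 1L])^2 +
           (contour[, 2L] - contour[nxt, 2L])^2))
}

.contour_area_mm2 <- function(contour) {
  contour <- unclass(contour)
  x <- contour[, 1L]; y <- contour[, 2L]
  nxt <- c(2:length(x), 1L)
  abs(sum(x * y[nxt] - x[nxt] * y)) / 2
}

#' Extract traditional anthropometrics from torso band profiles
#'
#' Girths are arc lengths of the smoothed band contours. The waist is the
#' minimum torso girth, searched over the mid-torso window (band centres
#' between 25% and 85% of torso length, away from the monotone taper at
#' the segment ends); the hip girth is taken at the lowest band (the
#' buttock level), the chest is the maximum girth of the upper torso
#' (centre height above 70% of torso length) and the stomach is the
#' maximum girth strictly between the hip and waist bands. Torso volume
#' and lateral surface area are integrated from the same contours, with
#' half-band extensions at both ends so the band centres cover the full
#' segment.
#'
#' @param profiles a `profile_set` in mm (unscaled).
#' @param height_cm participant stature; needed for WHT.5R.
#' @param limbs optional named list of limb measures to carry into the
#'   record: `thigh_girth_l_cm`, `thigh_girth_r_cm`, `bicep_girth_l_cm`,
#'   `bicep_girth_r_cm`, `leg_volume_l_l`, `leg_volume_r_l`,
#'   `arm_volume_l_l`, `arm_volume_r_l`, `leg_sa_l_m2`, `leg_sa_r_m2`,
#'   `arm_sa_l_m2`, `arm_sa_r_m2`.
#' @param M contour samples per band.
#' @param spar optional fixed smoothing parameter (NULL = GCV).
#' @return an object of class `anthro_record`: a list of girths (cm),
#'   torso length (cm), torso volume (L), torso surface area (m^2), limb
#'   measures, height and WHT.5R (waist girth / sqrt(height), cm^0.5).
#' @export
extract_anthropometrics <- function(profiles, height_cm, limbs = NULL,
                                    M = 128L, spar = NULL) {
  stopifnot(inherits(profiles, "profile_set"))
  if (inherits(profiles, "scaled_profile_set")) {
    stop("extract_anthropometrics needs unscaled profiles in mm")
  }
  contours <- lapply(profiles$bands, smooth_and_resample, M = M, spar = spar)
  girth_cm <- vapply(contours, .contour_perimeter_mm, 1.0) / 10

  # the waist (minimum torso girth) is searched in the mid-torso window,
  # away from the monotone taper at the hip and chest ends
  win <- which(profiles$t >= 0.25 & profiles$t <= 0.85)
  if (!length(win)) stop("waist search region empty")
  i_waist <- win[which.min(girth_cm[win])]
  waist <- girth_cm[i_waist]
  hip <- girth_cm[1L]
  upper <- profiles$t >= 0.7
  chest <- max(girth_cm[upper])
  stomach <- max(girth_cm[2:(i_waist - 1L)])

  vs <- compute_volume_surface(
    contours, profiles$centre_mm,
    end_extension_mm = rep(profiles$torso_length_mm / profiles$n_bands / 2, 2L))

  rec <- list(
    waist_girth_cm = waist, stomach_girth_cm = stomach,
    hip_girth_cm = hip, chest_girth_cm = chest,
    torso_length_cm = profiles$torso_length_mm / 10,
    torso_volume_l = vs$volume_l, torso_sa_m2 = vs$surface_area_m2,
    height_cm = height_cm,
    wht5r = waist / sqrt(height_cm),
    girth_by_band_cm = girth_cm, waist_band = i_waist
  )
  if (!is.null(limbs)) rec[names(limbs)] <- limbs
  class(rec) <- "anthro_record"
  rec
}

#' Volume and lateral surface area from a stack of cross-section contours
#'
#' Volume is the trapezoidal integral of the polygon cross-section areas
#' over height; the lateral surface is the sum of conical-frustum areas
#' between consecutive contours (mean perimeter times slant length, with
#' the slant computed from the change in effective radius). Optional end
#' extensions prolong the solid beyond the first and last contour with
#' constant section, for band stacks whose centres do not reach the
#' segment ends.
#'
#' @param contours list of M x 2 contour matrices (mm).
#' @param heights_mm strictly increasing contour heights (mm).
#' @param end_extension_mm length-2 extension below the first and above
#'   the last contour (mm).
#' @return list with `volume_l` and `surface_area_m2`.
#' @export
compute_volume_surface <- function(contours, heights_mm,
                                   end_extension_mm = c(0, 0)) {
  n <- length(contours)
  if (n < 2L) stop("need at least 2 contours to integrate")
  if (length(heights_mm) != n) stop("heights do not match contours")
  if (any(diff(heights_mm) <= 0)) stop("contour heights must be increasing")
  areas <- vapply(contours, .contour_area_mm2, 1.0)
  perims <- vapply(contours, .contour_perimeter_mm, 1.0)
  dz <- diff(heights_mm)
  vol <- sum((areas[-1L] + areas[-n]) / 2 * dz) +
    areas[1L] * end_extension_mm[1L] + areas[n] * end_extension_mm[2L]
  r_eff <- perims / (2 * pi)
  slant <- sqrt(dz^2 + diff(r_eff)^2)
  sa <- sum((perims[-1L] + perims[-n]) / 2 * slant) +
    perims[1L] * end_extension_mm[1L] + perims[n] * end_extension_mm[2L]
  list(volume_l = vol / 1e6, surface_area_m2 = sa / 1e6)
}

#' Allometric height normalization
#'
#' Removes the height dependence of a body measure under the allometric
#' model ln y = alpha + beta ln H by returning y / H^beta (the intercept
#' alpha is an additive constant in log space and preserves ordering, so
#' it is absorbed). Girths and lengths default to beta = 1; volumes and
#' surface areas are likewise normalized by height (beta = 1) because
#' published allometric exponents are not available for them. Per-measure
#' exponents from the literature can be supplied instead.
#'
#' @param y positive measure (vectorized).
#' @param height_cm positive stature.
#' @param beta allometric exponent.
#' @return y / height_cm^beta.
#' @export
allometric_normalize <- function(y, height_cm, beta = 1) {
  if (any(y <= 0) || any(height_cm <= 0)) {
    stop("allometric normalization needs positive inputs")
  }
  y / height_cm^beta
}

#' Derive the three 5-parameter model subsets from an anthropometric record
#'
#' Builds the parameter subsets used by the predictive models, designed to
#' minimise collinearity: size (hip girth, torso length, WHT.5R, average
#' thigh girth, average bicep girth), volumes (torso volume, average leg
#' and arm volumes, torso:limbs and legs:arms volume ratios) and surface
#' areas (analogous). Averages are means of the left and right sides; the
#' torso:limbs ratio divides the torso value by the summed limb values
#' (2 x average leg + 2 x average arm); legs:arms divides the two leg
#' values by the two arm values. When `normalize` is TRUE, girths,
#' lengths, volumes and surface areas are height-normalized
#' ([allometric_normalize()], exponents from `betas`); WHT.5R and the
#' ratios are already height-free.
#'
#' @param record an `anthro_record` with limb fields present.
#' @param normalize apply allometric height normalization.
#' @param betas named exponents (`girth`, `length`, `volume`, `sa`).
#' @return list with numeric vectors `size5`, `volume5`, `sa5` (5 named
#'   entries each).
#' @export
derive_model_parameters <- function(record, normalize = TRUE,
                                    betas = c(girth = 1, length = 1,
                                              volume = 1, sa = 1)) {
  stopifnot(inherits(record, "anthro_record"))
  need <- c("thigh_girth_l_cm", "thigh_girth_r_cm", "bicep_girth_l_cm",
            "bicep_girth_r_cm", "leg_volume_l_l", "leg_volume_r_l",
            "arm_volume_l_l", "arm_volume_r_l", "leg_sa_l_m2", "leg_sa_r_m2",
            "arm_sa_l_m2", "arm_sa_r_m2")
  miss <- setdiff(need, names(record))
  if (length(miss)) stop("record incomplete, missing: ",
                         paste(miss, collapse = ", "))
  H <- record$height_cm
  nz <- function(y, beta) if (normalize) allometric_normalize(y, H, beta) else y

  avg_thigh <- mean(c(record$thigh_girth_l_cm, record$thigh_girth_r_cm))
  avg_bicep <- mean(c(record$bicep_girth_l_cm, record$bicep_girth_r_cm))
  avg_leg_v <- mean(c(record$leg_volume_l_l, record$leg_volume_r_l))
  avg_arm_v <- mean(c(record$arm_volume_l_l, record$arm_volume_r_l))
  avg_leg_s <- mean(c(record$leg_sa_l_m2, record$leg_sa_r_m2))
  avg_arm_s <- mean(c(record$arm_sa_l_m2, record$arm_sa_r_m2))

  ratio <- function(num, den) {
    if (den <= 0) stop("zero or negative denominator in derived ratio")
    num / den
  }
  size5 <- c(
    hip_girth = nz(record$hip_girth_cm, betas[["girth"]]),
    torso_length = nz(record$torso_length_cm, betas[["length"]]),
    wht5r = record$wht5r,
    avg_thigh_girth = nz(avg_thigh, betas[["girth"]]),
    avg_bicep_girth = nz(avg_bicep, betas[["girth"]])
  )
  volume5 <- c(
    torso_volume = nz(record$torso_volume_l, betas[["volume"]]),
    avg_leg_volume = nz(avg_leg_v, betas[["volume"]]),
    avg_arm_volume = nz(avg_arm_v, betas[["volume"]]),
    torso_limbs_volume_ratio =
      ratio(record$torso_volume_l, 2 * avg_leg_v + 2 * avg_arm_v),
    legs_arms_volume_ratio = ratio(2 * avg_leg_v, 2 * avg_arm_v)
  )
  sa5 <- c(
    torso_sa = nz(record$torso_sa_m2, betas[["sa"]]),
    avg_leg_sa = nz(avg_leg_s, betas[["sa"]]),
    avg_arm_sa = nz(avg_arm_s, betas[["sa"]]),
    torso_limbs_sa_ratio =
      ratio(record$torso_sa_m2, 2 * avg_leg_s + 2 * avg_arm_s),
    legs_arms_sa_ratio = ratio(2 * avg_leg_s, 2 * avg_arm_s)
  )
  list(size5 = size5, volume5 = volume5, sa5 = sa5)
}
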