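# Body-composition reference measurements: air-displacement
# plethysmography (ADP) and segmental bioimpedance (BIA) emulation,
# including the repeat-measurement acceptance protocols.

# Density-equation coefficients, from the cited body-composition
# literature: fat fraction = a / density - b.
.DENSITY_EQ <- list(
  siri    = c(a = 4.950, b = 4.500), # white and Asian participants
  schutte = c(a = 4.374, b = 3.928), # Black participants
  brozek  = c(a = 4.570, b = 4.142)  # extremely lean or obese participants
)

#' Apply the ADP repeat-measurement acceptance rule
#'
#' With two body-volume readings the measurement is accepted as their
#' mean when they differ by at most 150 mL; a larger difference requires
#' a third reading. With three readings the mean of the closest pair is
#' reported (ties broken in favour of the earlier pair).
#'
#' @param readings numeric vector of 2 or 3 raw body-volume readings (L).
#' @return list with `volume_l` (NA while a third reading is required),
#'   `status` ("accepted" or "third_required"), `n_readings`, and
#'   `readings`.
#' @export
adp_accept_volume <- function(readings) {
  if (length(readings) < 2L) stop("need at least 2 volume readings")
  if (length(readings) > 3L) stop("at most 3 volume readings are taken")
  if (length(readings) == 2L) {
    if (abs(readings[1L] - readings[2L]) <= 0.150 + 1e-12) {
      return(list(volume_l = mean(readings), status = "accepted",
                  n_readings = 2L, readings = readings))
    }
    return(list(volume_l = NA_real_, status = "third_required",
                n_readings = 2L, readings = readings))
  }
  pairs <- rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  diffs <- abs(readings[pairs[, 1L]] - readings[pairs[, 2L]])
  best <- pairs[which.min(diffs), ]
  list(volume_l = mean(readings[best]), status = "accepted",
       n_readings = 3L, readings = readings)
}

#' Convert body density to fat percentage
#'
#' Two-compartment density equations: Siri (white and Asian participants),
#' Schutte (Black participants) and Brozek (extremely lean or obese
#' participants). All three are strictly decreasing in density. The
#' equation is chosen explicitly by tag; no automatic leanness threshold
#' is applied.
#'
#' @param density body density in kg/L, inside (0.9, 1.2).
#' @param equation one of "siri", "schutte", "brozek".
#' @return fat percentage (vectorized over `density`).
#' @export
density_to_fat_fraction <- function(density,
                                    equation = c("siri", "schutte", "brozek")) {
  equation <- match.arg(equation)
  if (any(density <= 0.9) || any(density >= 1.2)) {
    stop("body density outside the plausible range (0.9, 1.2) kg/L")
  }
  cf <- .DENSITY_EQ[[equation]]
  (cf[["a"]] / density - cf[["b"]]) * 100
}

# Inverse of the density equation: density implied by a fat percentage.
.fat_fraction_to_density <- function(fat_pct, equation = "siri") {
  cf <- .DENSITY_EQ[[equation]]
  cf[["a"]] / (fat_pct / 100 + cf[["b"]])
}

#' Emulate the ADP and BIA reference measurements for one participant
#'
#' ADP: the participant's true body volume (mass over the density implied
#' by the true fat fraction) is read with Gaussian noise; a third reading
#' is simulated when the first two differ by more than 150 mL, and the
#' acceptance rule of [adp_accept_volume()] is applied. Density is mass
#' over accepted volume and fat percentage follows from the selected
#' density equation.
#'
#' BIA: the true segmental fat masses (trunk, left/right arm, left/right
#' leg) are each read twice with Gaussian noise and averaged; the
#' trunk:peripheral fat ratio is the averaged trunk fat over the sum of
#' the four averaged limb fats.
#'
#' Uses the current RNG state. With zero noise both measured values equal
#' the generator truth exactly.
#'
#' @param p a `synthetic_participant`.
#' @param config a [generator_config()]; `adp_noise_sd_l` and
#'   `bia_noise_sd_kg` are honoured.
#' @param equation density equation tag.
#' @return list with elements `adp` (readings, accepted volume, density,
#'   `fat_pct`, equation, n_readings) and `bia` (repeat matrices, averaged
#'   segment fats, `tpfr`).
#' @export
emulate_measurements <- function(p, config, equation = "siri") {
  stopifnot(inherits(p, "synthetic_participant"),
            inherits(config, "generator_config"))
  true_density <- .fat_fraction_to_density(p$true_fat_pct, equation)
  true_volume <- p$weight_kg / true_density

  readings <- true_volume + rnorm(2L, sd = config$adp_noise_sd_l)
  acc <- adp_accept_volume(readings)
  if (acc$status == "third_required") {
    readings <- c(readings, true_volume + rnorm(1L, sd = config$adp_noise_sd_l))
    acc <- adp_accept_volume(readings)
  }
  density <- p$weight_kg / acc$volume_l
  fat_pct <- density_to_fat_fraction(density, equation)

  seg_true <- c(trunk = p$trunk_fat_kg,
                arm_l = p$arm_fat_l_kg, arm_r = p$arm_fat_r_kg,
                leg_l = p$leg_fat_l_kg, leg_r = p$leg_fat_r_kg)
  rep1 <- pmax(seg_true + rnorm(5L, sd = config$bia_noise_sd_kg), 0.01)
  rep2 <- pmax(seg_true + rnorm(5L, sd = config$bia_noise_sd_kg), 0.01)
  seg_avg <- (rep1 + rep2) / 2
  tpfr <- seg_avg[["trunk"]] / sum(seg_avg[c("arm_l", "arm_r",
                                             "leg_l", "leg_r")])

  list(
    adp = list(readings = acc$readings, volume_l = acc$volume_l,
               density = density, fat_pct = fat_pct,
               equation = equation, n_readings = acc$n_readings),
    bia = list(rep1 = rep1, rep2 = rep2, segments_kg = seg_avg, tpfr = tpfr)
  )
}
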