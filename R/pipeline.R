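# End-to-end drivers: scan -> features/anthropometrics for one subject,
# reference-basis fitting, cohort simulation and the six-model comparison.

#' Process one labeled scan into shape features and anthropometrics
#'
#' Runs the geometric chain (segmentation and alignment, 25-band
#' extraction, centroid-size scaling) and returns the 500-entry Fourier
#' feature vector together with the anthropometric record extracted from
#' the unscaled bands.
#'
#' @param scan a `labeled_scan`.
#' @param height_cm participant stature (cm), for WHT.5R.
#' @param limbs optional limb measures forwarded to
#'   [extract_anthropometrics()].
#' @param M contour samples per band.
#' @param spar optional fixed smoothing parameter (NULL = GCV).
#' @return list with `features` (length-500), `anthro` (an
#'   `anthro_record`), `centroid_size`, `torso_length_mm`.
#' @export
process_scan <- function(scan, height_cm, limbs = NULL, M = 128L,
                         spar = NULL) {
  seg <- segment_and_align(scan)
  profiles <- extract_band_profiles(seg)
  scaled <- centroid_size_scale(profiles)
  features <- torso_feature_vector(scaled, M = M, spar = spar)
  anthro <- extract_anthropometrics(profiles, height_cm = height_cm,
                                    limbs = limbs, M = M, spar = spar)
  list(features = features, anthro = anthro,
       centroid_size = scaled$centroid_size,
       torso_length_mm = profiles$torso_length_mm)
}

.limb_truth <- function(p) {
  p[c("thigh_girth_l_cm", "thigh_girth_r_cm", "bicep_girth_l_cm",
      "bicep_girth_r_cm", "leg_volume_l_l", "leg_volume_r_l",
      "arm_volume_l_l", "arm_volume_r_l", "leg_sa_l_m2", "leg_sa_r_m2",
      "arm_sa_l_m2", "arm_sa_r_m2")]
}

#' Fit the PCA shape basis on a synthetic reference cohort
#'
#' Generates a reference cohort (independent of any study cohort through
#' its own seed), runs every subject through the full scan-to-features
#' chain and fits the 10-component basis. Mirrors the use of externally
#' derived eigenvectors: study cohorts are projected onto this frozen
#' basis, which is why their PC scores are not exactly uncorrelated.
#'
#' @param config a [generator_config()]; `n_reference` and `seed` are
#'   honoured.
#' @param k number of components.
#' @return a `shape_basis`.
#' @export
fit_reference_basis <- function(config, k = 10L) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  feats <- matrix(NA_real_, config$n_reference, 500L)
  for (i in seq_len(config$n_reference)) {
    p <- generate_participant(config, id = i)
    scan <- render_scan(p, config)
    feats[i, ] <- process_scan(scan, p$height_cm)$features
  }
  fit_shape_basis(feats, k = k)
}

#' Simulate a complete study cohort through the full pipeline
#'
#' For every participant: generate the parametric body, render the scan,
#' run the geometric and feature chains, extract anthropometrics (limb
#' measures taken from generator truth, the fast mode for synthetic limb
#' cylinders), emulate the ADP and BIA reference measurements, and project
#' the shape features onto the (reference) PCA basis. Scans are processed
#' streaming; point clouds are not retained.
#'
#' @param config a [generator_config()] for the study cohort.
#' @param basis a `shape_basis`; when NULL one is fitted on a reference
#'   cohort of `config$n_reference` subjects with seed
#'   `config$seed + 999983`.
#' @param equation ADP density equation tag.
#' @return list with `params` (data frame: id, the 15 size/volume/SA
#'   parameters, PC1..PC10, `fat_pct`, `tpfr`), `truth` (ground-truth
#'   data frame), `basis`, `config`.
#' @export
simulate_study <- function(config, basis = NULL, equation = "siri") {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(basis)) {
    ref_cfg <- config
    ref_cfg$seed <- config$seed + 999983L
    basis <- fit_reference_basis(ref_cfg)
  }
  n <- config$n_subjects
  set.seed(config$seed)
  feats <- matrix(NA_real_, n, 500L)
  rows <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    p <- generate_participant(config, id = i)
    scan <- render_scan(p, config)
    pr <- process_scan(scan, p$height_cm, limbs = .limb_truth(p))
    meas <- emulate_measurements(p, config, equation = equation)
    feats[i, ] <- pr$features
    par <- derive_model_parameters(pr$anthro)
    rows[[i]] <- data.frame(
      id = p$id, t(par$size5), t(par$volume5), t(par$sa5),
      fat_pct = meas$adp$fat_pct, tpfr = meas$bia$tpfr)
    truth[[i]] <- data.frame(
      id = p$id, height_cm = p$height_cm, weight_kg = p$weight_kg,
      bmi = p$bmi, A = p$A, C = p$C, s_L = p$s_L, s_S = p$s_S,
      true_fat_pct = p$true_fat_pct, true_tpfr = p$true_tpfr)
  }
  params <- do.call(rbind, rows)
  scores <- project_to_shape_params(feats, basis)
  params <- cbind(params, as.data.frame(scores))
  list(params = params, truth = do.call(rbind, truth), basis = basis,
       config = config)
}

.PC_COLS <- paste0("PC", 1:10)
.SIZE5 <- c("hip_girth", "torso_length", "wht5r", "avg_thigh_girth",
            "avg_bicep_girth")
.VOL5 <- c("torso_volume", "avg_leg_volume", "avg_arm_volume",
           "torso_limbs_volume_ratio", "legs_arms_volume_ratio")
.SA5 <- c("torso_sa", "avg_leg_sa", "avg_arm_sa", "torso_limbs_sa_ratio",
          "legs_arms_sa_ratio")

#' Fit and evaluate the six model types for the two dependents
#'
#' Reproduces the model-comparison design: for each dependent variable
#' (body-fat percentage and trunk:peripheral fat ratio) fits shape-only
#' (10 PCs), the two size-only models (5 anthropometrics + 5 surface
#' areas, 5 anthropometrics + 5 volumes) and the three shape-augmented
#' models (size subset + the best 5-of-10 PC subset from the exhaustive
#' 252-subset search), all through the stepwise AIC procedure, and
#' evaluates each by adjusted R^2, training RMSE and seeded 10-fold CV
#' RMSE.
#'
#' @param params the `params` data frame from [simulate_study()] (or any
#'   table with the same columns).
#' @param dependents dependents to model.
#' @param models model types to fit.
#' @param cv_seed seed of the CV fold partition.
#' @return a `comparison_report` with an extra `fits` element (named list
#'   of `torso_model`) and `weights` (named list of relative-weight
#'   tables).
#' @export
run_model_comparison <- function(params,
                                 dependents = c("fat_pct", "tpfr"),
                                 models = c("shape_only", "anthro_sa",
                                            "anthro_vol", "anthro_shape",
                                            "shape_sa", "shape_vol"),
                                 cv_seed = 1L) {
  shape <- params[.PC_COLS]
  size_sets <- list(anthro = params[.SIZE5], vol = params[.VOL5],
                    sa = params[.SA5])
  rows <- list()
  fits <- list()
  weights <- list()
  for (dep in dependents) {
    y <- params[[dep]]
    for (mt in models) {
      subset_lab <- NA_character_
      if (mt == "shape_only") {
        fit <- stepwise_fit(y, shape)
      } else if (mt == "anthro_sa") {
        fit <- stepwise_fit(y, cbind(size_sets$anthro, size_sets$sa))
      } else if (mt == "anthro_vol") {
        fit <- stepwise_fit(y, cbind(size_sets$anthro, size_sets$vol))
      } else {
        size <- switch(mt, anthro_shape = size_sets$anthro,
                       shape_sa = size_sets$sa, shape_vol = size_sets$vol)
        bs <- best_shape_subset(y, shape, size)
        fit <- bs$fit
        subset_lab <- paste(bs$subset, collapse = " ")
      }
      ev <- evaluate_model(fit, seed = cv_seed)
      key <- paste(dep, mt, sep = ".")
      fits[[key]] <- fit
      weights[[key]] <- relative_weights(fit)
      rows[[key]] <- data.frame(
        dependent = dep, model = mt, adj_r2 = ev$adjusted_r2,
        rmse = ev$rmse, cv_rmse = ev$cv_rmse, n_terms = ev$p,
        shape_subset = subset_lab)
    }
  }
  rep <- comparison_report(do.call(rbind, rows))
  rep$fits <- fits
  rep$weights <- weights
  rep
}
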