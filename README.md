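# torsoshape

Quantifying human torso **shape** — not just size — from 3D body-scan
point clouds, and testing whether shape improves linear predictive
models of body-fat magnitude and distribution.

Central obesity drives metabolic-syndrome risk, but traditional
anthropometrics (waist girth, WHT.5R = waist/&radic;height, BMI)
summarise body size and are limited predictors of how fat is
*distributed*. This package implements a complete, reproducible
pipeline for the alternative: geometric-morphometric shape descriptors
of the torso.

For a torso segment between the buttock landmark and the xiphoid
process (at 60% of the buttock-to-neck distance), the pipeline

1. aligns the scan to the anatomical frame and extracts **25
   cross-section bands** (2 mm thick, uniformly spaced), rescaled by
   **centroid size** to remove scale;
2. fits periodic cubic smoothing splines to each band contour and keeps
   the **10 lowest-frequency complex Fourier coefficients** per band
   (frequencies 0, ±1, ±2, ±3, ±4, +5 of the complex contour
   *z* = *x* + i*y*), i.e. 250 complex coefficients per torso;
3. projects the 500-entry feature vector onto a frozen 10-component PCA
   basis fitted on a reference cohort, giving shape parameters
   **PC1–PC10**;
4. extracts traditional anthropometrics (girths, torso length, WHT.5R,
   volumes, surface areas; allometrically height-normalized,
   *y*/H<sup>β</sup>) and emulates the reference measurements: ADP
   body-fat percentage (Siri/Schutte/Brozek density equations, 150 mL
   repeat-acceptance rule) and BIA trunk:peripheral fat ratio (TPFR);
5. fits and compares **six model types** per dependent variable, each
   with 10 base parameters — shape-only, anthropometrics+surface-areas,
   anthropometrics+volumes, and three shape-augmented types whose 5
   shape parameters come from an exhaustive search of all
   C(10,5) = 252 subsets — via **stepwise AIC regression** with
   pairwise-interaction candidates, reporting adjusted R², RMSE,
   seeded 10-fold cross-validated RMSE and **Johnson relative weights**.

A synthetic-cohort generator (superellipse torso surfaces with
harmonic cross-section perturbations, latent adiposity/centrality/shape
factors, 2 mm scanner noise, calibrated to an adult-male cohort:
height 177.9 (6.8) cm, fat 21.02 (7.82) %, TPFR 1.57 (0.22)) makes the
whole pipeline testable without any scanner data. See the methods
vignette (`vignettes/torso-shape-methods.Rmd`) for the model,
assumptions and numerical choices.

## Worked example

```r
library(torsoshape)

cfg   <- generator_config(n_subjects = 150, seed = 11, n_reference = 100)
study <- simulate_study(cfg)          # scans -> features -> PCs -> measurements
rep   <- run_model_comparison(study$params, cv_seed = 11)
print(rep)
```

```
Model comparison
================
 dependent        model adj_r2  rmse cv_rmse n_terms shape_subset          group
   fat_pct   shape_only 0.8094 2.990   3.240      12         <NA>     shape_only
   fat_pct    anthro_sa 0.5264 4.780   5.060       8         <NA>      size_only
   fat_pct   anthro_vol 0.5598 4.650   4.860       5         <NA>      size_only
   fat_pct anthro_shape 0.8546 2.590   2.880      14    3 4 5 6 8 size_and_shape
   fat_pct     shape_sa 0.8496 2.610   2.930      16    1 3 5 6 8 size_and_shape
   fat_pct    shape_vol 0.8458 2.700   2.920      11    1 2 3 4 5 size_and_shape
      tpfr   shape_only 0.7498 0.111   0.128      14         <NA>     shape_only
      tpfr    anthro_sa 0.4329 0.171   0.184       8         <NA>      size_only
      tpfr   anthro_vol 0.4005 0.176   0.194       8         <NA>      size_only
      tpfr anthro_shape 0.7440 0.112   0.130      14    2 3 4 6 7 size_and_shape
      tpfr     shape_sa 0.7248 0.115   0.133      17    2 5 6 7 8 size_and_shape
      tpfr    shape_vol 0.7517 0.110   0.126      15    1 2 5 6 7 size_and_shape

Group aggregates (recomputed from the rows above)
 dependent          group n_models mean_adj_r2 mean_cv_inflation_pct
   fat_pct     shape_only        1      0.8094                   8.3
   fat_pct      size_only        2      0.5431                   5.2
   fat_pct size_and_shape        3      0.8500                  10.5
      tpfr     shape_only        1      0.7498                  15.0
      tpfr      size_only        2      0.4167                   9.1
      tpfr size_and_shape        3      0.7401                  15.1
```

Reading the output: every row is one stepwise-selected model
(`n_terms` selected terms, interactions included); `shape_subset` shows
which 5 of the 10 PCs won the 252-subset search. The aggregates carry
the scientific conclusion: shape-augmented models beat the size-only
models for both dependents (here adjusted R² 0.850 vs 0.543 for fat%,
0.740 vs 0.417 for TPFR), with a larger gain for fat distribution
(+0.32) than for fat magnitude (+0.31) — at the acceptance-scale
cohort (n = 500) the contrast is sharper, +0.40 vs +0.24. Size alone is
a reasonable proxy for how much fat there is; the small-scale shape
information is what predicts where it sits.

Term importance for any fitted model:

```r
top_weights_table(rep$weights[["tpfr.anthro_shape"]], k = 3)
#>              term raw_weight pct_weight      p_value
#> 1       hip_girth  0.1634941   21.28749 9.496085e-25
#> 2   hip_girth:PC7  0.1097231   14.28632 3.157815e-02
#> 3 avg_bicep_girth  0.1096943   14.28257 9.424039e-04
```

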