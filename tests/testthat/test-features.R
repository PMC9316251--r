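test_that("spline contour reproduces a noise-free circle", {
  set.seed(1)
  th <- sort(runif(200, 0, 2 * pi))
  pts <- cbind(cos(th), sin(th))
  ct <- smooth_and_resample(pts, M = 96)
  r <- sqrt(rowSums(unclass(ct)^2))
  expect_lt(max(abs(r - 1)), 1e-6)
})

test_that("smoothing reduces the radial noise of a noisy circle", {
  set.seed(2)
  th <- sort(runif(300, 0, 2 * pi))
  r_noisy <- 1 + rnorm(300, sd = 0.02)
  pts <- cbind(r_noisy * cos(th), r_noisy * sin(th))
  ct <- smooth_and_resample(pts, M = 128)
  rms_raw <- sqrt(mean((r_noisy - 1)^2))
  r_fit <- sqrt(rowSums(sweep(unclass(ct), 2, attr(ct, "centroid"))^2))
  rms_fit <- sqrt(mean((r_fit - 1)^2))
  expect_lt(rms_fit, rms_raw)
})

test_that("a broken arc raises the angular-gap error", {
  th <- seq(0, 1.5 * pi, length.out = 150) # 270 degree coverage
  pts <- cbind(cos(th), sin(th))
  expect_error(smooth_and_resample(pts), "gap")
  expect_error(smooth_and_resample(pts[1:5, ]), "at least 8")
})

test_that("Fourier descriptors match closed forms for circle and ellipse", {
  fd <- fourier_descriptors(circle_contour(radius = 1))
  expect_equal(Mod(fd[["f+1"]]), 1, tolerance = 1e-12)
  expect_lt(max(Mod(fd[names(fd) != "f+1"])), 1e-9)

  fe <- fourier_descriptors(ellipse_contour(a = 2, b = 1))
  expect_equal(fe[["f+1"]], 1.5 + 0i, tolerance = 1e-12)
  expect_equal(fe[["f-1"]], 0.5 + 0i, tolerance = 1e-12)
  expect_lt(max(Mod(fe[!names(fe) %in% c("f+1", "f-1")])), 1e-9)
})

test_that("translation moves only the frequency-0 coefficient", {
  base <- ellipse_contour(a = 2, b = 1)
  shifted <- sweep(base, 2, c(-0.7, 1.3), `+`)
  f0 <- fourier_descriptors(base)
  f1 <- fourier_descriptors(shifted)
  expect_equal(f1[["f0"]] - f0[["f0"]], -0.7 + 1.3i, tolerance = 1e-12)
  expect_equal(f1[-1], f0[-1], tolerance = 1e-12)
})

test_that("rotating the traversal start multiplies coefficient k by exp(i k phi)", {
  M <- 128
  th <- 2 * pi * seq(0L, M - 1L) / M
  shape <- function(t) {
    cbind(2 * cos(t) + 0.1 * cos(3 * t), 1.2 * sin(t) + 0.1 * sin(3 * t))
  }
  phi <- 2 * pi * 5 / M # a grid-compatible shift
  f0 <- fourier_descriptors(shape(th))
  f1 <- fourier_descriptors(shape(th + phi))
  for (k in c(1, -1, 2, -2)) {
    lab <- paste0("f", ifelse(k > 0, "+", ""), k)
    expect_equal(f1[[lab]], f0[[lab]] * exp(1i * k * phi), tolerance = 1e-10)
  }
})

test_that("every torso yields exactly 250 complex (500 real) features", {
  fx <- make_band_centred_scan(rings_per_band = 3)
  scaled <- centroid_size_scale(extract_band_profiles(
    segment_and_align(fx$scan, min_points = 100)))
  fv <- torso_feature_vector(scaled)
  expect_length(fv, 500)
  expect_true(all(is.finite(fv)))
  expect_match(names(fv)[1], "b01_f0_re")
  expect_match(names(fv)[500], "b25_fp5_im")
})

test_that("the 10 kept coefficients preserve the area of ellipse-like sections", {
  ct <- ellipse_contour(a = 1.8, b = 1.1)
  fd <- fourier_descriptors(ct)
  rec <- fourier_reconstruct(fd, M = 256)
  area <- function(m) {
    nxt <- c(2:nrow(m), 1)
    abs(sum(m[, 1] * m[nxt, 2] - m[nxt, 1] * m[, 2])) / 2
  }
  expect_lt(abs(area(rec) - area(ct)) / area(ct), 0.02)
})

test_that("PCA basis recovers a planted direction and stays orthonormal", {
  set.seed(3)
  dir <- rnorm(500); dir <- dir / sqrt(sum(dir^2))
  X <- outer(rnorm(60, sd = 3), dir) +
    matrix(rnorm(60 * 500, sd = 1e-4), 60, 500)
  basis <- fit_shape_basis(X, k = 10)
  expect_gt(abs(sum(basis$loadings[, 1] * dir)), 0.999)
  expect_lt(sum(basis$eigenvalues[2:10]), 0.01 * basis$eigenvalues[1])

  set.seed(4)
  Y <- matrix(rnorm(600 * 500), 600, 500)
  b2 <- fit_shape_basis(Y, k = 10)
  gram <- crossprod(b2$loadings)
  expect_lt(max(abs(gram - diag(10))), 1e-8)
  expect_true(all(diff(b2$eigenvalues) <= 1e-12))
})

test_that("the basis is invariant to row permutation", {
  set.seed(5)
  X <- matrix(rnorm(80 * 500), 80, 500) +
    outer(rnorm(80, sd = 2), rnorm(500))
  b1 <- fit_shape_basis(X, k = 5)
  b2 <- fit_shape_basis(X[sample(80), ], k = 5)
  expect_equal(b1$loadings, b2$loadings, tolerance = 1e-8)
  expect_equal(b1$mean, b2$mean)
})

test_that("basis fitting validates its inputs", {
  expect_error(fit_shape_basis(matrix(rnorm(5 * 500), 5, 500), k = 10),
               "more than k")
  X <- matrix(rnorm(20 * 500), 20, 500)
  X[3, 7] <- NA
  expect_error(fit_shape_basis(X, k = 2), "non-finite")
})

test_that("projection identities: centring and reconstruction", {
  set.seed(6)
  X <- matrix(rnorm(40 * 500), 40, 500) + outer(rnorm(40, sd = 2), rnorm(500))
  basis <- fit_shape_basis(X, k = 10)
  expect_equal(max(abs(project_to_shape_params(basis$mean, basis))), 0,
               tolerance = 1e-9)
  f <- basis$mean + 2 * basis$loadings[, 3]
  sc <- drop(project_to_shape_params(f, basis))
  expect_equal(unname(sc[3]), 2, tolerance = 1e-9)
  expect_lt(max(abs(sc[-3])), 1e-9)
  expect_error(project_to_shape_params(rnorm(499), basis), "does not match")
})

test_that("PC scores of a foreign cohort are correlated, unlike the fitting cohort", {
  set.seed(7)
  struct <- matrix(rnorm(500 * 6), 500, 6)
  fit_X <- matrix(rnorm(150 * 6), 150, 6) %*% t(struct) +
    matrix(rnorm(150 * 500, sd = 0.05), 150, 500)
  basis <- fit_shape_basis(fit_X, k = 6)
  own <- project_to_shape_params(fit_X, basis)
  own_cor <- cor(own)
  expect_lt(max(abs(own_cor[upper.tri(own_cor)])), 0.05)
  # a cohort drawn with a different latent covariance
  lat <- matrix(rnorm(150 * 6), 150, 6)
  lat[, 2] <- 0.8 * lat[, 1] + 0.6 * lat[, 2]
  other_X <- lat %*% t(struct) +
    matrix(rnorm(150 * 500, sd = 0.05), 150, 500)
  oth_cor <- cor(project_to_shape_params(other_X, basis))
  expect_gt(max(abs(oth_cor[upper.tri(oth_cor)])), 0.2)
})

test_that("shape basis survives a JSON round trip", {
  set.seed(8)
  X <- matrix(rnorm(30 * 500), 30, 500)
  basis <- fit_shape_basis(X, k = 4)
  tmp <- file.path(tempdir(), "basis_test.json")
  write_shape_basis(basis, tmp)
  back <- read_shape_basis(tmp)
  expect_equal(back$loadings, basis$loadings, ignore_attr = TRUE)
  expect_equal(unname(back$mean), unname(basis$mean))
  expect_equal(back$eigenvalues, basis$eigenvalues)
  unlink(tmp)
})
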