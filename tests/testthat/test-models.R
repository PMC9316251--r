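test_that("collinearity matrix behaves on identities and degenerate input", {
  set.seed(30)
  x <- rnorm(50)
  d <- data.frame(a = x, b = -x, c = rnorm(50))
  cm <- pearson_collinearity(d)
  expect_equal(unname(diag(cm)), rep(1, 3))
  expect_equal(cm["a", "b"], -1)
  expect_equal(cm, t(cm))
  expect_error(pearson_collinearity(data.frame(a = x, z = rep(1, 50))),
               "zero-variance")
  expect_error(pearson_collinearity(d[1:2, ]), "at least 3")
})

test_that("stepwise recovers a true main-effects model without interactions", {
  set.seed(31)
  n <- 200
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  y <- 2 * d$x1 + 3 * d$x2 + rnorm(n, sd = 0.01)
  fit <- stepwise_fit(y, d)
  expect_setequal(fit$terms, c("x1", "x2"))
  cf <- coef(fit$fit)
  expect_lt(abs(cf[["x1"]] - 2) / 2, 0.01)
  expect_lt(abs(cf[["x2"]] - 3) / 3, 0.01)
})

test_that("stepwise adds a planted pairwise interaction", {
  set.seed(32)
  n <- 150
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  y <- d$x1 + 0.5 * d$x2 + 2 * d$x1 * d$x2 + rnorm(n, sd = 0.3)
  fit <- stepwise_fit(y, d)
  expect_true("x1:x2" %in% fit$terms)
})

test_that("search AIC equals the lm AIC of the selected model", {
  set.seed(33)
  n <- 120
  d <- as.data.frame(matrix(rnorm(n * 4), n, 4))
  names(d) <- paste0("p", 1:4)
  y <- d$p1 - d$p2 + 0.8 * d$p1 * d$p3 + rnorm(n, sd = 0.5)
  fit <- stepwise_fit(y, d)
  expect_equal(fit$aic, AIC(fit$fit))
  expect_equal(fit$aic_trace$aic[nrow(fit$aic_trace)], AIC(fit$fit),
               tolerance = 1e-8)
})

test_that("the AIC path is invariant to rescaling of the predictors", {
  set.seed(34)
  n <- 100
  d <- as.data.frame(matrix(rnorm(n * 5), n, 5))
  names(d) <- paste0("p", 1:5)
  y <- d$p1 + 2 * d$p2 * d$p4 + rnorm(n, sd = 0.4)
  f1 <- stepwise_fit(y, d)
  d2 <- as.data.frame(mapply(`*`, d, c(10, 0.01, 5, 100, 0.2)))
  f2 <- stepwise_fit(y, d2)
  expect_identical(f1$terms, f2$terms)
  expect_equal(f1$aic_trace$aic, f2$aic_trace$aic, tolerance = 1e-6)
})

test_that("stepwise validates rank and sample size", {
  set.seed(35)
  d <- data.frame(x1 = rnorm(30))
  d$x2 <- d$x1
  expect_error(stepwise_fit(rnorm(30), d), "rank deficient")
  expect_error(stepwise_fit(rnorm(5), data.frame(a = rnorm(5),
                                                 b = rnorm(5),
                                                 c = rnorm(5),
                                                 d = rnorm(5))),
               "need n")
})

test_that("subset search enumerates 252 candidates and finds planted PCs", {
  set.seed(36)
  n <- 120
  shape <- as.data.frame(matrix(rnorm(n * 10), n, 10))
  names(shape) <- paste0("PC", 1:10)
  size <- as.data.frame(matrix(rnorm(n * 5), n, 5))
  names(size) <- paste0("s", 1:5)
  y <- 2 * shape$PC2 + 1.5 * shape$PC7 + 0.5 * size$s1 + rnorm(n, sd = 0.4)
  bs <- best_shape_subset(y, shape, size)
  expect_equal(bs$n_evaluated, 252L)
  expect_equal(ncol(combn(10, 5)), 252L)
  expect_true(all(c(2, 7) %in% bs$subset))
  expect_length(bs$subset, 5)
})

test_that("subset search on pure noise is deterministic across reruns", {
  set.seed(37)
  n <- 60
  shape <- as.data.frame(matrix(rnorm(n * 10), n, 10))
  names(shape) <- paste0("PC", 1:10)
  size <- as.data.frame(matrix(rnorm(n * 5), n, 5))
  names(size) <- paste0("s", 1:5)
  y <- rnorm(n)
  b1 <- best_shape_subset(y, shape, size)
  b2 <- best_shape_subset(y, shape, size)
  expect_identical(b1$subset, b2$subset)
  expect_identical(b1$mse, b2$mse)
})

test_that("adjusted R^2 matches its closed form and the degenerate fit", {
  expect_equal(adjusted_r2(0.8, 93, 10), 1 - 0.2 * 92 / 82)
  expect_equal(round(adjusted_r2(0.8, 93, 10), 5), 0.77561)
  set.seed(38)
  d <- data.frame(x1 = rnorm(40), x2 = rnorm(40))
  y <- 1 + d$x1 - d$x2 # residuals exactly zero
  fit <- stepwise_fit(y, d)
  ev <- suppressWarnings(evaluate_model(fit, k = 5, seed = 1))
  expect_lt(ev$rmse, 1e-8)
  expect_equal(ev$adjusted_r2, 1, tolerance = 1e-10)
  expect_error(evaluate_model(fit, k = 50), "at least k")
})

test_that("cross-validated RMSE exceeds training RMSE for overfit noise models", {
  set.seed(39)
  n <- 60
  d <- as.data.frame(matrix(rnorm(n * 8), n, 8))
  names(d) <- paste0("p", 1:8)
  y <- rnorm(n)
  fit <- stepwise_fit(y, d)
  ratios <- vapply(1:8, function(s) {
    ev <- evaluate_model(fit, k = 10, seed = s)
    ev$cv_rmse / ev$rmse
  }, 1.0)
  expect_gt(mean(ratios), 1)
})

test_that("relative weights reduce to squared correlations for orthogonal terms", {
  set.seed(40)
  n <- 80
  Q <- qr.Q(qr(matrix(rnorm(n * 4), n, 4)))
  Q <- sweep(Q, 2, colMeans(Q)) # exactly orthogonal, centred columns
  d <- as.data.frame(Q)
  names(d) <- paste0("q", 1:4)
  y <- drop(Q %*% c(3, 2, 1, 0.5)) + rnorm(n, sd = 0.2)
  fit <- stepwise_fit(y, d, interactions = FALSE)
  rw <- relative_weights(fit)
  r2 <- summary(fit$fit)$r.squared
  expect_equal(sum(rw$raw_weight), r2, tolerance = 1e-6)
  r_sq <- vapply(names(d), function(v) cor(d[[v]], y)^2, 1.0)
  expect_equal(rw$raw_weight[match(names(d), rw$term)], unname(r_sq),
               tolerance = 1e-2)
  expect_equal(sum(rw$pct_weight), 100, tolerance = 1e-6)
})

test_that("near-duplicated drivers share their relative weight equally", {
  set.seed(41)
  n <- 200
  x <- rnorm(n)
  d <- data.frame(a = x, b = x + rnorm(n, sd = 1e-3), c = rnorm(n))
  y <- 2 * x + rnorm(n, sd = 0.3)
  # keep both near-duplicates in the model: disable backward removal
  fit <- stepwise_fit(y, d, interactions = FALSE, drop_tol = Inf)
  rw <- relative_weights(fit)
  wa <- rw$raw_weight[rw$term == "a"]
  wb <- rw$raw_weight[rw$term == "b"]
  expect_lt(abs(wa - wb) / wa, 0.02)
  expect_equal(sum(rw$raw_weight), summary(fit$fit)$r.squared,
               tolerance = 1e-6)
})

test_that("raw weights always sum to the model R^2", {
  set.seed(42)
  n <- 90
  d <- as.data.frame(matrix(rnorm(n * 6), n, 6))
  names(d) <- paste0("v", 1:6)
  y <- d$v1 + 0.5 * d$v2 * d$v3 + rnorm(n)
  fit <- stepwise_fit(y, d)
  rw <- relative_weights(fit)
  expect_equal(sum(rw$raw_weight), summary(fit$fit)$r.squared,
               tolerance = 1e-6)
  expect_true(all(rw$raw_weight >= 0))
})
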