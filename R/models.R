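# Model engine: collinearity screening, stepwise AIC regression with
# pairwise interaction candidates, exhaustive 5-of-10 shape-subset
# search, adjusted R^2 / RMSE / 10-fold CV, and Johnson relative weights.

#' Pearson collinearity matrix
#'
#' Product-moment correlations between all parameter columns, used to
#' screen collinearity before model building.
#'
#' @param data a data frame or matrix of numeric parameters (>= 3 rows,
#'   >= 2 columns).
#' @return a symmetric correlation matrix with unit diagonal.
#' @export
pearson_collinearity <- function(data) {
  m <- as.matrix(data)
  if (nrow(m) < 3L) stop("need at least 3 subjects")
  if (ncol(m) < 2L) stop("need at least 2 parameters")
  sds <- apply(m, 2L, sd)
  if (any(sds == 0)) {
    stop("zero-variance column(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  }
  cor(m)
}

# Gaussian-likelihood AIC from a residual sum of squares; identical to
# stats::AIC on the corresponding lm fit (k slope terms + intercept +
# error variance).
.aic_rss <- function(rss, n, k) {
  n * log(2 * pi) + n * log(rss / n) + n + 2 * (k + 2)
}

# RSS of the least-squares fit restricted to columns `sel` of a centred
# design, from precomputed cross-products. Returns NA when the subset is
# (numerically) rank deficient.
.rss_subset <- function(G, gy, yy, sel) {
  R <- tryCatch(chol(G[sel, sel, drop = FALSE]), error = function(e) NULL)
  if (is.null(R) || min(diag(R)) < 1e-6 * max(diag(R))) return(NA_real_)
  u <- backsolve(R, gy[sel], transpose = TRUE)
  max(yy - sum(u^2), 0)
}

.tick <- function(x) paste0("`", x, "`")

#' Stepwise AIC regression with pairwise interaction candidates
#'
#' Starts from the main effects of all base parameters, then alternates
#' forward passes (add the pairwise-interaction candidate that most
#' improves -- decreases -- the AIC, if any does) and backward passes
#' (remove the term whose removal most decreases the AIC, provided the
#' decrease is at least `drop_tol`), stopping at the first full pass with
#' no change. No polynomial or higher-order terms are considered. The
#' procedure is deterministic given the column order of `data`, and the
#' AIC path is invariant to rescaling of the predictors. The selected
#' term structure is refit by ordinary least squares.
#'
#' The search runs on centred, scaled copies of the columns through
#' precomputed cross-products (Cholesky factorizations of Gram
#' submatrices), which leaves the AIC path identical to refitting each
#' candidate model while keeping the exhaustive subset search fast.
#'
#' @param y numeric response.
#' @param data data frame of base parameters (n > ncol + 1).
#' @param interactions logical; offer all pairwise products as candidates.
#' @param drop_tol backward-removal hysteresis on the AIC (default 0.01).
#' @param max_steps safety cap on add/remove actions.
#' @return an object of class `torso_model`: list with `fit` (the lm),
#'   `terms` (selected term labels, interactions as "a:b"), `base_terms`,
#'   `aic` (of the final model), `aic_trace` (data frame of actions),
#'   `n`, and `data` (the modelling frame including `.y`).
#' @export
stepwise_fit <- function(y, data, interactions = TRUE, drop_tol = 0.01,
                         max_steps = 200L) {
  data <- as.data.frame(data)
  n <- length(y)
  p_base <- ncol(data)
  if (nrow(data) != n) stop("y and data sizes differ")
  if (n <= p_base + 1L) stop("need n > number of base terms + 1")
  if (!all(vapply(data, is.numeric, TRUE))) stop("all parameters must be numeric")

  Xb <- as.matrix(data)
  labels <- colnames(Xb)
  if (interactions && p_base >= 2L) {
    prs <- combn(p_base, 2L)
    Xi <- Xb[, prs[1L, ], drop = FALSE] * Xb[, prs[2L, ], drop = FALSE]
    colnames(Xi) <- paste0(labels[prs[1L, ]], ":", labels[prs[2L, ]])
    X <- cbind(Xb, Xi)
  } else {
    X <- Xb
  }
  Xc <- sweep(X, 2L, colMeans(X))
  csd <- sqrt(colSums(Xc^2) / (n - 1L))
  usable <- csd > 0
  Xc[, usable] <- sweep(Xc[, usable, drop = FALSE], 2L, csd[usable], `/`)
  yc <- y - mean(y)
  G <- crossprod(Xc)
  gy <- drop(crossprod(Xc, yc))
  yy <- sum(yc^2)

  main_idx <- seq_len(p_base)
  int_idx <- setdiff(which(usable), main_idx)
  if (!all(usable[main_idx])) {
    stop("zero-variance base parameter(s): ",
         paste(colnames(X)[main_idx][!usable[main_idx]], collapse = ", "))
  }

  sel <- main_idx
  rss <- .rss_subset(G, gy, yy, sel)
  if (is.na(rss)) stop("design matrix of the base terms is rank deficient")
  cur_aic <- .aic_rss(rss, n, length(sel))
  trace <- list(list(step = 0L, action = "start", term = NA_character_,
                     aic = cur_aic, n_terms = length(sel)))

  step <- 0L
  repeat {
    changed <- FALSE
    # forward: best interaction candidate, added if it decreases the AIC
    cands <- setdiff(int_idx, sel)
    if (length(cands)) {
      aics <- vapply(cands, function(j) {
        r <- .rss_subset(G, gy, yy, c(sel, j))
        if (is.na(r)) Inf else .aic_rss(r, n, length(sel) + 1L)
      }, 1.0)
      jbest <- which.min(aics)
      if (aics[jbest] < cur_aic - 1e-10) {
        sel <- c(sel, cands[jbest])
        cur_aic <- aics[jbest]
        step <- step + 1L
        trace[[length(trace) + 1L]] <- list(
          step = step, action = "add", term = colnames(X)[cands[jbest]],
          aic = cur_aic, n_terms = length(sel))
        changed <- TRUE
      }
    }
    # backward: best removal, applied if the AIC decreases by >= drop_tol
    if (length(sel) > 1L) {
      aics <- vapply(seq_along(sel), function(i) {
        r <- .rss_subset(G, gy, yy, sel[-i])
        if (is.na(r)) Inf else .aic_rss(r, n, length(sel) - 1L)
      }, 1.0)
      ibest <- which.min(aics)
      if (cur_aic - aics[ibest] >= drop_tol) {
        dropped <- colnames(X)[sel[ibest]]
        sel <- sel[-ibest]
        cur_aic <- aics[ibest]
        step <- step + 1L
        trace[[length(trace) + 1L]] <- list(
          step = step, action = "remove", term = dropped,
          aic = cur_aic, n_terms = length(sel))
        changed <- TRUE
      }
    }
    if (!changed || step >= max_steps) break
  }

  sel_names <- colnames(X)[sel]
  frame <- data.frame(.y = y, data, check.names = FALSE)
  form_terms <- vapply(sel_names, function(s) {
    if (grepl(":", s, fixed = TRUE)) {
      paste(vapply(strsplit(s, ":", fixed = TRUE)[[1L]], .tick, ""),
            collapse = ":")
    } else .tick(s)
  }, "")
  form <- stats::as.formula(paste("`.y` ~", paste(form_terms, collapse = " + ")))
  fit <- lm(form, data = frame)

  out <- list(fit = fit, terms = sel_names, base_terms = labels,
              aic = AIC(fit),
              aic_trace = do.call(rbind, lapply(trace, as.data.frame)),
              n = n, data = frame)
  class(out) <- "torso_model"
  out
}

#' @export
print.torso_model <- function(x, ...) {
  cat(sprintf("<torso_model> %d terms selected from %d base parameters, AIC %.2f\n",
              length(x$terms), length(x$base_terms), x$aic))
  invisible(x)
}

#' Exhaustive search for the best 5-of-10 shape-parameter subset
#'
#' Enumerates all choose(10, 5) = 252 subsets of five shape parameters,
#' fits each combined 10-parameter model (5 size + 5 shape) with the full
#' stepwise procedure, and returns the subset whose selected model attains
#' the lowest training mean squared error. Ties are broken
#' lexicographically (the enumeration order of [utils::combn()]). Subsets
#' whose fit fails are skipped with a warning.
#'
#' @param y numeric response.
#' @param shape data frame of the 10 shape parameters (PC1..PC10).
#' @param size data frame of the 5 size parameters.
#' @param ... passed to [stepwise_fit()].
#' @return list with `subset` (indices into `shape`), `pcs` (names),
#'   `fit` (the winning `torso_model`), `mse`, `mse_all` (per-subset MSE),
#'   and `n_evaluated` (always 252 when all fits succeed).
#' @export
best_shape_subset <- function(y, shape, size, ...) {
  shape <- as.data.frame(shape)
  size <- as.data.frame(size)
  if (ncol(shape) != 10L) stop("expected 10 shape parameters")
  if (ncol(size) != 5L) stop("expected 5 size parameters")
  cb <- combn(10L, 5L)
  n_sub <- ncol(cb) # 252
  best <- NULL
  best_mse <- Inf
  best_idx <- NULL
  mse_all <- rep(NA_real_, n_sub)
  for (j in seq_len(n_sub)) {
    idx <- cb[, j]
    dat <- cbind(size, shape[, idx, drop = FALSE])
    fit <- tryCatch(stepwise_fit(y, dat, ...), error = function(e) {
      warning("subset {", paste(idx, collapse = ","), "} failed: ",
              conditionMessage(e))
      NULL
    })
    if (is.null(fit)) next
    mse <- mean(resid(fit$fit)^2)
    mse_all[j] <- mse
    if (mse < best_mse) {
      best_mse <- mse
      best <- fit
      best_idx <- idx
    }
  }
  if (is.null(best)) stop("all shape subsets failed to fit")
  list(subset = best_idx, pcs = colnames(shape)[best_idx], fit = best,
       mse = best_mse, mse_all = mse_all, n_evaluated = n_sub)
}

#' Adjusted R-squared
#'
#' 1 - (1 - R^2)(n - 1)/(n - p - 1), with p the number of model terms.
#'
#' @param r2 coefficient of determination.
#' @param n sample size.
#' @param p number of model terms (excluding the intercept).
#' @return adjusted R^2.
#' @export
adjusted_r2 <- function(r2, n, p) {
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Evaluate a fitted model: adjusted R^2, RMSE and 10-fold CV RMSE
#'
#' Cross-validation keeps the selected term structure frozen and refits
#' only the coefficients in each fold (a seeded random partition);
#' held-out squared errors are pooled into a single RMSE. Optionally the
#' full stepwise selection can be re-run inside every fold to probe
#' selection-induced optimism.
#'
#' @param model a `torso_model`.
#' @param k number of folds (n >= k required).
#' @param seed seed for the fold partition.
#' @param reselect re-run stepwise selection within each training fold.
#' @return list with `adjusted_r2`, `rmse`, `cv_rmse`, `r2`, `n`, `p`.
#' @export
evaluate_model <- function(model, k = 10L, seed = 1L, reselect = FALSE) {
  stopifnot(inherits(model, "torso_model"))
  frame <- model$data
  n <- model$n
  if (n < k) stop("need at least k = ", k, " observations for ", k, "-fold CV")
  y <- frame$.y
  r2 <- summary(model$fit)$r.squared
  p <- length(model$terms)
  adj <- adjusted_r2(r2, n, p)
  rmse <- sqrt(mean(resid(model$fit)^2))

  set.seed(seed)
  folds <- sample(rep_len(seq_len(k), n))
  pred <- numeric(n)
  base_cols <- setdiff(colnames(frame), ".y")
  for (f in seq_len(k)) {
    test <- folds == f
    train <- frame[!test, , drop = FALSE]
    fold_fit <- if (reselect) {
      stepwise_fit(train$.y, train[base_cols])$fit
    } else {
      lm(stats::formula(model$fit), data = train)
    }
    pred[test] <- predict(fold_fit, newdata = frame[test, , drop = FALSE])
  }
  list(adjusted_r2 = adj, rmse = rmse,
       cv_rmse = sqrt(mean((y - pred)^2)), r2 = r2, n = n, p = p)
}

#' Johnson relative weights of the terms of a fitted model
#'
#' Decomposes the model R^2 into non-negative contributions of the
#' (correlated) terms: the standardized term matrix is replaced by its
#' best-fitting orthogonal approximation (via the eigenstructure of the
#' term correlation matrix), the response is regressed on the orthogonal
#' variables, and the explained variance is attributed back to the
#' original terms through squared loadings. Raw weights sum to the model
#' R^2; they are also reported as percentages of R^2, alongside each
#' term's OLS p-value, sorted by descending weight.
#'
#' @param model a `torso_model`.
#' @return a data frame of class `relative_weights` with columns `term`,
#'   `raw_weight`, `pct_weight`, `p_value`.
#' @export
relative_weights <- function(model) {
  stopifnot(inherits(model, "torso_model"))
  X <- stats::model.matrix(model$fit)
  icpt <- colnames(X) == "(Intercept)"
  X <- X[, !icpt, drop = FALSE]
  if (ncol(X) == 0L) stop("model has no terms")
  n <- nrow(X)
  sds <- apply(X, 2L, sd)
  if (any(sds == 0)) stop("rank-deficient design: constant term column")
  Z <- scale(X)
  y <- model$data$.y
  ys <- (y - mean(y)) / sd(y)

  R <- crossprod(Z) / (n - 1L)
  ev <- eigen(R, symmetric = TRUE)
  keep <- ev$values > max(ev$values) * 1e-10
  V <- ev$vectors[, keep, drop = FALSE]
  lam_half <- sqrt(ev$values[keep])
  # Lambda = R^(1/2); loadings of terms on the orthogonal variables
  Lambda <- V %*% (lam_half * t(V))
  r_xy <- drop(crossprod(Z, ys)) / (n - 1L)
  # regression of the standardized response on the orthogonal variables
  b <- V %*% ((1 / lam_half) * drop(crossprod(V, r_xy)))
  raw <- drop(Lambda^2 %*% b^2)

  coefs <- summary(model$fit)$coefficients
  pvals <- setNames(rep(NA_real_, ncol(X)), colnames(X))
  hit <- intersect(rownames(coefs), colnames(X))
  pvals[hit] <- coefs[hit, "Pr(>|t|)"]

  out <- data.frame(term = colnames(X), raw_weight = raw,
                    pct_weight = 100 * raw / sum(raw),
                    p_value = unname(pvals), row.names = NULL)
  out <- out[order(-out$raw_weight), ]
  rownames(out) <- NULL
  class(out) <- c("relative_weights", "data.frame")
  out
}
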