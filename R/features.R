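# Shape features: periodic smoothing-spline contours, complex Fourier
# descriptors and the PCA shape basis.

#' Fit a smoothed closed contour to a band of cross-section points
#'
#' Converts the band to polar coordinates about its centroid, fits a
#' periodic cubic smoothing spline to the radius as a function of angle
#' (periodicity enforced by replicating the data over one period on each
#' side before fitting), and evaluates the smooth at `M` uniform angles.
#' The smoothing level is chosen by generalized cross-validation unless a
#' fixed `spar` is supplied.
#'
#' The polar origin matters: an origin offset `d` from the true section
#' centre leaks a spurious `d/2` into the low-frequency Fourier content of
#' a uniform-angle resampling, and the raw point centroid of a band is a
#' noisy origin when the angular coverage of the sampled points is uneven.
#' The fit therefore iterates: after each spline fit the origin is moved
#' to the area centroid of the fitted contour (which is a property of the
#' curve, not of the sampling) and the polar conversion is repeated until
#' the origin is stable.
#'
#' @param points an m x 2 matrix of band points (m >= 8).
#' @param M number of uniform angular samples of the output contour.
#' @param spar optional fixed smoothing parameter passed to
#'   [stats::smooth.spline()]; NULL selects by GCV.
#' @param max_gap_deg largest tolerated angular gap in the data; a larger
#'   gap means the contour is broken and cannot be smoothed.
#' @param max_iter origin-refinement iterations.
#' @return an M x 2 matrix (columns x, y) of class `closed_contour`, with
#'   attributes `theta` (the angles) and `centroid` (the final origin).
#' @export
smooth_and_resample <- function(points, M = 128L, spar = NULL,
                                max_gap_deg = 30, max_iter = 4L) {
  points <- as.matrix(points)
  if (nrow(points) < 8L) stop("need at least 8 points to fit a contour")
  ctr <- colMeans(points)
  theta_out <- 2 * pi * seq(0L, M - 1L) / M
  contour <- NULL
  for (iter in seq_len(max_iter)) {
    dx <- points[, 1L] - ctr[1L]
    dy <- points[, 2L] - ctr[2L]
    r <- sqrt(dx^2 + dy^2)
    th <- atan2(dy, dx) %% (2 * pi)

    sth <- sort(th)
    gaps <- c(diff(sth), sth[1L] + 2 * pi - sth[length(sth)])
    if (max(gaps) > max_gap_deg * pi / 180) {
      stop(sprintf("angular gap of %.1f deg exceeds %.1f deg: broken contour",
                   max(gaps) * 180 / pi, max_gap_deg))
    }

    th3 <- c(th - 2 * pi, th, th + 2 * pi)
    fit <- if (is.null(spar)) {
      smooth.spline(th3, rep(r, 3L))
    } else {
      smooth.spline(th3, rep(r, 3L), spar = spar)
    }
    r_hat <- predict(fit, theta_out)$y
    contour <- cbind(x = ctr[1L] + r_hat * cos(theta_out),
                     y = ctr[2L] + r_hat * sin(theta_out))
    new_ctr <- .polygon_centroid(contour)
    shift <- sqrt(sum((new_ctr - ctr)^2))
    ctr <- new_ctr
    if (shift < 1e-6 * max(mean(r), 1e-12)) break
  }
  attr(contour, "theta") <- theta_out
  attr(contour, "centroid") <- ctr
  class(contour) <- c("closed_contour", class(contour))
  contour
}

# Area centroid of a closed polygon (shoelace); independent of how the
# boundary is parameterized.
.polygon_centroid <- function(contour) {
  x <- contour[, 1L]; y <- contour[, 2L]
  nxt <- c(2:length(x), 1L)
  cr <- x * y[nxt] - x[nxt] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + x[nxt]) * cr) / (6 * a), sum((y + y[nxt]) * cr) / (6 * a))
}

# Frequencies kept from each band's transform, in fixed serialization
# order: the 10 smallest |frequency| terms of the complex-contour DFT.
# Negative frequencies are required to represent ellipses.
.FOURIER_FREQS <- c(0L, 1L, -1L, 2L, -2L, 3L, -3L, 4L, -4L, 5L)

#' Complex Fourier descriptors of a closed contour
#'
#' Computes the discrete Fourier transform of the complex sequence
#' z_j = x_j + i y_j (normalized by 1/M) and returns the coefficients at
#' the ten lowest frequencies, in the fixed order
#' 0, +1, -1, +2, -2, +3, -3, +4, -4, +5. For a unit circle traversed
#' counter-clockwise the +1 coefficient is 1 and all others vanish; for an
#' axis-aligned ellipse with semi-axes a, b the +1 and -1 coefficients are
#' (a+b)/2 and (a-b)/2.
#'
#' @param contour an M x 2 matrix of uniformly spaced contour samples.
#' @return a named complex vector of length 10.
#' @export
fourier_descriptors <- function(contour) {
  contour <- unclass(contour)
  M <- nrow(contour)
  zc <- complex(real = contour[, 1L], imaginary = contour[, 2L])
  co <- fft(zc) / M
  idx <- ifelse(.FOURIER_FREQS >= 0L, .FOURIER_FREQS + 1L,
                M + 1L + .FOURIER_FREQS)
  out <- co[idx]
  names(out) <- paste0("f", ifelse(.FOURIER_FREQS > 0L, "+", ""),
                       .FOURIER_FREQS)
  out
}

#' Reconstruct a contour from its 10 kept Fourier coefficients
#'
#' Inverse transform restricted to the kept frequencies; used to check
#' how much shape the truncation preserves.
#'
#' @param coefs a complex vector of length 10 in the standard order.
#' @param M number of output samples.
#' @return an M x 2 matrix.
#' @export
fourier_reconstruct <- function(coefs, M = 256L) {
  theta <- 2 * pi * seq(0L, M - 1L) / M
  z <- rep(0 + 0i, M)
  for (j in seq_along(.FOURIER_FREQS)) {
    z <- z + coefs[j] * exp(1i * .FOURIER_FREQS[j] * theta)
  }
  cbind(x = Re(z), y = Im(z))
}

#' Fourier feature vector of a scaled torso
#'
#' Fits a smoothed contour to each of the 25 scaled bands, extracts 10
#' complex Fourier coefficients per band (250 per torso) and serializes
#' them as 500 real numbers: band-major, each coefficient interleaved as
#' (Re, Im).
#'
#' @param scaled a `scaled_profile_set`.
#' @param M contour samples per band.
#' @param spar optional fixed smoothing parameter (NULL = GCV).
#' @return a named numeric vector of length 500.
#' @export
torso_feature_vector <- function(scaled, M = 128L, spar = NULL) {
  stopifnot(inherits(scaled, "scaled_profile_set"))
  coefs <- lapply(scaled$bands, function(b) {
    fourier_descriptors(smooth_and_resample(b, M = M, spar = spar))
  })
  n_bands <- length(coefs)
  out <- numeric(2L * 10L * n_bands)
  nm <- character(length(out))
  freq_lab <- sub("+", "p", names(coefs[[1L]]), fixed = TRUE)
  freq_lab <- sub("-", "m", freq_lab, fixed = TRUE)
  for (b in seq_len(n_bands)) {
    base <- (b - 1L) * 20L
    cc <- coefs[[b]]
    out[base + seq(1L, 20L, by = 2L)] <- Re(cc)
    out[base + seq(2L, 20L, by = 2L)] <- Im(cc)
    nm[base + seq(1L, 20L, by = 2L)] <- sprintf("b%02d_%s_re", b, freq_lab)
    nm[base + seq(2L, 20L, by = 2L)] <- sprintf("b%02d_%s_im", b, freq_lab)
  }
  names(out) <- nm
  out
}

#' Fit the PCA shape basis
#'
#' Column-mean-centred principal component analysis of an n x 500 feature
#' matrix; keeps the top `k` eigenvectors by explained variance with a
#' deterministic sign convention (the largest-magnitude loading of each
#' component is positive), so the basis is invariant to row permutation.
#'
#' @param features an n x 500 numeric matrix (n > k, all finite).
#' @param k number of components (10 by convention).
#' @return an object of class `shape_basis`: list with `mean` (length-500),
#'   `loadings` (500 x k, orthonormal columns), `eigenvalues`
#'   (non-increasing), `k`, `n`.
#' @export
fit_shape_basis <- function(features, k = 10L) {
  features <- as.matrix(features)
  if (!all(is.finite(features))) stop("non-finite values in feature matrix")
  n <- nrow(features)
  if (n <= k) stop("need more than k = ", k, " torsos to fit the basis")
  pr <- prcomp(features, center = TRUE, scale. = FALSE)
  k <- as.integer(k)
  load <- pr$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i0 <- which.max(abs(load[, j]))
    if (load[i0, j] < 0) load[, j] <- -load[, j]
  }
  colnames(load) <- paste0("PC", seq_len(k))
  basis <- list(mean = pr$center, loadings = load,
                eigenvalues = pr$sdev[seq_len(k)]^2, k = k, n = n)
  class(basis) <- "shape_basis"
  basis
}

#' @export
print.shape_basis <- function(x, ...) {
  cat(sprintf("<shape_basis> %d components fit on n = %d torsos\n", x$k, x$n))
  cat("explained variance: ",
      paste(sprintf("%.3g", x$eigenvalues), collapse = " "), "\n")
  invisible(x)
}

#' Project feature vectors onto a shape basis
#'
#' Shape parameters are the centred inner products with the basis
#' eigenvectors: PC_k = <f - mean, e_k>.
#'
#' @param features a length-500 vector or an n x 500 matrix.
#' @param basis a `shape_basis`.
#' @return an n x k matrix of PC scores (columns PC1..PCk).
#' @export
project_to_shape_params <- function(features, basis) {
  stopifnot(inherits(basis, "shape_basis"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  features <- as.matrix(features)
  if (ncol(features) != length(basis$mean)) {
    stop("feature length ", ncol(features), " does not match basis length ",
         length(basis$mean))
  }
  sweep(features, 2L, basis$mean) %*% basis$loadings
}

#' Save / load a shape basis as JSON
#'
#' The basis is persisted with a schema-version field so that study
#' cohorts can be projected onto a frozen basis fitted on a reference
#' cohort.
#'
#' @param basis a `shape_basis`.
#' @param path file path.
#' @return `write_shape_basis` returns `path` invisibly;
#'   `read_shape_basis` returns a `shape_basis`.
#' @export
write_shape_basis <- function(basis, path) {
  stopifnot(inherits(basis, "shape_basis"))
  obj <- list(schema_version = 1L, k = basis$k, n = basis$n,
              mean = unname(basis$mean),
              feature_names = names(basis$mean),
              eigenvalues = basis$eigenvalues,
              loadings = unname(basis$loadings))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_shape_basis
#' @export
read_shape_basis <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version) || obj$schema_version != 1L) {
    stop("unsupported shape-basis schema")
  }
  load <- as.matrix(obj$loadings)
  colnames(load) <- paste0("PC", seq_len(obj$k))
  basis <- list(mean = setNames(obj$mean, obj$feature_names),
                loadings = load, eigenvalues = obj$eigenvalues,
                k = as.integer(obj$k), n = as.integer(obj$n))
  class(basis) <- "shape_basis"
  basis
}
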