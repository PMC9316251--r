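# Scan geometry: torso segmentation, anatomical alignment, cross-section
# band extraction and centroid-size scaling.

#' Locate the xiphoid landmark from the neck and buttock heights
#'
#' The xiphoid process sits at 60% of the buttock-to-neck distance; the
#' population spread about that fraction is a reported statistic of real
#' cohorts, not a tolerance applied here.
#'
#' @param neck_height_mm,buttock_height_mm landmark heights in the scan
#'   frame (mm).
#' @return an object of class `torso_landmarks`: list with
#'   `neck_height_mm`, `buttock_height_mm`, `xiphoid_height_mm`.
#' @export
locate_xiphoid <- function(neck_height_mm, buttock_height_mm) {
  if (!is.finite(neck_height_mm) || !is.finite(buttock_height_mm) ||
      neck_height_mm <= buttock_height_mm) {
    stop("neck landmark must lie strictly above the buttock landmark")
  }
  lm <- list(
    neck_height_mm = neck_height_mm,
    buttock_height_mm = buttock_height_mm,
    xiphoid_height_mm = buttock_height_mm +
      0.60 * (neck_height_mm - buttock_height_mm)
  )
  class(lm) <- "torso_landmarks"
  lm
}

#' Segment the torso from a labeled scan and align it anatomically
#'
#' Keeps points between the buttock and xiphoid landmarks, removes limb
#' points by a robust per-slab radial trim, and places the cloud in the
#' local anatomical frame: x sagittal (positive anterior), y transverse,
#' z longitudinal with the origin at the bottom of the torso. The
#' rotation about z is recovered from the second moments of the mid-torso
#' cross-section (the transverse axis is the wider one) and the
#' anterior/posterior sign from the third moment of the sagittal
#' coordinate in the lower torso (the belly is the more protruding side,
#' standing in for the xiphoid/spinous-process midline of marked scans).
#'
#' Scans are assumed gravity-aligned (upright scanning booth); tilts about
#' the horizontal axes are not corrected.
#'
#' @param scan a `labeled_scan` (or a list with `points` and `landmarks`).
#' @param landmarks optional `torso_landmarks`; computed via
#'   [locate_xiphoid()] from the scan sidecar when NULL.
#' @param min_points minimum surviving point count.
#' @param trim_factor per-slab radial trim threshold, as a multiple of the
#'   slab median radius.
#' @return an object of class `torso_segment`: list with `points` (n x 3,
#'   mm, local frame), `torso_length_mm` and `landmarks`.
#' @export
segment_and_align <- function(scan, landmarks = NULL, min_points = 500L,
                              trim_factor = 1.6) {
  pts <- scan$points
  if (is.null(landmarks)) {
    landmarks <- locate_xiphoid(scan$landmarks$neck_height_mm,
                                scan$landmarks$buttock_height_mm)
  }
  z0 <- landmarks$buttock_height_mm
  z1 <- landmarks$xiphoid_height_mm
  zr <- range(pts[, 3L])
  if (z0 < zr[1L] - 1e-6 || z1 > zr[2L] + 1e-6) {
    stop("landmarks lie outside the z-range of the scan")
  }
  keep <- pts[, 3L] >= z0 & pts[, 3L] <= z1
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) < min_points) {
    stop("fewer than ", min_points, " points survive torso segmentation")
  }
  L <- z1 - z0
  z <- pts[, 3L] - z0

  # robust limb removal: per-slab median radius about the median centre
  cx <- median(pts[, 1L]); cy <- median(pts[, 2L])
  r <- sqrt((pts[, 1L] - cx)^2 + (pts[, 2L] - cy)^2)
  slab <- pmin(pmax(ceiling(z / L * 25), 1L), 25L)
  med <- tapply(r, slab, median)
  keep <- r <= trim_factor * med[as.character(slab)]
  pts <- pts[keep, , drop = FALSE]
  z <- z[keep]
  if (nrow(pts) < min_points) {
    stop("fewer than ", min_points, " points survive torso segmentation")
  }

  x <- pts[, 1L] - mean(pts[, 1L])
  y <- pts[, 2L] - mean(pts[, 2L])

  # rotation about z: align the major axis of the mid-torso section with y
  mid <- z / L >= 0.4 & z / L <= 0.6
  if (sum(mid) >= 10L) {
    cv <- cov(cbind(x[mid], y[mid]))
    ev <- eigen(cv, symmetric = TRUE)
    if (ev$values[1L] / max(ev$values[2L], 1e-12) > 1.02) {
      v <- ev$vectors[, 1L]
      phi <- atan2(v[2L], v[1L])
      rot <- pi / 2 - phi
      xr <- x * cos(rot) - y * sin(rot)
      yr <- x * sin(rot) + y * cos(rot)
      x <- xr; y <- yr
    }
  }
  # anterior sign: belly skewness in the lower torso
  low <- z / L >= 0.08 & z / L <= 0.35
  if (sum(low) >= 10L && mean((x[low] - mean(x[low]))^3) < 0) {
    x <- -x; y <- -y
  }

  seg <- list(points = cbind(x = x, y = y, z = z),
              torso_length_mm = L, landmarks = landmarks)
  class(seg) <- "torso_segment"
  seg
}

#' @export
print.torso_segment <- function(x, ...) {
  cat(sprintf("<torso_segment> %d points, length %.1f mm\n",
              nrow(x$points), x$torso_length_mm))
  invisible(x)
}

#' Extract uniformly spaced cross-section bands from a torso segment
#'
#' Band centres are placed at z = (i + 0.5)/n * L for i = 0..n-1, so the
#' end bands do not degenerate at the segment boundaries; each band
#' collects the points within half the band thickness of its centre,
#' projected to the band plane.
#'
#' @param torso a `torso_segment`.
#' @param n_bands number of bands (25 by convention).
#' @param band_thickness_mm slab thickness (2 mm by convention).
#' @return an object of class `profile_set`: list with `bands` (list of
#'   m x 2 matrices, mm), `centre_mm`, `t` (centre height fractions),
#'   `torso_length_mm`, `n_bands`, `band_thickness_mm`.
#' @export
extract_band_profiles <- function(torso, n_bands = 25L,
                                  band_thickness_mm = 2) {
  stopifnot(inherits(torso, "torso_segment"))
  pts <- torso$points
  if (nrow(pts) == 0L) stop("empty torso segment")
  L <- torso$torso_length_mm
  centres <- (seq_len(n_bands) - 0.5) / n_bands * L
  hw <- band_thickness_mm / 2
  bands <- lapply(centres, function(cz) {
    sel <- abs(pts[, 3L] - cz) <= hw
    pts[sel, 1:2, drop = FALSE]
  })
  empty <- vapply(bands, nrow, 1L) == 0L
  if (any(empty)) {
    stop("empty band(s) at index ", paste(which(empty), collapse = ", "),
         ": scan too sparse")
  }
  ps <- list(bands = bands, centre_mm = centres, t = centres / L,
             torso_length_mm = L, n_bands = as.integer(n_bands),
             band_thickness_mm = band_thickness_mm)
  class(ps) <- "profile_set"
  ps
}

#' Centroid size of a 2D point set
#'
#' The standard geometric-morphometrics scale measure: the square root of
#' the summed squared distances of all points from their centroid.
#'
#' @param points an m x 2 matrix.
#' @return a positive scalar.
#' @export
centroid_size <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) == 0L) stop("no points")
  ctr <- colMeans(points)
  sqrt(sum((points[, 1L] - ctr[1L])^2 + (points[, 2L] - ctr[2L])^2))
}

#' Rescale a profile set by centroid size
#'
#' Removes scale by dividing all band coordinates by the centroid size of
#' the pooled 25-band point set (computed about the pooled centroid, which
#' is also subtracted). Scaling jointly over all bands preserves the
#' waist-to-hip taper that per-band scaling would discard; per-band
#' scaling is available for sensitivity analysis.
#'
#' @param profiles a `profile_set`.
#' @param per_band scale each band by its own centroid size instead.
#' @return an object of class `scaled_profile_set`: as `profile_set` plus
#'   `centroid_size` (the scale divided out, mm).
#' @export
centroid_size_scale <- function(profiles, per_band = FALSE) {
  stopifnot(inherits(profiles, "profile_set"))
  out <- unclass(profiles)
  if (per_band) {
    cs <- vapply(profiles$bands, centroid_size, 1.0)
    out$bands <- Map(function(b, s) {
      sweep(b, 2L, colMeans(b)) / s
    }, profiles$bands, cs)
    out$centroid_size <- cs
  } else {
    all_pts <- do.call(rbind, profiles$bands)
    ctr <- colMeans(all_pts)
    cs <- centroid_size(all_pts)
    if (cs <= 0) stop("degenerate profile set: zero centroid size")
    out$bands <- lapply(profiles$bands, function(b) {
      sweep(b, 2L, ctr) / cs
    })
    out$centroid_size <- cs
  }
  class(out) <- c("scaled_profile_set", "profile_set")
  out
}
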