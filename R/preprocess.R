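#' @include fitting.R
NULL

#' Tilt angle of a fitted structure from its rotation matrix
#'
#' The angle between the structure's symmetry axis and the optical (z) axis:
#' \code{psi = atan(sqrt(1 - R33^2) / R33)} with R the z-y-x rotation matrix
#' of the fitted pose.
#'
#' @param angles numeric(3) pose angles (alpha, beta, gamma), radians.
#' @return tilt psi in radians.
#' @export
tiltAngle <- function(angles) {
  R33 <- rotationMatrix(angles)[3, 3]
  atan2(sqrt(pmax(1 - R33^2, 0)), R33)
}

#' Fit a depth-dependent axial distortion model
#'
#' Astigmatic 3D SMLM underestimates or overestimates z increasingly with
#' imaging depth. Structures of known axial extent calibrate this: for every
#' fitted two-ring site the vertical separation component
#' \code{s_z = s cos(psi)} is computed from the fitted separation and tilt,
#' converted to the tilt-corrected apparent separation \code{s_z / cos(psi)},
#' and a quadratic \code{s(z) = c1 z^2 + c2 z + c3} is fitted against depth.
#' The axial scaling factor is then \code{s_f(z) = E(s) / s(z)} with E(s) the
#' reference separation, and \code{z0} (where s_f = 1) is the origin of the
#' distortion.
#'
#' @param z per-site depth (z center), nm.
#' @param s per-site fitted ring separation, nm.
#' @param angles list (or 3-column matrix) of per-site pose angles, radians;
#'   NULL treats all sites as untilted.
#' @param expectedSeparation reference separation E(s), nm (default 49.3, the
#'   average two-ring separation of the Nup96 standard).
#' @return a \linkS4class{DistortionModel}.
#' @export
fitDistortion <- function(z, s, angles = NULL, expectedSeparation = 49.3) {
  if (length(z) < 10) stop("need at least 10 sites to fit the distortion")
  if (diff(range(z)) < 1e-6) stop("degenerate z spread")
  cosPsi <- if (is.null(angles)) rep(1, length(z)) else {
    am <- if (is.matrix(angles)) angles else do.call(rbind, angles)
    cos(apply(am, 1, tiltAngle))
  }
  sz <- s * cosPsi          # vertical separation component per site
  sApp <- sz / cosPsi       # tilt-corrected apparent separation vs depth
  fit <- lm(sApp ~ I(z^2) + z)
  cf <- coef(fit)
  coefs <- c(c1 = unname(cf[["I(z^2)"]]), c2 = unname(cf[["z"]]),
             c3 = unname(cf[["(Intercept)"]]))
  shat <- function(zz) coefs[1] * zz^2 + coefs[2] * zz + coefs[3]
  zr <- range(z)
  if (any(shat(seq(zr[1], zr[2], length.out = 64)) <= 0))
    stop("fitted separation curve is not positive over the z range")
  ## z0: closest point in the fitted range where s_hat = E(s)
  zz <- seq(zr[1], zr[2], length.out = 2048)
  z0 <- zz[which.min(abs(shat(zz) - expectedSeparation))]
  new("DistortionModel", coef = coefs,
      expectedSeparation = expectedSeparation, z0 = z0, zRange = zr)
}

## E(z) = integral of s_f from z0, with E(z0) = z0 (numeric, 1 nm grid)
.distortion_E <- function(model, z) {
  cf <- model@coef
  sf <- function(zz) model@expectedSeparation /
    (cf[1] * zz^2 + cf[2] * zz + cf[3])
  vapply(z, function(zi) {
    model@z0 + integrate(sf, model@z0, zi, rel.tol = 1e-8)$value
  }, 1.0)
}

#' Apply a depth-dependent distortion correction
#'
#' Replaces every z coordinate by \code{E(z) - E(0)}, where
#' \code{E(z) = integral of s_f(z) dz} with \code{E(z0) = z0}, keeping the
#' focal plane at zero. x, y and the precisions are untouched. z values
#' outside the fitted range are corrected by extrapolation and flagged with a
#' warning.
#'
#' @param locs a \linkS4class{LocalizationSet}.
#' @param model a \linkS4class{DistortionModel}.
#' @return the corrected \linkS4class{LocalizationSet}.
#' @export
applyDistortionCorrection <- function(locs, model) {
  stopifnot(locDim(locs) == 3)
  z <- coords(locs)[, 3]
  if (length(z) && (min(z) < model@zRange[1] - 1e-6 ||
                    max(z) > model@zRange[2] + 1e-6))
    warning("some z values lie outside the fitted range; extrapolating")
  e0 <- .distortion_E(model, 0)
  out <- locs
  out@coords[, 3] <- .distortion_E(model, z) - e0
  out
}

## ---- circle fitting --------------------------------------------------------

#' Fit a circle to 2D points
#'
#' Algebraic (Kasa) least-squares circle fit followed by one Gauss-Newton
#' refinement of the geometric distance; optionally with a fixed radius
#' (center-only refinement).
#'
#' @param xy 2-column matrix of points.
#' @param radius fixed radius, or NULL to fit it.
#' @return list with \code{center} (numeric(2)) and \code{radius}.
#' @export
circleFit <- function(xy, radius = NULL) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 3) stop("need at least 3 points")
  x <- xy[, 1]; y <- xy[, 2]
  if (is.null(radius)) {
    A <- cbind(2 * x, 2 * y, 1)
    b <- x^2 + y^2
    sol <- qr.solve(A, b)
    cx <- sol[1]; cy <- sol[2]
    r <- sqrt(sol[3] + cx^2 + cy^2)
  } else {
    cx <- mean(x); cy <- mean(y); r <- radius
  }
  ## one Gauss-Newton step on the geometric residuals
  for (it in 1:2) {
    dx <- x - cx; dy <- y - cy
    di <- sqrt(dx^2 + dy^2)
    di[di < 1e-9] <- 1e-9
    res <- di - r
    Jc <- cbind(-dx / di, -dy / di, if (is.null(radius)) -1 else NULL)
    upd <- tryCatch(qr.solve(Jc, -res), error = function(e) NULL)
    if (is.null(upd)) break
    cx <- cx + upd[1]; cy <- cy + upd[2]
    if (is.null(radius)) r <- r + upd[3]
  }
  list(center = c(cx, cy), radius = r)
}

## ---- site segmentation -----------------------------------------------------

## 2D FFT convolution, 'same' size, kernel centered
.conv2_same <- function(img, kern) {
  nr <- nrow(img) + nrow(kern) - 1
  nc <- ncol(img) + ncol(kern) - 1
  A <- matrix(0, nr, nc); A[seq_len(nrow(img)), seq_len(ncol(img))] <- img
  B <- matrix(0, nr, nc); B[seq_len(nrow(kern)), seq_len(ncol(kern))] <- kern
  full <- Re(fft(fft(A) * fft(B), inverse = TRUE)) / (nr * nc)
  r0 <- floor(nrow(kern) / 2); c0 <- floor(ncol(kern) / 2)
  full[r0 + seq_len(nrow(img)), c0 + seq_len(ncol(img))]
}

.ring_gauss_kernel <- function(pixel, ringRadius, gaussSD) {
  half <- ceiling((ringRadius + 3 * gaussSD) / pixel)
  ax <- (-half:half) * pixel
  dd <- sqrt(outer(ax^2, ax^2, "+"))
  k <- exp(-(dd - ringRadius)^2 / (2 * gaussSD^2))
  k / sum(k)
}

#' Segment candidate ring-shaped sites from a localization field
#'
#' Renders the 2D localization histogram, convolves it with a ring kernel
#' (a circle of approximately the expected structure radius convolved with a
#' Gaussian) and takes local maxima above a user-defined threshold as
#' candidates. Each candidate is then cleaned up in three steps: a
#' free-radius circle fit must land in [40, 70] nm; after a fixed-radius
#' refit of the center, at most 25\% of the localizations may lie closer
#' than 40 nm to the center and at most 40\% farther than 70 nm; and at
#' least 30 localizations are required. Surviving candidates are returned as
#' sites.
#'
#' @param locs a \linkS4class{LocalizationSet} (2D or 3D; segmentation uses
#'   the x-y projection).
#' @param threshold minimum filtered-image value (in localizations per
#'   pixel, after kernel normalization) for a candidate.
#' @param renderPixel histogram pixel size, nm.
#' @param ringRadius kernel ring radius, nm.
#' @param gaussSD kernel Gaussian SD, nm.
#' @param siteSide side length of the cropped sites, nm.
#' @param radiusRange acceptance interval for the free-radius circle fit, nm.
#' @param minLocs minimum localizations per site.
#' @param fixedRadius radius used for the center refit, nm.
#' @return list of \linkS4class{Site}s (possibly empty).
#' @export
segmentNpcSites <- function(locs, threshold, renderPixel = 5,
                            ringRadius = 55, gaussSD = 10, siteSide = 240,
                            radiusRange = c(40, 70), minLocs = 30,
                            fixedRadius = 53.4) {
  xy <- coords(locs)[, 1:2, drop = FALSE]
  if (nrow(xy) == 0) return(list())
  pad <- siteSide / 2
  xr <- range(xy[, 1]) + c(-pad, pad)
  yr <- range(xy[, 2]) + c(-pad, pad)
  nx <- max(8L, ceiling(diff(xr) / renderPixel))
  ny <- max(8L, ceiling(diff(yr) / renderPixel))
  ix <- pmin(pmax(floor((xy[, 1] - xr[1]) / renderPixel) + 1L, 1L), nx)
  iy <- pmin(pmax(floor((xy[, 2] - yr[1]) / renderPixel) + 1L, 1L), ny)
  img <- matrix(0, nx, ny)
  for (k in seq_len(nrow(xy))) img[ix[k], iy[k]] <- img[ix[k], iy[k]] + 1
  filt <- .conv2_same(img, .ring_gauss_kernel(renderPixel, ringRadius, gaussSD))
  ## local maxima above threshold, separated by at least the ring radius
  cand <- which(filt >= threshold, arr.ind = TRUE)
  if (nrow(cand) == 0) return(list())
  vals <- filt[cand]
  ord <- order(-vals)
  cand <- cand[ord, , drop = FALSE]
  minSep <- ringRadius
  centers <- matrix(numeric(0), 0, 2)
  for (r in seq_len(nrow(cand))) {
    cx <- xr[1] + (cand[r, 1] - 0.5) * renderPixel
    cy <- yr[1] + (cand[r, 2] - 0.5) * renderPixel
    if (nrow(centers) == 0 ||
        all(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) > minSep))
      centers <- rbind(centers, c(cx, cy))
  }
  out <- list()
  for (r in seq_len(nrow(centers))) {
    ctr <- centers[r, ]
    sel <- abs(xy[, 1] - ctr[1]) <= siteSide / 2 &
           abs(xy[, 2] - ctr[2]) <= siteSide / 2
    if (sum(sel) < 3) next
    sub <- xy[sel, , drop = FALSE]
    cf1 <- circleFit(sub)
    if (cf1$radius < radiusRange[1] || cf1$radius > radiusRange[2]) next
    cf2 <- circleFit(sub, radius = fixedRadius)
    dd <- sqrt((sub[, 1] - cf2$center[1])^2 + (sub[, 2] - cf2$center[2])^2)
    if (mean(dd < 40) > 0.25) next
    if (mean(dd > 70) > 0.40) next
    center <- c(cf2$center,
                if (locDim(locs) == 3)
                  median(coords(locs)[sel, 3]) else NULL)
    site <- cropSite(locs, center = center, sideLength = siteSide,
                     id = sprintf("seg%03d", length(out) + 1L))
    if (nLocs(site) < minLocs) next
    out[[length(out) + 1L]] <- site
  }
  out
}
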