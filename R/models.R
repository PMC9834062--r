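#' @include AllGenerics.R
NULL

#' Create a geometric model
#'
#' Low-level constructor, also the plug-in API: a model is a name, a kind, a
#' table of intrinsic parameters with finite bounds, and an evaluation
#' function. For point-producing kinds (\code{continuous-line},
#' \code{continuous-surface}, \code{discrete-points}) the evaluation function
#' has signature \code{function(params, spacing)} and must deterministically
#' return \code{list(points = <J x D matrix>, weights = <positive numeric>)}
#' with adjacent-point spacing no larger than \code{spacing} (ignored for
#' discrete points). For \code{density-image} models the signature is
#' \code{function(params, grid)} with \code{grid} a list of axis center
#' vectors, returning a non-negative array of fluorophore densities.
#'
#' @param name model identifier.
#' @param kind model kind (see \linkS4class{GeometricModel}).
#' @param dim 2 or 3.
#' @param params named list of intrinsic parameter defaults.
#' @param lower,upper named numeric vectors of finite bounds.
#' @param fun evaluation function.
#' @return a \linkS4class{GeometricModel}.
#' @export
geometricModel <- function(name, kind, dim, params, lower, upper, fun) {
  new("GeometricModel", name = name, kind = kind, dim = as.numeric(dim),
      params = params, lower = lower, upper = upper, fun = fun)
}

#' Evaluate a model at given parameters
#'
#' @param model a \linkS4class{GeometricModel} of a point-producing kind.
#' @param spacing maximum spacing between adjacent sampled points, nm.
#' @param params named list overriding the model's stored parameter values.
#' @return \code{list(points, weights)}.
#' @export
evaluateModel <- function(model, spacing = 1, params = list()) {
  stopifnot(is(model, "GeometricModel"))
  if (model@kind == "density-image")
    stop("density-image models are evaluated on a grid; see pdfImage()")
  p <- model@params
  p[names(params)] <- params
  out <- model@fun(p, spacing)
  out$points <- as.matrix(out$points)
  if (any(out$weights <= 0)) stop("model weights must be strictly positive")
  out
}

## ---- NPC models ------------------------------------------------------------

.ring_points <- function(r, z, n) {
  ang <- (seq_len(n) - 1) * 2 * pi / n
  cbind(x = r * cos(ang), y = r * sin(ang), z = rep(z, n))
}

#' Dual-ring model of the nuclear pore complex
#'
#' Two identical parallel circles of radius \code{r} in the planes
#' z = +/- s/2 (the model origin is the NPC center), with fluorophores
#' distributed continuously and uniformly along each ring. This is the smooth
#' backbone used to estimate pose, radius and ring separation before fitting
#' the discrete-corner model.
#'
#' @param r ring radius, nm (> 0).
#' @param s ring separation, nm (>= 0).
#' @return a continuous-line \linkS4class{GeometricModel} with intrinsic
#'   parameters \code{r} and \code{s}.
#' @examples
#' m <- npcDualRing(r = 53.4, s = 50.2)
#' pts <- evaluateModel(m, spacing = 3)$points
#' range(pts[, "z"])  # +/- 25.1
#' @export
npcDualRing <- function(r = 53.4, s = 50.2) {
  if (r <= 0) stop("ring radius r must be > 0")
  if (s < 0) stop("ring separation s must be >= 0")
  geometricModel(
    name = "npc_dual_ring", kind = "continuous-line", dim = 3,
    params = list(r = r, s = s),
    lower = c(r = 5, s = 0), upper = c(r = 200, s = 200),
    fun = function(params, spacing) {
      n <- max(8L, ceiling(2 * pi * params$r / spacing))
      pts <- rbind(.ring_points(params$r, -params$s / 2, n),
                   .ring_points(params$r, +params$s / 2, n))
      list(points = pts, weights = rep(1, nrow(pts)))
    })
}

#' Dual-ring density-image model
#'
#' The dual-ring geometry rendered as a fluorophore density map on a grid
#' (the radius is typically frozen in this form and only the pose, separation
#' and background are optimized; the smoothing with the mean localization
#' precision is applied by \code{\link{pdfImage}}).
#'
#' @inheritParams npcDualRing
#' @return a density-image \linkS4class{GeometricModel}.
#' @export
npcDualRingImage <- function(r = 53.4, s = 50.2) {
  if (r <= 0) stop("ring radius r must be > 0")
  geometricModel(
    name = "npc_dual_ring_image", kind = "density-image", dim = 3,
    params = list(r = r, s = s),
    lower = c(r = 5, s = 0), upper = c(r = 200, s = 200),
    fun = function(params, grid) {
      spacing <- min(vapply(grid, function(g)
        if (length(g) > 1) g[2] - g[1] else 1, 1.0)) / 3
      n <- max(8L, ceiling(2 * pi * params$r / spacing))
      pts <- rbind(.ring_points(params$r, -params$s / 2, n),
                   .ring_points(params$r, +params$s / 2, n))
      .points_to_grid(pts, rep(1, nrow(pts)), grid)
    })
}

## nearest-cell binning of weighted points onto a grid (density images)
.points_to_grid <- function(points, weights, grid) {
  dims <- vapply(grid, length, 1L)
  arr <- array(0, dim = dims)
  idx <- vapply(seq_along(grid), function(d) {
    g <- grid[[d]]
    step <- if (length(g) > 1) g[2] - g[1] else 1
    i <- round((points[, d] - g[1]) / step) + 1
    pmin(pmax(i, 1), length(g))
  }, numeric(nrow(points)))
  idx <- matrix(idx, ncol = length(grid))
  flat <- as.integer(idx[, 1])
  mult <- 1L
  for (d in seq_along(grid)[-1]) {
    mult <- mult * dims[d - 1]
    flat <- flat + (as.integer(idx[, d]) - 1L) * mult
  }
  acc <- tapply(weights, flat, sum)
  arr[as.integer(names(acc))] <- acc
  arr
}

.corner_angles <- function(n, copies, unitAngle) {
  corner <- (seq_len(n) - 1) * 2 * pi / n
  off <- (seq_len(copies) - (copies + 1) / 2) * unitAngle
  as.vector(outer(off, corner, "+"))
}

#' Discrete-corner model of the nuclear pore complex
#'
#' Two parallel rings of discrete fluorophore positions with n-fold rotational
#' symmetry. Each of the n symmetric units holds \code{copies} fluorophores
#' placed at identical radius, offset by +/- \code{unitAngle}/2 about the
#' corner angle (for the Nup96 NPC: n = 8, 2 copies, 32 positions in total).
#' The upper ring (z = +s/2) is rotated by the twist angle \code{theta}
#' relative to the lower ring.
#'
#' @param r ring radius, nm.
#' @param s ring separation, nm.
#' @param theta ring twist, radians.
#' @param symmetry rotational symmetry n (>= 3).
#' @param copies fluorophores per symmetric unit per ring.
#' @param unitAngle intra-unit angular spread, radians (structural constant,
#'   default 14 degrees).
#' @return a discrete-points \linkS4class{GeometricModel} with intrinsic
#'   parameters \code{r}, \code{s}, \code{theta}.
#' @examples
#' nrow(evaluateModel(npcDiscrete())$points)  # 32
#' @export
npcDiscrete <- function(r = 53.4, s = 50.2, theta = 8.8 * pi / 180,
                        symmetry = 8L, copies = 2L,
                        unitAngle = 14 * pi / 180) {
  if (symmetry < 3) stop("symmetry n must be >= 3")
  if (r <= 0) stop("ring radius r must be > 0")
  n <- as.integer(symmetry); cp <- as.integer(copies); ua <- unitAngle
  geometricModel(
    name = sprintf("npc_discrete_%dfold", n), kind = "discrete-points", dim = 3,
    params = list(r = r, s = s, theta = theta),
    lower = c(r = 5, s = 0, theta = -pi / n),
    upper = c(r = 200, s = 200, theta = pi / n),
    fun = function(params, spacing) {
      a_lo <- .corner_angles(n, cp, ua)
      a_hi <- a_lo + params$theta
      pts <- rbind(
        cbind(params$r * cos(a_lo), params$r * sin(a_lo), -params$s / 2),
        cbind(params$r * cos(a_hi), params$r * sin(a_hi), +params$s / 2))
      colnames(pts) <- c("x", "y", "z")
      list(points = pts, weights = rep(1, nrow(pts)))
    })
}

#' Elliptically deformed discrete NPC model
#'
#' Variant of \code{\link{npcDiscrete}} on an ellipse with semi-axes a, b
#' defined by the ellipticity \code{e = 1 - b/a} and the mean radius
#' \code{r = (a + b)/2}; \code{phi} rotates the long axis relative to the
#' first corner. \code{e = 0} reduces exactly to the circular model.
#'
#' @inheritParams npcDiscrete
#' @param e ellipticity in [0, 1).
#' @param phi internal rotation of the long axis, radians.
#' @return a discrete-points \linkS4class{GeometricModel} with intrinsic
#'   parameters \code{r}, \code{e}, \code{phi}, \code{s}, \code{theta}.
#' @export
npcElliptical <- function(r = 53.4, e = 0, phi = 0, s = 50.2,
                          theta = 8.8 * pi / 180, symmetry = 8L, copies = 2L,
                          unitAngle = 14 * pi / 180) {
  if (e < 0 || e >= 1) stop("ellipticity e must be in [0, 1)")
  if (symmetry < 3) stop("symmetry n must be >= 3")
  n <- as.integer(symmetry); cp <- as.integer(copies); ua <- unitAngle
  geometricModel(
    name = "npc_elliptical", kind = "discrete-points", dim = 3,
    params = list(r = r, e = e, phi = phi, s = s, theta = theta),
    lower = c(r = 5, e = 0, phi = -pi, s = 0, theta = -pi / n),
    upper = c(r = 200, e = 0.999, phi = pi, s = 200, theta = pi / n),
    fun = function(params, spacing) {
      a <- 2 * params$r / (2 - params$e)
      b <- a * (1 - params$e)
      ell <- function(t, z) {
        u <- t - params$phi
        xy <- cbind(a * cos(u), b * sin(u))
        rot <- matrix(c(cos(params$phi), sin(params$phi),
                        -sin(params$phi), cos(params$phi)), 2, 2)
        cbind(xy %*% t(rot), rep(z, length(t)))
      }
      a_lo <- .corner_angles(n, cp, ua)
      pts <- rbind(ell(a_lo, -params$s / 2),
                   ell(a_lo + params$theta, +params$s / 2))
      colnames(pts) <- c("x", "y", "z")
      list(points = pts, weights = rep(1, nrow(pts)))
    })
}

## ---- spline / tube models --------------------------------------------------

## control points built outward from the middle point; each point sits at
## distance h from its predecessor in the construction order, with direction
## given by (azimuth, elevation); the descending branch walks backwards.
.control_points <- function(xMid, h, azimuths, elevations, N) {
  q0 <- floor((N + 1) / 2)
  pts <- matrix(NA_real_, N, 3)
  pts[q0, ] <- xMid
  dir <- function(th, ph) c(cos(ph) * cos(th), cos(ph) * sin(th), sin(ph))
  # angle vectors are indexed by the non-middle point index q (1..N without q0)
  qs <- setdiff(seq_len(N), q0)
  th <- azimuths; ph <- elevations
  names(th) <- names(ph) <- qs
  if (q0 > 1)
    for (q in (q0 - 1):1)
      pts[q, ] <- pts[q + 1, ] -
        h * dir(th[[as.character(q)]], ph[[as.character(q)]])
  if (q0 < N)
    for (q in (q0 + 1):N)
      pts[q, ] <- pts[q - 1, ] +
        h * dir(th[[as.character(q)]], ph[[as.character(q)]])
  pts
}

## natural cubic spline through 3D control points, chord-length parameterized;
## returns equidistant (arc-length) samples and unit tangents
.spline_samples <- function(ctrl, spacing) {
  tknot <- c(0, cumsum(sqrt(rowSums(diff(ctrl)^2))))
  fx <- splinefun(tknot, ctrl[, 1], method = "natural")
  fy <- splinefun(tknot, ctrl[, 2], method = "natural")
  fz <- splinefun(tknot, ctrl[, 3], method = "natural")
  tt <- seq(0, max(tknot), length.out = max(200L, ceiling(4 * max(tknot) / spacing)))
  dense <- cbind(fx(tt), fy(tt), fz(tt))
  arc <- c(0, cumsum(sqrt(rowSums(diff(dense)^2))))
  total <- max(arc)
  ns <- max(2L, ceiling(total / spacing) + 1L)
  s_eq <- seq(0, total, length.out = ns)
  t_eq <- approx(arc, tt, xout = s_eq, ties = "ordered")$y
  pts <- cbind(fx(t_eq), fy(t_eq), fz(t_eq))
  tg <- cbind(fx(t_eq, deriv = 1), fy(t_eq, deriv = 1), fz(t_eq, deriv = 1))
  tg <- tg / sqrt(rowSums(tg^2))
  list(points = pts, tangents = tg, arcLength = total)
}

.mt_param_names <- function(N) {
  q0 <- floor((N + 1) / 2)
  qs <- setdiff(seq_len(N), q0)
  list(q0 = q0, qs = qs,
       th = paste0("theta", qs), ph = paste0("phi", qs))
}

#' Cubic-spline backbone model (curved filaments)
#'
#' A continuous curve defined by piece-wise third-order polynomials (a natural
#' cubic spline with chord-length parameterization) through an odd number N of
#' control points. The middle control point is the reference position; the
#' remaining points are built outward in both index directions, each at
#' distance \code{h} from its predecessor with direction given by an azimuth
#' and an elevation angle. With all angles zero the control points are
#' colinear along x with spacing h.
#'
#' @param xMid numeric(3), middle control point, nm.
#' @param h distance between consecutive control points, nm (> 0).
#' @param azimuths,elevations numeric vectors of length N - 1 (radians), one
#'   entry per non-middle control point in index order q = 1..N (skipping the
#'   middle).
#' @param N odd number of control points (>= 3).
#' @return a continuous-line \linkS4class{GeometricModel}; intrinsic
#'   parameters are \code{xmid, ymid, zmid, h} and the angles
#'   \code{theta<q>}, \code{phi<q>}.
#' @export
mtSpline <- function(xMid = c(0, 0, 0), h = 250, azimuths = numeric(N - 1),
                     elevations = numeric(N - 1), N = 5L) {
  N <- as.integer(N)
  if (N %% 2L == 0L) stop("N must be odd")
  if (N < 3) stop("N must be >= 3")
  if (h <= 0) stop("h must be > 0")
  nm <- .mt_param_names(N)
  params <- c(list(xmid = xMid[1], ymid = xMid[2], zmid = xMid[3], h = h),
              as.list(stats::setNames(azimuths, nm$th)),
              as.list(stats::setNames(elevations, nm$ph)))
  lower <- c(xmid = -1e5, ymid = -1e5, zmid = -1e5, h = 1,
             stats::setNames(rep(-pi, N - 1), nm$th),
             stats::setNames(rep(-pi / 2, N - 1), nm$ph))
  upper <- c(xmid = 1e5, ymid = 1e5, zmid = 1e5, h = 1e4,
             stats::setNames(rep(pi, N - 1), nm$th),
             stats::setNames(rep(pi / 2, N - 1), nm$ph))
  geometricModel(
    name = sprintf("mt_spline_N%d", N), kind = "continuous-line", dim = 3,
    params = params, lower = lower, upper = upper,
    fun = function(params, spacing) {
      ctrl <- .control_points(
        c(params$xmid, params$ymid, params$zmid), params$h,
        unlist(params[nm$th]), unlist(params[nm$ph]), N)
      sp <- .spline_samples(ctrl, spacing)
      list(points = sp$points, weights = rep(1, nrow(sp$points)))
    })
}

#' Curved-tube model (microtubules)
#'
#' Surface model built on the \code{\link{mtSpline}} backbone: circles of
#' radius \code{r} centered at equidistant points on the backbone spline, each
#' lying in the plane perpendicular to the local tangent.
#'
#' @inheritParams mtSpline
#' @param r tube radius, nm (> 0).
#' @return a continuous-surface \linkS4class{GeometricModel}; intrinsic
#'   parameters are the backbone parameters plus \code{r}.
#' @export
mtTube <- function(xMid = c(0, 0, 0), h = 250, azimuths = numeric(N - 1),
                   elevations = numeric(N - 1), N = 5L, r = 12.5) {
  if (r <= 0) stop("tube radius r must be > 0")
  backbone <- mtSpline(xMid, h, azimuths, elevations, N)
  nm <- .mt_param_names(as.integer(N))
  params <- c(backbone@params, list(r = r))
  lower <- c(backbone@lower, r = 1)
  upper <- c(backbone@upper, r = 200)
  geometricModel(
    name = sprintf("mt_tube_N%d", as.integer(N)), kind = "continuous-surface",
    dim = 3, params = params, lower = lower, upper = upper,
    fun = function(params, spacing) {
      ctrl <- .control_points(
        c(params$xmid, params$ymid, params$zmid), params$h,
        unlist(params[nm$th]), unlist(params[nm$ph]), as.integer(N))
      sp <- .spline_samples(ctrl, spacing)
      nring <- max(6L, ceiling(2 * pi * params$r / spacing))
      psi <- (seq_len(nring) - 1) * 2 * pi / nring
      out <- vector("list", nrow(sp$points))
      for (i in seq_len(nrow(sp$points))) {
        tg <- sp$tangents[i, ]
        ref <- if (abs(tg[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
        n1 <- c(tg[2] * ref[3] - tg[3] * ref[2],
                tg[3] * ref[1] - tg[1] * ref[3],
                tg[1] * ref[2] - tg[2] * ref[1])
        n1 <- n1 / sqrt(sum(n1^2))
        n2 <- c(tg[2] * n1[3] - tg[3] * n1[2],
                tg[3] * n1[1] - tg[1] * n1[3],
                tg[1] * n1[2] - tg[2] * n1[1])
        out[[i]] <- sweep(params$r * (outer(cos(psi), n1) +
                                        outer(sin(psi), n2)),
                          2, sp$points[i, ], "+")
      }
      pts <- do.call(rbind, out)
      colnames(pts) <- c("x", "y", "z")
      list(points = pts, weights = rep(1, nrow(pts)))
    })
}

## ---- endocytic models ------------------------------------------------------

#' 2D projection of a hemiellipsoid surface
#'
#' Surface of the upper half of an ellipsoid of revolution with half-axis
#' \code{a} along the invagination axis (+y) and lateral half-axis \code{b},
#' with the base in the plane y = 0, projected onto the x-y imaging plane by
#' numerically integrating out the depth coordinate (the surface is sampled
#' with area weights and the depth coordinate dropped). Describes e.g. the
#' Abp1-decorated actin dome at endocytic sites viewed side-on.
#'
#' @param a half-axis along the invagination axis, nm (> 0); doubles as the
#'   structure "length" used as a pseudotime proxy.
#' @param b lateral half-axis, nm (> 0).
#' @return a continuous-surface 2D \linkS4class{GeometricModel} with intrinsic
#'   parameters \code{a}, \code{b}.
#' @export
hemiellipsoidProjection <- function(a = 60, b = 50) {
  if (a <= 0 || b <= 0) stop("half-axes a and b must be > 0")
  geometricModel(
    name = "hemiellipsoid_projection", kind = "continuous-surface", dim = 2,
    params = list(a = a, b = b),
    lower = c(a = 1, b = 1), upper = c(a = 500, b = 500),
    fun = function(params, spacing) {
      a <- params$a; b <- params$b
      n_eta <- max(6L, ceiling((pi / 2) * max(a, b) / spacing))
      eta <- (seq_len(n_eta) - 0.5) * (pi / 2) / n_eta
      d_eta <- (pi / 2) / n_eta
      rho <- b * cos(eta)           # lateral ring radius at height y
      yy <- a * sin(eta)
      darc <- sqrt((a * cos(eta))^2 + (b * sin(eta))^2) * d_eta
      out <- vector("list", n_eta)
      for (i in seq_len(n_eta)) {
        npsi <- max(4L, ceiling(2 * pi * rho[i] / spacing))
        psi <- (seq_len(npsi) - 0.5) * 2 * pi / npsi
        # project (rho cos psi, y, rho sin psi) -> (x, y)
        w <- darc[i] * rho[i] * 2 * pi / npsi
        out[[i]] <- cbind(x = rho[i] * cos(psi), y = rep(yy[i], npsi),
                          w = rep(w, npsi))
      }
      m <- do.call(rbind, out)
      list(points = m[, c("x", "y")], weights = m[, "w"])
    })
}

#' 2D projection of a thick ring
#'
#' A ring with rectangular cross-section (solid of revolution about the
#' invagination axis +y): radii in [\code{rIn}, \code{rOut}], axial extent
#' [-t/2, +t/2], uniformly filled with fluorophores, projected onto the x-y
#' plane by dropping the depth coordinate (volume-weighted samples).
#' Describes e.g. the Las17 ring at the plasma membrane viewed side-on.
#'
#' @param rIn,rOut inner and outer radius, nm (0 < rIn < rOut).
#' @param t axial thickness, nm (> 0).
#' @return a continuous-surface 2D \linkS4class{GeometricModel} with intrinsic
#'   parameters \code{rin}, \code{rout}, \code{t}.
#' @export
thickRingProjection <- function(rIn = 40, rOut = 80, t = 30) {
  if (rIn <= 0 || rIn >= rOut) stop("need 0 < rIn < rOut")
  if (t <= 0) stop("thickness t must be > 0")
  geometricModel(
    name = "thick_ring_projection", kind = "continuous-surface", dim = 2,
    params = list(rin = rIn, rout = rOut, t = t),
    lower = c(rin = 1, rout = 2, t = 1),
    upper = c(rin = 500, rout = 600, t = 200),
    fun = function(params, spacing) {
      nr <- max(2L, ceiling((params$rout - params$rin) / spacing))
      nt <- max(2L, ceiling(params$t / spacing))
      rr <- params$rin + (seq_len(nr) - 0.5) * (params$rout - params$rin) / nr
      yy <- -params$t / 2 + (seq_len(nt) - 0.5) * params$t / nt
      dr <- (params$rout - params$rin) / nr
      dy <- params$t / nt
      out <- list()
      for (i in seq_len(nr)) {
        npsi <- max(4L, ceiling(2 * pi * rr[i] / spacing))
        psi <- (seq_len(npsi) - 0.5) * 2 * pi / npsi
        w <- rr[i] * dr * dy * 2 * pi / npsi
        for (j in seq_len(nt))
          out[[length(out) + 1L]] <-
            cbind(x = rr[i] * cos(psi), y = rep(yy[j], npsi),
                  w = rep(w, npsi))
      }
      m <- do.call(rbind, out)
      list(points = m[, c("x", "y")], weights = m[, "w"])
    })
}

#' Two-color endocytic site model
#'
#' Composite 2D model of an endocytic site viewed at the cell midplane: a
#' hemiellipsoid surface projection (channel 1, e.g. Abp1 on the actin dome)
#' and a thick-ring projection (channel 2, e.g. the Las17 ring at the plasma
#' membrane). Both components share the pose of the first; the hemiellipsoid
#' base coincides with the ring midplane and grows along +y, so the dome sits
#' at or above the ring.
#'
#' @param a,b hemiellipsoid half-axes, nm.
#' @param t ring thickness, nm.
#' @param rIn,rOut ring radii, nm (0 < rIn < rOut).
#' @param bgWeight shared background weight.
#' @return a \linkS4class{CompositeSpec} with one component per channel.
#' @export
endocyticModel <- function(a = 60, b = 50, t = 30, rIn = 40, rOut = 80,
                           bgWeight = 0) {
  if (rIn >= rOut) stop("need rIn < rOut")
  new("CompositeSpec",
      components = list(
        list(model = hemiellipsoidProjection(a, b), pose = Pose(),
             weight = 1 - bgWeight, channel = 1L),
        list(model = thickRingProjection(rIn, rOut, t), pose = Pose(),
             weight = 1 - bgWeight, channel = 2L)),
      bgWeight = bgWeight, colorWeights = "unit")
}

#' Connected line-segment model
#'
#' A discrete-points model whose fluorophore positions are the N vertices of a
#' chain of connected line segments; vertices are constructed exactly like the
#' control points of \code{\link{mtSpline}} (middle vertex as reference, each
#' neighbor at distance h in the direction given by its azimuth/elevation).
#' Adding one 3D vertex adds three free position parameters, which feeds the
#' AICc comparison between segment counts.
#'
#' @inheritParams mtSpline
#' @param N number of vertices (>= 2; even N allowed, the reference vertex is
#'   then index floor((N+1)/2)).
#' @return a discrete-points \linkS4class{GeometricModel}.
#' @export
lineSegments <- function(xMid = c(0, 0, 0), h = 100, azimuths = numeric(N - 1),
                         elevations = numeric(N - 1), N = 2L) {
  N <- as.integer(N)
  if (N < 2) stop("N must be >= 2")
  nm <- .mt_param_names(N)
  params <- c(list(xmid = xMid[1], ymid = xMid[2], zmid = xMid[3], h = h),
              as.list(stats::setNames(azimuths, nm$th)),
              as.list(stats::setNames(elevations, nm$ph)))
  lower <- c(xmid = -1e5, ymid = -1e5, zmid = -1e5, h = 1,
             stats::setNames(rep(-pi, N - 1), nm$th),
             stats::setNames(rep(-pi / 2, N - 1), nm$ph))
  upper <- c(xmid = 1e5, ymid = 1e5, zmid = 1e5, h = 1e4,
             stats::setNames(rep(pi, N - 1), nm$th),
             stats::setNames(rep(pi / 2, N - 1), nm$ph))
  geometricModel(
    name = sprintf("line_segments_N%d", N), kind = "discrete-points", dim = 3,
    params = params, lower = lower, upper = upper,
    fun = function(params, spacing) {
      pts <- .control_points(
        c(params$xmid, params$ymid, params$zmid), params$h,
        unlist(params[nm$th]), unlist(params[nm$ph]), N)
      colnames(pts) <- c("x", "y", "z")
      list(points = pts, weights = rep(1, N))
    })
}

## ---- model registry --------------------------------------------------------

.model_registry <- new.env(parent = emptyenv())

#' Model registry
#'
#' Built-in and user models are addressable by name. \code{registerModel}
#' stores a constructor under a name; \code{getModel} calls it with \code{...};
#' \code{listModels} returns the registered names.
#'
#' @param name model name.
#' @param constructor function returning a \linkS4class{GeometricModel} (or a
#'   \linkS4class{CompositeSpec} for multi-component entries).
#' @param ... arguments forwarded to the constructor.
#' @return \code{getModel}: the constructed model; \code{listModels}: a
#'   character vector.
#' @export
registerModel <- function(name, constructor) {
  stopifnot(is.character(name), is.function(constructor))
  assign(name, constructor, envir = .model_registry)
  invisible(name)
}

#' @rdname registerModel
#' @export
getModel <- function(name, ...) {
  if (!exists(name, envir = .model_registry))
    stop("unknown model: ", name)
  get(name, envir = .model_registry)(...)
}

#' @rdname registerModel
#' @export
listModels <- function() sort(ls(.model_registry))

registerModel("npc_dual_ring", npcDualRing)
registerModel("npc_dual_ring_image", npcDualRingImage)
registerModel("npc_discrete", npcDiscrete)
registerModel("npc_elliptical", npcElliptical)
registerModel("mt_spline", mtSpline)
registerModel("mt_tube", mtTube)
registerModel("hemiellipsoid_projection", hemiellipsoidProjection)
registerModel("thick_ring_projection", thickRingProjection)
registerModel("endocytic", endocyticModel)
registerModel("line_segments", lineSegments)
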