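#' @include models.R
NULL

#' Construct a Pose
#'
#' @param x0 translation, nm (length 2 or 3; padded to 3).
#' @param angles rotation angles (alpha, beta, gamma) in radians about the
#'   x, y, z axes; a scalar is taken as gamma (the in-plane rotation).
#' @param scale per-axis scale factors (scalar recycled).
#' @param extraSigma extra uncertainty epsilon, nm.
#' @param bgWeight background weight in [0, 1].
#' @return a \linkS4class{Pose}.
#' @export
Pose <- function(x0 = c(0, 0, 0), angles = c(0, 0, 0), scale = c(1, 1, 1),
                 extraSigma = 0, bgWeight = 0) {
  if (length(x0) == 2) x0 <- c(x0, 0)
  if (length(angles) == 1) angles <- c(0, 0, angles)
  if (length(scale) == 1) scale <- rep(scale, 3)
  new("Pose", x0 = as.numeric(x0), angles = as.numeric(angles),
      scale = as.numeric(scale), extraSigma = as.numeric(extraSigma),
      bgWeight = as.numeric(bgWeight))
}

#' Rotation matrix from z-y-x Euler angles
#'
#' Returns the 3 x 3 rotation matrix for angles (alpha, beta, gamma) about the
#' x, y and z axes, applied in the order z, then y, then x (i.e.
#' R = Rx(alpha) Ry(beta) Rz(gamma)).
#'
#' @param angles numeric(3): (alpha, beta, gamma) in radians.
#' @return a 3 x 3 orthonormal matrix with determinant 1.
#' @examples
#' rotationMatrix(c(0, 0, pi / 2)) %*% c(1, 0, 0)  # -> (0, 1, 0)
#' @export
rotationMatrix <- function(angles) {
  a <- angles[1]; b <- angles[2]; g <- angles[3]
  ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
  cg <- cos(g); sg <- sin(g)
  matrix(c(
    cb * cg,                  -cb * sg,                  sb,
    ca * sg + cg * sa * sb,    ca * cg - sa * sb * sg,  -cb * sa,
    sa * sg - ca * cg * sb,    cg * sa + ca * sb * sg,   ca * cb),
    nrow = 3, byrow = TRUE)
}

## forward transform of model points: v' = S R v + x0 (D = 2 uses gamma only)
.pose_forward <- function(pts, pose) {
  d <- ncol(pts)
  if (d == 3) {
    R <- rotationMatrix(pose@angles)
    t(diag(pose@scale) %*% R %*% t(pts) + pose@x0)
  } else {
    g <- pose@angles[3]
    R <- matrix(c(cos(g), sin(g), -sin(g), cos(g)), 2, 2)
    t(diag(pose@scale[1:2]) %*% R %*% t(pts) + pose@x0[1:2])
  }
}

## reverse transform of data coordinates: x' = R^-1 S^-1 (x - x0)
.pose_reverse <- function(pts, pose) {
  d <- ncol(pts)
  if (d == 3) {
    R <- rotationMatrix(pose@angles)
    t(t(R) %*% diag(1 / pose@scale) %*% (t(pts) - pose@x0))
  } else {
    g <- pose@angles[3]
    R <- matrix(c(cos(g), sin(g), -sin(g), cos(g)), 2, 2)
    t(t(R) %*% diag(1 / pose@scale[1:2]) %*% (t(pts) - pose@x0[1:2]))
  }
}

#' Apply a pose to localizations or model points
#'
#' Direction \code{"data-to-model"} reverse-transforms localization
#' coordinates into the model frame, \code{x' = R^-1 S^-1 (x - x0)}
#' (precisions are untouched); \code{"model-to-data"} transforms model points
#' into the data frame, \code{v' = S R v + x0}. The two directions are exact
#' inverses. 2D inputs use only the in-plane rotation gamma.
#'
#' @param target a \linkS4class{LocalizationSet}, \linkS4class{Site},
#'   \linkS4class{DiscretizedModel} or a coordinate matrix.
#' @param pose a \linkS4class{Pose} (scales must be non-zero).
#' @param direction "data-to-model" or "model-to-data".
#' @return an object of the same type with transformed coordinates.
#' @export
applyPose <- function(target, pose,
                      direction = c("data-to-model", "model-to-data")) {
  direction <- match.arg(direction)
  validObject(pose)
  tf <- if (direction == "model-to-data") .pose_forward else .pose_reverse
  if (is(target, "LocalizationSet")) {
    out <- target
    out@coords <- tf(target@coords, pose)
    out
  } else if (is(target, "Site")) {
    out <- target
    out@localizations@coords <- tf(target@localizations@coords, pose)
    out
  } else if (is(target, "DiscretizedModel")) {
    out <- target
    out@points <- tf(target@points, pose)
    out
  } else {
    tf(as.matrix(target), pose)
  }
}

#' Discretize a continuous model against a localization set
#'
#' Samples a continuous-line or continuous-surface model with maximum spacing
#' delta < 0.75 x the smallest localization precision component of the data
#' (after clamping precisions below \code{sigmaMin} up to \code{sigmaMin}),
#' which keeps the point-sampled Gaussian mixture indistinguishable from the
#' continuous density. Weights returned by the model sampler are carried
#' through (inversely scaled to the local sample density, so uniform samplers
#' give equal weights). Discrete-points models pass through unchanged.
#'
#' @param model a \linkS4class{GeometricModel}.
#' @param locs the \linkS4class{LocalizationSet} (or \linkS4class{Site}) to be
#'   fitted, from which the spacing rule is derived.
#' @param sigmaMin precision floor, nm; raising it coarsens the sampling and
#'   shrinks the model size.
#' @param params named list of parameter overrides.
#' @param maxPoints resource guard: error if the spacing rule would need more
#'   sample points than this (advises raising \code{sigmaMin}).
#' @return a \linkS4class{DiscretizedModel}.
#' @export
discretizeModel <- function(model, locs, sigmaMin = 0, params = list(),
                            maxPoints = 2e5) {
  if (is(locs, "Site")) locs <- localizations(locs)
  s <- precisions(locs)
  s[s < sigmaMin] <- sigmaMin
  delta <- 0.75 * min(s) * (1 - 1e-9)   # strictly below the 0.75 bound
  if (!is.finite(delta) || delta <= 0)
    stop("cannot derive a sampling spacing from the localization precisions")
  ev <- evaluateModel(model, spacing = delta, params = params)
  if (nrow(ev$points) > maxPoints)
    stop("discretization would need ", nrow(ev$points), " points ",
         "(> maxPoints); raise sigmaMin to coarsen the sampling")
  new("DiscretizedModel", points = ev$points, weights = as.numeric(ev$weights),
      spacing = delta, sigmaMin = sigmaMin)
}

#' Gaussian-mixture PDF of a discretized model
#'
#' Evaluates, for every localization, the probability density of the
#' point-sampled model: a mixture of axis-aligned Gaussians centered at the
#' model points v_j with mixture weights q_j / sum(q), where each localization
#' uses its own covariance diag(sigma^2 + eps^2) per axis and the normalizing
#' constant (2 pi)^(-D/2) det(Sigma)^(-1/2) of its dimensionality.
#'
#' @param locs a \linkS4class{LocalizationSet} or \linkS4class{Site}.
#' @param model a \linkS4class{DiscretizedModel}, or a J x D matrix of model
#'   points (unit weights).
#' @param extraSigma extra uncertainty epsilon (nm) added in quadrature to
#'   every precision component.
#' @param sigmaMin precision floor, nm: precision components below it are set
#'   to it (consistent with the floor used for the discretization spacing).
#' @return numeric vector of per-localization densities (nm^-D).
#' @examples
#' l <- LocalizationSet(matrix(0, 1, 2), matrix(1, 1, 2))
#' pdfDiscrete(l, matrix(0, 1, 2))  # 1 / (2 pi)
#' @export
pdfDiscrete <- function(locs, model, extraSigma = 0, sigmaMin = 0) {
  if (is(locs, "Site")) locs <- localizations(locs)
  if (is(model, "DiscretizedModel")) {
    v <- model@points; q <- model@weights
    sigmaMin <- max(sigmaMin, model@sigmaMin)
  } else {
    v <- as.matrix(model); q <- rep(1, nrow(v))
  }
  if (nrow(v) == 0) stop("empty model")
  if (ncol(v) != locDim(locs))
    stop("model and localization dimensionality differ")
  sm <- precisions(locs)
  if (sigmaMin > 0) sm[sm < sigmaMin] <- sigmaMin
  .gmmDensity(coords(locs), sm, v, q, extraSigma)
}

## ---- density-image PDF -----------------------------------------------------

## row-normalized 1D Gaussian kernel matrix (an averaging operator, so a
## flat density stays flat at the edges; total mass is restored afterwards)
.blur_matrix <- function(n, step, sd) {
  if (sd <= 0) return(diag(n))
  x <- (seq_len(n) - 1) * step
  K <- exp(-outer(x, x, "-")^2 / (2 * sd^2))
  sweep(K, 1, rowSums(K), "/")
}

.sep_blur <- function(arr, sds, steps) {
  dims <- dim(arr)
  nd <- length(dims)
  for (d in seq_len(nd)) {
    M <- .blur_matrix(dims[d], steps[d], sds[d])
    perm <- c(d, seq_len(nd)[-d])
    a <- aperm(arr, perm)
    a <- M %*% matrix(a, dims[d])
    arr <- aperm(array(a, dims[perm]), order(perm))
  }
  arr
}

## multilinear interpolation of an array at points (rows of pts)
.interp_grid <- function(arr, grid, pts) {
  nd <- length(grid)
  dims <- dim(arr)
  idx <- lapply(seq_len(nd), function(d) {
    g <- grid[[d]]
    step <- if (length(g) > 1) g[2] - g[1] else 1
    u <- (pts[, d] - g[1]) / step
    i0 <- floor(u)
    fr <- u - i0
    i0 <- pmin(pmax(i0, 0), dims[d] - 1)       # clamp to grid
    i1 <- pmin(i0 + 1, dims[d] - 1)
    fr[pts[, d] < g[1] | pts[, d] > g[length(g)]] <- 0
    list(i0 = i0 + 1, i1 = i1 + 1, fr = fr)
  })
  out <- numeric(nrow(pts))
  corners <- as.matrix(expand.grid(rep(list(0:1), nd)))
  for (r in seq_len(nrow(corners))) {
    w <- rep(1, nrow(pts))
    lin <- rep(1, nrow(pts))
    mult <- 1
    for (d in seq_len(nd)) {
      bit <- corners[r, d]
      w <- w * if (bit == 0) (1 - idx[[d]]$fr) else idx[[d]]$fr
      i <- if (bit == 0) idx[[d]]$i0 else idx[[d]]$i1
      lin <- lin + (i - 1) * mult
      mult <- mult * dims[d]
    }
    out <- out + w * arr[lin]
  }
  out
}

#' PDF of a density-image model
#'
#' Builds the model PDF from a fluorophore density map: the density is
#' rendered on a cell-centered grid covering the site, normalized so it
#' integrates to 1 over the site, convolved with a separable Gaussian of
#' per-axis SD sqrt(meanSigma^2 + extraSigma^2) (the mean localization
#' precision stands in for the per-localization precisions in this model
#' form), and evaluated at the localization coordinates by multilinear
#' interpolation.
#'
#' @param locs a \linkS4class{LocalizationSet} or \linkS4class{Site}.
#' @param model a density-image \linkS4class{GeometricModel}.
#' @param site the \linkS4class{Site} defining the normalization volume; may
#'   be omitted when \code{locs} is a Site.
#' @param meanSigma per-axis blur SD, nm; defaults to the column means of the
#'   localization precisions.
#' @param extraSigma extra uncertainty epsilon, nm (added in quadrature).
#' @param params named list of parameter overrides.
#' @param maxCells per-axis grid cap (grid spacing is half the smallest blur
#'   SD, but never finer than side/maxCells).
#' @return numeric vector of per-localization densities (nm^-D).
#' @export
pdfImage <- function(locs, model, site = NULL, meanSigma = NULL,
                     extraSigma = 0, params = list(), maxCells = 256) {
  if (is(locs, "Site")) {
    if (is.null(site)) site <- locs
    locs <- localizations(locs)
  }
  if (is.null(site)) stop("a site is required to normalize the density")
  stopifnot(model@kind == "density-image")
  d <- locDim(locs)
  if (is.null(meanSigma)) meanSigma <- colMeans(precisions(locs))
  meanSigma <- rep_len(meanSigma, d)
  blur <- sqrt(meanSigma^2 + extraSigma^2)
  side <- siteSide(site)
  step <- max(min(blur) / 2, side / maxCells)
  n <- ceiling(side / step)
  step <- side / n
  ax <- -side / 2 + (seq_len(n) - 0.5) * step
  grid <- rep(list(ax), d)
  p <- model@params
  p[names(params)] <- params
  f <- model@fun(p, grid)
  if (all(f == 0)) stop("density image is zero everywhere on the site")
  f <- .sep_blur(f, blur, rep(step, d))
  f <- f / (sum(f) * step^d)             # normalize over the site post-blur
  .interp_grid(f, grid, coords(locs))
}

#' Mix a model PDF with the uniform site background
#'
#' Returns \code{(1 - wBg) * density + wBg * d^(-D)} where d is the site side
#' length, so the background integrates to 1 over the site. The returned
#' vector carries the background bookkeeping as attributes: \code{Kbg = K *
#' wBg} (expected background localizations), \code{Km = K - Kbg} and the
#' background density \code{rhoBg = Kbg / d^2}.
#'
#' @param density per-localization model densities.
#' @param wBg background weight in [0, 1].
#' @param site a \linkS4class{Site} (or a single side length d).
#' @param dim dimensionality D (needed when \code{site} is a bare number;
#'   default 2).
#' @return numeric vector of mixed densities with attributes Kbg, Km, rhoBg.
#' @export
mixBackground <- function(density, wBg, site, dim = 2L) {
  if (wBg < 0 || wBg > 1) stop("wBg must be in [0, 1]")
  if (is(site, "Site")) {
    d <- siteSide(site)
    dim <- locDim(site)
  } else d <- as.numeric(site)
  out <- (1 - wBg) * density + wBg * d^(-dim)
  k <- length(density)
  attr(out, "Kbg") <- k * wBg
  attr(out, "Km") <- k * (1 - wBg)
  attr(out, "rhoBg") <- k * wBg / d^2
  out
}

## evaluate one component's density for a set of localizations:
## continuous/discrete models are discretized and transformed into the data
## frame (v' = S R v + x0); density images are evaluated with the
## localizations reverse-transformed into the model frame.
.component_density <- function(locs, cmp, site, sigmaMin, prePose = NULL) {
  pose <- cmp$pose
  model <- cmp$model
  if (is(model, "DiscretizedModel")) {
    pts <- model@points
    if (!is.null(prePose)) pts <- .pose_forward(pts, prePose)
    pts <- .pose_forward(pts, pose)
    dm <- model; dm@points <- pts
    return(pdfDiscrete(locs, dm, extraSigma = pose@extraSigma))
  }
  if (model@kind == "density-image") {
    l2 <- locs
    if (!is.null(prePose)) l2 <- applyPose(l2, prePose, "data-to-model")
    l2 <- applyPose(l2, pose, "data-to-model")
    return(pdfImage(l2, model, site = site, extraSigma = pose@extraSigma))
  }
  dm <- discretizeModel(model, locs, sigmaMin = sigmaMin)
  pts <- dm@points
  if (!is.null(prePose)) pts <- .pose_forward(pts, prePose)
  dm@points <- .pose_forward(pts, pose)
  pdfDiscrete(locs, dm, extraSigma = pose@extraSigma)
}

## validation-free mixture evaluation shared by compositePdf and the
## optimizer hot path; comps is a plain list of (model, pose, weight, channel)
.mixture_density <- function(locs, comps, bgWeight, site, sigmaMin) {
  d <- locDim(locs)
  out <- numeric(nLocs(locs))
  chans <- vapply(comps, function(x) as.integer(x$channel), 1L)
  firstPose <- comps[[1]]$pose
  for (ch in unique(channels(locs))) {
    sel <- channels(locs) == ch
    if (!any(sel)) next
    sub <- if (all(sel)) locs else locs[sel]
    dens <- numeric(sum(sel))
    for (m in which(chans == ch)) {
      cmp <- comps[[m]]
      pre <- if (m > 1) firstPose else NULL
      dens <- dens + cmp$weight *
        .component_density(sub, cmp, site, sigmaMin, prePose = pre)
    }
    if (!is.null(site))
      dens <- dens + bgWeight * siteSide(site)^(-d)
    out[sel] <- dens
  }
  out
}

#' Per-localization density of a composite model
#'
#' Evaluates, channel by channel, the mixture
#' \code{sum_m w_m M_m + w_bg M_bg} using only the components and the
#' localizations of each channel. Component poses beyond the first are
#' relative: the first component's transform is applied to all components
#' first, then each component's own transform.
#'
#' @param locs a \linkS4class{LocalizationSet} or \linkS4class{Site}.
#' @param spec a \linkS4class{CompositeSpec} (weights per channel plus the
#'   background weight must sum to 1).
#' @param site the \linkS4class{Site} providing the background volume; may be
#'   omitted when \code{locs} is a Site.
#' @param sigmaMin precision floor for the discretization spacing, nm.
#' @return numeric vector of densities, one entry per localization.
#' @export
compositePdf <- function(locs, spec, site = NULL, sigmaMin = 0) {
  if (is(locs, "Site")) {
    if (is.null(site)) site <- locs
    locs <- localizations(locs)
  }
  validObject(spec)
  .mixture_density(locs, spec@components, spec@bgWeight, site, sigmaMin)
}

.DENSITY_FLOOR <- 1e-300

#' Log-likelihood of a composite model
#'
#' The log-likelihood of the localization set under the model PDF:
#' \code{LL = sum_c w_c sum_(k in c) ln M_c(x_k, sigma_k | p)} (natural
#' logarithm). The per-channel weight w_c is 1 by default
#' (\code{colorWeights = "unit"}); with \code{"ratio"} weighting
#' \code{w_c = sum(K_c) / K_c}, which balances channels with unequal counts.
#' Densities are clamped at 1e-300 before the logarithm; if any localization
#' hits the floor the result carries the attribute \code{clamped = TRUE}
#' instead of an exception.
#'
#' @inheritParams compositePdf
#' @return scalar log-likelihood with attributes \code{perChannel} (named
#'   numeric) and, when triggered, \code{clamped}.
#' @export
logLikelihood <- function(locs, spec, site = NULL, sigmaMin = 0) {
  if (is(locs, "Site")) {
    if (is.null(site)) site <- locs
    locs <- localizations(locs)
  }
  dens <- compositePdf(locs, spec, site = site, sigmaMin = sigmaMin)
  clamped <- any(dens < .DENSITY_FLOOR)
  dens <- pmax(dens, .DENSITY_FLOOR)
  ch <- channels(locs)
  uch <- unique(ch)
  kc <- vapply(uch, function(u) sum(ch == u), 1L)
  wc <- if (spec@colorWeights == "ratio") sum(kc) / kc else rep(1, length(uch))
  per <- vapply(seq_along(uch),
                function(i) sum(log(dens[ch == uch[i]])), 1.0)
  ll <- sum(wc * per)
  attr(ll, "perChannel") <- stats::setNames(per, uch)
  if (clamped) attr(ll, "clamped") <- TRUE
  ll
}

#' Cross-correlation score of a composite model
#'
#' The sum (instead of the product) of the per-localization densities,
#' \code{L_cc = sum_k M(x_k, sigma_k | p)}: an alternative objective closely
#' related to the cross-correlation between model and data.
#'
#' @inheritParams compositePdf
#' @return scalar score.
#' @export
crossCorrelationScore <- function(locs, spec, site = NULL, sigmaMin = 0) {
  sum(compositePdf(locs, spec, site = site, sigmaMin = sigmaMin))
}
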