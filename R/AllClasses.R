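#' @useDynLib smlmfit, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats optim lm rnorm runif rpois rexp rgeom rbinom fft
#'   integrate coef approx splinefun quantile median sd
#' @importFrom utils head tail
NULL

#' LocalizationSet: SMLM coordinates with per-localization precisions
#'
#' The primary data container of the package. One row per localization, with
#' coordinates in nm and the per-axis localization precision (standard
#' deviation of the coordinate estimate) in nm. 2D data carry \code{x, y}
#' columns; 3D data add \code{z}. Optional per-localization metadata: an
#' integer color channel, the acquisition frame and the photon count.
#'
#' @slot coords numeric matrix (K x D), positions in nm, D in \{2, 3\}.
#' @slot precisions numeric matrix (K x D), per-axis standard deviations, nm;
#'   all entries must be strictly positive.
#' @slot channel integer vector of length K (color labels, default 0).
#' @slot frame integer vector of length K or length 0.
#' @slot photons numeric vector of length K or length 0.
#' @export
setClass("LocalizationSet",
  representation(
    coords     = "matrix",
    precisions = "matrix",
    channel    = "integer",
    frame      = "integer",
    photons    = "numeric"
  )
)

setValidity("LocalizationSet", function(object) {
  k <- nrow(object@coords)
  d <- ncol(object@coords)
  msg <- character()
  if (!d %in% c(2L, 3L))
    msg <- c(msg, "dimensionality must be 2 or 3")
  if (!identical(dim(object@coords), dim(object@precisions)))
    msg <- c(msg, "coords and precisions must have identical dimensions")
  if (k > 0 && any(!is.finite(object@coords)))
    msg <- c(msg, "coords must be finite")
  if (k > 0 && (any(!is.finite(object@precisions)) ||
                any(object@precisions <= 0))) {
    bad <- which(apply(object@precisions, 1L,
                       function(r) any(!is.finite(r)) || any(r <= 0)))[1L]
    msg <- c(msg, sprintf("all precisions must be > 0 (first bad row: %d)", bad))
  }
  if (length(object@channel) != k)
    msg <- c(msg, "channel must have one entry per localization")
  if (length(object@frame) > 0 && length(object@frame) != k)
    msg <- c(msg, "frame must be empty or have one entry per localization")
  if (length(object@photons) > 0 && length(object@photons) != k)
    msg <- c(msg, "photons must be empty or have one entry per localization")
  if (length(msg)) msg else TRUE
})

#' Site: a bounded region containing one structure
#'
#' A site is an axis-aligned box of side length \code{sideLength} (nm) that
#' contains the localizations of a single biological structure ("particle").
#' Localization coordinates are stored relative to the site center, so the box
#' is centered at the origin of the local frame; \code{center} records where
#' the site came from in the original coordinate system.
#'
#' @slot localizations a \linkS4class{LocalizationSet} in site-local
#'   coordinates.
#' @slot sideLength box side d, nm (> 0). The uniform background density over
#'   the site is d^(-D).
#' @slot center numeric vector, original center position, nm.
#' @slot id character label.
#' @export
setClass("Site",
  representation(
    localizations = "LocalizationSet",
    sideLength    = "numeric",
    center        = "numeric",
    id            = "character"
  )
)

setValidity("Site", function(object) {
  msg <- character()
  if (length(object@sideLength) != 1 || !is.finite(object@sideLength) ||
      object@sideLength <= 0)
    msg <- c(msg, "sideLength must be a single positive number")
  d <- ncol(object@localizations@coords)
  if (length(object@center) != d)
    msg <- c(msg, "center must match the data dimensionality")
  if (nrow(object@localizations@coords) > 0) {
    half <- object@sideLength / 2 + 1e-9
    if (any(abs(object@localizations@coords) > half))
      msg <- c(msg, "all localizations must lie within the closed site box")
  }
  if (length(msg)) msg else TRUE
})

#' Pose: extrinsic transformation parameters
#'
#' Extrinsic parameters of a model: translation, z-y-x rotation angles, per-axis
#' scale, extra uncertainty (blur beyond the localization precision, e.g.
#' linkage error) and the background mixture weight.
#'
#' @slot x0 numeric(3), translation in nm (2D data use the first two entries).
#' @slot angles numeric(3), rotation angles (alpha, beta, gamma) in radians
#'   about the x, y and z axes; the rotation is applied z, then y, then x.
#' @slot scale numeric(3), per-axis scale factors (> 0).
#' @slot extraSigma extra uncertainty epsilon in nm (>= 0), added in quadrature
#'   to each localization precision.
#' @slot bgWeight background weight w_bg in [0, 1].
#' @export
setClass("Pose",
  representation(
    x0         = "numeric",
    angles     = "numeric",
    scale      = "numeric",
    extraSigma = "numeric",
    bgWeight   = "numeric"
  ),
  prototype(
    x0 = c(0, 0, 0), angles = c(0, 0, 0), scale = c(1, 1, 1),
    extraSigma = 0, bgWeight = 0
  )
)

setValidity("Pose", function(object) {
  msg <- character()
  if (length(object@x0) != 3 || any(!is.finite(object@x0)))
    msg <- c(msg, "x0 must be a finite numeric vector of length 3")
  if (length(object@angles) != 3 || any(!is.finite(object@angles)))
    msg <- c(msg, "angles must be a finite numeric vector of length 3")
  if (length(object@scale) != 3 || any(object@scale <= 0))
    msg <- c(msg, "scale factors must be > 0")
  if (object@extraSigma < 0)
    msg <- c(msg, "extraSigma must be >= 0")
  if (object@bgWeight < 0 || object@bgWeight > 1)
    msg <- c(msg, "bgWeight must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' GeometricModel: a parameterized generator of fluorophore geometry
#'
#' A model is a named, parameterized description of where fluorophores sit:
#' a continuous curve (\code{"continuous-line"}), a continuous surface
#' (\code{"continuous-surface"}), an explicit list of fluorophore positions
#' (\code{"discrete-points"}) or a density image (\code{"density-image"}).
#' Continuous and discrete kinds expose a deterministic sampler
#' \code{fun(params, spacing)} returning \code{list(points, weights)}; the
#' density-image kind exposes \code{fun(params, grid)} returning an array of
#' non-negative densities on the grid.
#'
#' @slot name identifier used in the model registry.
#' @slot kind one of continuous-line, continuous-surface, discrete-points,
#'   density-image.
#' @slot dim model dimensionality (2 or 3).
#' @slot params named list of intrinsic parameter defaults.
#' @slot lower,upper named numeric vectors of finite intrinsic bounds.
#' @slot fun the evaluation function (see Description).
#' @export
setClass("GeometricModel",
  representation(
    name   = "character",
    kind   = "character",
    dim    = "numeric",
    params = "list",
    lower  = "numeric",
    upper  = "numeric",
    fun    = "function"
  )
)

setValidity("GeometricModel", function(object) {
  kinds <- c("continuous-line", "continuous-surface", "discrete-points",
             "density-image")
  msg <- character()
  if (!object@kind %in% kinds)
    msg <- c(msg, paste("kind must be one of:", paste(kinds, collapse = ", ")))
  if (!object@dim %in% c(2, 3))
    msg <- c(msg, "dim must be 2 or 3")
  pn <- names(object@params)
  if (!all(pn %in% names(object@lower)) || !all(pn %in% names(object@upper)))
    msg <- c(msg, "every intrinsic parameter needs lower and upper bounds")
  if (any(!is.finite(object@lower[pn])) || any(!is.finite(object@upper[pn])))
    msg <- c(msg, "intrinsic parameter bounds must be finite")
  if (length(msg)) msg else TRUE
})

#' DiscretizedModel: point-sampled form of a model
#'
#' The point-cloud form used by the Gaussian-mixture PDF: sampled positions
#' v_j with weights q_j, the sampling spacing delta and the precision clamp
#' sigma_min used to derive it.
#'
#' @slot points numeric matrix (J x D), nm.
#' @slot weights numeric vector (length J), strictly positive.
#' @slot spacing maximum spacing delta between adjacent points, nm.
#' @slot sigmaMin the precision floor applied before deriving delta, nm.
#' @export
setClass("DiscretizedModel",
  representation(
    points   = "matrix",
    weights  = "numeric",
    spacing  = "numeric",
    sigmaMin = "numeric"
  )
)

setValidity("DiscretizedModel", function(object) {
  msg <- character()
  if (nrow(object@points) == 0)
    msg <- c(msg, "a discretized model must contain at least one point")
  if (length(object@weights) != nrow(object@points))
    msg <- c(msg, "one weight per model point required")
  if (sum(object@weights) <= 0)
    msg <- c(msg, "weights must sum to a positive value")
  if (length(msg)) msg else TRUE
})

#' CompositeSpec: a multi-component, multi-channel model PDF specification
#'
#' Combines component models (each with a pose, a mixture weight and a color
#' channel) with a shared uniform background. Within every channel the
#' component weights plus the background weight must sum to 1 so that the
#' channel PDF is normalized. Poses of components beyond the first are
#' expressed relative to the first component: the first component's transform
#' is applied to all components, then each component's own transform.
#'
#' @slot components list; each element a list with entries \code{model}
#'   (GeometricModel or DiscretizedModel), \code{pose} (Pose), \code{weight}
#'   (numeric) and \code{channel} (integer).
#' @slot bgWeight shared background weight in [0, 1].
#' @slot colorWeights "unit" (w_c = 1, the default) or "ratio"
#'   (w_c = sum(K_c) / K_c).
#' @export
setClass("CompositeSpec",
  representation(
    components   = "list",
    bgWeight     = "numeric",
    colorWeights = "character"
  ),
  prototype(bgWeight = 0, colorWeights = "unit")
)

setValidity("CompositeSpec", function(object) {
  msg <- character()
  if (length(object@components) == 0)
    msg <- c(msg, "at least one component is required")
  for (cmp in object@components) {
    if (!all(c("model", "pose", "weight", "channel") %in% names(cmp)))
      msg <- c(msg, "each component needs model, pose, weight, channel")
  }
  if (object@bgWeight < 0 || object@bgWeight > 1)
    msg <- c(msg, "bgWeight must be in [0, 1]")
  if (!object@colorWeights %in% c("unit", "ratio"))
    msg <- c(msg, "colorWeights must be 'unit' or 'ratio'")
  if (length(msg) == 0) {
    chans <- vapply(object@components, function(x) as.integer(x$channel), 1L)
    for (ch in unique(chans)) {
      wsum <- sum(vapply(object@components[chans == ch],
                         function(x) x$weight, 1.0)) + object@bgWeight
      if (abs(wsum - 1) > 1e-8)
        msg <- c(msg, sprintf(
          "channel %d: component weights + bgWeight must sum to 1 (got %.6f)",
          ch, wsum))
    }
  }
  if (length(msg)) msg else TRUE
})

#' FitStep: one maximum-likelihood fitting step
#'
#' Describes one optimization problem: the component models, which parameters
#' are free vs fixed, their bounds and initial values, the optimizer and the
#' objective. Parameter names are the intrinsic parameter names of the first
#' component plus the extrinsic names \code{x, y, z, alpha, beta, gamma, eps,
#' wbg} (and \code{sx, sy, sz} for scale); parameters of component m > 1 are
#' prefixed \code{"c<m>."}.
#'
#' @slot components list of lists with entries \code{model} and \code{channel}.
#' @slot free character vector of free parameter names.
#' @slot fixed named numeric vector of fixed parameter values.
#' @slot lower,upper named numeric bounds for the free parameters.
#' @slot init named numeric initial values (within bounds).
#' @slot optimizer "de" (global differential evolution), "simplex"
#'   (Nelder-Mead) or "gradient" (L-BFGS-B).
#' @slot objective "mle" (log-likelihood) or "cc" (cross-correlation score).
#' @slot sigmaMin precision floor used for discretization spacing, nm.
#' @slot control list of optimizer settings.
#' @export
setClass("FitStep",
  representation(
    components = "list",
    free       = "character",
    fixed      = "numeric",
    lower      = "numeric",
    upper      = "numeric",
    init       = "numeric",
    optimizer  = "character",
    objective  = "character",
    sigmaMin   = "numeric",
    control    = "list"
  ),
  prototype(optimizer = "simplex", objective = "mle", sigmaMin = 0,
            control = list())
)

setValidity("FitStep", function(object) {
  msg <- character()
  if (!object@optimizer %in% c("de", "simplex", "gradient"))
    msg <- c(msg, "optimizer must be 'de', 'simplex' or 'gradient'")
  if (!object@objective %in% c("mle", "cc"))
    msg <- c(msg, "objective must be 'mle' or 'cc'")
  miss <- setdiff(object@free, names(object@lower))
  if (length(miss))
    msg <- c(msg, paste("free parameters missing bounds:",
                        paste(miss, collapse = ", ")))
  both <- intersect(object@free, names(object@fixed))
  if (length(both))
    msg <- c(msg, paste("parameters cannot be both free and fixed:",
                        paste(both, collapse = ", ")))
  if (length(object@init)) {
    common <- intersect(names(object@init), object@free)
    lo <- object@lower[common]; hi <- object@upper[common]
    bad <- common[object@init[common] < lo - 1e-12 |
                  object@init[common] > hi + 1e-12]
    if (length(bad))
      msg <- c(msg, paste("initial values outside bounds:",
                          paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' FitResult: output of a maximum-likelihood fit
#'
#' @slot estimates named numeric vector of parameter estimates (free and
#'   fixed; attribute-free).
#' @slot freeNames names of the parameters that were optimized.
#' @slot maxLogLik maximized log-likelihood.
#' @slot hessian observed-information Hessian of the log-likelihood at the
#'   optimum (P x P, free parameters only), or a 0 x 0 matrix if not computed.
#' @slot variances named numeric parameter variances.
#' @slot ci95 matrix with columns \code{lo}, \code{hi}: 95\% confidence
#'   intervals (estimate +/- 1.96 sd).
#' @slot aic,aicc,aiccPerLoc information criteria (see \code{\link{aicc}}).
#' @slot nParams number of free parameters P.
#' @slot nLocs number of localizations K.
#' @slot derived list with background bookkeeping: Kbg, Km, rhoBg.
#' @slot a0 constant of the quadratic log-likelihood approximation.
#' @slot converged logical.
#' @slot flags character vector of warnings raised during fitting.
#' @export
setClass("FitResult",
  representation(
    estimates  = "numeric",
    freeNames  = "character",
    maxLogLik  = "numeric",
    hessian    = "matrix",
    variances  = "numeric",
    ci95       = "matrix",
    aic        = "numeric",
    aicc       = "numeric",
    aiccPerLoc = "numeric",
    nParams    = "integer",
    nLocs      = "integer",
    derived    = "list",
    a0         = "numeric",
    converged  = "logical",
    flags      = "character"
  ),
  prototype(hessian = matrix(numeric(0), 0, 0), variances = numeric(0),
            ci95 = matrix(numeric(0), 0, 2), a0 = NA_real_,
            converged = TRUE, flags = character(0), derived = list())
)

#' SimConfig: fluorophore photophysics and imaging settings for simulation
#'
#' Parameters of the two-state (bright/dark) fluorophore model with bleaching
#' used by the simulator, plus the imaging settings that turn emitted photons
#' into localization precisions.
#'
#' @slot pLabel labeling probability in [0, 1].
#' @slot pReact reactivation probability in [0, 1] (a fluorophore re-blinks
#'   with this probability, otherwise it bleaches).
#' @slot meanOnTime mean bright-state lifetime t_l, s (exponential).
#' @slot frameTime camera frame time, s.
#' @slot brightness photon emission rate while on, photons/s.
#' @slot bgPhotons background photons per pixel per frame (enters the
#'   precision model only).
#' @slot extraDisplacementSD per-axis SD (nm) of the random displacement added
#'   to each fluorophore position (linkage error / drift proxy).
#' @slot nFrames number of acquisition frames.
#' @slot bgDensity density of spurious uniform background localizations,
#'   localizations per nm^D per site.
#' @slot nContinuous number of fluorophore positions drawn when the model is
#'   continuous (discrete models contribute all their positions).
#' @slot precisionModel function(photons, cfg) returning a K x D matrix of
#'   per-axis localization precisions in nm.
#' @export
setClass("SimConfig",
  representation(
    pLabel              = "numeric",
    pReact              = "numeric",
    meanOnTime          = "numeric",
    frameTime           = "numeric",
    brightness          = "numeric",
    bgPhotons           = "numeric",
    extraDisplacementSD = "numeric",
    nFrames             = "integer",
    bgDensity           = "numeric",
    nContinuous         = "integer",
    precisionModel      = "function"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@pLabel < 0 || object@pLabel > 1)
    msg <- c(msg, "pLabel must be in [0, 1]")
  if (object@pReact < 0 || object@pReact > 1)
    msg <- c(msg, "pReact must be in [0, 1]")
  for (nm in c("meanOnTime", "frameTime", "brightness")) {
    if (slot(object, nm) <= 0)
      msg <- c(msg, paste(nm, "must be positive"))
  }
  if (object@nFrames < 1) msg <- c(msg, "nFrames must be >= 1")
  if (length(msg)) msg else TRUE
})

#' SimilarityMatrix: all-against-all registration log-likelihoods
#'
#' @slot scores n x n matrix; entry [i, j] is the maximum log-likelihood of
#'   registering particle i (as a point model) to particle j; diagonal 0.
#' @slot rank integer permutation of 1..n ordering particles by decreasing
#'   row sum (total similarity); ties broken by lower index.
#' @export
setClass("SimilarityMatrix",
  representation(scores = "matrix", rank = "integer"))

setValidity("SimilarityMatrix", function(object) {
  msg <- character()
  n <- nrow(object@scores)
  if (n != ncol(object@scores)) msg <- c(msg, "scores must be square")
  if (!identical(sort(object@rank), seq_len(n)))
    msg <- c(msg, "rank must be a permutation of 1..n")
  if (length(msg)) msg else TRUE
})

#' Template: a fused particle average
#'
#' @slot localizations pooled pose-corrected localizations of the fused
#'   particles.
#' @slot score summed registration log-likelihood of the accepted iteration.
#' @slot iterations number of accepted + rejected iterations performed.
#' @slot history numeric vector of the summed scores of all iterations.
#' @export
setClass("Template",
  representation(
    localizations = "LocalizationSet",
    score         = "numeric",
    iterations    = "integer",
    history       = "numeric"
  ),
  prototype(score = -Inf, iterations = 0L, history = numeric(0))
)

#' DistortionModel: depth-dependent axial rescaling
#'
#' Quadratic model of the apparent (tilt-corrected) ring separation as a
#' function of depth z, from which the axial scaling factor
#' s_f(z) = E(s) / s_hat(z) and the undistorted coordinate
#' E(z) = integral of s_f are derived.
#'
#' @slot coef numeric(3): quadratic coefficients (c1, c2, c3) of
#'   s_hat(z) = c1 z^2 + c2 z + c3.
#' @slot expectedSeparation reference separation E(s), nm (default 49.3).
#' @slot z0 depth where s_f(z0) = 1 (origin of the distortion).
#' @slot zRange range of z covered by the fit, nm.
#' @export
setClass("DistortionModel",
  representation(
    coef               = "numeric",
    expectedSeparation = "numeric",
    z0                 = "numeric",
    zRange             = "numeric"
  )
)
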