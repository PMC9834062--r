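#' @include fitting.R
NULL

## pull a named estimate with a default for absent extrinsics
.est <- function(est, nm, default = 0)
  if (nm %in% names(est)) unname(est[[nm]]) else default

## wrap a fixed point cloud as a zero-parameter discrete model
.point_model <- function(points, dim = ncol(points)) {
  pts <- as.matrix(points)
  geometricModel(
    name = "point_cloud", kind = "discrete-points", dim = dim,
    params = list(), lower = numeric(0), upper = numeric(0),
    fun = function(params, spacing) list(points = pts,
                                         weights = rep(1, nrow(pts))))
}

.template_points <- function(target, cap) {
  locs <- if (is(target, "Template")) target@localizations
          else if (is(target, "Site")) localizations(target)
          else target
  pts <- coords(locs)
  if (nrow(pts) > cap) {
    ## prefer the most precise localizations: they carry the sharpest
    ## structural contrast for phase locking
    ord <- order(rowMeans(precisions(locs)))
    pts <- pts[ord[seq_len(cap)], , drop = FALSE]
  }
  pts
}

#' Register one particle to another (or to a template)
#'
#' Treats the target's localization coordinates as the fluorophore positions
#' of a point model and maximizes, over the pose of that model (translation
#' plus rotation), the likelihood of the moving particle's localizations,
#' each weighted by its own precision. The registration is asymmetric
#' (LL(A to B) != LL(B to A) in general). Multiple seeded restarts over the
#' in-plane rotation avoid rotational local maxima.
#'
#' @param moving a \linkS4class{Site} whose localizations are registered.
#' @param target a \linkS4class{Site} or \linkS4class{Template} providing the
#'   point model.
#' @param seed integer seed.
#' @param freeParams pose parameters to optimize; default translations plus
#'   the in-plane rotation gamma.
#' @param restarts number of best rotation-scan starts refined by the local
#'   optimizer.
#' @param gammaGrid number of in-plane rotation angles scanned (translations
#'   at zero) to seed the refinement.
#' @param bgWeight fixed background weight during registration (absorbs
#'   unmatched localizations).
#' @param extraSigma fixed extra uncertainty during registration, nm.
#' @param cap maximum number of target points used as the model (uniform
#'   subsample beyond this).
#' @param movingCap maximum number of moving localizations used during the
#'   pose search (the returned alignment always transforms all of them).
#' @param maxShift bound on the translation search, nm.
#' @param maxit simplex iterations per refinement start.
#' @param init optional named numeric vector (over \code{freeParams}) with an
#'   approximate pose used as an additional refinement start (e.g. the pose
#'   from a previous iteration).
#' @return list with \code{pose} (the fitted model pose), \code{logLik}, and
#'   \code{aligned}: the moving localizations mapped into the target frame.
#' @export
registerPair <- function(moving, target, seed = 1, freeParams = NULL,
                         restarts = 2, gammaGrid = 32, bgWeight = 0.05,
                         extraSigma = 0, cap = 1500, movingCap = 120,
                         maxShift = 60, maxit = 150, init = NULL) {
  set.seed(seed)
  d <- locDim(moving)
  if (is.null(freeParams))
    freeParams <- if (d == 3) c("x", "y", "z", "gamma") else
                              c("x", "y", "gamma")
  pts <- .template_points(target, cap)
  mod <- .point_model(pts, dim = d)
  side <- if (is(moving, "Site")) siteSide(moving) else 4 * maxShift
  mlocs <- localizations(if (is(moving, "Site")) moving else
                           asSite(moving, side))
  msub <- if (nLocs(mlocs) > movingCap)
    mlocs[order(rowMeans(precisions(mlocs)))[seq_len(movingCap)]] else mlocs
  site <- asSite(msub, side)
  lower <- c(x = -maxShift, y = -maxShift, z = -maxShift, alpha = -0.6,
             beta = -0.6, gamma = -pi)
  upper <- c(x = maxShift, y = maxShift, z = maxShift, alpha = 0.6,
             beta = 0.6, gamma = pi)
  step <- fitStep(mod, free = freeParams,
                  fixed = c(eps = extraSigma, wbg = bgWeight),
                  lower = lower[freeParams], upper = upper[freeParams],
                  optimizer = "simplex",
                  control = list(maxit = maxit, ci = FALSE))
  init0 <- stats::setNames(rep(0, length(freeParams)), freeParams)
  inits <- list()
  if (!is.null(init)) {
    ## known approximate pose as an additional refinement start
    inits <- list(pmin(pmax({
      p <- init0; p[names(init)] <- init; p
    }, step@lower[freeParams]), step@upper[freeParams]))
  }
  if ("gamma" %in% freeParams) {
    obj <- .make_objective(site, step)
    gs <- seq(-pi, pi, length.out = gammaGrid + 1L)[seq_len(gammaGrid)]
    scan <- vapply(gs, function(g) {
      p <- init0; p[["gamma"]] <- g; obj(p)
    }, 1.0)
    inits <- c(inits,
               lapply(gs[order(-scan)][seq_len(min(restarts, gammaGrid))],
                      function(g) { p <- init0; p[["gamma"]] <- g; p }))
  } else if (!length(inits)) inits <- list(init0)
  best <- NULL
  for (k in seq_along(inits)) {
    st <- step; st@init <- inits[[k]]
    fit <- runFit(site, st, seed = seed + k)
    if (is.null(best) || fit@maxLogLik > best@maxLogLik) best <- fit
  }
  est <- best@estimates
  g <- function(nm) if (nm %in% names(est)) unname(est[[nm]]) else
    .EXTRINSIC_DEFAULTS[[nm]]
  pose <- Pose(x0 = c(g("x"), g("y"), g("z")),
               angles = c(g("alpha"), g("beta"), g("gamma")),
               extraSigma = extraSigma, bgWeight = bgWeight)
  aligned <- applyPose(mlocs, pose, "data-to-model")
  list(pose = pose, logLik = best@maxLogLik, aligned = aligned,
       estimates = est[step@free])
}

#' Rank particles by all-against-all similarity
#'
#' Fills the similarity matrix M[i, j] with the maximum log-likelihood of
#' registering particle i (as a point model) to particle j, zero on the
#' diagonal, and ranks particles by decreasing row sum (ties broken by lower
#' index). The top-ranked particle best describes all others and serves as
#' the fusion seed.
#'
#' @param sites list of \linkS4class{Site}s.
#' @param seed integer seed.
#' @param ... forwarded to \code{\link{registerPair}}.
#' @return a \linkS4class{SimilarityMatrix}.
#' @export
similarityMatrix <- function(sites, seed = 1, ...) {
  n <- length(sites)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ## fitting particle i (model) to the data of particle j
    M[i, j] <- registerPair(sites[[j]], sites[[i]],
                            seed = seed + 997L * i + j, ...)$logLik
  }
  rs <- rowSums(M)
  rk <- order(-rs, seq_len(n))       # stable: ties toward the lower index
  new("SimilarityMatrix", scores = M, rank = as.integer(rk))
}

#' Build the initial data-driven template
#'
#' All-against-all registration of an n-particle subset, ranking by total
#' similarity, then cumulative fusion: the top-ranked particle seeds the
#' template and the remaining particles are registered to the growing
#' template in rank order, each fused in by taking the union of the
#' pose-corrected localizations.
#'
#' @param sites list of n >= 2 \linkS4class{Site}s (the subset).
#' @param seed integer seed.
#' @param ... forwarded to \code{\link{registerPair}}.
#' @return a \linkS4class{Template} with the similarity matrix in
#'   \code{attr(, "similarity")}.
#' @export
buildInitialTemplate <- function(sites, seed = 1, ...) {
  stopifnot(length(sites) >= 2)
  sim <- similarityMatrix(sites, seed = seed, ...)
  rk <- sim@rank
  fused <- localizations(sites[[rk[1]]])
  for (i in seq_along(rk)[-1]) {
    reg <- registerPair(sites[[rk[i]]], fused, seed = seed + 13L * i, ...)
    fused <- bindLocalizations(fused, reg$aligned)
  }
  tpl <- new("Template", localizations = fused, score = -Inf,
             iterations = 0L, history = numeric(0))
  attr(tpl, "similarity") <- sim
  tpl
}

#' Iterative model-free particle fusion
#'
#' Repeatedly registers all particles to the current template, pools the
#' pose-corrected localizations into a new candidate template and scores it
#' by the summed registration log-likelihood. An improved score is accepted
#' as the running best; the candidate always becomes the next registration
#' template. Stops after \code{J} consecutive iterations without improvement
#' and returns the best-scoring template.
#'
#' @param sites list of all k particles.
#' @param template the initial \linkS4class{Template}
#'   (from \code{\link{buildInitialTemplate}}).
#' @param J consecutive non-improving iterations tolerated before stopping.
#' @param seed integer seed.
#' @param maxIter hard cap on iterations.
#' @param ... forwarded to \code{\link{registerPair}}. After the first
#'   iteration each particle's previous pose is supplied as an additional
#'   refinement start alongside the rotational scan.
#' @return the best \linkS4class{Template}; its \code{history} slot holds the
#'   summed score of every iteration.
#' @export
iterativeAverage <- function(sites, template, J = 3, seed = 1, maxIter = 20,
                             ...) {
  stopifnot(nLocs(template@localizations) > 0)
  best <- template
  S <- -Inf
  cur <- template@localizations
  j <- 0L; it <- 0L
  hist <- numeric(0)
  warm <- vector("list", length(sites))   # per-particle pose warm starts
  while (j < J && it < maxIter) {
    it <- it + 1L
    lls <- numeric(length(sites))
    parts <- vector("list", length(sites))
    for (i in seq_along(sites)) {
      reg <- registerPair(sites[[i]], asSite(cur, 1e6),
                          seed = seed + 1000L * it + i, init = warm[[i]], ...)
      lls[i] <- reg$logLik
      parts[[i]] <- reg$aligned
      warm[[i]] <- reg$estimates
    }
    Snew <- sum(lls)
    hist <- c(hist, Snew)
    cand <- bindLocalizations(parts)
    if (Snew > S) {
      S <- Snew
      best <- new("Template", localizations = cand, score = S,
                  iterations = it, history = hist)
      j <- 0L
    } else {
      j <- j + 1L
    }
    cur <- cand                     # candidate is the next template
  }
  best@history <- hist
  best@iterations <- it
  best
}

#' Model-free averaging pipeline
#'
#' Convenience wrapper running \code{\link{buildInitialTemplate}} on a
#' subset, then \code{\link{iterativeAverage}} over the whole particle set.
#' With \code{prealign = TRUE} every particle is first centered and
#' axis-aligned by a smooth dual-ring fit (pose initialization only; no shape
#' parameter of the reference enters the average), which narrows the
#' rotational search as in reference workflows on ring-like particles.
#'
#' @param sites list of k particles.
#' @param nSubset subset size for the initial template (default
#'   min(50, k)).
#' @param J stopping patience of the iterative stage.
#' @param seed integer seed.
#' @param prealign pre-align particles with a dual-ring fit (3D ring-like
#'   particles only).
#' @param maxIter iteration cap of the fusion stage.
#' @param ... forwarded to \code{\link{registerPair}}.
#' @return a \linkS4class{Template}.
#' @export
modelFreeAverage <- function(sites, nSubset = min(50L, length(sites)), J = 3,
                             seed = 1, prealign = FALSE, maxIter = 20, ...) {
  if (prealign) sites <- lapply(seq_along(sites), function(i)
    prealignDualRing(sites[[i]], seed = seed + i))
  ## seed the template from the most azimuthally uniform particles: their
  ## corner signal is least masked by labeling-gap lumps (no shape model is
  ## involved -- only a per-particle uniformity score)
  uni <- vapply(sites, function(s) {
    sp <- azimuthalSpectrum(localizations(s), harmonics = 1:2)
    sum(sp) / max(nLocs(s), 1L)
  }, 1.0)
  subset <- order(uni)[seq_len(nSubset)]
  tpl <- buildInitialTemplate(sites[subset], seed = seed, ...)
  iterativeAverage(sites, tpl, J = J, seed = seed + 7919L,
                   maxIter = maxIter, ...)
}

#' Center and axis-align a ring-like particle by a smooth dual-ring fit
#'
#' Fits the continuous dual-ring model (free position, tilts, radius,
#' separation, background) and reverse-transforms the localizations so the
#' structure is centered with its symmetry axis along z. Used as optional
#' pose pre-alignment before model-free averaging.
#'
#' @param site a 3D \linkS4class{Site}.
#' @param seed integer seed.
#' @param sigmaMin precision floor, nm.
#' @param fitTilt also fit and remove the tilt (default FALSE: for
#'   near-perpendicular structures the tilt estimate's own error exceeds the
#'   true tilts at typical axial precisions).
#' @return a \linkS4class{Site} with pose-corrected localizations.
#' @export
prealignDualRing <- function(site, seed = 1, sigmaMin = 3, fitTilt = FALSE) {
  b <- siteSide(site) / 4
  tilt_names <- if (fitTilt) c("alpha", "beta") else character(0)
  tilt_fixed <- if (fitTilt) numeric(0) else c(alpha = 0, beta = 0)
  step <- fitStep(npcDualRing(),
                  free = c("x", "y", "z", tilt_names, "r", "s", "wbg"),
                  fixed = c(eps = 8, tilt_fixed),
                  lower = c(x = -b, y = -b, z = -b, alpha = -0.6,
                            beta = -0.6, r = 30, s = 15, wbg = 0),
                  upper = c(x = b, y = b, z = b, alpha = 0.6, beta = 0.6,
                            r = 80, s = 90, wbg = 0.5),
                  optimizer = "de", sigmaMin = sigmaMin,
                  control = list(generations = 25, popSize = 25,
                                 maxit = 300, ci = FALSE))
  fit <- runFit(site, step, seed = seed)
  est <- fit@estimates
  pose <- Pose(x0 = c(est[["x"]], est[["y"]], est[["z"]]),
               angles = c(.est(est, "alpha"), .est(est, "beta"), 0))
  aligned <- applyPose(localizations(site), pose, "data-to-model")
  ## re-crop: the alignment can push stray localizations past the box edge
  cropSite(aligned, center = rep(0, locDim(aligned)),
           sideLength = siteSide(site), id = site@id)
}

#' Reference-based averaging of multi-color sites
#'
#' Transforms every site into the model frame using its fitted reference
#' pose (Kx, reverse transform of the localizations) and pools the
#' localizations of the requested target channel across sites, yielding the
#' average distribution of the target protein in the reference coordinate
#' system. Sites whose reference fit did not converge are skipped with a
#' message.
#'
#' @param sites list of \linkS4class{Site}s.
#' @param fits list of reference \linkS4class{FitResult}s, one per site.
#' @param targetChannel channel to pool (NULL pools all channels).
#' @return a pooled \linkS4class{LocalizationSet} in the model frame.
#' @export
referenceAverage <- function(sites, fits, targetChannel = NULL) {
  stopifnot(length(sites) == length(fits))
  parts <- list()
  for (i in seq_along(sites)) {
    if (!fits[[i]]@converged) {
      message("site ", i, " skipped: reference fit not converged")
      next
    }
    est <- fits[[i]]@estimates
    pose <- Pose(x0 = c(.est(est, "x"), .est(est, "y"), .est(est, "z")),
                 angles = c(.est(est, "alpha"), .est(est, "beta"),
                            .est(est, "gamma")))
    al <- applyPose(localizations(sites[[i]]), pose, "data-to-model")
    if (!is.null(targetChannel)) al <- al[channels(al) == targetChannel]
    parts[[length(parts) + 1L]] <- al
  }
  if (!length(parts)) stop("no converged sites to average")
  bindLocalizations(parts)
}

#' Pseudotime reconstruction from static snapshots
#'
#' Sorts sites by a monotonically progressing fitted parameter (e.g. the
#' length of a growing structure), aligns each site with its fitted pose, and
#' pools the aligned localizations in consecutive bins, reconstructing a
#' dynamic process from fixed-cell snapshots. In binned mode, sites beyond
#' the last full bin are dropped; in moving-average mode (\code{window}
#' given), frames advance by \code{step} sites and all sites are used.
#'
#' @param sites list of \linkS4class{Site}s.
#' @param fits list of \linkS4class{FitResult}s, one per site; each must
#'   contain \code{sortKey} among its estimates.
#' @param sortKey name of the fitted parameter to sort by (ascending).
#' @param binSize sites per bin (binned mode).
#' @param window,step moving-average window and step in sites; \code{window}
#'   non-NULL selects moving-average mode.
#' @return list with \code{bins}: list of pooled \linkS4class{LocalizationSet}s,
#'   \code{order}: the site ordering, and \code{sortValues}: the sorted key
#'   values.
#' @export
pseudotimeReconstruct <- function(sites, fits, sortKey, binSize = 21,
                                  window = NULL, step = 1) {
  stopifnot(length(sites) == length(fits))
  vals <- vapply(fits, function(f) {
    if (!sortKey %in% names(f@estimates))
      stop("sort key '", sortKey, "' missing from a fit result")
    f@estimates[[sortKey]]
  }, 1.0)
  ord <- order(vals)
  aligned <- lapply(ord, function(i) {
    est <- fits[[i]]@estimates
    pose <- Pose(x0 = c(.est(est, "x"), .est(est, "y"), .est(est, "z")),
                 angles = c(.est(est, "alpha"), .est(est, "beta"),
                            .est(est, "gamma")))
    applyPose(localizations(sites[[i]]), pose, "data-to-model")
  })
  n <- length(aligned)
  if (is.null(window)) {
    nb <- floor(n / binSize)
    if (nb == 0) {
      warning("binSize exceeds the number of sites; returning a single bin")
      bins <- list(bindLocalizations(aligned))
    } else {
      bins <- lapply(seq_len(nb), function(b)
        bindLocalizations(aligned[((b - 1) * binSize + 1):(b * binSize)]))
    }
  } else {
    starts <- seq(1L, n - window + 1L, by = step)
    bins <- lapply(starts, function(s)
      bindLocalizations(aligned[s:(s + window - 1L)]))
  }
  list(bins = bins, order = ord, sortValues = vals[ord])
}

#' Azimuthal harmonic spectrum of a point cloud
#'
#' Histogram of the in-plane azimuthal angles about the z axis (360 bins)
#' followed by a discrete Fourier transform; returns the magnitudes of the
#' requested harmonics. The dominant harmonic of a well-resolved n-fold
#' symmetric particle average is n.
#'
#' @param locs a \linkS4class{LocalizationSet} or \linkS4class{Template}.
#' @param harmonics harmonic orders to report.
#' @return named numeric vector of spectral magnitudes.
#' @export
azimuthalSpectrum <- function(locs, harmonics = 1:16) {
  if (is(locs, "Template")) locs <- locs@localizations
  xy <- coords(locs)[, 1:2, drop = FALSE]
  xy <- sweep(xy, 2, colMeans(xy))
  ang <- atan2(xy[, 2], xy[, 1]) %% (2 * pi)
  h <- tabulate(pmin(floor(ang / (2 * pi) * 360) + 1L, 360L), nbins = 360L)
  sp <- Mod(fft(h))
  stats::setNames(sp[harmonics + 1L], harmonics)
}
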