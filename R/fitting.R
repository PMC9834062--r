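#' @include pdfcore.R
NULL

## extrinsic parameter names and their defaults / default bounds
.EXTRINSIC_DEFAULTS <- c(x = 0, y = 0, z = 0, alpha = 0, beta = 0, gamma = 0,
                         sx = 1, sy = 1, sz = 1, eps = 0, wbg = 0, w = 1)

#' Define a fitting step
#'
#' A fitting step is one maximum-likelihood optimization problem over a
#' composite model. The parameter space is the union of every component's
#' intrinsic parameters and the extrinsic parameters \code{x, y, z} (nm),
#' \code{alpha, beta, gamma} (rad), \code{sx, sy, sz} (scale), \code{eps}
#' (nm), \code{wbg} and the raw component weight \code{w}; parameters of
#' component m > 1 are prefixed \code{"c<m>."}. Every parameter not listed in
#' \code{free} is held at its value in \code{fixed} (or at its default:
#' model defaults for intrinsics, identity pose, eps = 0, wbg = 0). Raw
#' component weights are normalized within each channel so the channel PDF
#' sums to 1 with the background.
#'
#' @param models a \linkS4class{GeometricModel}, a \linkS4class{CompositeSpec}
#'   or a list of models (optionally named lists \code{list(model=, channel=)}).
#' @param free character vector of free parameter names.
#' @param fixed named numeric vector of fixed parameter values.
#' @param lower,upper named numeric bounds for free parameters; defaults are
#'   the model's intrinsic bounds and generic extrinsic bounds derived from
#'   the site.
#' @param init named numeric initial values (free parameters; others ignored).
#' @param optimizer "de" (seeded global differential evolution with simplex
#'   polish), "simplex" (Nelder-Mead on bound-transformed coordinates) or
#'   "gradient" (L-BFGS-B).
#' @param objective "mle" or "cc".
#' @param sigmaMin precision floor for discretization, nm.
#' @param control list of optimizer settings: \code{popSize}, \code{generations}
#'   (de), \code{maxit} (simplex/gradient), \code{polish} (de; default TRUE),
#'   \code{ci} (compute confidence intervals; default TRUE),
#'   \code{inheritMap} (named character: new name -> previous-step name, used
#'   by \code{\link{chainFit}}).
#' @return a \linkS4class{FitStep}.
#' @export
fitStep <- function(models, free, fixed = numeric(0),
                    lower = numeric(0), upper = numeric(0),
                    init = numeric(0),
                    optimizer = c("simplex", "de", "gradient"),
                    objective = c("mle", "cc"), sigmaMin = 0,
                    control = list()) {
  optimizer <- match.arg(optimizer)
  objective <- match.arg(objective)
  comps <- .as_components(models)
  tab <- .param_table(comps)
  ## merge user bounds over defaults
  lo <- tab$lower; hi <- tab$upper
  lo[names(lower)] <- lower
  hi[names(upper)] <- upper
  unknown <- setdiff(c(free, names(fixed)), names(tab$defaults))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  new("FitStep", components = comps, free = free,
      fixed = fixed, lower = lo[free], upper = hi[free],
      init = init[intersect(names(init), free)],
      optimizer = optimizer, objective = objective,
      sigmaMin = sigmaMin, control = control)
}

.as_components <- function(models) {
  if (is(models, "CompositeSpec")) {
    return(lapply(models@components, function(cmp)
      list(model = cmp$model, channel = as.integer(cmp$channel))))
  }
  if (is(models, "GeometricModel"))
    return(list(list(model = models, channel = 0L)))
  lapply(models, function(m) {
    if (is(m, "GeometricModel")) list(model = m, channel = 0L)
    else list(model = m$model, channel = as.integer(m$channel %||% 0L))
  })
}

.prefix <- function(m) if (m == 1) "" else sprintf("c%d.", m)

## paste0 maps zero-length inputs to ""; guard prefixed-name construction
.pfx_names <- function(pfx, pn) if (length(pn)) paste0(pfx, pn) else character(0)

## full parameter table of a component list: defaults and generic bounds
.param_table <- function(comps) {
  defaults <- numeric(0); lower <- numeric(0); upper <- numeric(0)
  ext_lo <- c(x = -500, y = -500, z = -500, alpha = -pi, beta = -pi,
              gamma = -pi, sx = 0.2, sy = 0.2, sz = 0.2, eps = 0, wbg = 0,
              w = 1e-6)
  ext_hi <- c(x = 500, y = 500, z = 500, alpha = pi, beta = pi, gamma = pi,
              sx = 5, sy = 5, sz = 5, eps = 100, wbg = 1, w = 1)
  for (m in seq_along(comps)) {
    pfx <- .prefix(m)
    mod <- comps[[m]]$model
    pn <- names(mod@params) %||% character(0)
    nm <- .pfx_names(pfx, pn)
    defaults <- c(defaults,
                  stats::setNames(vapply(mod@params, as.numeric, 1.0), nm),
                  stats::setNames(.EXTRINSIC_DEFAULTS,
                                  paste0(pfx, names(.EXTRINSIC_DEFAULTS))))
    lower <- c(lower, stats::setNames(mod@lower[pn], nm),
               stats::setNames(ext_lo, paste0(pfx, names(ext_lo))))
    upper <- c(upper, stats::setNames(mod@upper[pn], nm),
               stats::setNames(ext_hi, paste0(pfx, names(ext_hi))))
  }
  ## wbg is shared (unprefixed name only)
  list(defaults = defaults[!duplicated(names(defaults))],
       lower = lower[!duplicated(names(lower))],
       upper = upper[!duplicated(names(upper))])
}

## resolve the full parameter vector (defaults <- fixed <- free values)
.resolve_params <- function(step, pfree) {
  tab <- .param_table(step@components)
  p <- tab$defaults
  p[names(step@fixed)] <- step@fixed
  p[names(pfree)] <- pfree
  p
}

## prototype Pose reused by the optimizer hot path (slot assignment skips the
## full validity method; the optimizer keeps parameters inside valid bounds)
.POSE_PROTO <- NULL

.pose_quick <- function(x0, angles, scale, eps) {
  if (is.null(.POSE_PROTO))
    utils::assignInMyNamespace(".POSE_PROTO", Pose())
  p <- .POSE_PROTO
  p@x0 <- x0; p@angles <- angles; p@scale <- scale; p@extraSigma <- eps
  p
}

## plain component list (model, pose, weight, channel) from a resolved
## parameter vector; weights normalized per channel against the background
.build_components <- function(step, p) {
  comps <- vector("list", length(step@components))
  wbg <- unname(p[["wbg"]])
  for (m in seq_along(step@components)) {
    pfx <- .prefix(m)
    g <- function(nm) unname(p[[paste0(pfx, nm)]])
    mod <- step@components[[m]]$model
    if (length(mod@params)) {
      pars <- as.list(p[.pfx_names(pfx, names(mod@params))])
      names(pars) <- names(mod@params)
      mod@params <- pars
    }
    comps[[m]] <- list(
      model = mod,
      pose = .pose_quick(c(g("x"), g("y"), g("z")),
                         c(g("alpha"), g("beta"), g("gamma")),
                         c(g("sx"), g("sy"), g("sz")), g("eps")),
      weight = g("w"), channel = step@components[[m]]$channel)
  }
  chans <- vapply(comps, function(x) x$channel, 1L)
  for (ch in unique(chans)) {
    idx <- which(chans == ch)
    wsum <- sum(vapply(comps[idx], function(x) x$weight, 1.0))
    for (i in idx) comps[[i]]$weight <- comps[[i]]$weight / wsum * (1 - wbg)
  }
  list(components = comps, bgWeight = wbg)
}

## build a CompositeSpec from a resolved parameter vector
.build_spec <- function(step, p) {
  comps <- vector("list", length(step@components))
  wbg <- unname(p[["wbg"]])
  for (m in seq_along(step@components)) {
    pfx <- .prefix(m)
    g <- function(nm) unname(p[[paste0(pfx, nm)]])
    mod <- step@components[[m]]$model
    if (length(mod@params)) {
      pars <- as.list(p[.pfx_names(pfx, names(mod@params))])
      names(pars) <- names(mod@params)
      mod@params <- pars
    }
    pose <- Pose(x0 = c(g("x"), g("y"), g("z")),
                 angles = c(g("alpha"), g("beta"), g("gamma")),
                 scale = c(g("sx"), g("sy"), g("sz")),
                 extraSigma = g("eps"), bgWeight = 0)
    comps[[m]] <- list(model = mod, pose = pose, weight = g("w"),
                       channel = step@components[[m]]$channel)
  }
  ## normalize raw component weights within each channel
  chans <- vapply(comps, function(x) x$channel, 1L)
  for (ch in unique(chans)) {
    idx <- which(chans == ch)
    wsum <- sum(vapply(comps[idx], function(x) x$weight, 1.0))
    for (i in idx) comps[[i]]$weight <- comps[[i]]$weight / wsum * (1 - wbg)
  }
  new("CompositeSpec", components = comps, bgWeight = wbg,
      colorWeights = "unit")
}

## the objective as a function of the free-parameter vector (maximized)
.make_objective <- function(site, step) {
  locs <- localizations(site)
  force(step)
  tab <- .param_table(step@components)
  base <- tab$defaults
  base[names(step@fixed)] <- step@fixed
  mle <- step@objective == "mle"
  ## fast path: one point-producing component, single channel
  mod1 <- step@components[[1]]$model
  if (length(step@components) == 1L && mod1@kind != "density-image" &&
      length(unique(channels(locs))) == 1L) {
    xm <- coords(locs)
    D <- ncol(xm)
    sm <- precisions(locs)
    sm[sm < step@sigmaMin] <- step@sigmaMin   # floor both spacing and PDF
    spacing <- 0.75 * min(sm)
    pn <- names(mod1@params)
    bgdens <- siteSide(site)^(-D)
    fun <- mod1@fun
    return(function(pfree) {
      p <- base
      p[step@free] <- pfree
      ev <- fun(as.list(p[pn]), spacing)
      pts <- ev$points
      if (D == 3) {
        R <- rotationMatrix(c(p[["alpha"]], p[["beta"]], p[["gamma"]]))
        S <- p[c("sx", "sy", "sz")]
        v <- t((S * R) %*% t(pts) + c(p[["x"]], p[["y"]], p[["z"]]))
      } else {
        g <- p[["gamma"]]
        R <- matrix(c(cos(g), sin(g), -sin(g), cos(g)), 2, 2)
        v <- t((p[c("sx", "sy")] * R) %*% t(pts) + c(p[["x"]], p[["y"]]))
      }
      wbg <- p[["wbg"]]
      dens <- (1 - wbg) * .gmmDensity(xm, sm, v, ev$weights, p[["eps"]]) +
        wbg * bgdens
      if (mle) sum(log(pmax(dens, .DENSITY_FLOOR))) else sum(dens)
    })
  }
  function(pfree) {
    p <- base
    p[step@free] <- pfree
    built <- .build_components(step, p)
    dens <- .mixture_density(locs, built$components, built$bgWeight, site,
                             step@sigmaMin)
    if (mle)
      sum(log(pmax(dens, .DENSITY_FLOOR)))
    else
      sum(dens)
  }
}

## ---- optimizers ------------------------------------------------------------

## seeded differential evolution (rand/1/bin) with bound reflection
.de_optim <- function(fn, lower, upper, init = NULL, popSize = NULL,
                      generations = 40, F = 0.8, CR = 0.9) {
  P <- length(lower)
  if (is.null(popSize)) popSize <- max(15L, 6L * P)
  pop <- t(replicate(popSize, runif(P, lower, upper)))
  if (P == 1) pop <- matrix(pop, ncol = 1)
  if (!is.null(init)) pop[1, ] <- pmin(pmax(init, lower), upper)
  fit <- apply(pop, 1, fn)
  for (g in seq_len(generations)) {
    for (i in seq_len(popSize)) {
      r <- sample(setdiff(seq_len(popSize), i), 3L)
      mut <- pop[r[1], ] + F * (pop[r[2], ] - pop[r[3], ])
      ## reflect out-of-bound coordinates back into the box
      below <- mut < lower; mut[below] <- (2 * lower - mut)[below]
      above <- mut > upper; mut[above] <- (2 * upper - mut)[above]
      mut <- pmin(pmax(mut, lower), upper)
      cross <- runif(P) < CR
      cross[sample.int(P, 1L)] <- TRUE
      trial <- ifelse(cross, mut, pop[i, ])
      ft <- fn(trial)
      if (ft > fit[i]) { pop[i, ] <- trial; fit[i] <- ft }
    }
  }
  best <- which.max(fit)
  list(par = pop[best, ], value = fit[best])
}

## logistic map between the bounded box and unconstrained coordinates
.to_unbounded <- function(p, lo, hi) {
  u <- (p - lo) / (hi - lo)
  u <- pmin(pmax(u, 1e-8), 1 - 1e-8)
  log(u / (1 - u))
}
.to_bounded <- function(y, lo, hi) lo + (hi - lo) / (1 + exp(-y))

.simplex_optim <- function(fn, lower, upper, init, maxit = 600) {
  y0 <- .to_unbounded(init, lower, upper)
  if (length(y0) == 1L) {
    # 1-parameter problems: bracket with a coarse grid, then refine locally
    grid <- seq(lower, upper, length.out = 41L)
    vals <- vapply(grid, fn, 1.0)
    best <- which.max(vals)
    span <- c(grid[max(best - 1L, 1L)], grid[min(best + 1L, 41L)])
    opt <- stats::optimize(function(p) -fn(p), interval = span,
                           tol = 1e-10)
    cand <- c(opt$minimum, init)
    cv <- vapply(cand, fn, 1.0)
    return(list(par = cand[which.max(cv)], value = max(cv),
                convergence = 0L))
  } else {
    res <- optim(y0, function(y) -fn(.to_bounded(y, lower, upper)),
                 method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-10))
  }
  list(par = .to_bounded(res$par, lower, upper), value = -res$value,
       convergence = res$convergence)
}

.gradient_optim <- function(fn, lower, upper, init, maxit = 300) {
  res <- optim(init, function(p) -fn(p), method = "L-BFGS-B",
               lower = lower, upper = upper,
               control = list(maxit = maxit, factr = 1e4))
  list(par = res$par, value = -res$value, convergence = res$convergence)
}

#' Maximize the likelihood of one fitting step
#'
#' Runs the step's optimizer over its free parameters within bounds and
#' returns the parameter estimates, the maximum log-likelihood, AIC/AICc and
#' (by default) 95\% confidence intervals from a quadratic approximation of
#' the log-likelihood around the optimum. Deterministic for a given
#' \code{(site, step, seed)}.
#'
#' @param site a non-empty \linkS4class{Site}.
#' @param step a \linkS4class{FitStep}.
#' @param seed integer seed controlling all randomness in the optimizer and
#'   the confidence-interval sampling.
#' @return a \linkS4class{FitResult}.
#' @export
runFit <- function(site, step, seed = 1) {
  stopifnot(is(site, "Site"), is(step, "FitStep"))
  validObject(step)
  set.seed(seed)
  K <- nLocs(site)
  P <- length(step@free)
  if (K < P + 2)
    stop(sprintf("degenerate site: K = %d localizations cannot constrain %d free parameters", K, P))
  obj <- .make_objective(site, step)
  ctl <- step@control
  flags <- character(0)
  if (P > 0) {
    lo <- step@lower; hi <- step@upper
    init <- (lo + hi) / 2
    init[names(step@init)] <- step@init
    init <- pmin(pmax(init, lo), hi)
    res <- switch(step@optimizer,
      de = {
        r <- .de_optim(obj, lo, hi, init = init,
                       popSize = ctl$popSize,
                       generations = ctl$generations %||% 40)
        if (!isFALSE(ctl$polish))
          r <- .simplex_optim(obj, lo, hi, r$par, maxit = ctl$maxit %||% 400)
        r
      },
      simplex = .simplex_optim(obj, lo, hi, init, maxit = ctl$maxit %||% 600),
      gradient = .gradient_optim(obj, lo, hi, init, maxit = ctl$maxit %||% 300))
    if (!is.null(res$convergence) && res$convergence != 0)
      flags <- c(flags, "optimizer did not report convergence; best-so-far returned")
    pfree <- stats::setNames(res$par, step@free)
    ll <- res$value
  } else {
    pfree <- numeric(0)
    ll <- obj(numeric(0))
  }
  p <- .resolve_params(step, pfree)
  if (p[["wbg"]] > 0.95)
    flags <- c(flags, "degenerate fit: background weight near 1")
  ## fold n-fold-symmetric rotation into its fundamental interval
  ic <- aicc(ll, nParams = P, nLocs = K)
  wbg <- unname(p[["wbg"]])
  d <- siteSide(site)
  result <- new("FitResult", estimates = p, freeNames = step@free,
                maxLogLik = ll, aic = ic$aic, aicc = ic$aicc,
                aiccPerLoc = ic$aiccPerLoc, nParams = as.integer(P),
                nLocs = as.integer(K),
                derived = list(Kbg = K * wbg, Km = K * (1 - wbg),
                               rhoBg = K * wbg / d^2),
                converged = length(flags) == 0, flags = flags)
  if (P > 0 && !isFALSE(ctl$ci)) {
    ci <- estimateCI(site, step, pfree, seed = seed + 1L)
    result@hessian <- ci$hessian
    result@variances <- ci$variances
    result@ci95 <- ci$ci95
    result@a0 <- ci$a0
    result@flags <- c(result@flags, ci$flags)
  }
  result
}

#' Confidence intervals from a quadratic log-likelihood approximation
#'
#' Samples the log-likelihood at random free-parameter values around the
#' estimate (uniform within +/- 2\% of each bound range, 20 P (P + 3) / 2
#' points), least-squares-fits a quadratic surface, converts it to the
#' observed-information Hessian and reports per-parameter variances
#' \code{var_b = [(-H)^-1]_bb} and 95\% intervals
#' \code{p_b +/- 1.96 sqrt(var_b)}. If -H is not positive definite the
#' pseudo-inverse is used and the result is flagged unreliable.
#'
#' @param site the fitted \linkS4class{Site}.
#' @param step the \linkS4class{FitStep} that was optimized.
#' @param pfree named numeric vector of the free-parameter estimates.
#' @param seed integer seed for the sampling.
#' @return list with \code{hessian}, \code{variances}, \code{ci95},
#'   \code{a0}, \code{flags}.
#' @export
estimateCI <- function(site, step, pfree, seed = 1) {
  set.seed(seed)
  obj <- .make_objective(site, step)
  P <- length(pfree)
  lo <- step@lower; hi <- step@upper
  radius <- 0.02 * (hi - lo)
  nS <- 20L * P * (P + 3L) / 2L
  flags <- character(0)
  if (any(pfree <= lo + 1e-12) || any(pfree >= hi - 1e-12))
    flags <- c(flags, "estimate at a bound; confidence intervals unreliable")
  D <- t(replicate(nS, runif(P, -radius, radius)))
  if (P == 1) D <- matrix(D, ncol = 1)
  lls <- apply(D, 1, function(d) obj(pmin(pmax(pfree + d, lo), hi)))
  ## design: intercept + linear + quadratic monomials of the displacement
  X <- cbind(1, D)
  cn <- c("a0", paste0("l", seq_len(P)))
  for (i in seq_len(P)) for (j in i:P) {
    X <- cbind(X, D[, i] * D[, j])
    cn <- c(cn, sprintf("q%d_%d", i, j))
  }
  colnames(X) <- cn
  fit <- lm.fit(X, lls)
  cf <- fit$coefficients
  Hq <- matrix(0, P, P)
  for (i in seq_len(P)) for (j in i:P) {
    v <- cf[[sprintf("q%d_%d", i, j)]]
    if (i == j) Hq[i, i] <- v else Hq[i, j] <- Hq[j, i] <- v / 2
  }
  H <- 2 * Hq                      # Hessian of LL from the quadratic form
  negH <- -H
  ev <- eigen(negH, symmetric = TRUE)
  if (any(ev$values <= 0)) {
    flags <- c(flags, "observed information not positive definite; pseudo-inverse used")
    vals <- ifelse(ev$values > 1e-12 * max(abs(ev$values)), 1 / ev$values, 0)
    inv <- ev$vectors %*% diag(vals, P) %*% t(ev$vectors)
  } else {
    inv <- solve(negH)
  }
  variances <- stats::setNames(pmax(diag(inv), 0), names(pfree))
  half <- 1.96 * sqrt(variances)
  ci95 <- cbind(lo = pfree - half, hi = pfree + half)
  rownames(ci95) <- names(pfree)
  dimnames(H) <- list(names(pfree), names(pfree))
  list(hessian = H, variances = variances, ci95 = ci95,
       a0 = unname(cf[["a0"]]), flags = flags)
}

#' @rdname aicc
setMethod("aicc", "numeric", function(object, nParams, nLocs, ...) {
  P <- nParams; K <- nLocs
  if (K <= P + 1)
    stop("AICc undefined for K <= P + 1 (K = ", K, ", P = ", P, ")")
  aic <- 2 * P - 2 * object
  aicc <- aic + (2 * P^2 + 2 * P) / (K - P - 1)
  list(aic = aic, aicc = aicc, aiccPerLoc = aicc / K)
})

#' @rdname aicc
setMethod("aicc", "FitResult", function(object, ...) {
  list(aic = object@aic, aicc = object@aicc, aiccPerLoc = object@aiccPerLoc)
})

#' Chain several fitting steps
#'
#' Runs the steps in order; each step's initial values are inherited from the
#' previous step's estimates for every free parameter of the same name (or
#' through the step's explicit \code{control$inheritMap}, a named character
#' vector new-name -> previous-name). Explicit \code{init} values of a step
#' take precedence over inheritance. Chaining from a smooth, few-parameter
#' model to a detailed one avoids local maxima of the likelihood.
#'
#' @param site a \linkS4class{Site}.
#' @param steps list of \linkS4class{FitStep} objects.
#' @param seed integer; step i uses seed + i - 1.
#' @return list of \linkS4class{FitResult}, one per step.
#' @export
chainFit <- function(site, steps, seed = 1) {
  results <- vector("list", length(steps))
  prev <- NULL
  for (i in seq_along(steps)) {
    step <- steps[[i]]
    if (!is.null(prev)) {
      est <- prev@estimates
      map <- step@control$inheritMap
      inherit <- stats::setNames(est[intersect(step@free, names(est))],
                                 intersect(step@free, names(est)))
      if (!is.null(map)) {
        bad <- map[!map %in% names(est)]
        if (length(bad))
          stop("inheritMap refers to unknown previous parameter(s): ",
               paste(bad, collapse = ", "))
        inherit[names(map)] <- est[map]
      }
      inherit <- pmin(pmax(inherit, step@lower[names(inherit)]),
                      step@upper[names(inherit)])
      keep <- setdiff(names(step@init), names(inherit))
      step@init <- c(step@init[keep], inherit)
    }
    results[[i]] <- runFit(site, step, seed = seed + i - 1L)
    prev <- results[[i]]
  }
  results
}

#' Fit candidate models and rank them by AICc
#'
#' Fits every candidate (a \linkS4class{FitStep} or a chain given as a list of
#' steps) to the same site and ranks them by ascending AICc: the smallest
#' AICc indicates the best model for these data.
#'
#' @param site a \linkS4class{Site}.
#' @param candidates named list of FitStep objects or step lists.
#' @param seed integer seed (each candidate gets an offset seed).
#' @return a data.frame with columns \code{model}, \code{logLik}, \code{P},
#'   \code{K}, \code{aicc}, \code{aiccPerLoc}, sorted ascending by AICc,
#'   with the fitted \linkS4class{FitResult}s in \code{attr(x, "fits")}.
#' @export
selectModel <- function(site, candidates, seed = 1) {
  if (is.null(names(candidates)))
    names(candidates) <- paste0("model", seq_along(candidates))
  fits <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    cand <- candidates[[i]]
    fits[[i]] <- if (is.list(cand))
      tail(chainFit(site, cand, seed = seed + 100L * (i - 1L)), 1L)[[1L]]
    else runFit(site, cand, seed = seed + 100L * (i - 1L))
  }
  names(fits) <- names(candidates)
  tab <- data.frame(
    model = names(candidates),
    logLik = vapply(fits, maxLogLik, 1.0),
    P = vapply(fits, function(f) as.numeric(f@nParams), 1.0),
    K = vapply(fits, function(f) as.numeric(f@nLocs), 1.0),
    aicc = vapply(fits, function(f) f@aicc, 1.0),
    aiccPerLoc = vapply(fits, function(f) f@aiccPerLoc, 1.0),
    row.names = NULL)
  ord <- order(tab$aicc)                    # stable: ties keep input order
  tab <- tab[ord, , drop = FALSE]
  attr(tab, "fits") <- fits
  tab
}

## ---- the standard NPC fitting chain ---------------------------------------

#' Chained dual-ring fit of a nuclear-pore site
#'
#' The standard three-step chain for two-ring, n-fold-symmetric structures:
#' (1) a smooth dual-ring fit with fixed radius and a large fixed extra
#' uncertainty, optimized globally, to find position, orientation and ring
#' separation; (2) a dual-ring refinement with free radius, separation and
#' extra uncertainty; (3) the discrete-corner model adding the ring twist,
#' with the in-plane rotation initialized by a coarse grid search over its
#' n-fold fundamental interval. Returns the per-step results; the twist and
#' in-plane rotation of the final step are reported modulo the symmetry.
#'
#' @param site a \linkS4class{Site} holding one structure (3D).
#' @param seed integer seed.
#' @param symmetry rotational symmetry of the final discrete model.
#' @param rInit radius used (fixed) in the smooth first step, nm.
#' @param sigmaMin precision floor for discretization, nm.
#' @param maxTilt bound on the tilt angles alpha, beta (rad). The default 0
#'   fixes the tilt at zero: nuclear pores sit approximately perpendicular in
#'   the nuclear envelope, and at the axial precisions typical of astigmatic
#'   3D data the tilt trades against the ring separation (an inclined ring
#'   spreads in z much like two separated rings), biasing the separation
#'   downward when left free. Set a positive bound to fit the tilt.
#' @param ci compute confidence intervals for the final step.
#' @param nSteps 3 runs the full chain; 2 stops after the dual-ring
#'   refinement (when only pose, radius and separation are needed).
#' @return list of per-step \linkS4class{FitResult}s (smooth, ring, and with
#'   \code{nSteps = 3} the discrete-corner step).
#' @export
npcFitChain <- function(site, seed = 1, symmetry = 8L, rInit = 50,
                        sigmaMin = 5, maxTilt = 0, ci = FALSE,
                        nSteps = 3L) {
  d <- siteSide(site)
  b <- d / 4
  n <- as.integer(symmetry)
  tiltFree <- maxTilt > 0
  tilt_names <- if (tiltFree) c("alpha", "beta") else character(0)
  tilt_fixed <- if (tiltFree) numeric(0) else c(alpha = 0, beta = 0)
  tlo <- c(alpha = -maxTilt, beta = -maxTilt)[tilt_names]
  thi <- c(alpha = maxTilt, beta = maxTilt)[tilt_names]
  step1 <- fitStep(npcDualRing(r = rInit, s = 50),
                   free = c("x", "y", "z", tilt_names, "s", "wbg"),
                   fixed = c(r = rInit, eps = 10, tilt_fixed),
                   lower = c(x = -b, y = -b, z = -b, tlo, s = 15, wbg = 0),
                   upper = c(x = b, y = b, z = b, thi, s = 90, wbg = 0.5),
                   optimizer = "de", sigmaMin = sigmaMin,
                   control = list(generations = 30, popSize = 30,
                                  maxit = 300, ci = FALSE))
  step2 <- fitStep(npcDualRing(),
                   free = c("x", "y", "z", tilt_names, "r", "s", "eps",
                            "wbg"),
                   fixed = tilt_fixed,
                   lower = c(x = -b, y = -b, z = -b, tlo, r = 30, s = 15,
                             eps = 0, wbg = 0),
                   upper = c(x = b, y = b, z = b, thi, r = 80, s = 90,
                             eps = 25, wbg = 0.5),
                   optimizer = "de", sigmaMin = sigmaMin,
                   control = list(generations = 32, popSize = 24,
                                  maxit = 400, ci = FALSE))
  step3 <- fitStep(npcDiscrete(symmetry = n),
                   free = c("x", "y", "z", tilt_names, "gamma", "theta",
                            "r", "s", "eps", "wbg"),
                   fixed = tilt_fixed,
                   lower = c(x = -b, y = -b, z = -b, tlo, gamma = 0,
                             theta = -pi / n, r = 30, s = 15, eps = 0,
                             wbg = 0),
                   upper = c(x = b, y = b, z = b, thi, gamma = 2 * pi / n,
                             theta = pi / n, r = 80, s = 90, eps = 25,
                             wbg = 0.5),
                   optimizer = "simplex", sigmaMin = sigmaMin,
                   control = list(maxit = 1000, ci = ci))
  r12 <- chainFit(site, list(step1, step2), seed = seed)
  if (nSteps < 3L) return(r12)
  r3 <- .npc_step3(site, step3, r12[[2]]@estimates, n, seed + 2L)
  c(r12, list(r3))
}

## run the discrete-corner step with a joint coarse grid search over the
## in-plane rotation and the twist as initialization
.npc_step3 <- function(site, step3, est, n, seed) {
  inherit <- intersect(step3@free, names(est))
  init <- stats::setNames(pmin(pmax(est[inherit], step3@lower[inherit]),
                               step3@upper[inherit]), inherit)
  obj <- .make_objective(site, step3)
  gammas <- seq(0, 2 * pi / n, length.out = 13L)[-13L]
  thetas <- seq(-pi / n + 0.05, pi / n - 0.05, length.out = 7L)
  best <- c(-Inf, 0, 0)
  for (g in gammas) for (th in thetas) {
    p <- (step3@lower + step3@upper) / 2
    p[names(init)] <- init
    p[["gamma"]] <- g
    p[["theta"]] <- th
    v <- obj(p[step3@free])
    if (v > best[1]) best <- c(v, g, th)
  }
  step3@init <- c(init, gamma = best[2], theta = best[3])
  r3 <- runFit(site, step3, seed = seed)
  ## report gamma modulo the fundamental interval, ties toward its start
  r3@estimates[["gamma"]] <- r3@estimates[["gamma"]] %% (2 * pi / n)
  r3
}

#' Compare rotational symmetries of a two-ring site by AICc
#'
#' Fits the same site with discrete-corner models of different rotational
#' symmetries and ranks them by AICc. The smooth dual-ring steps of the
#' fitting chain do not depend on the symmetry and are run once; every
#' candidate symmetry then refines from the same smooth fit, so all
#' candidates see identical localizations and identical initialization
#' quality.
#'
#' @inheritParams npcFitChain
#' @param symmetries integer vector of candidate symmetries.
#' @return a data.frame (one row per symmetry, ascending AICc) with columns
#'   \code{symmetry}, \code{logLik}, \code{P}, \code{K}, \code{aicc},
#'   \code{aiccPerLoc}; fitted results in \code{attr(, "fits")}.
#' @export
npcSelectSymmetry <- function(site, symmetries = 6:10, seed = 1, rInit = 50,
                              sigmaMin = 5, maxTilt = 0) {
  chain <- npcFitChain(site, seed = seed, symmetry = symmetries[1],
                       rInit = rInit, sigmaMin = sigmaMin, maxTilt = maxTilt)
  est <- chain[[2]]@estimates
  d <- siteSide(site)
  b <- d / 4
  fits <- vector("list", length(symmetries))
  tiltFree <- maxTilt > 0
  tilt_names <- if (tiltFree) c("alpha", "beta") else character(0)
  tilt_fixed <- if (tiltFree) numeric(0) else c(alpha = 0, beta = 0)
  tlo <- c(alpha = -maxTilt, beta = -maxTilt)[tilt_names]
  thi <- c(alpha = maxTilt, beta = maxTilt)[tilt_names]
  for (k in seq_along(symmetries)) {
    n <- as.integer(symmetries[k])
    if (n == as.integer(symmetries[1])) {
      fits[[k]] <- chain[[3]]
      next
    }
    step3 <- fitStep(npcDiscrete(symmetry = n),
                     free = c("x", "y", "z", tilt_names, "gamma",
                              "theta", "r", "s", "eps", "wbg"),
                     fixed = tilt_fixed,
                     lower = c(x = -b, y = -b, z = -b, tlo, gamma = 0,
                               theta = -pi / n, r = 30, s = 15, eps = 0,
                               wbg = 0),
                     upper = c(x = b, y = b, z = b, thi, gamma = 2 * pi / n,
                               theta = pi / n, r = 80, s = 90, eps = 25,
                               wbg = 0.5),
                     optimizer = "simplex", sigmaMin = sigmaMin,
                     control = list(maxit = 1000, ci = FALSE))
    fits[[k]] <- .npc_step3(site, step3, est, n, seed + 2L + k)
  }
  tab <- data.frame(
    symmetry = as.integer(symmetries),
    logLik = vapply(fits, maxLogLik, 1.0),
    P = vapply(fits, function(f) as.numeric(f@nParams), 1.0),
    K = vapply(fits, function(f) as.numeric(f@nLocs), 1.0),
    aicc = vapply(fits, function(f) f@aicc, 1.0),
    aiccPerLoc = vapply(fits, function(f) f@aiccPerLoc, 1.0))
  ord <- order(tab$aicc)
  tab <- tab[ord, , drop = FALSE]
  attr(tab, "fits") <- stats::setNames(fits, symmetries)
  tab
}
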