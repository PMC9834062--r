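#' @include pdfcore.R
NULL

#' Default localization-precision rule
#'
#' Analytic Gaussian-PSF precision: \code{sigma_xy = sPsf / sqrt(photons)} and
#' \code{sigma_z = 3 sigma_xy}. This deliberately replaces the experimental
#' spline-PSF Cramer-Rao bound used on real microscopes; any rule with the
#' same signature can be plugged into \code{\link{SimConfig}}.
#'
#' @param photons photon counts.
#' @param cfg the \linkS4class{SimConfig} (uses \code{cfg@bgPhotons} only via
#'   user-supplied rules; the default ignores it).
#' @param sPsf PSF standard deviation, nm.
#' @return matrix with columns sx, sy, sz (nm).
#' @export
gaussianPsfPrecision <- function(photons, cfg, sPsf = 130) {
  sxy <- sPsf / sqrt(pmax(photons, 1))
  cbind(sx = sxy, sy = sxy, sz = 3 * sxy)
}

#' Construct a simulation configuration
#'
#' Defaults describe a typical blinking-dye acquisition of the nuclear pore
#' reference sample: 60\% labeling efficiency, 80\% reactivation probability
#' (cyanine dyes under standard blinking buffers re-blink several times, and
#' together with the on-time this reproduces the few hundred localizations
#' per nuclear pore seen in experimental reference data), 0.2 s mean bright
#' time, 0.1 s frames, a photon budget that yields a mean lateral
#' localization precision close to 10 nm under the default precision rule,
#' and a 6.4 nm random displacement standing in for linkage error and
#' residual drift.
#'
#' @param pLabel labeling probability.
#' @param pReact reactivation probability (must be < 1).
#' @param meanOnTime mean bright-state lifetime, s.
#' @param frameTime frame time, s.
#' @param brightness photons per second while on.
#' @param bgPhotons background photons/pixel/frame (used only by precision
#'   rules that model it).
#' @param extraDisplacementSD per-axis fluorophore displacement SD, nm.
#' @param nFrames number of frames.
#' @param bgDensity spurious uniform localizations per nm^D within a site.
#' @param nContinuous fluorophore positions drawn from continuous models.
#' @param precisionModel function(photons, cfg) -> matrix sx, sy, sz.
#' @return a \linkS4class{SimConfig}.
#' @export
SimConfig <- function(pLabel = 0.6, pReact = 0.8, meanOnTime = 0.2,
                      frameTime = 0.1, brightness = 4000, bgPhotons = 30,
                      extraDisplacementSD = 6.4, nFrames = 2000L,
                      bgDensity = 0, nContinuous = 64L,
                      precisionModel = gaussianPsfPrecision) {
  if (pReact >= 1) stop("pReact must be < 1 (otherwise fluorophores never bleach)")
  new("SimConfig", pLabel = pLabel, pReact = pReact, meanOnTime = meanOnTime,
      frameTime = frameTime, brightness = brightness, bgPhotons = bgPhotons,
      extraDisplacementSD = extraDisplacementSD, nFrames = as.integer(nFrames),
      bgDensity = bgDensity, nContinuous = as.integer(nContinuous),
      precisionModel = precisionModel)
}

#' Simulate labeled fluorophore positions from a model
#'
#' Discrete-points models contribute all their positions; continuous models
#' are sampled (\code{cfg@nContinuous} draws, probability proportional to the
#' sampling weights along the finely discretized geometry). Positions are
#' transformed into the data frame by the pose and thinned by the labeling
#' probability. The extra random displacement (drift/vibration/linkage proxy,
#' \code{cfg@extraDisplacementSD}) is applied per localization in
#' \code{\link{simulateLocalizations}}.
#'
#' @param model a \linkS4class{GeometricModel}.
#' @param pose a \linkS4class{Pose}.
#' @param cfg a \linkS4class{SimConfig}.
#' @param params named list of parameter overrides.
#' @return matrix of fluorophore positions (possibly 0 rows), D columns.
#' @export
simulatePositions <- function(model, pose = Pose(), cfg = SimConfig(),
                              params = list()) {
  if (model@kind == "discrete-points") {
    ev <- evaluateModel(model, spacing = 1, params = params)
    pts <- ev$points
  } else if (model@kind == "density-image") {
    stop("sampling from density-image models is not supported; use the ",
         "point-producing form of the geometry")
  } else {
    ev <- evaluateModel(model, spacing = 1, params = params)
    idx <- sample.int(nrow(ev$points), cfg@nContinuous, replace = TRUE,
                      prob = ev$weights)
    pts <- ev$points[idx, , drop = FALSE]
  }
  pts <- .pose_forward(pts, pose)
  keep <- runif(nrow(pts)) < cfg@pLabel
  pts[keep, , drop = FALSE]
}

#' Simulate blinking on-intervals
#'
#' Every label appears at a uniformly random time within the acquisition and
#' stays bright for an exponentially distributed time with mean
#' \code{cfg@meanOnTime}; after each bright period it is reactivated with
#' probability \code{cfg@pReact} (appearing again at a random later time),
#' otherwise it bleaches. The number of bright intervals per label is
#' therefore geometric with mean \code{1 / (1 - pReact)}.
#'
#' @param nLabels number of fluorophores (or a position matrix whose row
#'   count is used).
#' @param cfg a \linkS4class{SimConfig}.
#' @return data.frame with columns \code{id}, \code{start}, \code{end}
#'   (seconds, clipped to the acquisition).
#' @export
simulateBlinks <- function(nLabels, cfg = SimConfig()) {
  if (is.matrix(nLabels)) nLabels <- nrow(nLabels)
  total <- cfg@nFrames * cfg@frameTime
  out <- vector("list", nLabels)
  for (i in seq_len(nLabels)) {
    nb <- rgeom(1L, prob = 1 - cfg@pReact) + 1L
    start <- sort(runif(nb, 0, total))
    dur <- rexp(nb, rate = 1 / cfg@meanOnTime)
    out[[i]] <- data.frame(id = i, start = start,
                           end = pmin(start + dur, total))
  }
  do.call(rbind, out)
}

#' Simulate localizations from fluorophore positions and on-intervals
#'
#' For every frame overlapping an on-interval, the emitted photons are a
#' Poisson draw with mean \code{brightness x (on-time within the frame)};
#' zero-photon frames are dropped. The per-axis precision follows the
#' configured precision rule, and the localization is the true position plus
#' per-axis Gaussian noise of that SD plus an independent per-localization
#' displacement of SD \code{cfg@extraDisplacementSD} (residual drift,
#' vibrations and linkage error, the blur the extra-uncertainty fit parameter
#' epsilon describes). Precisions are floored at 1e-6 nm so idealized
#' zero-noise rules remain representable.
#'
#' @param positions matrix of fluorophore positions (D columns).
#' @param intervals data.frame from \code{\link{simulateBlinks}}.
#' @param cfg a \linkS4class{SimConfig}.
#' @param channel channel label to assign.
#' @return a \linkS4class{LocalizationSet} with frame and photon metadata.
#' @export
simulateLocalizations <- function(positions, intervals, cfg = SimConfig(),
                                  channel = 0L) {
  d <- ncol(positions)
  ft <- cfg@frameTime
  rows <- list()
  for (r in seq_len(nrow(intervals))) {
    st <- intervals$start[r]; en <- intervals$end[r]
    if (en <= st) next
    f0 <- floor(st / ft); f1 <- floor((en - 1e-12) / ft)
    for (f in f0:f1) {
      ontime <- min(en, (f + 1) * ft) - max(st, f * ft)
      if (ontime <= 0) next
      ph <- rpois(1L, cfg@brightness * ontime)
      if (ph <= 0) next
      rows[[length(rows) + 1L]] <-
        c(intervals$id[r], f, ph)
    }
  }
  if (length(rows) == 0) {
    return(LocalizationSet(matrix(numeric(0), 0, d),
                           matrix(numeric(0), 0, d)))
  }
  m <- do.call(rbind, rows)
  id <- m[, 1]; frame <- as.integer(m[, 2]); ph <- m[, 3]
  sig <- cfg@precisionModel(ph, cfg)
  if (nrow(sig) == 1L && length(ph) > 1L)    # allow constant-precision rules
    sig <- sig[rep(1L, length(ph)), , drop = FALSE]
  sig <- pmax(sig[, seq_len(d), drop = FALSE], 1e-6)
  xs <- positions[id, , drop = FALSE] +
    matrix(rnorm(length(sig)), nrow(sig)) * sig
  if (cfg@extraDisplacementSD > 0)
    xs <- xs + matrix(rnorm(length(sig), 0, cfg@extraDisplacementSD),
                      nrow(sig))
  LocalizationSet(xs, sig, channel = rep(as.integer(channel), nrow(xs)),
                  frame = frame, photons = ph)
}

#' Simulate a complete site
#'
#' Runs positions -> blinks -> localizations for a model (or each component
#' of a \linkS4class{CompositeSpec}, tagging localizations with the component
#' channels), adds uniform background localizations at \code{cfg@bgDensity},
#' and crops everything to a site box.
#'
#' @param model a \linkS4class{GeometricModel} or \linkS4class{CompositeSpec}.
#' @param pose site pose applied to the model (ignored for CompositeSpec,
#'   which carries component poses; the first component's pose is the site
#'   pose there).
#' @param cfg a \linkS4class{SimConfig}.
#' @param sideLength site box side, nm.
#' @param params parameter overrides (single-model case).
#' @param id site label.
#' @param seed optional integer; when given, makes the site reproducible.
#' @return a \linkS4class{Site}.
#' @export
simulateSite <- function(model, pose = Pose(), cfg = SimConfig(),
                         sideLength = 240, params = list(), id = "",
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  parts <- list()
  if (is(model, "CompositeSpec")) {
    first <- model@components[[1]]$pose
    for (m in seq_along(model@components)) {
      cmp <- model@components[[m]]
      ## the first component's transform applies to all components, then the
      ## m-th component's own transform to component m only
      pos <- simulatePositions(cmp$model, Pose(), cfg)
      if (nrow(pos) == 0) next
      pos <- .pose_forward(pos, first)
      if (m > 1) pos <- .pose_forward(pos, cmp$pose)
      iv <- simulateBlinks(pos, cfg)
      parts[[length(parts) + 1L]] <-
        simulateLocalizations(pos, iv, cfg, channel = cmp$channel)
    }
  } else {
    pos <- simulatePositions(model, pose, cfg, params = params)
    if (nrow(pos) > 0) {
      iv <- simulateBlinks(pos, cfg)
      parts[[1]] <- simulateLocalizations(pos, iv, cfg)
    }
  }
  d <- if (is(model, "CompositeSpec")) model@components[[1]]$model@dim
       else model@dim
  locs <- if (length(parts)) bindLocalizations(parts)
          else LocalizationSet(matrix(numeric(0), 0, d),
                               matrix(numeric(0), 0, d))
  if (cfg@bgDensity > 0) {
    nbg <- rpois(1L, cfg@bgDensity * sideLength^d)
    if (nbg > 0) {
      bx <- matrix(runif(nbg * d, -sideLength / 2, sideLength / 2), nbg)
      ph <- pmax(rpois(nbg, cfg@brightness * cfg@frameTime / 2), 1)
      sg <- pmax(cfg@precisionModel(ph, cfg)[, seq_len(d), drop = FALSE],
                 1e-6)
      locs <- bindLocalizations(locs, LocalizationSet(
        bx, sg, channel = rep(0L, nbg)))
    }
  }
  cropSite(locs, center = rep(0, d), sideLength = sideLength, id = id)
}

#' Simulate a batch of nuclear-pore sites
#'
#' Generates \code{n} sites from the discrete two-ring NPC model with random
#' poses (uniform in-plane rotation, Gaussian tilts, small random offsets)
#' and returns the sites together with the per-site ground truth.
#'
#' @param n number of sites.
#' @param seed integer seed (site i uses seed + i).
#' @param cfg a \linkS4class{SimConfig}.
#' @param r,s,theta intrinsic truth: ring radius and separation (nm) and
#'   twist (rad).
#' @param symmetry,copies,unitAngle model structure constants.
#' @param sideLength site box side, nm.
#' @param tiltSD SD of the tilt angles alpha, beta (rad), truncated at 2 SD.
#' @param offsetSD SD of the random position offset, nm.
#' @return list with elements \code{sites} (list of \linkS4class{Site}) and
#'   \code{truth} (data.frame of per-site generating parameters).
#' @export
simulateNpcSites <- function(n, seed = 1, cfg = SimConfig(), r = 53.4,
                             s = 50.2, theta = 8.8 * pi / 180, symmetry = 8L,
                             copies = 2L, unitAngle = 14 * pi / 180,
                             sideLength = 240, tiltSD = 0.1, offsetSD = 10) {
  model <- npcDiscrete(r = r, s = s, theta = theta, symmetry = symmetry,
                       copies = copies, unitAngle = unitAngle)
  sites <- vector("list", n)
  truth <- data.frame(gamma = numeric(n), alpha = numeric(n),
                      beta = numeric(n), x = numeric(n), y = numeric(n),
                      z = numeric(n))
  i <- 1L
  attempt <- 0L
  while (i <= n) {
    set.seed(seed + 1000L * attempt + i)
    attempt_pose <- Pose(
      x0 = pmin(pmax(rnorm(3, 0, offsetSD), -3 * offsetSD), 3 * offsetSD),
      angles = c(pmin(pmax(rnorm(2, 0, tiltSD), -2 * tiltSD), 2 * tiltSD),
                 runif(1, 0, 2 * pi)))
    site <- simulateSite(model, attempt_pose, cfg, sideLength = sideLength,
                         id = sprintf("npc%03d", i))
    if (nLocs(site) >= 30) {       # mirror the segmentation count filter
      sites[[i]] <- site
      truth$gamma[i] <- attempt_pose@angles[3]
      truth$alpha[i] <- attempt_pose@angles[1]
      truth$beta[i] <- attempt_pose@angles[2]
      truth$x[i] <- attempt_pose@x0[1]
      truth$y[i] <- attempt_pose@x0[2]
      truth$z[i] <- attempt_pose@x0[3]
      i <- i + 1L
      attempt <- 0L
    } else {
      attempt <- attempt + 1L
      if (attempt > 50L) stop("simulation keeps producing empty sites")
    }
  }
  truth$r <- r; truth$s <- s; truth$theta <- theta
  list(sites = sites, truth = truth)
}
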