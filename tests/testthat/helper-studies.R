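# Shared simulation studies for the acceptance suite. Heavy batches are
# computed once per test run and memoized, so several criteria can share the
# same simulated data and fitted chains.

.study_cache <- new.env(parent = emptyenv())

memoStudy <- function(key, fun) {
  if (!exists(key, envir = .study_cache))
    assign(key, fun(), envir = .study_cache)
  get(key, envir = .study_cache)
}

# batch of simulated NPC sites fitted with the standard chain
npcRecoveryStudy <- function(n = 200, seed = 4242) {
  memoStudy(sprintf("recovery_%d_%d", n, seed), function() {
    sim <- simulateNpcSites(n, seed = seed)
    chains <- lapply(seq_len(n), function(i)
      npcFitChain(sim$sites[[i]], seed = seed + i))
    list(sim = sim, chains = chains)
  })
}

# symmetry selection reusing the recovery chains' smooth prefits
npcSelectionStudy <- function(n = 100, seed = 4242, symmetries = 6:10) {
  rec <- npcRecoveryStudy(seed = seed)
  memoStudy(sprintf("selection_%d_%d", n, seed), function() {
    picks <- integer(n)
    for (i in seq_len(n)) {
      site <- rec$sim$sites[[i]]
      est <- rec$chains[[i]][[2]]@estimates
      b <- siteSide(site) / 4
      aiccs <- vapply(symmetries, function(nf) {
        if (nf == 8L) return(rec$chains[[i]][[3]]@aicc)
        step3 <- fitStep(npcDiscrete(symmetry = nf),
          free = c("x", "y", "z", "gamma", "theta", "r", "s", "eps", "wbg"),
          fixed = c(alpha = 0, beta = 0),
          lower = c(x = -b, y = -b, z = -b, gamma = 0, theta = -pi / nf,
                    r = 30, s = 15, eps = 0, wbg = 0),
          upper = c(x = b, y = b, z = b, gamma = 2 * pi / nf,
                    theta = pi / nf, r = 80, s = 90, eps = 25, wbg = 0.5),
          optimizer = "simplex", sigmaMin = 5,
          control = list(maxit = 1000, ci = FALSE))
        smlmfit:::.npc_step3(site, step3, est, nf, seed + 2L + nf)@aicc
      }, 1.0)
      picks[i] <- symmetries[which.min(aiccs)]
    }
    picks
  })
}

# dual-ring-only fit of a site (steps 1-2 of the chain), returning s-hat
ringSeparationFit <- function(site, seed, maxTilt = 0) {
  ch <- npcFitChain(site, seed = seed, maxTilt = maxTilt, nSteps = 2L)
  ch[[2]]@estimates[c("r", "s")]
}

# synthetic depth-dependent axial distortion: measured z = Dz(z_true)
# ~ -12% axial compression at the focus easing to -2% at 400 nm depth,
# the magnitude of depth wobble seen in astigmatic 3D data
zDistort <- function(z) 0.88 * z + z^3 / 4.8e6   # D'(z) = 0.88 + (z/1265)^2

# simulate NPC sites across depth, distort z, fit, correct, refit; run at
# the precision of filtered experimental two-ring data (lateral ~ 5 nm),
# which is the regime the depth calibration presumes
zCorrectionStudy <- function(nSites = 16, seed = 7117) {
  memoStudy(sprintf("zcorr_%d_%d", nSites, seed), function() {
    depths <- seq(-400, 400, length.out = nSites)
    sim <- simulateNpcSites(nSites, seed = seed,
                            cfg = SimConfig(brightness = 32000))
    # absolute-z, distorted localization sets per site
    distorted <- lapply(seq_len(nSites), function(i) {
      l <- localizations(sim$sites[[i]])
      l@coords[, 3] <- zDistort(l@coords[, 3] + depths[i])
      l
    })
    mkSite <- function(l) {
      zc <- median(coords(l)[, 3])
      cropSite(l, center = c(0, 0, zc), sideLength = 240)
    }
    sites1 <- lapply(distorted, mkSite)
    fits1 <- t(vapply(seq_len(nSites), function(i)
      ringSeparationFit(sites1[[i]], seed = seed + i), c(r = 0, s = 0)))
    zmeas <- vapply(sites1, function(s) siteCenter(s)[3], 1.0)
    model <- fitDistortion(zmeas, fits1[, "s"], expectedSeparation = 50.2)
    corrected <- lapply(distorted, function(l)
      suppressWarnings(applyDistortionCorrection(l, model)))
    sites2 <- lapply(corrected, mkSite)
    fits2 <- t(vapply(seq_len(nSites), function(i)
      ringSeparationFit(sites2[[i]], seed = seed + 500 + i),
      c(r = 0, s = 0)))
    list(model = model, sBefore = fits1[, "s"], sAfter = fits2[, "s"])
  })
}

# model-free averaging study: k particles, azimuthal spectrum + radius refit
averagingStudy <- function(k = 150, nSubset = 25, seed = 2024, maxIter = 3,
                           J = 2) {
  memoStudy(sprintf("avg_%d_%d", k, seed), function() {
    sim <- simulateNpcSites(k, seed = seed)
    tpl <- modelFreeAverage(sim$sites, nSubset = nSubset, J = J, seed = seed,
                            prealign = TRUE, maxIter = maxIter,
                            maxShift = 25, movingCap = 80, cap = 1000,
                            gammaGrid = 24, maxit = 100)
    sp <- azimuthalSpectrum(tpl)
    # refit the ring radius of the average with the smooth dual-ring model
    tl <- tpl@localizations
    set.seed(seed)
    idx <- sample.int(nLocs(tl), min(4000, nLocs(tl)))
    site <- cropSite(tl[idx], center = rep(0, 3), sideLength = 400)
    step <- fitStep(npcDualRing(),
                    free = c("x", "y", "z", "r", "s", "eps", "wbg"),
                    fixed = c(alpha = 0, beta = 0),
                    lower = c(x = -40, y = -40, z = -40, r = 30, s = 15,
                              eps = 0, wbg = 0),
                    upper = c(x = 40, y = 40, z = 40, r = 80, s = 90,
                              eps = 25, wbg = 0.5),
                    optimizer = "de", sigmaMin = 5,
                    control = list(generations = 40, popSize = 30,
                                   ci = FALSE))
    refit <- runFit(site, step, seed = seed + 1L)
    list(template = tpl, spectrum = sp, refit = refit)
  })
}
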