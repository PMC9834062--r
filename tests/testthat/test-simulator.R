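test_that("position generation respects labeling and pose", {
  cfg <- SimConfig(pLabel = 1, extraDisplacementSD = 0)
  set.seed(1)
  pos <- simulatePositions(npcDiscrete(), Pose(), cfg)
  truth <- evaluateModel(npcDiscrete())$points
  expect_equal(pos[order(pos[, 1]), ], truth[order(truth[, 1]), ],
               ignore_attr = TRUE, tolerance = 1e-12)
  # labeling is binomial with probability pLabel
  cfg2 <- SimConfig(pLabel = 0.5, extraDisplacementSD = 0)
  set.seed(2)
  counts <- replicate(400, nrow(simulatePositions(npcDiscrete(), Pose(),
                                                  cfg2)))
  se <- sqrt(32 * 0.25 / 400)
  expect_lt(abs(mean(counts) - 16), 4 * se)
  # pose is applied to the generated positions
  set.seed(3)
  shifted <- simulatePositions(npcDiscrete(), Pose(x0 = c(100, 0, 0)), cfg)
  expect_equal(mean(shifted[, 1]), 100, tolerance = 1e-9)
})

test_that("blinking follows the exponential/geometric photoswitching model", {
  cfg <- SimConfig(pReact = 0, meanOnTime = 0.2, nFrames = 10000L)
  set.seed(4)
  iv <- simulateBlinks(200, cfg)
  expect_identical(nrow(iv), 200L)           # exactly one interval per label
  # mean number of intervals per label is 1 / (1 - pReact)
  cfg2 <- SimConfig(pReact = 0.5, nFrames = 10000L)
  set.seed(5)
  iv2 <- simulateBlinks(2000, cfg2)
  mean_blinks <- nrow(iv2) / 2000
  expect_lt(abs(mean_blinks - 2), 0.12)      # geometric mean 1/(1-0.5)
  # interval durations are exponential with mean t_l
  cfg3 <- SimConfig(pReact = 0, meanOnTime = 0.15, nFrames = 100000L)
  set.seed(6)
  iv3 <- simulateBlinks(10000, cfg3)
  dur <- iv3$end - iv3$start
  ks <- ks.test(dur, "pexp", rate = 1 / 0.15)
  expect_gt(ks$p.value, 0.01)
})

test_that("localizations carry photon-dependent precisions and noise", {
  # an idealized zero-noise precision rule reproduces the true positions
  cfg0 <- SimConfig(extraDisplacementSD = 0,
                    precisionModel = function(ph, cfg)
                      cbind(sx = 0, sy = 0, sz = 0))
  pos <- matrix(c(10, 20, 30), 1, 3)
  iv <- data.frame(id = 1, start = 0.02, end = 0.35)
  set.seed(7)
  locs <- simulateLocalizations(pos, iv, cfg0)
  expect_true(all(abs(sweep(coords(locs), 2, c(10, 20, 30))) < 1e-4))
  # default rule: sigma_xy = s_psf / sqrt(photons), sigma_z = 3 sigma_xy
  expect_equal(unname(gaussianPsfPrecision(1000, cfg0)[1, ]),
               c(130 / sqrt(1000), 130 / sqrt(1000), 3 * 130 / sqrt(1000)))
  expect_equal(unname(gaussianPsfPrecision(1000, cfg0)[1, "sx"]),
               130 / sqrt(1000), tolerance = 1e-12)   # ~ 4.11 nm
  # empirical localization spread matches the emitted precisions
  cfgn <- SimConfig(extraDisplacementSD = 0,
                    precisionModel = function(ph, cfg)
                      cbind(sx = 7, sy = 7, sz = 21))
  set.seed(8)
  pos2 <- matrix(0, 1, 3)
  iv2 <- data.frame(id = rep(1, 4000), start = seq(0, 399.9, 0.1),
                    end = seq(0, 399.9, 0.1) + 0.099)
  cfgn@nFrames <- 400000L
  locs2 <- simulateLocalizations(pos2, iv2, cfgn)
  sds <- apply(coords(locs2), 2, sd)
  expect_true(all(abs(sds - c(7, 7, 21)) / c(7, 7, 21) < 0.05))
})

test_that("the per-localization extra displacement has the configured SD", {
  cfg <- SimConfig(extraDisplacementSD = 6.4,
                   precisionModel = function(ph, cfg)
                     cbind(sx = 1e-6, sy = 1e-6, sz = 1e-6))
  pos <- matrix(0, 1, 3)
  iv <- data.frame(id = rep(1, 3000), start = seq(0, 299.9, 0.1),
                   end = seq(0, 299.9, 0.1) + 0.09)
  cfg@nFrames <- 300000L
  set.seed(9)
  locs <- simulateLocalizations(pos, iv, cfg)
  sds <- apply(coords(locs), 2, sd)
  expect_true(all(abs(sds - 6.4) / 6.4 < 0.06))
})

test_that("photon counts are Poisson with on-fraction scaled means", {
  cfg <- SimConfig(brightness = 4000, frameTime = 0.1,
                   extraDisplacementSD = 0)
  # a fluorophore on for exactly half of one frame
  iv <- data.frame(id = 1, start = 0.00, end = 0.05)
  set.seed(10)
  ph <- replicate(2000, {
    l <- simulateLocalizations(matrix(0, 1, 3), iv, cfg)
    if (nLocs(l) > 0) photons(l)[1] else 0
  })
  expect_lt(abs(mean(ph) - 4000 * 0.05), 3 * sqrt(200 / 2000) + 1)
})

test_that("simulation is fully deterministic under a fixed seed", {
  s1 <- simulateSite(npcDiscrete(), Pose(), SimConfig(), seed = 77)
  s2 <- simulateSite(npcDiscrete(), Pose(), SimConfig(), seed = 77)
  expect_identical(coords(s1), coords(s2))
  expect_identical(precisions(s1), precisions(s2))
  expect_identical(photons(localizations(s1)), photons(localizations(s2)))
  s3 <- simulateSite(npcDiscrete(), Pose(), SimConfig(), seed = 78)
  expect_false(identical(coords(s1), coords(s3)))
})

test_that("mean localizations per label match the closed-form expectation", {
  cfg <- SimConfig(pLabel = 1, pReact = 0.5, meanOnTime = 0.2,
                   frameTime = 0.1, extraDisplacementSD = 0)
  # E[locs/label] ~ E[blinks] x E[frames per blink]; frames per blink for an
  # exponential on-time t_l starting uniformly in a frame:
  # 1 + t_l / frameTime (each blink spans on average one extra boundary)
  expected <- (1 / (1 - 0.5)) * (1 + 0.2 / 0.1)
  set.seed(11)
  pos <- matrix(rnorm(3 * 200, 0, 10), 200, 3)
  iv <- simulateBlinks(pos, cfg)
  locs <- simulateLocalizations(pos, iv, cfg)
  perLabel <- nLocs(locs) / 200
  expect_lt(abs(perLabel - expected) / expected, 0.12)
})

test_that("background density injects uniform spurious localizations", {
  cfg <- SimConfig(bgDensity = 5e-6, pLabel = 0)   # background only
  site <- simulateSite(npcDiscrete(), Pose(), cfg, sideLength = 200,
                       seed = 13)
  expect_gt(nLocs(site), 0)
  # roughly uniform: mean near 0, spread near the uniform SD d/sqrt(12)
  expect_lt(abs(mean(coords(site)[, 1])), 30)
})

test_that("simulated batches report ground truth and honor the count filter", {
  sim <- simulateNpcSites(3, seed = 5)
  expect_length(sim$sites, 3)
  expect_identical(nrow(sim$truth), 3L)
  expect_true(all(vapply(sim$sites, nLocs, 1L) >= 30))
  expect_true(all(c("r", "s", "theta", "gamma") %in% names(sim$truth)))
})
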