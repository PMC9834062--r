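test_that("AICc arithmetic and limits", {
  got <- aicc(-10, nParams = 2, nLocs = 10)
  expect_equal(got$aic, 24)
  expect_equal(got$aicc, 24 + 12 / 7)
  expect_equal(got$aiccPerLoc, (24 + 12 / 7) / 10)
  # K -> infinity: the small-sample penalty vanishes
  expect_equal(aicc(-10, 2, 1e9)$aicc, aicc(-10, 2, 1e9)$aic,
               tolerance = 1e-6)
  # penalty is monotone in P at equal likelihood
  expect_gt(aicc(-10, 3, 50)$aicc, aicc(-10, 2, 50)$aicc)
  expect_error(aicc(-10, nParams = 9, nLocs = 10), "undefined")
})

test_that("fixed-parameter steps evaluate without searching", {
  site <- asSite(makeCloud(15, center = c(3, -2), sigma = 5, seed = 1), 100)
  pm <- smlmfit:::.point_model(matrix(0, 1, 2))
  step <- fitStep(pm, free = character(0), fixed = c(x = 3, y = -2, wbg = 0))
  fit <- runFit(site, step, seed = 1)
  expect_identical(fit@nParams, 0L)
  # the reported LL equals a direct evaluation at those values
  dens <- pdfDiscrete(localizations(site), matrix(c(3, -2), 1, 2))
  expect_equal(maxLogLik(fit), sum(log(dens)), tolerance = 1e-9)
})

test_that("location fit matches the precision-weighted centroid", {
  # Gaussian MLE with per-point sigma: x0_hat = sum(x/s^2) / sum(1/s^2)
  set.seed(2)
  n <- 60
  s <- runif(n, 2, 12)
  xy <- cbind(rnorm(n, 5, s), rnorm(n, -8, s))
  locs <- LocalizationSet(xy, cbind(s, s))
  site <- asSite(locs, 200)
  pm <- smlmfit:::.point_model(matrix(0, 1, 2))
  step <- fitStep(pm, free = c("x", "y"), fixed = c(wbg = 0),
                  lower = c(x = -50, y = -50), upper = c(x = 50, y = 50),
                  optimizer = "simplex", control = list(ci = FALSE))
  fit <- runFit(site, step, seed = 3)
  w <- 1 / s^2
  expect_equal(unname(fit@estimates[c("x", "y")]),
               c(sum(w * xy[, 1]) / sum(w), sum(w * xy[, 2]) / sum(w)),
               tolerance = 1e-4)
})

test_that("estimates are reproducible bit-for-bit given the same seed", {
  site <- makeNpcSite(seed = 21)
  step <- fitStep(npcDualRing(), free = c("x", "y", "z", "s", "wbg"),
                  fixed = c(r = 50, eps = 8, alpha = 0, beta = 0),
                  lower = c(x = -40, y = -40, z = -40, s = 15, wbg = 0),
                  upper = c(x = 40, y = 40, z = 40, s = 90, wbg = 0.5),
                  optimizer = "de", sigmaMin = 5,
                  control = list(generations = 10, popSize = 15, ci = FALSE))
  f1 <- runFit(site, step, seed = 11)
  f2 <- runFit(site, step, seed = 11)
  expect_identical(f1@estimates, f2@estimates)
  expect_identical(maxLogLik(f1), maxLogLik(f2))
})

test_that("degenerate sites are refused", {
  tiny <- asSite(makeCloud(3, seed = 4), 100)
  pm <- smlmfit:::.point_model(matrix(0, 1, 2))
  step <- fitStep(pm, free = c("x", "y", "gamma"),
                  lower = c(x = -10, y = -10, gamma = -pi),
                  upper = c(x = 10, y = 10, gamma = pi))
  expect_error(runFit(tiny, step, seed = 1), "degenerate site")
})

test_that("confidence intervals recover the Fisher information", {
  # 1-parameter Gaussian location, n points with sigma = 1: var(x0) = 1/n
  set.seed(5)
  n <- 100
  locs <- LocalizationSet(cbind(rnorm(n), rnorm(n)), matrix(1, n, 2))
  site <- asSite(locs, 400)
  pm <- smlmfit:::.point_model(matrix(0, 1, 2))
  step <- fitStep(pm, free = "x", fixed = c(y = 0, wbg = 0),
                  lower = c(x = -50), upper = c(x = 50),
                  optimizer = "simplex")
  fit <- runFit(site, step, seed = 6)
  expect_equal(unname(fit@variances[["x"]]), 1 / n, tolerance = 0.05)
  # ci95 half-width = 1.96 sd
  half <- (fit@ci95[, "hi"] - fit@ci95[, "lo"]) / 2
  expect_equal(unname(half), 1.96 * sqrt(unname(fit@variances)),
               tolerance = 1e-9)
  # var = 4 corresponds to a half-width of 3.92
  expect_equal(1.96 * sqrt(4), 3.92)
})

test_that("quadratic surfaces give back their Hessian", {
  # LL(p) exactly quadratic: H recovered up to sampling noise
  site <- asSite(makeCloud(10, seed = 7), 100)
  pm <- smlmfit:::.point_model(matrix(0, 1, 2))
  step <- fitStep(pm, free = c("x", "y"), fixed = c(wbg = 0),
                  lower = c(x = -50, y = -50), upper = c(x = 50, y = 50))
  # analytic: LL = const - sum_k ((x - xk)^2 + (y - yk)^2) / (2 s^2)
  # Hessian = diag(-K / s^2) with s = 5
  ci <- estimateCI(site, step, c(x = 0, y = 0), seed = 8)
  expect_equal(unname(diag(ci$hessian)), rep(-10 / 25, 2), tolerance = 1e-6)
  expect_lt(abs(ci$hessian[1, 2]), 1e-6)
})

test_that("chained steps inherit initial values from previous estimates", {
  site <- asSite(makeCloud(40, center = c(6, -3), sigma = 5, seed = 9), 100)
  pm <- smlmfit:::.point_model(matrix(0, 1, 2))
  s1 <- fitStep(pm, free = c("x", "y"), fixed = c(wbg = 0),
                lower = c(x = -40, y = -40), upper = c(x = 40, y = 40),
                optimizer = "simplex", control = list(ci = FALSE))
  # step 2 fixes everything: evaluated at step 1 estimates
  s2 <- fitStep(pm, free = c("x", "y"), fixed = c(wbg = 0),
                lower = c(x = -40, y = -40), upper = c(x = 40, y = 40),
                optimizer = "simplex",
                control = list(maxit = 1, ci = FALSE))
  res <- chainFit(site, list(s1, s2), seed = 10)
  expect_equal(res[[2]]@estimates[c("x", "y")],
               res[[1]]@estimates[c("x", "y")], tolerance = 0.05)
  # unmappable inherited names are a configuration error
  s3 <- fitStep(pm, free = c("x", "y"),
                lower = c(x = -40, y = -40), upper = c(x = 40, y = 40),
                control = list(inheritMap = c(x = "no_such_parameter")))
  expect_error(chainFit(site, list(s1, s3), seed = 1), "unknown previous")
})

test_that("model ranking prefers fewer parameters at equal likelihood", {
  set.seed(11)
  site <- asSite(makeCloud(60, sigma = 6, seed = 11), 100)
  pm <- smlmfit:::.point_model(matrix(0, 1, 2))
  small <- fitStep(pm, free = c("x", "y"), fixed = c(wbg = 0),
                   lower = c(x = -30, y = -30), upper = c(x = 30, y = 30),
                   optimizer = "simplex", control = list(ci = FALSE))
  # nested: same model with a redundant free background weight
  big <- fitStep(pm, free = c("x", "y", "wbg", "eps"),
                 lower = c(x = -30, y = -30, wbg = 0, eps = 0),
                 upper = c(x = 30, y = 30, wbg = 0.9, eps = 20),
                 optimizer = "simplex", control = list(ci = FALSE))
  tab <- selectModel(site, list(small = small, big = big), seed = 12)
  expect_identical(tab$model[1], "small")
  # ranking is invariant to localization reordering
  perm <- sample(nLocs(site))
  site2 <- asSite(localizations(site)[perm], siteSide(site))
  tab2 <- selectModel(site2, list(small = small, big = big), seed = 12)
  expect_identical(tab$model, tab2$model)
})

test_that("optimum matches an exhaustive grid on a 2-parameter problem", {
  # 2 free location parameters; grid step = bound range / 2000
  set.seed(13)
  n <- 40
  s <- runif(n, 3, 9)
  xy <- cbind(rnorm(n, 4, s), rnorm(n, -6, s))
  locs <- LocalizationSet(xy, cbind(s, s))
  site <- asSite(locs, 120)
  pm <- smlmfit:::.point_model(matrix(0, 1, 2))
  lo <- c(x = -30, y = -30); hi <- c(x = 30, y = 30)
  step <- fitStep(pm, free = c("x", "y"), fixed = c(wbg = 0),
                  lower = lo, upper = hi, optimizer = "de",
                  control = list(ci = FALSE))
  fit <- runFit(site, step, seed = 14)
  # independent vectorized grid search (the oracle)
  gx <- seq(lo[1], hi[1], length.out = 2001)
  gy <- seq(lo[2], hi[2], length.out = 2001)
  w <- 1 / s^2
  # closed form: LL is separable, maximize each axis on its grid
  llx <- -outer(gx, xy[, 1], "-")^2 %*% w
  lly <- -outer(gy, xy[, 2], "-")^2 %*% w
  best <- c(gx[which.max(llx)], gy[which.max(lly)])
  cell <- (hi - lo) / 2000
  expect_lt(abs(fit@estimates[["x"]] - best[1]), cell[1] + 1e-9)
  expect_lt(abs(fit@estimates[["y"]] - best[2]), cell[2] + 1e-9)
})

test_that("background-dominated fits are flagged", {
  set.seed(15)
  locs <- LocalizationSet(matrix(runif(60, -50, 50), 30, 2),
                          matrix(5, 30, 2))
  site <- asSite(locs, 100)
  pm <- smlmfit:::.point_model(matrix(c(500, 500), 1, 2))  # model far away
  step <- fitStep(pm, free = c("wbg"), lower = c(wbg = 0),
                  upper = c(wbg = 1), optimizer = "simplex",
                  control = list(ci = FALSE))
  fit <- runFit(site, step, seed = 16)
  expect_true(any(grepl("background weight", fit@flags)))
})

test_that("two-channel composite fits recover the dome length", {
  # side-view endocytic geometry: hemiellipsoid dome (channel 1) over a
  # plasma-membrane ring (channel 2); the dome length a is the pseudotime
  # proxy and must be recoverable from a joint two-channel fit
  cfg <- SimConfig(extraDisplacementSD = 3, nContinuous = 30L,
                   brightness = 2000,
                   precisionModel = function(ph, cfg) {
                     s <- 130 / sqrt(pmax(ph, 1))
                     cbind(sx = s, sy = s, sz = s)
                   })
  truths <- c(45, 75, 105)
  fits <- vapply(seq_along(truths), function(i) {
    spec <- endocyticModel(a = truths[i], b = 50, t = 25, rIn = 35,
                           rOut = 70)
    site <- simulateSite(spec, cfg = cfg, sideLength = 320,
                         seed = 600 + i)
    step <- fitStep(spec, free = c("a", "x", "y"),
                    fixed = c(eps = 3, c2.eps = 3),
                    lower = c(a = 20, x = -30, y = -30),
                    upper = c(a = 150, x = 30, y = 30),
                    init = c(a = 70, x = 0, y = 0),
                    optimizer = "simplex", sigmaMin = 8,
                    control = list(maxit = 200, ci = FALSE))
    runFit(site, step, seed = 20 + i)@estimates[["a"]]
  }, 1.0)
  # growth ordering is recovered and estimates track the truth (the coarse
  # sigma floor used here for speed shrinks the dome length slightly)
  expect_identical(order(fits), 1:3)
  expect_true(all(abs(fits - truths) < 22))
})

test_that("the cross-correlation objective can drive the fit", {
  site <- asSite(makeCloud(30, center = c(4, -7), sigma = 5, seed = 31), 100)
  pm <- smlmfit:::.point_model(matrix(0, 1, 2))
  step <- fitStep(pm, free = c("x", "y"), fixed = c(wbg = 0, eps = 5),
                  lower = c(x = -30, y = -30), upper = c(x = 30, y = 30),
                  optimizer = "simplex", objective = "cc",
                  control = list(ci = FALSE))
  fit <- runFit(site, step, seed = 32)
  ctr <- colMeans(coords(site))
  expect_lt(sqrt(sum((fit@estimates[c("x", "y")] - ctr)^2)), 3)
})
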