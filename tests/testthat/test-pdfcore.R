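test_that("single-point densities match the closed-form Gaussian peaks", {
  l2 <- LocalizationSet(matrix(0, 1, 2), matrix(1, 1, 2))
  expect_equal(pdfDiscrete(l2, matrix(0, 1, 2)), 1 / (2 * pi),
               tolerance = 1e-14)
  l3 <- LocalizationSet(matrix(0, 1, 3), matrix(1, 1, 3))
  expect_equal(pdfDiscrete(l3, matrix(0, 1, 3)), (2 * pi)^(-3 / 2),
               tolerance = 1e-14)
  # extra uncertainty inflates each axis variance to sigma^2 + eps^2
  expect_equal(pdfDiscrete(l2, matrix(0, 1, 2), extraSigma = 1),
               1 / (2 * pi * 2), tolerance = 1e-14)
  expect_error(pdfDiscrete(l2, matrix(numeric(0), 0, 2)), "empty")
})

test_that("rotation matrix follows the z-y-x convention", {
  expect_equal(rotationMatrix(c(0, 0, 0)), diag(3))
  expect_equal(as.numeric(rotationMatrix(c(0, 0, pi / 2)) %*% c(1, 0, 0)),
               c(0, 1, 0), tolerance = 1e-12)
  set.seed(9)
  for (i in 1:5) {
    R <- rotationMatrix(runif(3, -pi, pi))
    expect_equal(det(R), 1, tolerance = 1e-12)
    expect_equal(t(R) %*% R, diag(3), tolerance = 1e-12)
  }
  # composition order: Rz first, then Ry, then Rx
  a <- c(0.3, -0.5, 0.8)
  Rx <- rotationMatrix(c(a[1], 0, 0))
  Ry <- rotationMatrix(c(0, a[2], 0))
  Rz <- rotationMatrix(c(0, 0, a[3]))
  expect_equal(rotationMatrix(a), Rx %*% Ry %*% Rz, tolerance = 1e-12)
})

test_that("pose directions are exact inverses and act as documented", {
  set.seed(4)
  pose <- Pose(x0 = c(10, -5, 3), angles = runif(3, -1, 1),
               scale = c(1.2, 0.8, 1.1))
  pts <- matrix(rnorm(30), 10, 3)
  fwd <- applyPose(pts, pose, "model-to-data")
  back <- applyPose(fwd, pose, "data-to-model")
  expect_equal(back, pts, tolerance = 1e-10)
  # identity pose leaves everything unchanged
  expect_equal(applyPose(pts, Pose(), "model-to-data"), pts)
  # pure translation shifts data by -x0 in the data-to-model direction
  l <- LocalizationSet(matrix(0, 2, 3), matrix(1, 2, 3))
  shifted <- applyPose(l, Pose(x0 = c(10, 0, 0)), "data-to-model")
  expect_equal(coords(shifted)[, 1], c(-10, -10))
  expect_equal(precisions(shifted), precisions(l))   # precisions untouched
})

test_that("discretization spacing follows the 0.75 x min precision rule", {
  locs <- LocalizationSet(matrix(0, 5, 3),
                          matrix(c(4, 6, 8), 5, 3, byrow = TRUE))
  dm <- discretizeModel(npcDualRing(r = 50), locs)
  expect_lt(dm@spacing, 3)                       # 0.75 * 4
  expect_gte(nrow(dm@points), 2 * ceiling(2 * pi * 50 / 3))
  # raising sigmaMin coarsens the sampling
  dm2 <- discretizeModel(npcDualRing(r = 50), locs, sigmaMin = 8)
  expect_lt(nrow(dm2@points), nrow(dm@points))
  expect_true(all(dm@weights > 0))
  expect_error(discretizeModel(npcDualRing(r = 50), locs, maxPoints = 10),
               "sigmaMin")
})

test_that("kernel density equals an independently coded oracle", {
  set.seed(21)
  x <- matrix(rnorm(60, 0, 30), 20, 3)
  s <- matrix(runif(60, 2, 15), 20, 3)
  v <- matrix(rnorm(150, 0, 30), 50, 3)
  q <- runif(50, 0.5, 2)
  locs <- LocalizationSet(x, s)
  dm <- new("DiscretizedModel", points = v, weights = q, spacing = 1,
            sigmaMin = 0)
  got <- pdfDiscrete(locs, dm, extraSigma = 3.5)
  expect_equal(got, oracleDensity(x, s, v, q, eps = 3.5),
               tolerance = 1e-10)
  # equal weights reduce exactly to the unweighted form
  dm1 <- new("DiscretizedModel", points = v, weights = rep(1, 50),
             spacing = 1, sigmaMin = 0)
  expect_equal(pdfDiscrete(locs, dm1), pdfDiscrete(locs, v),
               tolerance = 1e-14)
})

test_that("background mixing is affine with the uniform site density", {
  site <- asSite(makeCloud(10, seed = 2), 100)
  dens <- rep(0.002, 10)
  expect_equal(as.numeric(mixBackground(dens, 1, site)), rep(1e-4, 10))
  expect_equal(as.numeric(mixBackground(dens, 0, site)), dens)
  half <- mixBackground(dens, 0.5, site)
  expect_equal(as.numeric(half), 0.5 * dens + 0.5 * 1e-4)
  expect_equal(attr(half, "Kbg"), 5)
  expect_equal(attr(half, "Km"), 5)
  expect_equal(attr(half, "rhoBg"), 5 / 100^2)
  expect_error(mixBackground(dens, 1.2, site), "wBg")
})

test_that("composite PDFs respect weights, channels and relative poses", {
  site <- asSite(makeCloud(12, seed = 5, sigma = 30, center = c(0, 0, 0)),
                 200)
  ring <- npcDualRing(r = 40, s = 20)
  one <- new("CompositeSpec", components = list(
    list(model = ring, pose = Pose(), weight = 1, channel = 0L)),
    bgWeight = 0)
  d1 <- compositePdf(site, one)
  expect_equal(d1, as.numeric(mixBackground(d1, 0, site)))
  # two identical components at half weight equal one component (linearity)
  two <- new("CompositeSpec", components = list(
    list(model = ring, pose = Pose(), weight = 0.5, channel = 0L),
    list(model = ring, pose = Pose(), weight = 0.5, channel = 0L)),
    bgWeight = 0)
  expect_equal(compositePdf(site, two), d1, tolerance = 1e-12)
  # a zero relative pose co-locates component 2 with component 1
  p1 <- Pose(x0 = c(15, -10, 5), angles = c(0, 0, 0.7))
  moved1 <- new("CompositeSpec", components = list(
    list(model = ring, pose = p1, weight = 1, channel = 0L)), bgWeight = 0)
  moved2 <- new("CompositeSpec", components = list(
    list(model = ring, pose = p1, weight = 0.5, channel = 0L),
    list(model = ring, pose = Pose(), weight = 0.5, channel = 0L)),
    bgWeight = 0)
  expect_equal(compositePdf(site, moved2), compositePdf(site, moved1),
               tolerance = 1e-12)
  # weight-sum violation is rejected at construction
  expect_error(new("CompositeSpec", components = list(
    list(model = ring, pose = Pose(), weight = 0.6, channel = 0L)),
    bgWeight = 0), "sum to 1")
})

test_that("log-likelihood handles background, channels and clamping", {
  # pure background: LL = K ln(d^-D)
  site <- asSite(makeCloud(10, seed = 6, sigma = 15), 100)
  spec <- new("CompositeSpec", components = list(
    list(model = smlmfit:::.point_model(matrix(0, 1, 2)), pose = Pose(),
         weight = 1e-12, channel = 0L)), bgWeight = 1 - 1e-12)
  ll <- logLikelihood(site, spec)
  expect_equal(as.numeric(ll), 10 * log(1e-4), tolerance = 1e-6)
  # single channel with unit weighting equals the plain sum of logs
  d <- compositePdf(site, spec)
  expect_equal(as.numeric(ll), sum(log(d)), tolerance = 1e-9)
  # a localization with (near) zero density clamps instead of erroring
  far <- LocalizationSet(matrix(c(1e5, 1e5), 1, 2), matrix(1, 1, 2))
  site2 <- new("Site", localizations = far, sideLength = 3e5,
               center = c(0, 0), id = "far")
  spec2 <- new("CompositeSpec", components = list(
    list(model = smlmfit:::.point_model(matrix(0, 1, 2)), pose = Pose(),
         weight = 1, channel = 0L)), bgWeight = 0)
  ll2 <- logLikelihood(site2, spec2)
  expect_true(isTRUE(attr(ll2, "clamped")))
  expect_true(is.finite(as.numeric(ll2)))
})

test_that("ratio color weighting follows w_c = sum(K_c) / K_c", {
  # two channels with equal counts get w_c = 2 each
  a <- makeCloud(6, seed = 7); b <- makeCloud(6, seed = 8)
  locs <- bindLocalizations(a, b)
  locs@channel <- rep(c(1L, 2L), each = 6)
  site <- asSite(locs, 200)
  pm <- smlmfit:::.point_model(matrix(0, 1, 2))
  mk <- function(cw) new("CompositeSpec", components = list(
    list(model = pm, pose = Pose(), weight = 0.9, channel = 1L),
    list(model = pm, pose = Pose(), weight = 0.9, channel = 2L)),
    bgWeight = 0.1, colorWeights = cw)
  ll_unit <- logLikelihood(site, mk("unit"))
  ll_ratio <- logLikelihood(site, mk("ratio"))
  expect_equal(as.numeric(ll_ratio), 2 * as.numeric(ll_unit),
               tolerance = 1e-12)
})

test_that("cross-correlation score sums the densities", {
  site <- asSite(makeCloud(10, seed = 9, sigma = 15), 150)
  spec <- new("CompositeSpec", components = list(
    list(model = smlmfit:::.point_model(matrix(0, 1, 2)), pose = Pose(),
         weight = 1e-12, channel = 0L)), bgWeight = 1 - 1e-12)
  expect_equal(crossCorrelationScore(site, spec), 10 * 150^(-2),
               tolerance = 1e-6)
  # maximal when a single-point model sits at the precision-weighted centroid
  cloud <- makeCloud(40, center = c(7, -4), sigma = 6, seed = 10)
  site2 <- asSite(cloud, 100)
  score_at <- function(xy) {
    sp <- new("CompositeSpec", components = list(
      list(model = smlmfit:::.point_model(matrix(xy, 1, 2)), pose = Pose(),
           weight = 1, channel = 0L)), bgWeight = 0)
    crossCorrelationScore(site2, sp)
  }
  ctr <- colMeans(coords(cloud))
  grid <- expand.grid(x = ctr[1] + seq(-15, 15, 3),
                      y = ctr[2] + seq(-15, 15, 3))
  scores <- apply(grid, 1, score_at)
  bestxy <- unlist(grid[which.max(scores), ])
  expect_lt(sqrt(sum((bestxy - ctr)^2)), 5)
})

test_that("density-image PDFs normalize, blur and interpolate correctly", {
  # flat density over the site gives every localization d^-D
  flat <- geometricModel("flat", "density-image", 2, params = list(),
                         lower = numeric(0), upper = numeric(0),
                         fun = function(params, grid)
                           matrix(1, length(grid[[1]]), length(grid[[2]])))
  site <- asSite(makeCloud(8, seed = 13, sigma = 20), 100)
  d <- pdfImage(site, flat, meanSigma = c(5, 5))
  expect_equal(d, rep(1e-4, 8), tolerance = 1e-6)
  # numerical integral of the image PDF over the site is 1
  ringim <- npcDualRingImage(r = 30, s = 20)
  probe <- expand.grid(x = seq(-95, 95, 5), y = seq(-95, 95, 5),
                       z = seq(-95, 95, 5))
  locs <- LocalizationSet(as.matrix(probe), matrix(8, nrow(probe), 3))
  site3 <- asSite(LocalizationSet(matrix(0, 1, 3), matrix(8, 1, 3)), 200)
  dv <- pdfImage(locs, ringim, site = site3, meanSigma = rep(8, 3))
  expect_equal(sum(dv) * 5^3, 1, tolerance = 0.01)
  # a delta-like density blurred by <sigma> matches the discrete single-point
  # code path within grid error
  delta <- geometricModel("delta", "density-image", 2, params = list(),
                          lower = numeric(0), upper = numeric(0),
                          fun = function(params, grid) {
                            m <- matrix(0, length(grid[[1]]), length(grid[[2]]))
                            i <- which.min(abs(grid[[1]]))
                            j <- which.min(abs(grid[[2]]))
                            m[i, j] <- 1
                            m
                          })
  probe2 <- LocalizationSet(cbind(seq(-20, 20, 4), 0),
                            matrix(10, 11, 2))
  site2 <- asSite(LocalizationSet(matrix(0, 1, 2), matrix(10, 1, 2)), 120)
  d_img <- pdfImage(probe2, delta, site = site2, meanSigma = c(10, 10))
  d_pt <- pdfDiscrete(probe2, matrix(0, 1, 2))
  expect_equal(d_img, d_pt, tolerance = 0.05)
  expect_error(pdfImage(probe2, geometricModel(
    "zero", "density-image", 2, params = list(), lower = numeric(0),
    upper = numeric(0),
    fun = function(params, grid) matrix(0, length(grid[[1]]),
                                        length(grid[[2]]))),
    site = site2), "zero everywhere")
})

test_that("log-likelihood is invariant under a common rigid transform", {
  site <- makeNpcSite(seed = 31)
  ring <- npcDualRing()
  # no background so the (site-volume-dependent) uniform term cancels out
  base <- new("CompositeSpec", components = list(
    list(model = ring, pose = Pose(), weight = 1, channel = 0L)),
    bgWeight = 0)
  ll0 <- as.numeric(logLikelihood(site, base, sigmaMin = 5))
  set.seed(12)
  for (rep in 1:3) {
    # translate+rotate the data, compose the model pose with the same T
    tx <- Pose(x0 = c(runif(2, -20, 20), 0), angles = c(0, 0, runif(1, 0, 2 * pi)))
    moved <- asSite(applyPose(localizations(site), tx, "model-to-data"),
                    4 * siteSide(site))
    spec2 <- base
    spec2@components[[1]]$pose <- tx
    ll1 <- as.numeric(logLikelihood(moved, spec2, sigmaMin = 5))
    expect_equal(ll1, ll0, tolerance = 1e-8)
  }
})

test_that("shrinking a matched localization's precision raises the density", {
  v <- matrix(c(10, 0, 0), 1, 3)
  dens <- vapply(c(8, 4, 2, 1, 0.5), function(sig) {
    l <- LocalizationSet(v, matrix(sig, 1, 3))
    pdfDiscrete(l, v)
  }, 1.0)
  expect_true(all(diff(dens) > 0))
})
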