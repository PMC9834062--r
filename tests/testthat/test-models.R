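test_that("dual-ring geometry places rings at +/- s/2 on the right radius", {
  m <- npcDualRing(r = 53.4, s = 50.2)
  ev <- evaluateModel(m, spacing = 2)
  expect_setequal(round(unique(ev$points[, 3]), 6), c(-25.1, 25.1))
  rad <- sqrt(rowSums(ev$points[, 1:2]^2))
  expect_true(all(abs(rad - 53.4) < 1e-9))
  # degenerate separation: both rings coincide in the z = 0 plane
  ev0 <- evaluateModel(npcDualRing(r = 50, s = 0), spacing = 2)
  expect_true(all(ev0$points[, 3] == 0))
  expect_error(npcDualRing(r = -1), "r must be")
})

test_that("discrete NPC model has n x copies x 2 points and n-fold symmetry", {
  ev <- evaluateModel(npcDiscrete())
  expect_identical(nrow(ev$points), 32L)
  # rotating the whole point set by 2 pi / 8 about z maps it onto itself
  g <- 2 * pi / 8
  R <- matrix(c(cos(g), sin(g), -sin(g), cos(g)), 2, 2)
  rot <- cbind(ev$points[, 1:2] %*% t(R), ev$points[, 3])
  d2 <- apply(rot, 1, function(p)
    min(colSums((t(ev$points) - p)^2)))
  expect_true(max(d2) < 1e-18)
  # zero twist, zero separation, one copy: rings coincide point-for-point
  ev2 <- evaluateModel(npcDiscrete(s = 0, theta = 0, copies = 1))
  expect_equal(ev2$points[1:8, ], ev2$points[9:16, ], ignore_attr = TRUE)
  expect_error(npcDiscrete(symmetry = 2), "n must be")
})

test_that("elliptical NPC solves the axis relations and reduces to a circle", {
  # e = 1 - b/a and r = (a + b)/2 => a = 2r/(2 - e), b = a (1 - e)
  ev <- evaluateModel(npcElliptical(r = 50, e = 0.2, s = 0, theta = 0,
                                    copies = 1, phi = 0))
  a <- max(abs(ev$points[, 1]))
  expect_equal(a, 2 * 50 / 1.8, tolerance = 1e-9)       # 55.55...
  b <- max(abs(ev$points[, 2]))
  expect_true(abs(b - (2 * 50 * 0.8 / 1.8)) < 1.5)      # 44.44... (sampled)
  # recovered definitions
  expect_equal(1 - b / a, 0.2, tolerance = 0.02)
  # e = 0 gives exactly the circular model, for any internal rotation
  circ <- evaluateModel(npcDiscrete(r = 50))
  e0 <- evaluateModel(npcElliptical(r = 50, e = 0, phi = 1.1))
  expect_equal(e0$points, circ$points, ignore_attr = TRUE, tolerance = 1e-9)
  expect_error(npcElliptical(e = 1), "ellipticity")
})

test_that("spline backbone traverses its control points", {
  # all angles zero: N colinear points spaced h, straight spline
  m <- mtSpline(h = 250, N = 5)
  ev <- evaluateModel(m, spacing = 10)
  expect_true(all(abs(ev$points[, 2]) < 1e-9))
  expect_true(all(abs(ev$points[, 3]) < 1e-9))
  expect_equal(range(ev$points[, 1]), c(-500, 500))
  # a curved configuration still interpolates every control point
  az <- c(0.2, -0.1, 0.15, 0.3)
  el <- c(0.1, 0.05, -0.2, 0.1)
  ctrl <- smlmfit:::.control_points(c(0, 0, 0), 200, az, el, 5)
  mc <- mtSpline(h = 200, azimuths = az, elevations = el, N = 5)
  pts <- evaluateModel(mc, spacing = 1)$points
  miss <- apply(ctrl, 1, function(p) sqrt(min(colSums((t(pts) - p)^2))))
  expect_true(max(miss) < 0.5)
  expect_error(mtSpline(N = 4), "odd")
})

test_that("long spline chord length matches N and h", {
  # 27 control points, 200 nm apart: a 5.2 um segment
  ctrl <- smlmfit:::.control_points(c(0, 0, 0), 200, rep(0, 26), rep(0, 26),
                                    27)
  chord <- sum(sqrt(rowSums(diff(ctrl)^2)))
  expect_equal(chord, 26 * 200)
})

test_that("tube model rings are perpendicular to the backbone at radius r", {
  # straight backbone along x: all samples satisfy y^2 + z^2 = r^2
  mt <- mtTube(h = 250, N = 5, r = 12.5)
  ev <- evaluateModel(mt, spacing = 5)
  expect_true(all(abs(sqrt(ev$points[, 2]^2 + ev$points[, 3]^2) - 12.5)
                  < 1e-6))
  # curved backbone: every sample lies at distance r from the spline
  az <- c(0.3, -0.2, 0.2, 0.4)
  mt2 <- mtTube(h = 200, azimuths = az, N = 5, r = 15)
  ev2 <- evaluateModel(mt2, spacing = 8)
  dense <- evaluateModel(mtSpline(h = 200, azimuths = az, N = 5),
                         spacing = 0.5)$points
  dist <- apply(ev2$points, 1, function(p)
    sqrt(min(colSums((t(dense) - p)^2))))
  expect_true(max(abs(dist - 15)) < 1)
})

test_that("endocytic projections have the expected support", {
  # a = b: the projected hemiellipsoid outline is a half-disc of radius b
  hm <- evaluateModel(hemiellipsoidProjection(a = 50, b = 50), spacing = 4)
  expect_true(all(hm$points[, 2] >= 0))
  expect_true(max(sqrt(rowSums(hm$points^2))) <= 50 + 1e-6)
  expect_true(all(hm$weights > 0))
  # ring projection spans radius [rIn, rOut] laterally
  rg <- evaluateModel(thickRingProjection(rIn = 40, rOut = 80, t = 30),
                      spacing = 4)
  expect_true(max(abs(rg$points[, 1])) <= 80 + 1e-6)
  expect_true(max(abs(rg$points[, 1])) > 70)
  expect_true(all(abs(rg$points[, 2]) <= 15 + 1e-6))
  expect_error(thickRingProjection(rIn = 90, rOut = 80), "rIn < rOut")
  # doubling a doubles the axial extent (the pseudotime proxy)
  h2 <- evaluateModel(hemiellipsoidProjection(a = 100, b = 50), spacing = 4)
  expect_equal(max(h2$points[, 2]) / max(hm$points[, 2]), 2, tolerance = 0.05)
})

test_that("line segments expose N vertices built like control points", {
  ev <- evaluateModel(lineSegments(h = 100, N = 2))
  expect_identical(nrow(ev$points), 2L)
  expect_equal(sqrt(sum(diff(ev$points)^2)), 100)
  # colinear when all angles are zero
  ev5 <- evaluateModel(lineSegments(h = 80, N = 5))
  expect_true(all(abs(ev5$points[, 2:3]) < 1e-9))
  expect_error(lineSegments(N = 1), "N must be")
})

test_that("discretization density does not change the likelihood materially", {
  # PDF from 2x denser sampling moves the log-likelihood by < 0.1%
  site <- makeNpcSite(seed = 11)
  m <- npcDualRing()
  for (spac in list(c(4, 2), c(6, 3))) {
    ll <- vapply(spac, function(sp) {
      ev <- evaluateModel(m, spacing = sp)
      sum(log(pdfDiscrete(localizations(site), ev$points)))
    }, 1.0)
    expect_lt(abs(ll[1] - ll[2]) / abs(ll[2]), 0.001)
  }
})

test_that("model registry resolves names and accepts plug-ins", {
  expect_true("npc_discrete" %in% listModels())
  m <- getModel("npc_dual_ring", r = 40)
  expect_equal(m@params$r, 40)
  registerModel("unit_test_point", function()
    geometricModel("unit_test_point", "discrete-points", 2,
                   params = list(), lower = numeric(0), upper = numeric(0),
                   fun = function(params, spacing)
                     list(points = matrix(0, 1, 2), weights = 1)))
  expect_identical(nrow(evaluateModel(getModel("unit_test_point"))$points),
                   1L)
  expect_error(getModel("no_such_model"), "unknown model")
})
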