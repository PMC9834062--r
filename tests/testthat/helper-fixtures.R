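# Fixtures shared across the suite; all randomness seeded locally.

# isotropic Gaussian cloud around a center
makeCloud <- function(n = 20, center = c(0, 0), sigma = 5, seed = 1,
                      precision = sigma) {
  set.seed(seed)
  d <- length(center)
  LocalizationSet(
    sweep(matrix(rnorm(n * d, 0, sigma), n, d), 2, center, "+"),
    matrix(precision, n, d))
}

# noise-free samples on a circle, as a LocalizationSet
makeRingLocs <- function(n = 60, r = 50, center = c(0, 0), precision = 5,
                         jitter = 0, seed = 1) {
  set.seed(seed)
  ang <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  xy <- cbind(center[1] + r * cos(ang), center[2] + r * sin(ang))
  if (jitter > 0) xy <- xy + matrix(rnorm(2 * n, 0, jitter), n, 2)
  LocalizationSet(xy, matrix(precision, n, 2))
}

# small simulated NPC site with lighter-weight settings for unit tests
makeNpcSite <- function(seed = 1, cfg = SimConfig()) {
  simulateNpcSites(1, seed = seed, cfg = cfg)$sites[[1]]
}

# direct, independently coded density of Gaussian-mixture model points:
# mean over model points of axis-aligned Gaussians with per-localization
# covariance diag(sigma^2 + eps^2) -- the oracle for the fast kernel
oracleDensity <- function(x, s, v, q = rep(1, nrow(v)), eps = 0) {
  K <- nrow(x); D <- ncol(x)
  out <- numeric(K)
  for (k in seq_len(K)) {
    var <- s[k, ]^2 + eps^2
    norm <- (2 * pi)^(-D / 2) / sqrt(prod(var))
    acc <- 0
    for (j in seq_len(nrow(v))) {
      m <- sum((x[k, ] - v[j, ])^2 / var)
      acc <- acc + q[j] * exp(-m / 2)
    }
    out[k] <- norm * acc / sum(q)
  }
  out
}
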