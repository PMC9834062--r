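# smlmfit

Maximum-likelihood fitting of geometric models to single-molecule
localization microscopy (SMLM) coordinates.

SMLM experiments yield a table of fluorophore coordinates with
per-localization precision estimates rather than an image. `smlmfit` fits an
arbitrary parameterized geometry — rings, discrete fluorophore arrangements,
splines, tubes, projections, density maps — directly to such point clouds,
weighting every localization by its own anisotropic uncertainty. For a model
with point-form geometry $v_j$ (weights $q_j$) the per-localization density
is the Gaussian mixture

$$M(\vec x,\vec\sigma\mid p)=\frac{1}{\sum_j q_j}\sum_j q_j\,(2\pi)^{-D/2}\det(\Sigma)^{-1/2}\exp\left(-\tfrac12(\vec x-\vec v_j)^\top\Sigma^{-1}(\vec x-\vec v_j)\right),\qquad \Sigma=\mathrm{diag}(\sigma^2+\epsilon^2),$$

mixed with a uniform site background, and the parameters maximize
$LL(p)=\sum_k\ln M(\vec x_k,\vec\sigma_k\mid p)$. On top of this core the
package provides:

* a model library (dual-ring and discrete nuclear-pore models, elliptical
  variants, cubic-spline filaments and tubes, endocytic-site projections,
  line segments) plus a plug-in registry;
* global (differential evolution), simplex and gradient optimizers, chained
  fitting steps, confidence intervals from the observed information, and
  AICc model selection;
* a realistic blinking-fluorophore simulator (labeling efficiency,
  exponential on-times, geometric re-activation, Poisson photons,
  photon-dependent precisions) for validating any analysis workflow;
* reference-based multi-color averaging, pseudotime reconstruction of
  dynamic processes from fixed-cell snapshots, and model-free particle
  fusion by similarity-seeded iterative registration;
* depth-dependent axial distortion correction and ring-kernel site
  segmentation.

Audience: microscopists and image analysts quantifying multi-protein
structures (nuclear pores, cytoskeletal filaments, endocytic machinery) from
2D/3D SMLM localization tables.

## Worked example

Simulate a nuclear-pore site at realistic conditions and recover its
geometry with the standard three-step chain (smooth dual ring → refined dual
ring → discrete 32-position model):

```r
library(smlmfit)

sim  <- simulateNpcSites(1, seed = 7)     # truth: r 53.4, s 50.2, twist 8.8 deg
site <- sim$sites[[1]]
site
#> Site 'npc001': d = 240 nm, K = 374 localizations (3D)

fit <- npcFitChain(site, seed = 1)[[3]]   # final (discrete-corner) step
round(fit@estimates[c("r", "s", "theta")], 3)
#>      r      s  theta
#> 53.215 50.383  0.245
maxLogLik(fit)
#> [1] -5491.611
```

The fitted radius `r` and ring separation `s` are in nm; `theta` is the
inter-ring twist in radians (0.245 rad = 14.0°, truth 8.8°; single-site twist
estimates scatter by several degrees at this precision). `aicc(fit)`
returns the information criteria used by `npcSelectSymmetry()` /
`selectModel()` to rank competing geometries, and `confint95(fit)` the
quadratic-approximation confidence intervals.

Localization tables are read and written as plain CSV
(`readLocalizations()` / `writeLocalizations()`, nm units, configurable
column names); `cropSite()` cuts boxes around individual structures and
`segmentNpcSites()` finds ring-shaped candidates automatically.

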