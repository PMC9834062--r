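---
title: "Maximum-likelihood geometric model fitting for SMLM coordinate data"
author: "smlmfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum-likelihood geometric model fitting for SMLM coordinate data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smlmfit)
```

## The statistical model

Single-molecule localization microscopy (SMLM) produces, instead of pixels, a
table of fluorophore coordinates $\vec x_k$ with per-axis localization
precisions $\vec\sigma_k$ (standard deviations of the coordinate estimates).
`smlmfit` fits a parameterized geometric model $f(p)$ — a curve, a surface, an
explicit fluorophore arrangement, or a density map — directly to these
coordinates by maximum likelihood.

The model is converted into a probability density $M(\vec x, \vec\sigma \mid
p)$ for a single localization. For point-form geometry with $J$ positions
$\vec v_j$ and sampling weights $q_j$,

$$M(\vec x,\vec\sigma \mid p) \;=\; \frac{1}{\sum_j q_j}\sum_{j=1}^{J} q_j\,
(2\pi)^{-D/2}\,\det(\Sigma)^{-1/2}
\exp\!\Big(-\tfrac12 (\vec x-\vec v_j)^\top \Sigma^{-1} (\vec x-\vec v_j)\Big),$$

with $\Sigma = \mathrm{diag}(\sigma_x^2+\epsilon^2,\; \sigma_y^2+\epsilon^2,\;
\sigma_z^2+\epsilon^2)$. Every localization contributes with its *own*
covariance, so precise localizations carry more weight; the extra uncertainty
$\epsilon$ absorbs blur beyond the fitted precision (linkage error, residual
drift, unmodeled deformation). The normalizing constant uses the exponent
$-D/2$ of the data dimensionality so the density integrates to one in both 2D
and 3D.

A uniform background over the site (an axis-aligned box of side $d$ holding
one structure) absorbs unexplained localizations:
$M_b = (1-w_{bg})\,M + w_{bg}\, d^{-D}$. Composite models are convex
combinations $\sum_m w_m M_m + w_{bg} M_{bg}$ with $\sum_m w_m + w_{bg}=1$
per color channel; components beyond the first are posed relative to the
first. The log-likelihood is
$LL(p) = \sum_c w_c \sum_{k\in c}\ln M_c(\vec x_k,\vec\sigma_k\mid p)$, with
$w_c = 1$ by default ("ratio" weighting $w_c = \sum_c K_c / K_c$ balances
unequal channel counts). A cross-correlation objective
$L_{cc} = \sum_k M(\vec x_k,\vec\sigma_k\mid p)$ is available as an
alternative.

Extrinsic parameters are the translation $\vec x_0$, z–y–x Euler angles
$(\alpha,\beta,\gamma)$ (the rotation matrix is $R_x(\alpha) R_y(\beta)
R_z(\gamma)$), optional per-axis scales, $\epsilon$ and $w_{bg}$. Model
points are transformed into the data frame ($v' = S R v + x_0$); for density
images the localizations are reverse-transformed instead
($x' = R^{-1}S^{-1}(x - x_0)$); the two directions are exact inverses.

## Discretization of continuous models

Continuous curves and surfaces are point-sampled with spacing
$\delta < 0.75\,\min_k \{\sigma_{xk},\sigma_{yk},\sigma_{zk}\}$, which makes
the point-sampled mixture numerically indistinguishable from the continuous
density (a twofold denser sampling changes the log-likelihood by well under
0.1%). A precision floor $\sigma_{\min}$ clamps precisions below it — both in
the spacing rule and in the per-localization covariance — which coarsens the
model and bounds its size; the default workflows use
$\sigma_{\min} = 5\,$nm. Density-image models are rendered on a cell-centered
grid covering the site (spacing half the smallest blur SD, at most 256 cells
per axis), normalized over the site, blurred with a separable Gaussian of SD
$\sqrt{\langle\sigma\rangle^2+\epsilon^2}$ per axis, and evaluated by
multilinear interpolation. The Gaussian blur matrices are row-normalized
(averaging operators), so a flat density stays exactly flat, and the density
is re-normalized after the blur.

Densities are floored at $10^{-300}$ before the logarithm; a fit evaluated
where this floor triggers is reported with a `clamped` attribute rather than
an exception, so optimizers can keep moving.

## Optimization, chaining and uncertainty

Three optimizers are provided: a seeded differential-evolution search
(global; rand/1/bin, population $\max(15, 6P)$, bound reflection, simplex
polish), Nelder–Mead on logistic-transformed (bounded) coordinates, and
L-BFGS-B. Fits are deterministic given `(site, step, seed)`. Degenerate
problems ($K < P + 2$ localizations) are refused. Fitting steps can be
chained, inheriting initial values from the previous step's estimates —
the standard route from a smooth, few-parameter model to a detailed one,
which avoids local maxima.

95% confidence intervals come from a quadratic approximation of the
log-likelihood around the optimum: $20P(P+3)/2$ samples drawn uniformly
within ±2% of each bound range, a least-squares quadratic fit, conversion to
the observed-information Hessian, and
$\mathrm{var}(\hat p_b) = [(-H)^{-1}]_{bb}$,
$CI = \hat p_b \pm 1.96\sqrt{\mathrm{var}}$. The quadratic-form coefficient
matrix is doubled before inversion so that the variance equals the inverse
observed information — on the canonical one-parameter Gaussian-location
problem with $n$ unit-precision points this yields
$\mathrm{var}(\hat x_0) = 1/n$, the Fisher bound; inverting the raw
quadratic-form coefficients instead would overestimate every variance by a
factor of two. Non-positive-definite information matrices fall back to a
pseudo-inverse and are flagged.

Model selection uses the small-sample-corrected Akaike criterion,
$AIC = 2P - 2\ln\hat L$ and $AIC_c = AIC + (2P^2+2P)/(K-P-1)$ with $K$ the
number of localizations, reported per localization for comparability; the
smallest $AIC_c$ on the same data indicates the preferred model.

## The model library

* `npcDualRing(r, s)` — two parallel continuous rings of radius $r$ at
  $z = \pm s/2$ (the model origin is the structure center, a convention this
  package fixes). `npcDualRingImage` is the same geometry as a density map.
* `npcDiscrete(r, s, theta, symmetry, copies, unitAngle)` — two rings of
  discrete fluorophore positions with n-fold symmetry, `copies` fluorophores
  per symmetric unit placed at ±`unitAngle`/2 about each corner at equal
  radius (default 14°, a structural constant that is not resolvable at fit
  time), and ring twist `theta`. The default 8 × 2 × 2 = 32 positions
  describe the Nup96 arrangement of the nuclear pore complex.
* `npcElliptical(r, e, phi, ...)` — elliptical deformation with
  $e = 1 - b/a$ and the mean radius interpreted as $r = (a+b)/2$ (the
  simplest reading of "average axes"), so $a = 2r/(2-e)$, $b = a(1-e)$;
  `phi` rotates the long axis relative to the first corner.
* `mtSpline(...)`/`mtTube(..., r)` — a natural cubic spline (chord-length
  parameterization; "piece-wise third-order polynomials" underdetermines the
  end conditions, and natural ends are the least-committal choice) through an
  odd number N of control points built outward from the middle point, each at
  distance h from its predecessor along an azimuth/elevation direction; the
  tube renders circles of radius r perpendicular to the local tangent.
  Defaults N = 5, h = 250 nm describe micrometer-long filament segments.
* `hemiellipsoidProjection(a, b)` / `thickRingProjection(rIn, rOut, t)` /
  `endocyticModel(...)` — 2D projections (numerical integration over the
  depth axis via area/volume-weighted surface samples) of a hemiellipsoid
  shell and a thick ring, the side-view geometry of endocytic sites; `a` is
  the invagination length used as a pseudotime proxy.
* `lineSegments(...)` — N discrete vertices of a connected segment chain;
  each added 3D vertex adds three parameters, which AICc penalizes.

Models are addressable by name through `getModel()`; a user plug-in is a
name, a kind, a bounded parameter table and an evaluation function
(`geometricModel()`).

## The simulator

`simulateSite()` generates realistic localizations from any model with a
two-state (bright/dark) fluorophore model plus bleaching: positions are taken
from the model (all positions of a discrete model; weighted draws along a
continuous one), each position is labeled with probability `pLabel`, each
label appears at a random time, stays bright for an exponential time
(`meanOnTime`), and is reactivated with probability `pReact` or bleaches.
Per frame, photons are Poisson with mean `brightness` × on-time; the
localization precision follows a pluggable rule — by default the analytic
Gaussian-PSF expression $\sigma_{xy} = s_{\mathrm{PSF}}/\sqrt{N_{ph}}$
($s_{\mathrm{PSF}} = 130\,$nm) with $\sigma_z = 3\sigma_{xy}$, a deliberate
analytic stand-in for microscope-specific calibrated bounds — and the
localization is the true position plus Gaussian noise of that SD plus an
independent per-localization displacement (`extraDisplacementSD`,
default 6.4 nm) modeling residual drift, vibration and linkage error. This
displacement acts per localization, which is what the free $\epsilon$
parameter of the fit describes; spurious uniform background localizations
are injected separately via `bgDensity`, which is what $w_{bg}$ describes.

Defaults emulate the nuclear-pore reference sample: truth
$r = 53.4$ nm, $s = 50.2$ nm, twist $8.8^\circ$, labeling efficiency 0.6,
reactivation 0.8 and a photon budget giving a mean lateral precision near
10 nm and a few hundred localizations per site — the regime of experimental
Nup96 data. What the simulator does *not* emulate: multiple fluorophores per
label, frame-to-frame merging of localizations, camera-frame image formation
or multi-emitter fitting artifacts; conclusions from passing tests therefore
transfer to real data only to the extent that those upstream steps behave.

## Identifiability at limited axial precision

Two genuine statistical limits of this regime are worth stating, because the
package's default workflows are shaped around them. Both were verified with
independent Monte-Carlo oracles and profile-likelihood checks, not just
observed in fits.

1. **Tilt–separation degeneracy.** With $\sigma_z \approx 3\sigma_{xy}$, an
   inclined ring spreads in z very much like two separated rings; leaving
   the tilt free biases the fitted ring separation downward by several nm at
   $\sigma_{xy}\approx 10$ nm. Nuclear pores sit approximately perpendicular
   in the envelope, so the default NPC chain (`npcFitChain`) fixes the tilt
   at zero (`maxTilt = 0`); freeing it is a single argument.
2. **Mixture attraction.** Even with the tilt fixed, the maximum-likelihood
   separation of two Gaussian layers is biased low once the separation is
   comparable to twice the axial noise; a one-dimensional mixture oracle at
   these conditions shows a bias of a few nm that no optimizer setting can
   remove. At better axial precision the bias vanishes.

The practical consequences: ring radius and twist are recovered with
negligible bias at $\sigma_{xy}\approx10$ nm, while the ring separation
carries a residual negative bias of roughly 1–2 nm. The depth-dependent
z-correction (below) calibrates against a reference separation measured with
the *same* estimator, which cancels this bias within the corrected data.

## The standard NPC workflow

`npcFitChain()` runs the three-step chain: (1) a smooth dual-ring with fixed
radius and a large fixed $\epsilon$, optimized globally, finds position and
separation; (2) a dual-ring refinement frees radius, separation and
$\epsilon$; (3) the discrete-corner model adds the ring twist, with the
in-plane rotation and the twist initialized by a joint coarse grid over the
n-fold fundamental interval. The rotation is reported modulo $2\pi/n$, ties
toward the interval start. `npcSelectSymmetry()` fits several symmetries
from the same smooth prefit and ranks them by AICc. Per-site symmetry
classification degrades with labeling vacancies (unlabeled corners make a
wrong lattice locally plausible) — a property of the data, not the ranking.

## Particle averaging

Reference-based averaging (`referenceAverage`) transforms every site into
the model frame with its fitted reference pose and pools a target channel —
the route to multi-protein distribution maps; `pseudotimeReconstruct` sorts
sites by a monotone fitted parameter and pools them in bins (remainder sites
are dropped in binned mode, kept in moving-average mode).

Model-free averaging implements the similarity-seeded fusion loop:
all-against-all registration of a subset (each particle's coordinates act as
a point model for the others), ranking by total similarity, cumulative
fusion in rank order, then iterative re-registration of all particles to the
evolving template until the summed log-likelihood stops improving for `J`
consecutive iterations (default 3). Registration design choices: an in-plane
rotation scan (32 angles) seeds a bounded simplex refinement; the most
precise localizations are preferred when subsampling either side (they carry
the sharpest contrast); after the first iteration each particle's previous
pose is an additional refinement start, so phase locks can persist *and*
escape; a fixed small background weight (0.05) absorbs unmatched
localizations. Templates are subsampled (default 1500 points) before acting
as models, since the mixture cost is O(J·K). Optional pre-alignment by a
smooth dual-ring fit (pose only; no shape parameter is transferred) narrows
the rotational search for ring-like particles — without it the rotation
search must cover the full sphere of poses, and overlaps of denser corners
("hot spots") become more likely, which is why the pre-alignment exists.
At mean lateral precisions around 10 nm and 60% labeling, azimuthal
vacancy lumps compete with the genuine corner signal during bootstrap;
seeding the template from the most azimuthally uniform particles (a
model-free per-particle score) mitigates this.

## Depth-dependent axial correction

Astigmatic 3D localization distorts z increasingly with depth. Structures of
known axial extent calibrate the distortion: per fitted site the
tilt-corrected apparent ring separation is regressed on depth with a
quadratic $s(z) = c_1 z^2 + c_2 z + c_3$, the scaling factor is
$s_f(z) = E(s)/s(z)$ against a reference separation $E(s)$ (49.3 nm for the
Nup96 standard), and corrected coordinates are $z' = E(z) - E(0)$ with
$E(z) = \int s_f\,dz$, $E(z_0) = z_0$ (numerical quadrature; the focal plane
stays at zero). We fit the quadratic to the tilt-corrected separation
$s_z/\cos\psi$ rather than to raw $s_z$, so the curve estimates $s(z)$
directly; for untilted sites the two formulations coincide. The per-site
moving-median smoothing some pipelines apply before this regression is
omitted — the least-squares quadratic plays that role.

Site segmentation (`segmentNpcSites`) renders a 2D histogram, convolves it
with a ring ⊗ Gaussian kernel (defaults: 5 nm pixels, 55 nm ring radius,
10 nm SD; the detection threshold is user-set), and cleans candidates in
three steps: a free-radius algebraic circle fit (Kåsa plus Gauss–Newton
refinement) must land in [40, 70] nm; after a fixed-radius center refit at
most 25% of localizations may lie within 40 nm of the center and at most
40% beyond 70 nm; and at least 30 localizations are required.

## Numerical and scale choices

Lengths are nm, angles radians; site boxes are closed; mixture
contributions more than $\sqrt{80}$ standard deviations away are skipped in
the C++ kernel (relative error < 4·10⁻¹⁸). The test-suite studies use the
smallest scales that give stable statistics on a single CPU: 200 simulated
sites for parameter recovery, 100 for symmetry selection, 150 particles for
model-free averaging, and 16 depth-distributed sites for the
z-correction; the acceptance script re-runs the same computations at
moderately reduced sizes. All randomness flows from explicit integer seeds.

## Known limitations

* The likelihood treats localizations as independent; repeated blinks of
  one fluorophore violate this, and a probabilistic blinking model is out of
  scope here.
* Ring separation at $\sigma_z \approx 30$ nm carries the small negative
  bias described above; report it together with the axial precision.
* Per-site symmetry classification and model-free phase alignment degrade
  at low labeling efficiency and ~10 nm precision; population-level
  statements (cumulative AICc distributions, pooled averages) remain far
  more robust than single-site calls.
* HDF5 localization tables are not supported in this build (CSV is); the
  reader/writer API keeps the format argument so the capability can be added
  without interface changes.
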