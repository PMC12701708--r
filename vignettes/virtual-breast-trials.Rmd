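---
title: "Simulating longitudinal virtual imaging trials of breast anatomy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating longitudinal virtual imaging trials of breast anatomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breastsim)
```

Virtual imaging trials replace patients with simulated anatomy so that
imaging techniques — here, digital mammography and breast tomosynthesis —
can be compared over whole screening histories without dose or recruitment
constraints. `breastsim` provides the anatomy-and-population half of such a
trial: virtual women with realistic joint statistics, voxel breast phantoms
with tunable density, growing soft-tissue lesions, and temporal models that
move each woman through the screening ages 40–74. X-ray projection,
reconstruction, detector noise and observer models are deliberately out of
scope; phantoms are exported as raw voxel volumes with a material table so
external projection chains can consume them.

## The population model

Each woman is described by five variables: breast volume (cm³), dense
(fibroglandular) volume (cm³), age (years), and the annualized changes in
breast volume (cm³/yr) and volumetric breast density (percentage
points/yr) between two consecutive screens. Their joint distribution is
modeled as a Student-t copula with kernel-smoothed margins,

$$ (U_1,\dots,U_5) \sim C_{t}(\hat\rho, \hat\nu), \qquad
   X_j = F_j^{-1}(U_j), $$

where $F_j$ is a Gaussian-kernel CDF estimate of margin $j$ (Silverman
bandwidth, evaluated on a 1024-point grid and inverted by monotone
interpolation). Breast and dense volume are log-transformed before margin
estimation and exponentiated on the way back, which guarantees positive
sampled volumes. The t family is used rather than the Gaussian because the
screening data show visible tail dependence: extreme volumes and extreme
dense volumes co-occur.

Fitting is pseudo-maximum likelihood in two steps:

* $\hat\rho$ by Kendall-tau inversion, $\rho_{ij} = \sin(\pi
  \tau_{ij}/2)$, projected to the nearest positive-definite correlation
  matrix (eigenvalue clipping). Tau uses the tie-corrected tau-b statistic,
  computed in $O(n\log n)$ (Knight's algorithm) so that bootstrap
  replication at $n = 25{,}188$ stays cheap.
* $\hat\nu$ by profiling the t-copula log pseudo-likelihood over
  $\nu \in (2, 100]$ with margins and $\hat\rho$ fixed, optimized on the
  log scale.

For elliptical copulas $\tau = \tfrac{2}{\pi}\arcsin\rho$
(`copula_implied_tau()`), which the tests use as an analytic oracle: fit →
sample → tau must close this loop within Monte-Carlo error.

The synthetic cohort generator (`generate_cohort()`) is the package's
stand-in for the real screening register, which cannot be redistributed. It
samples the same t-copula with the published correlation matrix and
$\nu = 16.44$, and maps margins through simple moment-matched families:
lognormal for the two volumes (matching mean ± SD 848 ± 495 and 74 ± 42),
a truncated normal on [40, 74] for age (53 ± 10 before truncation), and
normals for the two change variables (14 ± 95 and 0.5 ± 11). These are the
study conditions; they are not tuning knobs. Two caveats are intentional:
the real register's administrative pile-up of ages at exactly 40 is *not*
emulated by default (an optional `age40_spike` mixture weight adds it), and
the published tables label the density change in cm³ while the rate tables
use percentage points per year — the generator uses percentage points. The
marginal families are analytic conveniences: passing tests demonstrate that
the copula machinery recovers *these* margins and dependence, not that real
screening margins are lognormal.

One published inconsistency is worth recording: the input correlation
matrix gives $\rho = -0.20$ for (dense volume, Δdensity), while the
published simulated tau for that pair is $+0.126$; the implied tau
$-0.128$ matches only in magnitude. The correlation matrix is treated as
authoritative for simulation input, and `goodness_of_fit()` flags the pair
in its report rather than silently absorbing it.

## Voxel phantoms from thresholded fractal noise

Tissue texture is classic lattice gradient (Perlin) noise: random unit
gradients on integer lattice nodes (hash-indexed from a per-seed table, so
fields are pure functions of seed and coordinate), quintic-smoothstep
interpolation, and several octaves summed with per-octave frequency ×
`lacunarity` and amplitude × `persistence`. Raw fields are mapped to
[0, 1) affinely using the theoretical amplitude bound $\pm\sqrt3/2$ per
octave — not per-block min/max, so a threshold means the same thing in
every phantom and every z-slab. A voxel becomes glandular structure when
its field value is at least the effective threshold $SF \cdot T$; `T = 1`
produces no structures, `T = 0` fills the volume, and raising the scaling
factor SF removes structure voxels while never adding any (set inclusion).
That monotonicity is the involution mechanism used for aging.

A phantom combines two default texture blocks — a coarse glandular block
(base frequency 8 cells across the 220 mm block, 4 octaves, persistence
0.55, T = 0.60) and a finer connective block (base frequency 20, 3
octaves, T = 0.62) — inside a half-superellipsoid breast outline with a
flat chest-wall face. The published description fine-tunes its noise
parameters to breast tissue without printing them; the defaults here were
fixed once so that structures have tissue-like scale (coarse structures a
few cm) and so that replicate phantoms at a fixed SF vary by well under the 2
percentage points of the calibration-accuracy contract (the per-level
spread is reported as `sd_vbd` by `calibrate_density()`). All of them are configuration, not constants.

The outline solves for the target breast volume by bisection on an exact
analytic voxel count (no mask array needed), scaling the semi-axes for
volumes that fit an ordinary half-ellipsoid and raising the superellipsoid
exponent (up to 8) for volumes that do not — the default 220 × 120 × 60 mm
block caps a pure half-ellipsoid at ~829 cm³, below the 848 cm³ population
mean, so large breasts bulge toward the block walls instead of failing.
Assembly is tiled in z-slabs (noise windows tile seamlessly), so the
full-scale grid of 2200 × 1200 × 600 voxels at 0.1 mm never needs more
than one slab of floating-point texture in memory; the desk-scale default
is the same physical block at 1 mm (220 × 120 × 60 voxels), and its
density calibration is statistically consistent with full scale because
the noise is parameterized in cells per physical block edge, not per
voxel.

Volumetric breast density is the weighted voxel fraction

$$ \mathrm{VBD\%} = 100 \cdot
   \frac{\sum_{v \in \mathrm{breast}} w_g(v)}{N_{\mathrm{breast}}}, $$

with air excluded from both sums and $w_g$ the per-index glandular weight
(defaults: adipose 0, glandular structure 1, plus a 0.1-step mixture
ladder used by heterogeneous lesions).

### Density calibration

`calibrate_density()` builds ten phantoms per SF level (defaults: five
levels from 0.95 to 1.09 spanning ~1–25% VBD) and fits
$\log \mathrm{VBD} = c_0 + c_1 SF + c_2 SF^2$ to the level means by least
squares, with a monotonicity guard and a pure-exponential fallback. The
quadratic-in-SF log form is not arbitrary: the structure fraction is the
upper tail of an approximately Gaussian field, so its log falls off
quadratically in the threshold; a pure exponential leaves systematic
residuals of several percentage points at the dense end, while the
quadratic fit's residuals are an order of magnitude smaller than the
phantom-to-phantom spread. `sf_for_density()` inverts
the curve by bisection (tolerance 1e-6) and refuses targets outside the
calibrated density range rather than extrapolating.

## Lesions and growth

A lesion is a sphere with a noise-perturbed margin, $r(\hat{u}) =
R(1 + a\,\eta(\hat{u}))$, where $\eta$ is fractal noise evaluated on the
*unit direction sphere* (amplitude default $a = 0.2$). Because the noise
frame never sees the diameter, regrowing a lesion with the same seed
preserves its margin shape — the property that makes longitudinal lesion
series look like one growing mass rather than three unrelated ones. After
voxelization the shape is rescaled so its largest grid-axis extent equals
the declared diameter, which is also how "diameter" is defined for
irregular masses. Three composition methods: (1) homogeneous mass; (2)
background enhancement — glandular weights inside the lesion multiplied by
1.5, clamped at 1; (3) enhancement plus an interior fractal texture mapped
onto the mixture-index ladder.

Growth follows the worked clinical scenario: linear diameter,
$d(t) = d_0 (1 + t/\mathrm{TDT})$, with the cohort-mean doubling period of
282 days (observed range 46–749). Note this period doubles the *diameter*
— the source scenario grows 5 mm to 10 mm over one period and to ~18 mm
(17.94) over two years, which a strict volume-doubling law cannot
reproduce. Both readings are implemented; `mode = "volume"`
($d_0 2^{t/3\mathrm{TDT}}$) is behind a flag, and the linear-diameter form
is the default because it reproduces the published worked example. Growth
is independent of the host woman's age.

## Lesion insertion

Automatic insertion samples a clinical quadrant — upper-outer 58.5%,
upper-inner 15.7%, lower-outer 8.4%, lower-inner 9.9%, renormalized over
the four quadrants because the published values sum to 92.5% (the residual
plausibly corresponds to central/retroareolar lesions the four-quadrant
scheme omits). Quadrants are defined by transverse and sagittal planes
through the nipple; a laterality flag states which side is lateral, so
flipping it exchanges outer and inner labels exactly. Within the quadrant,
the center voxel is drawn with probability proportional to the local
glandular weight plus a floor of 0.01 (so fully adipose quadrants remain
reachable) — the most direct operationalization of a linear relationship
between lesion position and local density; whether the published relation
is with local or quadrant-aggregate density is ambiguous, and the local
reading was chosen. Centers are restricted to an interior mask covering
90% of the breast volume (computed by ranking an exact Euclidean distance
transform and keeping the deepest voxels, ties broken deterministically),
which keeps lesions from being subcutaneous, further eroded by the
lesion's bounding radius so the whole mass stays inside the breast.
Manual and semi-automatic modes take explicit coordinates, with any subset
of axes fixed and the rest drawn uniformly over the admissible voxels.

## Temporal evolution

Three methods move a woman through her screening history:

* **Method A** (population curve): density follows the exponential through
  the anchor points (53 yr, 10.14%) and (54 yr, 9.89%) — i.e. rate
  $r = \ln(9.89/10.14) \approx -0.0250$/yr — and volume is linear through
  (53 yr, 848 cm³) at +14 cm³/yr. At the Swedish screening milestones
  40/57/74 this gives 14%, 9%, 6% density after rounding. The exponential
  is constructed from the two anchors rather than refit to anything,
  because that construction reproduces all three published milestone
  values.
* **Method B** (stepwise by age group): annualized rates per group
  (40–44: −0.27 pp and +16.64 cm³; 45–54: −0.38, +18.43; 55–64: −0.15,
  +11.68; 65–74: −0.028, +0.60), integrated year by year. The rate for
  the year $[a, a+1)$ is the rate of the group containing integer age $a$
  — a convention that has to be fixed for reproducibility. The density
  decrement is realized as a re-anchored exponential each year, whose
  full-year effect equals the tabulated percentage-point rate exactly, so
  the first simulated year matches the table. Under this convention the
  total 40→74 volume gain is 5·16.64 + 10·18.43 + 10·11.68 + 9·0.60 =
  389.7 cm³.
* **Method C** (individual draw): one joint sample of the two change
  variables from the fitted copula, applied over a single inter-screen
  interval. It is deliberately restricted to two time points: iterating
  individual draws accumulates random variation that the population-level
  methods avoid, so longer timelines must use A or B.

`build_timeline()` combines a method with a density calibration and an
optional growth model: per-age targets, SF via `sf_for_density()`, tumor
diameter at 365 days/year (so "two years" is exactly 730 days), and one
phantom seed per woman. Because the seed is fixed and only SF rises as
density falls, successive phantoms of one woman share the same noise
anatomy and glandular structures only ever disappear — involution on a
registered volume. Volume changes move the outline; density changes move
only the threshold.

## Numerical choices and degenerate inputs

* Rescaled noise is clamped to $[0, 1 - 10^{-9}]$ so a threshold of
  exactly 1 is always empty; thresholds are clamped to [0, 1] after SF
  scaling.
* Rotation uses nearest-neighbor resampling about the breast-mask centroid
  (so no interpolated tissue indices appear); a grid-center option makes
  90° rotations of cubic grids exact voxel permutations, which the tests
  exploit as an oracle.
* Erosion ties, quadrant-plane ties (assigned to the inner/inferior side)
  and Method B's year assignment are all fixed conventions, stated here
  because each would otherwise be an invisible source of irreproducibility.
* Degenerate requests error early with the offending quantity named:
  empty strata, non-positive-definite correlation inputs, constant
  variables, targets outside the calibrated density range, lesions below
  the resolvable size, centers outside the interior mask.
* Sub-seeds derive from the master seed by a Lehmer step, keeping every
  derived seed below $2^{31}$.

## Problem sizes

The test suite and the acceptance script run entirely at desk scale:
cohorts of 25,188 (the source register's size) for population statistics,
the 220 × 120 × 60 grid at 1 mm for calibration (five levels × ten
phantoms), and smaller grids for structural property checks. Full-scale
2200 × 1200 × 600 phantom assembly uses the identical tiled code path;
outline volume checks at full scale run analytically without voxel
arrays.

## Known limitations

* No skin layer, no compression, no microcalcifications or architectural
  distortions; texture is isotropic (no ductal convergence toward the
  nipple).
* The index-to-attenuation dictionary of downstream projection tools is
  not published; the exported material table is configurable and the
  mapping is the user's responsibility.
* Phantom realism is statistical (density, structure scale), not
  anatomical: passing tests show the density/dependence machinery is
  correct, not that images of these phantoms would read as mammograms.
* BI-RADS category replication and conditional sampling beyond age
  stratification are out of scope.

## A worked example

```{r example, eval = FALSE}
library(breastsim)

# virtual population
cohort <- generate_cohort(cohort_spec(n = 25188, seed = 1))
fit <- fit_copula(cohort)
glance(fit)

# density-calibrated phantom at the cohort-mean anatomy
spec <- phantom_spec()
cal <- calibrate_density(spec, seed = 1)
ph <- build_phantom(spec, sf = sf_for_density(cal, 10.14), seed = 1)
compute_vbd(ph)

# one woman, three screening rounds, a growing lesion
manifest <- run_pipeline(list(
  seed = 11, ages = c(40, 41, 42), method = "A",
  shape = c(110, 60, 30), voxel_mm = 2,
  sf_levels = c(0.95, 0.99, 1.03), calibration_phantoms = 3,
  lesion = list(d0_mm = 8, tdt_days = 282, method = 3, insert = "auto")))
manifest
```
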