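---
title: "Monte Carlo dosimetry and treatment planning for PDT of abscess cavities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo dosimetry and treatment planning for PDT of abscess cavities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cavityPDT)
```

## The problem

Percutaneously drained abscess cavities can be treated with antimicrobial
photodynamic therapy (PDT): methylene blue (MB) is instilled and aspirated,
the cavity is filled with dilute Intralipid as a biocompatible scattering
medium, and 665-nm light is delivered through a flat-cleaved optical fiber
advanced to the approximate center of the cavity. Whether a patient can
receive an efficacious light dose depends on the cavity's size and shape,
on absorption at the abscess wall (native chromophores plus retained MB),
on scattering and residual absorption inside the cavity, and on the maximum
power of the clinical laser. `cavityPDT` simulates the fluence-rate
distribution on the cavity wall by voxel Monte Carlo photon transport and
turns it into a treatment plan: the threshold optical power, the optimal
Intralipid concentration, and a PDT eligibility flag.

## Geometry model

All computations run on a three-region voxel geometry (`label_grid`):
cavity interior (label 2), abscess wall (label 1), and surrounding tissue
(label 0), on a CT-like, possibly anisotropic grid with lengths in cm.
Because patient CT segmentations are not distributed with the package, a
phantom generator supplies the study geometries: spheres, ellipsoids, and
lobulated cavities (the union of a base ellipsoid and several seeded,
jittered, shrunken ellipsoids, reduced to its largest 6-connected
component), which reproduces the spherical-to-highly-irregular morphology
range of drained abscesses. Cavities are capped at 8 cm maximum diameter,
mirroring the clinical exclusion criterion. Real segmentations can be
supplied as NIfTI-1 volumes, either full label maps or binary cavity masks.

Choices worth knowing:

* **Wall thickness** defaults to 0.2 cm. The imaging literature describes
  the abscess wall as a thin enhancing rim and the source study does not
  state its segmented thickness; 2 mm spans two voxels at the default
  0.1 cm spacing and exceeds one transport mean free path at
  $\mu_s = 100\,\mathrm{cm^{-1}}$, $g = 0.9$, so tissue deeper than the
  wall is represented by the generic exterior region without affecting
  wall dosimetry.
* **Wall shell extraction** marks as wall every non-cavity voxel whose
  center lies within the thickness of a cavity voxel center (a thresholded
  Euclidean distance transform). The digitized shell converges on the
  analytic shell as spacing shrinks; at 0.1 cm it runs roughly a third of
  a voxel thin, which is immaterial to wall-surface dosimetry because the
  sampling surface is the innermost wall layer.
* **Exterior padding** defaults to 1 cm of surrounding tissue beyond the
  wall so that the absorbing domain boundary (photons leaving the grid are
  tallied as escaped) does not perturb the fluence at the wall.
* **The wall sampling surface** is the set of wall voxels 6-adjacent to
  the cavity. Each carries a representative area of $2/3$ of its summed
  cavity-facing face areas: a voxelized interface overestimates a smooth
  surface by the orientation-averaged factor $|n|_1/|n|_2 = 3/2$, and the
  $2/3$ correction recovers the smooth area exactly for spheres in the
  fine-voxel limit (for a 2-cm-radius sphere at 0.1 cm spacing the summed
  area is within 1% of $4\pi r^2$). Only relative areas enter the
  area-weighted dose percentiles, so this convention matters mainly for
  reported totals.
* **Fiber placement**: the unweighted centroid of the cavity voxel
  centers, as in the clinical procedure. For strongly non-convex cavities
  the centroid can fall outside the cavity; the function reports it with a
  flag rather than guessing a better insertion point, since the procedure
  itself only reaches "the approximate center".

## Optical model

Each region carries $(\mu_a, \mu_s, g, n)$ at 665 nm. The exterior is
fixed at $(0.2, 100, 0.9, 1.4)$ and the wall at
$(\mu_{a,\mathrm{wall}}, 100, 0.9, 1.4)$; the cavity has $g = 0.7$,
$n = 1.33$ and sweep-controlled $\mu_{a,\mathrm{cavity}}$ and
$\mu_{s,\mathrm{cavity}}$. Concentrations map linearly to coefficients:

* MB: $0.17\,\mathrm{cm^{-1}}$ per µM, so the studied wall range 0.2-10
  cm⁻¹ reaches to roughly 60 µM of retained MB. The wall absorption is
  modeled as the total $\mu_a$ with no additive tissue baseline, because
  the 10 cm⁻¹ ↔ ~60 µM pairing implies none; a configurable baseline
  would multiply entities without data to set it.
* Intralipid: anchored at 2.3% ↔ $100\,\mathrm{cm^{-1}}$ (percent
  lipid, v/v), so that sweep axes in concentration units match the
  study conditions exactly. An independent Mie-based wavelength
  parameterization in the van Staveren form,
  $\mu_s(c, \lambda) = 16\,\lambda_{\mu m}^{-2.4}\, c$ cm⁻¹ per percent
  lipid, is provided as a cross-check only; at 665 nm the two agree to
  about 2% (the Mie model puts 100 cm⁻¹ at 2.35%, i.e. 2.3% at one
  decimal). The anisotropy inside the cavity stays at 0.7 for all
  concentrations.

## Transport kernel

The engine is a single-threaded voxel Monte Carlo in C++ (MCML lineage),
with weighted photon packets:

* **Sampling**: packets advance by scattering optical depth
  ($-\ln \xi$ consumed against $\mu_s$ per voxel, carried over across
  voxel boundaries), so regions with $\mu_s = 0$ produce free flight to
  the next interface. Deflection angles come from the Henyey-Greenstein
  inverse CDF; azimuths are uniform.
* **Absorption and tally**: absorption attenuates the weight continuously,
  and each traversed segment adds the exact integral
  $w\,(1 - e^{-\mu_a \ell})/\mu_a$ (or $w\ell$ when $\mu_a = 0$) to the
  voxel's track-length tally. This expected-track-length form, rather than
  the cruder $w\ell$ with stepwise weights, is what keeps the
  Beer-Lambert benchmark exact when $\mu_a \ell$ per voxel approaches 1
  (wall voxels at $\mu_a = 10\,\mathrm{cm^{-1}}$). A track-length
  estimator is required in any case because the cavity legitimately has
  $\mu_a = 0$, where absorption-deposition estimators are undefined.
* **Interfaces**: at any voxel face where the refractive index changes,
  unpolarized Fresnel reflection or Snell refraction is applied, with
  total internal reflection beyond the critical angle. The domain boundary
  is absorbing; escaping weight is tallied.
* **Termination**: Russian roulette below weight $10^{-4}$ with survival
  probability 0.1. Roulette weight changes are folded into the absorbed
  ledger (a kill books $+w$, a survival books $-(1/p-1)\,w$), so
  `absorbed + escaped` equals the launched weight to floating-point
  round-off on every run while remaining unbiased in expectation.
* **Reproducibility**: each packet draws from an RNG substream
  (xoroshiro128+ seeded by splitmix64) keyed by the run seed and the
  packet index, so results are bit-identical across runs and independent
  of execution order.
* **Source model**: the clinical fiber is a 400-µm flat-cleaved core
  (NA 0.22, core index 1.46) emitting uniformly over the core disk,
  uniformly in solid angle within the acceptance cone computed in the
  launch medium, $\theta_{max} = \arcsin(\mathrm{NA}/n_{med})$ (9.5° in
  water-like cavity contents). Fresnel loss at the fiber face is folded
  into the delivered, out-of-fiber power, which is how clinical laser
  power is specified. An isotropic point source is available for
  validation.

Fluence maps are stored per unit delivered power (cm⁻²·mW⁻¹ per mW, i.e.
cm⁻²) and scaled linearly to candidate powers, so each
geometry-properties cell needs a single simulation.

The suite validates the kernel against closed forms: inverse-square
fluence in a transparent medium and Beer-Lambert attenuation in a purely
absorbing one (both within 5% at $10^5$ packets), diffusion theory
$\phi(r) = 3\mu_{tr} P e^{-\mu_{eff} r}/(4\pi r)$ in a strongly
scattering medium (within 15% at 0.5-1.5 cm), and the integrating-sphere
buildup: with a transparent cavity and a weakly absorbing wall, the wall
behind the fiber — where the direct line-of-sight prediction is exactly
zero — still receives strictly positive fluence from diffuse wall
reflections.

## Planning model

Per-mW fluence values on the wall surface, paired with voxel areas, form
the wall distribution that all planning reads:

* **Threshold power** $P_{th} = T / q_{05}$ with
  $T = 4\,\mathrm{mW\,cm^{-2}}$ and $q_{05}$ the area-weighted lower
  quantile at 5%: the largest wall value with at most 5% of the wall area
  strictly below it. By linearity this equals the least power at which 95%
  of the wall area reaches $T$; a brute-force power scan on a 0.1-mW
  lattice is the test oracle. If 5% of the wall receives no light,
  $P_{th} = \infty$.
* **Hotspot constraint**: no more than 5% of the wall area at or above
  $400\,\mathrm{mW\,cm^{-2}}$ (the inequality is closed), checked by
  direct area counting; dose comparisons carry a $10^{-12}$ relative
  slack so that exact boundary products such as $P_{th} q_{05} = T$
  survive floating-point round-off.
* **Eligibility**: $P_{th}$ strictly below the 2000 mW laser cap and
  hotspot-feasible at $P_{th}$. The percentile shortcut
  ($q_{95}/q_{05} < H/T = 100$, with $q_{95}$ the largest value
  met-or-exceeded by more than 5% of the area) agrees with the counting
  route by construction; both are tested.
* **Optimal Intralipid**: the simulated concentration minimizing
  $P_{th}$ at the given wall absorption — no interpolation, ties toward
  the lower concentration, ineligible cells excluded unless every cell is
  ineligible (then the best ineligible cell is reported, flagged, so
  sweep tables stay rectangular). The comparator **uniform-dose plan**
  fixes Intralipid at the grid cell nearest 1% — the current clinical
  protocol — and optimizes power only.
* **Intracavity absorption (case 2)** evaluates three planning modes per
  cell: `fixed-plan` (power and concentration frozen at their zero-
  absorption values — planning blind to MB leakage), `power-only`
  (concentration frozen, power re-planned), and `full` (both re-planned).
  Nesting guarantees the eligibility dominance chain
  full ≥ power-only ≥ fixed-plan, which the tests assert cell-by-cell,
  and optimized-vs-uniform dominance holds for the same reason.

Sweeps derive one seed per task by stable hashing of the master seed and
the task key, so enlarging a grid never changes existing cells, and
per-cell fluence maps can be cached to disk (NIfTI + JSON sidecar),
making interrupted sweeps resumable. Friedman tests (threshold power or
optimal concentration across conditions) and Wilcoxon signed-rank tests
(paired eligibility between strategies) are available for sweep
summaries; outputs record whether an exact or asymptotic p-value was
computed.

## What the synthetic phantoms do and do not show

The phantom generator reproduces the geometric features the analysis
depends on — closed single cavities up to 8 cm, wall shells, convex and
lobulated shapes, CT-like anisotropic voxels — under exactly the region
optics of the study conditions. It does not reproduce patient-specific
morphology statistics, heterogeneous wall optics, partial-volume
segmentation error, or multiple cavities. Consequently the package's
property-level results (threshold power rising with wall and intracavity
absorption; optimized planning dominating the uniform dose; eligibility
falling as absorption grows) reproduce the direction and mechanism of the
cohort findings, but cohort-level percentages (such as eligibility
fractions over 60 patients) depend on the unavailable CT geometries and
are out of scope.

## Problem sizes and numerical choices

Default test and example runs use $10^4$-$10^5$ packets on 64³-70³ grids
at 0.1 cm spacing; at these sizes the wall-quantile Monte Carlo noise is
at the percent level, well below the effects being measured, and a cell
simulates in seconds to tens of seconds on one CPU. The monotonicity
checks use a 4-cm-diameter sphere at $10^5$ packets over three seeds and
ask for majority agreement, which is robust to the residual noise at the
ineligible extreme ($\mu_{a,wall} = 10\,\mathrm{cm^{-1}}$). Degenerate
inputs are first-class: empty masks, walls spanning the whole domain,
centroids outside non-convex cavities, all-dark wall patches
($P_{th} = \infty$), and all-ineligible sweep cells all have defined,
tested behavior.

## A worked example

```{r example, eval = FALSE}
phantom <- generate_phantom(phantom_spec("sphere", radius = 2, seed = 1))
source <- fiber_source(cavity_center_of_mass(phantom)$point)
cell <- property_cell(mu_a_wall = 1, mu_s_cavity = intralipid_to_mus(1),
                      mu_a_cavity = 0)
map <- simulate_fluence(phantom, assemble_properties(cell), source,
                        n_photons = 1e5, seed = 42)
dist <- wall_distribution(map, wall_surface(phantom))
eligibility(dist)
```

Sweeps over property grids, with plans and eligibility matrices written
as CSV, run through `run_sweep_case1()` / `run_sweep_case2()` or the
`cavitypdt` command-line front end in `inst/cli`.

## Known limitations

Single fiber placement only (as dictated by the drainage catheter);
uniform optical properties per region; fluence rate as the dose proxy
(no explicit photosensitizer-uptake or singlet-oxygen model, and the
hotspot limit stands in for thermal modeling); no polarization or
time-resolved transport; voxel (not mesh) geometry.
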