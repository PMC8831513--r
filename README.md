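# cavityPDT

Monte Carlo light dosimetry and patient-specific treatment planning for
photodynamic therapy (PDT) of hollow abscess cavities.

After image-guided drainage of a deep-tissue abscess, antimicrobial PDT
instills methylene blue (MB) as a photosensitizer, refills the cavity with
dilute Intralipid as a scattering medium, and delivers 665-nm light through
a flat-cleaved optical fiber placed at the center of the cavity. Whether an
efficacious light dose is achievable depends on the cavity morphology, on
absorption at the abscess wall (native tissue plus retained MB), on the
Intralipid concentration, on residual MB absorption inside the cavity, and
on the laser's 2000 mW power cap. `cavityPDT` is for researchers studying
this dosimetry problem: it simulates fluence-rate distributions in
voxelized three-region geometries (surrounding tissue / wall / cavity) and
computes treatment plans over grids of optical properties.

## The model

A weighted-packet voxel Monte Carlo (MCML lineage) propagates light from a
fiber source (400 µm core, NA 0.22, emission uniform over the core disk
and uniform in solid angle within the acceptance cone computed in the
cavity medium). Packets advance by scattering optical depth with carry-over
across voxel boundaries; absorption attenuates the weight continuously;
Henyey–Greenstein scattering (anisotropy g), unpolarized Fresnel
reflection / Snell refraction at refractive-index steps, and Russian
roulette termination complete the kernel. Per-voxel fluence rate per unit
delivered power, φ/P in cm⁻², is tallied with an expected-track-length
estimator, which stays defined in the non-absorbing cavity:

    φ/P = Σ w (1 − e^{−μa ℓ}) / μa / (V_voxel N)   (→ Σ w ℓ / (V N) as μa → 0)

Plans are read off the area-weighted per-mW fluence distribution on the
cavity-facing wall surface:

* threshold power `P_th = 4 mW/cm² / q05` — the least power at which 95%
  of the wall area reaches the 4 mW/cm² target;
* hotspot safety — at most 5% of the wall area at or above 400 mW/cm²;
* eligibility — both constraints met strictly below 2000 mW;
* optimal Intralipid — the simulated concentration minimizing `P_th` at a
  given wall absorption (no interpolation), compared against the clinical
  uniform-dose protocol (1% Intralipid, power optimized).

Synthetic phantoms (spheres, ellipsoids, seeded lobulated shapes, ≤ 8 cm
diameter) stand in for patient CT segmentations; NIfTI-1 masks of real
segmentations are also accepted.

## A worked example

```r
library(cavityPDT)

phantom <- generate_phantom(phantom_spec("sphere", radius = 2, seed = 1))
phantom
#> label_grid: 64 x 64 x 64 voxels, spacing 0.1 x 0.1 x 0.1 cm
#>   cavity: 33552 voxels (33.55 cm^3), wall: 9392 voxels

source <- fiber_source(cavity_center_of_mass(phantom)$point)
cell <- property_cell(mu_a_wall = 1, mu_s_cavity = intralipid_to_mus(1),
                      mu_a_cavity = 0)
map <- simulate_fluence(phantom, assemble_properties(cell), source,
                        n_photons = 1e5, seed = 42)
map
#> fluence_map: 64 x 64 x 64 voxels, N = 100,000, seed 42
#>   absorbed 0.981661, escaped 0.0183393, power 1 mW

dist <- wall_distribution(map, wall_surface(phantom))
str(eligibility(dist))
#> List of 5
#>  $ p_threshold: num 57.3
#>  $ hotspot_ok : logi TRUE
#>  $ eligible   : logi TRUE
#>  $ q05        : num 0.0699
#>  $ q95        : num 0.122
```

Reading: with 1 cm⁻¹ wall absorption and 1% Intralipid in a 4-cm spherical
cavity, 95% of the wall reaches 4 mW/cm² at 57.3 mW of delivered power —
far below the 2000 mW cap — and the 95th-to-5th percentile dose ratio
(~1.7) is nowhere near the 100× hotspot bound, so this geometry/optics
cell is PDT-eligible. Property sweeps, optimal-Intralipid and uniform-dose
plans, intracavity-absorption planning modes, and paired statistics run
through `run_sweep_case1()`, `run_sweep_case2()`, `friedman_test()`, and
`wilcoxon_signed_rank()`; `inst/cli/cavitypdt` wraps phantom generation,
single simulations, planning, and full sweeps for shell use.

See the vignette (`vignettes/treatment-planning.Rmd`) for the model,
conventions, and design choices.

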