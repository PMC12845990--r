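---
title: "Voxel point-density-proxy radiative transfer: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel point-density-proxy radiative transfer: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vpdp)
```

## The problem

Radiative transfer models of forest canopies normally require a 3-D field of
leaf area density (LAD), which is laborious and error-prone to estimate from
mobile LiDAR (UAV-mounted or handheld SLAM scanners). This package implements
a deliberately simplified alternative: the per-voxel LiDAR *point count* is
used directly as a proxy for the amount of light-intercepting material in
that voxel. The model's absolute radiometry is meaningless by construction;
what is informative is how well the *spatial pattern* of simulated radiance
correlates with an observed coarse satellite reflectance image. That
correlation, after calibration of the model's two empirical coefficients,
acts as a diagnostic score for the structural fidelity and completeness of
the input point cloud.

## The radiative transfer model

A point cloud is binned into a voxel grid with counts $P_{ijk}$ (half-open
cells, z index increasing upward). Light enters every $(i,j)$ column
vertically from above with irradiance $I$. The transmitted irradiance
reaching voxel $[i,j,k]$ follows a Beer–Lambert law with the cumulative
point count along the path as optical mass:

$$I'_{ijk} = I\, e^{-\alpha P_{\mathrm{sum}}}, \qquad
  P_{\mathrm{sum}} = \sum_{k' > k} P_{ijk'},$$

where $\alpha$ (per point) converts point density into attenuation.
$P_\mathrm{sum}$ covers the voxels strictly *between* the light source and
the target voxel: a voxel does not attenuate the light arriving at itself.
Each occupied voxel reflects as a Lambertian surface back toward a nadir
sensor, with a second coefficient $\beta$ attenuating the return path:

$$I''_{ijk} = \frac{R\, I'_{ijk}\, e^{-\beta \sum_{k'>k} P_{ijk'}}}{\pi},$$

and the per-column total is $I_{\mathrm{sum}}(i,j) = \sum_k I''_{ijk}$.
The fine map is then resampled to the satellite pixel size (10 m by
default) by average aggregation.

Two modelling choices deserve emphasis:

* **Occupied-voxel contribution.** A literal sum over all $k$ would let
  empty voxels "reflect", making column radiance depend on how much empty
  lattice sits in the column — an artifact of lattice extent, not of
  structure. Contributions are therefore restricted to voxels with
  $P_{ijk} \ge 1$; the literal reading remains available via
  `reflect_empty = TRUE` for comparison.
* **The $\alpha + \beta$ ridge.** With both paths vertical, the incident
  and return paths cross the same material, so every contribution is
  $\tfrac{RI}{\pi} e^{-(\alpha+\beta) P_\mathrm{sum}}$: the simulated map —
  and hence the correlation objective — depends on the coefficients only
  through their sum $\gamma = \alpha + \beta$. This is a property of the
  nadir geometry, not a numerical accident. The two-coefficient
  parameterization is retained because incident- and return-path
  attenuation are physically distinct processes and the pair becomes
  separately identifiable the moment an off-nadir geometry is added; ties
  along the ridge are broken
  deterministically (smallest $\gamma$, then smallest $\alpha$), and the
  fitted $\gamma$ is the physically identified quantity reported alongside
  the pair.

### Parameters

| parameter | units | default | role |
|---|---|---|---|
| $I$ | — | 1 | incident irradiance; pure scale factor |
| $R$ | — | 0.05 | leaf NIR reflectance (larch mean); pure scale factor |
| $\alpha$ | point$^{-1}$ | fitted in $[10^{-4}, 1]$ | incident-path attenuation per point |
| $\beta$ | point$^{-1}$ | fitted in $[10^{-4}, 1]$ | return-path attenuation per point |
| voxel size | m | 0.5 | lattice resolution; 0.5 m balances detail vs. count stability |
| pixel size | m | 10 | observed raster resolution |

Because the evaluation is a Pearson correlation, $I$ and $R$ only rescale
the simulated map linearly and provably cannot change the objective; the
package asserts this to machine precision in its tests.

## Structural metrics

**Vertical profiles.** Layer statistics (default 10 m layers above the grid
origin) report the *median* count over occupied voxels ($P \ge 1$). Medians
over all lattice cells would be identically zero in any realistic forest
lattice, where the overwhelming majority of voxels are empty air; the
occupied-voxel convention is the one that yields informative per-layer
values, and it is declared rather than inferable.

**Coverage gap ratio.** Given a reference occupancy set $V_{All}$ (by
default the union of all datasets' occupied voxels, optionally an external
ground-truth set) and a dataset's set $V_c$ on the same lattice, each
height bin $z$ gets

$$\mathrm{CGR}_z = \frac{|\{v \in V_{All,z} : v \notin V_c\}|}{|V_{All,z}|}.$$

Bins are voxel-center heights above the lattice origin; with the default
0.5 m bins and 0.5 m voxels each bin is one voxel layer. Bins with no
reference voxel are NA, never 0 — an empty reference carries no evidence of
coverage. CGR is *relative* to the chosen reference; when the reference is
the merged model it measures complementarity, not absolute occlusion.

All cross-dataset comparisons use one shared lattice computed from the
union bounding box (`shared_lattice()`), since comparing voxel index sets
across different origins is meaningless.

## Calibration and validation

The fit (`vpdp()`) is a deterministic two-stage log-spaced grid search:
a 17 × 17 grid over $(\alpha, \beta) \in [10^{-4}, 1]^2$, then a 9 × 9
refinement spanning one coarse-grid spacing around the incumbent (clipped
to the range). A grid is reproducible, free of tuning, monotone under
refinement (the incumbent is never discarded), and entirely adequate for a
one-dimensional effective parameter. Each candidate is scored at its best
horizontal shift: the fine map is shifted on a $\{-3, \dots, +3\}$ m grid
(0.5 m steps, matching the voxel size) before aggregation, reflecting
coarse-sensor geolocation uncertainty, and the maximum-correlation shift is
adopted. Nesting the shift search inside the coefficient objective means
every candidate is judged at its own best alignment. Shift ties are broken
toward the smallest magnitude, then lexicographically.

Cells shifted in from outside the fine-map extent are NA and excluded from
the pixel averages; a pixel covered only by NA cells is dropped from the
correlation. Degenerate candidates (zero variance) are skipped inside the
search, but a fully degenerate objective is an error, as is a correlation
over fewer than 3 pixels.

`subsample_validate()` repeats the whole fit on random 70/30 pixel splits
(20 iterations by default), evaluating each fitted model on its held-out
30%. Splits are stratified by observed-reflectance quartiles by default so
both subsets span the radiometric range — the stratification variable is a
design choice here, made because reflectance is the only variable shared by
every observed raster; plain random splitting is available
(`strata = "none"`). Iteration $i$ uses seed `base_seed + i`, making the
summary bit-reproducible.

## The synthetic scene generator

No suitable public LiDAR + satellite benchmark exists for this pipeline, so
the package generates its own study conditions: a 150 m × 70 m plot on a
3.0° planar slope with ~730 stems ha⁻¹ of 25–38 m trees (spheroidal crowns
of 1.5–3 m radius and 8–14 m depth above bare cylindrical stems) over a
sparse shrub layer — a structure with the characteristic mid-canopy density
minimum of mature plantations. From the resulting ground-truth cloud
(~0.4 M points; crown shells plus interiors, stems, terrain):

* the **aerial scan** keeps at most `max_returns` (default 5) top-down hits
  per 0.5 m pulse cell, occluding deeper material — upper canopy nearly
  complete, understory shadowed;
* the **ground scan** retains each point with probability
  $e^{-d/\lambda} e^{-\mu n_\mathrm{below}}$ ($d$ = horizontal distance to
  the walking path, $\lambda$ = 15 m; $n_\mathrm{below}$ = points beneath
  the target in its 0.5 m column, $\mu$ = 0.08) — dense near-path
  understory, strongly occluded upper canopy. These two coefficients are
  declared emulation choices: no quantitative occlusion model exists for
  either platform, and the values were chosen once to produce the
  qualitative crossing CGR profiles that motivate multi-platform fusion
  (aerial low-CGR canopy / high-CGR understory, ground the reverse);
* the **satellite stand-in** is produced by the package's *own* forward
  model on the truth cloud at known coefficients
  ($\alpha^\* = 0.02$, $\beta^\* = 0.01$ per point — mid-range values giving
  strong but not saturating attenuation for typical column counts),
  affinely rescaled into a plausible NIR TOA range (0.15–0.45) and
  degraded with i.i.d. Gaussian noise, by default at half the spatial
  standard deviation of the noise-free signal.

Every generator output is a pure function of its config and seed.

**What passing tests do and do not show.** Because the observation is
generated by the same forward model, calibration against it is an
internal-consistency experiment: it demonstrates that the pipeline recovers
known coefficients, planted shifts and noise-attenuated correlations, and
that the platform asymmetries propagate through to the radiometric score.
It cannot demonstrate that the proxy model is physically adequate for real
canopies — real leaf clumping, multiple scattering, off-nadir sun angles,
sensor radiometry and SLAM drift are all absent. Results on real data also
depend on the outlier filter (`remove_isolated_outliers()`), a
deterministic k-NN stand-in (k = 5, 3 sd) for what is, in practice, a
manual editing step.

## Numerical contracts

* One binning convention everywhere: half-open intervals $[lo, hi)$ with
  floor indexing; boundary points belong to the higher-index cell.
* Attenuation uses per-column cumulative sums computed top-down once;
  results are independent of traversal order; double precision throughout.
* Average aggregation is exact block averaging for integer fine/coarse
  ratios and area-weighted otherwise; aggregate means equal fine means when
  pixels tile the map exactly.
* The calibration engine factorizes shifted aggregation into two small
  per-axis 0/1 matrices and caches coarse maps per $\gamma$; its output is
  asserted (to $10^{-12}$) against the plain shift-then-aggregate pipeline.
* Count invariants: voxel totals equal in-bounds point counts; merging
  grids equals voxelizing concatenated clouds; fine grids re-binned to a
  nested coarser size equal direct coarse voxelization.

## Problem sizes

The bundled scene uses the full 150 m × 70 m plot (fine lattice roughly
320 × 160 × 93 at 0.5 m, 16 × 8 satellite pixels); unit tests that need a
complete pipeline but not the full plot use a 60 m × 40 m variant.
Property tests run on 10 × 10 × 10 random lattices, where the naive
per-voxel triple-loop oracle is affordable.

## Known limitations

* Strictly vertical light geometry: no solar zenith, no off-nadir viewing,
  hence the $\alpha+\beta$ degeneracy above.
* No multiple scattering, no wavelength dependence beyond the scalar $R$,
  no BRDF beyond Lambertian, no atmospheric modelling (the evaluation is
  correlation-based on purpose).
* LAS support is minimal (uncompressed LAS, point formats 0–3, x/y/z
  only); LAZ must be decompressed externally.
* CGR against a merged reference measures relative completeness only; an
  external truth reference (supported) is needed for absolute statements.
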