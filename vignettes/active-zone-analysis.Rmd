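---
title: "Quantifying calcium-channel topography in active zones from immunogold point patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying calcium-channel topography in active zones from immunogold point patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(azpoints)
```

## The measurement problem

SDS-digested freeze-fracture replica labeling (SDS-FRL) projects membrane
proteins onto a two-dimensional replica and marks each detected protein with
a gold particle. For voltage-gated calcium channels (Ca~V~2) at presynaptic
active zones (AZs), the data reduce to planar point patterns: particle
coordinates in nanometres inside polygonal AZ outlines, plus sparse
particles on the surrounding (extra-AZ) membrane. Three quantitative
questions follow:

1. **Calibration** — how many channels does one gold particle represent?
   Gold counts underestimate channels (epitopes missed, antibodies blocked)
   or overestimate them (antibody aggregation), so particle densities must
   be anchored to an independent channel count.
2. **Clustering** — are channels clustered within the AZ, or random?
3. **Topography** — how are channel clusters arranged relative to docked
   synaptic vesicles (SVs)?

No replica coordinates are distributed with this package; instead a
synthetic-data module generates point patterns with known ground truth
(including the channel/vesicle topography models below), so every stage of
the analysis can be validated end to end.

## The calibration chain

Let $\rho_{AZ}$ and $\rho_{ex}$ be observed particle densities
(particles/µm²) inside and outside AZs, $A_{AZ}$ and $A_{ex}$ the
corresponding membrane areas per bouton (µm²), and $N$ the total number of
channels per bouton from independent functional estimates. Assuming a common
labeling efficiency in both compartments,

$$f_{AZ} = \frac{\rho_{AZ} A_{AZ}}{\rho_{AZ} A_{AZ} + \rho_{ex} A_{ex}},
\qquad
D_{AZ} = \frac{N \, f_{AZ}}{A_{AZ}}, \qquad
\text{efficiency} = \frac{\rho_{AZ}}{D_{AZ}},$$

where $f_{AZ}$ is the fraction of channels inside AZs and $D_{AZ}$ the true
channel density there. Channel numbers then follow by dividing any particle
count by the efficiency (`channels_per_az()`, `cluster_summary()`). The
reference constants for hippocampal mossy-fiber boutons
($N = 1320$, $A_{AZ} = 3.33$, $A_{ex} = 75.5$, $\rho_{AZ} = 232$,
$\rho_{ex} = 0.84$) give $f_{AZ} \approx 92\%$, $D_{AZ} \approx 365$
channels/µm² and an efficiency of about $64\%$:

```{r calibration}
inp <- calibration_inputs(n_total_channels = 1320, az_total_area_um2 = 3.33,
                          extra_area_um2 = 75.5, rho_az = 232,
                          rho_extra = 0.84)
true_density_and_efficiency(inp)
```

These constants are preparation-specific and always enter through
`calibration_inputs()`; nothing is hard-coded. An efficiency above 1 raises
an over-labeling warning (aggregation / multiple binding) instead of being
clamped.

## Clustering statistics

**Mean NND with a Monte-Carlo CSR null.** For each AZ, the mean
nearest-neighbour distance of the observed particles is paired with the mean
of `n_sims` (default 200) complete-spatial-randomness simulations with the
same particle count in the same polygon (`csr_null()`). A two-sided paired
t-test across AZs (`paired_nnd_test()`) then asks whether real patterns are
tighter (clustered) or looser (dispersed) than random. **No edge correction
is applied to NNDs**: the null is simulated in the same window with the same
n, so boundary bias is identical in both arms and cancels in the paired
comparison.

**Pair-correlation function.** `pair_correlation()` implements the kernel
estimator

$$\hat g(r) = \frac{\sum_{i \ne j} k_h(r - d_{ij})\, w_{ij}}
{\lambda^2 |W|\, 2\pi r},$$

with a Gaussian kernel ($h$ = 5 nm by default) and isotropic (Ripley) edge
correction: $w_{ij}$ is the reciprocal of the fraction of the circle of
radius $d_{ij}$ centred on particle $i$ lying inside the window — important
because AZ polygons are small relative to the distances examined. $g = 1$
indicates randomness, $> 1$ clustering, $< 1$ dispersion. The scalar
summary used in the paired test is the mean of $g(r)$ over
$r \in [10, 50]$ nm (configurable), spanning the nearest-neighbour scale of
channel labeling (mean NNDs around 27–29 nm).

**DBSCAN.** `dbscan_cluster()` uses the standard semantics (a particle is a
core point when at least `min_points` particles, counting itself, lie
within ε; clusters are ε-reachable components of core points plus border
points; the rest is noise). Defaults follow field practice: `min_points = 3`
and ε resolved per AZ as mean NND + 2 SD (`resolve_epsilon()`); a fixed
radius (default 100 nm) is available both for DBSCAN and for the simpler
fixed-radius linkage (`fixed_radius_cluster()`). Labels are renumbered by
lowest member index, so results are deterministic and permutation-invariant
up to renumbering.

**Centre-periphery index.** For a window star-shaped about its centroid,
each particle at distance $d$ from the centroid along a ray that meets the
boundary at distance $D$ scores $\mathrm{CPI} = (d/D)^2$, an enclosed-area
fraction: 0 at the centre, 1 on the boundary, mean 0.5 under CSR in windows
that scale about their centroid. Lower mean CPI means channels sit nearer
the AZ centre.

## The synthetic-data generators

`simulate_csr()` (uniform points by rejection sampling; axis-aligned
rectangles are sampled directly), `simulate_clustered()` (a Thomas-style
parent–offspring process conditioned on the window, with ground-truth
parent assignments retained), and `simulate_topography()` with four
channel/vesicle arrangements:

* **random** — channels and vesicle centres independently CSR;
* **perimeter_release** — vesicles docked at the convex hull of a channel
  cluster dilated by `offset_nm` (default 10 nm, the reported
  vesicle–cluster association distance at stellate-cell synapses);
* **one_to_one** — at most one vesicle per channel cluster, each vesicle
  assigned to a distinct cluster;
* **exclusion_zone** — unclustered channels conditioned on lying at least
  `exclusion_radius_nm` (default 50 nm) from every vesicle centre.

`virtual_labeling()` turns ground truth into "observed" particles:
independent Bernoulli detection (`efficiency`), isotropic Gaussian
localisation jitter (`jitter_sd`, default 0 — the linkage error of
antibody + gold is not well constrained, 10 nm is a plausible setting),
Poisson background (`background_rate`, particles/µm²; 0.84/µm² over a
75.5 µm² membrane reproduces the reference extra-AZ background), and
optional antibody-aggregation clumps that emulate the classic artefact of
poorly behaved secondary antibodies. `qc_report()` screens for exactly that
artefact: wrong-face background particles that themselves form DBSCAN
clusters trigger a warning, as do duplicate coordinates and particles
rejected at read time.

Scene defaults are scaled to a typical complete AZ of ~0.1 µm²: ~30
channels in ~3 clusters of ~10 channels (the reference data report 2.6
clusters/AZ of 6.8 particles ≈ 10.6 channels each) and a handful of docked
vesicles of 20 nm radius.

What the generators deliberately do **not** emulate: 3-D membrane
curvature (replicas are treated as planar, as in the source analyses),
fracture-face mislabeling beyond a constant background rate, spatially
inhomogeneous labeling efficiency, and physical hard-core repulsion between
gold particles (a `min_separation` option exists for parent centres only).
Passing tests on these fixtures therefore validate the estimators and the
pipeline plumbing, not the biology of any particular synapse.

## Numerical choices

* **Geometry.** Areas by the shoelace formula (orientation-independent);
  containment by even–odd ray casting with boundary points counted inside
  (tolerance 1e-9 nm), so particles digitised on the AZ outline are kept.
  Polygons are validated simple (non-self-intersecting) at construction.
* **Units.** All internal geometry is in nm; densities are converted to
  particles/µm² only at reporting boundaries (1 µm² = 10⁶ nm²).
* **Isotropic correction.** The circle fraction inside the window is
  evaluated on 180 equally spaced directions; pairs whose circle lies
  entirely inside (distance to boundary ≥ $d_{ij}$) take weight 1 exactly.
  The weight is capped at `n_angles` to keep a stray sliver from exploding
  the estimate.
* **Kernel support.** Only pairs with $d_{ij} \le r_{max} + 4h$ enter the
  kernel sums. Near $r = 0$ part of the kernel mass falls at negative lags;
  this small-r bias affects the observed and simulated patterns equally in
  the paired comparison.
* **SD convention.** The ε rule uses the sample SD (n − 1) of per-particle
  NNDs — per-AZ counts are small, so the sample convention is the
  conservative, conventional choice.
* **Epsilon scope.** ε is resolved per AZ by default (the rule follows the
  per-AZ NND analysis); `pooled_epsilon()` offers a dataset-wide value for
  cross-AZ comparability.
* **Degenerate inputs.** Duplicate coordinates are kept but flagged;
  all-coincident patterns are an error for $g(r)$; clusters of ≤ 2 points
  or collinear sets get hull area 0 rather than an error; a particle at the
  window centroid has CPI 0 without division.
* **Seeding.** Every generator accepts an integer seed and restores the
  caller's RNG state. Dataset-level analyses expand one master seed into
  per-AZ substreams keyed on (seed, region_id) via `substream_seed()`, so
  results are independent of dataset ordering and any single AZ can be
  replayed in isolation (the pipeline logs each AZ's substream seed).

## Validation experiments and their problem sizes

The test suite validates each estimator against an independent oracle or a
closed form, at sizes chosen to balance statistical resolution against a
short default run:

* CSR mean NND vs the Poisson closed form $1/(2\sqrt{\lambda})$ (= 50 nm at
  n = 100 in 1 µm²): 500 seeds; the small positive edge-effect bias is
  expected and asserted to stay within 10%.
* $g(r)$ under CSR: n = 2000 in a 2 × 2 µm window, mean over
  r ∈ [20, 200] nm within [0.9, 1.1]; exact agreement (1e-10) with a
  brute-force kernel pair-sum oracle, and a cross-check against an
  independently published pair-correlation implementation where available.
* DBSCAN vs a brute-force density-reachability oracle (transitive closure
  over the ε-graph of core points): 50 random configurations of ≤ 30
  points, label-partition equality up to renumbering.
* Paired Monte-Carlo test: power on 20 clustered AZs (200 sims/AZ,
  p < 0.05 for both statistics) and level on 200 CSR repetitions
  (rejections within the central ~99.9% binomial band of a 5% test).
* End-to-end efficiency recovery: 200 simulated boutons at the reference
  geometry, |bias| < 0.02 at efficiency 0.64.
* CPI under CSR in a disc: n = 10,000, mean 0.5 ± 0.02.

`scripts/acceptance.R` reruns all of the above from scratch with a caller
seed and writes the resulting numbers as JSON.

## Known limitations

* **The mean NND + 2 SD ε rule fragments tight, pure clusters.** On
  synthetic scenes made only of compact Gaussian clusters (sd ~10 nm), the
  per-AZ NND scale shrinks with cluster density while cluster extent does
  not, so the resolved ε under-links cluster fringes and DBSCAN can split
  true clusters. Real AZ patterns contain dispersed particles that
  inflate the NND spread, where the rule behaves better. The package's
  parameter-recovery experiment therefore uses the fixed 100-nm radius
  parameterization for cluster counting on such scenes; both rules are
  exposed and the choice is explicit in `cluster_config()`.
* The isotropic correction is numeric (1° angular resolution), not an
  exact circular-arc/polygon intersection; the residual weight error is
  well below the estimator's sampling noise at the sizes used here.
* CPI requires windows star-shaped about their centroid and its CSR mean of
  0.5 is exact only for windows that scale about the centroid; for strongly
  irregular AZ outlines the CSR mean can deviate slightly — the Monte-Carlo
  route (CSR simulation in the same window) is the robust comparison.
* No cross-type (channel–vesicle) second-order statistics and no fitting of
  topography models to data: the topography generators produce scenes for
  power and recovery studies only.
* Replicas are treated as flat; no correction for membrane curvature or
  fracture-plane distortion is attempted.
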