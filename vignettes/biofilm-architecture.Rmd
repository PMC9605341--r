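---
title: "Quantifying and simulating early biofilm architecture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and simulating early biofilm architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Surface-attached bacterial microcolonies grow from a single founder cell to
a few thousand cells within an extracellular matrix. At that stage the
colony's three-dimensional architecture — how densely cells pack, how they
orient, how the colony envelope is shaped — varies widely between species
and mutants, yet is believed to be governed by a small number of mechanical
control parameters: the cell aspect ratio and the local cell number
density. `biofilmarch` provides the three ingredients needed to study this
quantitatively from segmented single-cell data:

1. **Feature extraction** — per-cell architectural properties and emergent
   whole-colony summaries computed from tables of cell centroids,
   orientations and dimensions.
2. **Distributional statistics** — a compact Chebyshev-coefficient
   representation of each property's distribution and a dissimilarity (cd)
   between biofilms that upper-bounds the cumulative L1 distance between
   their property distributions, plus redundancy reduction and a PCA
   embedding whose first component is the biofilm architecture index (BAI).
3. **A mechanistic model** — an overdamped agent-based simulation of
   growing, dividing rod-shaped cells on a substrate, and a parameter-scan
   fitting loop that matches simulations to target biofilms by minimal cd.

A fast statistical generator of non-overlapping cell packings stands in for
the microscopy/segmentation stage, so the entire pipeline can be exercised
and tested without imaging data.

## Input data model

A biofilm sample is a table with one row per segmented cell: integer `id`,
centroid `x, y, z` (micrometres, substrate at z = 0, colony in z >= 0), a
unit orientation vector `nx, ny, nz` (nematic: n and -n are the same
orientation), pole-to-pole `length` and `width` (micrometres,
`length >= width > 0`), plus optional extra scalar columns carried through
from segmentation. Metadata (group label, condition, replicate, provenance)
live in a JSON sidecar next to the CSV. Floats are serialised at 12
significant digits so a write/read round trip reproduces every field to
well below 1e-9.

## Per-cell and emergent properties

The standard property set is: aspect ratio (length/width), length, width,
local number density (count of other cells with centroids within a 2 um
radius — the neighbourhood used throughout), local nematic order, distance
to the substrate (centroid height) and distance to the colony centroid.
Segmentation-derived voxel properties (e.g. convexity) are accepted as
pass-through extras but never computed here.

The local nematic order of cell i is the largest eigenvalue of the
orientational order tensor Q = (3<nn^T> - I)/2 averaged over the focal cell
and its neighbours within the radius (de Gennes convention: S = 1 perfectly
aligned, 0 isotropic; the analytic range is [-1/2, 1] and values are never
clipped in statistics). Including the focal cell stabilises S for isolated
cells (a lone cell has S = 1); excluding the focal cell from its own
neighbour *count* matches the plain meaning of "number of neighbours".

Two emergent summaries characterise a whole colony: the population variance
of the per-cell nematic order, and the surface area per volume of the
colony. The latter is computed on the 3D convex hull of the cell centroids
(own incremental-hull implementation): early microcolonies are compact
domes for which the hull is a faithful envelope proxy, and for a ball of
radius R the ratio converges to the closed form 3/R. Concave envelopes
(e.g. late-stage fingering colonies) would need an alpha-shape and are
outside this package's regime.

## Chebyshev representation and the cd dissimilarity

Summary statistics such as means and variances discard the shape of a
property's distribution. Instead, each distribution is smoothed with a
Gaussian KDE and represented by the degree-20 Chebyshev interpolant of the
KDE through the 21 Chebyshev–Gauss–Lobatto nodes of a canonical interval
[-1, 1]:

* **Shared supports.** Coefficients are only comparable on a common domain,
  so each property's support is pooled over the whole collection (the
  [0.005, 0.995] quantile range widened by 5% a side); values outside it
  are clamped to the edges, preserving sample size. A constant-valued
  property has no usable support and is rejected (or dropped with a
  warning in the pipeline).
* **Bandwidth.** Silverman's rule on the canonical-coordinate data, floored
  at 0.01 canonical units, and additionally at half the minimal gap between
  distinct values: integer-valued properties (neighbour counts) otherwise
  yield comb-shaped KDEs whose coefficients encode the value grid rather
  than the distribution. A Gaussian of half-gap width leaves under 1%
  ripple.
* **Determinism.** The fit involves no randomness: identical inputs give
  bit-identical coefficients.

A biofilm with p properties is thus compressed to a 21 x p coefficient
matrix — 273 numbers for p = 13 — independent of its cell count.

Two representations on the same support are compared by

    cd = 2 * sum_k | c_k^A - c_k^B |

Since |T_k(x)| <= 1 and the canonical interval has length 2, cd bounds the
L1 distance between the reconstructed densities from above; summing over
properties bounds the cumulative L1 distance between the two collections
of distributions. cd is a weighted L1 metric on coefficient space, so
non-negativity, identity, symmetry and the triangle inequality hold
exactly. The package asserts the bound numerically against fine-grid
quadrature in its test suite. The same construction applied to one
property's coefficients across all biofilms (after z-normalising each
coefficient index) gives a property-by-property dissimilarity used for
redundancy reduction: average-linkage clustering with the cluster number
chosen by the mean silhouette coefficient (ties to the smallest k), each
cluster represented by its medoid. Exactly duplicated properties merge at
dissimilarity zero.

## PCA, the BAI, and the phase diagram

The retained properties' coefficient matrices are flattened to one vector
per biofilm, centred, and decomposed by PCA. The dimensions are *not*
rescaled to unit variance: canonical-interval density coefficients are
already unit-free and mutually comparable (every represented density
integrates to one over [-1, 1]), so the raw coefficient variance measures
how much a property's distribution actually moves across the collection.
Rescaling would promote noise-dominated high-order coefficients to the
same weight as the informative ones; on synthetic collections this
measurably buries the density signal. The preprocessing record (means,
kept dimensions) is stored in the embedding so results are reproducible.

The first principal component score is the biofilm architecture index
(BAI). PCA signs are arbitrary, so the BAI sign is fixed by requiring the
summed PC1 loading of the local-density coefficient block to be
non-negative: denser colonies get larger BAI by construction. The
contribution of a property to the BAI is the sum of squared PC1 loadings
over its coefficient block, normalised to sum to one. Plotting each
biofilm in the mean aspect ratio vs mean local density plane, coloured by
BAI (or by nematic order variance or surface area per volume), gives the
two-control-parameter phase diagram of early architectures.

## The mechanistic model

Cells are rods: for contact purposes the ellipsoidal body is reduced to its
axis segment (length `L - w`) dilated by the width w, and the separation
delta between two cells is the minimal segment–segment distance minus the
mean width (delta < 0 is steric overlap; coincident axes fall back to a
deterministic perpendicular contact normal). Forces are exact negative
gradients of pair and surface potentials:

* **Steric repulsion** (Hertzian): magnitude `k_rep (r_rep - delta)^(3/2)`
  for `delta < r_rep`.
* **Cell–cell adhesion** (the matrix-protein-mediated attraction): a linear
  ramp `f_att (1 - (delta - r_rep)/r_att)` vanishing at
  `r_rep + r_att`, clamped at full strength `f_att` inside the repulsive
  zone. The clamp keeps the total force continuous and gives the
  equilibrium spacing a direct dependence on `f_att`.
* **Surface anchoring**: each cap-sphere centre at height h feels the same
  two laws against the substrate (`k_rep (w/2 - h)^(3/2)` below contact, a
  clamped ramp of strength `f_surf` and range `r_surf` above), so an
  isolated horizontal cell rests at `h* = w/2 - (f_surf/k_rep)^(2/3)`.

These functional forms are this package's own reconstruction: the scanned
quantities are the ranges and strengths, not the force shapes, and any
smooth short-ranged pair of laws with these ranges produces the same
qualitative mechanics.

Dynamics are overdamped: the net force is decomposed along and
perpendicular to the cell axis with drags `zeta_par * L` and
`zeta_par * zeta_ratio * L` (the ratio >= 1 models the matrix polymer
network suppressing transverse motion), and torques rotate the cell
against a drag proportional to `L^3`. Integration is explicit Euler with
an internal stability guard: whenever a displacement would exceed w/10 the
step is subdivided, keeping the integration robust through division
events. Cells elongate exponentially (`length *= exp(gamma dt)`) and divide
at a lognormally noised threshold around `L_div` into two daughters of
half the mother length placed end-to-end along the mother axis — the
daughters' spherocylinders exactly tile the mother, so siblings are born
in contact and a newborn takes `ln 2 / gamma` to regrow to the division
length, making the population doubling time exactly `ln 2 / gamma` (30
minutes at the default elongation rate). Daughter orientations get a small
random tilt and independent fresh thresholds (whether real daughters
inherit growth phase is unknown; independence is the simpler choice).

All randomness (founder orientation, division noise, tilts) is drawn from
R's RNG in a fixed documented order, so a run is bit-reproducible from its
seed. Neighbour search uses a uniform spatial grid with bins at least as
large as the maximal interaction reach, keeping 2,000-cell colonies
tractable on one CPU (about 20 s).

### Default parameters

| parameter | default | meaning |
|---|---|---|
| `L_div` | 3.5 um | division length (scanned) |
| `r_rep` | 0.15 um | repulsion range beyond contact (scanned) |
| `r_att` | 0.5 um | adhesion shell width (scanned) |
| `f_att` | 5 | adhesion strength (scanned) |
| `k_rep` | 5e3 | Hertzian stiffness |
| `width` | 0.8 um | cell width |
| `gamma` | ln 2 / 0.5 h | elongation rate (30-min doubling) |
| `f_surf`, `r_surf` | 20, 0.2 um | surface anchoring |
| `zeta_ratio` | 5 | transverse/axial friction |
| `dt` | 2e-4 h | timestep |

The non-scanned defaults are calibrated only against the package's own
invariant suite (monotone density response to adhesion, monotone aspect
ratio response to division length, surface attachment, stable
integration); they are not a fit to any experimental dataset. With the
defaults, the mean local density at 500 cells rises monotonically from
about 6.2 to 8.6 neighbours as `f_att` goes from 0 to 80, and the mean
aspect ratio tracks `L_div` almost linearly.

## Parameter fitting

`scan_grid()`/`run_scan()` enumerate the Cartesian grid over the four
scanned parameters times seeds, writing standard cell tables plus a
resumable manifest (failures are recorded, completed runs are skipped on
rerun). `best_fit()` pools supports jointly over targets and library —
coefficients are only comparable on a common domain, which also means
library cd values legitimately change when the targets change — and ranks
every library simulation by its mean cd to the target group's replicates
(arithmetic mean, the natural reading of averaging over experimental
replicates; per-replicate fitting is available via a flag). On a 3 x 2
grid (adhesion strengths 0/20/80, division lengths 2.4/3.6 um, 4 seeds
per point) with 500-cell targets in replicate groups of three, the
generating grid point is recovered by minimal cd in 10 of 10 repetitions
of the package's self-consistency experiment.

## The synthetic generator

`generate_packing()` places non-overlapping rods by random sequential
addition around a founder on the substrate: each candidate sits at the
prescribed spacing from a randomly chosen existing cell (heights below
half a width are reflected back above the substrate) and is rejected on
steric overlap, producing a compact dome whose density is controlled by
the spacing. Aspect ratios are lognormal about a median; widths are fixed
at 0.8 um. Three orientation models are available; the default, `"local"`,
lets each new cell inherit its reference neighbour's orientation with
Gaussian tilt noise (0.35 rad default), which creates the locally nematic
domains seen in real rod colonies, produces realistically broad
nematic-order distributions, and lets elongated cells pack densely
(independent isotropic orientations jam below spacing ~1.1 um at aspect
ratio 3.5). Group seeds derive per-sample seeds deterministically, so a
spec list always regenerates the identical collection.

What the generator does *not* emulate: growth lineage correlations, cell
size gradients with depth, matrix heterogeneity, and envelope fluctuations
of real colonies. Passing tests on synthetic collections therefore
demonstrates that the statistical machinery distinguishes the prescribed
density/shape structure — not that real inter-species differences are
fully captured.

### The four-group benchmark construction

The package's phase-diagram checks use a 2 x 2 synthetic design: aspect
ratio medians 2.0 and 3.2 (bracketing the cell-shape mutant range),
spacings 1.0 and 2.1 um (a roughly 2–4x range of realized local density,
like an adhesion-induction scan), five 500-cell biofilms per group. On
this construction the PCA embedding separates the four groups with a label
silhouette around 0.9, PC1 explains about 60% of the variance, and the
top-two BAI contributions are the aspect-ratio and local-density blocks.

## Numerical choices and limitations

* Problem sizes in the tests and acceptance script (500-cell colonies,
  5 seeds per condition, 10 fitting repetitions) are the package's chosen
  desk-scale study conditions; all scale up linearly.
* Reconstructed densities can be slightly negative through truncation;
  they are reported as-is and only compared in L1.
* The silhouette-based cluster search examines k = 2..m-1 and breaks ties
  towards the smallest k; medoid ties break towards input order.
* The cd is a reconstruction of the published dissimilarity up to its
  (unpublished) normalisation: qualitative structure (block patterns,
  orderings, bounds) is reproducible, exact numeric identity with
  published cd values is not guaranteed.
* Degenerate geometry (coplanar centroids) raises an error in the
  surface-area-per-volume computation rather than returning a value.
* The simulator omits external flow, nutrient fields and motility; it is a
  model of mechanically interacting growing rods only, appropriate for
  early microcolonies.
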