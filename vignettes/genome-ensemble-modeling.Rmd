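---
title: "Contact-restrained genome ensembles and nuclear density maps"
author: "pombe3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact-restrained genome ensembles and nuclear density maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pombe3d)
```

## The model

`pombe3d` represents an interphase (G1) fission-yeast genome as three
worm-like polymer chains of spherical granules, each granule 30 nm in
diameter and carrying 3.5 kb of DNA, confined to a spherical nucleus of
radius 1300 nm, excluded from the nucleolus, and tethered in the Rabl
configuration: centromeric granules to a zone around the spindle pole
body (SPB), telomeric granules to the nuclear periphery or the nucleolar
surface.  Population-averaged chromosomal contacts from
proximity-ligation experiments (GCC/Hi-C style pair lists) enter as
attractive restraints.  Because a ligation library mixes contacts from
many cells, no single structure should satisfy all of them: each
structure of an ensemble is restrained by its own random subset of
contact pairs, drawn without replacement with probability proportional to
detection frequency, and any pair never drawn is force-assigned to a
structure so that every captured interaction is present somewhere in the
ensemble.

Each structure is optimized independently by Metropolis Monte Carlo with
simulated annealing.  The energy surface, in units of kT:

* **Bonds** — harmonic, rest length one granule diameter (30 nm),
  `kBond = 2` kT/nm².
* **Bending** — Kratky–Porod term `kappa * (1 - cos theta)` per interior
  granule.  `kappa` equals the persistence length in granule units;
  default 5 granules = 150 nm, an ordinary stiffness for a chromatin
  fiber at this coarse-graining.
* **Excluded volume** — soft-core quadratic penalty below one diameter
  during sampling, backed by a *hard* floor (no non-bonded pair below
  99% of a diameter) enforced by move rejection.
* **Confinement and nucleolar exclusion** — quadratic penalties outside
  the allowed region, likewise backed by hard rejection, so every
  reported structure satisfies them exactly.
* **Tethers** — flat-bottomed harmonic wells: zero energy inside the
  target region (SPB zone radius 300 nm; peripheral shell width 150 nm;
  nucleolar-surface shell width 150 nm), quadratic in the distance to the
  region outside.  The data motivating tethering say *where* loci sit,
  not what force holds them, so the well shape is a package choice.
* **Contact springs** — flat-bottomed: zero inside the rest length
  45 nm (1.5 diameters, "touching"), harmonic beyond with
  `kContact = 0.003` kT/nm².  The flat bottom stops restrained pairs
  from collapsing into each other.

The move set mixes single-granule displacements (max 9 nm, keeping the
hard bond window 0.8–1.2 × rest length satisfiable), crankshaft rotations
of one granule about its neighbour axis, pivots of short chain tails
(≤ 20 granules), and rare rigid chromosome translations.  Cooling is
geometric, `T_k = 2 * 0.85^k` over 30 temperatures with 60 sweeps each.
Because hard constraints are enforced by rejection from a feasible start
(a self-avoiding constrained random walk; anchored granules begin inside
or biased towards their wells), feasibility is an invariant of the run,
not a post-hoc filter.

The *random model* keeps chain connectivity, excluded volume and
confinement but drops tethers and contacts; it is the null against which
the contribution of the contact data is judged.

## Calibrating the subset size

Ensembles built from different contact technologies are made comparable
by fixing the ensemble-mean radius of gyration (Rg, the RMS distance of
granules from their centroid) to half the nuclear radius, 650 nm, and
choosing the per-structure subset fraction that achieves it:
`calibrateFraction()` bisects the fraction (geometrically, since Rg
responds roughly to the logarithm of the restraint count), generating a
20-structure calibration ensemble per candidate and accepting when the
mean Rg is within 5% of target.  More contacts always compact the
genome, so the bracket is checked and a violation reported.

Calibration runs by default *without* tethers: the tethered toy genome
is already more compact than 650 nm on its own, and the quantity being
calibrated is the contact-driven compaction against the confinement-only
baseline.  Tethers are then switched on for the analysis ensembles.

A desk-scale subtlety: with three short chains, the genome Rg is
dominated by how far apart the three chromosome *centroids* sit, so a
single inter-chromosomal spring moves Rg far more than dozens of
intra-chromosomal ones (which merely crumple a chain locally).  The
synthetic contact generator therefore keeps planted inter-chromosomal
(centromere/telomere cluster) pairs rare, and the subset fraction tunes
the *probability* that a structure carries such a spring — which is
exactly how the mean Rg of the ensemble becomes a smooth, monotone
function of the fraction at this scale.  At full genome scale the same
machinery recovers the usual regime where the calibrated fraction is a
sizeable share of the contact list.

## From linear tracks to granule signals

Feature tracks arrive as BED-like records (0-based, half-open — the BED
convention is used for *all* bp coordinates, so nothing is shifted on
read).  Mapping to granules is binary ("is the element present in this
granule?", any overlap counts) or by count (records whose midpoint falls
in the granule; the midpoint rule keeps counts additive across the
partition).  ChIP tracks are first restricted to their top 5% of signals
(`topFractionFilter`), because flooding 3.5 kb granules with every weak
probe hit erases the contrast between enriched zones; the filter keeps
`ceiling(0.05 * N)` records, breaking ties at the threshold by genomic
order so the count is exact.  The filter is applied per track, not per
chromosome.  Replication origins come classified by firing time
(early/late) and efficiency (high/medium/low); each class becomes its own
binary signal.

## Density maps, contours, differences, impact

G1 nuclei are rotationally symmetric about the SPB–nucleolus axis, so a
3D structure projects onto the (z, r) half-plane: z the signed
projection onto the axis (SPB side positive), r the distance from the
axis.  The density of a weighted granule set is evaluated on a 266 × 266
pixel grid covering z ∈ [−R, R], r ∈ [0, R] at pixel centres with an
isotropic 2D Gaussian kernel of width σ = 15 nm (the granule radius),
truncated at 4σ (truncation loses < 0.1% of on-grid mass), summed over
granules and averaged over structures.  Pixel values therefore count
kernel-smoothed granule occurrences per structure; the kernel is
deliberately *unnormalized* so that one granule contributes 1 at its own
position.

Relative density divides the element map pixel-wise by the total
chromatin map plus a small additive regularizer (`Dempf`, default 1.33
in the same density units — about one granule's worth at the periphery),
which tames discretization noise where absolute density is low.  No
2πr Jacobian is applied in the projection: it would cancel in the ratio
anyway, and the relative map is the quantity of interest.

Contours mark localization: `topSignalContour()` takes pixels in
decreasing value order (ties by pixel index, so the greedy prefix is
deterministic) until 15% of the map's total signal is enclosed; the
enclosed share can exceed the target by at most one pixel's share.
Difference maps are percentage-point changes, `100 * (a − b)` — the
percentage-point reading keeps the map antisymmetric and defined where
the reference is zero, which a ratio would not be.

Per-granule impact asks which granules drive a density change between
two ensembles (e.g. wild type vs a methyltransferase deletion): within
the region of interest (pixels ≤ 670 nm from the axis) and restricted to
pixels where the element-level difference has the chosen sign, the
relative density map of each granule alone is differenced between the
ensembles and averaged over those pixels.  Kernel sums are linear in the
weights, so the per-granule maps decompose the total map exactly — a
property the test suite checks to 1e−9.

## Overlap statistics

Linear overlap counts granules flagged by both of two binary signals;
spatial overlap counts shared contour pixels.  Both report the Jaccard
index and the min-normalized overlap (the proportional-area Venn of the
counts is a rendering of these numbers; since both contours enclose the
same signal fraction their Venn circles are drawn equal).  `coincidence`
is the directional statistic |A∩B| / |A| — the natural reading of
"feature A coincides with region B in ≥ 90% of its extent" — and is not
symmetric, which the tests exercise on asymmetric fixtures.

## The synthetic generator

`syntheticConfig()` fixes the desk-scale study conditions: three
chromosomes of 350/280/175 kb (100 + 80 + 50 = 230 granules), interior
centromeres at 40% of each chromosome with 10.5 kb centromeric and
telomeric intervals.  `makeContacts()` emulates a ligation pair list:
760 intra-chromosomal background pairs with distance-decay exponent 1,
negative-binomial detection frequencies (mean 5, size 2), plus planted
centromere–centromere and telomere–telomere pairs (2 + 2, frequency
boosts 2 and 1) carrying the inter-chromosomal clustering signal.
`makeChipTrack()` draws 1000 records of 300 bp (probe-sized) with
log-normal signals; a `peripheral_het` track places records in
pericentromeric (±20 kb) and subtelomeric (30 kb) zones with probability
0.8, a `central_eu` track avoids them.  Signal strength is independent
of position, so with bias 0 the top-signal records are uniform — the
generator plants *placement* structure, not signal structure.
`makeOrigins()` draws class-labelled origins (timing takes precedence):
early ones on the euchromatic arms, late ones subtelomeric, with
probability 0.9.

The compartment-recovery tests use two fixture variants of these
conditions, for the desk-scale reason given in the calibration section:
radial het/eu separation is probed on a *sparse* ligation library
(60 background + 2 + 2 planted pairs) with firmer tethers
(k = 0.2 kT/nm²) and fully biased tracks, because the dense library's
coverage guarantee loads every structure of a small ensemble with enough
springs to ball the toy genome up at the SPB pole, erasing radial
structure that a full-scale ensemble retains; the spatial-versus-linear
overlap comparison, by contrast, uses the dense defaults, where the
shared compartment is realized as a common density region.

What the generator does **not** emulate: restriction-fragment geometry,
ligation noise and spurious junctions, array normalization artifacts,
copy-number and mappability biases, or any coupling between ChIP signal
strength and position.  Passing the planted-structure tests shows the
pipeline recovers compartmentalization it was given under these clean
conditions; it does not validate peak calling or contact-matrix
normalization on real data, which are out of scope.

## Numerical choices and degenerate inputs

* Coordinates: 0-based half-open bp everywhere; granule indices global,
  1-based, consecutive in chromosome order.  The last granule of a
  chromosome may span less than 3.5 kb (ceiling partition).
* Contact aggregation: same-pair records merge by summing frequency;
  self pairs and backbone-adjacent pairs are dropped (the chain already
  connects neighbours).  Subsets are fractions of *distinct pairs*, not
  of read events.
* Weighted sampling without replacement = successive draws with
  renormalization; validated against exact enumeration on small sets.
* Rg tolerance 5% and 20-structure calibration ensembles balance
  calibration cost against the ~25 nm standard error of a 20-structure
  mean at this scale.
* An all-zero density map yields an empty contour with a warning; an
  empty pixel selection in the impact profile yields zeros with a
  warning; a zero-radius nucleolus makes the exclusion vacuous.
* The confinement-only radial law (granule density ∝ r²) holds exactly
  only for unlinked granules; for chains, wall depletion of order the
  chain size bends it.  The sampler's distributional test therefore uses
  a genome of single-granule chromosomes, where uniform-in-sphere is the
  exact equilibrium, and checks the polymer case through the Rg ordering
  (restrained < random) instead.
* Problem sizes in the tests and in `scripts/acceptance.R` — 10–50
  structure ensembles, 230 granules, 20-structure calibration — are the
  package's desk-scale defaults; every size is a function argument and
  scales up unchanged.

## Limitations

The sampler is a G1 snapshot: no replication, cell-cycle dynamics, or
molecular-dynamics realism, and the annealed ensemble is a spectrum of
optimized conformations, not a thermodynamic ensemble at fixed
temperature.  Functional forms for energies are reconstructions —
the underlying experimental literature specifies restraint *sources*
but not potentials — and all constants are exposed in `energyParams()`.
At 230 granules the genome Rg is centroid-dominated (see the calibration
section), so calibrated fractions are not numerically comparable to
full-scale ones, only mechanistically.
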