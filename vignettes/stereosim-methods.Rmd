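---
title: "Design-based stereology on synthetic tissue: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design-based stereology on synthetic tissue: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereosim)
```

## Why simulate stereology

Design-based stereology estimates 3D quantities — total axon length, total
neuron number, mean cell size — from systematically sampled thick sections.
The estimators are unbiased by construction, but a concrete analysis chains
many steps (sectioning, shrinkage, probe placement, counting rules,
stratification, group statistics), and each step has failure modes that are
invisible on real tissue because the truth is unknown. `stereosim` builds
synthetic 3D scenes with *known* ground truth — fiber fields of prescribed
length density, spherical amyloid-type deposits, neuron populations — and
runs the full estimation chain on them, so every estimator can be validated
by parameter recovery. The motivating application is the quantification of
cholinergic and serotonergic afferent loss around amyloid plaques in
transgenic mouse cortex and hippocampus, where fiber density is compared
near versus distant from deposit edges and basal-forebrain neuron numbers
are estimated with the optical fractionator.

## The scene model

**Region.** A `region_box` is an axis-aligned box in micrometers; z is the
cutting axis and must be an integer multiple of the section thickness
(default 40 μm, the usual cryostat setting for free-floating sections).

**Fibers.** Axonal afferents are piecewise-linear polylines. Chains start at
uniform positions, advance in exponentially distributed inter-vertex steps
(mean 10 μm) and turn by a bounded random angle (≤ 30°) at each vertex;
per-fiber length is exponential with mean 250 μm. Orientation models:
`isotropic`, `parallel-<axis>` (straight fibers along one axis — the
worst case for orientation-sensitive probes), and `mixed`. Generation
continues until the total length equals `target_Lv × volume` *exactly*
(the final segment is trimmed), so the scene's length density is a known
constant, not an estimate.

A detail that matters: chains wrap around the box periodically (a torus)
rather than stopping at the boundary, and an interrupted segment continues
across the seam with the *same* direction. Either killing chains at the
faces or re-drawing the direction at the seam makes fibers linger near the
boundary and measurably distorts the density profile (several percent
within a few micrometers of the faces); with the periodic rule the process
is translation-invariant and the realized density is flat to well under 1%,
which is what makes the probe estimators exactly unbiased in expectation.

**Plaques.** Compact deposits are spheres (center, radius) placed by
rejection sampling with a minimum edge separation; intersected with a
section they produce the circular profiles seen on 2D micrographs. Radii
default to 7–11 μm (profile diameters ≈ 15–22 μm, typical of compact
deposits at mid pathology); plaque size distributions and burdens are not
measured quantities and are flagged as assumptions in `presets.yaml`.
Infeasible packings fail with an explicit error naming the achieved count.

**Depletion.** Plaque-local toxicity is modeled with three zones measured
from the *nearest deposit edge*: inside a plaque (all fiber length removed
deterministically — compact cores displace neuropil), a near shell
(default ≤ 20 μm) and the distant remainder. Every polyline is split
exactly at zone boundaries and each resulting element survives
independently with probability `survival_near` or `survival_distant`.
Surviving and pre-depletion length per zone are recorded, so the imposed
contrast is part of the scene truth. With no plaques the same operation is
a uniform global thinning.

**Neurons.** Cells are reference points (uniform in the region) carrying a
sphere or triaxial-ellipsoid shape; thinning retains each cell
independently, so a 20% loss preset means exactly that in expectation.

**Sectioning and shrinkage.** Consecutive z-slabs partition the region;
every k-th slab is kept starting from a uniformly random phase
(systematic-uniform-random sampling, required for unbiased totals). Within
a sampled slab, local z is rescaled from the cut thickness (40 μm) to the
mounted thickness (default 20 μm): a uniform axial shrinkage model. The
paper trail for DAB-processed tissue suggests roughly 50% axial collapse;
the value is configurable and recorded in the `section_set` as the factor
`shrink = mounted/cut`.

## The estimators

**Spherical probes ("spaceballs").** A sphere of surface area *s* embedded
in a fiber process of length density `L_V` is crossed on average
`E(Q) = L_V · s/2` times, for *any* orientation distribution — the sphere
is an isotropic probe. The estimator is `L_V = 2 ΣQ / Σs` over all probes,
and total length is `L = L_V × V(reference)`. Probes default to the 10 μm
diameter used at high magnification; placement is a SUR grid in the plane
(inset by one probe radius so the sphere stays inside the region) with the
center depth uniform inside guard margins (default 1 μm).

Counting solves the segment–sphere quadratic per polyline segment; each
root strictly inside the open segment interval counts once. Tangencies
(zero discriminant) count zero; a vertex lying exactly on the surface is
nudged radially outward by 1e-9 μm; zero-length segments are dropped.
Because the mounted section is axially compressed, both the section
geometry and the probe are mapped back to cut (tissue) coordinates before
counting — the probe is a true sphere *in tissue*, which is precisely what
makes the estimator orientation-free; this is where the recorded shrinkage
factor enters the estimate.

**Proximity stratification.** Each probe is classed by the signed distance
`d*` of its *center* from the nearest deposit edge: `d* ≤ 0` within (and
excluded from analysis), `d* ≤ 20 μm` near, else distant. The default
threshold is 20 μm, following the results-section definition (a 10 μm
variant appears elsewhere in the source protocol; both are exercised in
tests and the threshold is a parameter). Two modes exist: `in_plane_2d`
(default) classifies against the plaque's circular profile at the section
mid-plane, mirroring classification on a stained micrograph; `full_3d`
uses true 3D distance. Validation presets use `full_3d`, because the
synthetic truth is 3D and the 2D projection only adds label noise. The
stratified statistic is the mean crossings per probe in each class —
a density surrogate proportional to local length density.

**Optical fractionator.** Total neuron number is estimated as
`N = ΣQ⁻ / (ssf · asf · hsf)` with section sampling fraction `1/k`, area
fraction `frame/grid`, and thickness fraction `dissector/mounted`. The
counting frame applies the unbiased rule: a cell's reference point counts
if it is inside the frame or on the top/right inclusion edges, never on
the left/bottom forbidden edges or their extensions, and only within the
dissector z-window `[guard, guard + height)` of the mounted section.
Defaults are the classical design: 100×100 μm frame, 200×200 μm grid,
10 μm dissector, 1 μm guard, every 6th section. The reference point is the
cell centroid (well-defined for synthetic ellipsoids; configurable in
principle, and the estimator only requires it to be unique).

**Nucleator.** Cell size is estimated from rays cast from the reference
point: volume `V = (4π/3)·mean(l³)` and profile area `A = π·mean(l²)`.
Rays are drawn in vertical planes (vertical axis = cutting axis) with
sine-weighted colatitude, which makes the directions isotropic in 3D; on a
centered sphere every ray has `l = r` and the estimate is exact with zero
variance, which the tests assert. The default of 6 rays per cell trades
per-cell variance against work, as in common practice; the dense-ray limit
(2×10⁵ rays) is used as the oracle in tests.

**Group statistics.** Tables are tidy data frames (subject × region ×
proximity class). Densities are normalized to the age- and region-matched
non-transgenic control group's *overall* mean (100%), with an optional
age-pooling switch — the source protocol does not state which was used.
One- and two-way fixed-effects ANOVA use type-II sums of squares via
linear-model comparisons (reducing to the textbook decomposition when
balanced); degenerate all-equal data report F = 0, p = 1 rather than 0/0.
Post-hoc options are Tukey's HSD (default, matching the reported figure
captions), Newman–Keuls (span-based studentized range, constrained so a
pair is never more significant than an ordered range containing it) and
Fisher's LSD; for every pair `p(LSD) ≤ p(SNK) ≤ p(Tukey)`. Significance
tiers A/B/C/D correspond to p < 0.05/0.01/0.001/0.0001.

## Scenario presets

`inst/extdata/presets.yaml` encodes the study conditions used for
validation: per-region near-zone survival at 12 months (DG 0.40, Cg 0.55,
S1BF/CA1 0.75 — i.e. imposed near-vs-distant reductions of 60/45/25%),
a uniform 0.50 survival for the monoaminergic-type global loss, a 0.60
global survival for the 18-month cortical scenario, a null preset with
equal survival in both zones, and a neuron preset with a 0.20 loss
fraction under the printed fractionator design. Groups default to 6
subjects (7 at 18 months; 4 per group for neuron counts). Scene geometry
for afferent presets is a 200×200×80 μm region (two 40 μm sections, every
2nd sampled, so one section per subject) with 500 probes per subject —
sizes chosen so a full 20-replicate recovery run completes in minutes on
one core while each stratum still collects hundreds of probes.

## What passing tests do and do not show

The generator emulates thick sections, SUR sampling, axial shrinkage,
anisotropy, plaque-local depletion and neuron thinning. It does **not**
emulate staining chemistry, optics (PSF, light scatter), dystrophic
neurite morphology, vascular or laminar structure, observer
segmentation error, or non-uniform shrinkage. Parameter recovery here
therefore validates the *estimators and their implementation*, not the
histology upstream of them.

One genuine measurement property is worth spelling out. The probe is a
10 μm sphere, but proximity classes are assigned from its center against
20 μm zones. A near-classified probe therefore samples tissue on both
sides of its zone: probes at 0–5 μm from the edge dip into the empty
deposit core, and probes at 15–20 μm pick up undepleted distant tissue;
moreover the near stratum is volume-weighted toward its outer shell
(weight ≈ (R+d)²). The net effect is a smeared, attenuated version of the
imposed contrast: an imposed 60% near-vs-distant reduction is *measured*
as roughly 53–55%, and an imposed 45% as roughly 40–42%, essentially
independent of plaque radius over the 7–25 μm range. The package's tests
validate the stratified means against an independent surface-integration
oracle that predicts exactly this smeared expectation; the recovery
scenarios report the measured (attenuated) values. Real micrograph-based
analyses with the same probe and threshold are subject to the same
geometric smearing, so measured near-vs-distant percentages should be
read as conservative lower bounds on the underlying depletion contrast.

## Numerical choices

* Zone splitting and section clipping reuse one segment–sphere /
  segment–slab kernel; length is conserved to 1e-9 relative throughout.
* Ties: vertices exactly on a probe surface are perturbed radially
  outward by 1e-9 μm; tangent contacts count zero crossings; half-open
  slabs `[z0, z0+t)` and half-open counting frames `(0, w] × (0, h]`
  guarantee each point belongs to exactly one section and one frame.
* Scene JSON is written at 17 significant digits, so a write/read round
  trip reproduces geometry bit-exactly.
* Every generator is a pure function of (parameters, seed); one master
  seed spawns per-stage child seeds (`child_seeds`), so each pipeline
  stage is independently reproducible, and all seeds stay below 2³¹.
* Empty strata yield flagged `NA`, never silent zeros; all-`within`
  probe sets, missing control strata, infeasible packings and probes that
  do not fit the mounted section raise explicit errors.

## Known limitations

* The near/distant contrast is attenuated by probe-footprint smearing as
  described above; no correction is applied because the surrogate
  (crossings per probe) is the quantity reported in the motivating
  analyses.
* Burden bookkeeping ignores the sliver of plaque volume protruding
  beyond the region boundary (centers are inside; spheres may poke out).
* Probe-level significance tests on crossing counts are anticonservative:
  neighbouring probes sample the same fibers, and near-classified probes
  cluster around plaques, so two-sample t-tests at the probe level show
  7–10% empirical size at α = 0.05 (a conditional binomial test is worse
  still, since the counts are overdispersed). Inference should aggregate
  to the subject level first — the package's null-size validation runs
  groups of synthetic subjects and applies a paired t-test to per-subject
  near/distant means, which restores nominal size. This mirrors how
  animal-level analyses are done in practice.
* The fractionator assumes sections are complete and the mounted
  thickness uniform; lost caps or variable compression are not modeled.
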