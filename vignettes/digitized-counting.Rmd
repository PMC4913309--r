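---
title: "Digitized spot counting and drug-insensitivity scoring: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digitized spot counting and drug-insensitivity scoring: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qdcount)
```

## The measurement problem

Signaling proteins — phosphoproteins especially — are often present at a
few hundred copies or fewer per cell, and kinase-inhibitor treatment
suppresses them further. Conventional single-cell quantitation sums a
cell's diffuse fluorescence over its volume, which folds cellular
autofluorescence and other broad sources into the same number as the
specific label. When each labeled protein complex instead carries a
bright, discrete reporter (a quantum dot), the per-cell level can be
*digitized*: the measurement becomes the integer number of discrete spots
in the cell's z-stack. Autofluorescence is smooth and does not produce
spots, so the digitized readout rides on a much lower noise floor.

`qdcount` implements that pipeline — segmentation, spot detection,
sub-pixel localization, slice linking, aggregate rejection, per-cell
counting — alongside the diffuse-fluorescence comparator and the
population-level scoring used to rank drugs by how completely they
suppress signaling. A synthetic scene generator with full ground truth
makes every stage testable.

## The insensitivity index

For untreated per-cell measurements $X = \{x_1,\dots,x_M\}$ and treated
measurements $Y = \{y_1,\dots,y_N\}$ the **index of drug insensitivity**
is

$$\mathrm{index}(X, Y) \;=\; \frac{1}{MN} \sum_{i=1}^{M} \sum_{j=1}^{N}
\bigl[\,\delta(x_i < y_j) + 0.5\,\delta(x_i = y_j)\,\bigr],$$

the probability that a random treated cell measures at least as high as a
random untreated cell, with ties split evenly (the common-language effect
size of the Mann–Whitney statistic: $U = MN \cdot \mathrm{index}$). It is
distribution-free and threshold-free. An index of 0.5 means the treated
population is indistinguishable from untreated (complete insensitivity);
values near 0 mean essentially every treated cell fell below every
untreated cell (complete inhibition). `index_of_insensitivity()` computes
it via midranks in $O((M{+}N)\log(M{+}N))$, exactly equal to the double
sum — midranks carry the $0.5\,\delta(x=y)$ tie term without
approximation.

`ranksum_test()` attaches a p-value for the hypothesis that both
populations share one distribution: exact enumeration of the $U$ null
distribution when $MN \le 64$ with no ties, otherwise a normal
approximation with tie-corrected variance and a continuity correction.
Both tails are available; the default is two-sided, with
`"treated_lower"` for the directional question "did the drug lower the
signal". Across a drug panel the p-values are adjusted by step-down
Holm–Šidák (`adjust_pvalues()`); Holm and Bonferroni are offered for
users who prefer them. The panel (all drugs tested against one
phospho-target in one run) is the adjustment family.

Two companion summaries mirror common practice: `mean_phosphoresponse()`,
the treated-minus-untreated mean shift in units of the untreated sample's
standard deviation ($M-1$ denominator), and `signal_to_noise()`, the
ratio of mean signal to the mean of an isotype control, which defines the
assay's noise floor.

## The counting pipeline and its assumptions

**Segmentation** (`segment_cells()`) is deliberately plain: a global
threshold (Otsu by default, absolute override available) on a reference
image — typically a z-projection via `make_reference()` — followed by
8-connected component labeling. The default reference is the *sum*
projection: summing averages noise away and preserves the contrast of
dim cells, whereas a max projection over a deep stack accumulates noise
maxima and can trim the dimmest cells (measured on synthetic scenes as a
mean intersection-over-union of 0.95 for sum vs 0.78 for max against
ground-truth masks). Components below `min_area` are debris,
above `max_area` are cell aggregates; both are excluded rather than
split, and border-touching components are excluded by default because
partial cells bias counts low. Purity of retained cells matters more
than recall here: a missed cell costs sample size, a wrong region
corrupts measurements. Areas are in pixels; at the default 160 nm pixel
size the default bounds 300–8000 px² correspond to roughly 8–200 µm².

**Candidate detection** (`detect_candidates()`) band-passes each slice
with a difference of Gaussians (σ 1.0 and 2.5 px around the ~1.1 px PSF)
and keeps strict 3×3 local maxima above a per-slice robust threshold,
median + k·1.4826·MAD of the filtered slice. The median/MAD pair is
insensitive to the bright tail the spots themselves create. The default
k = 8.5 is higher than the 4–5 a Gaussian intuition suggests, for a
specific reason: the slice-wide MAD is dominated by the quiet
extracellular background, while shot noise *inside* cells (autofluorescence
photons) is substantially larger, so the threshold must clear the
in-cell noise, not the field-wide estimate. k = 8.5 was validated on
synthetic scenes: candidate recall 0.99 at peak S/N 10, at most 2
spurious spots per cell on emitter-free scenes, and ~3% median per-cell
count error under the default conditions below. A small absolute floor
(`candidate_floor`, 1 count) guards the threshold on noiseless or
near-noiseless data, where the MAD collapses to zero and sub-quantization
filter ripple would otherwise count as candidates.

**Sub-pixel localization** (`localize_radial_symmetry()`) uses
gradient-based radial symmetry: intensity gradients at the midpoints of
2×2 pixel blocks (from the two diagonal differences, 3×3 mean-smoothed)
each define a line through the midpoint along the gradient direction; for
a radially symmetric spot every such line passes through the center, so
the center is recovered as the weighted least-squares point minimizing
squared point-to-line distances. Weights are the squared gradient
magnitude divided by the midpoint's distance to the gradient-magnitude
centroid, which suppresses far-field noise. The method needs no PSF
model, no initial guess and no iteration, is exact in the noiseless
limit, and reaches ~0.1 px RMS per axis at peak S/N 5 — comfortably
sub-pixel for counting purposes. Localization runs on the 2D patch at a
spot's brightest slice only; axial position is reported as that slice
index. Counting needs identity, not axial super-resolution.

**Slice linking** (`link_across_slices()`): one emitter's PSF spans
several 275–300 nm slices, so per-slice candidates are collapsed by
greedy linking in descending intensity (ties broken by (z, y, x) for
determinism). A seed candidate absorbs the nearest unused candidate
within `link_radius_xy` (1.5 px) in each neighboring slice, walking
contiguously in z and bridging at most `link_max_gap` (1) missing
slices. Greedy linking is deterministic and adequate at counting
densities; global assignment would add cost without changing counts
except in pathological near-coincidences that are unresolvable anyway.
The 1.5 px radius is a compromise measured on synthetic scenes: large
enough that localization jitter never splits one emitter, small enough
to keep accidental merges of distinct emitters rare at ~100 spots/cell.

**Aggregate rejection** (`classify_aggregates()`): the modal spot
intensity (kernel density peak) estimates single-complex brightness;
spots brighter than `aggregate_intensity_factor` (3) times the mode are
classed aggregates and excluded from counts by default — counting
targets discrete, non-aggregated complexes, and an aggregate of unknown
multiplicity is better dropped than guessed. `count_aggregates = "one"`
is available for the defensible alternative. With fewer than
`min_spots_for_mode` (20) spots the mode is unreliable and all spots
pass with a warning.

**Per-cell counting** (`count_spots_per_cell()`) assigns each spot to the
retained region containing its nearest pixel; spots outside every
retained region are orphans, reported but never counted. Conservation —
counts + orphans = countable detections — holds exactly and is asserted
in the tests.

## The diffuse-fluorescence comparator

`global_background()` implements the column-minimum estimator: per
column of the field, the minimum over rows; the background is the mean of
the column minima. `diffuse_per_cell()` sums a cell's footprint over all
slices and subtracts background × area per slice. Two choices are
deliberate. First, the background is estimated *per slice* rather than
once per stack — "each image" is most literally each slice, and
z-dependent haze is then handled; a `"projection"` mode is exposed for
the other reading. Second, negative net values are kept: clipping at
zero would bias exactly the S/N comparison this comparator exists for,
and would break linearity (scaling intensities and backgrounds by *s*
scales the result by *s*, a tested invariant). Note the estimator is
biased low by noise (minima of noisy columns sit below the true
background), so spot-free cells average slightly positive — visible in
the tests as a small per-voxel offset.

## The synthetic generator: what it emulates, what it does not

`simulate_scene()` builds one field of view with full ground truth:
non-overlapping circular cells; per-cell true counts; emitters uniform
over each cell's pixelated footprint at uniform random depth; a
separable 3D Gaussian PSF per emitter; a smooth per-cell diffuse
autofluorescence field; Poisson shot noise on expected photons; Gaussian
read noise; a camera baseline; 16-bit quantization. Defaults state the
intended acquisition regime and were fixed once:

| parameter | default | rationale |
|---|---|---|
| field | 512×512 px, 160 nm/px | typical EMCCD field at high magnification |
| slices | 60 × 300 nm (18 µm) | covers a suspended cell's full depth |
| cell radius | 24–32 px (≈ 8–10 µm diameter) | leukemia-line / mononuclear cell scale |
| PSF σ | 1.1 px lateral, 1.2 slices axial | diffraction-limited red emitter |
| peak photons | 50 | peak S/N ≈ 10 over the in-cell noise floor |
| autofluorescence | 15 photons/px/slice, 40 px scale | moderate diffuse cellular background |
| counts | NB(mean 100, dispersion 5) | overdispersed per-cell molecule counts |
| read noise, baseline | 3, 100 counts | conventional camera settings |

Per-cell counts are negative binomial because overdispersion is the norm
for per-cell molecule counts; the scoring method is deliberately
distribution-free, so nothing downstream depends on this family.
Randomness is organized as one master seed with a derived sub-stream per
cell, so adding a cell never perturbs earlier cells, and identical specs
give bit-identical stacks.

Simplifications to keep in mind when reading test results: the PSF is a
separable Gaussian, not a measured optical PSF; emitters do not blink
(counting operates on z-integrated detections, so blinking is an optical
nuance the pipeline never sees); cells are discs with softened
autofluorescence edges, not irregular cell shapes; there is no
slide-surface fluorescence gradient or debris. Passing tests therefore
demonstrate correctness of the algorithms under controlled optics, not
robustness to every artifact of real acquisitions — segmentation
thresholds and detection parameters still need adjustment on real data,
which is why every tunable lives in `detection_params()` and the
`segment_cells()` arguments.

`simulate_count_populations()` generates the population-level analogue:
untreated counts NB(µ, dispersion); treated counts a mixture in which a
fraction `insensitive_fraction` of cells keeps the untreated mean and
the rest is inhibited to µ(1 − inhibition). Either `inhibition = 0` or
`insensitive_fraction = 1` collapses the mixture to the null exactly.

## Numerical and degenerate-input choices

- **Ties** appear twice: in the index via the exact midrank 0.5 term, and
  in the rank-sum variance via the standard $\sum(t^3-t)$ correction.
  All-tied data yields p = 1 with a warning rather than an error.
- **Exactness boundary**: the exact U enumeration is used when
  $MN \le 64$ and no ties; beyond that the tie-corrected normal
  approximation with continuity correction takes over (it matches
  `wilcox.test`'s approximation to 1e-9 in the tests).
- **Otsu on a flat image** finds nothing (zero regions, not an error);
  `min_area >= max_area` is an error.
- **Rasterization rule** for outlines: a pixel belongs to a cell iff its
  center lies inside or on the polygon boundary, even-odd rule —
  deterministic and checked against an independent point-in-polygon
  oracle. Coordinates are 0-based, (x, y) = (column, row), pixel centers
  at integers.
- **Connectivity** is 8-connected, fixed for determinism (the underlying
  4-connected labeling is upgraded by merging diagonally touching
  labels).
- **Degenerate localization patches** (flat, or singular normal
  equations) raise errors; the linker falls back to the integer pixel
  when a patch would leave the field or localization fails.
- **Placement failure** (too many cells for the field) errors out after a
  bounded number of rejection attempts, naming the constraint.

## Problem sizes in the test suite

The suite exercises full-size default scenes where the claim concerns
the default conditions (count recovery uses the 512×512 × 60-slice,
20-cell, NB(100, 5) scene) and smaller scenes (128–384 px, 8–20 slices)
where the property under test is size-independent, keeping the whole
suite under a minute of simulation time. Monte-Carlo claims use 500–1000
replicates: the null index and type-I calibration use 1000 replicates at
M = N = 100; localization accuracy uses 500 noisy patches.

## Known limitations

- Aggregates are excluded, never split; heavy aggregation will bias
  counts low. The modal-intensity estimate assumes singles dominate.
- Above roughly 150–200 spots per 8–10 µm cell, distinct emitters begin
  to fall within one link radius of each other and counts saturate
  low — the regime where digitized counting itself stops being the right
  readout.
- The column-minimum background is biased low in proportion to noise;
  comparisons should use it consistently on both sides, as
  `diffuse_table()` does.
- Segmentation has no watershed: touching cells become one aggregate and
  are excluded. This is the intended behavior for purity, but dense
  fields lose cells.
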