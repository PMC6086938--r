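---
title: "From multicycle voxels to niches: the models behind codexpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From multicycle voxels to niches: the models behind codexpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

codexpipe processes highly multiplexed fluorescence images of tissue
(CODEX-style multicycle acquisitions) into single-cell tables and spatial
statistics. This vignette explains the models and the numerical choices, in
the order the pipeline applies them, and states what the built-in phantom
suite does and does not establish about real data.

```{r setup, eval = FALSE}
library(codexpipe)
```

## The tissue phantom: what it emulates

Every stage of the pipeline is validated against synthetic tissue phantoms
with complete ground truth (`phantom_spec()`, `make_cell_map()`,
`render_image_stack()`). A phantom is a thin slab (default 9 z-planes,
mirroring a cryosection imaged at 11 planes with ~0.9 µm axial spacing)
densely packed with spherical cells whose nuclei are concentric spheres and
whose membranes are shells of fixed voxel thickness. Cells are placed by
rejection sampling under the constraint that nuclei never overlap, while
membranes may touch — exactly the regime that makes crowded lymphoid tissue
hard to segment. Nearest-center painting resolves overlapping cell spheres
into a clean voxel partition, so the true label mask, the true contact graph
(shared boundary voxel faces) and the true per-cell expression are all known
exactly.

Marker intensities live on the membrane shell, scaled by the cell's
type-specific expression profile; the default panel mimics the marker logic
of splenic tissue (mutually exclusive B220 / CD90 / F4/80 over shared CD45).
Optional compartments partition the xy plane into named regions with their
own type frequencies, emulating anatomical subdivisions such as follicles
versus red pulp.

What the phantom deliberately does **not** emulate: realistic optics (no
PSF; the optional blur is a per-z-plane Gaussian, with no axial component),
autofluorescence spectra, tile boundaries, or non-spherical morphology.
Passing the phantom suite therefore demonstrates the *algorithms* are
correct and calibrated under known truth; it does not certify performance on
any particular real acquisition.

Two generator conditions are fixed once for the whole suite:

* the *dense phantom* (200 cells of radius 4–5 voxels on a 192×192×9 slab)
  is the standard segmentation benchmark;
* *well-separated niche archetypes* put 90% of the ring on one dominant
  type, the purity of real lymphoid compartments (a follicular ring is
  roughly 90% B cells), with first-tier ring sizes of 5–7 — the typical
  degree of a 2-D Delaunay node.

## Drift alignment

Cycles are aligned to the first cycle by 3-D phase correlation of the
reference membrane channel, which is present in every cycle. The integer
peak of the correlation within `max_shift` is the estimated displacement;
subvoxel refinement (parabolic fit through the peak) is available but off by
default, since integer recovery is exact on translated stacks and the
downstream quantification operates on voxels anyway. A flat (zero-variance)
reference channel is an error, not a zero: it means the field or the channel
assignment is wrong.

## Segmentation of crowded tissue

The core difficulty in lymphoid tissue is that nuclei nearly touch and
membranes do touch. The pipeline builds a *contrast image*: both channels
are min-max scaled to [0, 1] and the inverted membrane is multiplied
voxel-wise with the nuclear channel. Membrane ridges between adjacent cells
become valleys, so each nucleus sits on its own peak. Scaling before the
multiply keeps the construction scale-free; inversion as (max − value) is
bounded and needs no tuning.

The contrast image is then low-pass filtered with a hard spherical mask in
frequency space (per-axis scaled, as a fraction of each axis' Nyquist
frequency; DC always kept, so the mean is preserved). The cutoff should
match the nucleus scale: a cutoff of `1/r` (r = expected nucleus radius in
voxels) smooths each nuclear plateau into a single dome without merging
neighboring domes. The op-level default of 0.15 corresponds to a ~13-voxel
smoothing scale, appropriate for nuclei imaged at ~188 nm/pixel; phantom-
scale cells (nucleus radius ~2.2 voxels) need ~0.45, which is what the
pipeline wrapper derives from the phantom spec. A hard (not smooth) mask was
chosen for exact idempotence and analyzable behavior on pure tones; ringing
is immaterial because only seed detection and flooding consume the result.

Seeds are local maxima (26-connectivity) of the filtered contrast above half
the Otsu threshold, thinned greedily so no two seeds are closer than
`min_distance` (≈ one cell radius). The watershed then floods the *inverted*
contrast from those seeds, restricted to a foreground mask (Otsu on the sum
of the scaled nuclear and membrane channels, closed with radius 1 to fill
the thin cytoplasmic gap between nucleus and membrane). Flooding the
inverted contrast — i.e., descending the contrast gradient from each nuclear
peak — makes opposing basins collide in the membrane valleys, which is where
the cell boundary belongs. The alternative relief, the gradient-magnitude
surface, fails structurally in dense tissue: the cytoplasm/membrane network
has near-zero gradient and is *connected across cells*, so the first basin
to breach its nucleus-edge gradient wall floods the entire network. On the
dense phantom this manifests as a few giant regions and many slivers; the
inverted-contrast relief segments the same phantom perfectly.

Ties during flooding are broken by insertion order, which is itself
deterministic (seeds labeled in ascending x, y, z scan order), so the same
stack and parameters always give the identical mask. Regions smaller than
`min_size` are merged into the touching neighbor with the longest shared
boundary, or dropped if isolated.

Quantification is deliberately plain: per cell, the intensity-unweighted
centroid, the size in voxels, and for every (cycle, channel) the summed
intensity inside the cell divided by its size. Blank-cycle channels are
quantified identically and tagged — they power the cleanup gate. Ring
background quantification (mean inside minus mean in an external
morphological ring that excludes other cells) is provided for
dissociated-cell style data where local background subtraction is the
appropriate estimator.

## Positional spillover compensation

Touching cells contaminate each other's membrane signal. The model: a fixed
fraction *c* of the signal a cell presents on a stretch of membrane leaks to
the neighbor across it, so with b_ij the shared boundary faces and B_j the
total boundary faces of cell j,

S_ij = c · b_ij / B_j (i ≠ j),  S_jj = 1 − c · Σ b_ij / B_j.

Columns sum to 1 exactly — the forward model conserves each marker's total —
and the matrix is strictly diagonally dominant, hence invertible, for any
c < 0.5. Compensation multiplies the raw intensity vectors by S⁻¹ (sparse
solve; the matrix is banded because most cells touch few others). The same
constructor builds the matrix for the phantom's forward spill and for
compensation, so inverse-recovers-truth holds by construction and is tested
to 10⁻⁶ relative error. Negative compensated values (possible under shot
noise) are clamped to zero and flagged rather than re-normalized: the
pre-clamp solution is exactly conserving, and re-normalization would smear
one cell's noise over its neighbors. The boundary census counts voxel faces
(6-connectivity), including faces to background and to the volume edge, so
B_j is the cell's full membrane area and c stays interpretable as "fraction
of membrane signal facing this neighbor that leaks".

The paper-scale observable reproduced here is the roughly two-fold reduction
of spurious double positives for mutually exclusive lineage-marker pairs:
under Poisson noise on the dense adjacency phantom, compensation cuts the
double-positive fraction (both markers above 5% of their positive level) by
at least 2×.

The spill coefficient is a single global constant (default 0.3,
configurable); per-pair estimation from the data is intentionally out of
scope since the shared-boundary fraction already carries the geometry.

## Cleanup gating

Three sequential gates remove debris, doublets and autofluorescent objects:
(1) nuclear stain density (the quantified nuclear value is already
signal/size) within range AND cycle-to-cycle profile homogeneity
(var/mean² of per-cycle totals) below threshold; (2) every blank-cycle
channel below `blank_max`; (3) cell size within range. Gates are applied in
order and the report counts removals per gate, so the order-dependence is
explicit. Thresholds are plain numbers in a `gate_config()`; `default_gates()`
derives them from a trusted table's percentiles ([1st, 99th] by default,
configurable — gates this tight by construction remove ~2–4% of genuine
cells, which is the intended strictness for real data but worth remembering
when reading the gate report).

## Interaction statistics on the Delaunay graph

First-tier neighbors are edges of the 2-D Delaunay triangulation of cell
centroids, pruned at 3× the median edge length (default) so links across
empty space do not count as contacts. N_AB counts edges whose endpoint types
are {A, B}, homotypic edges once.

The observed co-occurrence frequency is the Beta mean N_AB / E (shape
N_AB, E − N_AB). For the expected frequency two conventions are offered,
because the natural-language definition — the product of the "total
frequencies of edges incident to each type" — admits both:

* **incident** (the package's op-level default, matching the documented
  worked example): f_A = fraction of edges with ≥1 endpoint of type A,
  expected = f_A·f_B for every pair. This form over-counts shared edges;
  on a *randomly labeled* graph its log-odds sit below zero (≈ log 2/(2−p)²
  heterotypic and ≈ −1 homotypic), a type-frequency-dependent offset.
* **mixing** (the default wherever significance is computed): f_A = the
  half-edge (degree) fraction, expected = 2·f_A·f_B heterotypic and f_A²
  homotypic — the co-occurrence probability under random mixing. Its null
  is centered on zero, which is the property the binomial test needs: the
  lower-tail p-value P(X ≤ N_AB), X ~ Binomial(E, expected), is only
  calibrated if `expected` is the genuine null probability.

The permutation suite quantifies this: over 1000 label permutations of a
2000-cell phantom the mixing-convention per-pair mean log-odds is zero to
within Monte-Carlo resolution (the homotypic diagonal shows the expected
O(1/E) Jensen bias of a log of a binomial ratio, visible at exactly this
resolution) and the dual-threshold significance rule (BH q < 0.05 avoidance,
q > 0.95 attraction, on lower-tail p-values) fires on well under 7% of pairs
per tail.

Binomial p-values are exact (term summation) up to E = 10⁴ edges; above
that, a continuity-corrected normal approximation with a first-order
Edgeworth (skewness) term keeps the error under 10⁻³ at the switchover.
Zero-count pairs carry a −∞ log-odds sentinel and are excluded from
downstream regressions; a pseudocount is available but defaults to 0.

Cross-condition work uses per-sample counts normalized to each sample's
total edges, compared pair-wise with the pooled-variance two-sample t-test
(Welch via argument), BH-corrected across pairs. The χ statistic —
√Σ z² with z-scores taken against the control samples' element-wise mean and
SD — applies identically to count matrices and log-odds matrices, which is
how "counts changed more than mixing propensities" is made quantitative.
`interaction_change_summary()` reports, per pair, the change in counts,
log-odds and summed incident frequencies, plus the OLS R² of the two
co-distributions; frequency-driven rewiring shows up as r²(freq) ≫ r²(odds).

A structural note on planting attractions: a target log-odds is only
feasible if the implied A–B edge frequency e^t·2f_Af_B stays below
2·min(f_A, f_B) (each A–B edge consumes one half-edge of each type), so +1
targets need the attracted types to be minorities. The label-swap annealer
(swaps preserve type frequencies) reaches ≈0.85–0.88 against a +1 target at
2000 cells, within the ±0.15 planting tolerance and comfortably detected.

## i-niches

The i-niche of an index cell is its ring of first-tier Delaunay neighbors,
summarized as a type-fraction vector that excludes the index cell's own
identity. Cells with fewer than 3 ring members (default) are excluded from
clustering — a 1- or 2-cell ring makes the fraction vector degenerate — and
reported. K-means runs on the raw fraction vectors (no transform,
squared-Euclidean, 10 restarts, mandatory seed); niche ids are relabeled by
decreasing abundance so "niche 1" is always the most common microenvironment.
K defaults to 100, the study-scale choice; phantom-scale data uses K equal
to the number of planted archetypes. Ring-size weighting was considered and
rejected: an unweighted fraction vector keeps the space a simplex and the
centroids interpretable as compositions.

Niche-conditioned marker profiles average compensated, gated intensities of
index cells of one chosen type per niche; niches holding no such cell are
masked, never imputed. Z-scaling is for heatmap display only and never
enters the F-test. Compartment mapping flags niches whose index cells sit
>90% in one region.

Whether the neighborhood explains marker expression *beyond* cell identity
is tested with a nested linear model: marker ~ type versus
marker ~ type + niche, both categorical, compared by the partial F-test
((RSS_r − RSS_f)/Δdf) / (RSS_f/df_f) with the R² gain reported. The niche
enters as a *predictor* — the phrasing "adding the niche as a dependent
variable" in the source methods is read as a wording slip, since the marker
is the response in both models. With a single cell type the reduced model
degenerates to intercept-only, which is the hand-checkable base case. The
phantom suite calibrates the test (type-I error 3–7% at α = 0.05 over 1000
null simulations at n = 600, 15 niches) and powers it (≥90% for a +1 SD
effect in 10% of niches at n = 5000); the F-values a full tissue dataset
would produce are not reproducible at this scale, so calibration and power
stand in for them.

Cell-type labels themselves are a pluggable input: external labels are
validated and passed through, and a baseline K-means on standardized marker
space (clusters named by their argmax marker) exists so the pipeline runs
end to end without an external phenotyping tool. It is plumbing, not a
phenotyping method.

## Numerical and size choices

Problem sizes throughout (200-cell dense phantom, 120-cell adjacency
phantom, 2000-cell interaction graphs, 1000 permutations, 1000 null
F-simulations at n = 600, 20 niche-recovery seeds) were chosen so the whole
validation suite completes in a few minutes on one CPU while keeping every
Monte-Carlo margin wide. Stacks are written as multipage TIFF with 32-bit
integer samples scaled by the stack range (exact to one part in 2³²); masks
as 16-bit labeled TIFF (≤65535 cells per field). FCS export writes
FCS 3.0 (float32, little-endian) with one event per cell and one parameter
per marker plus x, y, z and size. All exported coordinates are 0-based.

Degenerate inputs are defined, not accidental: empty phantoms render
all-background masks; a blank volume segments to zero cells; c = 0 spill is
the identity; equal-condition comparisons return t = 0, p = 1 with a
zero-variance flag; A = B change summaries report R² as NA.

## Known limitations

* Membrane-marker quantification assumes uniformly distributed surface
  markers; polarized or subcellular-localized signals are outside the model.
* The spill model is positional only — spectral crosstalk between
  fluorophores is a different mechanism and is not compensated here.
* Segmentation quality is reported against phantom truth; hand-labeled
  benchmarks on real tissue (the regime where ~87% found / ~90% singlets is
  the realistic ceiling) require expert annotations the package cannot ship.
* Interaction statistics stop at first-tier contacts; Ripley-type functions
  and higher-order neighborhoods are out of scope.
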