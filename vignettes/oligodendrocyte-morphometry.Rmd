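---
title: "Quantifying transitional oligodendrocyte morphology and putative internodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transitional oligodendrocyte morphology and putative internodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligotrace)
```

## The biological problem

Transitional oligodendrocytes (TOL) are the intermediate maturation stage
between pre-myelinating oligodendrocytes, whose process branches are all
non-myelinating, and mature myelinating oligodendrocytes. A TOL carries a
mixture of non-myelinating process branches (NM_PB) and myelinating branches
(M_PB): putative internodes, visible in membrane-labelled reconstructions as
thickened, longitudinal membrane segments running parallel to the
white-matter tract and reached from fine connecting branches. Quantifying
how many branches a cell commits to internodes, how long those internodes
are, and where along the branching hierarchy they initiate is how
activity-dependent myelination and demyelinating injury are measured at the
single-cell level.

`oligotrace` implements that measurement pipeline for SWC reconstructions
(as exported by NeuronStudio or Simple Neurite Tracer), together with the
image-level companion measurement (MBP/NF200 colocalization), the
statistical workflow used for two-condition comparisons, and a synthetic
generator that produces cells and images with recorded ground truth so every
stage can be validated without access to the original data.

## Decomposition and centrifugal ordering

A reconstruction is decomposed by `decompose_cell()`:

* all contiguous structure-code-1 points form the soma complex; every
  non-soma child of a soma point seeds one **process arbor**;
* a **branch segment** is a maximal chain of points between topological
  nodes (soma attachment, junction = point with two or more children, or
  terminal tip); its length is the sum of 3-D Euclidean inter-point
  distances times `unit_scale`;
* **centrifugal order** is 1 on soma-attached segments and increases by one
  at every junction, for every child (not Strahler ordering). This matches
  the reporting convention in which internode initiations are observed from
  1st to 9th order, with minimum order near 1;
* additional roots (disconnected components, as produced by injury) become
  *fragment arbors*, and the fragment count is reported per cell.

Two conventions are worth stating because the source literature is ambiguous
about them. First, the per-cell "total branches" (TB) denominator is the
number of branch segments under the default `all_segments` mode; a
`terminal_tips` mode is provided because per-process branch-point counts and
per-cell TB in published tables are not mutually consistent under any single
definition. The mode is recorded in every output. Second, per-arbor "length"
defaults to total path length per arbor, with the longest root-to-tip path
also emitted, since either reading is defensible.

Zero-length duplicate points (closer than 1e-6 um to their parent) are
merged before decomposition; they are a common tracing artifact and
otherwise create spurious zero-length segments.

## Internode identification

Two classification modes are supported by `classify_branches()` /
`identify_internodes()`, because deposited reconstructions may or may not
delimit internodes explicitly:

* **annotation mode** (default whenever annotated points are present): a
  segment is M_PB iff more than half of its points carry the internode
  structure code (default 7). Requesting annotation mode on a cell with no
  annotated points is an error rather than a silent "zero internodes".
* **criteria mode**: a maximal run of contiguous same-thickness segments is
  an internode iff it is (i) at least `min_length_um` long (default 25 um,
  just below the shortest putative internodes seen in these preparations,
  roughly 29 um), (ii) at least `radius_ratio` times thicker than its
  connecting (parent) branch (default 2; for arbor roots the reference is
  the cell-wide median segment radius), and (iii) straighter than
  `min_straightness` (end-to-end distance over path length, default 0.8).
  These thresholds are reconstructions of the qualitative description of
  internodes as thickened longitudinal segments arising from fine connecting
  branches - the original quantitative criteria are not available - so all
  of them are configuration, echoed into a JSON sidecar next to every output
  table.

Fine branches sprouting from an internode (a recognised feature of
developing internodes) split it into contiguous segments at the
decomposition level but do not split the internode: contiguous M_PB segments
merge into a single internode unless separated by a non-myelinating
connecting branch. Internode length is the path length of the merged run,
consistent with segment lengths elsewhere; initiation order is the
centrifugal order of its first segment.

The ratios M_PB/TB and NM_PB/TB share the TB denominator and therefore sum
to one exactly; this identity is asserted in the test suite rather than
assumed.

The spatial envelope of the internode field (`spatial_envelope()`)
summarises the flattened tube the internodes occupy: the in-plane tract axis
is estimated as the first principal direction of the internode points
projected to XY (a `fixed_axis` override is available when the white-matter
path is known), and the extents perpendicular to it and along Z are
reported. With an estimated axis the perpendicular extent is a
reconstruction-dependent estimate; with a known axis it is exact, which is
how the generator's ground truth is checked.

## Colocalization metrics

The image-level measurement mirrors the morphometry: `max_project()` takes
per-pixel maxima across planes, `make_mask()` thresholds each channel (Otsu
on a 256-level histogram by default; the method and threshold are always
recorded because the original analysis does not state its rule), and
`coloc_metrics()` reports

* the NF200 pixel fraction (percent of image area covered by the axon mask,
  an axonal-density measure), and
* the MBP/NF200 ratio |MBP and NF200| / |NF200| - myelination normalised
  against axonal density. Normalisation makes the ratio insensitive to MBP
  signal outside the axon mask, which is exactly what allows myelination
  changes to be read independently of axonal-density changes. This
  invariance is tested explicitly.

Overlap is counted at pixel level with no dilation by default; a
configurable dilation radius absorbs chromatic offset when needed.

## Two-group statistics

`normality_gate()` applies the Shapiro-Wilk test to each sample;
`compare_groups()` then uses the two-sided unpaired t test when both samples
are normal (equal-variance form by default - the original reports say only
"unpaired t test", so the Welch form is a recorded switch) and the
two-sided Mann-Whitney U test otherwise (exact for combined n <= 20 without
ties, normal approximation with tie correction otherwise). Summaries follow
the convention mean (+/- SEM) for normal data and median (Q1-Q3) otherwise.
The gate is applied per metric, so a comparison table can mix t and U rows.
No multiple-testing correction is applied, matching the original workflow;
the table metadata records this. `report_table()` refuses to compare cohorts
analysed under different internode criteria.

Rows whose data make Shapiro-Wilk undefined (constant samples, e.g. minimum
initiation order equal to 1 in every cell) fall back to the nonparametric
branch - the same situation produces U-test rows in the published tables.

## The synthetic generator: what it emulates

`morph_params()` + `generate_cell()` produce seeded cells with recorded
ground truth. The model:

* arbor count: rounded normal (mean 7.7, sd 1.6, floor 3) - unchanged
  between presets because activity blockade does not alter arbor counts;
* fine process trees: order-dependent bifurcation with probability
  `p0 * decay^(order-1)` up to order 9, lognormal branch lengths (median
  12 um), radius 0.3 um;
* internodes: lognormal lengths parameterised by median and IQR - control
  84.7 um (68.6-101), TTX 53.8 um (39.3-81.2) - radius 1.2 um, directions
  within 5 degrees of the tract axis, all geometry confined to a
  36.5 x 17.33 um envelope cross-section by reflecting directions at the
  walls (so path lengths stay exact);
* placement: the per-cell internode count is drawn as a rounded normal
  around the preset target (5.5 control, 4.7 TTX) with sd 1.5, matching the
  cell-to-cell dispersion reported for these cells, then grouped into
  chains by a geometric continuation probability (0.4): internode, fine
  connector, next internode - the "interconnected internodes" configuration.
  About 30% of chains sit directly on the soma (order-1 initiations); the
  rest attach at interior points of fine tree branches, so every attachment
  is a proper junction. Each internode sprouts one fine internodal branch
  with probability 0.25;
* injury (`apply_injury()`): internode branches are deleted with
  probability 1 by default and surviving branches detached with probability
  0.3, reproducing the fragmented, internode-free phenotype of
  complement-mediated injury.

Calibration is analytic, not fitted: given the targets (internodes per cell
and M_PB/TB, 0.28 control / 0.20 TTX), closed-form expectations of the
chain/sprout bookkeeping give the expected M_PB segment count, hence the TB
needed for the target ratio, hence the fine-tree size per arbor and - through
the branching recursion implemented in `expected_fine_segments()` - the
bifurcation probability `p0`. The TTX preset's ~20% higher TB is emergent
from holding internode counts nearly fixed while halving the myelinating
share, which is the published interpretation (extra branches that fail to
myelinate).

### What the generator does not emulate

Cells whose TB, internode counts and branch-class ratios match the published
values cannot simultaneously match the published per-arbor mean length
(~178 um), per-process branch points (~7.3) and maximum branch order
(~7.25): those numbers are mutually inconsistent under any single branching
model, as the per-cell TB of ~20-25 with ~7.7 arbors implies far fewer
branch points per arbor. The presets anchor TB, ratios, internode lengths,
initiation orders and internode counts - the quantities the two-condition
contrasts are built on - and accept shallower, shorter arbors (max order ~6,
arbor length ~90-110 um). Passing recovery tests therefore validate the
pipeline's measurement machinery, not the realism of every marginal
statistic; real tracings also contain noise the generator omits (radius
measurement error, tortuous paths, annotation mistakes).

Image stacks are likewise stylised: straight fibers of constant width with
Gaussian noise and clean bimodal intensities. They validate the projection,
thresholding and normalisation logic, not robustness to uneven staining or
out-of-focus light.

## Numerical choices and degenerate inputs

* SWC output is written with 17 significant digits, so read-write-read is
  the identity on points.
* Components, arbors and segments are ordered by minimum sample id -
  deterministic across platforms.
* Duplicate-point merge tolerance: 1e-6 um. Radius ties during run
  extension break towards the thicker child, then the lower segment id.
* Envelope axis sign is fixed to positive x (then positive y), so reported
  axes are comparable across cells.
* Cells with no soma code: the root of the largest component becomes a soma
  surrogate with a warning; analysis proceeds rather than failing silently.
* Zero internodes is a valid analysis outcome (the injury phenotype):
  ratios remain defined, order statistics and envelope are reported absent.
* Seeded generation restores the caller's RNG state, and identical seeds
  produce byte-identical SWC files and image arrays.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script cohorts mirror the study design: 12
cells per condition, the cohort sizes on which the published morphometry
rests. Replicate effect-direction checks use 100 control-vs-TTX cohort
pairs; length-median recovery uses 50 cells; image recovery uses 20 stack
pairs of 128 x 128 x 3 at coverage 0.4. A control-preset cell has roughly
100-200 points and 25-35 branch segments, so the full battery runs in a few
minutes on one CPU.

## Known limitations

* Criteria-mode thresholds are reconstructions, not the original study's
  (unavailable) values; with annotations present, annotation mode is
  preferred and the criteria are a cross-check.
* The envelope's perpendicular extent depends on the estimated axis when no
  tract direction is supplied; for sparse internode fields the principal
  direction can tilt and shrink the estimate by tens of percent.
* The Mann-Whitney branch switches to the tie-corrected normal
  approximation whenever ties are present, even at small n, where an exact
  tie-aware enumeration would be preferable.
* `fetch_neuromorpho()` depends on the NeuroMorpho.Org REST API and file
  layout remaining stable, and obviously on network access.
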