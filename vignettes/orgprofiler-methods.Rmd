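---
title: "Multi-parametric phenotypic profiling of 3-D organoid stacks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-parametric phenotypic profiling of 3-D organoid stacks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(orgprofiler)
```

# The problem

Image-based high-content screens of 3-D cultured microtissues ("organoids")
measure treatment-induced changes of tissue architecture — invasiveness,
polarisation, branching, growth — that single-endpoint assays such as
viability read-outs miss. This package implements a complete analysis
pipeline for such screens: two-channel (filamentous-actin, nuclei)
multi-section image stacks per well are segmented into 3-D organoid objects
with child nuclei; a 294-entry feature vector is extracted per well and
z-score normalized against buffer-control wells; accumulative random-forest
feature selection identifies the features that robustly discriminate
treatments from controls; and Ward clustering of per-dose treatment profiles
defines phenotypic classes, signed class signatures and per-treatment
dose-label sequences.

Because screens of this kind are proprietary, the package also contains a
first-class synthetic microtissue generator that renders seeded,
ground-truthed image stacks and planted feature tables. Every downstream
stage is tested against that ground truth.

# The six morphology features

All six are defined on per-section binary masks with Euclidean distances
between pixel centres; the boundary of a mask is the set of its pixels
8-adjacent to background.

* **Per-organoid size** — the pixel count of one organoid's section mask.
* **Invasion inhibition** — per-organoid roundness,
  `4 * area / (pi * major_axis^2)`, where the major axis is the maximum
  distance between any two mask pixels. A disk scores ~1; elongated or
  branched (invasive) shapes score lower.
* **Total proliferation** — the accumulated mask area over the whole stack,
  `sum_i sum_j Area[i, j]` over sections `i` and organoids `j`.
* **Organoid count** — as printed in its defining formula, `sum_i n_i`: the
  per-section mask counts summed over sections, so an object spanning five
  sections contributes five. The alternative reading (number of distinct
  linked 3-D objects) is available via `organoid_count(masks, distinct =
  TRUE)`; the per-section sum is the default because it is what the formula
  states, and the two readings disagree whenever objects span multiple
  sections.
* **Cell polarity** — for each nucleus assigned to an organoid, the shortest
  distance from its mass centre to the organoid's section-mask boundary; the
  feature is the mean of these minima, and their standard deviation is
  carried alongside. Hollow, polarised structures (nuclei lining a lumen)
  yield low values with low spread; solid structures with scattered nuclei
  yield high values with high spread.
* **Organoid branching** — the mask is skeletonized (Zhang-Suen thinning)
  and decomposed into a graph whose vertices are endpoints (one skeleton
  neighbour) and junctions (three or more); a *branch* is an edge with
  exactly one endpoint vertex, and the feature is the mean branch length.
  On a pixel grid a crossing is a small cluster of junction pixels rather
  than a single pixel; adjacent junction pixels are collapsed into one
  vertex and branch length counts the arm's pixels excluding that cluster
  (the endpoint pixel included). A compact disk or a bare segment has no
  branch and scores 0.

Single-pixel masks are rejected by `invasion_inhibition()` (the major axis
is 0 and the formula is undefined); in practice they are removed by the
minimum-area filter long before. The standard deviation of a single
observation is defined as 0 so single-organoid wells stay in the table.

# Segmentation

The per-section segmenter is a documented substitute for the screen
software's unpublished method, built from standard components (EBImage):
rolling-ball style background subtraction (grayscale opening with a disc,
radius 21 px actin / 11 px nuclei — larger than any organoid's inscribed
radius), an Otsu threshold computed once per channel from the pooled
background-subtracted stack, 8-connected component labelling, and a
watershed split of touching blobs for the nuclei channel. Two numerical
guards matter in practice:

* Otsu's threshold collapses into the noise band on sections that are
  almost entirely background, so the threshold is floored at
  `median + 6 * MAD` of the background-subtracted intensities.
* The threshold is global per channel and well (not per section), so mask
  extents do not drift between sections of one object.

Out-of-focus masks are discarded by a boundary-sharpness score (mean
gradient magnitude on the mask boundary divided by mean interior
intensity). The default threshold 0.2 was calibrated on synthetic fixtures:
in-focus rendered boundaries score ~0.4 and sections blurred with a sigma
≥ 3 px Gaussian fall below 0.1.

Masks in adjacent sections are linked into 3-D objects when their overlap
ratio — intersection over the smaller mask — is at least 0.5; the
smaller-mask denominator keeps the ratio symmetric under growth or
shrinkage between sections, and linking is transitive. Nuclei become
children of the organoid whose same-section mask contains their mass
centre, falling back to the nearest mask within 5 px, and are otherwise
left unassigned.

All coordinates are 1-based (R convention): pixel centres at integer
(x, y), z equal to the 1-based section index.

# The 294-entry feature battery

Seventy morphological features per channel (65 per-object-per-section, 5
per-well) plus 7 two-channel correlative features, each aggregated per well
by mean and standard deviation: `(70 * 2 + 7) * 2 = 294` named values.
Per-well features enter with their SD aggregate fixed at 0, and features
that are constant across buffer wells are excluded at normalization, so the
vector width is always 294 while the analysable width is somewhat smaller.

The battery is deliberately **non-redundant**: each morphological degree of
freedom is carried by exactly one descriptor — the six formula features
above — and every other per-object descriptor is an intensity or texture
statistic constructed to be blind to geometry:

* statistics are computed on a fixed-size (128-pixel) deterministic
  subsample of the mask's eroded interior. Boundary pixels are excluded
  because their share of a mask equals the perimeter/area ratio, which
  duplicates shape information; the fixed subsample size removes
  sample-size effects (entropy, extremes and estimator variances all
  depend on n and would otherwise duplicate size information in both the
  mean and the SD aggregates);
* texture (the 26 Haralick features, via `EBImage::computeFeatures.haralick`)
  is measured on a fixed square patch at the mask's interior centre
  (9 x 9 px for organoids, 3 x 3 for nuclei), again so that texture
  estimates are independent of object size;
* the correlative features are pooled per linked organoid (e.g. polarity
  over the organoid's full complement of nuclei), keeping each
  observation's sample size independent of how many sections the organoid
  spans.

A JSON sidecar (`inst/extdata/feature_definitions.json`) documents every
definition. Redundant batteries are common in real screens; the
non-redundant design here is what makes the feature-selection stage
interpretable — a selected feature names a phenotype axis rather than one
of a dozen aliases of it.

# Normalization

Each feature is centred and scaled by the mean and sample (n−1) SD of the
buffer-control wells across the experiment. Features with zero buffer SD
cannot be normalized and are excluded (recorded on the result, reported via
a message) rather than propagated as NaN; k in the selection stage is not
rescaled when that happens.

# Accumulative feature selection

For every (treatment, dose) group versus the buffer controls, a random
forest classifier is fitted repeatedly: per repetition, 30 rows per class
are drawn with replacement (class-wise bootstrap — with quadruplicate wells
this is the only reading under which "30 samples per class" is possible),
features are ranked by impurity importance with ties broken by canonical
feature order, and the top 10 are recorded. The default is 500 repetitions;
the desk-scale configuration uses 50. Frequencies are accumulated over all
(pair x repetition) draws — they always sum to exactly k — and features at
or above the 5 % cutoff are selected, in decreasing frequency order.

The forest is pinned for reproducibility: ranger, 200 trees, default mtry,
impurity importance, single-threaded, seeded per repetition. The
stabilisation of the procedure comes from the repetition loop, not the
forest size (verified: selected sets are essentially unchanged between 25
and 200 trees per repetition).

## Panel breadth and what the 5 % cutoff can resolve

The cutoff's ability to reject spurious features is a *dilution* property:
a feature that separates one particular group's four wells from buffer by
chance (|z| of a 4-well mean around 1 arises freely among ~250 null
features) will appear in that pair's top-10 in most repetitions, because
the class-wise bootstrap resamples the same wells and the chance pattern
persists. Its overall frequency is capped at roughly
`(pairs in which it is lucky) / (total pairs)`. With P pairwise comparisons
the cutoff therefore excludes single-pair flukes only when P > 20, and
excludes features lucky in several pairs only when P reaches the hundreds —
the scale of a real screen panel (dozens of treatments at six doses). The
default synthetic plate uses a four-treatment panel (24 pairs; two opposing
invasion phenotypes, one growth inhibitor, one inactive binder), which is
desk-computable in minutes: the six planted features rank first by a clear
frequency gap, but a tail of pair-specific chance features also clears 5 %.
The selected-set *size* printed for a full screen is thus a screen-scale
property; at desk scale the selected set is the six plus that tail. This is
a property of the method itself, not of the implementation, and it is the
package's main known limitation (see below).

# Phenotypic clustering

Replicate wells are averaged into one profile per (treatment, dose); the
profiles are clustered on the selected features with Ward's method
(`hclust`, `ward.D2`, Euclidean distances). The cluster count is chosen by
computing the Davies-Bouldin and Calinski-Harabasz indices over k = 2..10:
the Davies-Bouldin minimiser is taken, and when the Calinski-Harabasz
maximiser disagrees both curves are still reported (a deterministic rule is
required; no rule was given). A 2-fold stability diagnostic is reported
alongside: observations are split into halves, each half is clustered, each
half is also projected onto the other half's centroids, and the adjusted
Rand agreement between projected and direct labels is averaged. It is a
diagnostic only and never alters k.

Classes are labelled A, B, ... in dendrogram order. Each class's signature
is `F_i`, the mean z-score of feature i over members, and the signed
partition size `%(i) = 100 * F_i / sum_j F_j`; signed values outside
[0, 100] are legal, and the partition is flagged undefined when
`sum_j F_j = 0` (raw F still reported).

Each dose of a treatment is then assigned the label of the nearest class
centroid, producing an ordered dose-label sequence; profiles whose
root-mean-square z over the selected features falls below 1 receive the
distinguished "no-effect" label. The RMS rather than the raw norm keeps the
floor calibrated in z units regardless of how many features were selected
(a raw norm grows like sqrt(p) even for pure noise). The treatment's
general class is the most frequent non-"no-effect" label, ties broken in
favour of the label observed at the highest dose; an all-"no-effect"
sequence stays "no-effect".

# The synthetic microtissue generator

The generator emulates the screen's acquisition and plate semantics:
two-channel 16-bit multi-section stacks, buffer controls distributed across
the plate at 25 % of wells, and treatments at six doses in quadruplicate.
Defaults are desk-scale: 8 sections of 320 x 320 px with a z spacing of 6
px per section (the screen geometry, 20 sections of 1344 x 1024, is
available through `stack_geometry()`), 8 organoids per well, ~64 nuclei.

Rendering model and the dials it exposes:

* an organoid is an **extruded ellipse**: an area-preserving elliptical
  footprint (elongation = major/minor ratio) constant through the object's
  depth of `2 * radius / zscale` sections, truncated by the capture window.
  The constant cross-section keeps per-section measurements of one object
  homoscedastic while the z extent still grows with size, which is how the
  size dial reaches the per-section organoid count;
* optional radial **arms** (count and length) attached to the footprint
  boundary, which lengthen the major axis (lowering roundness) and create
  skeleton branches;
* an optional concentric **lumen** (hollow flag) for polarised, ring-like
  cross-sections;
* **nuclei** are Gaussian-shaded blobs whose half-maximum contour is a disc
  of the nominal radius (3 px), placed one section each, either in a shell
  at a controlled distance from the footprint boundary ("boundary"
  placement; that distance is the polarity dial) or uniformly inside the
  footprint. At zero noise, thresholding a channel at half-maximum
  recovers the ground-truth voxel sets exactly.

Organoid parameters are sampled **homoscedastically in the measured
feature's own units** (footprint area ~ N(620, 110 px^2), target roundness
~ N(0.72, 0.05), arm length ~ N(9, 1.8 px), nucleus shell depth
~ N(4.5, 1.1 px)), so a treatment effect shifts well means without
inflating within-well dispersion — the mean aggregate responds, the SD
aggregate does not. Effect templates map dials to dose-response slopes with
a quadratic ramp over normalised dose (low doses near-null, as treated
wells in the screen behaved): `anti_invasive` (rounder, smaller, shorter
arms, nuclei pulled to the boundary), `pro_invasive` (the opposite),
`growth_inhib` (smaller only) and `none`. Placement keeps every organoid's
arms clear of its neighbours (objects never merge), and nuclei keep a
minimum separation so blobs never touch.

The untreated baseline is a moderately invasive culture (roundness 0.72,
two short arms, mid-depth nuclei), consistent with an invasive prostate
line in a permissive gel; treatments move the culture towards either the
polarised or the invasive extreme.

`simulate_feature_table()` bypasses imaging entirely and plants class
centroids plus unit-variance noise in a 294-column table; it drives the
selection and clustering tests directly.

What the generator does **not** emulate: optical physics (PSF,
photobleaching, depth attenuation), cell-level texture inside organoid
bodies (bodies are flat + noise), organoid-organoid contact and merging,
mixed phenotype populations within a well, and plate-position effects.
Passing tests therefore demonstrate the pipeline's correctness and its
statistical behaviour under controlled conditions, not segmentation
robustness on real micrographs.

# Numerical choices and conventions

* 1-based pixel and section indices; distances between pixel centres.
* Images live on [0, 1] quantized to the 16-bit grid, so in-memory stacks
  round-trip losslessly through the TIFF files written by
  `write_image_stack()`.
* Overlap-ratio ties: linking uses `>=` on the ratio; frequency cutoff uses
  `>=`; importance ties break by canonical feature order.
* SD of one observation = 0; buffer z-scores use the sample (n−1) SD;
  buffer-constant features are excluded with a record.
* All generators and the selection stage are pure functions of their
  inputs and a seed; per-well seeds are derived deterministically from the
  plate seed.
* Desk-scale problem sizes used throughout the tests: 8-section stacks of
  up to 320 x 320 px, a 128-well default plate, 50 selection repetitions
  (the method's own default is 500), and 24 pairwise comparisons.

# Known limitations

* The selected-set *size* under the 5 % cutoff is a screen-scale property
  (see the panel-breadth section): at 24 pairwise comparisons the six
  planted features sit at the top of the ranking but chance features also
  clear the cutoff, so the selected set is larger than six. Analyses that
  need only the leading axes should take the top of the frequency ranking
  rather than the raw cutoff set.
* The per-section organoid count (the printed formula) conflates object
  number with z extent; the `distinct` variant is provided.
* 2-fold clustering stability is reported but, with ~24 dose profiles, is
  a coarse diagnostic.
* The focus filter discards per-section masks, not whole objects, so an
  object blurred in its top sections keeps its sharp sections (its z-span
  stays contiguous only because linking is per adjacent section).
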