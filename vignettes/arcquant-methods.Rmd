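---
title: "Methods: image-derived measurements of perinatal subventricular migratory streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-derived measurements of perinatal subventricular migratory streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arcquant)
```

## Scope

The neonatal brains of gyrencephalic species carry an expanded
subventricular zone — the "Arc" — from which streams of migratory young
(DCX⁺) neurons, most of them GABAergic interneurons, move into the
postnatal cortex. Characterizing this system from microscopy images
requires four kinds of computation, all implemented here:

1. **Per-cell transcript quantification** from multiplexed smFISH probe
   channels (area-based readout, not spot counting).
2. **Cell-type neighborhood interaction analysis** with a within-image
   label-permutation null and a cross-image aggregation rule.
3. **Section-level morphometrics**: region area ratios, tier areas, the
   gyrification index (GI), vascular/positive-area fractions, tier
   intensity profiles, and serial-section volume estimation.
4. **Synthetic data generation** with planted ground truth, so that each
   of the above can be validated quantitatively without access to raw
   specimen images.

The package deliberately does not attempt nucleus segmentation, imaging
round registration, snRNA-seq processing, or automated anatomical
delineation: those are upstream of the computations here and, in the
studies this pipeline serves, are manual or vendor-software steps.

## smFISH quantification

### Thresholding

Each probe channel is binarized with a Rényi-entropy threshold
(`renyi_threshold()`). Intensities are binned to 256 levels over the
image range; for a candidate split $t$ the objective is the sum of the
Rényi entropies of the renormalized sub-histograms below and above $t$,

$$H_\alpha(t) = \frac{1}{1-\alpha}\Big[\log\sum_{i \le t} q_i^\alpha +
  \log\sum_{i > t} r_i^\alpha\Big],$$

with $q$ and $r$ the class-conditional histograms and the Shannon form at
$\alpha = 1$. Each order's optimum is found by exhaustive search over the
256 candidates (cheap and exact — there is no reason to approximate). The
default order set $\{0.5, 1, 2\}$ produces three candidate splits that
are blended by the classical ordering-and-weighting rule: sorted splits
$t_1 \le t_2 \le t_3$ are combined as

$$t^* = t_1\!\left(P(t_1) + \tfrac14\,\omega\,\beta_1\right)
      + \tfrac14\, t_2\, \omega\, \beta_2
      + t_3\!\left(1 - P(t_3) + \tfrac14\,\omega\,\beta_3\right),$$

where $P$ is the cumulative histogram, $\omega = P(t_3) - P(t_1)$, and
$(\beta_1,\beta_2,\beta_3)$ is $(1,2,1)$, $(0,1,3)$ or $(3,1,0)$
depending on which of the sorted splits agree within 5 bins. Every
$\beta$ triple sums to 4, so $t^*$ is a convex combination of the three
candidates. When all three orders agree, $t^*$ is exactly their common
split. `alpha_set` is configurable because the order set used by any
particular lab's filter is rarely recorded; a single order skips the
blending.

The returned threshold is placed midway between the largest background
pixel and the smallest foreground pixel, so `image > threshold`
reproduces the selected histogram split exactly and the foreground mask
is invariant to a constant intensity offset.

### Pixel-percentage expression and the matrix

A cell's expression of a gene is the percentage of its ROI pixels covered
by thresholded probe signal: `quantify_cell()` computes
$100\,|M \cap R|/|R|$ for probe mask $M$ and ROI $R$, and
`build_expression_matrix()` applies this per channel per ROI after
optionally removing connected foreground components smaller than
`min_object_px` pixels (4-connectivity via EBImage). That component
filter is this pipeline's automated, reproducible replacement for the
manual removal of spurious speckle "by eye"; with `min_object_px = 0` and
no background speckle the pipeline reproduces planted per-cell fractions
*exactly*, which the test suite asserts entry by entry. A constant
channel (no separable signal) quantifies to zero rather than erroring, so
an empty gene does not abort a 30-channel run.

### Median zeroing

Area-based FISH values carry a nonspecific background floor. The rule
applied here: for each gene, only cells strictly greater than that gene's
median value (over all cells, zeros included) are treated as truly
expressing; all other entries are set to zero (`median_zero()`). Ties at
the median are zeroed — "strictly greater" is the contract, and the tests
count it against a brute-force oracle. The median is taken over the
pooled dataset (one matrix); a per-image variant can be had by splitting
the matrix first. The rule is single-pass by definition: re-applying it
to its own output would zero further entries because the medians move,
so the stage flag on the matrix prevents accidental double application.

### Clustering and subtype assignment

`normalize_cluster_embed()` follows the standard expression-matrix
workflow: $\log(1+x)$ on the 0–100 percent scale, per-gene
standardization, PCA with **all** components retained, a k-nearest-
neighbor graph (default $k = 20$) on the full PC space, and Leiden
community detection (modularity objective, default resolution 1) via
igraph. The defaults for $k$ and resolution are ordinary single-cell
practice; with a few hundred to a few thousand cells and strong marker
structure the results are insensitive to them (with very small datasets,
$k$ should not exceed a planted group's size or the graph can split
artificially).

The default 2-D embedding is the first two principal components: it is
exactly reproducible, dependency-free, and sufficient for the package's
purposes. UMAP — the embedding this workflow classically pairs with
Leiden — is available as `embedding = "umap"` when the uwot package is
installed. Cluster labels never depend on the embedding.

`assign_subtypes()` turns clusters into biological labels: each cluster
is scored for each subtype rule as the mean standardized log expression
of the rule's required markers, and receives the best-scoring subtype if
it leads the runner-up by `margin` (default 0.25 z-units), else
"unassigned". The default rules are the seven perinatal classes: the
MGE-derived NKX2.1⁺MAF1⁺ and SST⁺LHX6⁺ types, the CGE-derived
COUP-TFII⁺SP8⁺, COUP-TFII⁺TBR1⁺, COUP-TFII⁺CALB2⁺ and VIP⁺GAD1⁺ types,
and the SATB2⁺ excitatory class. The margin guards against calling a
cluster that sits between two COUP-TFII⁺ siblings; 0.25 is small enough
that any cluster with a genuinely dominant marker pair is assigned.

## Neighborhood interaction analysis

`build_neighbor_graph()` connects cells whose centroid distance is
**strictly less than** the threshold (default 4 pixels — the image-space
contact rule; no physical-unit conversion is applied). For an ordered
type pair $(A, B)$ the observed statistic is the mean number of
$B$-neighbors per $A$-cell, the histoCAT-style interaction score; both
orderings are informative and both are reported by `test_all_pairs()`.

`permutation_test()` holds the graph fixed and permutes the observed
label vector over node positions (fixed label composition — the standard
exchangeable null), recomputing the statistic each round. The one-tailed
enrichment p-value uses the add-one estimator
$p = (1 + \#\{S_{\text{null}} \ge S_{\text{obs}}\})/(1 + N)$, which is
never zero and is a valid p-value under exchangeability; the avoidance
tail is available behind a flag. A pair is "present" in an image when
both types occur there; absent pairs are flagged and not tested.

`aggregate_images()` applies the cross-image visualization rule: keep a
pair if it is significant ($p < 0.05$) in at least 30% of images **and**
present in at least 90% of them, both fractions computed over all images
and compared with $\ge$ so the thresholds are attainable exactly.

Because the statistic is a count ratio, its permutation distribution is
discrete; with few contacts per image the add-one p-values are visibly
conservative (super-uniform). The calibration experiment therefore uses
a density at which the test is informative: 100 cells in a 40 × 40 px
image (0.0625 cells/px², about 3 neighbors per cell under the 4-px
rule), emulating densely packed migratory streams rather than sparse
fields. Under that null, across 400 simulated images with 1,000
permutations each, the empirical type-I error at $\alpha = 0.05$ sits in
0.03–0.07 and the p-value ECDF passes a Kolmogorov–Smirnov uniformity
check at the 1% level — exact uniformity is not attainable for a
discrete, add-one estimator, which is slightly conservative by
construction.

`map_to_stream()` orders cells topographically: each cell is projected
to its nearest point on a stream polyline and reported as normalized
arc-length position in $[0,1]$ plus a signed perpendicular offset.

## Morphometry

* `area_ratio()` — region pixels over reference pixels × 100; the pixel
  area cancels and is kept only for absolute-area reporting.
* `tier_areas()` — tier 1 measured directly; tiers 2–3 by subtraction
  from the whole region, which is how tiered areas are defined for this
  system.
* `gyrification_index()` — full contour length over outer envelope
  length. When no envelope is supplied the convex hull of the full
  contour is used: the manual "line connecting the cortical surface" is
  not reproducible, and the hull is the canonical deterministic
  surrogate (it touches every gyral crest and never enters a sulcus).
  For the synthetic folded contours the hull's length is within a
  fraction of a percent of the circumscribing circle the generator uses
  as ground truth. GI is invariant to rigid motion and uniform scaling,
  and equals 1 for convex outlines.
* `positive_area_fraction()` and `tier_intensity_profile()` — percent of
  region pixels above threshold, and mean positive intensity per tier
  band; an empty band is a missing value, not an error, since deep tiers
  legitimately contain no signal in lissencephalic sections.
* `estimate_volume()` — the serial-section estimator
  $$V = \sum_{k=2}^{n}\left(A_{k-1} + A_k + \sqrt{A_{k-1}A_k}\right)
  \frac{h}{3},$$
  the sum of conical-frustum volumes between consecutive sections
  (spacing $h$, e.g. 0.75 mm serial Nissl sections; per-gap spacings are
  supported). The estimator is *exact* — to rounding error — for any
  solid whose cross-section radius is linear between sections
  (cylinders, cones, frustum stacks), and converges for smooth solids:
  a unit sphere cut into 21 sections is recovered within 1%, with the
  error shrinking as sections are refined. Negative areas are rejected;
  a zero area (apex section) is valid and handled by the formula.
* `correlate()` — Pearson's $r$ with the two-sided $t$ test, for
  relating GI to the area ratio across specimens.

## The synthetic-data generators

Every generator is a pure function of its arguments including the seed
(no global RNG state is touched), and each attaches the ground truth its
consumer is validated against.

* `generate_section_profile()` — analytic cross-sections of cylinders,
  cones, spheres and frustum stacks at evenly spaced planes, with the
  closed-form volume attached. Sectioning spans that exceed the solid
  are rejected.
* `generate_contour()` — closed polar contour $r(\theta) = R +
  a\sin(k\theta)$ plus its outer envelope (the circumscribing circle of
  radius $R + a$; the circle of radius $R$ itself when $k = 0$).
  Ground-truth lengths come from 20,000-point trapezoidal quadrature of
  $\sqrt{r^2 + r'^2}$; amplitudes $a \ge R$ are rejected since the
  radius would reach zero and the curve self-intersect.
* `generate_cell_map()` — cell centroids with type labels. CSR mode
  places cells uniformly with iid multinomial labels (the exchangeable
  null of the permutation test). Attract mode places each attracted
  type by a Neyman–Scott (Thomas) process: uniformly scattered parents,
  `mean_offspring` cells per parent on average, isotropic Gaussian
  dispersion `cluster_sd`; offspring falling outside the image are
  reflected at the borders. Coordinates are 0-based pixels, origin
  top-left, y downward.
* `generate_probe_images()` — per gene, ROI pixels positive with the
  cell type's probability, background pixels at the speckle rate; ROIs
  are disks at centroids (radius configurable), overlaps resolved by
  nearest centroid so the ROIs partition their union and pixel-count
  oracles are unambiguous. The truth table stores each cell's realized
  positive fraction.
* `generate_region_masks()` — labeled regions with exactly the requested
  pixel counts, laid out as contiguous row-major runs (a strict
  rectangle cannot realize every count; exactness is the property the
  downstream oracles need).
* `arc_subtype_model()` / `simulate_arc_fish()` — the planted seven-type
  experiment: marker probes cover 50% of an expressing cell's ROI,
  nonspecific coverage 3%, the pan-inhibitory marker GAD1 at 20% in
  inhibitory types whose rule does not already require it, DCX in every
  cell, background speckle rate 0.002, ROI radius 4 px. These defaults
  make per-cell marker readouts separate from background by many times
  the binomial noise of a ~50-pixel ROI (s.d. ≈ 7 percentage points) —
  a clean but not noise-free readout, chosen to represent a
  well-executed multiplexed FISH run.

### What the simulations do and do not show

The generators plant the *statistical* structure the pipeline must
recover: known per-cell positive fractions, exchangeable or clustered
labels, analytic geometry. They do not emulate optics (no PSF, no
chromatic shift between rounds), segmentation error (ROIs are ideal
disks, not drawn nuclei), intensity gradients, or tissue deformation.
Passing the suite therefore demonstrates that the *computations* are
correct and calibrated — not that any particular wet-lab image will be
quantified without bias. On real data the dominant error sources are
upstream of this package (registration, ROI drawing, probe chemistry).

## Numerical choices and degenerate inputs

* Problem sizes used by the validation suite and the acceptance script:
  400 CSR images (100 cells, 1,000 permutations) for calibration; 20
  images × 20 replicates for the aggregation recovery; 700 cells × 12
  genes for the end-to-end subtype run; 50 histogram fixtures for the
  threshold oracle; 100 random matrices for the median-zero contract.
  The whole suite runs in well under a minute on one core.
* Ties: the first maximizer wins in the entropy search; label ties at
  the median zero out; equal subtype scores within the margin give
  "unassigned"; a cell exactly at a polyline vertex projects with
  position equal to that vertex's arc fraction.
* Degenerate inputs that *error*: constant images in
  `renyi_threshold()`, empty ROIs and reference masks, zero-length
  stream paths, tier masks outside their region, zero variance in
  `correlate()`, permutation counts below 1.
* Degenerate inputs that are *handled*: constant probe channels (zero
  column), all-zero genes in `median_zero()` (pass through), empty tier
  bands (`NA`), absent type pairs (`present = FALSE`, no test).
* Seeds: every stochastic function takes an explicit seed and
  restores the caller's RNG state; derived sub-seeds stay below
  $2^{31}$.

## Known limitations

* The Rényi order set used by any given lab's filter is rarely
  documented; results can shift by a few histogram bins across orders.
  The default triple with the ordering-weighting blend is the widely
  distributed convention, and `alpha_set` makes the choice explicit.
* The interaction statistic is discrete; at very low cell density the
  permutation p-values are conservative no matter the estimator. The
  calibration conditions above state the density at which the pipeline's
  guarantees are established.
* The convex-hull GI envelope slightly underestimates a manually drawn
  envelope that dips between widely separated gyri; for strongly folded
  contours the difference is far below the fold-driven signal.
* `aggregate_images()` treats images as exchangeable replicates; it does
  not model per-specimen nesting.
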