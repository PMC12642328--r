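---
title: "Methods: annotation-free CE/N-CE classification and spatial immune geometry"
author: "glandmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotation-free CE/N-CE classification and spatial immune geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Prostate adenocarcinoma is diagnosed morphologically: benign glands keep a
basal cell layer (p63+, CK5+) around their secretory epithelium, and loss
of that layer is a hallmark of carcinoma. Multiplexed immunofluorescence
gives per-cell intensities for these basal markers, so cancerous
epithelial (CE) and non-cancerous epithelial (N-CE) cells can in principle
be separated without manual annotation — if the positive/negative boundary
can be estimated from the data itself, and if cell-level calls can be
reconciled with gland-level anatomy (a benign gland is a *structure*, not
a bag of cells). `glandmark` implements that two-level classification and
the downstream spatial statistics linking immune geography to biochemical
recurrence.

# Cell-level model

## QC and normalization

Cells pass QC when: epithelial cells contain 1–2 segmented nuclei; each
epithelial sub-compartment (nucleus, membrane, cytoplasm) area is greater
than 10 px but at most 1500 px; whole-cell area is 50–3500 px
(epithelial) or 30–1500 px (stromal); the cyclic-registration quality
score is strictly above 0.85; and epithelial cells failing marker-specific
QC for p63 or CK5 are removed before classification. `applyQC()` reports
per-rule removal counts (a cell may fail several rules; the `total` row is
deduplicated). The filter is idempotent.

Raw intensities are transformed as `log2(v + pseudocount)` with
pseudocount 1 (the transform must be defined at v = 0; 1 is the smallest
choice that maps 0 to 0), then median-centered per core and marker.
Median-centering is our reading of "batch-effect minimization": it is the
simplest location adjustment that makes cores comparable without assuming
anything about scale, and it is what makes *pooled* mixture fitting across
cores meaningful. It can be disabled (`centerByCore = FALSE`). An optional
upper-quantile cap (`capQuantile`) stands in for manual review of
artifactual intensity outliers; it is off by default because automated
winsorization is not a substitute for looking at the images.

## Mixture gating

For each marker the log2 intensities of epithelial cells are modeled as a
K-component Gaussian mixture

$$f(x) = \sum_{k=1}^{K} \pi_k\, \mathcal{N}(x \mid \mu_k, \sigma_k^2),$$

fitted by EM (`fitGmmEM()`): the E-step computes responsibilities
$\gamma_{ik}$, the M-step the weighted updates of $\pi_k, \mu_k,
\sigma_k^2$. Iteration stops when the relative log-likelihood change drops
below $\varepsilon = 10^{-8}$ or after 1000 iterations; the log-likelihood
trace is stored and asserted non-decreasing on every fit.

Numerical choices:

* **Initialization** is quantile-based — component means at the
  $(2k-1)/(2K)$ quantiles, equal weights, pooled variance. It is
  deterministic, which we value above occasional likelihood gains from
  random restarts in an annotation-free pipeline meant to be reproducible.
  A seeded k-means initialization is available (`init = "kmeans"`).
* **Variance floor** at $10^{-6}$ of the total variance prevents a
  component collapsing onto a point mass.
* **Degenerate components** (weight below $10^{-6}$) are pruned with a
  warning and the fit restarts at K−1.
* **K** defaults to 2; K = 3 accommodates a shoulder population and is the
  user's call from the histogram, as in interactive use of this kind of
  gating. K = 1 returns the plain Gaussian MLE.

A cell is *positive* when the component with the highest posterior at its
value is the component with the largest mean — "the high end of the
histogram" — with exact posterior ties broken toward negative (the
conservative direction: fewer spurious basal calls). Basal markers combine
by logical OR: $P_i = \bigvee_b C_{ib}$. Epithelial cells with $P_i = 1$
are N-CE, double negatives are CE, stromal cells are `stroma`.

By default the mixtures are fitted **pooled across the cohort's cores**
(`fitCohortMixtures()`, used by `runAll()`): after per-core median
centering the log2 scales are comparable, and a pooled fit estimates the
boundary from thousands of cells instead of a few hundred, which matters
because the gland-eligibility rule below is sensitive to the false-positive
rate. Per-core fitting remains available (`runCorePipeline()` without
`fits`).

Immune phenotypes use the same gating machinery on stromal cells:
T-regulatory cells are CD3+CD4+FOXP3+, T-helper cells CD3+CD4+ and (by
default) FOXP3−, macrophages CD68+. The disjoint T_H convention is a
deliberate choice — the literal CD3+CD4+ definition would count every
T_reg as a T_H too; `thIncludesTreg = TRUE` restores the overlapping
convention for comparability.

# Gland-level model

Cells are assigned to glands by the mask label under their rounded pixel
position (0-based coordinates, x = column, y = row, applied uniformly to
tables and masks). A gland is *eligible* for shape modeling when it holds
at least one N-CE cell and its pixel area per N-CE cell is at most
25,000 — an oversized gland with a few scattered basal-positive cells is
most plausibly a cancerous gland with gating noise, not a benign
structure. We read the threshold as area/count (exclude when the ratio
*exceeds* 25,000): that is the direction under which sparsely populated
structures are excluded.

For an eligible gland the N-CE cells are ordered along the Euclidean
minimum spanning tree: the ordering is the tree's diameter path (double
traversal), with off-path branch points inserted at their nearest path
vertex, nearest first. The MST itself is delegated to igraph; the
ordering logic is ours. This yields one continuous walk along the gland
contour even when the points branch.

The principal curve $\gamma(t)$ minimizes the mean squared distance
between the points and their projections. We alternate (i) cubic
smoothing-spline fits of $x(t)$ and $y(t)$ at df = 8 against the current
arc-length parameters with (ii) re-projection of the points onto the
sampled curve polyline (10 samples per input point). df = 8 balances
fidelity against over-smoothing for gland-scale structures. Numerical
choices: initial parameters are cumulative chord length along the MST
order; ties in the parameter are broken by an infinitesimal jitter; the
iteration stops on relative residual improvement below $10^{-4}$, at 20
iterations, or as soon as a step fails to improve the residual, in which
case the previous iterate is kept — the recorded residual trace is
therefore non-increasing by construction (the raw alternation carries no
such guarantee). For fewer than df + 1 points the df is lowered to n − 1
with a warning; for fewer than 4 points the curve is the ordered polyline
itself. Curves are fitted open, not periodic: a ring-shaped gland yields
an open curve covering the ring with a seam. The seam costs a little
accuracy where the ends meet and is the main known limitation of the
shape model.

The curve is expanded into a band of half-width 10 px as a Euclidean
dilation with round caps — a true union of per-segment perpendicular
strips would leave wedge gaps at vertices. Membership (distance to the
polyline ≤ 10) is boundary-inclusive; ties are measure-zero and
inclusivity is fixed for reproducibility. Final labels: an eligible gland
is an N-CE gland, its epithelial cells inside the band are N-CE and the
rest CE; an ineligible gland with any epithelial cell is a CE gland and
all its epithelial cells become CE; a gland without epithelial cells is
excluded. Cells outside every gland keep their mixture-model labels — band
relabeling never reaches across gland boundaries.

# Spatial features

Three feature families, computed per core and summarized per patient
(`coreSpatialFeatures()`, `summarizePatients()`):

* **Cell-centric**: distance from each T cell to the nearest CE gland
  *centroid* (unweighted mean of the label's pixel coordinates),
  summarized by the patient median. Units are micrometres at 0.325 µm per
  pixel — the value implied by a 6.5 µm camera pixel behind a 20×
  objective. The scale is overridable (`umPerPx`), and all geometry is
  internal in pixels with conversion applied at output.
* **Region-centric**: macrophage-dense (MD) regions are radius-linked
  clusters of CD68+ cells (eps = alpha, minimum 5 points) wrapped in an
  alpha-shape polygon; region area is the shoelace area of the outer ring
  minus any holes. The alpha default of 30 px (≈10 µm) is one
  cell-neighborhood radius; both alpha and the minimum cluster size are
  exposed because the clustering notion of "dense" is not canonical. The
  feature is the shortest boundary-to-boundary distance to a CE gland
  (mask contour, not the principal curve, since CE glands carry no fitted
  curve), summarized by the mean of natural-log areas.
* **Infiltration**: an MD region at distance 0 — its polygon intersects or
  is contained in a CE gland — counted per patient. The test is two
  independent predicates (edge intersection or containment), which are
  cross-checked in the test suite.

Our alpha shape uses the classical empty-disk edge criterion (a pair at
distance ≤ 2α is boundary iff one of the two α-disks through it is empty)
with ring assembly and a convex-hull fallback when the boundary does not
close cleanly. It is implemented in the package because no suitable
alpha-shape library is among our dependencies; it reduces to the convex
hull as α → ∞ and carves holes (e.g. a gland lumen ringed by macrophages)
out of the area.

Cores lacking a CE gland are unusable for these features and excluded
before patient summaries; a patient with no T cells of a phenotype gets a
missing median and is excluded from that phenotype's survival analysis
rather than imputed.

# Outcome statistics

* Composition-by-grade: Pearson χ² with a permutation null from cell-level
  grade shuffles (10,000 by default) and the add-one p-value
  $(1 + \#\{T^* \ge T\})/(1 + B)$, never exactly zero. Cell-level
  shuffling matches the method being emulated; a per-core block shuffle is
  available (`block =`) to acknowledge within-core correlation.
* Benjamini–Hochberg adjustment within presentation families
  (composition; AMACR; trends; survival).
* AMACR validation: two-sided permutation test of the difference in
  medians between CE and N-CE, pooled and per grade, plus the fold change
  as the ratio of linear-scale medians (a value above 1 means higher
  expression in CE).
* Grade trends: Kruskal–Wallis with tie correction (all-identical input
  returns H = 0, p = 1 rather than an error).
* Survival: patient features dichotomized at the cohort median with the
  ≥-goes-far convention, then Kaplan–Meier curves and the two-group
  log-rank test (via the survival package). Patients without recurrence
  are censored at last follow-up; administrative censoring at 60 months
  (5-year recurrence) is on by default and can be disabled
  (`censorAt = NULL`), since both conventions are defensible for a cohort
  described by its 5-year recurrence data.

All permutation seeds are explicit arguments; results are bit-reproducible
and the caller's RNG state is untouched.

# The synthetic tissue generator

`simulateCore()` emulates the data-generating regime the pipeline assumes,
with complete ground truth:

* **Geometry** on the physical 0.325 µm/px scale: glands are perturbed
  circles (radius 100–160 px, sinusoidal boundary wobble of relative
  amplitude 0.06 with 5 waves), placed without overlap. Benign glands are
  *rings*: basal N-CE cells spaced ~25 px along the boundary in a 12 px
  rim around an empty lumen. Cancerous glands are lumenless fills of CE
  cells at ~28 px spacing. Stromal cells scatter outside glands; T cells
  are placed at truncated-normal distances from gland boundaries
  (configurable mean/sd — this is the knob cohort simulation uses);
  macrophages arrive in Gaussian clusters whose centers may overlap gland
  boundaries, producing infiltration events.
* **Intensities** are two-component Gaussians in log2 space — the same
  generative family the classifier assumes, which makes parameter recovery
  a fair test. Foreground markers per true type: p63/CK5 for N-CE, AMACR
  for CE, CD3/CD4(±FOXP3) for T cells, CD68 for macrophages. The default
  background/foreground separation is 5 pooled sd (means 2 and 5.5, sd
  0.7), the regime that reproduces ≈99% gating specificity — the operating
  point at which the 25,000 px/cell gland rule discriminates. Raw linear
  intensities are stored as $\max(2^v - 1, 0)$ so the default transform
  recovers $v$ exactly. 60% of glands are cancerous (cancer-bearing cores
  are CE-dominated).
* **Reproducibility**: one seed per core, split into named substreams per
  sub-step, so changing the number of cells of one type does not perturb
  the draws of another; identical seeds give byte-identical cores.

`simulateCohort()` adds outcomes: each patient receives a latent spatial
feature (their T-cell placement-distance mean, µm), a grade group, and a
recurrence time drawn from an exponential with hazard
$h_0 \cdot m(\text{feature})$, administratively censored at a horizon
(default $h_0 = 0.02$/month, horizon 60 months, i.e. roughly 70% events
at baseline). With `coresPerPatient = 0` only features and outcomes are
generated, which is how the survival statistics are exercised at
realistic n without simulating hundreds of images.

**What the generator does not emulate** — and hence what passing tests do
not show about real tissue: segmentation errors and doublets, spatially
varying background and autofluorescence, heavy-tailed intensity outliers,
partial basal rims and touching glands, marker co-expression structure
beyond the phenotype rules, and any relationship between morphology and
grade. Tests against generator truth validate the *algorithms under their
stated assumptions*, not clinical performance.

# Problem sizes

The shipped tests and the acceptance script run, by choice, at: cores of
800–2000 px with 3–10 glands (up to ~2300 cells); EM recovery at n = 5000;
calibration studies of 500 null replicates (199 permutations each — the
smallest grid-aligned count, since rejection at α = 0.05 then has
probability exactly 10/200 under exchangeability); log-rank power at 400
patients × 100 replicates; and a 16-patient imaged cohort for the
end-to-end run. These sizes make every quantity measurably stable while
keeping a full run in minutes.

# Known limitations

* The open-curve seam on ring glands biases the curve near the ends; with
  the 10 px band this leaves a few percent of rim cells outside the band
  on strongly wobbled glands.
* The eligibility ratio cannot rescue very small CE glands (area below
  ~2× 25,000 px): one or two false basal calls already satisfy the ratio.
  This is a property of the published rule at its stated threshold, which
  we keep.
* Alpha-shape assembly falls back to the convex hull when the boundary
  graph is not a clean set of rings (α near the point spacing).
* The permutation χ² treats cells as exchangeable across a grade; cells
  within a core are correlated, so cell-level shuffling is anti-
  conservative on real cohorts. The block-shuffle option exists for that
  reason, and defaults off only to match the emulated method.
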