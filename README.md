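# glandmark

Annotation-free classification of cancerous versus non-cancerous
epithelial cells **and glands** in multiplexed immunofluorescence data of
prostate tissue, with spatial immune-geometry features and survival
statistics.

Benign prostate glands keep a basal cell layer (p63+, CK5+); its loss is a
hallmark of carcinoma. Given a per-cell table (coordinates, compartment,
marker intensities, QC fields) and a gland label mask, `glandmark`:

1. **Gates markers without manual thresholds.** Per marker, the log2
   intensities of epithelial cells are modeled as a Gaussian mixture
   f(x) = Σₖ πₖ N(x | μₖ, σₖ²) fitted by EM (ε = 1e-8, ≤1000 iterations);
   a cell is positive when the highest-mean component has the top
   posterior at its value. Basal markers combine by logical OR
   (Pᵢ = ⋁_b C_ib): positive epithelial cells are **N-CE**
   (non-cancerous), double negatives **CE** (cancerous). The same gating
   yields immune phenotypes (T_reg = CD3+CD4+FOXP3+, T_H = CD3+CD4+FOXP3−,
   macrophage = CD68+).
2. **Classifies whole glands.** A gland whose pixel area per N-CE cell is
   at most 25,000 has its N-CE cells ordered along the Euclidean minimum
   spanning tree's diameter path, a principal curve γ(t) fitted through
   them with cubic smoothing splines (df = 8, minimizing mean squared
   projection distance), and the curve expanded into a 10 px band: cells
   in the band are N-CE, the gland is an N-CE gland. Oversized, sparsely
   basal glands are CE glands and their epithelial cells relabel CE.
3. **Extracts spatial immune features.** T-cell distances to the nearest
   CE gland centroid (µm at 0.325 µm/px); macrophage-dense (MD) regions as
   alpha-shape polygons around CD68+ clusters with their areas and
   boundary distances to CE glands; infiltration events (distance 0).
   Patient summaries: medians, log-mean areas, infiltration counts.
4. **Links features to outcome.** Permutation χ² for composition by
   grade (10,000 shuffles, BH adjustment), two-sided permutation tests for
   AMACR between CE and N-CE, Kruskal–Wallis grade trends, and
   Kaplan–Meier/log-rank tests of biochemical recurrence with features
   dichotomized at the cohort median.

A synthetic tissue generator (`simulateCore()`, `simulateCohort()`)
produces ring-shaped benign glands, CE-filled glands, immune cells at
configurable distances, and exponential recurrence outcomes with full
ground truth, so every stage is testable without restricted patient data.

Intended users: computational pathology and spatial-proteomics analysts
working with segmented single-cell tables plus gland masks (Cell
DIVE-style multiplexed panels or similar).

## Worked example

```r
library(glandmark)

core <- simulateCore(simCoreConfig(seed = 3))
core$table
#> CellTable: 753 cells, core 'sim_core', patient 'sim_patient'
#>   markers (raw): p63, CK5, AMACR, CD3, CD4, CD8, CD68, FOXP3
#>   compartments: epithelial=288, stromal=465

tab <- normalizeLog2(applyQC(core$table)$table)
cls <- classifyCells(tab)                  # EM gating of p63 and CK5
cls$fits$p63
#> MixtureFit: K = 2, n = 288, 24 EM iterations (converged)
#>   component 1: pi = 0.7936, mu = -0.0244, sigma2 = 0.5020
#>   component 2: pi = 0.2064, mu = 3.3373, sigma2 = 0.4158
#>   final log-likelihood: -447.7725

table(cellData(cls$table)$cell_type)
#>     CE   N-CE stroma
#>    228     60    465

res <- classifyGlands(assignCellsToGlands(cls$table, core$mask), core$mask)
res$glands[, c("gland_id", "area_px", "n_nce", "ratio", "eligible",
               "gland_label")]
#>   gland_id area_px n_nce ratio eligible gland_label
#> 1        1   56906     0   Inf    FALSE          CE
#> 2        2   47525     0   Inf    FALSE          CE
#> 3        3   74816     0   Inf    FALSE          CE
#> 4        4   39989    28  1428     TRUE        N-CE
#> 5        5   50831    32  1588     TRUE        N-CE
```

Reading the output: the p63 mixture separates a background component
(μ ≈ 0 after median centering, 79% of epithelial cells) from a positive
component (μ ≈ 3.3); 60 basal-positive cells become N-CE. Three glands
contain no N-CE cells at all (ratio ∞ > 25,000) and are called CE; the two
ring glands carry 28 and 32 basal cells each (≈1,400–1,600 px per cell,
well under the threshold), get principal curves, and are called N-CE —
matching the generator's ground truth for this core.

The cohort-level entry point chains everything (QC → pooled mixture fits →
cell and gland labels → spatial features → statistics) and writes
deterministic CSV outputs:

```r
res <- runAll(seed = 1, nPatients = 16, outDir = "out")
```

A thin command-line front end with `simulate`, `classify`, `glands`,
`features`, `stats`, and `run-all` subcommands is installed at
`inst/exec/glandmark` (see its header for usage).

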