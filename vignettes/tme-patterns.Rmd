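---
title: "Immune activation and exclusion patterns from spatial transcriptomics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immune activation and exclusion patterns from spatial transcriptomics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`spatialtme` classifies lattice-based spatial transcriptomics samples of
tumor tissue into immune-activation versus immune-exclusion
microenvironments, working only from a spot × gene count matrix, spot
lattice coordinates and a gene-position table. This vignette is the
package's own account of the model: what each stage assumes, which
parameters matter, how the synthetic generator that backs the test suite is
built, and where the method's limits are.

```{r setup, eval = FALSE}
library(spatialtme)
```

## The pipeline at a glance

1. median-total scaling + `log1p` normalization;
2. PCA → shared-nearest-neighbor (SNN) graph → Louvain clustering of spots;
3. per-spot immune score = mean normalized expression of a fixed immune
   marker panel; the cluster with the highest median score becomes the
   copy-number-neutral reference;
4. expression-based CNV inference relative to that reference
   (center → clip → chromosome-window smoothing → six-state
   discretization → `|state − 3|` scoring → Ward subclustering → malignant
   cluster calls);
5. tumor-boundary extraction and the activation/exclusion call;
6. signature co-localization, TLS scoring, ligand–receptor communication
   with a permutation null, and survival/IHC statistics.

## Normalization and clustering

Counts are scaled per spot to a common total (the median library size by
default) and `log1p`-transformed. A regularized negative-binomial
regression would also be defensible here; we use median-total scaling
deliberately because every downstream quantity — immune scores, CNV
ratios, fold changes, communication scores — consumes *relative*
expression, and the simpler transform keeps the pipeline dependency-light
and exactly reproducible. Spots with zero counts stay in the matrix as
all-zero rows (with a warning) so that positions tables never go out of
alignment.

Highly variable genes are ranked by dispersion (variance/mean of the
normalized values), z-standardized within 20 gene-mean bins so selection is
not confounded by expression level; constant genes can never outrank a
variable gene. Clustering runs PCA on the scaled HVG submatrix (30
components by default, clipped with a warning on smaller inputs), builds a
k = 15 nearest-neighbor graph, weights edges by the Jaccard overlap of
neighbor sets (pruning below 1/k), and applies Louvain modularity
optimization at resolution 0.8. The community detection is seeded
(default 0), so runs are deterministic; labels are relabeled 0, 1, 2, …
by decreasing cluster size.

Marker detection is one-vs-rest per cluster: a gene is emitted only if
detected in at least `min_pct = 0.1` of either group and
`|avg_log2FC| ≥ 0.25`, where
`avg_log2FC = log2((mean(expm1(in)) + 1) / (mean(expm1(out)) + 1))` — the
+1 pseudocount bounds fold changes of lowly expressed genes. P-values come
from the Wilcoxon rank-sum test with Benjamini–Hochberg adjustment within
each cluster; clusters under 3 spots are skipped with a warning. Ties in
top-n signatures break by smaller p-value, then gene name.

## Immune score and reference selection

The immune score is the unweighted mean of normalized expression over one
pooled panel (pan-immune, T, B, myeloid markers); we read "average of the
marker values" as a single pooled mean rather than a mean of per-panel
means because the panel sizes are unbalanced (1 pan-immune vs 4 T-cell
genes) and the pooled mean is what the reference selection actually needs —
a monotone, low-variance ranking of spots by immune content. Genes missing
from the matrix are dropped, never zero-filled, so scores do not depend on
which extraneous genes a signature file happens to carry. Reference
selection takes the cluster with the highest *median* score (robust to a
tail of mixed spots); exact ties break toward the smaller label.

## CNV inference and malignant calling

Genes below a mean raw count of 0.1 are removed; the rest are centered on
the reference-spot mean and clipped to ±0.3. Clipping before smoothing is
the denoising step: a single outlier gene cannot drag a 101-gene window.
Smoothing is a centered moving average over the canonical gene order
(position table sorted by chromosome, then start), with windows shrinking
symmetrically at chromosome edges and never spanning chromosomes. The
101-gene default matches chromosomes carrying on the order of a hundred or
more mapped genes; on small simulated gene panels a proportionally smaller
window should be used (the tests do exactly that).

The six copy-number states come from deterministic symmetric thresholding
of the smoothed values at `clip × (−2/3, −1/3, 1/3, 2/3, 1)` — at the
default clip 0.3: state 1 below −0.2, state 2 in (−0.2, −0.1], state 3 in
the open interval (−0.1, 0.1), states 4 and 5 in [0.1, 0.2) and
[0.2, 0.3), state 6 at or above 0.3. The asymmetry (two loss states, three
gain states) mirrors the i6 convention in which state 3 is diploid. A
hidden-Markov state model could replace this mapping — the scoring only
consumes `|state − 3|`, so the state-assignment mechanism is swappable —
but thresholding is deterministic, parameter-free beyond the clip, and
sufficient for the score's purpose. Value 0 maps to state 3 exactly.

Per-gene CNV score is `|state − 3|`; per-spot scores sum over genes;
cluster scores sum the within-cluster mean per gene (so duplicating spots
changes nothing). Non-reference spots are Ward-clustered (Euclidean,
`ward.D2`) on the smoothed profiles and cut at k = 8; Ward linkage replaces
the random-trees partitioning of the reference tool because it is
deterministic. A cluster is malignant when its score exceeds
`theta × median` of cluster scores (theta = 2 by default); if none passes
and a unique top-scoring cluster with positive score exists, that cluster
is flagged (ties disable the fallback, and all-zero scores yield a warning
and no calls).

One failure mode is worth knowing: when the tumor's spots split across
three or four of the eight Ward clusters, those clusters pull the median up
and only the top one may clear `theta × median`, under-calling the tumor.
In the package's recovery study this affects a few percent of simulated
samples; the affected samples either lose sensitivity or (if the called
area becomes all boundary) fail the pattern call with an explicit error.
`theta` and `k` are configuration parameters precisely so analysts can
loosen the rule on fragmented samples.

## Boundary, tumor area and the pattern call

The boundary is defined by lattice adjacency only (4-neighborhood by
default; a 6-neighbor hex-like option adds one diagonal axis): the inner
ring is malignant spots touching a non-malignant neighbor, the outer ring
the reverse. The *tumor area* is the malignant spots plus any enclosed
non-malignant spots (hole-filling by flood fill from the lattice hull):
intra-tumor immune aggregates are exactly such holes, and excluding them
from the area would make an activation sample look immune-free inside its
own tumor. The interior is the area minus the inner ring.

The pattern call computes the sample-wide q-th percentile of the immune
score (q = 75) and measures `f_intra`, the interior fraction above it;
activation requires `f_intra ≥ f_min = 0.10`. Both q and f_min are our
operationalization of what is usually a visual call on score maps; they sit
in the configuration, and the call is monotone — raising interior immune
scores can only move a sample toward activation. A sample with zero
interior spots errors rather than guessing.

## Co-localization

Spot-level co-localization is Spearman correlation on mid-ranks (tie
corrected). For n ≤ 10 the two-sided p-value is exact, from the full
permutation distribution of the rank correlation; above that, the usual t
approximation on n − 2 degrees of freedom. Constant score vectors are an
error, not a zero.

## Ligand–receptor communication

The communication score from sender A to receiver B for a pair is the
product of A's mean normalized ligand expression and the geometric mean
over receptor subunits of B's mean normalized expression — a mass-action
simplification chosen because the downstream claims (role totals and
rankings) depend only on relative magnitudes. A zero subunit zeroes the
receptor (a complex missing one chain cannot signal), and ligands detected
in under `min_pct = 0.1` of sender spots score zero. The null permutes
cluster labels across spots; p-values use the add-one estimator
`(1 + #{perm ≥ obs}) / (n_perm + 1)`, so they are never zero and have
resolution `1/(n_perm + 1)`. Outgoing/incoming role totals conserve mass
exactly. The bundled pair table covers the SPP1 (CD44 and integrin
complexes), MIF (CD74-containing complexes), CCL19/CCL21 → CCR7 and
CXCL12 → CXCR4 axes; users supply their own table for anything broader.

## Survival and IHC statistics

Kaplan–Meier estimation and the two-group log-rank test use the standard
aggregated-risk-set formulations (via the survival package). The optimal
cutpoint is a maximally selected log-rank scan: every split leaving at
least `min_prop = 0.1` of records per side is scored by the standardized
log-rank statistic and the maximizer is returned. The reported p-value is
the plain log-rank p at the chosen split, with a warning that selection
inflates type-I error — the scan is meant for stratification, not for
inference on the cutpoint, and the package's null study demonstrates the
inflation rather than hiding it. The Mann–Whitney U test is exact (full
enumeration over label assignments, symmetric two-sided rule) up to a
combined n of 12 and a tie-corrected normal approximation without
continuity correction beyond. The IHC composite is the exact product of
the intensity (0–3) and positive-area (0–4) categories, range 0–12.

## The synthetic generator

The generator emulates the tissue architecture the pipeline targets on a
square lattice: a central circular tumor core covering `tumor_fraction` of
the area (25% by default), a boundary immune ring (width 4 steps), a
stromal band (width 2), surrounding normal tissue, and — in the activation
pattern only — three intra-tumor immune aggregates of radius 2.5 placed
within half the tumor radius. Counts are negative binomial with a single
global dispersion (size 2) around means proportional to per-gene baseline
rates (gamma-distributed), modulated by planted structure and scaled to a
log-normal library size (mean 5000). Planted structure:

* **CNV segments** (count multipliers in tumor spots only): by default a
  2.0× gain, a 0.5× loss and a 1.75× gain, each spanning 40% of a
  150-gene chromosome, on chromosomes that carry no marker panels — so CNV
  recovery and immune scoring stay identifiable, and the configuration
  validates that separation.
* **Marker panels** with fold-elevation in their regions: the 10-gene
  immune panel (8×) and receptor panel (4×) in immune regions, a
  fibroblast-chemokine and a plasma-cell panel (6×), and a tumor-ligand
  panel (SPP1, MIF, DKK1; 6×) in tumor spots.
* **Co-localization**: a shared bivariate-normal latent factor with
  correlation `coloc_rho` scales the two designated panels' means through a
  unit-mean log-normal link (`sigma` 0.6). The recovered Spearman
  correlation is attenuated by count noise, so recovery tests compare
  against a Monte-Carlo rendering of the same model at large n rather than
  against `coloc_rho` itself.

One master seed drives separate named RNG streams (layout, counts,
co-localization latent, survival, IHC), so identical configurations
reproduce byte-identical samples and each stage can be re-drawn
independently. The survival generator draws exponential event times with
rate multiplied by `hazard_ratio^z` for standardized log-expression z of
one effect gene, with independent exponential censoring calibrated to the
requested censoring fraction; the IHC generator draws intensity and area
categories from group-shifted latent-normal distributions.

What the generator does **not** emulate — and what passing tests therefore
cannot certify on real data: hexagonal Visium geometry (the neighborhood
logic supports 6-neighbor adjacency, but the generator lays out a square
lattice), per-spot cell-type mixtures and deconvolution, spatial bleed-over
between spots, gene-specific dispersion and zero inflation, batch and
section effects, irregular tumor shapes and multifocal tumors, and any
realistic gene-gene correlation beyond the planted panels. The region
geometry itself (circle + rings + aggregates) is our construction; real
activation/exclusion architectures are not quantitatively defined anywhere
we could borrow from.

## Study sizes and numerical conventions

The package's simulation studies use 30 × 30 lattices (900 spots, ≥ 150
tumor spots each) with the default 900-gene panel: 50 samples for
malignant-spot recovery (asserting mean sensitivity and specificity
≥ 0.90), 100 samples split between patterns for classification accuracy
(asserting ≥ 0.95), one ~1000-spot sample against a 20,000-spot
Monte-Carlo target for co-localization (±0.1), 28 structure-free datasets
× 36 pair-tests for permutation-test calibration and 500 null cohorts for
log-rank calibration (both asserting a rejection rate within 0.05 ± 0.02).
These sizes are the package's chosen study conditions; they are small
enough to re-run routinely and large enough that the asserted margins are
several binomial standard errors wide.

Conventions worth restating: gene positions are 1-based inclusive
(GTF-style) and lattice coordinates 0-based; gene matching is by
case-sensitive symbol; genes absent from the position table are excluded
from CNV smoothing with a message, not an error; chromosome labels sort
naturally (chr2 before chr10); all tabular outputs are tibbles and all
file outputs are UTF-8 text (MatrixMarket, TSV, CSV, JSON).

## Known limitations

* The malignant-calling rule (`theta × median`) is brittle when Ward
  subclustering fragments the tumor (documented above).
* The pattern rule reduces a rich spatial phenotype to one fraction; q and
  f_min were fixed once against the generator's geometry and have not been
  validated against pathologist calls on real tissue.
* Expression-based CNV inference cannot see copy-neutral events and is
  confounded by strong transcriptional programs; on real data the
  malignant calls should be reviewed against histology, a step that is
  manual by nature and out of the package's reach.
* The communication score ignores receptor co-factor logic, signaling
  cascades and spatial proximity; it ranks axes, it does not estimate
  biophysical flux.
* The post-selection survival p-value is intentionally uncorrected and
  flagged; treat it as descriptive.
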