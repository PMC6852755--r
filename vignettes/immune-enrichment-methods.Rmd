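---
title: "Methods: signature-based immune cell enrichment for bulk transcriptomes"
author: "immunoscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature-based immune cell enrichment for bulk transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunoscope)
```

## The problem

Bulk expression profiles of inflamed tissue — for instance colonic biopsies
from patients with Crohn's disease or ulcerative colitis — are weighted
averages over every cell type in the sample. A shift in a bulk profile can
therefore reflect a change in cellular composition rather than
transcriptional reprogramming. `immunoscope` estimates the *relative
enrichment* of immune cell types from such mixtures using cell-type gene
signatures: sets of genes that are coordinately high in one sorted cell
population. The package does not attempt full compositional deconvolution;
it follows the enrichment-score school (GSEA/ssGSEA, as popularized for
immune profiling by signature compendia such as xCell), which is more
robust to platform and normalization differences because it works on ranks.

Four questions drive the design, mirroring a typical IBD study layout:

1. Which cell types are enriched in inflamed versus non-inflamed tissue
   (two-sample GSEA per signature, averaged per cell type)?
2. How does enrichment vary per sample and with disease severity
   (single-sample scores plus rank-based group tests)?
3. Do cell-type signatures predict treatment non-response (median
   signature expression as a classifier score, evaluated by ROC/AUC)?
4. Which signatures co-vary with each other and with inflammatory marker
   panels (Spearman correlation with common-gene removal)?

## Preprocessing

Within each dataset, samples are standardized by **quantile
normalization**: every column is mapped onto the mean of the column-sorted
value vectors. Tied values receive the mean of the reference values over
their tied rank positions, so equal inputs remain equal. Two consequences
worth knowing:

* On tie-free data the transform is exactly idempotent and all
  post-normalization columns share one sorted vector — both are tested to
  1e-12.
* With ties, a tied block absorbs the mean of its reference segment, so a
  second pass can move *untied* columns by a small amount at the tied
  ranks. Expression intensities are effectively continuous, which is why
  the contract is stated (and checked) on tie-free input.

Normalization is performed once per dataset, before any stratification
(e.g. by gut location); stratified analyses subset the already-normalized
matrix. Gene identifiers are matched case-insensitively after whitespace
stripping throughout, and duplicate gene rows collapse by per-sample
maximum — the common probe-collapse convention, declared rather than
inferred, since array probe handling is out of scope.

## Two-sample enrichment

Genes are ranked by the **signal-to-noise ratio**
$r = (\mu_A - \mu_B)/(\sigma_A + \sigma_B)$, with each group's standard
deviation floored at $\max(0.2\,|\mu|,\,10^{-8})$ so that near-constant
genes cannot produce unbounded statistics. The metric is configurable
(`log2fc`, `tstat`) because the upstream literature rarely states its
choice; signal-to-noise is the default of the GSEA family. Ties in the
metric are broken by gene identifier in C-locale order, making the ranking
deterministic.

The **enrichment score** of a signature is the classical weighted
Kolmogorov–Smirnov running sum: walking the list from top to bottom, a
signature gene ("hit") adds $|r_i|^p / \sum_{hits} |r_j|^p$ (weight
$p = 1$ by default), a miss subtracts $1/(N - N_{hit})$, and ES is the
signed extremum of the walk. Numerical conventions:

* If every hit weight is zero (a degenerate all-flat ranking), hit mass
  falls back to uniform $1/N_{hit}$.
* When the positive and negative extrema tie in magnitude (within 1e-9
  relative — exact ties occur for symmetric profiles), the positive
  extremum is reported. Without a fixed rule the sign would be decided by
  floating-point summation order.
* A signature overlapping the whole universe has no miss mass and is
  rejected ("empty complement"); overlaps below `min_overlap = 5` genes
  are skipped with a warning. The source compendium is itself filtered to
  signatures with at least 15 genes (`filter_signatures()`), but an
  overlap floor is still needed after intersecting with a matrix.

Significance uses **phenotype permutation**: group labels are permuted,
the full ranking is recomputed, and every signature is re-scored on each
permuted ranking (permutations are shared across signatures, as in the
standard implementation). The normalized enrichment score divides the
observed ES by the mean |ES| of same-sign permutations, and the nominal p
is one-sided on the observed sign with +1 smoothing,
$p = (1 + \#\{|ES_{perm}| \ge |ES|\}) / (1 + \#\,\text{same-sign})$, so p
can never be zero and is bounded below by $1/(n_{perm}+1)$. When the
number of distinct label assignments is at most `n_perm` (3 vs 3 gives
20), the null is enumerated exhaustively and the p-value is exact. Groups
smaller than 7 proceed with a warning that the permutation null is coarse
rather than silently switching to a gene-set null. Per-signature p-values
are reported raw (with an optional Benjamini–Hochberg column), matching
the starred-figure convention of the field; NES and p are then averaged
over each cell type's signatures.

## Single-sample scores

`ssgsea_score()` computes the rank-weighted single-sample statistic: per
sample, genes are ranked by descending expression (average ranks on ties);
the score is the summed difference between the cumulative hit mass —
weighted by $\mathrm{rank}^{\alpha}$, $\alpha = 0.25$ — and the cumulative
miss mass. The score depends only on within-sample ranks, so any strictly
increasing transform of one sample's values leaves its scores unchanged
(tested exactly). Cell-type scores average the member signatures; min–max
rescaling to [0, 1] is available for presentation.

This raw ssGSEA statistic deliberately stands in for xCell-style scores:
xCell's calibration-curve transform and spillover compensation require
externally trained matrices tied to their compendium and are out of scope.
The consequence is that scores are comparable across samples *within* a
dataset, not across platforms, and are relative enrichments, not cell
fractions.

Group differences in scores use the two-sided **Mann–Whitney** test (exact
null when the combined n is at most 12 and untied, normal approximation
with tie correction otherwise) — score distributions are bounded and
skewed, so a rank test is safer than a t-test. Stars follow the usual
thresholds (\* p < 0.05, \*\* p < 0.01), uncorrected, with an optional BH
column.

## Treatment-response prediction

A signature's prediction score for a sample is the **median expression of
its member genes** present in the matrix. Classification performance for
non-response is summarized by ROC/AUC with the non-responder label as the
positive class and higher score ⇒ predicted non-response (the enrichment
direction observed for myeloid signatures); the orientation is
configurable and recorded in the output. The AUC is computed through the
rank/Mann–Whitney identity with ties counting 1/2, and the ROC point
sequence walks all distinct thresholds so that its trapezoidal area equals
the rank AUC to 1e-12 (both facts are tested against brute-force pair
counting). Cell-type AUCs average the member signatures' AUCs and are
reported as a descending top-k table. Pre- and post-treatment samples are
scored separately by default — pooling is opt-in — because response
markers can differ by timepoint.

## Association analyses

`pairwise_spearman()` correlates signatures (and named marker panels such
as the built-in proinflammatory cytokine panel) across samples. Two rules
matter:

* **Common-gene removal**: genes shared by a pair are removed from *both*
  members before each side is reduced to its per-sample median, so an
  observed correlation cannot be driven by literal gene sharing. The
  symmetric interpretation is the conservative reading of "after removing
  common genes"; the gene sets actually used are provably disjoint
  (tested). A pair left empty after removal yields a missing value with a
  warning; diagonal entries are 1 by convention and flagged `self`.
* Spearman's rho uses average ranks on ties and is validated against a
  rank-then-Pearson oracle.

`panel_group_medians()` summarizes a marker panel (e.g. myeloid
chemokines) per sample group with pairwise Mann–Whitney stars.

## The synthetic cohort generator

Because the motivating analyses run on controlled-access clinical
cohorts, every stage is validated by **parameter recovery** on synthetic
data with known ground truth. The generator emulates exactly the structure
the enrichment model assumes:

* each of 8 cell types owns 2 disjoint 30-gene signatures (within a
  2000-gene universe by default);
* a cell type's archetype profile is a $N(6, 1)$ log2 background with its
  own signature genes elevated by $\delta = 2$ log2 units;
* per sample, cell-type fractions are drawn from a group-specific
  Dirichlet (base concentration 2 per type; a shifted type's concentration
  is multiplied, ×4 by default, raising its mean fraction from ~12.5% to
  ~36%);
* the bulk profile mixes archetypes on the *linear* scale — expression
  adds in transcript space — then is log2-transformed and perturbed with
  additive Gaussian noise (sd 0.5). Post-log noise is a simplification
  that is sufficient for rank-based statistics.

Defaults (40 samples in two groups of 20, δ = 2, noise sd 0.5) are the
study conditions under which the recovery properties are stated: the
spiked cell type attains positive mean NES with mean p below 0.05, and
Spearman correlation between each cell type's true fraction and its
aggregated single-sample score exceeds 0.8. Null calibration (δ = 0, no
fraction shift) uses a reduced design — 500 genes, 4 cell types, 10 vs 10
samples, 200 permutations, 200 replicates — chosen as the smallest cohort
at which the per-signature type-I error is measured stably; the observed
rejection rate at p < 0.05 sits near the nominal level.

What the generator does **not** emulate: probe-level noise and platform
effects, correlated gene–gene noise within cell states, partially
overlapping real-world signatures (overlap can be injected explicitly with
`overlap_injection()`), and cell states absent from the signature
compendium. Passing recovery tests therefore demonstrates correctness of
the statistical machinery on data satisfying the model's assumptions, not
robustness to everything real biopsies do.

### Compositional closure and "unperturbed" cell types

One genuine property of convex mixtures deserves emphasis. Fractions sum
to one, so elevating monocytes from ~12.5% to ~36% of the mixture
*necessarily* depletes every other type by about a quarter of its share.
In responder/non-responder cohorts built this way, the signatures of
non-elevated cell types are genuinely (negatively) informative about
response: their cell-type AUCs concentrate around 0.40 rather than 0.50,
and with seven such types measured on 20 vs 20 samples the minimum
regularly falls near 0.30. This is real signal induced by closure, not an
artifact of the scoring; an analysis expecting non-elevated types to be
exactly random classifiers would only hold if compositions were
unconstrained. The acceptance checks report both the mean and the minimum
unperturbed AUC so this behaviour is visible rather than hidden.

## Worked example

```{r example, eval = FALSE}
set.seed(1)
ds <- simulate_cohort(simulation_config(seed = 1))
res <- gsea(ds$expression, ds$metadata, ds$signatures,
            group_a = "inflamed", group_b = "non_inflamed",
            n_perm = 1000, seed = 1)
aggregate_by_cell_type(res)

scores <- ssgsea_score(ds$expression, ds$signatures)
ct <- aggregate_cell_type_scores(scores, ds$signatures)
compare_groups(ct, ds$metadata)
```

The same stages run from one config via `run_pipeline()`, which writes
per-stage TSVs and a JSON manifest; identical config and seed reproduce
byte-identical numeric outputs.

## Known limitations

* Enrichment scores are relative, unit-free and dataset-internal; they are
  not cell fractions and should not be compared across platforms.
* Raw microarray processing (CEL files, probe annotation) is out of scope;
  inputs are expression tables already summarized to gene symbols.
* The permutation null is coarse for very small groups; exhaustive
  enumeration mitigates this only when the label-assignment space is
  small.
* No cross-signature multiple-testing correction is applied by default
  (BH columns are provided); starred summaries inherit the usual caveats
  of unadjusted screening.
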