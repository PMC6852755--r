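# immunoscope

Signature-based immune cell enrichment analysis for bulk transcriptomes.

Bulk expression profiles of inflamed tissue — e.g. colonic biopsies from
IBD patients — are mixtures over all cell types present, so expression
shifts often reflect changes in cellular composition. `immunoscope`
quantifies the relative enrichment of immune cell types (monocytes,
macrophage subsets, dendritic cell subsets, lymphocytes, ...) from
cell-type gene signatures, for analysts comparing patient groups —
inflamed vs non-inflamed tissue, disease-severity grades, or treatment
responders vs non-responders.

## What it computes

For an expression matrix $X$ (genes × samples), sample annotations and a
signature collection (GMT), the package provides:

* **Quantile normalization** of each dataset (tied values get the mean of
  the reference values at their tied ranks).
* **Two-sample GSEA** per signature: genes ranked by signal-to-noise
  $r = (\mu_A-\mu_B)/(\sigma_A+\sigma_B)$ (sd floored at
  $\max(0.2|\mu|, 10^{-8})$); enrichment score = signed extremum of the
  weighted Kolmogorov–Smirnov running sum (hit mass
  $|r_i|^p/\sum_{hits}|r_j|^p$, miss mass $1/(N-N_{hit})$); significance
  from phenotype permutation with
  $NES = ES / \overline{|ES_{perm}^{same\,sign}|}$ and
  $p = (1+\#\{|ES_{perm}|\ge|ES|\})/(1+\#\,same\,sign)$, enumerated
  exhaustively when the label-assignment space fits the permutation
  budget. NES and p are averaged per cell type.
* **Single-sample (ssGSEA) scores** with rank weight $\alpha = 0.25$,
  cell-type aggregation, min–max rescaling, and Mann–Whitney group
  comparisons with significance stars.
* **Treatment-response prediction**: a signature's score is the median
  expression of its genes; performance is ROC/AUC via the rank identity
  (ties count 1/2), averaged per cell type into a top-k table.
* **Association**: pairwise Spearman correlation of signature/panel
  median scores after removing genes shared by each pair from both sides;
  built-in proinflammatory and chemokine marker panels; panel group
  medians with rank tests.
* **Synthetic cohorts**: bulk samples as noisy convex mixtures of
  cell-type archetypes with Dirichlet-distributed fractions and known
  ground truth, so every stage is testable by parameter recovery.

`run_pipeline()` orchestrates all stages from one config (R list or YAML)
and writes TSV outputs plus a JSON manifest; identical config + seed give
byte-identical numeric outputs.

## Worked example

Simulate the default cohort (40 samples, 8 cell types, monocyte fraction
elevated in the "inflamed" group) and test which cell types are enriched:

```r
library(immunoscope)

ds <- simulate_cohort(simulation_config(seed = 1))
res <- gsea(ds$expression, ds$metadata, ds$signatures,
            group_a = "inflamed", group_b = "non_inflamed",
            n_perm = 1000, seed = 1)
aggregate_by_cell_type(res)
#>        cell_type mean_nes  mean_p n_signatures
#> 1      Monocytes    1.876 0.00195            2
#> 2 Macrophages.M1   -0.745 0.73252            2
#> 3 Macrophages.M2   -0.267 0.61459            2
#> 4            aDC   -1.132 0.33050            2
#> 5            pDC    0.636 0.84146            2
#> 6    CD4.T.cells   -1.011 0.48521            2
#> 7    CD8.T.cells   -1.172 0.34580            2
#> 8        B.cells   -1.132 0.33486            2
```

The spiked cell type (Monocytes) is recovered with a strongly positive
mean normalized enrichment score and mean p ≈ 0.002; all other cell types
stay non-significant. The same machinery predicts treatment non-response
when monocytes are elevated in non-responders:

```r
cohort <- simulate_cohort(simulation_config(
  group_sizes = c(NR = 20, R = 20),
  shift = list(NR = c(Monocytes = 4)),
  response_map = c(NR = "NR", R = "R"), seed = 1))
ms <- median_signature_score(cohort$expression, cohort$signatures)
ca <- cell_type_auc(signature_auc(ms, cohort$metadata, positive = "NR"),
                    cohort$signatures, top_k = 5)
ca
#>        cell_type   auc n_signatures
#> 1      Monocytes 0.981            2
#> 2            pDC 0.552            2
#> 3 Macrophages.M2 0.374            2
#> 4            aDC 0.374            2
#> 5 Macrophages.M1 0.356            2
```

Monocyte signatures classify non-responders nearly perfectly (AUC 0.98).
Note the non-elevated cell types sitting slightly *below* 0.5: fractions
sum to one, so elevating monocytes genuinely depletes the other types —
their signatures carry negative information about response. See the
methods vignette (`vignettes/immune-enrichment-methods.Rmd`) for the full
model, parameter meanings and limitations.

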