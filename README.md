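# trgtools

Tools for studying **taxonomically restricted genes** (TRGs) — genes with
no detectable homology outside a narrow set of closely related species —
and in particular for asking what distinguishes the rare *essential* TRGs
from the nonessential majority. Although TRGs encode novel protein
sequences, essential TRGs turn out to look remarkably like deeply
conserved essential genes: they are coexpressed with core functional
modules, sit in actively transcribed genomic neighbourhoods, make many
protein–protein interactions, and are enriched in rapidly evolving core
machineries such as chromosome segregation. trgtools packages that whole
analysis as composable, tested R functions.

## What it computes

* **TRG classification** from BLAST-style homology hit tables: a gene is
  a TRG iff it has no out-of-lineage hit with E < 10⁻⁶ over > 30% of the
  query protein length *and* encodes no annotated domain
  (`classify_trg()`), plus relaxed-cutoff sensitivity scans
  (`relaxed_scan()`), per-genome best-hit profiles
  (`best_hit_profile()`), and the four analysis classes TRG-E / TRG-NE /
  Shared-E / Shared-NE (`assign_four_classes()`).
* **Coexpression pathway features**: per gene pair, Pearson correlations
  are Fisher Z-transformed, *z* = ½ log((1+r)/(1−r)), averaged across
  expression datasets, then averaged over pathway members to one number
  per (TRG, pathway) (`pairwise_mean_z()`, `pathway_features()`).
* **Essentiality prediction**: elastic-net logistic regression
  (α = 0.5) fit by coordinate descent, scored by cross-validated ROC
  AUC over a λ path, with single-feature AUC rankings
  (`fit_enet_logistic()`, `cross_validated_auc()`,
  `single_feature_auc()`).
* **Genomic context**: expression of genes 1–3 positions away
  (`neighbor_expression()`) and base-weighted median chromatin signal in
  gene-body ± 5 kb windows (`window_median_signal()`), compared between
  classes by Wilcoxon rank-sum tests.
* **Interaction networks**: degree comparisons, Markov Clustering
  (inflation 1.5) and hypergeometric TRG enrichment of clusters with
  more than 30 members, Bonferroni-corrected (`degree_compare()`,
  `mcl_cluster()`, `enrich_clusters()`, `enrich_sets()`).
* **Protein features and rates**: Kolmogorov–Smirnov comparisons of
  predicted ordered fraction, χ² comparisons of coiled-coil prevalence,
  and per-functional-class dN/dS reports with TRG proportions
  (`disorder_compare()`, `coiled_coil_compare()`,
  `class_rate_analysis()`).
* **A synthetic-data generator** (`world_config()`, `generate_world()`)
  that emulates every input format with planted effects and full ground
  truth, so the entire pipeline is testable without any download.

All functions take tibbles and return tibbles (or small S3 objects with
`tidy()`/`glance()`/`autoplot()` methods), so stages chain with the pipe.

## Worked example

```r
library(trgtools)

w <- generate_world(world_config(seed = 1))   # synthetic inputs + truth
report <- run_stages(w, params = list(seed = 1))
report
#> TRG pipeline report
#> # A tibble: 4 × 2
#>   four_class     n
#>   <chr>      <int>
#> 1 TRG-E         60
#> 2 TRG-NE       240
#> 3 Shared-E     280
#> 4 Shared-NE   1420
#> classifier cv_auc: 1
#> network: 15 clusters; 1 TRG-enriched after Bonferroni

report_headline(report)
#> # A tibble: 1 × 8
#>   p_coexpression p_neighbor p_chromatin p_degree  p_disorder p_coiled_coil
#>            <dbl>      <dbl>       <dbl>    <dbl>       <dbl>         <dbl>
#> 1       9.13e-32   4.99e-12    3.16e-32 2.96e-17 0.000000309      1.50e-13
#>   n_enriched_clusters cv_auc
#> 1                   1      1
```

Reading the headline row: each `p_*` column is the TRG-E vs TRG-NE
comparison for one planted effect (strongest Bonferroni-corrected
pathway coexpression difference, flanking-gene expression one position
away, activation-mark window medians, interaction degrees, ordered
fraction, coiled-coil prevalence) — all far below 0.01, as planted.
Exactly one MCL cluster is significantly TRG-enriched after Bonferroni
(the planted block), and the elastic-net classifier separates essential
from nonessential TRGs with a cross-validated AUC of 1.0 on this clean
simulated compendium.

The same pipeline runs from files on disk: `write_world(w, "world/")`
emits BLAST-tabular hits, BED6 loci, bedGraph tracks, GMT gene sets and
TSV tables, and `run_pipeline("run.yaml", out_dir = "report/")` consumes
a config pointing at any such inputs (only hits, lineage and the
essential-gene list are mandatory; missing optional inputs skip their
stage with a logged reason).

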