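# droughtmem

Transcriptional drought-memory analysis for recurring-dehydration RNA-seq
designs, with the physiological water-status indices that accompany them.

## The scientific problem

Plants exposed to a drought often respond differently to the *next* drought
— "drought memory". In a control / first-stress / third-stress design
(R0, S1, S3), a gene's memory behaviour is captured by the sign pattern of
two differential-expression contrasts, S1 vs R0 and S3 vs S1. Writing `+`,
`−` and `=` for significantly up, significantly down and no significant
change, every gene falls into one of nine trajectory categories:

- **memory genes** `[+/+]`, `[−/−]`, `[+/−]`, `[−/+]` — drought-responsive
  and changed *again* at the later stress (e.g. `[+/−]` is
  R0 < S1 > S3);
- **non-memory genes** `[+/=]`, `[−/=]` — responsive once, then flat;
- **late-response genes** `[=/+]`, `[=/−]` — flat at first, responsive at
  the third stress;
- `none`.

Significance uses adjusted p < 0.05 with |log2 fold change| ≥ 1, from an
internal negative-binomial Wald caller (median-of-ratios normalisation,
method-of-moments dispersion, BH adjustment); externally produced contrast
tables can be substituted. Downstream, the package:

- builds the standard summary table with its exact percentage bases
  (memory/non-memory as % of responsive genes, late response as % of all
  genes, half-up rounding to one decimal);
- partitions drought-memory orthogroups into shared / species-unique /
  ecotype-unique hierarchies from an OrthoFinder-style `Orthogroups.tsv`;
- tests term over-representation with the upper-tail hypergeometric
  distribution and BH correction;
- screens for transcription-factor **"molecular switch" modules**: gene
  sets whose members correlate with one regulator at Pearson r > 0.9
  (p < 0.05) and with another at r < −0.9, as if toggled between on and
  off by the pair;
- ranks interaction-network hubs by degree and maximal clique centrality,
  MCC(v) = Σ over maximal cliques C ∋ v of (|C|−1)!;
- computes leaf relative water content, RWC (%) = (FW−DW)/(TW−DW)×100, and
  water loss (g/g) = (FW−wilted)/DW, with per-stage group comparisons;
- simulates complete datasets with planted trajectory categories, switch
  modules and physiology, so the whole pipeline is testable offline.

It is aimed at plant-stress transcriptomics practitioners who want the
drought-memory classification and switch screen as tested, scriptable
building blocks rather than one-off analysis code.

## Worked example

```r
library(droughtmem)

sim <- simulate_drought_memory(sim_config(n_genes = 2000,
                                          n_replicates = 3, seed = 42))
res <- run_pipeline(sim)
res
#> Drought-memory pipeline run
#> # A tibble: 7 × 2
#>   stage          n
#>   <chr>      <int>
#> 1 genes       2000
#> 2 deg_s1       252
#> 3 dmg_memory    90
#> 4 regulatory     4
#> 5 functional    86
#> 6 edges        121
#> 7 modules        3
```

2,000 simulated genes yield 252 drought-responsive genes at S1, 90 of which
are memory genes; 4 planted regulators among them give 121 retained
co-expression edges and 3 signed signature groups. The classification
summary reproduces the standard table layout:

```r
res$summary
#> Drought-memory classification summary (2000 total genes)
#> # A tibble: 14 × 5
#>    group            category      count percent percent_base
#>  1 drought_response DEG             252    12.6 total_genes
#>  7 memory           memory           90    35.7 DEG
#>  8 memory           [+/+]            29    32.2 memory
#> 10 memory           [+/-]            27    30   memory
#> 12 late_response    late_response    59     2.9 total_genes
#> ...
```

and the two largest detected modules are the two planted ones — one
regulator pair controlling 28 genes positively/negatively and the mirrored
signature of the same pair on 13 genes:

```r
res$modules
#> # A tibble: 3 × 6
#>   module signature         positive_tfs negative_tfs members    n_members
#> 1      1 g01173:-|g01732:+ <chr [1]>    <chr [1]>    <chr [28]>        28
#> 2      2 g01173:+|g01732:- <chr [1]>    <chr [1]>    <chr [13]>        13
#> 3      3 g00296:-|g01068:+ <chr [1]>    <chr [1]>    <chr [9]>          9
```

Each stage is also exposed directly — `nb_test()`, `classify_all()`,
`dmg_summary()`, `partition_orthogroups()`, `enrich()`, `correlate()` /
`filter_edges()` / `detect_switch_modules()`, `mcc_score()`,
`relative_water_content()`, `summarize_physiology()` — all taking and
returning tibbles, with `tidy()` / `glance()` methods and
`autoplot()` / `plot_*()` figures.

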