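---
title: "Methods: trajectory-based drought-memory analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory-based drought-memory analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droughtmem)
```

# The experimental design and the model

`droughtmem` analyses recurring-dehydration transcriptome experiments in
which plants are sampled under well-watered control conditions (R0), at the
end of a first dehydration (S1) and at the end of a third dehydration (S3),
with biological replicates at each point. The central idea of transcriptional
drought memory is that a drought-responsive gene may respond *differently*
to a later stress than it did to the first one. Two differential-expression
contrasts — S1 vs R0 and S3 vs S1 — give each gene a pair of calls in
{up, down, ns}, and the pair maps onto nine trajectory categories:

| category | trajectory | group |
|---|---|---|
| `[+/+]` | R0 < S1 < S3 | memory |
| `[-/-]` | R0 > S1 > S3 | memory |
| `[+/-]` | R0 < S1 > S3 | memory |
| `[-/+]` | R0 > S1 < S3 | memory |
| `[+/=]` | R0 < S1 = S3 | non-memory |
| `[-/=]` | R0 > S1 = S3 | non-memory |
| `[=/+]` | R0 = S1 < S3 | late response |
| `[=/-]` | R0 = S1 > S3 | late response |
| `none` | no significant change | — |

Here `=` means "not significant at the DEG thresholds", never numerical
equality. The second symbol compares S3 with **S1** (the chained
inequalities above), which is the default; callers preferring an S3-vs-R0
second contrast can simply pass that contrast to `classify_all()`.

Summary percentages follow the conventional bases: drought-responsive genes
(DEGs; memory plus non-memory categories) as a share of all genes, memory
and non-memory totals as shares of DEGs, each memory subtype as a share of
memory genes, and late-response genes as a share of all genes. Printed
percentages are half-up rounded to one decimal (`round_half_up()`), matching
how such tables are typically formatted.

# Differential expression: an internal NB Wald caller

The classifier consumes calls at adjusted p < 0.05 and |log2 fold change|
>= 1 (strict `<` on the adjusted p, `>=` on the fold change). Calls are
produced by a deliberately transparent negative-binomial pipeline rather
than a heavyweight external dependency:

1. **Normalisation** — median-of-ratios size factors: a geometric-mean
   reference over genes expressed in every sample, then the per-sample
   median of count/reference ratios. If no gene is expressed everywhere the
   caller falls back to library-size factors with a warning.
2. **Dispersion** — per-gene method of moments,
   $\hat\alpha = \max\{0, (s^2 - \bar\mu)/\bar\mu^2\}$, pooled across the
   two groups and floored at 1e-8. There is no shrinkage across genes; this
   is a documented simplification, and `read_contrast()` accepts externally
   produced contrast tables (e.g. DESeq2 output) wherever a moderated caller
   is preferred.
3. **Test** — Wald statistic on the difference of log2 group means with a
   delta-method standard error from the NB variance $\mu + \alpha\mu^2$;
   two-sided normal p-values; Benjamini–Hochberg adjustment across all
   tested genes. Genes with all-zero counts in both groups are excluded and
   reported. The reported log2 fold change carries a 0.5 pseudo-count on
   both group means (to avoid infinities at zero counts); the test statistic
   does not.

Exchanging baseline and comparison negates the fold change and swaps
up/down calls; ties exactly at the thresholds are not called.

# Water-status physiology

Leaf records carry fresh (FW), turgid (TW), wilted and dry (DW) weight, and
must satisfy 0 < DW <= wilted <= FW <= TW (violations are rejected
per-record, never clipped). Two indices are computed:

- relative water content, RWC (%) = (FW − DW)/(TW − DW) × 100;
- water loss of isolated leaves (g/g) = (FW − wilted)/DW.

`summarize_physiology()` reports mean ± SD and n per (ecotype, stage), a
one-way ANOVA across stages within each ecotype, pairwise Welch t-tests
rendered as a compact letter display, and per-stage between-ecotype t-tests
flagged at 0.05/0.01. Pairwise p-values are used raw by default — the
superscript-letter convention in this field ordinarily reports unadjusted
0.05-level tests — with `p_adjust = "BH"` available when a corrected display
is wanted.

# TF "molecular switch" detection

The analysis splits drought-memory genes into regulatory genes (a supplied
TF/TR list) and functional genes, computes Pearson correlation between every
regulator and every functional gene over one ecotype's sample profiles, and
keeps edges with |r| > 0.9 and p < 0.05 (strict inequalities). The
correlation magnitude is thresholded because the phenomenon of interest is a
*signed* pattern: a gene set whose members correlate strongly positively
with one regulator and strongly negatively with another, as if toggled
between "on" and "off" by the pair.

Design choices worth stating explicitly:

- **Profiles** are log2(FPKM + 1) over replicate-level samples (6 with two
  replicates, 9 with three). Treatment-mean profiles would leave only three
  points and one residual degree of freedom, making p < 0.05 unattainable,
  so replicate-level profiles are the default.
- **p-values** use the t transform $t = r\sqrt{m-2}/\sqrt{1-r^2}$ with
  m − 2 degrees of freedom; at m = 6 this matches the exhaustive
  720-permutation p-value within about 0.02 (tested).
- **Modules** are exact signed-signature groups: each functional gene's
  retained edges define a map regulator → sign, and genes sharing the exact
  map form a candidate module. A module is reported when its signature has
  at least one positive and one negative regulator and at least
  `min_module_size` (default 5) members. Exact grouping is deterministic,
  makes modules disjoint by construction, and admits a one-line brute-force
  oracle; a relaxed mode (`relax_jaccard`) merges near-identical signatures
  when biological noise fragments a module.
- Genes constant across samples are skipped (their r is undefined), with a
  report.

No claim of direct TF–target binding is made; co-expression at these
thresholds is a screen, not a regulatory proof.

# Orthogroup hierarchies

Cross-species context comes from an orthogroup table (the OrthoFinder
`Orthogroups.tsv` dialect). Outgroup species are collapsed into a single
"other plants" party, and every orthogroup containing at least one
drought-memory gene is placed in a three-party Venn: shared by both focal
ecotypes and an outgroup; shared by the focal ecotypes only (the
species-unique tier); unique to one ecotype; the two pairwise regions
(one ecotype plus an outgroup); or outgroup-only. Membership is driven by
*DMG* membership, not mere gene presence, because the partition describes
drought-memory orthogroups. Focal DMGs absent from every orthogroup are
retained as flagged singleton ecotype-unique entries by default (silently
dropping them would bias the unique tiers); this is toggleable.

# Enrichment

Term over-representation is the upper-tail hypergeometric test
P(X ≥ k) for k query hits among n query genes, K term genes and an
N-gene background, BH-adjusted across tested terms. The background defaults
to all genes in the count matrix. Terms with fewer than two background genes
are excluded by default (noise control), and term hierarchies are not
traversed — each term is tested on its direct annotations only.

# Network hubs

Interaction networks are scored by degree and by maximal clique centrality,
$MCC(v) = \sum_{C \ni v} (|C|-1)!$ over the maximal cliques containing v;
isolated nodes score 0. Maximal cliques are enumerated exactly
(Bron–Kerbosch with pivoting), so graphs above a configurable bound (5,000
nodes) are refused with guidance to prune by edge confidence first. Ties in
the top-k ranking break lexicographically by gene ID, making reports
reproducible.

# The synthetic-data generator

`simulate_drought_memory()` plants known structure so that every stage of
the pipeline can be validated end to end without any external download:

- **Counts** are negative binomial with variance $\mu + \alpha\mu^2$
  (matching the caller's model). Each gene draws a baseline mean
  log-uniformly on 2^3–2^10 — a realistic expressed-gene depth range for a
  bulk RNA-seq library of a few tens of millions of reads — and its
  category's chained fold changes (default 2^2 per step) set the S1/S3
  means. Default category proportions (1% per memory subtype, 4% per
  non-memory subtype, 1.5% per late subtype) mirror the roughly 12%
  drought-responsive / 3% late-response composition typical of these
  designs.
- **Library sizes** are equal by default, with optional uniform size-factor
  jitter; equal sizes isolate classification error from normalisation error
  in tests.
- **Switch modules** share a latent log2 trajectory: the module category's
  treatment pattern plus shared per-sample jitter (default SD 0.3). Members
  and positive TFs follow the latent plus independent gene-level noise
  (`noise_sd`); negative TFs follow the latent reflected about its midrange,
  a monotone-decreasing transform that keeps counts positive and
  Pearson-valid. The shared jitter exists because with only 6–9 samples any
  gene merely sharing the module's treatment pattern would otherwise
  correlate above 0.9 with the module's TFs, making exact recovery
  meaningless; jitter decorrelates pattern-mates without breaking
  within-module collinearity. Module categories alternate between `[+/-]`
  and `[+/+]`, whose centred patterns are orthogonal and not mirror images —
  with more than two modules categories repeat and cross-module correlations
  rise, a known limitation. In the noiseless diagnostic mode
  (`noise_sd = 0`) the latent is rounded to integers so planted counts are
  exact powers of two and within-module correlations are exactly ±1 even
  after integer rounding.
- **Physiology** records emulate the six-stage dehydration/rehydration
  design for both ecotypes with a planted drought effect (RWC drops at every
  stress, most at S1) and a planted memory contrast (the arid-land ecotype
  holds its water status after the first stress).

## What passing tests do and do not show

The generator draws from the same NB family the caller assumes, uses equal
library sizes by default, and plants clean, identical effect sizes. Real
data have gene-specific dispersions, composition biases, batch effects and
a continuum of effect sizes; recovery rates measured here are therefore an
upper bound on real-data performance and validate the *implementation*, not
the biology.

## Validation problem sizes and the two validation datasets

The acceptance suite validates on 2,000-gene simulations with three
replicates per treatment, planted effect 2^2 and dispersion 0.05 — small
enough to run in seconds, large enough for stable rates. Two configurations
are used deliberately:

- **Label recovery** uses the default category proportions. Mean exact-label
  recovery of planted memory categories is about 91%; the residue is
  genuinely information-limited (e.g. the second down-step of a `[-/-]`
  gene whose baseline is a few dozen counts leaves S3 means near 1–2
  counts, where no test at n = 3 can call a fold change). A reference
  moderated NB caller does not do better on the same data.
- **Exact switch recovery** uses a configuration whose non-module genes are
  all `none`. With background drought-responsive genes present, chance
  correlations above 0.9 at 6–9 samples admit occasional intruders into an
  exact signature group (roughly one per module per 2,000 genes), so exact
  recovery is not a meaningful target there; the co-expression
  configuration isolates detection quality from classification noise, in
  the same spirit as the equal-library-size default.

# Numerical conventions

- Dispersion floor 1e-8; 0.5 pseudo-count in reported log2 fold changes
  only; 1.0 pseudocount inside log2(FPKM + 1).
- FPKM denominators default to per-sample column sums (whether "mapped
  reads" includes non-exonic reads is dataset-specific; explicit totals can
  be supplied).
- Percent rounding is half-up to one decimal; hub-ranking ties break
  lexicographically; BH adjustment caps at 1.
- The q-PCR utility (`ddct_relative_expression()`) implements
  2^−ΔΔCt; with several reference genes, their Ct values are averaged,
  which corresponds to the geometric mean of the reference abundances (the
  standard multi-reference rule).
- All randomness flows from a single configuration seed, fanned out per
  stage, so a fixed seed reproduces a dataset bit for bit.

# Known limitations

- The NB caller has no dispersion shrinkage; at two or three replicates its
  per-gene dispersion estimates are noisy, and very low-count genes are
  under-powered (as they are for any caller).
- Exact-signature module grouping fragments under heavy noise; the Jaccard
  relaxation recovers some of this at the cost of determinism guarantees.
- More than two planted switch modules reuse trajectory categories and are
  not guaranteed recoverable exactly.
- The compact letter display uses raw pairwise p-values by default, which is
  the reporting convention being mirrored, not a recommendation against
  multiplicity correction.
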