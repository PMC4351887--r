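# polyzf

Comparative evolution of poly-zinc-finger transcription factors across a
clade of species.

## The problem

Cys2-His2 zinc-finger (C2H2-ZF) proteins are the largest class of metazoan
transcription factors. Each ~21-residue domain binds 3–4 bases of DNA, with
specificity carried largely by four residues of the recognition helix —
positions −1, 2, 3 and 6 (position 7 being the first zinc-coordinating
histidine). Because the specificity-determining positions are known,
changes in DNA-binding *function* between 1-to-1 orthologous TFs can be
assessed directly from protein sequence: a substitution at −1/2/3/6 of a
shared domain very likely changes what the factor binds.

`polyzf` is a tidyverse-native pipeline for exactly this analysis, aimed at
comparative/regulatory genomicists working with a clade of sequenced
genomes and one reference species:

1. **Domain calling** — HMMER hit tables combined with the structural
   expression `C-X(2-4)-C-X(8-12)-Ψ-X(2)-H-X(3-5)-[H|C]` (Ψ large
   hydrophobic), bit-score thresholds with tandem-rescue, representative
   isoform selection, and tandem-array construction with canonical-linker
   (5–12 aa, consensus `TGE[K|R]P[F|Y]X`) classification.
2. **Orthology** — reference-anchored 1-to-1 orthogroups from pairwise
   ortholog lists; 1-to-many truncation; many-to-many families resolved by
   parsimony duplication/loss reconciliation of gene trees against the
   species tree (LCA mapping) and extraction of duplication-free subtrees.
3. **Divergence** — global alignment to the reference, helix-window domain
   correspondence, per-species percent of domains lost / gained / diverged
   (a domain is *diverged* iff positions −1, 2, 3 or 6 differ), stratified
   by array structure.
4. **Constraint statistics** — clade support in sister-species pairs
   (exact binomial vs. the background class), evolutionary-rate rank
   normalization (Wilcoxon), fixation-versus-polymorphism classification
   against population data, and folded site-frequency spectra.
5. **Predicted specificity** — per-domain PWMs over b1..b4 from a pluggable
   predictor (bundled deterministic baseline; external predictors plug in
   as MEME files), consensus-confidence filtering (average PCC > 0.25 to a
   secondary predictor), and Spearman trends of specificity change versus
   phylogenetic distance.
6. **Binding landscape** — PWM quality control, promoter scanning with
   exact dynamic-programming p-values, 25-bp cross-species conservation
   windows, and a rank-normalized Wilcoxon comparison of binding-site
   turnover between conserved and diverged TFs.
7. **Synthetic data** — a fully ground-truth-labelled generator
   (`simulate_families()`, `simulate_polymorphisms()`,
   `simulate_promoters()`) that emulates the statistical structure the
   analysis assumes, so the entire pipeline runs and is tested hermetically.

All user-facing functions take data frames and return tibbles;
`tidy()`/`glance()` methods cover the fitted objects and `plot_*()` /
`autoplot()` helpers produce the standard figures. See the methods vignette
(`vignettes/polyzf-methods.Rmd`) for the models, conventions and design
decisions.

## A worked example

Simulate a 30-gene, 12-species dataset and run every stage:

```r
library(polyzf)
library(dplyr)

cfg <- sim_config(n_genes = 30, n_tfs = 8, n_promoters = 40,
                  promoter_length = 500, seed = 7)
res <- simulate_and_run(7, config = cfg)
glance(res)
#> # A tibble: 1 × 8
#>    seed n_domains n_genes_with_domains n_orthogroups pct_diverged_min ...
#> 1     7      1675                  360            30             2.10
```

Per-species domain divergence (percent of aligned domains with a changed
DNA-contacting residue, here for four of the eleven non-reference species):

```r
res$divergence_summary |>
  filter(stratum_type == "overall", metric == "pct_domains_diverged") |>
  select(species, numerator, denominator, value) |> head(4)
#>   species numerator denominator value
#> 1 dana           17         140 12.1
#> 2 dere            8         141  5.67
#> 3 dgri           33         134 24.6
#> 4 dmoj           37         138 26.8
```

Divergence grows with distance from the reference (`dere` is close,
`dmoj`/`dgri` distant). The clade-support comparison asks whether divergent
binding residues are shared by the sister species more often than background
residues (exact binomial, null = background support proportion):

```r
glance(res$clade_support) |>
  select(species, statistic, p_value, null_proportion) |> head(4)
#>   species statistic  p_value null_proportion
#> 1 dere            7 1                  0.812
#> 2 dmoj           39 0.000208           0.795
#> 3 dper           37 0.176              0.933
#> 4 dpse           37 0.176              0.898
```

In the distant species, where divergent sites are plentiful, binding-residue
changes show significant clade support — the generator plants 80% of binding
substitutions on internal branches, and the pipeline recovers the signal.
`res$fixation`, `res$rate_ranks`, `res$sfs`, `res$specificity_distance` and
`res$landscape_comparison` hold the remaining analyses;
`plot_divergence_summary()`, `plot_rate_ranks()`, `plot_sfs()` and
`plot_landscape_comparison()` draw them.

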