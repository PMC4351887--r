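---
title: "Methods: comparative analysis of poly-zinc-finger orthologs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative analysis of poly-zinc-finger orthologs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question and the unit of analysis

Cys2-His2 zinc fingers (C2H2-ZFs) are the largest class of metazoan
transcription-factor DNA-binding domains. Each ~21-residue domain contacts
three to four bases, and binding specificity is carried largely by four
residues of the recognition helix: positions −1, 2, 3 and 6 (numbering the
helix 1..6, with −1 immediately before it and position 7 being the first
zinc-coordinating histidine). Because the specificity-carrying positions are
known, divergence in DNA-binding *function* between orthologous TFs can be
read off a sequence comparison: if two 1-to-1 orthologs differ at positions
−1/2/3/6 of a shared domain, their binding preferences have very likely
changed.

`polyzf` implements this comparison as a pipeline over a clade of species
with one designated reference: domain calling, reference-anchored 1-to-1
orthogroup assembly (with duplication/loss reconciliation for ambiguous
families), per-domain loss/gain/divergence classification, three
functional-constraint statistics, predicted-specificity comparison, and a
binding-site turnover analysis in aligned promoters. The unit of analysis is
the *poly-ZF* gene — a gene with two or more C2H2-ZF domains — because
single domains rarely confer specific binding on their own.

## Domain calling

Domains are called from HMMER per-domain hits (`read_domtblout()`) combined
with the structural expression

```
C - X(c1) - C - X(c2) - Psi - X(2) - H - X(c3) - [H|C]
```

where Psi is a large hydrophobic residue (default set F, Y, W, L, I, V, M).
A hit becomes a domain only when its envelope contains a match of this
expression; high-scoring hits without one lack the zinc-coordinating
geometry and are treated as degenerate. Sub-threshold hits that do match are
rescued only when the protein also carries an above-threshold domain,
reflecting the strong tandem organization of this family. Pure-regex calling
(`call_domains(..., hits = NULL)`) supports inputs without hit tables, and
is what the synthetic pipeline uses.

The spacer counts of the structural expression are configurable. The default
ranges are c1 ∈ [2,4], c2 ∈ [8,12], c3 ∈ [3,5] — the classic C2H2 envelope —
with `zf_pattern(preset = "strict")` providing the literal fixed-count
reading (2, 8, 3). Matching is left-greedy: earliest start wins, shortest
spacers at each level, and scanning resumes after each reported match. The
anchor for all coordinate bookkeeping is position 7 (the first coordinating
histidine); positions −1..6 are the seven residues immediately preceding it,
so the −1..7 window is a contiguous 8-residue string.

Tandem arrays are assembled from inter-domain gaps: domains separated by at
most 12 residues share an array. A linker is *canonical* when its length is
5–12 residues; the consensus motif `TGE[K|R]P[F|Y]X` is recorded as a
separate flag but not required, since many genuine canonical linkers deviate
from it (a motif-strict mode is available). A domain is *canonically linked*
when at least one bordering linker is canonical. Within arrays of three or
more domains the positions are labelled beginning/middle/end; pairs are
beginning and end with no middle.

When a gene has several isoforms, the longest isoform containing every
unique domain represents the gene; domain identity for this purpose is the
exact −1..7 window string, because that window is what the downstream
binding comparison consumes. If no single isoform covers all windows, a
minimum-cardinality covering set is selected — exactly, by subset
enumeration, for up to 15 candidate isoforms (ties prefer longer proteins,
then smaller ids), and greedily above that.

## Orthogroups and reconciliation

Raw orthogroups collect, per reference gene, all partner genes from pairwise
ortholog lists. Species contributing more than one gene are truncated away;
groups retaining fewer than two species are dropped. Families whose raw
groups overlap (shared member genes) are merged and resolved by
reconciliation: a gene tree (supplied, or built by neighbor joining on
pairwise alignment distances) is rooted to minimize duplications and mapped
onto the species tree by the standard last-common-ancestor construction. A
node is a duplication when its species image equals a child's image; losses
are counted per edge from species-tree path lengths. Maximal duplication-free
subtrees become candidate 1-to-1 orthogroups; candidates without exactly one
reference gene, or with fewer than two species, are discarded. For a fixed
rooted topology the LCA mapping attains the parsimony minimum of
duplications and losses, which the test suite verifies against exhaustive
enumeration.

## Divergence classification

Each orthogroup is aligned per species against the reference protein with a
global affine-gap alignment (BLOSUM62, gap opening 10, extension 0.5, via
Biostrings); externally computed alignments are accepted verbatim. Reference
and species domains correspond when their −1..7 windows share at least 5 of
8 aligned columns (greedy by overlap, ties N-terminal first). Unmatched
reference domains are *lost* in that species; unmatched species domains are
*gained*; a reference domain with no aligned partner in any species is
*not evaluated*, as it is most plausibly a reference-specific gain.

An aligned domain pair is *diverged* when at least one of positions −1, 2,
3, 6 differs. Gapped positions are skipped — neither match nor mismatch —
and a pair with all four specificity positions gapped is not evaluable.
Every reference residue takes exactly one class: BINDING (−1/2/3/6),
HELIX_EXCLUDED (helix 1/4/5 — in the helix but not DNA-contacting, with
position 4 structurally constrained), C2H2_NONBINDING (the rest of the
domain, including the coordinating cysteines and histidines), LINKER
(between canonically linked adjacent domains; non-canonical gaps are
BACKGROUND), and BACKGROUND. Summaries report percent lost / gained /
diverged per species, overall and stratified by canonical linkage, array
size, array position and bordering-linker length; empty strata report `NA`,
never zero.

## Constraint statistics

Three analyses ask whether divergent DNA-contacting residues behave like
functional changes rather than noise.

**Clade support.** For sister-species pairs, a divergent site in one partner
is supported when the other partner carries the identical residue at the
same reference column; a shared substitution most likely predates the
split. Sites whose partner column is gapped, or whose partner lacks the
ortholog, are excluded. BINDING is compared to BACKGROUND with an exact
two-sided binomial test whose null probability is the background support
proportion — background is the largest and most stable class, so its
proportion is the natural null. Sidedness and the null class are
configurable, since reasonable alternatives exist.

**Evolutionary-rate ranks.** Per-site rates (Rate4Site output, or the
built-in Fitch-parsimony proxy: minimum substitution count divided by tree
length, computed per complete column) are ranked within each sequence's
divergent sites, normalized to [0,1] as (rank−1)/(m−1) with 0.5 for a lone
site, pooled per species and class, and compared BINDING versus BACKGROUND
with a two-sided Wilcoxon rank-sum test.

**Fixation versus polymorphism.** A cross-species divergent site that never
segregates in the reference population is a candidate rapid fixation. Per
class, the proportion of divergent sites absent from the polymorphism table
is compared BINDING versus BACKGROUND with the same binomial construction.
Site identity is the reference amino-acid position; nucleotide-level mapping
is out of scope. Folded site-frequency spectra of the divergent-and-
polymorphic sites are tallied per class with minor-allele-count bins 1..6
and an aggregate 7+ bin.

The statistical kernels (`binomial_compare()`, `wilcoxon_rank_sum()`,
`spearman()`) are implemented in-package with explicit conventions — exact
minimum-likelihood two-sided binomial; exact Wilcoxon below n = 20 without
ties, otherwise normal approximation with tie and continuity correction;
Pearson-on-average-ranks Spearman with all-tied inputs flagged and recorded
as 0 — and are cross-checked against the corresponding stats-package
implementations in the tests.

## Predicted specificities

Per-domain binding preferences over base positions b1..b4 come from a
pluggable predictor interface. Trained machine-learning predictors are out
of scope; any external predictor plugs in by supplying per-domain PWMs in
MEME minimal format (`table_predictor()`). The bundled baseline exists so
the whole pipeline runs hermetically: a lookup table
(`inst/extdata/baseline_zf_code.tsv`) maps each DNA-contacting residue to a
base-preference column, and a 7-edge contact model (the four canonical
contacts 6–b1, 3–b2, −1–b3, 2–b4′ plus three secondary edges) combines
multi-edge contributions by normalized product. The table is versioned data,
not a trained model; its entries encode coarse, literature-style preferences
(e.g. arginine at position 6 prefers G). Unknown residues contribute a
uniform column; a gapped specificity position yields no prediction.

Consensus confidence follows the multiple-predictor design: a prediction is
kept when its average b1..b4 Pearson correlation (PCC) to at least one
secondary predictor exceeds 0.25 (0, 0.25, 0.5, 0.75 preconfigured). The
bundled secondaries are deterministic exponent-transformed variants of the
baseline table. Column PCCs between zero-variance pairs are 1 when the
columns are equal within 1e-9 and 0 otherwise — a declared convention for
degenerate columns.

Specificity change versus phylogenetic distance uses the patristic
reference-to-species distance and the average PCC of each species'
prediction to the reference prediction; per-domain Spearman correlations
need at least three species, and all-tied profiles are recorded as 0 with a
flag. Reported summaries are the fractions of domains with ρ < 0 and
ρ < −0.5.

## Binding landscapes

Experimentally derived (or synthetic) PWMs pass quality control: at least
six columns with information content above 0.5 bits (IC = 2 + Σ p·log2 p
against a uniform background), no more than 80% of informative columns
sharing one consensus base, and a 1-to-1 orthogroup covering at least two
non-reference species. Promoter windows (default 2000 bp upstream) are
scanned on both strands after gap removal; the log-odds score (bits, small
pseudocount, default 0.001) gets an exact p-value from dynamic programming
over the discretized score distribution (default granularity 1/1000 of the
score range), and sites with p ≤ 1e-4 are reported — the conventional
scanner default, declared rather than inferred. Distances between sites are
measured between site starts after mapping through alignment columns.

A reference site is *high-confidence* when every species of the confidence
set (default: the four species closest to the reference; presets of one to
four species) has a site within 25 alignment columns (15/25/50
preconfigured; conservation is provably monotone in this window, which the
suite asserts). Conservation fractions per TF and species — the fraction of
confident sites conserved, and of bound promoters still bound — exclude the
species used to establish confidence. TF constructs are labelled from the
divergence calls (conserved in all species, conserved here but diverged
elsewhere, diverged here, absent), and conserved-versus-diverged fractions
are compared by rank-normalizing within species to [0,1] (a lone observation
maps to 0.5), pooling, and applying the two-sided Wilcoxon rank-sum test.

## The synthetic data generator

`simulate_families()` evolves ancestral poly-ZF proteins along a species
tree; its defaults define the study conditions the pipeline is tested
under. The built-in tree has 12 fly-like species with four sister pairs and
reference `dmel`, spanning ~0.1–0.7 substitutions/site to the reference.
Defaults: 200 genes with 2–8 domains each, class-specific substitution rates
(per site per unit branch length) of 0.08 for BINDING, 0.04 helix-excluded,
0.02 domain non-binding, 0.03 linker, 0.06 background — DNA-contacting
residues evolve below the background rate, and the resulting per-species
domain divergence spans roughly 3–30% across the clade; per-branch domain
loss rate 0.15 and gain rate 0.04 per domain/gene (a few percent of domains
lost or gained per species, increasing with distance);
`clade_consistent_fraction = 0.8` of BINDING substitutions placed on
internal branches so sister pairs share them; polymorphism probabilities
0.35 for divergent non-binding sites versus 0.06 for divergent binding sites
in a sample of 139 individuals, with 1/i folded-spectrum minor-allele
counts; 20 TFs × 200 promoters × 2000 bp with planted-site density 5e-4 per
bp and per-branch site-loss probabilities 0.02 (conserved TFs) versus 0.12
(diverged TFs). Every event is recorded in a ledger keyed by stable residue
and domain ids, so expected summaries can be recomputed without touching the
pipeline.

Three design choices matter for interpreting what passing tests show:

* **The reference architecture is held fixed.** Domain loss and gain events
  are placed only on non-reference branches, and gained domains are inserted
  into the middle of the C-terminal flank. Reciprocal losses on the
  reference lineage versus another lineage can otherwise leave equal-length
  architectures in which a global aligner must pair two non-homologous
  domains — indistinguishable, by any alignment method, from divergence.
  Holding the reference ancestral keeps reference-anchored loss/gain ground
  truth well defined, mirroring the reference-anchored design of the
  analysis itself. Real data contain such ambiguous events; on real data the
  loss/gain/divergence partition is correspondingly an approximation.
* **The substitution alphabet excludes C and H** (and the structural
  positions — the coordinating C/C/H/H and the hydrophobic position 4 — are
  immutable). The analysis consumes only identity versus difference, never
  exchangeabilities, so this does not bias any statistic; it guarantees that
  planted domains are re-found exactly and that no spurious structural
  matches arise, which the exact ledger-identity checks require.
* **Promoter sites are never destroyed on the reference lineage**, since a
  site planted in the reference is present there by construction.

What the generator does not emulate: codon-level evolution (and hence
dN/dS), realistic amino-acid exchangeabilities, demography behind the site
frequency spectrum, promoter alignment error, and assembly artefacts.
Passing the ledger and recovery tests therefore demonstrates correctness of
the bookkeeping and statistical machinery under the stated model, not
robustness to the noise sources of real genome data.

## Numerical choices and problem sizes

Exact binomial ties use the standard (1 + 1e-7) relative tolerance;
Wilcoxon continuity correction follows the direction of the alternative;
PWM columns are validated to sum to 1 within 1e-9; scan p-values are exact
for the discretized score (matched-discretization enumeration agrees to
1e-9). Gene-tree rooting ties break by losses and then edge order. All
randomness flows from a single integer seed; equal seeds give byte-identical
results end to end.

The test suite runs the sequence-level pipeline at 8–50 genes and promoter
modules at 20–60 promoters of 200–1000 bp; the statistical-recovery
properties (type-I calibration of the clade-support binomial over 400 null
replicates, power at support probabilities 0.8 versus 0.3, landscape
detection at site-loss 0.5 versus 0.1 over 100 replicates each) use the
site-level and fraction-level generators directly, which draw from exactly
the distributions the sequence-level path induces at those parameters. The
clock-like regime for the specificity-versus-distance property uses a
BINDING rate of 0.8 with length-proportional branch placement, chosen so
domains accumulate two to three substitutions across the clade and rank
correlations are resolvable; at weaker signal, tied profiles (recorded as
ρ = 0) dominate and the negative-fraction drops — a resolution limit, not a
failure of the trend. `scripts/acceptance.R` runs the full default-scale
pipeline (200 genes, 12 species, 20 TFs, 200 promoters of 2000 bp).

## Known limitations

Orthology resolution ignores synteny and sequence-similarity-only
inference. The Fitch rate proxy is coarser than likelihood-based rates and
is intended for hermetic runs, not as a Rate4Site replacement on real data.
The baseline specificity predictor is a stand-in interface, not a trained
model; conclusions about real binding preferences require plugging in real
predictors or experimental PWMs. Promoter extraction from genomes is out of
scope — aligned promoter blocks are an input. The exact binomial's null
treats the background proportion as fixed, which is mildly anti-conservative
when the background class is small; with the large background classes this
analysis produces, the type-I calibration test shows the effect is
negligible.
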