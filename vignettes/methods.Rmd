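---
title: "Methods: duplication, Ka/Ks dating, and expression divergence of paralogs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: duplication, Ka/Ks dating, and expression divergence of paralogs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paralogdiv)
```

This vignette is the package's own account of the models it implements, the
parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic-data tests do and do not establish.

## The analysis

The pipeline reproduces the standard genome-wide gene-family survey: classify
family members into subfamilies on a protein phylogeny, identify duplicate
pairs and their mechanism (tandem vs segmental), quantify selection pressure
on each pair with Ka/Ks, date the duplication events with a molecular clock,
and ask whether duplicate pairs have diverged in expression. The packaged
fixtures describe a 64-member monosaccharide-transporter-type family in rice
(seven subfamilies, 12 duplicate pairs), but nothing in the code is specific
to that family.

## Phylogeny and subfamily assignment

Distances come from pairwise global protein alignment (BLOSUM62, gap open 10,
extend 0.5 — delegated to `Biostrings::pairwiseAlignment`) as the proportion
`p` of mismatches over aligned non-gap columns, optionally Poisson-corrected
`-ln(1 - p)`. This replaces a progressive ClustalW-style MSA: for distance
input to neighbor joining, pairwise global alignments are an adequate and far
simpler substitute, and the bootstrap path accepts any externally aligned
FASTA when a true MSA is preferred.

`neighbor_joining()` is the Saitou–Nei agglomeration, written here rather than
delegated so its determinism contract is explicit:

* Q ties are broken by the lexicographically smallest pair of representative
  taxon ids (the smallest leaf label in each cluster), making output
  bit-stable for a fixed input order and topology-invariant under input
  permutation.
* Negative branch-length estimates (a known NJ artefact on non-additive
  input) are clamped to zero with the deficit moved to the sibling edge, so
  pendant-path lengths are conserved and trees are printable.

On additive matrices the tree's path-length matrix equals the input to
machine tolerance; the test suite checks this against random trees and against
`ape::nj` as an independent reference.

Bootstrap supports resample alignment columns with replacement (one RNG
stream, integer seed), rebuild NJ per replicate, and score each internal edge
of the full-data tree by the percentage of replicates containing the same
bipartition. Splits are compared as canonical leaf sets (complemented so the
alphabetically first taxon is never in the key), which makes support counting
independent of tree orientation.

Subfamily labels propagate from reference leaves by the *smallest pure clade*
rule: an unlabelled leaf takes the label of the smallest enclosing clade whose
labelled members are unanimous. If the first labelled clade above the leaf is
mixed, no larger clade can be pure, so the leaf falls back to the nearest
labelled leaf by patristic distance and is tagged `nearest-leaf` so the weaker
evidence is visible. This rule is this package's explicit policy; published
family surveys rarely state how subfamily boundaries were drawn on the tree.

## Duplication classification

Tandem detection is purely positional: genes are ranked 0..n−1 per chromosome
by start coordinate (ties by end, then id), and a homolog pair is tandem when
at most `max_gap` genes intervene. Defaults follow MCScanX semantics:
`max_gap = 1`, proximal window 20 genes. When a registry carries no
coordinates (a printed family table), `assign_ranks(use_locus_order = TRUE)`
ranks by the numeric index of the TIGR-style locus tag, which ascends along
the chromosome in MSU-style annotation; a warning notes that gaps are then
measured in family-gene units rather than whole-annotation units, which makes
tandem calls *more* permissive and is the right bias for a family-only
fixture.

Segmental evidence comes from chaining homolog anchors into collinear blocks:
per chromosome pair, anchors sorted by rank on the first chromosome are
chained by dynamic programming, allowing steps of at most `max_anchor_gap`
(default 25) ranks on both sides in a consistent direction (same or inverted
orientation, recorded). Chains of at least `min_block_size` anchors
(default 5) are emitted greedily by summed score, each anchor consumed once.
Final classification applies the fixed priority segmental > tandem >
proximal > dispersed, so a rank-adjacent pair inside a block is segmental.
Whole-genome-duplication remnants are not distinguished from other collinear
blocks; both report as "segmental".

## Ka/Ks, selection, and dating

`nei_gojobori()` implements the 1986 counting method:

* Synonymous sites: at each codon position, the fraction of the three
  possible single-base changes that preserve the amino acid (changes creating
  stops count as nonsynonymous in the denominator of 3); site totals are
  averaged between the two sequences. By construction
  `N_sites + S_sites = 3 × comparable codons`, asserted on every run in the
  tests.
* Differences: differing codons are decomposed over all orderings of their
  differing positions with equal weight; orderings passing through a stop are
  excluded; if every ordering crosses a stop the codon pair is excluded from
  sites and differences alike and counted in `codons_excluded`. Codon columns
  containing gaps or ambiguity codes are excluded pairwise.
* Correction: Jukes–Cantor, `d = -(3/4) ln(1 - (4/3)p)`; `p >= 3/4` sets a
  per-rate `saturated` flag and an `NA` rate rather than an error, because
  saturation is a data property, not a usage error. `Ks = 0` likewise yields
  an `NA` ratio, not an exception.

The test suite validates the pathway decomposition against an independent
oracle that enumerates complete mutational paths recursively (a different
algorithm over the same definition), exhaustively over an 8-codon set chosen
to include stop-adjacent codons, plus randomized longer pairs.

Dating uses `T = K / (2λ) × 10⁻⁶` Mya with λ = 9.1 × 10⁻⁹
substitutions/site/year, the standard rice clock. The substrate is selectable
(`rate_column = "ks"` or `"ka"`, default `ks`) because the packaged
duplicate-pair fixture is internally inconsistent: its printed dates equal
`Ka/(2λ)` for every pair (e.g. Ka = 0.3290306 → 18.0786 Mya, the printed
value), while the stated formula uses Ks (which would give 31.75 Mya for that
pair). The package implements both columns and refuses to conflate them: the
default follows the stated formula, the fixture-reproduction test runs the Ka
column, and both dates appear in the pipeline report.

Selection classes compare Ka/Ks to 1 with tolerance 1e-9 (positive above,
negative below, neutral at equality); all 12 fixture pairs classify negative.

## Expression: 2^−ΔΔCT and divergence

Replicates are averaged in two stages — technical within biological, then
biological — matching a 3 × 3 qRT-PCR design; pooling all wells directly would
overweight samples with extra technical replicates. Then
`ΔCt(g,s) = Ct(g,s) − Ct(ref,s)`, `ΔΔCt = ΔCt(g,s) − ΔCt(g,calibrator)`,
fold `= 2^−ΔΔCt`; the calibrator column is identically 1 and adding any
constant to all Cts of a sample cancels exactly (both asserted as
properties). Regulation calls use fold > 1.5 for up and, symmetrically on the
log scale, fold < 1/1.5 for down; only the up threshold is conventional, the
reciprocal down rule is this package's choice.

Duplicate-pair divergence is the Pearson correlation of the two genes'
concatenated condition profiles: r < 0.3 divergent, 0.3 ≤ r < 0.5 ongoing
divergence, r ≥ 0.5 non-divergent. The defining intervals are open at 0.3 and
0.5, leaving the boundaries unassigned; this package assigns boundary values
to the higher class so classification is total and deterministic. Profiles of
length < 3 or with zero variance return a flagged `NA` rather than an error.

`row_scale()` (heatmap export) z-scores log2 folds per gene using the
population standard deviation (denominator n), so a three-value row (1, 2, 4)
maps to (−1.2247, 0, 1.2247); constant rows become zeros and are flagged.

## The synthetic-data world

Generator defaults state the world the tests assume:

* **Genomes** — a few hundred filler genes per chromosome; tandem arrays as
  runs of adjacent family genes (a length-k array yields k−1 true tandem
  pairs); segments as rank-parallel anchor runs (default 8 anchors) across
  two chromosomes; optional random noise pairs. Placement is collision-free
  or errors out.
* **Codon pairs** — random sense-codon ancestor; uniform single-base
  proposals accepted with probability 1 (synonymous), ω (nonsynonymous), or 0
  (stop-creating); evolution stops when the realized synonymous divergence
  reaches the target (default Ks 0.3 over 300 codons, the moderate-divergence
  regime of the fixture pairs). Under this kernel the realized dN/dS is ω in
  the low-divergence limit; the acceptance suite recovers ω = 0.2 within
  ±0.05 (median over 200 pairs) through the full estimator.
* **Ct tables** — `Ct = baseline − planted_log2fold + N(0, sd)` per technical
  well, reference gene flat, 3 biological × 3 technical replicates, sd 0.2
  cycles (a typical well-to-well SYBR spread). Zero noise recovers planted
  folds exactly.

One interpretive note: with per-well sd 0.2 and a 3 × 3 design, the ΔΔCt
estimate of each cell has analytic standard deviation (0.2/3) × 2 ≈ 0.133
log2 units, so the *mean absolute* per-cell error is ≈ 0.106 and cannot fall
below 0.1. The recovery tests therefore check *bias* (mean signed log2
error within ±0.1), which is the claim the estimator actually makes.

What a green suite does **not** establish: the generators draw Gaussian,
homoscedastic noise, uniform codon usage, no indels, no
amplification-efficiency differences between primer pairs, and no correlation
between biological replicates — real qRT-PCR and real paralog sequences
violate all of these to some degree. Green recovery tests certify the
estimators' arithmetic and their behaviour under the stated noise model, not
performance on any particular real dataset; the original rice expression
calls are not reproducible here at all because the underlying Ct data were
never deposited.

## Known limitations

* NJ only — no ML/Bayesian trees; bootstrap cost grows as O(reps × n³).
* The pairwise-alignment distance path can disagree with a full progressive
  MSA for gappy, divergent families; supply an external MSA to
  `bootstrap_support()` in that case.
* Nei–Gojobori with Jukes–Cantor ignores transition/transversion and codon
  bias; for deeply diverged pairs (p near 3/4) rates saturate and are flagged
  rather than estimated.
* Collinearity chaining takes the homolog hit list as given; no sequence
  search is performed, and block calls inherit the hit list's quality.
  Duplication-event counts are notoriously parameter- and tool-sensitive;
  every threshold is surfaced in the report header for that reason.
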