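---
title: "Methods: detecting, classifying and testing coevolution of rhizobial quorum-sensing systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting, classifying and testing coevolution of rhizobial quorum-sensing systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsce)
```

`qsce` implements a comparative-genomics workflow for AHL quorum-sensing
systems (QSSs) in multipartite rhizobial genomes: LuxI-like synthase /
LuxR-like regulator pairs, the genomic contexts they sit in, the
replicons that carry them, and the degree to which each pair has
coevolved. This vignette is the package's own account of the methods:
what each stage assumes, which tunable parameters matter, and where
design decisions were genuinely open.

## Coordinate conventions

All sequence coordinates (nucleotide and amino acid) are 1-based and
inclusive. Neighbourhoods are measured in **gene ranks** — the position
of a gene in a replicon's gene order — not in base pairs, because gene
content, not physical distance, is what is conserved in these loci. The
default window is 15 genes each way. Windows clip at replicon ends and
do not wrap around: circularity handling is not modelled, and for the
small fraction of loci near a contig boundary a clipped window only
removes vocabulary, never invents it.

## Domain architectures

A protein's architecture is the ordered set of non-overlapping Pfam
domains that covers as much of the sequence as possible. Hits are first
filtered at E-value strictly below 0.001 (the hmmscan reporting
convention this pipeline expects as input). Overlap resolution then has
two informally stated goals — maximise coverage, prefer low E-values —
which we make precise and consistent as a lexicographic objective:

1. maximise total covered amino acids over non-overlapping subsets
   (exact, via dynamic programming on end-sorted intervals);
2. among equal-coverage subsets, minimise the summed log10 E-value;
3. any remaining tie breaks lexicographically on Pfam accessions.

Two intervals overlap when they share at least one residue; no
tolerance window is applied, because any nonzero tolerance would need a
justification the data do not supply. The resolver is validated against
an exhaustive-search oracle on a thousand random instances in the test
suite. Architectures with identical signatures are the same vocabulary
token wherever they occur; a user-supplied synonym map can merge
signatures that manual curation would treat as the same contextual
protein — the package never guesses such merges.

## QSS detection

A LuxI-like gene is any gene whose architecture contains
`Autoind_synth` (PF00765); fusions (e.g. `Autoind_synth|WGR`) qualify.
A LuxR-like partner must contain `Autoind_bind` (PF03472) *followed by*
`GerE` (PF00196) in coordinate order — a GerE-only regulator is not a
LuxR, and receptor genes with no synthase in the window (LuxR solos)
are inventoried but excluded from all downstream analyses. The nearest
partner by gene distance wins; exact ties go to the lower index, and
farther candidates are kept as secondary partners, so a synthase with
two receptors yields two LuxI–LuxR combinations, each a distinct unit
downstream (the unique-identifier-per-combination convention).

Pair configuration follows strand geometry: same strand is tandem;
on opposite strands the pair is head-to-head when the 5' ends face each
other (divergent transcription) and tail-to-tail when the 3' ends face.
We note that "head-to-head" is occasionally used in the arrow-drawing
sense (3' ends meeting); we follow the transcription-based definition
stated above, and the configuration strings carry the rank gap
(`tandem_separated_by_4`) so no information is lost either way.

Degradation flags: pseudogene annotations propagate to
`luxI_pseudo`/`luxR_pseudo`; a missing partner sets `luxR_missing`; and
`luxI_short` fires at or below 170 aa. The observed non-functional
synthases range from 42 to 162 aa while intact ones are near 200 aa, so
170 covers the observed range with margin without encroaching on
functional lengths; the threshold is a parameter, not a claim about
where function ends. Transposase context flags scan the window for
three families (HTH_Tnp_1 = PF01527, DDE_Tnp_IS240 = PF13610, and the
composite DEDD_Tnp_IS110|Transposase_20 = PF01548|PF02371, which must
co-occur in one protein) and distinguish `flanked_both_sides` from
`single_adjacent`.

## Context clustering

Each canonical QSS's window is fingerprinted as a binary
presence/absence vector over architecture signatures (binary, not
counts, because presence is what the matrices describe; constant
columns are retained so the vocabulary stays auditable). Distances are
Jaccard; two all-zero rows are at distance 0 by convention.

Clustering is UPGMA. The implementation is in-package rather than a
wrapper because we require a *stated* deterministic tie-break (the
lowest-index pair merges first) and heights on the ultrametric scale
(two leaves at distance d merge at height d/2); `stats::hclust` and a
naive O(n³) re-implementation serve as independent oracles in the
tests. The dendrogram cut is chosen by silhouette: candidate thresholds
are midpoints just below each distinct merge height — cuts only change
at merge heights, so this candidate set is exhaustive — restricted to
2..n−1 clusters, scored by the mean silhouette width on the Jaccard
matrix, ties resolved toward the finer clustering. Two degenerate cases
are defined explicitly: all-identical points return a single cluster
with silhouette 0 and a warning; fully tied merge heights (e.g. three
equidistant leaves) fall back to the coarsest two-group cut. No minimum
cluster size is imposed — real context inventories contain singleton
contexts, and a constraint would hide them. Manual curation of cluster
labels is supported only as an explicit reassignment map recorded in
the result. The dendrogram can be rerooted on a designated outgroup
context (the convention: the QSS context of the *B. diazoefficiens*
outgroup genome).

## Replicon grouping and plasmid categories

ANI grouping is single-linkage: replicon pairs passing both thresholds
(identity ≥ 95%; coverage ≥ 70% for genomes, ≥ 75% for plasmids, both
directions by default) form a graph whose connected components are the
groups. The two-stage description often used — group mutual matches,
then attach anything matching at least one member — is exactly
connected components, so the implementation reproduces it by
construction. Non-singleton groups are numbered by decreasing size;
orphan plasmids are pooled into a miscellaneous group labelled "77"
(the conventional label for the heterogeneous orphan set). Cluster
naming follows reference-strain precedence: one reference names the
cluster; with several, the earliest-described species wins and a
missing publication year is an error rather than a guess; clusters
without references become sequential `tax_group` letters; singletons
are `sp.`.

Plasmid traits are detected from annotations alone (the pipeline is
sequence-free by design): Fer4_NifH and NodA domains mark symbiosis,
configurable marker names mark repABC and RctA (these were originally
protein-similarity searches, which are out of scope here), and
conjugation requires a configurable fraction — default 0.75 — of a
ten-domain tra/trb (Dtr + Mpf) fixture, shipped editable because the
canonical domain list and completeness rule are collection-specific. A
QS gene within 25 gene ranks of a tra/trb gene marks QS-linked
conjugation; conjugative neighbourhoods are larger and more variable
than ordinary QSS contexts, hence the wider window (also exposed as
`conj_window`).

Categories A–H are a total decision table evaluated top-down over
traits (symbiotic = nif or nod): QS∧conj∧sym → D; QS∧conj∧RctA → G;
QS∧conj → B; QS∧sym → C; QS → A; sym → E; conj → F; else H (cryptic).
Two choices were open. G vs B for a QS+conjugative+RctA plasmid: G
wins, because RctA repression is the more specific condition. E vs F:
we assign E = symbiotic-without-QS and F = conjugative-without-QS;
both assignments are configurable, and the exhaustive-enumeration test
pins whichever table is active.

## Cophylogeny

Given matched LuxI and LuxR trees (tips named identically per
combination), the package computes patristic matrices, the cophenetic
(Pearson, upper-triangle) correlation, the Robinson–Foulds distance
normalised by the sum of the two trees' internal-edge counts (the
maximum attainable value; correct also for non-binary trees, where
fixed 2(n−3) normalisation would be wrong), root-to-tip distance
summaries per partition (chromosomal vs plasmid taxa), and PACo:

1. each distance matrix is embedded by principal coordinates; if its
   Gower-centred form has a negative eigenvalue beyond 1e-8 (relative),
   the smallest Cailliez additive constant is computed from the 2n×2n
   companion eigenproblem and added to off-diagonal distances, making
   the matrix Euclidean — the embeddings then reproduce distances to
   numerical precision, and minimality of the constant is
   property-tested;
2. the two embeddings are matched through the one-to-one association
   and the LuxR configuration is translated, scaled and rotated
   (reflections allowed) onto the LuxI configuration by least squares;
   the residual sum of squares is the global statistic m², and each
   link's residual is its post-superimposition distance (residuals²
   sum to m²);
3. significance: the association is randomly re-paired (the appropriate
   null for an identity matching) `n_perm` times. Because a *small* m²
   is a *good* fit, the phrase "proportion of randomized associations
   with fit ≥ observed" is sign-ambiguous; we define
   p = #{permuted m² ≤ observed m²}/n_perm, so small p indicates
   congruence, and expose the verbatim reading (`better = "ge"`) and an
   add-one correction (`plus_one = TRUE`) as options, both off by
   default to keep the plain proportion estimator. Defaults are 1000
   permutations, seed 42.

Link residuals are banded by empirical quantiles (type-7 linear
interpolation — band edges move with the quantile method, so it is
fixed and documented): Low below Q1, High at or above the 90th
percentile, Extreme above Q3 + 3·IQR. The definitions overlap by
construction; precedence Extreme > High > Medium > Low resolves every
value to one band, and a degenerate all-equal distribution lands in
High (by the ≥ rule) with a warning.

## The synthetic-data generator

The generator emulates the *study conditions* of a desk-scale survey,
not any particular genome collection. Each simulated strain carries one
chromosome and 2–3 plasmids; each of the four shipped context templates
is planted once per strain on a replicon of its kind: A (tandem
cinI/cinR pair with seven conserved flanking genes, DUF4174/DUF2934
among them) and E (rhiI–rhiABCD–rhiR inside a nod/nif region; rhiA and
rhiC deliberately carry no Pfam domain) on chromosomes, AA (raiI/raiR
with the Lrp-family dadR and alanine-metabolism genes) and AI
(divergent traI/traR between complete tra and trb operons) on plasmids.
Every other gene is noise with a globally unique architecture signature
disjoint from all template vocabularies — the cleanest realisation of
"accessory genes differ between strains", and the regime in which exact
cluster recovery is a fair expectation. Planted blocks are kept more
than a detection window apart (configurations violating this are
rejected), plasmids get a repABC block at their head, and domain hits
receive E-values log-uniform in [1e-30, 1e-4] with optional spurious
overlapping hits that cover strictly less and score at least 10× worse,
so overlap resolution is decidable by design.

Degradation draws LuxI lengths uniformly from 42–162 aa or deletes the
LuxR slot; transposase planting inserts PF01527 genes on both sides of
the pair. The tree simulator produces a random coalescence topology
with exponential branch lengths (mean 0.1 substitutions/site — a
plausible protein-tree scale; only ratios matter downstream), and the
partner tree adds multiplicative log-normal branch noise (sdlog 0.25,
enough to decorrelate without destroying structure) plus leaf-pair
label swaps as host switches — chosen over SPR moves because swaps give
unambiguous ground truth and residual enrichment is the only property
asserted. ANI tables are block-structured with between-block identity
drawn below 90%.

What the generator does *not* emulate — sequence evolution, unequal
genome sizes, shared accessory content between related strains, partial
window overlap between neighbouring systems, annotation errors — bounds
what passing tests show: they demonstrate that each algorithm recovers
exactly what was planted under its stated assumptions, not that real
*Rhizobium* data are this clean.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: 1000 random instances
(≤ 12 hits) for the resolver oracle, 500 matrices (≤ 7 leaves) for
UPGMA, 500 tree pairs (≤ 8 tips) for nRF, 32-tip trees with 1000
permutations for the PACo identity limit, 200 null runs at 199
permutations for p-value calibration, and 50 seeds of 64-tip/8-switch
simulations for host-switch recovery — sizes at which the exhaustive
oracles are exact and the Monte-Carlo fractions have low variance.
Floating-point tolerances: 1e-8 (relative) for Euclidean/PSD decisions
and residual decomposition; eigenvalues below that are treated as zero
axes. All stochastic entry points take explicit seeds and restore the
caller's RNG state.

## Known limitations

Detection is architecture-only: a LuxI homolog that has lost PF00765
entirely is invisible, and confirmation-by-similarity against curated
query proteins is intentionally out of scope. Window-based partner
assignment cannot distinguish a true cognate pair from a fortuitously
close solo. ANI grouping inherits single-linkage chaining; with
borderline blocks a bridge replicon can merge groups. PACo residuals
flag incongruence but not its mechanism (host switching, paralogy,
recombination and rate heterogeneity all inflate them), and the
permutation null assumes exchangeable links. The manual-curation hooks
(architecture synonym map, cluster reassignment) are by design inert
unless supplied.
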