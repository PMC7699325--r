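---
title: "Classifying insect chemosensory gene families and calling tissue enrichment"
author: "chemosensr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying insect chemosensory gene families and calling tissue enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemosensr)
```

## The problem

Insects detect odor and taste compounds through a small set of gene
families: secreted carrier proteins — odorant binding proteins (OBPs) and
chemosensory proteins (CSPs) — that ferry ligands through the sensillar
lymph, and three membrane receptor families — odorant (OR), gustatory (GR),
and ionotropic (IR) receptors. In transcriptome surveys of non-model
insects these families are identified by sequence signatures rather than
curated gene models: OBPs and CSPs by a conserved arrangement of cysteine
residues, receptors by protein-domain hits and transmembrane topology.
Candidates are then screened for enrichment in chemosensory tissue (head
appendages: antennae, maxillary palps, proboscis) relative to the rest of
the body, and placed in family phylogenies.

`chemosensr` implements that workflow end to end for a four-condition,
single-replicate design (female/male x head appendage/headless body), with
seeded synthetic-data generators that plant known truth at every stage so
the whole pipeline can be validated without the original sequencing data.

## Cysteine-signature classification

A motif is an ordered series of cysteine anchors with an admissible range
of **spacer** residues between consecutive anchors. Spacer counts are
residues *strictly between* the two cysteines, and all coordinates are
1-based. Under this reading the minimal CSP motif
C–X6–C–X18–C–X2–C is exactly 30 residues with anchors at positions
1, 8, 27, 30; the notation itself does not state inclusivity, so this is a
package definition, chosen so the arithmetic of anchor positions is exact.

The shipped patterns are:

* **Classical OBP** (6 anchors): spacers (26–34), (3), (25–38), (8–11), (8).
* **CSP** (4 anchors): spacers (6), (18), (2).
* **Minus-C OBP backbone** (4 anchors): the Classical pattern with C2 and
  C5 deleted. Deleting an anchor merges its two flanking spacers plus the
  anchor position itself: 26–34 + 1 + 3 gives (30–38) between C1 and C3,
  and 8–11 + 1 + 8 gives (17–20) between C4 and C6; the central (25–38)
  spacer is unchanged.

`match_pattern()` performs a leftmost-greedy *complete* search: the first
anchor is tried at each cysteine left to right, each later anchor takes the
smallest admissible gap first, and the search backtracks when an extension
cannot finish. The first reported match is therefore the lexicographically
smallest valid anchor tuple, and a match is reported whenever *any* valid
tuple exists — the scan provably agrees with a brute-force enumeration of
all cysteine k-tuples (this equivalence is a tested property). Successive
matches may not share residues; each scan resumes after the previous
match's last anchor. Backtracking matters in practice: in a Minus-C
sequence the alternate cysteine sits inside the C3–C4 spacer region and can
be mistaken for an anchor by a purely greedy scan.

Subclass priority is **Dimer > Classical > Minus-C > None**. Two
non-overlapping Classical matches make a dimer (so a fused double motif is
never reported as one Classical OBP), and its two domains are returned as
sub-sequences labeled "a" (N-terminal) and "b" — the labels used as tree
tips. A Minus-C call requires the 4-anchor backbone *plus* an alternate
cysteine at a fixed offset: 7 positions before C4 (`alt_upstream_C4`) or 3
positions after the expected C5 (`alt_downstream_C5`). "Seven residues
upstream" is read as a position offset of 7; the expected C5 is placed 9
positions before C6, which is exact because the C5–C6 spacer is fixed at 8.
Both offsets accept an optional tolerance (default 0, i.e. exact).

Signal-peptide presence is carried through as an annotation (`secreted`)
but never gates classification: secreted carriers lacking a predicted
signal peptide do occur, so the motif alone decides. Truncated proteins
whose motif runs off a missing 5' or 3' end are reported as `None` with a
`partial_motif` note rather than guessed into a subclass.

## Receptor families and phylogeny filters

`assign_family()` maps controlled-vocabulary domain hits (`OR_7tm`,
`GR_chemo_trehalose`, `IR_iGluR`, `OBP_domain`, `CSP_domain`) to a family
with fixed precedence OR > GR > IR > OBP > CSP. Multi-hit conflicts are not
expected in practice; the precedence simply makes the function
deterministic, and unknown terms warn rather than fail.

Two phylogeny-inclusion filters follow. GRs without any predicted
transmembrane domain are excluded (`no_tm`) — one TM alone is sufficient to
pass. Separately, tips whose pendant branch exceeds `factor` times the
median pendant length (default 10) are flagged by `flag_long_branches()`
and can be excluded as `long_branch`. Published analyses typically drop
such taxa by visual inspection without a stated criterion; the package
instead makes the rule explicit and parametric. It is scale-invariant, so
the time units of the tree do not matter.

## Expression and tissue enrichment

For transcript *i* with length `len_i` (bp) and count `c_i`:

* `TPM_i = (c_i/len_i) / sum_j(c_j/len_j) * 1e6` per sample — every TPM
  column sums to one million by construction.
* `FPKM_i = c_i / (len_i/1e3 * lib/1e6)` with `lib` the (effective)
  library size.

Between-sample scaling uses the trimmed mean of M-values (TMM): reference
sample by upper-quartile closest to the mean upper-quartile; genes zero in
either sample removed; 30% of the M tails and 5% of the A tails trimmed;
factor = 2 to the precision-weighted mean of the surviving M values;
factors rescaled to geometric mean 1. The trim fractions and reference rule
are the standard published constants. The implementation agrees with
edgeR's `calcNormFactors` to eight decimals on shared inputs (a tested
cross-check, not a dependency). Note what TMM can and cannot absorb: a
single extreme spike is trimmed out of the *fit*, so the ratio of effective
library sizes returns to 1 within 1%, but the factors themselves shift away
from (1, 1) by the spike's share of the library — that is the correct
behavior of the published formula.

With one library per condition, a dispersion cannot be estimated, so the
exact test takes an assumed negative-binomial dispersion (default 0.16, a
biological CV of 0.4 — a conventional figure for bulk tissue from a
genetically heterogeneous pool). Counts are scaled to the geometric mean of
the two effective library sizes and rounded; conditional on the pair total
the first count is beta-binomial(s, 1/φ, 1/φ) under the null — symmetric,
reducing to Binomial(s, 1/2) at φ = 0 — and the p-value is the doubled
smaller tail, capped at 1. Because the null conditional is symmetric, the
smaller tail is evaluated as the lower tail of the smaller count, which
makes the p-value bitwise invariant under swapping the two samples (and the
log2 fold change exactly negates). Fold changes use a prior count of 0.5 on
both sides so zeros never produce infinities. Benjamini–Hochberg adjustment
runs across all transcripts, and a transcript is significant iff
`adj_p < alpha` **and** `|log2FC| >= lfc_min` (defaults 0.01 and 2,
inclusive). Published workflows sometimes quote an FDR of 0.05 or a raw-p
0.001 rule for cluster input alongside these thresholds; all are exposed as
configuration, with 0.01/2 the defaults.

Cluster partitioning log2-transforms expression (+1), centers rows by their
mean, agglomerates with Euclidean distance and complete linkage, and cuts
the dendrogram at 60% of its maximum merge height (all configurable).
Cutting at 100% yields one cluster; cutting near zero yields singletons.
Heat-map matrices are `log2(TPM + 1)` with row/column dendrogram orders
attached.

## Tree post-processing

Newick IO, midpoint rooting, and outgroup rooting are thin validated layers
over `ape`/`phangorn`. Midpoint rooting minimizes the maximum root-to-tip
distance; the suite checks it against a brute-force search over every edge.
Outgroup rooting requires the outgroup to be separable by a single edge
("outgroup not monophyletic" otherwise) and places the root at that edge's
midpoint — the placement along the edge is a package choice, made explicit
because rooted figures rarely state it. Both operations preserve the
unrooted bipartition set and the total tree length.

## What the generators emulate — and what they do not

`gen_proteins()` plants motifs with spacers drawn uniformly within the
admissible ranges inside cysteine-free random flanks, so planted cysteines
are the only anchors; annotation rows (signal peptide, TM count, domain
hit) are consistent with the planted class. Decoys either lack cysteine
entirely or carry six cysteines with spacing (22, 1, 22, 5, 5), chosen so
that no sub-tuple satisfies any shipped pattern (including merged Minus-C
gaps); a `hard_decoys` mode sprinkles extra cysteines into the flanks.
Planted-class recovery must be exact, with zero decoy calls — both are
tested on every run.

`gen_counts()` draws per-transcript baselines log-normally
(`sdlog = 1`, mean equal to `depth`; default depth 1000 — a moderately
expressed transcript in a ~30M-read library), scales head means of the
enriched fraction (default 10%) by `2^planted_lfc` (default 4) in *both*
sexes, and draws negative-binomial counts at the stated dispersion. The
head-vs-head comparison is therefore null by construction. `gen_tree()`
grows random topologies with exponential branch lengths, attaches the
outgroup as a separable clade, and sets planted long-branch pendants to 20
times the median pendant — defined relative to the final tree so the
default 10x-median flag always recovers them. A random tree can also
contain a *naturally* extreme pendant, which the rule then (correctly)
flags as well.

Features of real data the generators deliberately do not emulate: assembly
chimerism and fragmented isoforms, homology between planted sequences (each
is an independent random draw, so the unigene collapser sees no structure
unless you plant it), GC/length bias in counts, and ortholog evolution on
the trees. Passing the closed-loop suites therefore demonstrates the
correctness of the algorithms under their stated model, not robustness to
every artifact of a real assembly.

## Sensitivity of the single-replicate design

With one library per condition, the sampling standard deviation of the
per-pair log2 ratio has a floor of `sqrt(2 * dispersion)/ln 2` — about 0.82
log2 units at dispersion 0.16, at any depth. Individual fold-change
estimates therefore scatter widely around the planted value even though
their mean recovers it closely; and a single head-vs-body comparison at
`adj_p < 0.01, |log2FC| >= 2` detects a planted 16-fold enrichment with
probability only ~0.85 (edgeR's exact test gives the same figure on the
same data). The design plants each enrichment in both sexes, so the
pipeline's detection is assessed at the design level: a planted transcript
counts as found when either head-vs-body comparison calls it, exactly as
enriched candidates are tallied across the two sex-specific comparisons in
practice. Under the default simulation (2500 transcripts, 10% enriched,
depth 1000) this design-level sensitivity is ~0.97–0.99 with a false-call
rate among nulls well under 1% — recomputed on every run by the acceptance
script.

## Numerical choices and degenerate inputs

* Unigene collapsing: greedy longest-first, ties by lexicographic id;
  identity = exact matches in a global alignment (match 1, mismatch 0,
  simple affine gap penalty) divided by the *shorter* sequence length — the
  CD-HIT denominator convention. Re-collapsing the representatives is a
  no-op.
* Whether collapsing runs on nucleotide or peptide space is the caller's
  choice via `moltype`; the package does not prefer one.
* Exact test: scaled counts are rounded to integers; the (0, 0) pair gets
  p = 1; a column of all zeros is an error naming the sample in TMM, and a
  warning with an all-zero column in TPM.
* Trimming degenerate inputs: when the M/A trim would discard every gene,
  the untrimmed weighted mean is used.
* Clustering requires two or more rows; constant rows (zero distances) are
  allowed.
* Trees: fewer than 3 tips yields no long-branch flags (with a warning);
  all-zero branch lengths make the midpoint undefined (error).

## Problem sizes

The validation suites run at desk scale, chosen to exercise every code
path while keeping a full run to a couple of minutes: simulated count
matrices of 2 500 transcripts (at least 1 000 nulls for the false-call
property), synthetic protein sets of ~220 records, trees of 4–24 tips, and
brute-force oracles on sequences up to 300 residues and trees up to 12
tips. The analysis scripts under `analysis/` use a carrier-protein
composition mirroring the study scale (34 Classical, 8 Minus-C, 1 dimer,
5 CSP, plus decoys; 44/27/34 OR/GR/IR annotations).

## Known limitations

* The no-replicate exact test quantifies sampling noise only under an
  *assumed* dispersion; it cannot estimate biological variance, and its
  calls should be read as candidate screening, not inference about
  population differences.
* The Minus-C alternate-cysteine offsets are implemented as exact position
  offsets; homologs with shifted alternates need a nonzero
  `alt_tolerance`.
* The long-branch rule is an explicit stand-in for expert curation; no
  default threshold reproduces any particular published exclusion list.
* The unigene collapser performs exhaustive pairwise alignment and is
  intended for candidate-set scale (hundreds of sequences), not full
  assemblies.
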