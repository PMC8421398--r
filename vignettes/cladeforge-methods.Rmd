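---
title: "Methods: subgroup delineation and gene-content evolution in cladeforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subgroup delineation and gene-content evolution in cladeforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladeforge)
```

cladeforge packages the computations a comparative-genomics study of a
poorly characterised lineage of metagenome-assembled genomes (MAGs) runs
between tree inference and biological interpretation: partitioning a
phylogenomic tree into subgroups, gating genomes on marker-based quality,
profiling gene-family occurrence per subgroup, summarising
reconciliation-inferred gene-content changes, and classifying
[FeFe]-hydrogenase loci. This vignette explains each model, its assumptions,
the tunable parameters, and the design decisions that were genuinely open.

## Trees and node supports

Trees are `ape::phylo` objects read from Newick. Internal node labels may
carry two support values separated by a slash — ultrafast bootstrap (UFBOOT)
and SH-aLRT, both percentages in [0, 100]. Which value comes first depends
on the inference tool's version, so the order is an explicit argument
(`ufboot_first`) rather than a guess; the default reads `x/y` as
SH-aLRT/UFBOOT, matching trees produced with both supports requested
together. Zero-length and missing branch lengths are accepted with a warning
(draft-genome trees often contain them); negative lengths and duplicate leaf
names are rejected. Polytomies are allowed everywhere and treated like any
other internal node.

Outgroup rooting (`root_by_outgroup()`) places the root on the branch
separating a monophyletic outgroup from the ingroup. Total branch length and
all leaf-to-leaf path lengths are conserved; both properties are tested.

## Ultrametric conversion and depth normalisation

The stem-length criterion below is defined on an ultrametric tree, but no
dating method is implied by the delineation procedure itself. cladeforge
uses mean-path-length (MPL) smoothing: every internal node is aged at the
mean path length to its descendant leaves, then a top-down pass clamps each
age to its parent's age so branch lengths stay non-negative and the result
is exactly ultrametric. MPL was chosen because it is deterministic,
parameter-free and hand-checkable (the package's tests verify worked
examples such as a three-leaf tree whose root age is 10/3); the `method`
argument is an enum so penalised-likelihood style alternatives could be
added without changing the interface.

A fixed stem-length threshold is only meaningful on a known scale, so
`normalize_depth()` rescales the ultrametric tree to unit root-to-tip depth
and all stem thresholds are applied on that normalised scale. This is a
design decision of the package: an absolute threshold on raw branch lengths
would silently change meaning with alignment length and model choice.

## Relative evolutionary divergence

RED interpolates divergence between root (0) and leaves (1): in preorder,
`RED(n) = RED(p) + (d/u) (1 - RED(p))` with `d` the parent branch and `u`
the mean path length from the parent to the leaves below `n`. Leaves are
pinned to 1. RED is computed on the original rooted tree — the convention of
rank-normalisation pipelines — with a flag (`red_on_ultrametric`) to compute
it on the smoothed tree instead; on a unit-depth ultrametric tree RED equals
node depth exactly, which the tests exploit as a closed-form oracle next to
an independently coded naive recursion. A subtree whose branches are all
zero gives `u = 0`; the node then inherits its parent's RED with a warning
rather than failing, since such subtrees do occur in trees built from
near-identical genomes.

## Subgroup delineation

A clade is a subgroup when, simultaneously:

* UFBOOT >= 95 and SH-aLRT >= 80 (non-strict, following the usual
  "well-supported" convention; nodes without supports fail),
* RED strictly greater than 0.4 (the wording "exceeded" is read as strict),
* stem length on the unit-depth ultrametric tree strictly greater than 0.4.

Traversal is preorder and selection is maximal: once a node qualifies, its
descendants are not considered, so subgroups are disjoint — the nesting
behaviour is otherwise undefined, and disjoint subgroups are what the
procedure is for. Thresholds are parameters (`delineation_params()`) with
the values above as defaults. A per-clade exception (one deep-rooting
subgroup delineated at RED 0.3) is expressed as an *override*: a declared
anchor leaf set whose MRCA gets its own RED threshold. That keeps the
exception declarative and reproducible instead of a post-hoc relabelling.
Labels are assigned `A`, `B`, ... in preorder encounter order with children
visited in order of their lexicographically smallest leaf name; any
deterministic order would do, since figure layouts are not recoverable
programmatically. The stem criterion is applied to the subgroup MRCA's stem
only, not to internal branches — the reading consistent with delineating the
clade by its own divergence from the backbone.

## Marker-based genome quality

`refine_marker_set()` drops markers absent from every genome: when a
domain-level marker set is applied to a reduced-genome lineage, universally
absent markers deflate completeness for all genomes equally and carry no
signal. `estimate_quality()` is a deliberately simple flat-list estimator:
completeness = % markers present, contamination = % surplus copies. It
ignores marker collocation, which full-featured tools use; that
approximation is documented on the function and is adequate after
lineage-level refinement, and it makes the estimator exactly testable
(Bernoulli-sampled genomes recover their true completeness within binomial
error, and estimated contamination is monotone in the duplicate rate).
Quality gates take explicit per-gate strictness because both conventions
(`>=50 %/<=10 %` for admission, `>79 %/<5 %` for high-quality
representatives) occur in practice.

## Gene families, occurrence and medoids

Families below 4 total sequences are dropped before tree-based analyses.
Ortholog selection keeps families present in at least
`ceiling(0.85 * n_genomes)` genomes and single-copy everywhere except an
explicit allow-list of genomes where paralogy is tolerated. Occurrence per
subgroup is the percentage of the subgroup's genomes with at least one copy;
`UNGROUPED` and `OUTGROUP` genomes are excluded from the denominator of
every subgroup.

The medoid of a family minimises the summed pairwise distance
`d(a,b) = 1 - S(a,b) / max(S(a,a), S(b,b))` with `S` the global alignment
score under BLOSUM62 (gap open 11, extend 1). Only the substitution matrix
is fixed by the procedure's definition; the normalisation and gap penalties
are package choices, documented and configurable — any monotone rescaling of
scores leaves the argmin unchanged when self-scores are comparable. Ties
break lexicographically by sequence id. Tests check the selection against an
exhaustive brute-force scan.

COG-category compositions include an explicit `NA` class, and a family
annotated with several letters contributes `1/k` to each — the fractional
split keeps every composition summing to exactly 1, which whole-assignment
alternatives do not.

## Reconciliation event summaries

Reconciliation output gives, per family and species-tree branch, expected
frequencies of duplications (D), intra-transfers (T), losses (L) and
originations (O — arrivals from unsampled lineages or de novo genes), plus
expected copy numbers per node. Frequencies are expectations over sampled
reconciliations, so an event is *counted* only when its frequency is
strictly over a threshold, default `tau = 0.3` — deliberately relaxed,
because alignment and gene-tree noise dilute the frequency of true events.
The strict reading follows the "over 0.3" phrasing; `inclusive = TRUE`
provides the `>=` alternative, and the same switch applies to copies, whose
counting convention is ambiguous in prose descriptions. Gains are defined as
D + T + O: printed origination and intra-transfer shares of gains (43 % and
32 % on the focal branch) sum to well under 100 %, implying a third gain
component, consistent with duplications. Shares are reported to the nearest
whole percent, `NA` when a branch gained nothing.

Two dialects are parsed: a bit-exact simple TSV
(`family branch D T L O copies`) and per-family ALE 1.0 `uml_rec` files,
from which the `S_terminal_branch`/`S_internal_branch` table rows are read.
Absent cells are zero; unknown branch ids and negative frequencies are
errors reported with line numbers.

## [FeFe]-hydrogenase operons and motifs

Group A [FeFe] hydrogenases are not reliably subtyped by phylogeny and are
classified by gene organisation. The trimeric group A3 form is a catalytic
H-cluster subunit with nuoF-like and nuoE-like partners; cladeforge encodes
"trimeric context" as: each partner within at most `max_gene_gap = 1`
intervening gene of the catalytic gene, on the same strand by default. The
numeric window is a package decision — organisations are usually shown
graphically, not as a rule — and both knobs are arguments. The
classification is invariant under reversing gene order with a strand flip,
and that invariance is property-tested.

Motif windows (P1/P2/P3) are inputs, as alignment-coordinate column ranges,
because published positions are only meaningful in their own trimmed
alignment. Profiles are exact per-column empirical frequencies including the
gap character; conservation against reference sequences requires identity
with *every* reference at the column; hydrophobicity classes use the
Kyte–Doolittle scale (no scale is canonical for this display; the neutral
band is ±0.5 by default and configurable). Catalytic-cysteine checks require
`C` at every listed column; a gap fails.

## The synthetic-data generators

Every pipeline input has a seeded generator (`sim_config()`), and each
generator draws from its own stream derived from the master seed and the
generator's name, so outputs are byte-reproducible and adding a generator
never perturbs existing ones.

The default configuration emulates the statistical shape of a
phylum-level MAG study: 152 leaves; 10 planted clades of sizes
26, 20, 18, 16, 15, 14, 12, 10, 9, 8 (148 genomes) with stems of 0.45 and
RED targets 0.46–0.64 on a unit-depth ultrametric tree (margins of at least
0.05 over the 0.4 thresholds, so recovery is a property of the method, not
of luck at the boundary); two outliers attached to failing-support (90/70)
backbone nodes; 143 markers; thousands of gene families with a handful of
clade-enriched ones per subgroup (presence 0.9 inside vs 0.1 outside); 2320
reconciled families; and a 60/20/20 mixture of trimeric, untyped and
non-hydrogenase operons. Trees are generated *directly* as unit-depth
ultrametric ladders with coalescent clade interiors, which makes the planted
RED of a clade equal to its depth exactly.

Reconciliation noise is truncated on both sides of `tau`: true events report
`1 - min(|N(0, 0.1)|, 1 - tau - 0.01)` and non-events report 0 or
sub-threshold noise. The truncation is a deliberate choice so that the
round-trip test (generator truth vs thresholded counts) is exact rather than
probabilistic; it also means the generators do **not** model the hard part
of real reconciliations — frequencies hovering at the threshold. Likewise
the tree generator plants clean margins rather than boundary cases (those
are tested separately and exactly), marker presence is independent across
markers (no collocation structure), family presence is independent across
genomes given the subgroup, and the motif alignments have i.i.d.
substitutions with no indels. Passing the recovery tests therefore shows the
*procedures* are correct and their thresholds act as specified; it does not
show that real MAG data are this well separated.

## Problem sizes and numerical choices

The test suite runs the RED oracle on 100 random trees of 4–64 leaves,
delineation recovery on 50 study-shaped trees (152 leaves each),
quality recovery on 200 genomes x 143 markers, reconciliation round trips on
50 seeded tables of 400 families x 20 branches, and medoid agreement on 20
families of 3–10 sequences — sizes chosen so the full suite completes in
about a minute while keeping every statistical check comfortably powered.
Numerical tolerances are 1e-9 for tree geometry and RED, 1e-12 for
probability sums; trees are serialised with 9 significant digits, so one
write/read round trip moves a branch length by at most half an ulp at that
precision. Degenerate inputs have defined behaviour rather than crashes:
all-zero trees are an error for depth normalisation, all-zero subtrees
inherit parental RED with a warning, empty family sets give empty
compositions, and a branch without gains reports `NA` shares.

## Limitations

* Completeness/contamination estimation ignores marker collocation and
  lineage-specific marker weighting; it is a transparent approximation, not
  a replacement for a full quality tool.
* Delineation depends on the supplied supports; trees without support
  labels cannot yield subgroups (by design — unsupported clades fail).
* The MPL ultrametric conversion is not a dating method; stems on the
  normalised tree are relative, not ages.
* Reconciliation parsing consumes event frequencies; it does not run or
  validate the reconciliation sampler itself.
* Operon classification trusts the provided domain labels; no HMM search is
  performed.
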