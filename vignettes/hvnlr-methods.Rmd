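---
title: "Partitioning pan-NLRomes and predicting binding sites from sequence diversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning pan-NLRomes and predicting binding sites from sequence diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hvnlr)
```

## The problem

Plant genomes carry large repertoires of Nucleotide-binding Leucine-Rich
Repeat (NLR) immune receptors, and pan-genome sequencing of many accessions
(ecotypes) of a species shows that allelic diversity is distributed very
unevenly across the family: most NLR lineages are nearly invariant between
accessions, while a minority accumulates exceptional amino-acid diversity.
Receptors in that minority — highly variable NLRs, or hvNLRs — are
candidates for direct pathogen-effector binding, and the residues driving
their diversity are candidate specificity determinants. This package
implements the full computational chain for that analysis: grouping a
pan-NLRome into near-allelic clades on a shared NB-ARC phylogeny, scoring
per-column diversity of clade alignments, flagging hvNLR clades, projecting
high-diversity residues onto the leucine-rich repeat (LRR) surface, and
checking the resulting binding-site predictions against an experimental
receptor–ligand structure.

The package consumes the outputs of standard external tools (an aligner
such as PRANK or MAFFT, and a maximum-likelihood tree builder such as
RAxML); it does not infer alignments or trees itself.

## Clade partition

The unit of analysis is a *near-allelic clade*: a phylogenetic group that
approximates the alleles of a single gene across ecotypes. Because NLR
lineages diversify at very different rates, fixed-threshold distance
clustering tends to shatter exactly the high-diversity clades that matter;
a phylogeny-based partition does not.

**Initial assignment** (`initialAssignment()`). For every leaf of the
rooted NB-ARC tree, the containing clade with size inside a window
(default 40–500 sequences) and the strongest bootstrap support is
selected; leaves with no clade in the window fall back to smaller clades,
again by maximal support. Selected clades are made non-nesting by
discarding any selected clade wholly contained in another, whose leaves it
inherits; since clades of a tree are either nested or disjoint, the result
is a disjoint, exhaustive partition. Three deterministic tie-break rules
apply when supports are equal: prefer the larger clade, then the clade
whose defining node is closer to the root. Missing supports count as zero
so that unsupported groupings never win. The test suite checks this
procedure against an independent brute-force implementation on hundreds of
random trees.

**Refinement** (`refineClade()`). Each clade's own full-length-alignment
tree is then cut into subclades by branch length (substitutions/site):

* branches longer than `long_branch_cutoff` (default 0.3) are always cut;
* branches at or below `short_branch_cutoff` (default 0.1) are always
  retained;
* intermediate branches are cut when bootstrap support is at least
  `intermediate_support_min` (default 70) **and** the Jaccard index of the
  ecotype sets on the two sides is at most
  `intermediate_ecotype_jaccard_max` (default 0.25).

The intermediate rule deserves a note: the original procedure for this
band of branch lengths was interactive tree inspection, weighing bootstrap
support and ecotype overlap by eye. Reproducibility requires removing the
human step, so this package encodes that judgement as the explicit
support-and-Jaccard rule above, with both thresholds exposed in
`partitionConfig()` and every per-branch decision recorded in a log table
(branch length, support, Jaccard, rule fired, cut or kept). The rule is a
declared automation of the manual step, not a reconstruction of it; users
who disagree with a particular cut can replay the log and adjust the
thresholds. Only internal branches are considered, so refinement alone
never produces singleton clades. Terminal gap-rich alignment columns can
be removed beforehand with `maskGappyColumns()` (columns with ≥ 90% gaps
by default, the convention for first-round refinement).

`allelicSeriesStats()` summarises how allelic the final partition is: the
fraction of clades with at most one gene per represented ecotype, and the
fraction of sequences in clades of at least 20 genes (clades that are
large enough to sample diversity meaningfully).

## Diversity profiling

Per alignment column the package computes the plug-in Shannon entropy

$$H = -\sum_{i=1}^{20} p_i \log_2 p_i,$$

where $p_i$ is the frequency of amino acid $i$ among the counted residues
of the column. Gap characters and ambiguity codes (`X`, `B`, `Z`, `*`)
are excluded from both numerator and denominator: the frequencies are over
the 20 standard amino acids only. $H$ is 0 for an invariant column, 1 bit
for a balanced two-residue column, and at most $\log_2 20 \approx 4.32$
bits. No small-sample correction is applied — the plug-in estimator is the
statistic itself here, and the per-column count of observed residues
(`n_obs`) is reported so users can filter sparse columns if they wish.

A clade is called **hvNLR** when its alignment has at least
`min_positions` (default 10) columns with $H \ge$ `entropy_cutoff`
(default 1.5 bits); both comparisons are inclusive. The per-column
hydrophobic percentage uses the residue set {A, V, L, I, M, F, W, C} by
default — the aliphatic and aromatic side chains typical of
protein–protein interface cores — and is configurable because no single
canonical set exists.

Two conventions were genuinely open and are fixed as follows. First, hv
classification runs on unmasked alignments (masking is a refinement-stage
device; profiling reports gap-aware counts anyway). Second, when
high-entropy columns are tallied per domain (`countHvByDomain()`, over
preNB / NB-ARC / linker / LRR / postLRR intervals on a reference gene),
columns where the reference is gapped — or that fall between annotated
intervals — are attributed to the nearest *preceding* domain and flagged
in the output; columns before any domain go to preNB. Some convention is
required because entropy lives on alignment columns while domains live on
one reference sequence; "nearest preceding" keeps insertions with the
domain they extend.

## LRR surface mapping

LRR domains fold predictably: the 8-residue LxxLxLxx core of each repeat
contributes a beta strand whose conserved leucine-class positions (core
offsets 1, 4, 6) are buried, while the intervening positions are exposed
on the concave face. This makes a 2D surface approximation possible
without structure prediction. `annotateLrr()` finds repeat cores by a
greedy left-to-right scan for the pattern (aliphatic class at offsets 1,
4, 6; default class {L, I, V, F, M, C, A}, minimum 8 residues between
core starts). The detector is deliberately a configurable stand-in for
expert annotation — the tolerance real annotators use is not a published
constant — and user-supplied repeat tables are first-class inputs that
bypass detection entirely. On random (non-repeat) sequence the pattern
will match by chance, so detection should be run on, or restricted to, the
annotated LRR region.

`buildSurfaceMatrix()` lays the repeats out as rows and repeat-relative
positions as columns: core positions 1–8 plus five flanking residues on
either side, labelled −5…−1 and 9…13 (there is no position 0). When
adjacent repeats sit closer than the full flank width, each inter-core
residue is assigned to the nearer core, ties to the preceding repeat —
this guarantees every reference residue occupies at most one cell, which
the class validity enforces. Hiding columns 1, 4 and 6 reproduces the
concave-face array; `trimMatrix()` keeps the nine surface-informative
positions {−2, −1, 2, 3, 5, 7, 8, 10, 11} used for compact comparisons
across receptors. `surfaceReport()` overlays entropy and hydrophobicity
and flags candidate binding cells: entropy at or above the cutoff in a
column that contains hydrophobic residues.

## Structural evaluation

Given a receptor–ligand complex, `contactsFromStructure()` defines the
true binding residues: a receptor residue is a contact when any of its
heavy atoms lies within `cutoff` Å (default 4.5) of any ligand heavy
atom. The distance criterion is a package default, chosen as the common
any-heavy-atom convention, and is configurable — published analyses of
specific complexes do not always state theirs, so evaluations against
real structures are sensitive to this choice. `precisionRecall()` then
sweeps entropy cutoffs (default 0.1–3.0 bits in 0.1-bit steps, bracketing
the useful 0.8–1.8 bit range) and reports, per cutoff, the predicted
residue count, precision (NA when nothing is predicted, rather than an
arbitrary 0 or 1) and recall. Recall and the predicted count are
non-increasing in the cutoff by construction, and the implementation is
tested against a brute-force set-arithmetic oracle. `entropyToStructure()`
plus `writeAttributeFile()` export per-residue entropies as UCSF Chimera
attribute files (and iTOL annotations for trees) for visualisation.

## The synthetic generator

`simulateNlrome()` provides the controlled testbed for every claim above.
It emulates: a pan-genome of `n_ecotypes` accessions (default 62) and
`n_families` NLR families (default 20); allelic structure (one gene per
ecotype per family, unless duplications are injected at
`duplication_rate`); a gene tree whose within-family branches are short
(subtree depth `intra_branch_scale` = 0.04 substitutions/site, below the
0.1 retain threshold) and whose between-family branches are long (0.6,
above the 0.3 cut threshold) with full support on family nodes and weak
support on the backbone; per-family alignments in which a fraction of
families (default 0.25) carries `n_hv_columns` (default 15) planted
high-diversity columns at surface-exposed LRR positions, drawn i.i.d.
from `hv_k` = 6 equiprobable residues (expected entropy
$\log_2 6 \approx 2.58$ bits, comfortably above the 1.5-bit cutoff, while
`hv_k = 2` cannot exceed 1 bit and must not classify); a near-invariant
background (per-residue substitution probability 0.005); and gap
structure from terminal truncations plus short internal deletions. The
reference sequence of each family is the ungapped family consensus, so
repeat and domain coordinates are exact.

Evolution is simulated by independent per-column sampling, not by a
substitution-model simulator along the tree. That is a deliberate trade:
per-column sampling gives analytically known expected entropies, which is
what the downstream assertions need, at the cost of realism. Consequently
passing tests demonstrate correctness of the machinery — partition rules,
entropy arithmetic, surface geometry, contact evaluation — under the
stated conditions; they do not demonstrate robustness to phylogenetic
autocorrelation, recombination, gene conversion, alignment error, or
annotation noise, all of which real pan-NLRomes contain. All sampling
flows through one seeded generator, so a configuration reproduces its
outputs byte for byte.

## Problem sizes and numerical choices

The test suite verifies the initial-assignment rule against brute force on
100 random trees of up to 12 leaves, the branch rules on 100 random clade
trees, precision/recall against set arithmetic on 200 random instances,
and full family-and-hv recovery on 20 simulated pan-NLRomes at the default
configuration (20 families × 62 ecotypes, alignments of 606 columns).
These sizes were chosen so the whole suite completes in well under a
minute while still exercising every rule branch; all are ordinary
single-CPU workloads. Entropies are compared exactly where analytic
(0, 1, $\log_2 20$) and to standard floating-point tolerance elsewhere.
Degenerate inputs are defined, not patched around: all-gap columns have
zero entropy and zero hydrophobicity with `n_obs = 0`; a clade tree with
all internal branches retained refines to itself; an empty repeat scan is
a valid annotation; precision at zero predictions is missing.

## Known limitations

* The intermediate-branch rule is an automation of an expert judgement;
  its two thresholds are honest knobs, and different settings change the
  final clade count.
* The repeat detector is pattern-based and will both miss irregular
  repeats and fire on random sequence; curated repeat annotations are
  preferred where available.
* Entropy is computed per column without phylogenetic weighting, so a
  clade dominated by one expanded lineage can overstate or understate
  diversity relative to an ecotype-balanced sample.
* The contact definition (any heavy atom, 4.5 Å) is one of several
  reasonable conventions; precision/recall against real structures shifts
  with it.
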