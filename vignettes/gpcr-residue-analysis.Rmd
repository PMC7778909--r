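---
title: "Residue-level GPCR analysis: numbering, property conservation, signatures and segment RMSD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residue-level GPCR analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcrsig)
```

G protein-coupled receptors (GPCRs) share a seven-transmembrane (7TM)
architecture that makes residue positions comparable across hundreds of
receptors once they are indexed by *generic residue numbers*. `gpcrsig`
implements the residue-level machinery built on that idea: numbering-scheme
conversion, a physicochemical property taxonomy for measuring positional
conservation, a two-set sequence-signature algorithm for finding functional
determinant positions, and a segment-wise RMSD protocol for comparing
structure models. This vignette records the models, the tunable parameters,
and the design decisions behind each component.

## Generic residue numbering

Each annotated segment (TM1–TM7, H8, ICL1/2, ECL1/2) anchors its numbering at
a reference residue assigned index 50; other residues count contiguously
outward. Two schemes coexist:

* **sequence-based** (Ballesteros–Weinstein style, `5.42`): counts residues
  along the gene product, suited to evolutionary comparisons;
* **structure-based** (`5x43`): aligns *structurally equivalent* positions,
  so a helix **bulge** (a one-residue insertion relative to the structural
  consensus) gets a three-digit number (`5x461`) and a **constriction** (a
  one-residue deletion) makes the scheme skip an index.

On the affected side of an offset, structure-based indices therefore run one
ahead (bulge) or one behind (constriction) of sequence-based indices, while
index 50 is fixed in both schemes. Because 50 is fixed, the side that shifts
is fully determined by which side of 50 the anchor sits on;
`offset_annotations()` validates the `applies_before_anchor` flag against
that fact rather than trusting it.

Conversion is implemented by materialising the segment's *physical residue
map*: the ordered list of consensus slots with bulge rows inserted and
constriction slots removed, with sequence indices assigned contiguously so
that both schemes agree at 50. Conversion is then a table lookup. This
makes round-trips exact by construction for arbitrarily many offsets per
segment, at the cost of bounding indices to 1–99 (ample for GPCR segments).
A structure-based index removed by a constriction, or a bulge digit without
a matching annotation, has no counterpart and raises an error rather than
guessing. Multiple *adjacent* bulges are rejected: no published convention
covers the digit assignment, so we refuse rather than invent one silently.

Offsets are curated inputs, not inferred from structures. The shipped class
A annotation (`class_a_offsets()`) carries the TM5 bulge (anchor 46,
extracellular side) and the TM7 extracellular constriction, which reproduce
the canonical pairs `5.42 ↔ 5x43` and `7.32 ↔ 7x31` and the bulge residue
`5.46 ↔ 5x461`:

```{r numbering}
convert_generic(c("5.42", "7.32", "6.51"), class_a_offsets())$text
```

Loop positions use two-digit segment codes (ICL1 = 12, ECL1 = 23, ICL2 = 34,
ECL2 = 45) with the same index-50 anchoring. Whether loop positions can
carry bulge digits is undefined in any scheme we know of; the parser rejects
them.

## The 56 amino-acid property groups

Positional conservation of amino-acid *identity* is too strict for
function: positions that bind the same ligand moiety often admit several
residues sharing a property. The taxonomy therefore groups amino acids by a
base property (charge, hydrogen-bond donor/acceptor capacity,
aromatic/aliphatic character, size, helical propensity) refined by the
**backbone bond distance**: the number of covalent bonds from Cα to the most
terminal sidechain atom bearing the property, computed here by
breadth-first search over embedded heavy-atom sidechain graphs. A group is
a base property plus either any distance or a bin of at most two consecutive
distances, and its membership is *derived*, not listed — editing the
sidechain topology or the bins regenerates the memberships.

The charge subtree is fixed by the published decomposition — 12 groups:
any-charge with bins {any, 3–4, 4–5}, negative with {any, 3, 4} (Asp at 3,
Glu at 4), and positive with {any, 4, 4–5, 5, 5–6, 6} (His 4, Lys 5,
Arg 6). Realising the positive bins requires classifying histidine as
positively charged, which we do. The remaining 44 groups are this package's
reconstruction: donor and acceptor subtrees with singleton and paired bins,
a combined hydrogen-bonding subtree with paired bins (mirroring the
any-charge pattern), aromatic and aliphatic subtrees, and any-distance-only
size and helical-propensity classes (those properties have no single
characteristic atom, so distance bins would be arbitrary). The full table
ships as an editable TSV (`system.file("extdata", "property_groups.tsv",
package = "gpcrsig")`) and is validated on load (56 groups, non-empty
memberships, consecutive bins), so it can be revised against any external
reference without touching code.

```{r groups}
groups <- aa_property_groups()
dplyr::count(groups, base)
```

Conservation of a group at an alignment column is the percentage of
receptors whose residue belongs to the group. Two conventions matter and
are deliberate:

* **gap rows stay in the denominator** — a receptor that lacks the
  structural position is evidence against the property being conserved
  there, and this keeps signatures robust to rows missing a segment.
  `n_nongap` is reported so callers can re-normalise if they prefer the
  other reading, which is defensible but unverifiable from published
  material;
* `X` (unknown residue) counts in the denominator and belongs to no group.

Percentages are carried at full floating precision; rounding happens only
at presentation.

## z-scale descriptors

Each amino acid also carries the five-component z-scale descriptor vector
(principal-component scores over experimental and calculated
physicochemical properties; published constants embedded in
`aa_zscales()`). Per column, `column_profiles()` reports the mean and
standard deviation of each z-scale over non-gap residues; all-gap columns
are flagged and their z summaries are `NA` rather than 0.

## The sequence signature

Given two alignments over the same column list — receptors *with* and
*without* a function of interest — `compute_signature()` scores every
column with every group's conservation difference (set 1 minus set 2) and
selects, per column, the group with the largest absolute difference. Ties
are broken toward the **fewest distinct member amino acids** (the most
restrictive, hence most informative, group), then by taxonomy order so
output is reproducible. Columns whose best absolute difference reaches the
cutoff (inclusive `>=`; published usage does not state strictness, and the
inclusive reading keeps a 100% separation detectable at a 100 cutoff) form
the signature. A negative difference marks a property *depleted* in set 1 —
exclusion features such as "not small" are represented by this polarity,
not by complement groups.

Each entry carries Welch two-tailed t-tests (via `stats::t.test`) on the
five z-scales. Two contrasts are implemented behind the `ttest` switch
because the published description admits both readings:

* `"sets"` (default): set-1 versus set-2 descriptor values at the column —
  this matches how the statistics are used to colour the two sets'
  differences;
* `"conservation"`: residues inside versus outside the selected group,
  pooled over both sets.

The Welch (unequal-variance) variant is used; the published description
says only "two-tailed t-test", and Welch is the safer default for unequal
set sizes. Degenerate inputs follow fixed conventions: fewer than two
values in either set is "not computable" (flagged, never an error); two
constant samples give p = 1 when equal and p = 0 when distinct. The
significance flag is exactly `p <= 0.05`.

`match_signature()` scores any receptor against a signature: a position
matches when the residue is a member of the entry's group (or, for
set-2-enriched entries, when it is not). A gap never matches under either
polarity — an absent residue is no evidence of sharing the function.

```{r signature}
fx <- ergotamine_fixture(seed = 1)
sig <- compute_signature(fx$aln1, fx$aln2, cutoff = 50)
sig[, c("position", "group", "polarity", "difference")]
glance(sig)
```

## Segment-wise RMSD

`superpose_rmsd()` implements the model-evaluation protocol: pair the atoms
present in both coordinate sets (on generic position + atom name when
available, else residue number + atom name), fit **one** least-squares
rigid-body superposition (Kabsch, via SVD with a determinant correction
enforcing a proper rotation) on the paired 7TM backbone atoms — backbone
taken as {N, CA, C, O} — and evaluate every reporting scope (7TM all atoms,
7TM backbone, ICL1/2, ECL1/2/3, H8) under that single transform, without
per-segment re-fitting. Loop scopes therefore measure how well the loop
sits *given* the helix-bundle frame, which is the quantity the protocol is
after. Fewer than three paired fit atoms is an error; hydrogens are
excluded on reading (their presence is inconsistent across structures);
alternate locations keep the highest-occupancy altloc so pairing is
deterministic.

## What the synthetic generators emulate — and what they do not

`generate_contrast_alignments()` emulates the *statistical structure* of a
selectivity case study: a handful of fully property-separated positions
planted among background columns shared by both sets. Defaults are two sets
of 8 receptors, 50 columns and 5 planted positions — set sizes and planted
count mirror the published ergotamine case (7–9 strong binders versus
non-binders, five headline determinant positions), and 50 columns
approximates the numbered extent of the 7TM bundle at one column per
generic position per segment stretch. With equal set sizes, background
columns hand both sets the *same* residue multiset (row-permuted), so
background conservation differences are exactly zero and recovery of the
planted truth is exact at any positive cutoff; with unequal sizes,
backgrounds are drawn independently from the same distribution and carry
binomial sampling noise. Real alignments differ in ways the generator does
not model: phylogenetic correlation between receptors, segment-length
variation and gap blocks, and partially (rather than fully) separated
determinants. Passing the planted-recovery tests therefore demonstrates
correctness of the algorithm, not an error rate on real receptor sets.

`generate_toy_structures()` builds an ideal helical backbone (1.5 Å rise,
100° twist, four backbone atoms per residue) and a copy moved by a random
rigid transform plus an optional per-atom displacement of known magnitude —
enough to exercise rigid-motion invariance, closed-form single-displacement
RMSDs and agreement with a brute-force rotation-grid oracle, but not a
model of real structural error, which is spatially correlated.

Published model-benchmark figures (e.g. per-segment RMSD deltas between
modelling pipelines over 21 receptors) depend on external experimental
structures and third-party models and are out of scope here; the test suite
replaces them with the property-based checks above.

## Problem sizes and numerical choices

The default verification sizes — 1 000 randomised annotation sets for
numbering round-trips, 100 seeds for planted-signature recovery, 1 000
random pairs for the Welch cross-check at 1e-9, 100 random 5×10 alignments
for the conservation oracle, and ≤ 10-atom clouds for the rotation-grid
oracle at 1e-3 Å — were chosen as the package's own verification scale:
large enough that each property is exercised across its input space, small
enough to run interactively. Ties in consensus/signature selection are
resolved deterministically (cardinality, then taxonomy order); random
number use is always routed through an explicit seed and restores the
caller's RNG state.

## Known limitations

* The 44 non-charge property groups are a reconstruction; the shipped TSV
  is the contract, flagged as editable, not a published reference.
* Sequence-based numbering is modelled class-agnostically: class-specific
  schemes differ only via the curated reference annotations supplied, which
  is sufficient for conversion but does not encode class B/C/F naming
  conventions.
* Multiple adjacent bulges, and bulge digits on loop positions, are
  rejected rather than numbered.
* `7TM_all` means all *heavy* atoms; hydrogens are never included.
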