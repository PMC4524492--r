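---
title: "Methods: comparative plastome architecture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative plastome architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastarch)
```

`plastarch` analyzes the architecture of circular chloroplast genomes:
the large inverted repeat (IR) and the quadripartite layout it induces,
signed circular gene orders and their strand clustering, exact inversion
distances between genomes, Dollo-parsimony histories of binary genomic
characters on a fixed rooted phylogeny, exact repeat landscapes, and
nucleotide composition. This vignette records the models, the parameter
choices and their rationale, the numerical conventions, and what the
simulator-based validation does and does not establish.

## Coordinates and containers

All genomic intervals are 0-based and half-open, which keeps arithmetic on
circular molecules unambiguous; a feature that wraps the origin is stored
as two sub-intervals sharing one feature id. A genome is a `plastome`
(sequence string plus a feature tibble); gene orders are tibbles with one
row per gene (`taxon`, `position`, `symbol`, `sign`) so that multi-genome
sets stack into one long table and flow through dplyr verbs; trees are
`ape::phylo` objects. User-facing functions take these tables first and
return tibbles, with `tidy()`/`glance()`/`autoplot()` methods on the
structured results.

## Sidedness

For a circular signed gene order of `n` genes forming `n_SB` maximal
same-strand blocks, the sidedness index is
`C_s = (n − n_SB) / (n − 1)`. Because plastomes are circles, blocks are
counted circularly by default — the first and last runs merge when they
share a strand — with a `circular = FALSE` switch for sensitivity
analysis, since linear counting can differ by exactly one block. The index
is 1 when all genes are cotranscribed from one strand and 0 when strands
strictly alternate. The implementation is audited in the tests against
brute-force run counting over every rotation.

## Signed reversal distance

Two circular gene orders on the same gene set are compared by the minimum
number of segmental inversions separating them. We use the standard
equivalence between circular and anchored-linear signed reversal distance:
both circles are rotated (and reflected if needed) so a shared anchor gene
sits first on the forward strand, the target order is renumbered to the
identity, and the Hannenhalli–Pevzner formula

d = (m + 1) − c + h + f

is evaluated on the breakpoint graph of the framed permutation, with `c`
the number of cycles, `h` the number of hurdles and `f` the fortress
indicator. Components are built by joining gray edges that share a cycle
or whose position intervals strictly cross; a component is unoriented when
none of its gray edges connects same-parity positions. Hurdles are
detected with the circular-contiguity criterion — an unoriented component
whose vertices form a single contiguous run in the circular order of all
unoriented-component vertices — which uniformly covers both minimal and
"greatest" hurdles; a hurdle is a superhurdle when deleting it promotes a
protected non-hurdle component, and a fortress is an odd number of hurdles
all of which are superhurdles. The anchor choice provably does not affect
the distance, and the suite verifies this exhaustively on small orders.

Correctness is established against an independent oracle: breadth-first
search over the inversion graph, exhaustively for every signed permutation
of up to six elements (46,080 permutations in the acceptance suite, up to
five in the unit suite). Fortresses require three or more superhurdles and
first arise far beyond that range; their handling follows the standard
theory and is exercised on constructed nested-component cases. The
interleaving test is quadratic in the number of genes, which is ample at
plastome scale (about 100 genes).

Genomes with unequal gene sets are compared on their symbol intersection
with a warning, mirroring the fixed shared-gene matrices used in
comparative studies.

## IR detection and quadripartite partitioning

The IR detector finds the longest pair of exact, non-overlapping,
reverse-complementary segments of length at least `min_len` (default
1,000 bp). Exactness is a deliberate v1 scope decision: real plastome IR
copies are homogenized by recombination and are typically identical, and
an exact definition makes detection deterministic and testable; a
mismatch-tolerant mode is out of scope. The default cutoff sits far below
real IR sizes (the smallest true IR in the packaged study table is
6,786 bp) while staying above background palindromic noise. Ties are
broken toward the candidate containing `rrs` — the IR characteristically
encodes the rRNA operon — then by leftmost start. The two single-copy gaps
are labeled purely by length (longer = LSC), and the identity
`2·IR + LSC + SSC = genome length` plus the exact reverse-complement
identity of the copies are asserted on every detection.

Partition classification assigns each gene to IR, LSC or SSC from its
coordinates; a gene spanning an IR junction is assigned to the single-copy
side, the convention used in study figures of gene partitioning. Ancestral
sides come from a packaged curated table encoding the
prasinophycean/streptophyte-like pattern: the rDNA operon
(`rrs, trnI(gau), trnA(ugc), rrl, rrf`), an SSC-side set (`psaC`, `ccsA`,
`rpl32`, `rps15`, `chlB/L/N`, `trnL(uag)`), and everything else LSC-side.
Genes observed in the single-copy region opposite their ancestral side are
flagged as relocations.

The rDNA operon check declares an internal adjacency broken when the two
genes are not adjacent in the signed order, not colinear in sign, or —
when coordinates are available — separated by more than `max_spacer`
(default 3,000 bp, chosen because a linked-but-distant gene pair with a
spacer above about 3 kb is unlikely to be cotranscribed). Orientation is
reported relative to the SSC when an IR annotation makes that meaningful.

## Dollo parsimony

A binary character under the Dollo principle is gained exactly once and
only lost afterwards. On a rooted tree the loss-minimal single-gain
reconstruction is unique: gain at the MRCA of the state-1 leaves, one loss
on the branch to every maximal subtree of that clade containing no state-1
leaf. Rooting is required (the packaged study tree is rooted on the
pedinophycean branch); polytomies are permitted, each polytomy child
branch counting its own loss. Leaves with unknown state (incomplete
genomes) are excluded from gain placement and never force a loss, but are
reported. The tests compare loss counts against an independent dynamic
program minimizing losses over all single-gain placements, on random trees
of up to ten leaves, and assert that replaying the reconstruction down the
tree reproduces every observed leaf state. A complementation-asymmetry
test guards against accidentally implementing an unrooted/Fitch-style
criterion.

## Repeat landscape

Maximal exact repeats are found by seeding identical k-mers — within the
sequence for direct repeats, between the sequence and its reverse
complement for palindromic ones — and merging runs of seeds along
diagonals. Because a seed is taken at every position, a maximal run on a
diagonal corresponds exactly to a maximal (inextensible) match, so
boundaries are exact; every emitted hit is re-verified by string
comparison before it is reported. The seed length is
`min(min_len, 32)` so that any match at or above the reporting cutoff
(default 30 bp) contains a seed at every offset. Circular detection
doubles the sequence (capped), reports coordinates mod the genome length
and deduplicates. Masking counts every position once regardless of
coverage depth; distinct elements for the six size classes (30–39, 40–59,
60–89, 90–149, 150–249, ≥250 bp) are connected components of overlapping
hit intervals grouped by exact sequence identity — a deliberate
simplification relative to similarity-based repeat-family clustering, and
labeled as such. The two large IR copies are excluded from the masked
fraction by default, since study tables list the IR separately from the
small-repeat percentage; `include_ir = TRUE` reverses this. The suite
checks the finder against a quadratic all-substring-pair brute force on
sequences up to 2 kb and checks the algebraic identity that the
length-weighted mean of repeat and unique G+C equals whole-genome G+C to
1e-9.

## Composition

A+T percent is `(A+T)/(A+C+G+T) × 100` with ambiguity codes excluded from
both numerator and denominator; G+C by codon position is computed over the
concatenated in-frame coding sequences, again excluding ambiguity codes
position-wise. Stop codons annotated within the CDS span are included by
default (configurable), a choice that shifts third-position G+C only
marginally at plastome scale.

## The synthetic plastome evolver

The simulator is the package's test bed: it generates an ancestral
quadripartite genome and evolves it along a rooted tree, logging every
event so that any downstream inference can be compared with planted truth.

The ancestor realizes the layout LSC | IRA | SSC | IRB with IRB the exact
reverse complement of IRA — the quadripartite invariants hold by
construction — and the rDNA operon colinear at the SSC-proximal end of
IRA on the forward strand, i.e. transcribed toward the SSC as in
ancestral-pattern plastomes. Defaults emulate a mid-sized AT-rich
plastome: 91 standard genes (the packaged core set, with the curated
SSC-side genes in the SSC so the ancestor classifies with zero
deviations), a 10-gene IR, a 120 kb length target and 65% A+T — typical
values for the compact half of the size range in the packaged study
table. rRNA genes get
realistic lengths (about 1.4 kb, 2.8 kb and 120 bp), tRNAs 72 bp, and
protein genes random in-frame lengths of 150–450 codons; gene sequence
content is random at the target composition. The simulator targets
architecture, not homology — no substitution model, no intron mobility —
because no alignment stage exists downstream.

Per branch, Poisson numbers of events are drawn at configured rates:
inversions with uniform endpoints confined to one region (an inversion
never takes one endpoint inside a single IR copy and the other outside,
keeping the copies identical by construction); IR boundary shifts moving
one gene across a junction, duplicated or deduplicated in both copies;
irreversible IR loss (IRB deleted, later IR events skipped); and insertion
of small direct or palindromic repeats (30–120 bp by default) into
single-copy spacers. Default rates (inversion 1, boundary shifts 0.2
each, loss 0.05, repeat insertion 0.5 per branch) give trees in which most
lineages keep an ancestrally recognizable architecture while deeper clades
accumulate visible rearrangement — the regime the analysis stages are
meant for. Every event is logged with explicit parameters (including the
inserted repeat sequence), and tip sequences derive from per-tip seeds, so
replaying a truth log is bit-identical. One realization detail matters for
exactness: after assembly, a single spacer base is edited wherever a
chance complementary base would extend the planted IR, so the planted
coordinates are exactly the maximal ones the detector must find.

What passing simulator-based tests shows: the detectors and distances
recover planted architecture exactly under the stated event model. What it
does not show: robustness to annotation noise, near-identical (inexact)
IR copies, nested repeat families, or sequence-level homoplasy — real
accessions bring those, and the exact-match design decisions above define
how far the guarantees extend.

## Study fixtures

The package ships a transcription of the 38-taxon study table (metadata,
quadripartite lengths validated against the `2·IR + LSC + SSC` identity,
gene counts in the published 105–114 range) and the matching rooted
phylogeny; shallow nodes not pinned down by the running text are stored as
polytomies and listed in the fixture manifest, which also carries md5
checksums enforced at load. One row is worth noting: one prasiolalean
genome carries an 8.3 kb IR that lacks the rRNA genes, so the table
distinguishes `ir_present` (any large IR, 19 genomes) from `ir_rdna` (an
rDNA-encoding IR, 18 genomes); Dollo mapping of `ir_rdna` on the packaged
tree yields seven independent losses, falling in the clades the study
names. Intron counts in the source table could not always be split
unambiguously between the group I and group II columns; they are
best-effort and no analysis in this package depends on them.

## Problem sizes used in validation

The routine suite exercises: exhaustive reversal-distance checks for all
signed permutations up to size 5 (size 6, 46,080 permutations, in the
acceptance tests), simulated clades of five 25 kb genomes, brute-force
repeat scans on sequences up to 2 kb, Dollo brute force on trees up to ten
leaves, and 200 seeded inversion-recovery runs on 40-gene orders. These
sizes were chosen to pin down each algorithm's behavior exhaustively where
the state space allows it and statistically where it does not, while
keeping the full suite comfortably interactive.

## Known limitations

* Exact-match IR detection and exact repeats only; degenerate copies are
  out of scope by design.
* Repeat "families" are exact-identity groups, not similarity clusters.
* The reversal distance models inversions only — no translocations,
  transpositions, or rearrangement medians — matching its role as a
  pairwise architectural distance.
* Dollo mapping reports the unique loss-minimal single-gain
  reconstruction on the given rooted tree; alternative scenarios on other
  rootings or with de novo re-gains are not explored.
* The GenBank parser targets the feature-table subset common to organelle
  records (CDS/tRNA/rRNA/gene keys, join/complement locations); exotic
  location operators are rejected with a pointer to the offending line.
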