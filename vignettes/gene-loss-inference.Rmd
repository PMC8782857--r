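---
title: "Inferring gene loss from comparative genomic sequences"
author: "geneDecay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring gene loss from comparative genomic sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geneDecay)
```

## The inference problem

A gene is pseudogenized when it accumulates mutations that destroy its
protein-coding capacity: insertions or deletions whose length is not a
multiple of three (frameshifts) and substitutions that create an in-frame
stop codon before the natural one (premature stops). Given genomic
sequences from many species, an intact reference ortholog and a rooted
species tree, the package answers three questions in sequence:

1. *Which species carry an inactivated gene?* Translate each locus from
   the conserved start codon to the first in-frame stop and call
   inactivating mutations against the reference.
2. *Were the mutations inherited from a common ancestor?* A mutation of
   identical kind, length and reference position carried by every member
   of a clade — and by no outgroup — is parsimoniously explained by a
   single event on the clade's stem branch.
3. *Where and when on the tree did the gene arise and disappear?* Map
   presence/absence states by maximum parsimony and bracket the loss
   between the calibrated ages of the nodes flanking its branch.

The archetype is a large plakin-family gene whose protein consists solely
of tandem plakin repeat domains, encoded by a single exon several
kilobases long — intact across jawed vertebrates, inactivated on the stem
lineage of whales and dolphins. The package generalizes the approach to
any single-exon, reference-anchored gene-loss problem.

## The simulator defines the study conditions

Because real loci live in public archives, the package carries a
first-class simulator whose defaults emulate the study system, so every
downstream stage can be validated against known truth:

- **Gene architecture.** The ancestral protein is `repeatCopies` (default
  40) near-identical tandem copies of a random `repeatUnitLengthAa`
  (default 60) residue unit, giving a 7,206-nt single-exon CDS — inside
  the 6,000–12,000-nt range typical of epiplakin-like genes. Copies
  diverge from the master unit at 2% per residue, the empirically
  sensible scale for a conserved tandem array (close enough that every
  copy is detectable in a dot plot, far enough that adjacent copies are
  not byte-identical).
- **Tree and divergence.** A 15-taxon tree — 12 cetacean-like tips in two
  subclades plus three terrestrial outgroups — with branch lengths in
  units of 100 My taken from round-number divergence times (root 96,
  reference–clade split 60, sister split 54, crown clade 33 Mya).
  Substitutions are i.i.d. per site per branch with probability
  `subRate × branch length` (default rate 0.05 per site per 100 My, a
  conservative neutral mammalian rate), uniform over the three
  alternative nucleotides; there are no stochastic indels, so indel truth
  stays unambiguous.
- **Injected events.** Inactivating mutations are declared, not sampled:
  by default a nonsense codon at codon 70 and a 1-nt deletion at CDS
  offset 300, both on the cetacean stem branch, plus two tip-private
  frameshifts when the CDS is long enough. Events are inherited by every
  descendant of their branch, and the truth table records each event's
  descendant tip set and the true loss branch.
- **Truth preservation.** Substitutions never touch injected-event sites
  or the start codon, and on any branch with at least one intact
  descendant a substitution that would create an in-frame stop (or
  destroy the terminal stop) is redrawn. This separates declared
  inactivating events from stochastic noise: intact tips stay intact by
  construction, while lineages already pseudogenized are free to
  accumulate secondary stops — as real pseudogenes do.
- **Genomic context.** Each tip locus is the evolved CDS flanked by
  200 nt of random untranslated sequence, so start-codon location is a
  real subproblem rather than an offset convention.

What the simulator does *not* model: transition/transversion bias, codon
models and selection (dN/dS), stochastic indels, intron/exon structure,
segmental duplications, and assembly or sequencing error. Passing tests
therefore demonstrate correctness of the inference machinery under clean
single-copy orthology, not robustness to assembly artifacts — on real
data, apparent single-nucleotide discrepancies in one assembly should be
cross-checked against independent genomes before being scored as
mutations.

## Numerical and algorithmic choices

**Translation and the stop-scan.** Translation uses the standard genetic
code; codons containing ambiguity symbols translate to the residue they
unambiguously encode, else to `X`. Only literal TAA/TAG/TGA terminate the
theoretical-protein scan: an `N`-containing codon never truncates, so
sequencing ambiguity cannot fake a pseudogene. Coordinates are 0-based
and half-open throughout.

**Start-codon location.** The "conserved start" is operationalized by
aligning the reference's first 90 nt against the locus (reference side
global, locus side local) and taking the ATG at the anchored reference
start, or the nearest ATG within 30 nt 3′ of it. If neither exists the
nearest downstream ATG is used and flagged `nonOrthologousStart`. Ties
resolve to the 5′-most candidate.

**Alignment.** Pairwise global alignment with EMBOSS-style nucleotide
scoring (match +5, mismatch −4, gap open 10, gap extend 0.5), computed by
`Biostrings::pairwiseAlignment` and post-processed so that every gap run
sits at its left-most equivalent position (the convention used for
variant normalization). Sequences are capped at 50,000 nt; longer loci
should be anchored first.

**Mutation calling.** Indel runs separated by fewer than 3 aligned
columns are merged before the mod-3 test, because optimal alignments
split single biological events at that scale. Premature stops are
detected in the query's *own* running frame — the frame in which the
mutated locus would actually be translated — not the reference frame.
Two caveats discovered by measurement, both exposed as parameters:

- *Slippage pairs.* At ~9% divergence the optimal alignment of two
  intact orthologs occasionally introduces a complementary equal-length
  1-nt insertion/deletion pair a few columns apart: it buys back two or
  three mismatches at the cost of two gap openings and shifts no reading
  frame overall. Reporting such a pair as two frameshifts would
  misclassify an intact gene, so complementary equal-length pairs within
  `slippageWindowNt` (default 30 nt) are dropped. Genuinely compensated
  frameshift pairs at larger distances are still reported individually,
  with `netFrameRestored` flagging the overall frame.
- *Cross-species position jitter.* One inherited indel does not land on
  the same normalized coordinate in every species: a substitution
  adjacent to the gap shifts its optimal placement by 1–2 nt, and when
  the indel sits in a homopolymer whose reference copy has itself
  mutated, the left-aligned position can migrate by the run length
  (6 nt observed). `findSharedMutations()` therefore merges calls of
  identical kind and length within a 9-nt (three-codon) window by
  default. Two *independent* same-length frameshifts within 9 nt of each
  other in different species are far less likely than one inherited
  event; setting `toleranceNt = 0` restores exact-position merging.

**Status classification.** A gene is a pseudogene when it carries at
least one frameshift or premature stop, or when its theoretical protein
is shorter than half the reference (strict inequality at the boundary).
The truncation fraction matters for loci where alignment evidence is
unavailable; with the default simulator both signals agree.

**Repeat profiling.** The self dot plot follows windowed un-normalized
sum semantics: cell (i, j) is marked when the BLOSUM62 score summed over
a 10-residue window along the diagonal reaches 23, and overlapping marked
windows merge into maximal segments. The unit length is the smallest
off-diagonal offset holding at least half of the maximal per-offset
support; copy number is one plus the longest chain of offsets at
consecutive multiples of the unit, each offset supporting only its
nearest multiple, with 10% jitter allowed for unit-length drift. A
repeat unit can itself contain internal sub-repeats, in which case the
reported unit is the shortest strongly supported period — when comparing
a truncated product against an intact reference, compare at the
*reference* unit length.

**Parsimony.** Presence/absence/copy-number states are unordered. The
bottom-up pass keeps, at each node, the states shared by the largest
number of children and adds (children − sharers) to the change count —
the n-ary generalization of intersection/union that also handles
polytomies. The top-down pass takes the parent's state when admissible,
otherwise prefers presence (state `1`): when a gene is demonstrably
ancient, ambiguity at the root is resolved toward ancestral presence,
and the `ambiguous` flag reports that alternatives exist. The count is
verified against exhaustive labeling enumeration in the test suite.
Ordered (Wagner-type) costs are not implemented; with at most three
states and losses vastly outnumbering regains in these data, unordered
parsimony is the defensible default.

**Dating.** Node ages are inputs (a `tipA`/`tipB`/`ageMya` calibration
table assigning ages to most recent common ancestors), never computed
from sequences. An event on a branch is bracketed by the ages of the
nodes below and above it; an uncalibrated endpoint yields `NA` on that
side.

## Problem sizes used in the test suite

The shipped tests run the full machinery at two scales: the default
7,206-nt gene for single end-to-end demonstrations, and a 906-nt
(15 aa × 20 copies) configuration for the ten-replicate recovery studies,
which exercises the identical code paths on the same 15-taxon tree at a
fraction of the alignment cost. Oracle comparisons use brute-force
implementations: an independent Gotoh dynamic program for alignment
scores (pairs up to 300 nt), a naive O(n²) window scan for dot plots
(sequences up to ~250 aa), a hand-typed codon table for translation and
exhaustive labeling enumeration for parsimony (trees up to 6 tips).

## Known limitations

- Reference-anchored pairwise calling, not multiple alignment: mutation
  coordinates are only as stable as the pairwise optimum, hence the
  jitter window above.
- Single-exon gene models only; splice-site mutations and
  transposon insertions are out of scope.
- `absent` status is driven by locus presence in the input, not by
  synteny-based absence proof; a gene missing from an assembly gap will
  look absent.
- No statistical significance is attached to a loss call — the evidence
  is the explicit mutation list, as in the underlying comparative
  approach.
- Copy-number states beyond 2 and reconciliation of gene trees with the
  species tree are not modeled.
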