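---
title: "Designing paired guide RNAs for CRISPR deletion"
author: "crisprPairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing paired guide RNAs for CRISPR deletion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(crisprPairs))
```

## The design problem

Deleting a genomic region with CRISPR-Cas9 requires *two* single guide
RNAs (sgRNAs): Cas9 is recruited to a site on each flank of the target,
both strands are cut, and non-homologous end joining fuses the outer
ends, excising the intervening segment. Designing for deletion is
therefore a *pairing* problem: each member must individually be
efficient and specific, and the pair must jointly satisfy constraints —
combined efficiency, diversity across the returned set, and cloning
rules imposed by dual-promoter vectors.

A protospacer is the 20 bp of genomic DNA immediately 5' of an `NGG`
PAM (S. pyogenes Cas9); the sgRNA's variable region matches it. For
each target this package scans two *design regions* — windows of `du`
and `dd` bp on the target's 5' and 3' sides, held off the target edge
by *exclude regions* of `eu` and `ed` bp — enumerates all NGG-adjacent
20-mers on both strands, filters them, scores them, and returns up to
`n` ranked upstream/downstream pairs.

Sides are interpreted relative to the target's own strand: for a
minus-strand target the upstream design region lies genomically to the
right. The genome never says which convention a target list assumes,
so this choice is documented here and applied uniformly; for the
symmetric defaults (`du = dd`, `eu = ed`) the two conventions coincide.

## Candidate filters

**Pol III terminator.** Any 20-mer containing `TTTTT` is removed — the
run would terminate Pol III transcription of the sgRNA. Only the
protospacer is examined, not the PAM or flanks.

**Off-target counts.** Specificity is summarised per 20-mer as the
number of genomic NGG-adjacent sites at *exact* Hamming distance 0, 1,
2, 3 and 4, counted genome-wide on both strands with multiplicity. The
0-bin counts the site itself, so the default cap string `1,0,0,x,x`
("x" = unlimited) reads: the guide's own site and nothing else within
two mismatches. Bins are exact, not cumulative; that is what makes a
cap of 1 in the 0-bin admit the guide itself. Profiles are precomputed
into a flat 6-field CSV database (`SEQ,c0,c1,c2,c3,c4`), built once per
genome with `buildOffTargetTable()` and reused across design jobs.

Counting uses a bit-packed kernel (2 bits per base, XOR + popcount over
all site pairs). Correctness is defined by brute force: the test suite
holds a deliberately naive per-character C++ counter and a pure-R
character-matrix counter, and the packed kernel must agree with them
bin-exactly on seeded genomes.

**Coding-region exclusion.** Guides resembling sites in protein-coding
sequence are disqualified outright: a candidate within 2 mismatches of
any 20-mer lying 5' of an `NGG` *or non-canonical `NAG`* PAM inside a
supplied coding annotation is marked excluded and never used. NAG sites
participate only in this pass, not in the count profiles. Without an
annotation the pass is skipped with a warning. Excluded guides are also
omitted from written databases, matching how filtered databases are
distributed; consequently a database read from disk has an empty
excluded set, and write–read–write of such a file is byte-stable.

**On-target efficiency.** Each candidate's 30-mer context
`NNNN[20-mer]NGGNNN` is scored with the Doench 2014 Rule Set 1
logistic regression:

$$ s = \operatorname{logit}^{-1}\Big(\beta_0 + \beta_{GC}\,|GC-10| +
\sum_{f \in F(x)} \beta_f\Big) $$

with an intercept, a GC-content deviation term (separate slopes below
and above 10 G/C in the 20-mer), and position-specific nucleotide and
dinucleotide features over the 30-mer. The published coefficients ship
as plain text in `inst/extdata/ruleset1_coefficients.tsv`; the scorer
is stateless, and the tests pin a seeded panel of 30-mers against an
independent per-sequence transcription of the published scoring script
to within 1e-6. Candidates with `score >= si` (default 0.2,
inclusive; 0 disables the filter) proceed.

**Masks.** Optional BED masks bias but never remove: with a positive
mask, candidates not fully contained in a favoured interval are tagged
*disfavoured*; with a negative mask, a single base pair of overlap
suffices for the tag. The mask footprint is the full 23-bp
protospacer+PAM interval — the PAM is part of the functional site, so
a mask boundary through the PAM counts. Tiers are binary
(neutral/disfavoured) and act only on ranking.

## Pair assembly and prioritisation

All upstream × downstream combinations are formed (never two guides
from one side), scored by `sum` (default; the pair threshold
`sp = 0.4` is defined on this [0, 2] scale) or `product`, and filtered
at `sp`. When `sc = "product"` the same `sp` value is applied unchanged
on the product scale — the interaction is otherwise unspecified, so the
package does not silently rescale a user-chosen threshold.

Ranking is by mask tier first (neutral before disfavoured), then pair
score descending — or deletion size ascending under
`r = "distance"`. The predicted deletion is the distance between the
two blunt-cut positions, each placed between protospacer positions 17
and 18 (3 bp 5' of the PAM), the canonical SpCas9 cleavage point.
Remaining ties resolve by smaller deletion, smaller upstream start,
smaller downstream start, then lexicographic sequences, so a run is a
pure function of its inputs; the batch driver re-run on identical
inputs produces byte-identical files.

**Diversity.** A single excellent guide would otherwise dominate all
`n` returned pairs. The diversity fraction `v` caps per-protospacer
usage at `max(1, floor(v * n))`, enforced greedily down the ranking: a
pair is skipped if either member has exhausted its budget, and
selection stops at `n`. Tests verify on small instances (up to 8
candidates per side) that this greedy choice equals the
rank-lexicographically maximal feasible set from exhaustive
enumeration. One known divergence from the original tool's published
benchmark: at `v = 0.1, n = 10` (usage cap 1) the original reports
exactly one pair per designed target, which a pure usage cap does not
force; the cap semantics used here are the documented, tested ones.

**DECKO construction.** Dual-promoter vectors express the first sgRNA
from a U6 promoter, which requires a leading G. Under `c = "DECKO"`,
if exactly one member starts with G it is placed first; if both do,
the upstream member stays first; if neither does, the upstream member
goes first with a prepended G (21 nt) — so oligo lengths may differ by
one nucleotide across a library.

Each target finishes with a depth label: *full* (`n` pairs), *partial*
(1 to `n − 1`) or *failed* (none). One target's failure never aborts a
batch.

## Parameters

| Symbol | Default | Meaning |
|--------|---------|---------|
| `n`  | 10 | pairs returned per target |
| `du`, `dd` | 500 bp | design region lengths (strand-relative) |
| `eu`, `ed` | 100 bp | exclude region lengths |
| `t`  | `1,0,0,x,x` | off-target caps for mismatch bins 0–4 |
| `v`  | 0.5 | diversity fraction (usage cap `max(1, floor(v*n))`) |
| `si` | 0.2 | minimum individual Rule Set 1 score (inclusive) |
| `sp` | 0.4 | minimum pair score, on the `sc` scale |
| `sc` | `sum` | score combination (`sum`/`product`) |
| `r`  | `score` | ranking (`score`/`distance`) |
| `c`  | `none` | construct rule (`none`/`DECKO`) |
| `mp`, `mn` | — | positive / negative mask BED |

`designConfig()` validates and carries all of these;
`exec/crisprPairs` exposes them as command-line flags with a
`key=value` config file layered between defaults and flags.

## Degenerate inputs and numerical choices

* Coordinates are 1-based closed GRanges in R and 0-based half-open in
  every BED file read or written; conversion happens only at the file
  boundary.
* Unstranded BED records are assigned `+`; unnamed records get the
  deterministic name `chrom_start_end` rather than a random identifier,
  so repeated runs and tests are reproducible.
* Design regions running off a chromosome are clipped (possibly to zero
  width) with a warning; the target degrades to partial or failed
  rather than erroring.
* Sites whose 20-mer or PAM contains a non-ACGT character, or with
  fewer than 20 bases upstream on their strand, are skipped both as
  candidates and as off-target sites. A candidate whose 30-mer context
  would cross a chromosome end is dropped; a context containing `N` is
  unscorable and dropped with a warning.
* Scoring contexts may extend a few bases past the design-region edge
  into the genome — the alternative would silently shrink every design
  region by 7 bp.
* A candidate absent from a supplied off-target database (a
  database/genome mismatch) is dropped with a warning rather than
  trusted.

## The synthetic-genome generator

`simGenome()` builds seeded random backgrounds (default GC 0.41,
human-like — PAM density rises with GC) and plants protospacer
cassettes described by `plantSpec()`: a 4-nt flank, the 20-mer, an
`N`, `GG` or `AG`, and a 3-nt flank, with optional extra copies at
chosen exact Hamming distances, coding-interval membership, mask
intervals, or an embedded `TTTTT`. After assembly the generator
*verifies* every planted NGG 20-mer's genome-wide profile with the
brute-force counter and re-rolls the background if the random sequence
created an unintended neighbour within 4 mismatches — a fixture that
violates its own specification is never emitted. With `pamFree = TRUE`
the background contains no GG/CC dinucleotide at all, so planted
cassettes are the *only* sites genome-wide and a design region's exact
candidate set is known by construction; the test suite uses this to
pin full/partial/failed depth outcomes and exact pair sets against an
independent straight-line reimplementation of the whole per-target
pipeline.

What the generator does *not* emulate: repeat families and segmental
duplications (beyond what the acceptance benchmark plants explicitly),
chromatin, assembly gaps at realistic frequencies, and base
composition structure beyond a single GC fraction. Passing tests
therefore demonstrate algorithmic correctness on controlled sequence,
not performance claims on real genomes — on random sequence nearly
every guide is unique, so off-target failure is far rarer than in the
human genome.

## Problem sizes

The test suite works at sizes chosen to keep the brute-force oracles
exact and affordable: pure-R oracle comparisons on 3–8 kb genomes,
packed-versus-naive kernel equivalence on twenty 50–200 kb genomes,
depth fixtures of 3–10 targets, and exhaustive diversity enumeration
on instances up to 8 candidates per side. `scripts/acceptance.R` runs
the full pipeline on a 150 kb genome carrying a planted family of
duplicated 1.5 kb segments (duplication is what makes off-target
filtering bite) with 40 targets at the default configuration, and
reports depth percentages, mean scores, mean deletion distance and
database statistics as JSON.

## Limitations

* Off-target similarity is mismatch-only (exact Hamming, up to 4); no
  indels or cleavage-likelihood scoring of off-target sites.
* Rule Set 1 is the only bundled on-target model. The scorer sits
  behind a single function so a successor model can be swapped in, but
  no training or alternative parameterisation ships.
* No estimation of achieved deletion efficiency; depth labels describe
  design coverage, not biology.
* Masks are user-supplied intervals; the package infers nothing about
  chromatin accessibility or repeats.
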