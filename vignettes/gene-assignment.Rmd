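---
title: "Alignment-free gene assignment: model, index and design notes"
author: "kassign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free gene assignment: model, index and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kassign)
```

## The gene assignment model

An RNA-seq read is a substring of a transcript, which is itself a
concatenation of exons of one gene locus. kassign decides, for every
read *s* in a sample and every gene *g* in a user-chosen panel, whether
*g* is a plausible origin of *s* — without alignment, using only shared
k-mer content.

A *base* of *s* is a (character, position) pair; base *b* is *shared*
with *g* if some k-mer of *s* containing *b* also occurs in *g*.
K-mers are always compared in *canonical form* — the lexicographically
smaller of the k-mer and its reverse complement under A < C < G < T —
so both sequencing strands index identically. Writing SHARED(s, g) for
the set of shared bases, *g* is a putative origin of *s* iff

1. |SHARED(s, g)| / |s| ≥ τ, and
2. no other gene has a strictly larger |SHARED(s, g′)|.

The gene assignment of a sample is the family of per-gene read sets
S_i induced by this criterion. It is deliberately *not* a partition: a
read may tie between paralogous genes (both are reported in *multiple*
mode; the read is dropped entirely in *single* mode), or match no gene.

Two properties motivate counting shared *bases* rather than shared
k-mers. First, a substitution (sequencing error or polymorphism)
destroys up to k windows but removes only about one covered base when
the read otherwise matches, so the score degrades gently. Second, a
read spanning an exon–exon junction contains k-mers that occur in no
contiguous genomic window, yet all bases at distance ≥ k from the
junction remain covered by exonic windows — which is what makes the
criterion robust to unannotated splicing, the situation the filter is
designed for.

### Assumptions

* Genes are given as locus (genomic) sequences; introns are present in
  the reference but absent from reads.
* Reads are short relative to exons, so a read rarely spans more than
  one junction (with 100 bp reads and exons of a few hundred bases, at
  most one junction per read is the norm; each junction can cost at
  most k − 1 covered bases on the shorter side).
* Substitutions are the dominant error mode; indels shift every
  downstream window and are not modelled.

## The succinct index

The naive solution — a hash table from each canonical k-mer to its gene
set — answers queries exactly but stores every k-mer explicitly.
kassign replaces it with a triple ⟨BF, P, I⟩:

* **BF**: a Bloom filter of m bits holding the panel's canonical
  k-mers, written with a *single* hash function. With the panel sizes
  the tool targets, the filter is sparse (load factors around 10⁻³),
  where one hash function loses almost nothing in false-positive rate
  and halves the random memory accesses per query.
* **I**: for each set bit of BF, in bit-position order, the strictly
  increasing list of IDs of genes containing a k-mer that hashes to
  that bit; the lists are concatenated.
* **P**: one bit per entry of I; a 1 marks the last entry of each list.

A query hashes the k-mer to position *h*. If BF[h] = 0 the k-mer is
definitively absent. Otherwise, if the bit is the v-th 1 of BF (one
rank), the gene list occupies I between the (v−1)-th and v-th 1s of P
(two selects). Construction makes three passes: set bits; append gene
IDs to per-bit lists scanning genes in ID order (duplicates from a
repeated k-mer within a gene are then adjacent and dropped on the fly,
which also keeps each list sorted); concatenate and mark boundaries.

Collisions — two distinct indexed k-mers sharing a position, or an
absent k-mer landing on a set bit — merge or borrow gene lists. The
effect is one-sided: a query result is always a superset of the true
gene set, so the index can inflate a spurious gene's score but can
never lose a true origin. The test suite checks this characterisation
exactly: equality with an exact-dictionary oracle wherever no collision
exists, and equality with the collision-merged union where one does.

### Rank/select conventions

Bit vectors use the 1-based half-open rank convention: `bitRank1(B, i)`
counts 1s strictly before position i, so a set bit at position p has
ordinal `bitRank1(B, p) + 1`, and `bitSelect1(B, j)` returns the
1-based position of the j-th 1. The v = 1 edge (first list, left
boundary 0) is handled explicitly and tested. Packed vectors use the
bit order of base R's `rawToBits()`. Rank uses cumulative popcounts
per 512-bit superblock plus an in-block scan; select materialises the
positions of the 1s once per query batch. These are modest structures
chosen for clarity — the contract under test is correctness and
effectively constant query cost at panel scale, not asymptotic
optimality.

### The read scan

Scanning a read's admissible windows left to right, the classifier
keeps two accumulators per touched gene: `pos_g`, the exclusive end of
the last covering window (sentinel −1), and `card_g`. A hit at 0-based
offset *i* adds `min(k, i + k − pos_g)` newly covered bases and sets
`pos_g = i + k`; at the end `card_g = |SHARED(s, g)|` exactly (the
suite verifies this against an explicit covered-set union). Storage is
a dense per-gene array with a touched list, reset in O(hits) per read —
for panel-scale gene counts this is both the fast and the simple
option; the worst case remains O(|s|·|G|) per read.

## Parameters

| Parameter | Default | Meaning and effect |
|---|---|---|
| k | 17 | window length (1..32, one 64-bit word). Larger k: more specific, more error-fragile. |
| τ | 0.6 | minimum covered fraction of the read. Larger τ: more precise, less sensitive. |
| q | 10 | skip windows spanning a base with Phred quality < q. 0 disables. |
| m | 2³³ bits | Bloom filter size (1 GB at the default; tests use 2²²–2²⁶). |
| mode | multiple | report all tied maximal genes, or none in single mode. |
| seed | 13 | hash seed; index and queries must agree. |

The defaults are the operating point at which the k/τ/q trade-off
balances precision and recall in the package's own benchmark. Raising
τ or k trades recall for precision monotonically (a property the
acceptance suite asserts on a τ grid); an aggressive quality cut-off
(q = 20) can *reduce* accuracy by leaving too few windows per read —
the τ denominator is deliberately the full read length |s|, not the
number of unmasked bases, so masking is conservative: it can only
remove evidence, never lower the bar.

## The synthetic benchmark generator

`simConfig()` defaults define the package's reference study
conditions, fixed once as a desk-scale benchmark: 50 gene loci built
from 2–5 exons of 250–600 bp separated by introns of 100–300 bp
(≈ 2 kb loci), one transcript per gene (the exon concatenation), a
random 10-gene panel, and 50,000 single-end 100 bp reads drawn
uniformly from the transcripts of *all* 50 genes (so 80% of reads
originate outside the panel), on either strand, with 0.2% i.i.d.
substitution errors and Phred qualities ~ N(35, 3²) clamped to 2..40,
1% of bases replaced by a low quality in 2..9. Everything is
deterministic given the config seed; reads carry no truth in their
names (origins are returned separately).

What this emulates: junction-spanning reads (generated on transcript
coordinates, so junction k-mers are absent from the locus), strand
symmetry, error-induced window loss, quality-driven masking, and
out-of-panel read capture. `plantShared` can copy an exon segment
between two genes to create paralogy and hence genuinely ambiguous
reads. What it does *not* emulate: realistic expression skew (weights
are configurable but default uniform), indels, position-dependent
error/quality profiles, fragment-length and amplification biases, and
real genomic repeat structure. Passing the benchmark therefore shows
the method's accounting and error tolerance under controlled
conditions, not its precision on a real transcriptome, where repeats
and overlapping genes dominate the false-positive budget.

Evaluation uses per-read accounting: an assignment to the true origin
(when it is in the panel) is a true positive; every assignment to a
non-origin panel gene is a false positive — whether the read's origin
is another panel gene or outside the panel; a panel-origin read with no
assignment to its origin is one false negative (never more than one
per read). A read assigned to its origin plus a paralog thus counts
both a tp and an fp; a read assigned only to a wrong gene counts both
an fp and an fn. Precision is tp/(tp+fp) (undefined → NA/null), recall
tp/(tp+fn); recall's denominator equals the number of panel-origin
reads.

## Numerical and design choices

* **Hash.** The single hash is the murmur3 64-bit finaliser applied to
  the 2-bit-encoded canonical value xored with seed·0x9e3779b97f4a7c15,
  reduced mod m — branch-free, well mixed, identical across platforms
  and thread counts. The seed defaults to 13 and is stored in the
  index; loading and querying validate k, so a k-mismatch is a usage
  error rather than silent nonsense.
* **Encoding.** A = 0, C = 1, G = 2, T = 3, leftmost base most
  significant: unsigned comparison of encoded values is exactly
  lexicographic comparison, making canonicalisation branch-free.
  Lowercase input is accepted (soft-masked references); every non-ACGT
  code is treated like N and masks its windows. At the R surface the
  numeric k-mer value is exact for k ≤ 26 (52 bits); the canonical
  string is the authoritative representation beyond that, and all
  internal arithmetic is exact 64-bit.
* **Ties.** No tie-breaking beyond the definition: all maximal-card
  genes meeting τ are reported in multiple mode; any tie empties the
  read's assignment in single mode.
* **Threshold comparison.** The criterion is evaluated as
  `card / read_length >= tau` in double precision; with integer cards
  and read lengths the boundary case (e.g. 60/100 vs 0.6) rounds
  identically on both sides.
* **Degenerate inputs.** Reads shorter than k have no windows and are
  processed but never assigned. Genes shorter than k keep their ID (a
  warning) so the gene-ID map is stable. An empty panel is an error; an
  empty sample yields an empty assignment.
* **Paired ends.** Mates are classified independently. The `union`
  policy (default) retains a pair for gene g if either mate is
  assigned to g, reporting the larger mate count; `separate` treats
  mates as independent reads. Both are exposed because mate coupling
  is genuinely a user-level choice for a filtering tool: `union`
  preserves read pairing for downstream aligners, `separate` is the
  cleaner statistical unit.
* **Determinism.** Classification involves no randomness; the
  `threads` argument only batches reads, and output rows are sorted by
  (read_id, gene_name), so results are byte-identical for any batch
  count. Only the simulator consumes seeds, via isolated RNG scopes
  (`withr::with_seed`), with the read stage offset by +1 so panel and
  reads are independently reproducible.
* **Persistence.** `saveIndex()`/`loadIndex()` use a versioned
  little-endian container (magic `KASSIDX1`) holding parameters, the
  gene-name table and the three vectors; loading is bit-exact and
  truncation or a wrong magic is a format error. Persistence exists
  because rebuilding the index per sample is pure overhead when one
  panel is applied to many samples.

## Problem sizes used by the tests

The suite builds everything programmatically. Unit tests use panels of
2–20 genes (tens of bases to 2 kb) with m from 64 (to force
collisions) to 2²², and samples of a few hundred to a few thousand
reads; the oracle-equivalence suite runs 100 random panels against the
exact-dictionary and covered-union oracles; the acceptance benchmark
runs the full reference scenario above (50 genes / 50,000 reads,
m = 2²⁶) and requires recall ≥ 99% at k = 17, τ = 0.6, q = 10 —
which `scripts/acceptance.R` recomputes end-to-end and reports as a
percentage. These sizes keep a full run in the low minutes on one core
while leaving each property with real statistical content.

## Known limitations

* Precision on real panels is limited by genomic repeats and
  overlapping genes: collisions of biology, not of hashing. The method
  reports all tied candidates and leaves resolution to the user
  (single mode, or downstream alignment).
* Spurious shared-base counts from Bloom collisions are not verified
  against the gene sequence; with sparse filters they are one or two
  windows and fall far below any useful τ, but adversarially small m
  inflates them.
* Indels and structured error profiles are outside the error model,
  and k > 32 is unsupported by construction (one word per k-mer).
* The index targets panel-scale gene sets; indexing an entire
  transcriptome works but erodes the memory advantage the structure
  exists for.
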