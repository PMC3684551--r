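---
title: "Detecting putative mobile elements by anchor-based chromosome comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting putative mobile elements by anchor-based chromosome comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobscan)
```

## The problem

In yeast and other organisms with many sequenced strains, most of the
base-level differences between homologous chromosomes are point mutations,
while the *large* differences — indels of thousands of bases — are dominated
by the mobilome: LTR retrotransposons (full-length elements of roughly 4–8 kb)
and the ~300 b solo LTRs they leave behind after recombination. `mobscan`
exploits this: instead of aligning chromosomes base by base, it locates the
exactly conserved backbone shared by two homologous chromosomes and reads the
*non*-conserved islands in between as putative mobile-element (PME) events.
Because many strain assemblies are low-coverage, runs of unresolved bases (N)
are treated as first-class signal rather than noise.

## Exact L-gram anchoring

The unit of comparison is the L-gram: a window of `L` consecutive bases
(default `L = 32`). Each base `c` is assigned a pseudo-random `w`-bit word
`h_c` (default `w = 32`), and the hash of a gram `t = t[1]..t[L]` is the XOR
of cyclically rotated base codes

```
h(t) = s^(L-1)(h_t[1]) ⊕ s^(L-2)(h_t[2]) ⊕ … ⊕ s(h_t[L-1]) ⊕ h_t[L]
```

where `s` rotates a `w`-bit word one position left. Sliding the window one
base right updates the hash in constant time:
`h(t') = s(h(t)) ⊕ s^L(h_t[1]) ⊕ h_t[L+1]`. The reference chromosome's grams
go into a hash table (load factor 0.75); the strain chromosome is then scanned
with the same rolling hash, and every hash hit is **verified by direct base
string comparison**, so hash collisions can never create a false common
L-gram. Windows overlapping an N are never hashed: only maximal ACGT runs of
length at least `L` are scanned.

Numerical choices worth stating:

* Hash words are carried across the R boundary as doubles, which are exact
  integers up to 2^53; the supported width is therefore 1–53 bits rather than
  {32, 64}. The default 32 bits is kept. Width only affects collision rates
  — never correctness, because matches are string-verified.
* With `L = w = 32` the cyclic rotation satisfies `s^L = identity`, which
  weakens mixing for the first/last term of the update. This is harmless for
  the same reason, and the equality of rolling and direct hashing in exactly
  this corner is part of the test suite.
* Base codes are drawn once from a fixed, documented seed
  (`hash_config(seed = 1009)`), so runs are reproducible; any injective
  assignment works.

## Greedy colinear chaining

Phase 2 aggregates common L-grams into conserved segment pairs with a single
left-to-right greedy scan:

1. **Starting point.** The next segment starts at the leftmost common L-gram
   (query position `j1`) not consumed by an earlier segment. Its image is the
   occurrence `i*` nearest to `j1` (`argmin |j1 − i|`), ties to the smaller
   coordinate — occurrence lists are singletons in the vast majority of
   positions anyway.
2. **Extension.** A following common L-gram at `j2` with chosen occurrence
   `k*` extends the segment iff `i* < k*`, the query-side gap satisfies
   `d2 = j2 − j_last − L ≤ δ1`, and the gap mismatch satisfies
   `|d1 − d2| ≤ δ2` with `d1 = k* − i_last − L`. Among admissible occurrences
   the one minimizing `|d1 − d2|` is chosen (ties to the smaller coordinate).
   Anchors whose every occurrence is inadmissible are skipped; extension
   terminates at the first anchor beyond `δ1`.
3. **Update.** The closed pair `[first, last + L)` on both sides is emitted.

Two design choices resolve points the greedy scheme leaves open. First, when
starting a new segment, only occurrences at or beyond the end of the last
emitted reference interval are admissible, so the output is colinear and
disjoint on both sides *by construction*; a backward match (a translocation)
then surfaces as a non-conserved region rather than a crossing segment.
Second, the minimal-`|d1 − d2|` rule for choosing among several admissible
occurrences is our determinization; any choice satisfying the constraints
would be valid.

Defaults `δ1 = 200`, `δ2 = 50`: events shorter than 200 b are treated as
insignificant throughout (point-mutation scale), so intra-segment query gaps
up to 200 b are tolerated, while `δ2 = 50` keeps the largest bridgeable indel
(`d1 ≤ δ1 + δ2`) well below the ~300 b solo-LTR scale — a solo-LTR-sized or
larger indel always opens a new segment. Consequently any planted insertion
longer than `δ1 + δ2 + 2L` can never be bridged by one segment (tested).

The whole phase is linear on average: hashing is amortized constant per
window and each anchor is examined a bounded number of times. A soft runtime
check (doubling the input less than triples the time) is part of the suite.

## Classifying non-conserved regions

Between consecutive segment pairs lies a gap with reference-side length `gA`
and strain-side length `gB`; gaps with `max(gA, gB) < 200` b are discarded.
The taxonomy, applied in this order:

* **pCONSu** — `gA ≥ 200`, `|gA − gB| ≤ 0.2·max(gA, gB)`, and the strain-side
  gap is at least 50% N: the region is presumed conserved but unreadable.
  "About the same length" is quantified as a 20% relative tolerance and
  "unresolved" as a 50% N fraction; both constants are judgement calls,
  exposed in `classifier_config()`.
* **pDEL** — only the reference side is significant: sequence present in the
  reference, absent from the strain. Specializes to **pDEL_Ty** / **pDEL_LTR**
  when the reference gap overlaps an annotated full-length transposon /
  solo-LTR.
* **pINS** — only the strain side is significant: extra sequence in the
  strain, almost point-wise on the reference. **pINSu** when the inserted
  sequence is mostly unresolved.
* **COMPLEX** — both sides significant without being pCONSu. Kept as an
  explicit bucket rather than silently splitting it into an insertion plus a
  deletion.

The size class compares the event's characteristic length (`gA` for
deletions, `gB` for insertions, the larger for the two-sided categories) with
4000 b (`Ty_c`, compatible with a full-length transposon) and 500 b (`ltr_c`,
compatible with a solo LTR). `prox_mobil` flags events whose reference gap
lies within 200 b (boundary-to-boundary) of an annotated transposon or
solo-LTR.

## Multi-strain analysis

With `K` strains anchored against one reference, the conserved core is the
interval intersection of all reference-side segment intervals. The intervals
between consecutive core pieces — the *slots* — form a coordinate system
shared by all strains. Two refinements matter:

* Segment boundaries are preserved as cut points when intersecting. An
  insertion interrupts a strain's segments while leaving an almost
  point-like gap on the reference; merging touching intervals would erase
  that junction and make insertions invisible to the multi-strain layer, so
  zero-width slots are legitimate and carry the strain-side signal.
* Core fragments shorter than `L` cannot host an anchor and are absorbed
  into the surrounding slot.

Each slot's strain-side length is the span between the images of its
flanking core boundaries in that strain's coordinates (terminal slots run to
the chromosome ends). When a flank is not covered by any segment of a strain
the slot falls back to its reference-side length with a warning — the
behaviour in that corner is not prescribed anywhere, and the fallback at
least never invents a difference between strains. The binary profile sets
bit `n` to 1 iff the strain-side length of slot `n` is at least the size
threshold `d` — 4000 b to track full transposons, 300 b to include solo-LTR
scale events. Strains are then compared by raw Hamming distance between
profiles (normalization would only rescale an average-linkage tree) and
clustered by UPGMA — unweighted average linkage with node heights at half
the merge distance, computed via `stats::hclust(method = "average")` and
returned as an `ape` tree; ties between equal-distance pairs follow
`hclust`'s deterministic ordering. Per-slot column sums give a conservation
score from 0 to `K`: slots scoring `K` are *almost conserved*
(length-conserved everywhere), the rest *fully non-conserved* (at least one
strain lacks the element).

Detection quality is summarized as sensitivity `Sn = TP/(TP+FN)` and
specificity `Sp = TN/(TN+FP)`, with a prediction hitting a truth element iff
their intervals overlap by at least one base.

## The synthetic strain-set generator

`simulate_strain_set()` produces the fixture the whole stack is validated
on. Its defaults are the study conditions, chosen once:

* a 100 kb uniform random reference — long enough for a dozen well-separated
  transposon-scale events, small enough that the full 5-strain analysis runs
  in seconds;
* 5 strains, each with 3 insertions and 3 deletions of 5000–8000 b
  (full-length transposon scale), at loci separated by far more than
  `2L + δ1 + δ2` so planted events can never interact;
* insertions draw prefixes of canonical 8 kb element sequences from a fixed
  synthetic library, so repeated copies of a family are near-identical, the
  way real transposon copies are; deleted reference intervals are annotated
  as synthetic Ty copies, and a synthetic 300 b solo-LTR annotation is placed
  next to each insertion point, emulating the tendency of insertions to land
  near resident elements;
* point mutations at rate 0.005 per base — the strain-divergence scale at
  which anchoring still finds a dense backbone (a SNP kills `L` consecutive
  anchors, so the mean SNP spacing of 200 b comfortably exceeds `L`);
* two 1–2 kb N-runs per strain, emulating low-coverage assembly holes.

SNPs and N-runs are kept one gram length (`L` bases) away from planted event
boundaries, so measured gap lengths match the truth log to within `2L` and
acceptance margins stay crisp rather than fuzzy. The truth log records every
event in both reference and strain coordinates, every SNP, every N-run and
the seed; the same seed reproduces the same strain set exactly.

What the generator does **not** emulate: real transposition mechanisms
(no target-site preference, no LTR recombination leaving solo LTRs), genuine
repeat landscapes (a uniform random reference has essentially no repeated
32-grams, whereas real chromosomes have many), GC skew or mutation-rate
heterogeneity, and structurally rearranged strains (inversions,
translocations). Passing tests therefore demonstrate the correctness of the
anchoring, chaining, classification and profiling machinery under clean
planted events — not the field performance of the taxonomy on a real,
repeat-rich genome.

## Problem sizes used in validation

The test suite and the acceptance script run entirely on generated data: the
hash layer is validated on 10^5-window sequences, the Phase-1 map against a
naive all-window matcher on one hundred 2 kb pairs, and the full pipeline on
the default 5-strain / 100 kb fixture plus a 6-strain two-clade fixture of
80 kb. These sizes were chosen so the complete suite runs in well under a
minute on one core while every code path (N-runs, insertions, deletions,
zero-width slots, degenerate distance matrices) is exercised. Chromosome-
scale inputs (megabases) run through the same code paths; only the hash
table grows.

## Known limitations

* Forward strand only: an inverted or translocated block is reported as
  non-conserved, not as a rearrangement call.
* No base-level alignment of conserved regions and no dynamic-programming
  gap closing — by design, since the anchors are dense enough on
  strain-level divergence.
* The pDEL/pINS direction is relative to the chosen reference; the method
  cannot distinguish an insertion in the strain from a deletion in the
  reference lineage.
* Classification of insertions relies on reference annotations (only the
  reference is assumed annotated); the inserted sequence itself is not
  searched against an element library.
* One homologous chromosome per strain per run; multi-chromosome profiles
  are obtained by concatenating per-chromosome slot structures in a fixed
  order.
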