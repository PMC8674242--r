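---
title: "Filtering microhomology-induced chimeric read artifacts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filtering microhomology-induced chimeric read artifacts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micrfilter)
```

## The problem

Formalin fixation fragments DNA and leaves a substantial single-stranded
fraction. During library end-repair, a single-stranded molecule can anneal
to itself at two proximal reverse-complementary (palindromic) sequences,
forming a hairpin, or to another single-stranded molecule from a distant
genomic region with locally identical sequence. Either way, polymerase
fill-in produces a chimeric double-stranded molecule. After sequencing and
alignment, such a molecule yields a read in which one part maps to the
locus, the rest is soft-clipped, and the base at which the two annealed
sequences disagree is read out as an apparent somatic mutation, often at
appreciable allele fraction. These microhomology-induced chimeric reads
(MICRs) are a dominant source of false somatic mutation calls in
formalin-fixed, paraffin-embedded (FFPE) capture-based sequencing, and no
amount of consensus barcoding removes them, because they form before
adapters are ligated.

The package classifies each *called* mutation post hoc, from the aligned
reads alone. Variant calling itself is out of scope: the input is a
mutation list, a coordinate-sorted BAM and the reference FASTA.

## Read-level evidence

For every read overlapping the locus the package walks the CIGAR string and
determines whether the read carries the mutation (alternate bases present;
for a deletion, a `D` operation of the right length at the locus; for an
insertion, an `I` operation with the inserted bases), is
reference-conforming, or is undetermined (locus inside a soft-clip, or a
different event at the locus). Undetermined reads take part in neither the
mutant nor the null set.

The **supporting lengths** of a read are the numbers of non-clipped read
bases strictly 5' and 3' of the event, in reference orientation. Counting
is over *read* bases: bases consumed by insertions elsewhere in the
alignment count, deleted reference bases do not, soft- and hard-clipped
bases never count. The **shorter supporting length** is the minimum of the
two. For a fully mapped substitution read, `len5 + len3 + N = L` with `N`
the event size and `L` the post-trim read length.

Adapter read-through is trimmed first (longest flush-end suffix matching an
adapter prefix with at most 10% mismatches), so libraries that skipped
adapter trimming are handled; on pre-trimmed libraries this is a no-op.
Within evidence assembly the trim is confined to the soft-clipped tail on
the sequencing 3' end — mapped bases are by definition not adapter — which
keeps the alignment geometry consistent without re-alignment.

## The positional-bias test (Filters 1 and 3)

Fragmentation positions are random, so for a true mutation the supporting
lengths of mutant reads spread over everything the aligner can produce. A
chimeric read, by contrast, has only a short stretch beyond the mutated
base before the clip, so its supporting lengths are pinned.

The theoretically achievable range `[C, D]` is:

| event | directional (3' side) | shorter |
|---|---|---|
| N-base substitution | `0 … L−N` | `0 … ⌊(L−N)/2⌋` |
| N-base deletion | `max(R3, N+1) … L − max(R5, N+1)` | `min(max(R3,N+1), max(R5,N+1)) … ⌊L/2⌋` |
| N-base insertion | `max(R3, N+1) … L−N − max(R5, N+1)` | `min(max(R3,N+1), max(R5,N+1)) … ⌊(L−N)/2⌋` |

The `N+1` terms come from the aligner's scoring: an `N`-base gap costs
`N+6`, a soft-clip costs 5 and each mapped base scores 1, so an indel with
`N+1` or fewer matching bases outside the gap scores no better than the
clipped alternative and is clipped. `R5`/`R3` are the flanking repeat runs:
a read must contain the entire repeat stretch around an indel before the
indel's presence is determined. The package measures them by tandem
extension of the event unit `U` — the maximal stretch adjacent to the event
over which the reference equals cyclic copies of `U`, counting a trailing
partial copy base by base. Substitutions have `R5 = R3 = 0`.

With observed mutant range `[A, B]` (each observation clamped into
`[C, D]`; out-of-range values are counted and reported, not fatal), `E`
mutation-supporting reads, and `f(x)` the number of *non-mutant* reads at
the locus with supporting length `x`, the probability of the concentration
is

$$p = \left( \sum_{m=A}^{B} f(m) \Big/ \sum_{n=C}^{D} f(n) \right)^{E}$$

evaluated in log space so that deep coverage cannot underflow
intermediates; `p` below about `1e-300` is still reported (down to the
subnormal floor). Filter 1 applies the test to the shorter supporting
length; Filter 3 to the 5' and 3' lengths separately, flagging if either
falls below threshold. Each statistic has its own `[C, D]` and exemptions.

A mutation is flagged when `p < 1e-6` (strict), **unless**

* `B − A + 1 > 0.75 (D − C + 1)` (observed range exemption), or
* `Σ_{A..B} f > 0.75 Σ_{C..D} f` (observed mass exemption), or
* there are no usable mutant or null reads (`insufficient_reads`).

The exemptions exist because `p` shrinks geometrically in `E`: at depth
several hundred, even a mild concentration would otherwise be flagged. The
threshold default `1e-6` is deliberately conservative (a looser `1e-5`
also separates the classes, but over-filtering true mutations is the worse
error in clinical use); it is exposed as `p_threshold`.

If any supporting read has more than three mismatches within the ten bases
around the mutation (five on each side, mutated bases excluded — the
symmetric reading of "ten bases surrounding"), neighboring mutations are
inflating the minimum achievable supporting length, and the theoretical
minimum is set to zero before testing. We zero the minimum for all three
statistics, the conservative direction (it can only prevent flagging).

### Null distribution choices

`f` is taken from the reads *without* the mutation at the same locus: they
share the locus's fragment-length and capture geometry and are plentiful.
When the statistic's equation is read with `f` from the mutant reads
themselves, the test degenerates toward `p = 1` for concentrated reads
with nothing to compare against; the package nevertheless implements that
variant behind `micr_config(null_from = "mutant")` for comparison. When
the null has zero mass on `[C, D]` (e.g. all null reads clipped), the test
falls back to the uniform distribution on `[C, D]` and records the
fallback. When bounds invert (`C > D`, possible only when the event size
approaches the read length), the mutation is marked unfilterable by length
and the length filters abstain.

## Hairpin detection (Filter 2)

A fold-back read copies the opposite strand across the arm mismatch, so the
sequence around the artifact base — taken from the *read*, which carries
the artifact — occurs exactly on the opposite strand nearby. For each
supporting read the package extracts the window of `max(15, N + 14)` bases
centered on the mutated bases (7 read bases on each flank; for deletions,
the 15 bases around the junction). Soft-clipped bases are included: the
chimeric tail is precisely where the opposite-strand sequence lives. Reads
with fewer than 7 bases on either flank yield no query and count as
non-hairpin-derived. The query matches if its reverse complement occurs
exactly (zero mismatches) in the reference within 200 bases of the locus
(window anchored at the locus; ambiguity codes never match). If more than
half of the supporting reads match — strictly more, exactly half does not
flag — the mutation is an artifact. The 200-base window follows the
saturation behavior of palindrome counts in FFPE data: extending the search
beyond 200 bases finds essentially nothing new, consistent with the short
insert sizes of FFPE libraries.

## Distant-homology detection (Filter 4)

Mis-annealing of molecules from two distant regions produces reads whose
mutation-containing window is verbatim the *other* region's sequence. From
each supporting read the package builds two 40-base queries around the
mutated core (the event bases plus the read bases covering the flanking
repeat runs): one anchored 4 bases 5' of the core and extended 3'-ward to
40 bases, one mirrored. A query is absent when the read is too short on the
required side; a repeat run so large that core + anchor exceed 40 leaves
both absent. Queries are searched for exact occurrences on both strands of
the entire genome — the mis-annealing mechanism is strand-agnostic — with
matches overlapping the locus ± 200 bases excluded so a read's own origin
never self-matches (the proximal palindrome case belongs to Filter 2). If
more than 15% of supporting reads (strict; denominator: *all* supporting
reads, again the conservative choice) have a matching query, the mutation
is an artifact.

Search uses `Biostrings` exact matching (`matchPattern`, or a `PDict`
multi-pattern pass for large batches); correctness is defined by
equivalence with a brute-force string scan, which the test suite enforces
on tens of thousands of random and planted instances.

## Verdict and reporting

A mutation is an artifact iff any of Filters 1–4 fires; per-filter flags,
the probabilities, both rates and the exemption flags are all reported, one
output row per input mutation (the filters annotate, never drop). Per-filter
summary counts overlap, as one mutation commonly trips several filters. A
locus depth below 100 yields an advisory message, not an error: the test
loses power and false positives increase at low coverage. Mutations with
zero supporting reads pass with `insufficient_reads`.

Coordinates are 1-based inclusive everywhere — input, output and internal —
the native R/Bioconductor convention, so file boundaries involve no
conversion. Paired-end mates that both overlap a locus count as two
observations; reads with mapping quality 0 are retained (the method makes
no mapping-quality assumption); duplicate-flagged, secondary and
supplementary alignments are excluded at fetch.

## The synthetic fixture generator

Real FFPE validation data are controlled-access, so the package generates
its own ground truth. The generator plants three site classes in a random
toy genome (default two contigs, 220 kb total):

* **hairpin sites** — two reverse-complementary 20-base arms within 200
  bases of each other, differing at exactly one internal base; supporting
  reads are chimeric: mapped up to the 3' end of the arm (an aligner
  extends through matching arm sequence before clipping, so the 3'
  supporting length is pinned exactly at the arm overhang), remainder
  soft-clipped with fold-back (reverse-complemented upstream) content;
* **homology sites** — a 60-base copy of the locus region planted on the
  other contig, differing at exactly the mutation base; supporting reads
  are fully mapped with uniform placement, so only the distant exact match
  betrays them. The copy is positioned to cover the 3'-anchored 40-mer
  query span (`pos − 35 … pos + 24`): a 60-base block cannot cover both
  query spans (71 bases would be needed), and one suffices;
* **true-mutation sites** — placed on sequence whose mutation-context
  k-mers are verified unique by a self-scan; supporting reads drawn
  per-read Bernoulli at the configured allele fraction with uniform
  placement.

Every locus also receives reference-conforming background reads (depth
minus mutant count; at the default depth 200 and VAF 0.25, three times the
mutant depth), which populate the null distribution `f`. Defaults — depth
200, VAF 0.25, 150-base reads, 50 sites per class — represent deep targeted
panel sequencing, where called mutations are backed by tens of supporting
reads. Base qualities are constant-high; the filters do not use them.

What the generator deliberately does **not** emulate: FFPE fragment-size
distributions, cytosine-deamination (C→T) chemistry, sequencing error, or
partially palindromic arms with multiple mismatches. Artifacts are planted
at the read-evidence signature level — constrained supporting lengths,
opposite-strand 15-mers, verbatim distant 40-mers, soft-clipped CIGARs —
because that signature is exactly what the filters examine. Passing the
recovery tests therefore demonstrates that the filters read the evidence
correctly, not that real FFPE artifacts always present this cleanly;
borderline real-data cases (low VAF, degraded arms, short inserts) will be
harder than the fixture.

`(spec, seed)` determines every output byte, which the test suite asserts;
the depth sweep uses an exact mutant-depth override (`mut_depth`) instead
of the binomial draw.

## Validation strategy and problem sizes

The test suite validates each layer against an independent oracle rather
than against itself:

* the closed-form theoretical bounds against an exhaustive placement
  oracle that enumerates every read placement over the event and applies
  the aligner decision rules (gap-vs-clip score comparison for indels,
  with ties resolved toward the gapped alignment, matching the inclusive
  `N+1` bound; repeat-run containment `len ≥ R`; substitutions are never
  clip-competed, as a realistic per-base mismatch cost never favors
  clipping a short mismatch) — all event types, `N ≤ 3`, `L` 20–60,
  repeat runs 0–6, ≈ 12,500 parameter combinations;
* the multinomial probability against direct summation on 10,000 random
  distributions (agreement to 1e-12 relative), plus closed forms
  (`(1/k)^E` on uniform nulls, 1 on full ranges);
* both exact-search primitives against brute-force string scans on more
  than 10,000 random and planted instances, genomes up to 1 Mb;
* strict-inequality behavior exactly at `p = 1e-6` (constructed so the
  boundary value is exact in double precision), rate 0.5, rate 0.15 and
  the 75% exemptions;
* end-to-end recovery on the default fixture (150 loci at depth 200:
  ≥ 95% of planted artifacts flagged, zero true mutations flagged,
  byte-identical reruns) and a supporting-depth sweep 5–50 with the
  threshold varied `1e-2`–`1e-9` (≥ 90% flagging at depths 10–22;
  false-positive rate non-increasing as the threshold tightens).

These sizes keep the full suite within a few minutes on one CPU while
covering the parameter space the method actually operates in.

## Known limitations

* The repeat-run definition is one of several defensible readings. Under
  tandem extension *excluding* the event unit, a literal string argument
  says a read needs `R + 1` bases on a side before an indel in a repeat is
  distinguishable from an ungapped, repeat-shifted alignment, while the
  bound used here — `max(R, N+1)`, inclusive — is the published closed
  form. The discrepancy is at most one base at the range edge, affects
  only indels inside repeats, and is diluted by the empirical null; but on
  homopolymer indels the theoretical minimum may be one base optimistic.
* The whole reference is held in memory and searched per batch; this is
  designed for panel-sized references and toy genomes. A genome-scale
  deployment would add an on-disk k-mer index behind the same interface.
* Directional supporting lengths are defined in reference orientation. A
  sequencing-orientation convention would relabel 5'/3' for reverse-strand
  reads; the shorter supporting length, and hence Filter 1, is identical
  under both conventions.
* One mutation is processed at a time against its own locus; multi-sample
  joint filtering and phasing-aware handling of nearby co-occurring
  mutations (beyond the dense-mismatch exemption) are out of scope.

## Session info

```{r}
sessionInfo()
```
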