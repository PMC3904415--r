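---
title: "Read-pair concordant variant calling for fully overlapping amplicon sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Read-pair concordant variant calling for fully overlapping amplicon sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paircall)
```

## The method

Highly multiplexed PCR target enrichment can produce amplicon libraries of
uniform, short insert size. When the insert (the primer-intervening
sequence) is shorter than one sequencing read, both mates of a paired-end
read-pair cover the *entire* insert, in opposite orientations: every insert
position is sequenced twice, once per mate, from the same template
molecule. `paircall` exploits this regime. Its unit of evidence is the
*concordant variant*: a mismatch, insertion or deletion observed with
identical position and alleles in **both** mates of one pair. A base-calling
error in one read is essentially never mirrored at the same position with
the same alternate allele in its mate (per site, the probability is roughly
$(e/3)^2$ for per-base error rate $e$), so requiring concordance suppresses
sequencing-chemistry error and leaves polymerase misincorporation during
PCR as the dominant residual error mode — which, for germline material, is
then removed by the read-pair support thresholds below, since the many
template copies entering a PCR reaction essentially never acquire the same
early polymerase error in a substantial proportion of pairs.

For each amplicon $a$ with insert interval $[s_a, e_a)$ and each alignment
file, the caller:

1. fetches all reads overlapping $[s_a, e_a)$, keeps primary, mapped,
   paired records, and groups them by read name; a pair is **assigned** to
   the amplicon when each mate's aligned reference span overlaps
   $[s_a, e_a)$ by at least a fraction $f$ (default $f = 0.9$) of the
   mate's own span length. The number of assigned pairs $N_a$ is the
   denominator for all proportions and is reported as the amplicon's
   coverage.
2. extracts each mate's variants by walking its CIGAR string against the
   reference, and intersects the two mates' variant sets by identity
   (chromosome, position, kind, reference allele, alternate allele).
3. discards variants whose reference footprint leaves $[s_a, e_a)$. Because
   the BED interval is the insert, this *clips primer-derived positions by
   coordinates*: primer synthesis errors and mispriming artifacts that
   surface as apparent variants inside primer sequence can never be called,
   and no error-prone sequence matching against primer sequences is needed.
4. counts, for each surviving variant $v$, the number of assigned pairs
   $k_{a,v}$ that carry it concordantly, and calls $v$ when

   $$k_{a,v} \ge \texttt{absthresh} \quad\text{and}\quad
     k_{a,v} / N_a \ge \texttt{proportionthresh},$$

   both inclusive. An optional base-quality gate (`qualthresh`) requires
   every base supporting an SNV or insertion allele to reach a Phred
   minimum *in both mates* before the pair may contribute; deletions carry
   no alternate bases and are exempt.

The reference bases needed in step 2 are recovered from the alignment
itself: the MD tag's matched-run lengths, mismatch letters and `^`-prefixed
deletion runs, interleaved with the CIGAR, reconstruct the aligned
reference span exactly, so no reference FASTA is required.

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `absthresh` | 2 | minimum concordant read-pairs per call (count) |
| `proportionthresh` | 0.15 | minimum fraction of the amplicon's assigned pairs |
| `qualthresh` | off | minimum Phred quality of every supporting base, both mates |
| `min_overlap` / `--overlap` | 0.9 | per-mate overlap fraction for pair assignment |

The defaults are a working operating point for germline screening of
multiplexed amplicon panels: `absthresh` 2 removes singleton PCR artifacts,
`proportionthresh` 0.15 sits well below the heterozygous expectation of 0.5
while rejecting low-fraction polymerase noise, and `qualthresh` 20 (when
enabled) corresponds to a 1% base-call error ceiling.

## Variant representation and output

Variants are normalised as: SNV at the substituted base; deletion at the
first deleted reference base with the deleted bases as the reference
allele; insertion anchored at the reference base immediately left of the
insertion point (`-` reference allele). Adjacent mismatches remain separate
SNVs, and indels are reported exactly where the aligner placed them — no
left-alignment across repeat tracts is attempted. Both choices keep mate
concordance exact (both mates of a pair are aligned consistently) but mean
that comparing calls against differently normalised call sets may need
external normalisation; this is a known limitation.

Internally all coordinates are 0-based half-open; the call writer converts
once to the 1-based inclusive convention used by common variant annotation
tools (SNV `start = end = pos + 1`; deletion spanning the deleted bases;
insertion `start = end` at the anchor), followed by sample, amplicon,
supporting pair count, total pairs and the proportion to four decimal
places. Calls are sorted per sample by chromosome, position, alleles and
amplicon name (C-locale radix order), making repeated runs byte-identical.
A per-sample coverage file lists every amplicon in region-file order with
its assigned pair count, zero rows included, so under-performing regions
are visible rather than silently absent.

Amplicon target regions are read from BED (0-based half-open, tab
delimited); when target regions overlap, a pair may be assigned to several
amplicons and is then tallied under each, and the same variant can appear
once per qualifying amplicon (the records differ in their amplicon name).
The proportion denominator is *all* assigned pairs — including pairs that
contributed no variants and pairs rejected by the quality gate — because
assignment happens at fetch time, before any per-variant filtering.

## The synthetic data generator

`simulate_amplicon_run()` builds complete, fully synthetic studies: a
random reference contig, a BED file of insert intervals, and per-sample
coordinate-sorted, indexed BAMs with exact CIGAR and MD tags. Each
read-pair is simulated as one amplicon molecule: planted variants are drawn
per pair at their allele fraction (0.5 emulates a heterozygote, 1.0 a
homozygote), both mates receive the molecule's content — the forward mate
reads from the molecule start, the reverse mate (stored reference-oriented
with the reverse flag) from the molecule end — and independent per-base
substitution errors are then injected into each mate separately. The
generator keeps an exact per-pair record of each mate's variants, computed
directly from its simulation columns rather than from the emitted tags, so
it doubles as independent ground truth: `truth_expected_calls()` applies
the threshold arithmetic to those counts, and the test suite compares the
caller against this bookkeeping and against a naive pair-enumeration
oracle.

Default geometry: 140 bp inserts, 150 bp reads, 5 bp primers, 20 pairs per
amplicon, error rate 0, constant Q38 base qualities (a two-point
low-quality mixture is available). The short primer flank is deliberate:
each mate's span is primer + insert + primer = 150 bp, giving an overlap
fraction of 140/150 ≈ 0.93, above the 0.9 assignment default. With
realistic ~20–25 nt primers and insert-interval target regions, read spans
of primer + insert would dilute the overlap fraction below 0.9, and
`--overlap` would need lowering (or the target regions widening); the
geometry here keeps the default operating point exercised end to end.
What the generator does *not* emulate: quality-score/error correlation,
GC and amplicon-efficiency bias, primer-synthesis errors, chimeric or
off-target reads, and alignment ambiguity in repetitive sequence. Passing
tests therefore demonstrate algorithmic correctness under the complete
overlap regime, not robustness to every artifact of real libraries.

## Numerical and degenerate-input choices

* Thresholds are inclusive (`>=`); `absthresh = 1, proportionthresh = 0`
  reports every in-bounds concordant variant; an amplicon with zero
  assigned pairs emits nothing but still appears in coverage with 0.
* Pairing is by query name among primary records in the fetch window; mate
  position fields are not trusted. Name groups of one (singletons) or more
  than two primary records are dropped and counted in the log.
* Reads without an MD tag are rejected with a pointer to `samtools calmd`
  rather than silently skipped; `P` (padding) CIGAR operations are
  rejected; `N` skips advance the reference cursor without emitting
  variants.
* Multi-base deletions are one event per `^`-run; multi-base insertions one
  event per `I`-run, with the quality gate applying to every inserted base
  in both mates (the strictest reading, chosen for error suppression).
* Mate order within a pair never affects output (concordance is
  symmetric), and two runs over identical inputs produce byte-identical
  files.

## Scale of the validation suite

The test suite validates against fixtures of up to ~5 amplicons and ~200
read-pairs per sample — sizes at which the naive enumeration oracle is
exact and the whole suite runs in a couple of minutes — plus 1,000
randomized CIGAR/MD round-trip cases. The acceptance script simulates 3
samples × 8 amplicons × 40 pairs. Runtime scales linearly in total
read-pairs; a single in-memory pass per amplicon keeps memory flat.
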