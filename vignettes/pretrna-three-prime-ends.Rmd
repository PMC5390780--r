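---
title: "Calling pre-tRNA 3' ends: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling pre-tRNA 3' ends: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pretRNAends)
```

## The biological question and the measurement

Pre-tRNAs are transcribed with a 5' leader, a 3' trailer and, for many
genes, an intron. The 3' end of a precursor is a moving target: the trailer
is removed endo- and exonucleolytically, the CCA trinucleotide is then added
without a template by the tRNA nucleotidyltransferase (passing through +C
and +CC intermediates), and precursors routed to surveillance acquire short
non-templated oligo(A) tails. A targeted library that ligates an adapter to
RNA 3' ends and amplifies from intron-specific primers yields reads whose 3'
terminus is exactly the molecule's 3' terminus. Classifying that terminus
per read, and normalizing per gene, turns sequencing into a quantitative
assay of 3'-end processing status.

This package reimplements that analysis as a reusable pipeline with a
simulator in place of the (undeposited) original libraries.

## Read model and preprocessing

The library design implies the read structure

```
read = 5' adapter (TGGAATTCTCGGGTGCCAAGGC) + reverseComplement(RNA fragment)
```

because sequencing proceeds from the reverse-transcription primer through
the ligated 3' adapter into the fragment. Preprocessing therefore:

1. **Quality filter.** Reads whose *mean* Phred score is below 30 are
   dropped (inclusive comparison). The upstream vendor filter this mirrors
   is described only as "quality score equal or higher than 30"; whether it
   was a per-read mean, per-base minimum or chastity filter is not
   recoverable, so the summary statistic is configurable
   (`qualityFilter(method = "mean" | "min")`); the mean is the conventional
   read-level reading and the default. Only Phred+33 encoding is supported.
2. **Adapter removal.** The adapter is searched as a 5' prefix: the full
   adapter, or a suffix of it at least `minOverlap = 4` bases long (the
   behaviour of the original trimmer's `ao 4` option), allowing
   `floor(0.1 * overlap)` mismatches. The 10% mismatch tolerance is a
   conventional choice; the original tool's exact threshold formula is not
   published. Reads shorter than `minLength = 15` after trimming are
   discarded (`m 15`). Reads with no adapter hit are kept unmodified —
   nothing in the design guarantees every read saw the adapter, and
   alignment adjudicates them later.
3. **Orientation and collapsing.** Survivors are reverse-complemented into
   sense orientation and identical sequences are collapsed into unique
   reads with counts (descending count, then lexicographic, so output order
   is deterministic). All downstream work is per unique sequence, weighted
   by count.

Read accounting is exact at every stage: input = quality-discarded +
length-discarded + sum of unique-read counts, and the test suite asserts
this conservation on simulated libraries.

## Alignment

Each unique read is aligned to per-gene *precursor references* — leader (30
nt) + gene body with intron + trailer (50 nt), in sense orientation — by
optimal local alignment with affine gaps via
`Biostrings::pairwiseAlignment`: match +1, mismatch −3, gap of length *k*
costs 2 + *k*. These are the classic blastn-era parameters matching the
quoted gap costs of the original analysis. Two deliberate substitutions:

* **Score threshold instead of E-value.** The original BLAST run used
  `e 0.001`; reproducing Karlin–Altschul statistics is out of scope and
  adds nothing for a five-reference target set. The contract here is
  *oracle-equal optimal local alignment* with a raw score cutoff
  (`minScore = 20`, roughly 20 matched bases). The test suite checks score
  equality against an independent brute-force Gotoh dynamic program on
  hundreds of random instances; word-size seeding is treated as an
  optimization that may never change results.
* **Per-gene references instead of the whole genome.** The original
  analysis aligned against the full genome. For a targeted library the
  per-gene references are equivalent for every on-target read; off-target
  reads surface as unmapped and are reported by the mapping-rate QC, which
  warns (never fails) below the 96% rate a well-behaved targeted library
  should exceed.

The best-scoring gene takes the read; exact score ties across genes go to
an `AMBIGUOUS` bin that is excluded from per-gene tables and counted in QC.
The five fixture genes are built pairwise 8-mer-distinct, so ties are
essentially impossible there by construction.

## Calling the 3' end

Given the best alignment, the caller must split the read 3' tail into
*templated* (genomically explained) and *non-templated* parts:

1. Walk back from the alignment's 3' terminus, peeling terminal columns
   that are not matches (terminal mismatches and insertions belong to the
   candidate suffix, not the template).
2. Greedily re-extend the templated end forward while the next read base
   equals the next reference base (`N` in the reference never matches).
3. What remains of the read tail is the non-templated suffix; the signed
   `end_offset` is the reference position of the last templated base minus
   the position of the last gene base.

Step 2 encodes the central **maximal-templated-extent** policy: a base the
genome can explain is never called an addition. This is conservative — for
a gene whose genomic trailer happens to begin with C, CC or CCA, a genuine
CCA addition is indistinguishable from trailer sequence and will be called
trailer. Such genes are flagged (`geneAmbiguityFlags`), reads whose calls
would change under the opposite reading are counted
(`boundary_ambiguous`), and `addedFirst = TRUE` implements the opposite
policy (terminal templated A-runs, then templated C/CC/CCA at the gene end,
are reassigned to the suffix). The default fixtures avoid the issue
entirely: their trailers start with G or T.

Internal mismatches (sequencing errors in the gene body) do not disturb the
call because peeling stops at the last terminal *match*; an error in the
last few bases, however, genuinely changes the observed suffix and lands
the read in `OTHER` — at a per-base substitution rate of 0.001 this affects
a fraction of a percent of reads, which is why the stochastic recovery
checks are binomial-error-aware rather than exact.

### Category rules

Exactly one category per read, in fixed decision order: `PLUS_CCA` (offset
0, suffix `CCA`); `OLIGO_A` (suffix ends in ≥1 A and the pre-run remainder
is empty, or is `C`/`CC`/`CCA` at offset 0); `PLUS_CC`; `PLUS_C`;
`PROCESSED_EXACT`; `TRAILER` (empty suffix, positive offset); `TRIMMED`
(empty suffix, negative offset); `OTHER`. Two rules deserve comment:

* A full or partial CCA counts **only at the gene end** (offset 0) — a
  `CCA` suffix four bases into the trailer is `OTHER`, not a CCA addition.
* Oligo-adenylation **dominates** CCA intermediates: `CCAA` at offset 0 is
  `OLIGO_A`, because the published category definition ("at least one extra
  adenine at the 3' end") textually covers it and the categories must
  partition. The per-read suffix is retained in the calls table so the
  decision is reversible in reporting.

The classifier is validated against an exhaustively enumerated,
independently implemented truth table over all suffixes of length ≤ 4 at
offsets {−2, 0, +3} (1023 cases). Suffixes that are neither templated nor a
recognized addition pattern fall to `OTHER` whatever their length; a hard
cap on suffix length was rejected because genuine oligo(A) tails from a
geometric length distribution with mean 3 exceed 8 nt about 4% of the time
and would be misbinned.

## Summaries

* `table1Percentages`: per-gene category percentages over **all** reads
  assigned to that gene, full precision retained (one decimal is the
  display convention).
* `endProcessedShares`: the −/C/CC/CCA forms renormalized to sum to 100.
  The operation is scale invariant, so it gives identical results from raw
  counts or printed percentages — which is exactly how the published
  per-gene shares can be reproduced from a printed percentage table
  (22% and 32% full-CCA for the leucine-CAA and tryptophan-CCA precursors
  in the Maf1-deletion stress library; both recomputed in the test suite
  and the acceptance script). Oligo-adenylated reads are **excluded** from
  the denominator: the share plot this mirrors shows only the −/C/CC/CCA
  forms, and this exclusion is the main reason share values differ from a
  naive renormalization that keeps them. By default shares are computed
  over intron-overlapping reads only (≥ 6 bases of intron overlap),
  matching the design's focus on intron-containing end-matured precursors;
  `intronFilter = FALSE` drops that requirement since the exact published
  filter is not fully specified.
* `processingEfficiency`: the processed / trailer-containing / trimmed /
  oligo(A) partition per gene, as fractions.
* `mappingQC`: assigned fraction with the 96% expectation.

`OTHER` and `AMBIGUOUS` are reported, never silently dropped; the published
table's columns do not sum to 100%, implying such unlisted reads existed in
the original analysis too.

## The simulator

`simulateLibrary` inverts the wet-lab protocol: per read it draws a gene
(`gene_mixture`), a category (`category_mixture`), a fragment 5' start
uniform inside the intron (intron-primed selection) and a 3' end per
category, then emits `adapter + reverseComplement(fragment)` truncated — or
padded with templated upstream sequence — to 100 nt, with substitution
errors and a two-level quality model. Default study conditions: read length
100; substitution error 0.001 (a typical high-quality base-calling error
rate); trailer extensions uniform on 1–20 nt; trimming depths uniform on
1–10 nt; oligo(A) lengths geometric with mean 3 (support ≥ 1); 1% of reads
at Q20 and the rest at Q37, existing only to exercise the quality filter;
default category mixture trailer-rich (35%) with moderate CCA intermediates
(5/10/20% for +C/+CC/+CCA), 10% each exactly-processed, trimmed and
oligo-adenylated. The RNG consumption order is fixed and documented in the
source, so identical seeds give byte-identical libraries.

Ground truth must be *recoverable*, so the generator refuses placements
whose truth decomposition is not the unique maximal-templated one: fixture
trailers never start with A or C, and an oligo(A) run is re-placed
(bounded retries) if any of its prefixes could align to the reference
continuation with non-negative score — otherwise the aligner would
legitimately absorb the tail as templated sequence and the "truth" would be
wrong, not the pipeline. An `ambiguous = TRUE` fixture variant instead
plants one CCA-leading trailer specifically to test the boundary policies.

What the simulator does **not** model: indels (an option exists but is
excluded from the validation conditions, to keep truth unambiguous), PCR
duplication and ligation bias, reverse-transcription misincorporation at
modified nucleotides, multi-locus tRNA gene families, and real tRNA
sequences (the fixtures are random, structure-free stand-ins). Passing the
round-trip and proportion-recovery checks therefore demonstrates that the
*pipeline logic* is correct and well calibrated under the stated error
model — not that real libraries are free of the biological and technical
artifacts above.

## Validation conditions and problem sizes

The test suite runs, among others: a zero-error round trip (5 genes ×
2,000 reads, fixed seed) requiring 100% correct gene and category; a
stochastic recovery check (20 seeds × 10,000 reads/gene at error 0.001)
requiring ≥ 95% of (gene, category) cells within 3 binomial standard errors
of truth; 500-instance score equality against the brute-force alignment
oracle (reads ≤ 40 nt, references ≤ 120 nt); the 1023-case classifier truth
table; and partition/normalization invariants (percentages sum to 100 ±
0.05, shares to 100 ± 0.01, exact read-count conservation). These sizes
were chosen to give the binomial arguments real power while keeping the
suite comfortably interactive.

## Numerical and coordinate conventions

Internally everything is 1-based, closed-interval (the IRanges convention
native to this ecosystem); the on-disk annotation dialect keeps BED-style
0-based half-open intervals and is converted at the I/O boundary, as
standard BED readers do. `end_offset` semantics are convention-free: 0
means the last templated base is the last gene base. The annotation format
is 6 BED-like columns plus a seventh listing gene-relative intron intervals
(`start-end`, comma-separated, `.` for none) — flat, hand-writable, and
round-trips exactly. Degenerate inputs are defined, not crashed on: empty
FASTQ yields empty tables with a warning; an all-N read is unmapped; a gene
with no introns flags all reads non-intron-containing with a one-time
warning; zero denominators yield `NA` with a warning.

## Known limitations

* Single-end, 5'-adapter-only trimming; no paired-end or UMI support.
* No splice-aware or modification-aware alignment (precursors retain
  introns, so none is needed for the targeted design).
* Boundary ambiguity at CCA-like trailers is flagged and policy-switchable
  but cannot be resolved from sequence alone.
* The E-value semantics of the original BLAST filtering are approximated by
  a raw score threshold; for short (< 20 nt) genuine fragments this is more
  stringent than the original.
* Percentages from the bundled published table reproduce the published
  worked examples for the Maf1-deletion stress library; wild-type
  counterparts printed alongside them do not reproduce from the rounded
  printed percentages (the original authors evidently used unrounded counts
  and/or a slightly different denominator), so only the reproducible pair
  is asserted.
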