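---
title: "Benchmarking mappers and variant callers with simulated truth"
author: "varbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking mappers and variant callers with simulated truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varbench)
```

## The problem

Accuracy claims for short-read mappers and germline variant callers are only
as good as the truth they are scored against. Two complementary truth
channels are in common use: simulation, where every read's origin and every
variant is known by construction, and curated high-confidence call sets
(such as the Genome in a Bottle integrated genotypes for NA12878), where
comparison must be restricted to regions in which the truth set actually
asserts a genotype. `varbench` implements the full desk-scale loop: a
simulator that embeds truth in its output, an alignment judge, and a variant
call comparator that follows the high-confidence-region conventions, so it
can score either a simulated truth VCF or a user-supplied curated one.

## The simulation model

**Mutation process.** Every reference base independently nucleates a
mutation with probability $r$ (default $10^{-3}$). A mutation is an indel
with probability $p_I$ (default 0.1), otherwise a SNP. Indel lengths are
drawn uniformly from the small range 1–10 bp, or, for a fraction $p_L$
(default 0.1) of indels, from the large range 10–24 bp; insertions and
deletions are equally likely. A mutation is heterozygous with probability
$p_h$ (default 0.5), landing on one uniformly chosen haplotype; otherwise it
is homozygous-alternate. Indels follow the VCF anchor-base convention
(deletion removes bases after the anchor; insertion inserts after it). A
proposed mutation whose reference footprint touches an already-accepted
mutation on the same haplotype is rejected without resampling, which keeps
per-base independence approximately intact; at $r = 10^{-3}$ rejections
affect roughly 0.2% of proposals, well inside the binomial tolerance used by
the tests.

The mutation rate, indel fraction, indel ranges, insert geometry, read
length and coverage defaults are the conditions the benchmark emulates. The
large-indel mix $p_L$, the zygosity probability $p_h$ and the sequencing
error rate are not determined by those conditions; their defaults (0.1, 0.5,
0.01) are explicit stand-ins, chosen once as typical of short-read
simulators, and are all configurable.

**Library process.** The number of pairs is the closed form
$n = \mathrm{round}(C \cdot L / (2\ell))$ for coverage $C$, reference length
$L$ and read length $\ell$, so realized coverage differs from $C$ only by
pair-count rounding. Fragments choose a haplotype uniformly; outer fragment
length is $\mathcal{N}(500, 50^2)$ (resampled until it fits in
$[\ell, L_h]$), and the fragment start is uniform. "Insert size" here means
the outer fragment length, the usual convention of read simulators — an
alternative reading (inner mate gap) exists, so the choice is stated rather
than silent. Mate 1 reads the forward strand of the left fragment end, mate
2 the reverse complement of the right end (FR layout). Substitution errors
are injected per base at the configured rate with a flat quality string at
the matching Phred score; platform-specific error profiles (homopolymer
errors, quality decay along the read) are deliberately out of scope.

**Truth channel.** Each fragment's true placement — contig, both mates'
leftmost reference coordinates and strands, haplotype, serial — is encoded
colon-separated in the read name and decoded by parsing fixed fields from
the right, so contig names containing colons survive. Coordinates are
reported on the *unmutated* reference so they are comparable with an
aligner's positions; a read starting inside an inserted run maps to the base
after the insertion anchor, an approximation bounded by the indel length
(≤ 24 bp) and absorbed by the correctness tolerance below.

**Random streams.** The mutation stage and the fragmentation stage take
separate seeds (the driver derives them from one master seed), and the error
stage uses `seed + 1` relative to fragmentation. Changing the error rate
therefore never perturbs fragment placement — a property the tests rely on to
measure the error rate by direct read comparison.

## Judging alignments

A mapped record is *correct* when contig and strand match its origin and the
leftmost-position distance is at most a tolerance, default 20 bp. Exact
equality would be wrong: a deletion of up to 24 bp upstream of a read's
start legitimately shifts its leftmost coordinate, and different gap
placements around indels shift it further. The tolerance is a flag, not a
constant, because no single value is canonical. Secondary (0x100) and
supplementary (0x800) records are skipped so each read is judged once; a
read name that fails to decode aborts the run rather than being dropped,
since silent drops would bias percentages.

The ROC-like curve sweeps the MAPQ threshold from the highest observed value
downwards, accumulating correct and incorrect reads with MAPQ ≥ t; ties
share a point, both coordinates are non-decreasing, and the terminal point
equals the totals over mapped reads. The calibration histogram assigns every
mapped read a rank-based MAPQ percentile (mean rank for ties, scaled to
(0, 100]) and counts incorrect reads per decile; rank-based normalization is
stated explicitly because "percentile" alone is ambiguous for the heavily
tied MAPQ distributions real mappers emit.

## Comparing call sets

Both call sets are decomposed to biallelic records and normalized (shared
trailing bases trimmed with leftward reference extension, then shared
leading bases trimmed) — the canonical leftmost minimal representation, so
representational differences between callers cannot masquerade as
disagreements. Comparison is restricted to the high-confidence regions:
calls or truth variants starting outside them are excluded, as are records
whose footprints overlap a *complex region* — for every truth indel with
another truth variant starting within 9 bp (a 10-base window), the span of
both footprints is excluded. Matching is exact on (chrom, pos, ref, alt) and
one-to-one; genotype-aware matching is the default because the truth is a
genotype call set, and a correct allele with the wrong zygosity then counts
as one FP and one FN (the alternative, allele-only matching, is a flag). A
call with a missing quality score still participates in the overall metrics
but sits below every explicit threshold of the quality ROC; a trailing
$-\infty$ point then restores the unthresholded totals, keeping the curve
consistent with the headline metrics.

True negatives are counted per base: every confident base not covered by a
variant footprint in either set. Because almost all confident bases are
homozygous reference, TN is enormous relative to FP and specificity
saturates near 100%; the outputs flag this and precision should be read as
the informative "positive" statistic. Depth stratification bins TP and FP
records by their per-sample depth annotation (site-level `INFO/DP` as a
fallback); FN records carry no caller depth and are not binned, and records
without depth form an explicit "unknown" stratum.

## Numerical and design choices

- Coordinates: VCF and read origins are 1-based (matching SAM `POS`); BED is
  0-based half-open; intervals are handled as `GRanges` internally.
- Normalization at position 1 stops right-trimming when no reference base
  remains for leftward extension, leaving the leftmost valid representation.
- Undefined ratios (0/0) are `NA`, never 0 or 1.
- Duplicate test representations of one truth variant yield one TP and the
  rest FP (one-to-one matching), preserving the conservation identities
  TP + FN = evaluable truth and TP + FP = evaluable test.
- Percentages print with two decimals; tables (TSV/JSON) are the contract,
  plots are conveniences and headless-safe.
- Every JSON report embeds the full stage configuration, the seed and an MD5
  of the serialized configuration, so a report can be regenerated and
  verified byte-for-byte for the deterministic stages.

## What the generator does and does not establish

The synthetic contig is i.i.d. uniform-GC sequence. It contains no repeats,
segmental duplications or low-complexity tracts, so a mapper's near-perfect
score here does not predict its behaviour in the repetitive fraction of a
real genome — which is precisely where real mappers diverge. What the green
tests do establish is the correctness of the accounting machinery: parameter
recovery (mutation rate, indel mix, insert geometry, coverage) within
binomial/normal sampling tolerances, exact haplotype reconstruction from the
truth VCF, closed-loop 100% scores for truth-derived alignments and calls,
and agreement with independent brute-force oracles for every judging,
exclusion, comparison and ROC operation on randomized small instances.
Benchmarks of real tools on real data remain subject to the biases of the
truth set itself.

## Limitations

Structural variants, phasing-aware (haplotype-path) comparison, somatic
allele fractions, trio simulation and platform error profiles are out of
scope. The comparator matches normalized records site-by-site; a
representationally different but haplotype-equivalent cluster of calls
(e.g. an MNP called as two SNPs plus an indel) is handled only by the
complex-region exclusion, not by path matching.
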