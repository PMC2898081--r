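---
title: "Measuring 10-bp dinucleotide periodicity at transcription start sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring 10-bp dinucleotide periodicity at transcription start sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotasig)
```

## The signal and why it matters

DNA wrapped on a nucleosome faces the histone core on one side of the
helix. Because the helical repeat is close to 10 bp, sequence features that
favor bending recur every helical turn on rotationally positioned
nucleosomes. Around transcription start sites (TSSs), aggregate promoter
composition shows exactly this signature: purine-purine (RR = AA, AG, GA,
GG) dinucleotide frequencies oscillate with a ~10-bp period downstream of
the start site, in phase with the TSS, and pyrimidine-pyrimidine (YY)
frequencies oscillate in counter-phase. The oscillation overlaps the +1
nucleosome (roughly +40..+190 in TSS coordinates) and is invisible in any
single promoter — it emerges only when many promoters are aligned at their
first transcribed base, which is why alignment quality and phase coherence
are the whole game.

`rotasig` turns this observation into a measurement pipeline: extract
TSS-aligned promoters, compute dinucleotide-class frequency profiles,
summarize the downstream window by a single spectral statistic (the
area-normalized periodogram power at period 10 bp), attach uncertainty via
resampling, and stratify promoters by the properties the signal correlates
with (CpG-island status, expression level, tissue specificity, motif
matches, ChIP tag enrichment).

## Coordinates

Genomic input is 1-based inclusive. Internally every promoter lives on a
0-based TSS-relative axis where offset 0 is the first transcribed base (the
"+1" base); minus-strand promoters are reverse-complemented so increasing
offset is always downstream of transcription. The display convention that
skips zero (..., -2, -1, +1, +2, ...) is applied only in printed reports
and plots. A dinucleotide "at offset i" starts at offset i. One convention
everywhere removes off-by-one ambiguity from every windowed computation.

## TSS filtering

Raw TSS tables contain redundant and weakly supported entries. Two filters
are applied (`filter_tss()`): records supported by fewer than 2 cDNAs at
the exact position are dropped, and same-chromosome records linked by
pairwise distance of at most 200 bp are collapsed — transitively, i.e.
single-linkage per chromosome — to the record with maximal support.
Whether the collapsing should be transitive, and how support ties break,
is not fixed by the data model; we chose single-linkage with ties going to
the smaller coordinate (then lexicographically smaller id) because it is
deterministic and order-independent, and exposed both knobs
(`min_support`, `cluster_bp`). Contig-edge windows are padded with `N`
rather than dropped, and `N` positions are excluded from every frequency
denominator, so the number of sequences is constant across positions.

## The periodicity statistic

`periodicity_stat()` composes, in order:

1. **Mean frequency series.** The RR (by default) class frequency at each
   dinucleotide start offset +40..+189 — a 150-point series covering bases
   +40..+190. RR frequencies serve as a proxy for the joint RR/YY signal,
   since the two are counter-phased realizations of the same purine-track
   structure.
2. **3-bp moving average.** A centered window that shrinks at the series
   edges (length is preserved). Smoothing attenuates position-level noise
   without moving the phase of 10-bp peaks.
3. **Hamming taper and DFT.** The series mean is subtracted, the series is
   multiplied by `w(n) = 0.54 - 0.46 cos(2*pi*n/(N-1))`, and the
   periodogram is `|X_k|^2 / N` for `k = 1..N/2`.
4. **Area normalization and read-out.** Power is normalized to total 1
   (DC excluded) and the value at the bin whose period is nearest 10 bp is
   reported. With N = 150 the 10-bp period is bin k = 15 *exactly*, which
   is why the window is 150 points: no interpolation at the target period.

Numerical choices worth recording: the series mean is subtracted because
otherwise the DC term dominates the normalization area (a flag restores
the DC bin for sensitivity analysis); band read-out is nearest-bin, with
the exact bin period reported alongside; a zero-variance series yields a
flagged all-zero spectrum rather than an error, so degenerate strata
surface visibly in group analyses. The `+40 and +190` span is inclusive of
both ends at the base level and maps to dinucleotide start offsets
+40..+189.

## Null and sampling distributions

**Shift null** (`shift_null()`). Each sequence is independently offset
from the TSS anchor by a uniform random 1-9 bp (the analysis window slides
upstream, equivalent to prepending bases at the 5' end), destroying phase
coherence while leaving composition untouched; the statistic is recomputed
per iteration (500 by default). Shifts are per-sequence — a single global
shift per iteration provably leaves the magnitude unchanged (the
periodogram is phase-invariant), and the package exposes that mode only as
a sanity check. One structural property deserves emphasis: shifts drawn
from {1..9} rather than {0..9} leave a small coherent residual, because
the phase factors over a full 10-bp period sum to zero, so excluding the
zero shift leaves a residual of relative amplitude 1/9. For weak signals
(planted amplitude below ~0.05 at cohort sizes near 1,000) the residual
sits below the sampling noise floor and the null fully abolishes the
signal; for strong plants the null median remains visibly elevated, though
still clearly below the observed statistic. The test suite asserts the
complete-abolition property in the weak regime and the
observed-exceeds-null-maximum property in the strong regime.

**Bootstrap** (`bootstrap_magnitudes()`). A single magnitude for a
promoter group carries no uncertainty, so groups are compared through
bootstrap distributions: sample 500-1,000 promoters with replacement,
compute the magnitude of the sample's mean RR series, repeat 2,000-5,000
times. `normality_check()` (Kolmogorov-Smirnov against a moment-matched
normal) is the stopping diagnostic for the number of samplings;
`compare_groups()` applies the Wilcoxon rank-sum test to two such
distributions.

**Permutation association** (`label_association_test()`). Binary
promoter properties (e.g. has a motif match / carries a mark) are tested
for co-occurrence by shuffling one label vector; the statistic is the
both-positive count and p-values carry the `(b+1)/(n+1)` correction with
10,000 shuffles by default.

All stochastic operations take an explicit seed and are reproducible
bit-for-bit; the pipeline derives per-stage seeds from one master seed so
stages can be rerun independently.

## CpG-island and expression stratification

Both stratifications use the same 2-component univariate Gaussian mixture
(`fit_gmm2()`), fitted by EM with deterministic initialization (component
means at the 25th/75th percentiles, common starting sd, equal weights) —
model-based partitions in place of ad hoc thresholds. Components are
ordered by mean, and a fit is flagged degenerate when Ashman's
`D = |mu2 - mu1| / sqrt((s1^2 + s2^2)/2)` falls below 2, the point where
two Gaussians stop describing distinct modes; this catches unimodal input
reliably, whereas a naive small-mean-difference check does not (EM on a
single Gaussian happily converges to two overlapping components about one
sd apart).

The CpG feature is the observed/expected CpG ratio
`(#CG * L)/(#C * #G)` with `L` the non-N length, over the 1,000-bp window
centered on the TSS (internal offsets -500..+499); the exact feature and
window are configuration, since the choice of islands-versus-not is a
classification target rather than a segmentation. The high-mean component
is the island class; posterior ties break to it.

Median expression across tissues is fitted on `log2(median + 1)` (the +1
guards genes with zero medians; expression bimodality is log-scale). Tissue
specificity uses the tau index,
`tau = sum_i (1 - x_i / max_i x_i) / (n - 1)`, which is 0 for uniform and
1 for single-tissue profiles; the three-way low/medium/high split is by
rank tertiles by default, with explicit score cut-points as a first-class
alternative because published group sizes for this kind of analysis are
typically unequal — i.e. derived from score-valued boundaries, not
quantiles.

## Motif scanning

`call_matches()` implements a local-probability scan: at each start offset
in -500..+500 the score is the product of per-column base probabilities of
a 7-bp position weight matrix (pseudocount 0.01 per cell before column
normalization), and a match is an offset in 0..+40 whose score exceeds the
promoter's own regional mean, reported only when unique in that region.
The threshold is the arithmetic mean of the defined scores; a
density-derived threshold would be more stringent (the arithmetic-mean
rule admits a nontrivial background rate of unique exceedances — about a
fifth of uniform-background promoters in our simulations — so absolute
match counts should be read against the shuffle control, not alone). The
column-shuffle control permutes the matrix columns, recounts matches over
the cohort, and reports an empirical p-value; permutations that reproduce
the original matrix exactly (the identity, or swaps of identical columns)
are redrawn, since the control is meant to compare against perturbed
matrices. Scanning is forward-strand only by default: promoters are
already transcription-oriented.

## Tag summaries

Tag 5' ends (BED input, `start+1` on the plus strand, `end` on minus) are
mapped to transcription-oriented offsets — for minus-strand TSSs offsets
mirror and tag strands swap — counted per offset, averaged per TSS, and
smoothed with a sliding 70-bp window (shrinking at the edges; for the even
default width the window takes the extra position on the right, so a
single tag at +60 smears uniformly over +25..+94). Forward and reverse
densities mark the two boundaries of nucleosome-protected DNA. Per-TSS
enrichment is the tag count in +40..+200 (closed bounds);
`quantile_partition()` cuts scores into near-equal rank groups (ties by
stable id order, lower-score groups take the remainder), and
`periodicity_by_group()` couples group intensity to the bootstrap
magnitude distributions, testing the trend by Pearson correlation between
each replicate's group score and its magnitude.

## The synthetic-data generator

`synth_config()` + `generate_promoters()` produce cohorts in which the
periodic signal is planted on the purine/pyrimidine track: inside the
planted region the per-position purine probability is
`0.5 + a*cos(2*pi*(i - phase)/10)`, and bases are drawn within class from
the background frequencies. Planting on the track rather than on RR
dinucleotides directly controls RR and YY jointly and in counter-phase
with one knob — the structure the biological signal shows — at the cost
that the realized RR amplitude is slightly attenuated
(about `a*cos(pi/10)`) and RR peaks sit half a position upstream of the
purine peaks. Optional blocks add CpG-island composition (elevated G+C
plus planted CpG dinucleotides, versus CpG-depleted background emulating
methylation-driven loss), planted motif instances sampled from a PWM,
nucleosome-boundary tag clouds (`Normal(center -/+ 73, jitter)` for the
two strands), and expression matrices with bimodal log-normal medians
(log-median components 5 sd apart, mirroring the separation of the CpG
mixture we validate against) and a three-level specificity gradient built
by boosting k tissues. Every bundle records its generative truth, and
recovery tests read planted parameters from the bundle rather than from
constants.

What the generator does **not** emulate: positional base-composition
gradients around real TSSs (GC plateaus, TATA/initiator peaks), linked
nucleosome arrays, correlated occupancy between marks, probe-level
expression noise, or sequence evolution. Passing recovery tests therefore
demonstrates that the measurement machinery is correct and calibrated on
data satisfying its assumptions — not that real promoters carry a signal
of any particular strength.

## Problem sizes and determinism

The validation suite runs cohorts of 300-1,800 promoters with sequences
trimmed to the statistic's working window (240 bp) — the statistic never
looks outside it — 50 replicates per amplitude for monotonicity, 200
unplanted cohorts for type-I calibration, 500-iteration shift nulls,
2,000-sample bootstraps, and 100-shuffle motif controls; these sizes give
stable pass/fail behavior at fixed seeds while keeping a full run in
minutes. The pipeline writes no timestamps into its outputs, so a rerun
with the same seed is byte-identical — which is itself one of the checks.

## Known limitations

- The statistic is cohort-level; the package deliberately offers no
  per-sequence periodicity calls (single promoters do not carry a
  detectable signal).
- The shift null's 1/9 coherent residual (above) makes "null mean" an
  overestimate of the noise floor for strongly periodic cohorts.
- The arithmetic-mean match threshold is permissive; treat match counts
  comparatively (against the shuffle control or between cohorts).
- Expression matrices are consumed already normalized; no probe handling.
- Genome-scale inputs are streamed naively (whole FASTA in memory via
  Biostrings), adequate for promoter-window extraction but not for
  assembly-scale scans.
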