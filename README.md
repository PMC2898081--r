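# rotasig

Detection and quantification of the 10-bp periodic RR/YY dinucleotide
signal phased to transcription start sites.

## The problem

Nucleosomes with a fixed rotational setting expose the same face of the
DNA helix every helical turn (~10 bp). Around transcription start sites
this leaves a sequence fingerprint: when thousands of promoters are
aligned at their first transcribed base (+1), the aggregate frequency of
purine–purine dinucleotides (RR = {AA, AG, GA, GG}) oscillates with a
10-bp period over the region of the +1 nucleosome (+40..+190), in phase
with the TSS, while pyrimidine–pyrimidine (YY) frequencies oscillate in
counter-phase. No individual promoter shows the signal — it exists only in
phase-coherent aggregate — so measuring it honestly requires careful
alignment, a well-defined spectral statistic, and resampling nulls.

`rotasig` is for regulatory genomicists who want to measure this signal in
their own TSS collections and ask which promoter classes carry it. The
core statistic is the area-normalized periodogram power at period 10 bp of
the mean RR-frequency series *f* over dinucleotide start offsets
+40..+189:

    x(n) = f(n) - mean(f),  smoothed by a 3-bp moving average
    w(n) = 0.54 - 0.46 cos(2*pi*n/(N-1))          (Hamming taper)
    P(k) = |DFT(x*w)(k)|^2 / N,   normalized so that sum_k P(k) = 1
    magnitude10 = P(k = 15)                        (N = 150, period 10 exactly)

Supporting machinery: TSS quality filters (support >= 2, 200-bp
single-linkage clustering), strand-aware promoter extraction from FASTA, a
1–9-bp shift-randomization null, bootstrap magnitude distributions for
group comparisons (rank-sum tests), CpG-island classification by a
2-component Gaussian mixture on CpG observed/expected, expression and
tissue-specificity (tau) partitions, a sliding local-probability PWM scan
with a column-shuffle control, ChIP tag density summaries, and a
synthetic-data generator that plants all of the above with known truth.

## Worked example

Plant a 10-bp RR periodicity of amplitude 0.2 into 1,000 synthetic
promoters, measure it, and compare against its shift null:

```r
library(rotasig)

cfg <- synth_config(n_promoters = 1000, amplitude = 0.2, seed = 7)
gp  <- generate_promoters(cfg)
gp$seqs
#> AlignedSeqSet: 1000 sequences of length 2000 | +1 base at offset 1000 (spanning -1000..+1000 in display coordinates)

st <- periodicity_stat(gp$seqs)   # RR class, window +40..+190
st
#> PeriodicityStat [RR]: magnitude at 10 bp = 0.7186 (window 41..190)

nd <- shift_null(gp$seqs, n_iter = 500, seed = 8)
nd
#> NullDistribution [shift]: 500 replicates, mean 0.4871, sd 0.07591, seed 8

empirical_p(st$magnitude10, nd)
#> [1] 0.001996008
```

The observed statistic (0.72: nearly three quarters of the normalized
spectral power sits in the 10-bp bin) exceeds every one of the 500
shift-randomized replicates, so the signal is phased to the TSS — randomly
offsetting each promoter by 1–9 bp destroys it. The elevated null mean is
expected for so strong a plant: 1–9-bp shifts leave a 1/9 coherent
residual (see the methods vignette). On an unplanted cohort the same
statistic lands near the flat-spectrum level (~1/75 ≈ 0.013) and inside
its null.

The full pipeline (`run_pipeline()`) chains ingestion, profiles, the
statistic, nulls and the stratifications from one seeded config and writes
TSVs plus a machine-readable `summary.json`; `inst/scripts/rotasig` wraps
`synth` and `run` for shell use.

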