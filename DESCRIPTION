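Package: rotasig
Title: Detection of 10-bp Dinucleotide Periodicity at Transcription Start Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and quantifies the 10-bp periodic purine-purine (RR) and
    pyrimidine-pyrimidine (YY) dinucleotide signal phased to transcription
    start sites (TSSs), a sequence correlate of nucleosome rotational
    positioning over the +1 nucleosome. Provides TSS table ingestion and
    quality filtering, strand-aware promoter extraction from genome FASTA,
    per-position composition profiles, Hamming-windowed periodogram
    estimation of the normalized power at period 10 bp, shift-randomization
    and bootstrap null distributions, promoter stratification by CpG-island
    status (Gaussian mixture), expression level and tissue specificity,
    position-weight-matrix promoter scanning with a column-shuffle control,
    ChIP tag density summaries, a synthetic-data generator with planted
    signals for validation, and an end-to-end deterministic pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
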