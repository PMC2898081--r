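## Independent reference implementations used as oracles. These stay
## deliberately naive (O(N^2) sums, per-window loops) and never share code
## with the package internals they check.

## Direct DFT-definition periodogram: mean-subtract, Hamming taper computed
## from the cosine definition, then literal complex sums per bin.
oracle_periodogram <- function(series, normalize = TRUE) {
  n <- length(series)
  x <- series - mean(series)
  w <- vapply(0:(n - 1), function(i) 0.54 - 0.46 * cos(2 * pi * i / (n - 1)),
              numeric(1))
  x <- x * w
  ks <- seq_len(n %/% 2)
  power <- vapply(ks, function(k) {
    re <- sum(x * cos(-2 * pi * k * (0:(n - 1)) / n))
    im <- sum(x * sin(-2 * pi * k * (0:(n - 1)) / n))
    (re^2 + im^2) / n
  }, numeric(1))
  if (normalize) power <- power / sum(power)
  power
}

## Hand reverse complement, independent of Biostrings.
oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

## Per-window PWM probability product, looped base by base.
oracle_pwm_scores <- function(seq, prob) {
  ch <- strsplit(seq, "")[[1]]
  W <- ncol(prob)
  vapply(seq_len(length(ch) - W + 1L), function(i) {
    p <- 1
    for (j in seq_len(W)) {
      b <- ch[i + j - 1L]
      if (!b %in% c("A", "C", "G", "T")) return(NA_real_)
      p <- p * prob[b, j]
    }
    p
  }, numeric(1))
}

## Brute-force transitive (single-linkage) clustering of positions.
oracle_cluster_keep <- function(pos, support, cluster_bp = 200) {
  n <- length(pos)
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (abs(pos[i] - pos[j]) <= cluster_bp && grp[i] != grp[j]) {
        grp[grp == max(grp[i], grp[j])] <- min(grp[i], grp[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  vapply(split(seq_len(n), grp), function(ix) {
    ix[order(-support[ix], pos[ix])][1]
  }, integer(1))
}

## Small planted-periodicity cohort used across tests: sequences only need
## to cover the +40..+190 statistic window plus the 9-bp shift slack.
planted_cohort <- function(n = 300, amplitude = 0.25, seed = 1, phase = 0,
                           upstream = 20, downstream = 220, ...) {
  cfg <- synth_config(n_promoters = n, upstream = upstream,
                      downstream = downstream, amplitude = amplitude,
                      phase = phase, seed = seed, ...)
  generate_promoters(cfg)
}

## Toy FASTA on disk; returns the path.
write_toy_fasta <- function(contigs) {
  path <- withr::local_tempfile(fileext = ".fa",
                                .local_envir = parent.frame())
  writeLines(unlist(lapply(names(contigs), function(nm)
    c(paste0(">", nm), contigs[[nm]]))), path)
  path
}

write_toy_tss <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
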