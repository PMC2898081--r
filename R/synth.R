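## Synthetic promoter cohorts with planted structure: an in-phase 10-bp
## RR/YY periodicity of tunable amplitude in a tunable downstream region,
## optional CpG-island composition, planted motif instances,
## nucleosome-boundary tag clouds, and bimodal expression with a tissue-
## specificity gradient. Every generated bundle records its generative truth
## so recovery tests read planted parameters from the bundle, not from
## constants.

#' Synthetic cohort configuration
#'
#' The periodic signal is planted on the purine/pyrimidine track: inside
#' `region` the per-position purine probability is
#' `0.5 + amplitude * cos(2*pi*(i - phase)/period)`, and bases are then
#' drawn within class from `base_freqs`. This controls RR and YY jointly
#' and in counter-phase with a single knob, mirroring the structure of the
#' biological signal. The resulting RR dinucleotide frequency oscillates
#' with period `period` around ~0.25 with amplitude close to
#' `amplitude * cos(pi/period)`.
#'
#' @param n_promoters cohort size (default 1000).
#' @param upstream,downstream extent of each promoter around the TSS
#'   (defaults 1000/1000; the `+1` base sits at offset `upstream`).
#' @param period planted period in bp (default 10).
#' @param amplitude planted amplitude `a` in `[0, 0.5]` (default 0 = no
#'   signal).
#' @param phase offset (mod `period`) at which purine probability peaks
#'   (default 0: peaks at multiples of 10 bp from the TSS, in phase with
#'   it).
#' @param region inclusive TSS-relative interval of planted positions
#'   (default `c(40, 190)`).
#' @param base_freqs background base frequencies (named, default uniform).
#' @param cpg optional list(`fraction`, `window`, `island_gc`,
#'   `island_cpg_rate`, `other_gc`, `depletion`): a `fraction` of promoters
#'   get a CpG-island block (elevated G+C and planted CpG dinucleotides)
#'   over `window`; the rest get CpG-depleted composition there.
#' @param motif optional list(`pwm`, `offset`, `fraction`): plant one motif
#'   instance (sampled from the PWM columns) at `offset` in a `fraction` of
#'   promoters.
#' @param tags optional list(`center`, `jitter`, `n_forward`, `n_reverse`):
#'   nucleosome-boundary tag clouds with forward 5' ends ~
#'   `Normal(center - 73, jitter)` and reverse ~ `Normal(center + 73,
#'   jitter)` per promoter (defaults: center 115 — the midpoint of the
#'   planted region — jitter 20 bp, 5 tags per strand).
#' @param expression optional list(`n_tissues`, `meanlog_low`,
#'   `meanlog_high`, `sdlog`, `weight_low`, `noise_sdlog`,
#'   `spec_fractions`, `spec_boost`, `spec_k`): bimodal log-normal medians
#'   and a 3-level tissue-specificity gradient.
#' @param groups optional data frame(`label`, `fraction`, `amplitude`)
#'   assigning promoters to groups with group-specific planted amplitudes
#'   (overrides `amplitude`).
#' @param seed master seed; all sampling is reproducible from it.
#' @return object of class `SynthConfig`.
#' @export
synth_config <- function(n_promoters = 1000L, upstream = 1000L,
                         downstream = 1000L, period = 10, amplitude = 0,
                         phase = 0, region = c(40L, 190L),
                         base_freqs = c(A = 0.25, C = 0.25,
                                        G = 0.25, T = 0.25),
                         cpg = NULL, motif = NULL, tags = NULL,
                         expression = NULL, groups = NULL, seed = 1L) {
  amps <- if (is.null(groups)) amplitude else groups$amplitude
  if (any(amps < 0 | amps > 0.5))
    stop("amplitude must lie in [0, 0.5] (purine probability in [0, 1])")
  if (!is.null(groups) && abs(sum(groups$fraction) - 1) > 1e-8)
    stop("group fractions must sum to 1")
  stopifnot(length(region) == 2, region[2] >= region[1])
  if (any(amps > 0) && region[1] > downstream - 2)
    stop("planted region lies entirely outside the sequences")
  if (abs(sum(base_freqs) - 1) > 1e-8) stop("base_freqs must sum to 1")
  if (!is.null(cpg))
    cpg <- utils::modifyList(list(fraction = 0.5, window = c(-250L, 250L),
                                  island_gc = 0.62, island_cpg_rate = 0.10,
                                  other_gc = 0.42, depletion = 0.75), cpg)
  if (!is.null(tags))
    tags <- utils::modifyList(list(center = 115, jitter = 20,
                                   n_forward = 5L, n_reverse = 5L), tags)
  if (isTRUE(expression)) expression <- list()
  if (is.list(expression))
    expression <- utils::modifyList(
      list(n_genes = n_promoters, n_tissues = 72L, meanlog_low = 1,
           meanlog_high = 3, sdlog = 0.4, weight_low = 0.42,
           noise_sdlog = 0.1,
           spec_fractions = c(L_S = 0.274, M_S = 0.494, H_S = 0.232),
           spec_boost = c(L_S = 1, M_S = 2, H_S = 50),
           spec_k = c(L_S = 0L, M_S = 10L, H_S = 2L)), expression)
  structure(list(n_promoters = as.integer(n_promoters),
                 upstream = as.integer(upstream),
                 downstream = as.integer(downstream), period = period,
                 amplitude = amplitude, phase = phase,
                 region = as.integer(region), base_freqs = base_freqs,
                 cpg = cpg, motif = motif, tags = tags,
                 expression = expression, groups = groups,
                 seed = as.integer(seed)),
            class = "SynthConfig")
}

## Rows assigned to each group (deterministic blocks in id order).
group_assignment <- function(cfg) {
  n <- cfg$n_promoters
  if (is.null(cfg$groups))
    return(data.frame(row = seq_len(n), label = "all",
                      amplitude = cfg$amplitude))
  sizes <- diff(round(cumsum(c(0, cfg$groups$fraction)) * n))
  data.frame(row = seq_len(n),
             label = rep(cfg$groups$label, times = sizes),
             amplitude = rep(cfg$groups$amplitude, times = sizes))
}

#' Generate a synthetic aligned promoter cohort
#'
#' @param cfg a [synth_config()].
#' @return list with `seqs` (an [aligned_seq_set()]) and `truth` (the
#'   planted parameters and per-promoter labels).
#' @export
generate_promoters <- function(cfg) {
  stopifnot(inherits(cfg, "SynthConfig"))
  with_seed(derive_seed(cfg$seed, 1L), {
    n <- cfg$n_promoters
    L <- cfg$upstream + cfg$downstream
    off <- cfg$upstream
    i_rel <- (0:(L - 1L)) - off
    ga <- group_assignment(cfg)
    in_region <- i_rel >= cfg$region[1] & i_rel <= cfg$region[2]
    wave <- cos(2 * pi * (i_rel - cfg$phase) / cfg$period)
    p_pur <- matrix(0.5, n, L)
    for (amp in unique(ga$amplitude)) {
      if (amp == 0) next
      rows <- ga$row[ga$amplitude == amp]
      p_pur[rows, in_region] <- rep(0.5 + amp * wave[in_region],
                                    each = length(rows))
    }
    pur <- matrix(stats::runif(n * L), n, L) < p_pur
    bf <- cfg$base_freqs
    pA <- bf[["A"]] / (bf[["A"]] + bf[["G"]])
    pC <- bf[["C"]] / (bf[["C"]] + bf[["T"]])
    u <- matrix(stats::runif(n * L), n, L)
    ch <- matrix(ifelse(pur, ifelse(u < pA, "A", "G"),
                        ifelse(u < pC, "C", "T")), n, L)
    is_island <- rep(NA, n)
    if (!is.null(cfg$cpg)) {
      cp <- cfg$cpg
      cols <- which(i_rel >= cp$window[1] & i_rel <= cp$window[2])
      is_island <- seq_len(n) <= round(cp$fraction * n)
      for (i in seq_len(n)) {
        gc <- if (is_island[i]) cp$island_gc else cp$other_gc
        m <- length(cols)
        b <- sample(BASES, m, replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
        if (is_island[i]) {
          ## plant non-overlapping CpG dinucleotides at even offsets
          starts <- cols[seq(1L, m - 1L, by = 2L)]
          sel <- starts[stats::runif(length(starts)) < cp$island_cpg_rate]
          b[match(sel, cols)] <- "C"
          b[match(sel, cols) + 1L] <- "G"
        } else {
          ## CpG depletion: most CG pairs lose the C (methylation mimic)
          cg <- which(b[-m] == "C" & b[-1] == "G")
          hit <- cg[stats::runif(length(cg)) < cp$depletion]
          b[hit] <- "T"
        }
        ch[i, cols] <- b
      }
    }
    motif_rows <- integer(0)
    if (!is.null(cfg$motif)) {
      mo <- cfg$motif
      stopifnot(inherits(mo$pwm, "Pwm"))
      motif_rows <- sort(sample.int(n, round(mo$fraction * n)))
      cols <- off + mo$offset + seq_len(mo$pwm$width)
      for (i in motif_rows)
        ch[i, cols] <- vapply(seq_len(mo$pwm$width), function(j)
          sample(BASES, 1L, prob = mo$pwm$prob[, j]), character(1))
    }
    ids <- sprintf("synth_%05d", seq_len(n))
    seqs <- aligned_seq_set(apply(ch, 1, paste, collapse = ""), off, ids)
    truth <- list(seed = cfg$seed, n_promoters = n, period = cfg$period,
                  phase = cfg$phase, region = cfg$region,
                  amplitude = stats::setNames(ga$amplitude, ids),
                  group = stats::setNames(ga$label, ids),
                  is_island = stats::setNames(is_island, ids),
                  motif_ids = ids[motif_rows],
                  motif_offset = if (is.null(cfg$motif)) NA_integer_
                                 else cfg$motif$offset)
    list(seqs = seqs, truth = truth)
  })
}

#' Generate nucleosome-boundary tag clouds
#'
#' Forward tag 5' ends are drawn from `Normal(center - 73, jitter)` and
#' reverse from `Normal(center + 73, jitter)` (rounded) around each
#' promoter's TSS, emulating the two boundaries of a well-positioned +1
#' nucleosome. Genomic convention matches [write_fixtures()]: one contig
#' per promoter, TSS at `upstream + 1`, plus strand.
#'
#' @param cfg a [synth_config()] with a `tags` component.
#' @return a [tag_set()].
#' @export
generate_tags <- function(cfg) {
  stopifnot(inherits(cfg, "SynthConfig"), !is.null(cfg$tags))
  with_seed(derive_seed(cfg$seed, 2L), {
    tg <- cfg$tags
    n <- cfg$n_promoters
    ids <- sprintf("synth_%05d", seq_len(n))
    tss_pos <- cfg$upstream + 1L
    nf <- tg$n_forward; nr <- tg$n_reverse
    f_off <- round(stats::rnorm(n * nf, tg$center - 73, tg$jitter))
    r_off <- round(stats::rnorm(n * nr, tg$center + 73, tg$jitter))
    chrom <- c(rep(ids, each = nf), rep(ids, each = nr))
    pos <- pmax(tss_pos + c(f_off, r_off), 1L)
    strand <- c(rep("+", n * nf), rep("-", n * nr))
    tag_set(chrom, pos, strand, source = "synthetic nucleosome")
  })
}

#' Generate a synthetic expression matrix with truth labels
#'
#' Per-gene medians are bimodal (two log-normal components); tissue
#' specificity is induced by boosting expression in `k` tissues, with the
#' boost graded over the L_S/M_S/H_S groups (flat profile for L_S, mild
#' 10-tissue boost for M_S, strong 2-tissue boost for H_S), plus
#' multiplicative log-normal noise.
#'
#' @param cfg a [synth_config()] with an `expression` component.
#' @return list with `matrix` (genes x tissues) and `truth` (component and
#'   specificity-group labels).
#' @export
generate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "SynthConfig"), !is.null(cfg$expression))
  with_seed(derive_seed(cfg$seed, 3L), {
    ex <- cfg$expression
    n <- ex$n_genes; nt <- ex$n_tissues
    ids <- sprintf("gene_%05d", seq_len(n))
    comp <- ifelse(stats::runif(n) < ex$weight_low, "L_E", "H_E")
    meanlog <- ifelse(comp == "L_E", ex$meanlog_low, ex$meanlog_high)
    base <- stats::rlnorm(n, meanlog, ex$sdlog)
    sg <- sample(names(ex$spec_fractions), n, replace = TRUE,
                 prob = ex$spec_fractions)
    m <- matrix(rep(base, nt), n, nt)
    for (g in names(ex$spec_k)) {
      k <- min(ex$spec_k[[g]], nt)
      if (k == 0) next
      rows <- which(sg == g)
      for (i in rows) {
        act <- sample.int(nt, k)
        m[i, act] <- m[i, act] * ex$spec_boost[[g]]
      }
    }
    m <- m * matrix(stats::rlnorm(n * nt, 0, ex$noise_sdlog), n, nt)
    dimnames(m) <- list(ids, sprintf("tissue_%02d", seq_len(nt)))
    list(matrix = m,
         truth = list(component = stats::setNames(comp, ids),
                      spec_group = stats::setNames(sg, ids)))
  })
}

#' A synthetic 7-bp activator-like PWM
#'
#' A built-in informative count matrix (consensus `TGACTCA`-like) used as a
#' stand-in for proprietary motif databases in examples and fixtures. It is
#' synthetic: constructed in code, not derived from any curated matrix.
#'
#' @param strength count mass on the consensus base per column (of 100;
#'   default 85).
#' @return a [pwm()].
#' @export
example_pwm <- function(strength = 85) {
  cons <- c("T", "G", "A", "C", "T", "C", "A")
  counts <- matrix((100 - strength) / 3, 4, length(cons),
                   dimnames = list(BASES, NULL))
  for (j in seq_along(cons)) counts[cons[j], j] <- strength
  pwm(counts, id = "synthetic_activator_7bp")
}

#' Write a complete fixture bundle
#'
#' Materializes the synthetic cohort as the plain-text inputs the pipeline
#' consumes: genome FASTA (one contig per promoter, TSS at
#' `upstream + 1` on the plus strand), TSS TSV, tag BED, expression TSV,
#' PWM file and a truth JSON. Re-ingesting the bundle through
#' [read_tss_table()] / [extract_flanks()] reproduces the in-memory
#' sequences exactly.
#'
#' @param cfg a [synth_config()].
#' @param outdir output directory (created if needed).
#' @return invisibly, a named list of written paths plus the in-memory
#'   objects (`seqs`, `truth`).
#' @export
write_fixtures <- function(cfg, outdir) {
  stopifnot(inherits(cfg, "SynthConfig"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  gp <- generate_promoters(cfg)
  paths <- list(genome = file.path(outdir, "genome.fa"),
                tss = file.path(outdir, "tss.tsv"),
                truth = file.path(outdir, "truth.json"))
  dna <- Biostrings::DNAStringSet(gp$seqs$sequences)
  names(dna) <- gp$seqs$source_ids
  Biostrings::writeXStringSet(dna, paths$genome, width = 80L)
  support <- with_seed(derive_seed(cfg$seed, 4L),
                       2L + stats::rpois(cfg$n_promoters, 5))
  tss_df <- data.frame(id = gp$seqs$source_ids, chrom = gp$seqs$source_ids,
                       pos = cfg$upstream + 1L, strand = "+",
                       support = support,
                       gene_id = sub("synth", "gene", gp$seqs$source_ids))
  utils::write.table(tss_df, paths$tss, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(cfg$tags)) {
    tg <- generate_tags(cfg)
    paths$tags <- file.path(outdir, "tags.bed")
    bed <- data.frame(chrom = tg$chrom, start = tg$pos - 1L, end = tg$pos,
                      name = paste0("tag_", seq_len(nrow(tg))), score = 0L,
                      strand = tg$strand)
    utils::write.table(bed, paths$tags, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(cfg$expression)) {
    ge <- generate_expression(cfg)
    paths$expression <- file.path(outdir, "expression.tsv")
    utils::write.table(
      data.frame(gene_id = rownames(ge$matrix), ge$matrix,
                 check.names = FALSE),
      paths$expression, sep = "\t", quote = FALSE, row.names = FALSE)
    gp$truth$expression <- ge$truth
  }
  pw <- if (!is.null(cfg$motif)) cfg$motif$pwm else example_pwm()
  paths$pwm <- file.path(outdir, "pwm.txt")
  write_pwm(pw, paths$pwm)
  jsonlite::write_json(
    lapply(gp$truth, function(v) if (is.null(names(v))) v else as.list(v)),
    paths$truth, auto_unbox = TRUE, digits = NA, null = "null",
    na = "null", pretty = TRUE)
  invisible(c(paths, list(seqs = gp$seqs, truth = gp$truth)))
}
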