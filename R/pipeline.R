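## End-to-end orchestration: ingest -> profiles -> periodicity statistic ->
## shift null -> stratifications -> machine-readable summary. Every
## stochastic stage derives its own seed from the single run seed, so
## stages are independently reproducible and a full run is deterministic.

#' Build a pipeline run configuration
#'
#' @param genome,tss paths to the genome FASTA and TSS TSV (required).
#' @param tags,expression,pwm optional paths to a tag BED, an expression
#'   TSV and a TRANSFAC-style PWM file; the corresponding stages run only
#'   when provided.
#' @param outdir output directory.
#' @param seed master seed for all stochastic stages.
#' @param upstream,downstream promoter window (defaults 1000/1000).
#' @param min_support,cluster_bp TSS filters (defaults 2 and 200).
#' @param cls dinucleotide class of the statistic (default `"RR"`).
#' @param region_start,series_len,smooth statistic window (defaults 40, 150,
#'   3).
#' @param shift_iters shift-null iterations (default 500).
#' @param boot_sample_size,boot_n bootstrap parameters for group comparisons
#'   (defaults 500 and 2000).
#' @param cpg_window CpG feature window (default `c(-500, 499)`).
#' @param scan_region,match_region,n_shuffles PWM scan parameters.
#' @param tag_region region for per-TSS tag counts (default `c(40, 200)`).
#' @param tag_quantiles number of tag-enrichment groups (default 4).
#' @return object of class `RunConfig`.
#' @export
run_config <- function(genome, tss, tags = NULL, expression = NULL,
                       pwm = NULL, outdir = "rotasig_run", seed = 1L,
                       upstream = 1000L, downstream = 1000L,
                       min_support = 2L, cluster_bp = 200L, cls = "RR",
                       region_start = 40L, series_len = 150L, smooth = 3L,
                       shift_iters = 500L, boot_sample_size = 500L,
                       boot_n = 2000L, cpg_window = c(-500L, 499L),
                       scan_region = c(-500L, 500L),
                       match_region = c(0L, 40L), n_shuffles = 100L,
                       tag_region = c(40L, 200L), tag_quantiles = 4L) {
  cfg <- as.list(environment())
  class(cfg) <- "RunConfig"
  cfg
}

log_line <- function(con, ...) writeLines(paste0(...), con)

#' Run the full analysis pipeline
#'
#' Stages: (1) TSS ingestion, quality filtering and promoter extraction;
#' (2) RR/YY composition profiles; (3) periodogram and 10-bp magnitude;
#' (4) shift-randomization null and its p-value; (5) CpG-island mixture
#' classification; (6, optional) PWM match calling with column-shuffle
#' control; (7, optional) tag density profiles, per-TSS counts, quantile
#' groups and the group-periodicity trend; (8, optional) median-expression
#' and tissue-specificity partitions with bootstrap group comparisons.
#' Outputs are TSVs plus a `summary.json`; a `run.log` records each stage,
#' its parameters and its derived seed (no timestamps, so reruns are
#' byte-identical).
#'
#' @param cfg a [run_config()].
#' @return the summary list, invisibly; written to
#'   `file.path(cfg$outdir, "summary.json")`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(cfg$outdir, "run.log"), "w")
  on.exit(close(logf))
  summary <- list(seed = cfg$seed)
  stage <- function(name, expr) {
    ok <- try(force(expr), silent = TRUE)
    if (inherits(ok, "try-error"))
      stop("pipeline stage '", name, "' failed: ",
           attr(ok, "condition")$message, call. = FALSE)
    ok
  }
  wtsv <- function(df, name) {
    utils::write.table(df, file.path(cfg$outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  ## 1. ingest
  log_line(logf, "stage=ingest genome=", cfg$genome, " tss=", cfg$tss,
           " min_support=", cfg$min_support, " cluster_bp=", cfg$cluster_bp)
  seqs <- stage("ingest", {
    raw <- read_tss_table(cfg$tss)
    kept <- filter_tss(raw, cfg$min_support, cfg$cluster_bp)
    summary$n_tss_raw <- nrow(raw)
    summary$n_tss <- nrow(kept)
    extract_flanks(kept, cfg$genome, cfg$upstream, cfg$downstream)
  })

  ## 2. profiles
  log_line(logf, "stage=profiles cls=RR,YY smooth=", cfg$smooth)
  stage("profiles", {
    rr <- dinucleotide_class_profile(seqs, "RR")
    yy <- dinucleotide_class_profile(seqs, "YY")
    df <- as.data.frame(window_profile(rr, -cfg$upstream,
                                       cfg$downstream - 2L))
    df$value_yy <- yy$values
    df$value_rr_smoothed <- smooth_profile(rr, cfg$smooth)$values
    wtsv(df, "profiles.tsv")
  })

  ## 3. spectral statistic
  log_line(logf, "stage=spectral region_start=", cfg$region_start,
           " series_len=", cfg$series_len, " smooth=", cfg$smooth)
  stat <- stage("spectral", {
    st <- periodicity_stat(seqs, cfg$cls, cfg$region_start, cfg$series_len,
                           cfg$smooth)
    wtsv(as.data.frame(st$periodogram), "psd.tsv")
    summary$magnitude10 <- st$magnitude10
    summary$period_bin <- st$period_bin
    st
  })

  ## 4. shift null
  sd4 <- derive_seed(cfg$seed, 41L)
  log_line(logf, "stage=shift_null n_iter=", cfg$shift_iters, " seed=", sd4)
  stage("shift_null", {
    nd <- shift_null(seqs, cfg$cls, n_iter = cfg$shift_iters, seed = sd4,
                     region_start = cfg$region_start,
                     series_len = cfg$series_len, smooth = cfg$smooth)
    wtsv(data.frame(iteration = seq_along(nd$values),
                    magnitude10 = nd$values), "shift_null.tsv")
    summary$shift_null_mean <- mean(nd$values)
    summary$shift_null_p <- empirical_p(stat$magnitude10, nd)
    nd
  })

  ## 5. CpG classification
  log_line(logf, "stage=cpg window=", cfg$cpg_window[1], ":",
           cfg$cpg_window[2])
  stage("cpg", {
    feats <- cpg_features(seqs, cfg$cpg_window)
    if (nrow(feats) >= 100) {
      fit <- fit_cpg_gmm(feats)
      cl <- classify_cpg(fit, feats, override = TRUE)
      wtsv(cbind(feats[c("tss_id", "cpg_oe", "gc_frac")],
                 cl[c("cpg_island", "posterior")]), "cpg.tsv")
      summary$cpg <- list(n_island = sum(cl$cpg_island),
                          n_other = sum(!cl$cpg_island),
                          fraction_island = mean(cl$cpg_island),
                          means = fit$means, degenerate = fit$degenerate)
    } else {
      wtsv(feats, "cpg.tsv")
      summary$cpg <- list(note = "too few promoters for the mixture fit",
                          n = nrow(feats))
    }
  })

  ## 6. motif scan (optional)
  if (!is.null(cfg$pwm)) {
    sd6 <- derive_seed(cfg$seed, 61L)
    log_line(logf, "stage=motif pwm=", cfg$pwm, " shuffles=",
             cfg$n_shuffles, " seed=", sd6)
    stage("motif", {
      pw <- read_pwm(cfg$pwm)
      mm <- call_matches(seqs, pw, cfg$scan_region, cfg$match_region)
      wtsv(mm, "motif_matches.tsv")
      ctrl <- column_shuffle_control(seqs, pw, cfg$n_shuffles, seed = sd6,
                                     scan_region = cfg$scan_region,
                                     match_region = cfg$match_region)
      summary$motif <- list(n_unique_match = nrow(mm),
                             shuffle_max = max(ctrl$values),
                             p_value = ctrl$params$p_value)
    })
  }

  ## 7. tag profiles and intensity-periodicity trend (optional)
  if (!is.null(cfg$tags)) {
    sd7 <- derive_seed(cfg$seed, 71L)
    log_line(logf, "stage=tags region=", cfg$tag_region[1], ":",
             cfg$tag_region[2], " q=", cfg$tag_quantiles, " seed=", sd7)
    stage("tags", {
      tgs <- read_tags_bed(cfg$tags)
      kept <- filter_tss(read_tss_table(cfg$tss), cfg$min_support,
                         cfg$cluster_bp)
      fwd <- tag_density_profile(tgs, kept, strand = "forward")
      rev <- tag_density_profile(tgs, kept, strand = "reverse")
      df <- as.data.frame(fwd)
      df$value_reverse <- rev$values
      wtsv(df, "tag_density.tsv")
      counts <- region_tag_counts(tgs, kept, cfg$tag_region)
      qp <- quantile_partition(counts, cfg$tag_quantiles)
      wtsv(qp, "tag_groups.tsv")
      min_n <- min(table(qp$group))
      if (min_n >= 100) {
        pg <- periodicity_by_group(seqs, qp, cfg$boot_sample_size,
                                   cfg$boot_n, cfg$cls, seed = sd7)
        summary$tags <- list(trend_r = pg$trend$estimate,
                              trend_p = pg$trend$p_value,
                              pairwise_p = as.list(pg$pairwise),
                              group_magnitude = as.list(pg$group_magnitude))
      } else {
        summary$tags <- list(note = "groups too small for bootstrap",
                              min_group_size = min_n)
      }
    })
  }

  ## 8. expression partitions (optional)
  if (!is.null(cfg$expression)) {
    sd8 <- derive_seed(cfg$seed, 81L)
    log_line(logf, "stage=expression seed=", sd8)
    stage("expression", {
      m <- read_expression_matrix(cfg$expression)
      if (nrow(m) < 200) {
        summary$expression <- list(note = "too few genes for the mixture fit",
                                   n = nrow(m))
      } else {
      mp <- median_expression_partition(m)
      tau <- tissue_specificity(m)
      sp <- specificity_partition(tau)
      wtsv(data.frame(gene_id = rownames(m), median = mp$medians,
                      expression_class = as.character(mp$labels),
                      tau = tau[rownames(m)],
                      spec_label = sp$label[match(rownames(m), sp$gene_id)]),
           "expression_groups.tsv")
      summary$expression <- list(
        n_low = sum(mp$labels == "L_E"), n_high = sum(mp$labels == "H_E"),
        gmm_means = mp$fit$means, degenerate = mp$fit$degenerate,
        spec_sizes = as.list(table(sp$label)))
      }
    })
  }

  summary_path <- file.path(cfg$outdir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log_line(logf, "stage=done summary=", basename(summary_path))
  invisible(summary)
}

#' Render a run summary as human-readable text
#'
#' @param summary the list returned by [run_pipeline()], or the path of a
#'   `summary.json`.
#' @param file where to print (default stdout).
#' @return the rendered lines, invisibly.
#' @export
report <- function(summary, file = stdout()) {
  if (is.character(summary)) summary <- jsonlite::read_json(summary)
  ln <- c(
    "== rotasig run summary ==",
    sprintf("TSSs: %s raw, %s after support/cluster filters",
            summary$n_tss_raw, summary$n_tss),
    sprintf("10-bp %smagnitude: %.4g (exact bin period %.4g bp)",
            "", as.numeric(summary$magnitude10),
            as.numeric(summary$period_bin)),
    sprintf("shift null: mean %.4g, p = %.3g",
            as.numeric(summary$shift_null_mean),
            as.numeric(summary$shift_null_p)))
  if (!is.null(summary$cpg$n_island))
    ln <- c(ln, sprintf(
      "CpG islands: %s of %s promoters (%.1f%%)%s",
      summary$cpg$n_island,
      as.numeric(summary$cpg$n_island) + as.numeric(summary$cpg$n_other),
      100 * as.numeric(summary$cpg$fraction_island),
      if (isTRUE(summary$cpg$degenerate)) " [degenerate fit]" else ""))
  if (!is.null(summary$motif))
    ln <- c(ln, sprintf(
      "motif: %s promoters with a unique match (shuffle max %s, p = %.3g)",
      summary$motif$n_unique_match, summary$motif$shuffle_max,
      as.numeric(summary$motif$p_value)))
  if (!is.null(summary$tags)) {
    if (!is.null(summary$tags$trend_r))
      ln <- c(ln, sprintf(
        "tag groups: intensity-periodicity trend r = %.3f (p = %.3g)",
        as.numeric(summary$tags$trend_r), as.numeric(summary$tags$trend_p)))
    else ln <- c(ln, paste0("tag groups: n=",
                            summary$tags$min_group_size %||% 0,
                            " (too small for bootstrap)"))
  }
  if (!is.null(summary$expression$n_low))
    ln <- c(ln, sprintf(
      "expression: %s low / %s high by median; specificity groups %s",
      summary$expression$n_low, summary$expression$n_high,
      paste(names(summary$expression$spec_sizes),
            unlist(summary$expression$spec_sizes),
            sep = "=", collapse = ", ")))
  writeLines(ln, con = file)
  invisible(ln)
}
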