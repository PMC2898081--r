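## Mapped-tag summaries around TSSs and the link between mark intensity and
## the periodicity statistic. Tags are 5' positions of sequenced reads:
## forward/reverse tag 5' ends mark the two boundaries of
## nucleosome-protected DNA.

#' Construct a tag set
#'
#' @param chrom,pos,strand per-tag fields; `pos` is the 1-based genomic
#'   coordinate of the tag 5' end.
#' @param source label of the experiment (e.g. `"nucleosome"`,
#'   `"H3K18ac"`).
#' @return object of class `TagSet` (a data frame).
#' @export
tag_set <- function(chrom, pos, strand, source = "tags") {
  if (length(pos) && any(pos < 1)) stop("positions must be >= 1")
  if (length(strand) && !all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  x <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                  strand = as.character(strand), stringsAsFactors = FALSE)
  attr(x, "source") <- source
  class(x) <- c("TagSet", "data.frame")
  x
}

#' Read tag 5' positions from a BED6 file
#'
#' Converts 0-based half-open intervals: the 5' end is `start + 1` on the
#' plus strand and `end` on the minus strand.
#'
#' @param path BED6 file.
#' @param source label stored on the set.
#' @return a [tag_set()].
#' @export
read_tags_bed <- function(path, source = basename(path)) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          colClasses = "character", comment.char = "#",
                          quote = "")
  if (ncol(df) < 6) stop("BED6 requires 6 columns")
  strand <- df[[6]]
  pos <- ifelse(strand == "+", as.integer(df[[2]]) + 1L, as.integer(df[[3]]))
  tag_set(df[[1]], pos, strand, source = source)
}

## Transcription-oriented offsets of tags relative to each TSS: for a
## minus-strand TSS offsets mirror and tag strands swap. Returns a data
## frame (tss_index, offset, rel_strand).
tags_relative_to_tss <- function(tags, tss, window) {
  by_chrom <- split(seq_len(nrow(tags)), tags$chrom)
  out <- vector("list", nrow(tss))
  for (i in seq_len(nrow(tss))) {
    ix <- by_chrom[[tss$chrom[i]]]
    if (is.null(ix)) next
    if (tss$strand[i] == "+") {
      off <- tags$pos[ix] - tss$pos[i]
      rel <- tags$strand[ix]
    } else {
      off <- tss$pos[i] - tags$pos[ix]
      rel <- ifelse(tags$strand[ix] == "+", "-", "+")
    }
    keep <- off >= window[1] & off <= window[2]
    if (!any(keep)) next
    out[[i]] <- data.frame(tss_index = i, offset = off[keep],
                           rel_strand = rel[keep])
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(tss_index = integer(), offset = integer(),
                      rel_strand = character()))
  do.call(rbind, out)
}

#' Strand-separated tag density profile around TSSs
#'
#' Counts tag 5' ends at each transcription-oriented offset (forward and
#' reverse tags mark the 5' and 3' nucleosome boundaries respectively, with
#' strands swapped and offsets mirrored for minus-strand TSSs), averages per
#' TSS, and smooths with a sliding window.
#'
#' @param tags a [tag_set()].
#' @param tss a [tss_set()].
#' @param window inclusive TSS-relative offset interval (default
#'   `c(-1000, 1000)`).
#' @param strand `"forward"` or `"reverse"` (transcription-oriented).
#' @param smooth_bp sliding window width in bp (default 70; the window
#'   shrinks at the profile edges).
#' @param per_tss average counts over the number of TSSs (default) rather
#'   than reporting pooled raw counts.
#' @return a `PositionProfile` of mean smoothed tag density.
#' @export
tag_density_profile <- function(tags, tss, window = c(-1000L, 1000L),
                                strand = c("forward", "reverse"),
                                smooth_bp = 70L, per_tss = TRUE) {
  strand <- match.arg(strand)
  if (smooth_bp < 1) stop("smooth_bp must be >= 1")
  rel <- tags_relative_to_tss(tags, tss, window)
  want <- if (strand == "forward") "+" else "-"
  rel <- rel[rel$rel_strand == want, , drop = FALSE]
  offs <- window[1]:window[2]
  counts <- tabulate(rel$offset - window[1] + 1L, length(offs))
  vals <- if (per_tss) counts / nrow(tss) else counts
  new_position_profile(run_mean(vals, smooth_bp), offs,
                       paste0(attr(tags, "source") %||% "tags", " (",
                              strand, ")"),
                       rep(nrow(tss), length(offs)), smoothed = smooth_bp > 1)
}

#' Per-TSS tag counts in a downstream region
#'
#' Number of tag 5' ends with transcription-oriented offsets inside the
#' closed region (both strands by default) — the enrichment score used for
#' quantile stratification.
#'
#' @param tags a [tag_set()].
#' @param tss a [tss_set()].
#' @param region inclusive offset interval (default `c(40, 200)`, over the
#'   +1 nucleosome).
#' @param strand `"both"` (default), `"forward"` or `"reverse"`.
#' @return data frame (`tss_id`, `score`) — an enrichment table.
#' @export
region_tag_counts <- function(tags, tss, region = c(40L, 200L),
                              strand = c("both", "forward", "reverse")) {
  strand <- match.arg(strand)
  rel <- tags_relative_to_tss(tags, tss, region)
  if (strand != "both") {
    want <- if (strand == "forward") "+" else "-"
    rel <- rel[rel$rel_strand == want, , drop = FALSE]
  }
  counts <- tabulate(rel$tss_index, nrow(tss))
  data.frame(tss_id = tss$id, score = counts)
}

#' Partition scores into quantile groups
#'
#' Ranks ids by score (ties broken by stable id order) and cuts the ranking
#' into `q` groups of near-equal size; when `n` is not divisible by `q` the
#' lower-score groups take the extra members, so group sizes differ by at
#' most 1. Group 1 holds the lowest scores.
#'
#' @param scores data frame (`tss_id`, `score`) as from
#'   [region_tag_counts()], or a named numeric vector.
#' @param q number of groups (>= 2).
#' @return data frame (`tss_id`, `score`, `group`).
#' @export
quantile_partition <- function(scores, q = 4L) {
  if (!is.data.frame(scores))
    scores <- data.frame(tss_id = names(scores), score = as.numeric(scores))
  n <- nrow(scores)
  if (q < 2) stop("q must be >= 2")
  if (n < q) stop("fewer observations than groups")
  o <- order(scores$score, scores$tss_id)
  base <- n %/% q; extra <- n %% q
  sizes <- rep(base, q) + c(rep(1L, extra), rep(0L, q - extra))
  grp <- integer(n)
  grp[o] <- rep(seq_len(q), times = sizes)
  data.frame(tss_id = scores$tss_id, score = scores$score, group = grp)
}

#' Per-group bootstrap periodicity and its trend with group intensity
#'
#' For each score group, draws the bootstrap distribution of the 10-bp
#' magnitude ([bootstrap_magnitudes()]); tests the intensity-periodicity
#' trend by Pearson correlation between each bootstrap replicate's group
#' score (the group mean score, or the group rank when no scores are given)
#' and its magnitude; and reports one-sided pairwise rank-sum comparisons of
#' consecutive groups.
#'
#' @param seqs an [aligned_seq_set()].
#' @param groups data frame (`tss_id`, `group`) as from
#'   [quantile_partition()], covering ids of `seqs`; each group must have at
#'   least 100 sequences.
#' @param sample_size,n_boot,cls,seed,... passed to
#'   [bootstrap_magnitudes()] (per-group seeds are derived from `seed`).
#' @return list with `distributions` (named list of `NullDistribution`s),
#'   `group_magnitude` (full-group point statistics), `trend` (Pearson
#'   estimate and p-value), `pairwise` (one-sided rank-sum p-values, lower
#'   vs next group).
#' @export
periodicity_by_group <- function(seqs, groups, sample_size = 500L,
                                 n_boot = 2000L, cls = "RR", seed = 1L, ...) {
  gl <- sort(unique(groups$group))
  if (length(gl) < 2) stop("need at least 2 groups")
  idx <- split(match(groups$tss_id, seqs$source_ids), groups$group)
  for (g in names(idx)) {
    if (anyNA(idx[[g]])) stop("group ", g, " contains unknown ids")
    if (length(idx[[g]]) < 100)
      stop("group ", g, " has fewer than 100 sequences (",
           length(idx[[g]]), ")")
  }
  has_score <- !is.null(groups$score)
  gscore <- if (has_score)
    vapply(split(groups$score, groups$group), mean, numeric(1))
  else stats::setNames(as.numeric(seq_along(gl)), as.character(gl))
  dists <- list(); gmag <- numeric(0)
  for (j in seq_along(gl)) {
    g <- as.character(gl[j])
    sub <- aligned_seq_set(seqs$sequences[idx[[g]]], seqs$offset_of_tss,
                           seqs$source_ids[idx[[g]]])
    dists[[g]] <- bootstrap_magnitudes(sub, sample_size = sample_size,
                                       n_boot = n_boot, cls = cls,
                                       seed = derive_seed(seed, j), ...)
    gmag[g] <- periodicity_stat(sub, cls = cls)$magnitude10
  }
  xs <- rep(gscore[names(dists)], each = n_boot)
  ys <- unlist(lapply(dists, `[[`, "values"), use.names = FALSE)
  tr <- stats::cor.test(xs, ys, method = "pearson")
  pw <- vapply(seq_len(length(gl) - 1L), function(j) {
    compare_groups(dists[[j]], dists[[j + 1L]], alternative = "less")
  }, numeric(1))
  names(pw) <- paste(gl[-length(gl)], gl[-1], sep = "<")
  list(distributions = dists, group_magnitude = gmag,
       trend = list(estimate = unname(tr$estimate), p_value = tr$p.value),
       pairwise = pw)
}
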