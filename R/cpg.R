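## CpG-island stratification of promoters: a CpG observed/expected feature
## over a TSS-centered window, partitioned model-wise by the 2-component
## Gaussian mixture rather than by ad hoc length/frequency thresholds.

#' CpG enrichment feature of a sequence window
#'
#' `cpg_oe` is the observed/expected CpG ratio
#' `(#CG dinucleotides * L) / (#C * #G)` with `L` the number of non-N bases
#' (0 when the window has no C or no G); `gc_frac` is `(#C + #G) / L`.
#'
#' @param window a sequence string of length >= 200 with non-N fraction
#'   >= 0.5.
#' @param tss_id optional id carried through.
#' @return list with `tss_id`, `cpg_oe`, `gc_frac`.
#' @export
cpg_feature <- function(window, tss_id = NA_character_) {
  ch <- strsplit(toupper(window), "", fixed = TRUE)[[1]]
  if (length(ch) < 200) stop("window must be at least 200 bp")
  ok <- ch %in% BASES
  L <- sum(ok)
  if (L == 0) stop("all-N window")
  if (L < length(ch) / 2) stop("non-N fraction below 0.5")
  nC <- sum(ch == "C"); nG <- sum(ch == "G")
  nCG <- sum(ch[-length(ch)] == "C" & ch[-1] == "G")
  list(tss_id = tss_id,
       cpg_oe = if (nC * nG == 0) 0 else nCG * L / (nC * nG),
       gc_frac = (nC + nG) / L)
}

#' CpG features for every promoter of an aligned set
#'
#' @param seqs an [aligned_seq_set()].
#' @param window inclusive TSS-relative offset interval (default
#'   `c(-500, 499)`, the 1000-bp window centered on the TSS; in skip-zero
#'   display coordinates this is -500..+500).
#' @return data frame with one row per promoter (`tss_id`, `cpg_oe`,
#'   `gc_frac`).
#' @export
cpg_features <- function(seqs, window = c(-500L, 499L)) {
  lo <- offset_col(seqs, window[1]); hi <- offset_col(seqs, window[2])
  if (lo < 1 || hi > seq_width(seqs)) stop("window outside the sequences")
  rows <- lapply(seq_along(seqs$sequences), function(i)
    cpg_feature(substr(seqs$sequences[i], lo, hi), seqs$source_ids[i]))
  data.frame(tss_id = vapply(rows, `[[`, character(1), "tss_id"),
             cpg_oe = vapply(rows, `[[`, numeric(1), "cpg_oe"),
             gc_frac = vapply(rows, `[[`, numeric(1), "gc_frac"))
}

#' Fit the CpG-island mixture
#'
#' Two-component Gaussian mixture on the `cpg_oe` feature; see [fit_gmm2()].
#'
#' @param features numeric vector of `cpg_oe` values (or the data frame from
#'   [cpg_features()]).
#' @param ... passed to [fit_gmm2()].
#' @return a `GmmFit`.
#' @export
fit_cpg_gmm <- function(features, ...) {
  x <- if (is.data.frame(features)) features$cpg_oe else features
  fit_gmm2(x, ...)
}

#' Classify promoters as CpG-island-associated
#'
#' The high-mean component of the mixture is the CpG-island class.
#'
#' @param fit a [fit_cpg_gmm()] result.
#' @param features as in [fit_cpg_gmm()].
#' @param override classify from a flagged fit anyway.
#' @return data frame with `cpg_island` (logical) and `posterior` of the
#'   assigned class (plus `tss_id` when available).
#' @export
classify_cpg <- function(fit, features, override = FALSE) {
  x <- if (is.data.frame(features)) features$cpg_oe else features
  cl <- classify_gmm2(fit, x, override = override)
  out <- data.frame(cpg_island = cl$component == 2L,
                    posterior = cl$posterior)
  if (is.data.frame(features) && !is.null(features$tss_id))
    out <- cbind(tss_id = features$tss_id, out)
  out
}
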