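## PWM promoter scanning: sliding local-probability score over a
## TSS-centered region, match calling against the regional mean, and a
## column-shuffle specificity control.

#' Construct a position weight matrix
#'
#' @param counts 4 x W numeric matrix (rows A, C, G, T) of base counts or
#'   probabilities per motif column.
#' @param pseudocount added to every cell before column normalization
#'   (default 0.01). With `pseudocount = 0` a zero count stays probability 0
#'   (a warning notes the hard zero).
#' @param id matrix identifier.
#' @return object of class `Pwm` with `counts`, `prob` (columns summing to
#'   1), `width`, `pseudocount`, `id`.
#' @export
pwm <- function(counts, pseudocount = 0.01, id = "pwm") {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop("counts must have 4 rows (A, C, G, T)")
  if (ncol(counts) < 2) stop("motif width must be >= 2")
  if (any(counts < 0)) stop("negative counts")
  rownames(counts) <- BASES
  p <- counts + pseudocount
  cs <- colSums(p)
  if (any(cs == 0)) stop("all-zero column")
  p <- sweep(p, 2, cs, "/")
  if (pseudocount == 0 && any(counts == 0))
    warning("pseudocount 0 with zero counts: hard-zero probabilities retained")
  structure(list(counts = counts, prob = p, width = ncol(counts),
                 pseudocount = pseudocount, id = id),
            class = "Pwm")
}

#' Read a TRANSFAC-style PWM count block
#'
#' Expects a block with a `P0` (or `PO`) header giving the base order and
#' one numbered row per motif position; `ID`/`NA`/`DE` lines and a trailing
#' consensus column are tolerated, `//` ends the block.
#'
#' @param path file to read.
#' @param pseudocount passed to [pwm()].
#' @return a [pwm()].
#' @export
read_pwm <- function(path, pseudocount = 0.01) {
  lines <- readLines(path, warn = FALSE)
  id <- "pwm"
  idl <- grep("^ID\\s+", lines, value = TRUE)
  if (length(idl)) id <- sub("^ID\\s+", "", idl[1])
  hdr <- grep("^P[O0]\\b", lines)
  if (!length(hdr)) stop("no P0 header line found")
  order_bases <- strsplit(trimws(sub("^P[O0]\\s*", "", lines[hdr[1]])),
                          "\\s+")[[1]]
  if (!setequal(order_bases, BASES))
    stop("P0 header must name A, C, G and T")
  rows <- list()
  for (ln in lines[-seq_len(hdr[1])]) {
    if (grepl("^//", ln)) break
    if (!grepl("^\\s*[0-9]+\\s", ln)) next
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(tok[2:5]))
    if (anyNA(vals)) stop("ragged or non-numeric matrix row: ", ln)
    rows[[length(rows) + 1L]] <- vals
  }
  if (!length(rows)) stop("no matrix rows found")
  m <- do.call(cbind, rows)  # 4 x W in file base order
  m <- m[match(BASES, order_bases), , drop = FALSE]
  pwm(m, pseudocount = pseudocount, id = id)
}

#' Write a PWM as a TRANSFAC-style count block
#'
#' @param x a [pwm()].
#' @param path output file.
#' @export
write_pwm <- function(x, path) {
  stopifnot(inherits(x, "Pwm"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ID", x$id), "P0      A      C      G      T"), con)
  for (j in seq_len(x$width))
    writeLines(sprintf("%02d %6g %6g %6g %6g", j, x$counts[1, j],
                       x$counts[2, j], x$counts[3, j], x$counts[4, j]), con)
  writeLines("//", con)
  invisible(path)
}

#' @export
print.Pwm <- function(x, ...) {
  cons <- paste(BASES[apply(x$prob, 2, which.max)], collapse = "")
  cat("Pwm [", x$id, "]: width ", x$width, ", pseudocount ", x$pseudocount,
      ", consensus ", cons, "\n", sep = "")
  invisible(x)
}

## Per-promoter score matrix over every start offset of the scan region.
## Returns list(scores = N x n_offsets matrix, offsets, regional_mean).
scan_scores <- function(seqs, pw, scan_region = c(-500L, 500L)) {
  stopifnot(inherits(pw, "Pwm"))
  W <- pw$width
  starts <- scan_region[1]:(scan_region[2] - W + 1L)
  if (length(starts) < 1) stop("scan region shorter than the motif")
  lo <- offset_col(seqs, scan_region[1])
  hi <- offset_col(seqs, scan_region[2])
  if (lo < 1 || hi > seq_width(seqs)) stop("scan region outside the sequences")
  code <- seq_code_matrix(seqs)[, lo:hi, drop = FALSE]
  ns <- length(starts)
  lp <- log(pw$prob)
  S <- matrix(0, nrow(code), ns)
  for (j in seq_len(W)) {
    sub <- code[, j:(j + ns - 1L), drop = FALSE]
    S <- S + matrix(lp[, j][sub], nrow(code))  # NA (N base) propagates
  }
  scores <- exp(S)
  list(scores = scores, offsets = starts,
       regional_mean = rowMeans(scores, na.rm = TRUE))
}

#' Sliding local-probability scan of one promoter window
#'
#' At each start offset the score is the product of the per-column base
#' probabilities of the motif under the window (undefined over N bases).
#' The regional mean of the defined scores is the match threshold used by
#' [call_matches()].
#'
#' @param seq a sequence string covering the scan region.
#' @param pw a [pwm()].
#' @param offset_of_tss 0-based index of the `+1` base within `seq`; the
#'   returned offsets are TSS-relative. Default 0 treats the string start as
#'   the TSS.
#' @return object of class `PwmScores`: `values`, `offsets`,
#'   `regional_mean`.
#' @export
scan_local_probability <- function(seq, pw, offset_of_tss = 0L) {
  s1 <- aligned_seq_set(seq, offset_of_tss)
  L <- nchar(seq)
  res <- scan_scores(s1, pw,
                     scan_region = c(-offset_of_tss, L - 1L - offset_of_tss))
  structure(list(values = res$scores[1, ], offsets = res$offsets,
                 regional_mean = res$regional_mean[1]),
            class = "PwmScores")
}

#' Call PWM matches in a TSS-proximal region
#'
#' Scores every promoter over `scan_region`, then reports start offsets
#' inside `match_region` whose local probability exceeds the promoter's own
#' regional mean. With `require_unique = TRUE` (the default) a promoter is
#' reported only when exactly one such offset exists in the match region.
#'
#' @param seqs an [aligned_seq_set()] covering `scan_region`.
#' @param pw a [pwm()].
#' @param scan_region inclusive TSS-relative base interval over which the
#'   sliding score and its regional mean are computed (default
#'   `c(-500, 500)`).
#' @param match_region inclusive interval of eligible match start offsets
#'   (default `c(0, 40)`, the region immediately downstream of the TSS).
#' @param require_unique report only promoters with a single eligible match.
#' @return data frame of matches: `tss_id`, `offset`, `local_prob`,
#'   `regional_mean`, `unique_in_window`.
#' @export
call_matches <- function(seqs, pw, scan_region = c(-500L, 500L),
                         match_region = c(0L, 40L), require_unique = TRUE) {
  res <- scan_scores(seqs, pw, scan_region)
  sel <- res$offsets >= match_region[1] & res$offsets <= match_region[2]
  if (!any(sel)) stop("match region contains no scan offsets")
  out <- vector("list", nrow(res$scores))
  for (i in seq_len(nrow(res$scores))) {
    sc <- res$scores[i, sel]
    hits <- which(!is.na(sc) & sc > res$regional_mean[i])
    uniq <- length(hits) == 1L
    if (require_unique && !uniq) next
    if (!length(hits)) next
    out[[i]] <- data.frame(tss_id = seqs$source_ids[i],
                           offset = res$offsets[sel][hits],
                           local_prob = sc[hits],
                           regional_mean = res$regional_mean[i],
                           unique_in_window = uniq)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(tss_id = character(), offset = integer(),
                      local_prob = numeric(), regional_mean = numeric(),
                      unique_in_window = logical()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Column-shuffle specificity control for a PWM scan
#'
#' Permutes the motif's column order, re-runs the match calling over all
#' promoters, and records the total reported match count per shuffle. A
#' compositional (position-independent) bias in the region produces similar
#' counts under shuffling; a specific motif does not.
#'
#' @inheritParams call_matches
#' @param n_shuffles number of column permutations (default 100).
#' @param seed RNG seed.
#' @return a `NullDistribution` of kind `"permutation"` whose `params` carry
#'   the observed count and its empirical p-value.
#' @export
column_shuffle_control <- function(seqs, pw, n_shuffles = 100L, seed = 1L,
                                   scan_region = c(-500L, 500L),
                                   match_region = c(0L, 40L),
                                   require_unique = TRUE) {
  if (pw$width < 3) stop("motif too short to shuffle")
  obs <- nrow(call_matches(seqs, pw, scan_region, match_region,
                           require_unique))
  counts <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      ## the control must perturb the matrix: redraw permutations that
      ## reproduce the original column content exactly (identity, or swaps
      ## of identical columns). A column-constant matrix admits no such
      ## perturbation; after 100 attempts the draw stands.
      attempt <- 0L
      repeat {
        perm <- sample.int(pw$width)
        attempt <- attempt + 1L
        if (!identical(pw$prob[, perm, drop = FALSE], pw$prob) ||
            attempt >= 100L) break
      }
      shuf <- pwm(pw$counts[, perm, drop = FALSE],
                  pseudocount = pw$pseudocount,
                  id = paste0(pw$id, "_shuffle"))
      nrow(call_matches(seqs, shuf, scan_region, match_region,
                        require_unique))
    }, numeric(1))
  })
  new_null_distribution(counts, "permutation", seed,
                        list(observed = obs,
                             p_value = (sum(counts >= obs) + 1) /
                               (n_shuffles + 1)))
}
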