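## Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

## The 16 dinucleotides in row-major (first base fast over second) code order:
## code = (first-1)*4 + second with A=1,C=2,G=3,T=4.
DINUCS <- as.vector(outer(BASES, BASES, paste0))  # "AA","CA","GA","TA","AC",...
dimnames_dinuc <- function() DINUCS

#' Expand a dinucleotide class shorthand
#'
#' Named classes follow IUPAC-style composition: `"RR"` (purine-purine),
#' `"YY"`, `"RY"`, `"YR"`, `"WW"` (A/T only), `"SS"` (C/G only). Any other
#' input is taken as a character vector of explicit dinucleotides.
#'
#' @param cls class name or character vector of 2-mers.
#' @return character vector of dinucleotides.
#' @examples dinuc_class("RR")
#' @export
dinuc_class <- function(cls) {
  if (length(cls) == 1L && cls %in% c("RR", "YY", "RY", "YR", "WW", "SS")) {
    R <- c("A", "G"); Y <- c("C", "T"); W <- c("A", "T"); S <- c("C", "G")
    sets <- list(RR = list(R, R), YY = list(Y, Y), RY = list(R, Y),
                 YR = list(Y, R), WW = list(W, W), SS = list(S, S))
    pair <- sets[[cls]]
    return(as.vector(outer(pair[[1]], pair[[2]], paste0)))
  }
  cls <- toupper(cls)
  bad <- cls[!cls %in% DINUCS | nchar(cls) != 2L]
  if (length(bad)) stop("not dinucleotides: ", paste(bad, collapse = ", "))
  cls
}

dinuc_codes <- function(cls) {
  d <- dinuc_class(cls)
  (match(substr(d, 1, 1), BASES) - 1L) * 4L + match(substr(d, 2, 2), BASES)
}

## Evaluate `code` with the RNG seeded at `seed`, restoring the caller's
## RNG state afterwards so seeded operations do not perturb the session.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

## Running mean with shrinking edges. The window for output i covers
## [i - hl, i + hr] with hl = (w-1) %/% 2 and hr = w %/% 2, so odd widths are
## symmetric and even widths take one extra position on the right.
run_mean <- function(x, w) {
  if (w < 1) stop("window width must be >= 1")
  if (w == 1L) return(x)
  n <- length(x)
  hl <- (w - 1L) %/% 2L
  hr <- w %/% 2L
  nas <- is.na(x)
  xz <- ifelse(nas, 0, x)
  cs <- cumsum(c(0, xz))
  cn <- cumsum(c(0, !nas))
  lo <- pmax(seq_len(n) - hl, 1L)
  hi <- pmin(seq_len(n) + hr, n)
  num <- cs[hi + 1L] - cs[lo]
  den <- cn[hi + 1L] - cn[lo]
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

## Display convention: genomic positions around a TSS skip zero
## (..., -2, -1, +1, +2, ...). Internal offsets are 0-based with 0 = the +1
## base; conversion happens only in reports and plots.
display_coord <- function(offset) ifelse(offset >= 0, offset + 1L, offset)

## Derive a per-stage seed from a master seed; stays below 2^31.
derive_seed <- function(seed, stage) {
  (as.numeric(seed) * 7919 + 104729 * stage) %% 2147483629 + 1
}

## Empirical p-value with the +1 correction (b + 1) / (n + 1).
#' Empirical p-value of an observed statistic against a null sample
#'
#' @param observed scalar statistic.
#' @param null numeric vector of null replicates (or a [NullDistribution]).
#' @param alternative `"greater"` (default) or `"less"`.
#' @return p-value with the `(b + 1) / (n + 1)` correction.
#' @export
empirical_p <- function(observed, null, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  v <- if (inherits(null, "NullDistribution")) null$values else null
  b <- if (alternative == "greater") sum(v >= observed) else sum(v <= observed)
  (b + 1) / (length(v) + 1)
}
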