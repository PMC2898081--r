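## Null and sampling distributions for the periodicity statistic:
## shift-randomization nulls, bootstrap distributions, and permutation
## association tests.

new_null_distribution <- function(values, kind, seed, params = list()) {
  structure(list(values = as.numeric(values), kind = kind,
                 n_iter = length(values), seed = seed, params = params),
            class = "NullDistribution")
}

#' @export
print.NullDistribution <- function(x, ...) {
  cat("NullDistribution [", x$kind, "]: ", x$n_iter, " replicates, mean ",
      signif(mean(x$values), 4), ", sd ", signif(stats::sd(x$values), 4),
      ", seed ", x$seed %||% NA, "\n", sep = "")
  invisible(x)
}

#' @export
summary.NullDistribution <- function(object, ...) {
  c(mean = mean(object$values), sd = stats::sd(object$values),
    stats::quantile(object$values, c(0.025, 0.5, 0.95, 0.975)))
}

#' Shift-randomization null of the periodicity magnitude
#'
#' Destroys the phase coherence between promoters without changing their
#' composition: in each iteration every sequence is offset from the TSS
#' anchor by a random 1-9 bp shift (the analysis window slides upstream by
#' the shift, equivalent to prepending bases at the 5' end) before the mean
#' frequency series and its 10-bp magnitude are recomputed.
#'
#' @param seqs an [aligned_seq_set()] covering
#'   `region_start - shift_max .. region_start + series_len`.
#' @param cls,region_start,series_len,smooth,period_bp as in
#'   [periodicity_stat()].
#' @param n_iter number of null replicates (default 500).
#' @param shift_min,shift_max inclusive shift range in bp (defaults 1 and 9;
#'   `shift_min` must be >= 1 — a zero shift is the observed statistic, not a
#'   null draw).
#' @param per_sequence draw an independent shift per sequence (default,
#'   matching the construction of the null) or one global shift per
#'   iteration.
#' @param seed RNG seed; replicate values are reproducible bit-for-bit.
#' @return a `NullDistribution` of kind `"shift"`.
#' @export
shift_null <- function(seqs, cls = "RR", n_iter = 500L, shift_min = 1L,
                       shift_max = 9L, seed = 1L, region_start = 40L,
                       series_len = 150L, smooth = 3L, period_bp = 10,
                       per_sequence = TRUE) {
  if (shift_min < 1) stop("shift_min must be >= 1")
  if (shift_max < shift_min) stop("shift_max < shift_min")
  offs <- (region_start - shift_max) + 0:(series_len + shift_max - 1L)
  ind <- dinuc_indicator(seqs, cls, offs)
  cnt <- !is.na(ind)
  ind[!cnt] <- FALSE
  storage.mode(ind) <- "double"
  storage.mode(cnt) <- "double"
  nshift <- shift_max - shift_min + 1L
  N <- nrow(ind)
  col0 <- function(s) shift_max - s + 1L  # column of offset region_start - s
  vals <- with_seed(seed, {
    vapply(seq_len(n_iter), function(it) {
      s <- if (per_sequence)
        shift_min + sample.int(nshift, N, replace = TRUE) - 1L
      else rep(shift_min + sample.int(nshift, 1L) - 1L, N)
      num <- numeric(series_len); den <- numeric(series_len)
      for (sv in unique(s)) {
        rows <- which(s == sv)
        colr <- col0(sv) + 0:(series_len - 1L)
        num <- num + colSums(ind[rows, colr, drop = FALSE])
        den <- den + colSums(cnt[rows, colr, drop = FALSE])
      }
      series_magnitude(num / den, smooth, period_bp)
    }, numeric(1))
  })
  new_null_distribution(vals, "shift", seed,
                        list(shift_min = shift_min, shift_max = shift_max,
                             per_sequence = per_sequence,
                             region_start = region_start,
                             series_len = series_len, cls = cls))
}

#' Bootstrap distribution of the periodicity magnitude
#'
#' Repeatedly draws `sample_size` promoters with replacement and computes
#' the 10-bp magnitude of the sample's mean dinucleotide-class frequency
#' series (RR frequencies serve as a proxy for the joint RR/YY signal).
#' Because a single magnitude for a promoter group carries no uncertainty,
#' these bootstrap distributions are what group comparisons operate on.
#'
#' @inheritParams shift_null
#' @param sample_size promoters per draw (with replacement; default 1000,
#'   minimum 50; may equal or exceed the population size).
#' @param n_boot number of bootstrap samples (default 5000).
#' @return a `NullDistribution` of kind `"bootstrap"`.
#' @export
bootstrap_magnitudes <- function(seqs, sample_size = 1000L, n_boot = 5000L,
                                 cls = "RR", seed = 1L, region_start = 40L,
                                 series_len = 150L, smooth = 3L,
                                 period_bp = 10) {
  if (sample_size < 50) stop("sample_size must be >= 50")
  offs <- region_start + 0:(series_len - 1L)
  ind <- dinuc_indicator(seqs, cls, offs)
  N <- nrow(ind)
  has_na <- anyNA(ind)
  cnt <- NULL
  if (has_na) {
    cnt <- !is.na(ind)
    ind[!cnt] <- FALSE
    storage.mode(cnt) <- "double"
  }
  storage.mode(ind) <- "double"
  vals <- with_seed(seed, {
    vapply(seq_len(n_boot), function(it) {
      w <- tabulate(sample.int(N, sample_size, replace = TRUE), N)
      num <- as.vector(w %*% ind)
      den <- if (has_na) as.vector(w %*% cnt) else sample_size
      series_magnitude(num / den, smooth, period_bp)
    }, numeric(1))
  })
  new_null_distribution(vals, "bootstrap", seed,
                        list(sample_size = sample_size, n_boot = n_boot,
                             region_start = region_start,
                             series_len = series_len, cls = cls))
}

#' Kolmogorov-Smirnov normality diagnostic for a replicate distribution
#'
#' Compares the replicate values against a normal with the sample's own mean
#' and standard deviation. Used as a stopping diagnostic for the number of
#' bootstrap samplings: enough samplings have been taken once the
#' distribution is indistinguishable from normal at the working threshold.
#'
#' @param d a `NullDistribution` (or numeric vector), `n >= 100`.
#' @return list with `statistic` (KS D) and `p_value`.
#' @export
normality_check <- function(d) {
  v <- if (inherits(d, "NullDistribution")) d$values else as.numeric(d)
  if (length(v) < 100) stop("need at least 100 replicates")
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) stop("degenerate (zero-variance) distribution")
  ks <- suppressWarnings(stats::ks.test(v, "pnorm", mean(v), s))
  list(statistic = unname(ks$statistic), p_value = ks$p.value)
}

#' Rank-sum comparison of two replicate distributions
#'
#' @param a,b `NullDistribution`s (or numeric vectors).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (alternative that `a` tends below/above `b`, as in
#'   [stats::wilcox.test()]).
#' @return Wilcoxon rank-sum p-value.
#' @export
compare_groups <- function(a, b,
                           alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  va <- if (inherits(a, "NullDistribution")) a$values else as.numeric(a)
  vb <- if (inherits(b, "NullDistribution")) b$values else as.numeric(b)
  if (!length(va) || !length(vb)) stop("empty distribution")
  suppressWarnings(
    stats::wilcox.test(va, vb, alternative = alternative)$p.value)
}

#' Permutation test of association between two binary labels
#'
#' Tests whether promoters positive for label `a` are enriched for label `b`
#' beyond chance. The statistic is the count of cases positive for both; the
#' null is built by shuffling `b`, and the p-value carries the
#' `(b + 1)/(n + 1)` correction.
#'
#' @param labels_a,labels_b logical or 0/1 vectors of equal length, each with
#'   both classes present.
#' @param n_perm number of shuffles (default 10000).
#' @param seed RNG seed.
#' @return list with `p_value`, `statistic` (observed both-positive count)
#'   and `null` (the shuffled counts).
#' @export
label_association_test <- function(labels_a, labels_b, n_perm = 10000L,
                                   seed = 1L) {
  a <- as.logical(labels_a); b <- as.logical(labels_b)
  if (length(a) != length(b)) stop("label vectors differ in length")
  if (anyNA(a) || anyNA(b)) stop("labels contain NA")
  if (length(unique(a)) < 2 || length(unique(b)) < 2)
    stop("both classes must be present in each label vector")
  obs <- sum(a & b)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) sum(a & b[sample.int(length(b))]),
           numeric(1))
  })
  list(p_value = (sum(null >= obs) + 1) / (n_perm + 1),
       statistic = obs, null = null)
}
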