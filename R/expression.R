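## Expression-based gene stratification: bimodal median-expression split
## (Gaussian mixture) and tissue-specificity grouping.

#' Read an expression matrix
#'
#' TSV with gene ids in the first column and one column per tissue.
#'
#' @param path file to read.
#' @return numeric matrix (genes x tissues) with dimnames.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric expression values")
  if (anyNA(m)) stop("expression matrix contains missing values")
  m
}

#' Partition genes by median expression level
#'
#' The per-gene median across tissues is typically bimodal; a 2-component
#' Gaussian mixture ([fit_gmm2()]) splits it into low- (`L_E`) and
#' high-expression (`H_E`) classes without an arbitrary threshold.
#'
#' @param m genes x tissues numeric matrix (already normalized), >= 200
#'   genes and >= 2 tissues.
#' @param log2_transform fit the mixture on `log2(median + 1)` (default
#'   `TRUE`; expression mixtures are log-scale bimodal).
#' @param override classify from a flagged fit anyway.
#' @return list with `labels` (named factor `L_E`/`H_E`), `medians`,
#'   `fitted_on`, `fit` (the `GmmFit`; check its `degenerate` flag on
#'   unimodal input).
#' @export
median_expression_partition <- function(m, log2_transform = TRUE,
                                        override = FALSE) {
  if (ncol(m) < 2) stop("need at least 2 tissues")
  if (nrow(m) < 200) stop("need at least 200 genes")
  med <- apply(m, 1, stats::median)
  x <- if (log2_transform) log2(med + 1) else med
  fit <- fit_gmm2(x)
  cl <- classify_gmm2(fit, x, override = override || fit$degenerate)
  labels <- factor(ifelse(cl$component == 2L, "H_E", "L_E"),
                   levels = c("L_E", "H_E"))
  names(labels) <- rownames(m)
  list(labels = labels, medians = med, fitted_on = x, fit = fit)
}

#' Tissue-specificity score (tau)
#'
#' `tau(g) = sum_i (1 - x_i / max_i x_i) / (n_tissues - 1)`: 0 for a
#' uniform profile, 1 for single-tissue expression. Requires non-negative
#' values; all-zero genes get `NA` with a warning.
#'
#' @param m genes x tissues non-negative numeric matrix.
#' @param method only `"tau"` is implemented; the argument names the score
#'   in outputs so alternative indices can slot in.
#' @return named numeric vector of scores in `[0, 1]`.
#' @export
tissue_specificity <- function(m, method = "tau") {
  method <- match.arg(method, "tau")
  if (any(m < 0)) stop("tau requires non-negative expression values")
  mx <- apply(m, 1, max)
  tau <- rowSums(1 - m / ifelse(mx == 0, NA, mx)) / (ncol(m) - 1)
  if (anyNA(tau))
    warning(sum(is.na(tau)), " all-zero gene(s): specificity undefined")
  stats::setNames(tau, rownames(m))
}

#' Partition genes by tissue specificity
#'
#' Cuts specificity scores into low/medium/high (`L_S`/`M_S`/`H_S`) groups,
#' by rank tertiles by default or at explicit score cut-points (which
#' reproduce unequal group sizes when the working boundaries are
#' score-valued rather than quantiles).
#'
#' @param scores named numeric vector from [tissue_specificity()]; `NA`
#'   scores are dropped.
#' @param n_groups number of groups (default 3).
#' @param bounds optional increasing vector of `n_groups - 1` score
#'   cut-points; group `k` is `bounds[k-1] < score <= bounds[k]`.
#' @return data frame (`gene_id`, `score`, `group`, `label`) where `label`
#'   is `L_S`/`M_S`/`H_S` for 3 groups, otherwise `S1..Sk`.
#' @export
specificity_partition <- function(scores, n_groups = 3L, bounds = NULL) {
  scores <- scores[!is.na(scores)]
  if (length(scores) < n_groups) stop("fewer scores than groups")
  if (is.null(bounds)) {
    qp <- quantile_partition(
      data.frame(tss_id = names(scores), score = as.numeric(scores)),
      q = n_groups)
    grp <- qp$group[match(names(scores), qp$tss_id)]
  } else {
    if (length(bounds) != n_groups - 1L || is.unsorted(bounds))
      stop("bounds must be an increasing vector of n_groups - 1 cut-points")
    grp <- findInterval(scores, bounds, left.open = TRUE) + 1L
  }
  lab <- if (n_groups == 3L) c("L_S", "M_S", "H_S")[grp]
         else paste0("S", grp)
  data.frame(gene_id = names(scores), score = as.numeric(scores),
             group = grp, label = lab)
}
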