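## Two-component univariate Gaussian mixture, fitted by EM with a
## deterministic quantile-based initialization. Used for the CpG-island
## partition of promoters and the bimodal median-expression partition of
## genes; model-based splits are preferred over ad hoc thresholds for both.

#' Fit a 2-component univariate Gaussian mixture
#'
#' Plain EM with deterministic initialization (component means at the 25th
#' and 75th percentiles, common starting sd, equal weights), so the fit is
#' reproducible without a seed. Components are ordered by mean. A fit is
#' flagged degenerate when the mean separation in units of component spread
#' (Ashman's D) falls below 2 — the point where the two fitted Gaussians no
#' longer describe distinct modes.
#'
#' @param x numeric vector, `n >= 100`.
#' @param max_iter maximum EM iterations (default 500).
#' @param tol convergence threshold on the log-likelihood increase
#'   (default 1e-8).
#' @return object of class `GmmFit`: `means`, `sds`, `weights` (summing to
#'   1), `loglik`, `n_iter`, `converged`, `separation` (Ashman's D),
#'   `degenerate`.
#' @export
fit_gmm2 <- function(x, max_iter = 500L, tol = 1e-8) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 100) stop("need at least 100 observations")
  mu <- unname(stats::quantile(x, c(0.25, 0.75)))
  s0 <- stats::sd(x)
  if (s0 == 0) stop("zero-variance input")
  sg <- c(s0, s0) / 2
  w <- c(0.5, 0.5)
  sd_floor <- 1e-6 * s0
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sg[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r <- d1 / tot
    ll <- sum(log(tot))
    if (is.finite(ll) && ll - ll_old < tol && iter > 1L) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    n1 <- sum(r); n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) break  # one component emptied out
    mu[1] <- sum(r * x) / n1
    mu[2] <- sum((1 - r) * x) / n2
    sg[1] <- max(sqrt(sum(r * (x - mu[1])^2) / n1), sd_floor)
    sg[2] <- max(sqrt(sum((1 - r) * (x - mu[2])^2) / n2), sd_floor)
    w <- c(n1, n2) / n
  }
  o <- order(mu)
  ## Ashman's D: mean separation in units of component spread; D < 2 means
  ## the two fitted components do not describe distinct modes.
  D <- diff(mu[o]) / sqrt((sg[1]^2 + sg[2]^2) / 2)
  structure(list(means = mu[o], sds = sg[o], weights = w[o],
                 loglik = ll_old, n_iter = iter, converged = converged,
                 separation = D, degenerate = D < 2),
            class = "GmmFit")
}

#' Posterior classification under a fitted 2-component mixture
#'
#' Assigns each observation to the component with the higher posterior;
#' exact posterior ties go to the high-mean component.
#'
#' @param fit a [fit_gmm2()] result. Unless `override = TRUE`, the fit must
#'   have converged and be non-degenerate.
#' @param x numeric vector of observations.
#' @param override classify anyway from a flagged fit.
#' @return data frame with `component` (1 = low-mean, 2 = high-mean),
#'   `posterior` (of the assigned component) and `posterior_high` (of the
#'   high-mean component).
#' @export
classify_gmm2 <- function(fit, x, override = FALSE) {
  stopifnot(inherits(fit, "GmmFit"))
  if (!override && (!fit$converged || fit$degenerate))
    stop("fit did not converge cleanly; pass override = TRUE to classify anyway")
  d1 <- fit$weights[1] * stats::dnorm(x, fit$means[1], fit$sds[1])
  d2 <- fit$weights[2] * stats::dnorm(x, fit$means[2], fit$sds[2])
  tot <- d1 + d2
  tot[tot == 0] <- .Machine$double.xmin
  p2 <- d2 / tot
  comp <- ifelse(p2 >= 0.5, 2L, 1L)  # tie -> high-mean component
  data.frame(component = comp,
             posterior = ifelse(comp == 2L, p2, 1 - p2),
             posterior_high = p2)
}

#' @export
print.GmmFit <- function(x, ...) {
  cat("GmmFit: means ", paste(signif(x$means, 4), collapse = " / "),
      ", sds ", paste(signif(x$sds, 4), collapse = " / "),
      ", weights ", paste(signif(x$weights, 3), collapse = " / "),
      "\n  loglik ", signif(x$loglik, 6), " after ", x$n_iter,
      " iterations; converged: ", x$converged,
      if (x$degenerate) "; DEGENERATE (single mode?)" else "", "\n", sep = "")
  invisible(x)
}
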