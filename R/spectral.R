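## Periodogram estimation and the 10-bp periodicity magnitude.
##
## The scalar statistic used throughout is the area-normalized power
## spectral density at the discrete-Fourier-transform bin whose period is
## closest to 10 bp, computed on the mean dinucleotide-class frequency
## series over a downstream window (+40..+190 by default). With the default
## 150-point series, period 10 bp is bin k = 15 exactly, so no interpolation
## is involved.

#' Periodogram of a real series
#'
#' The series mean is subtracted (so the DC term does not dominate the area
#' normalization), the series is multiplied by a Hamming window
#' `w(n) = 0.54 - 0.46 cos(2*pi*n/(N-1))`, and the squared modulus of each
#' DFT coefficient is divided by the series length. Bins `k = 1..floor(N/2)`
#' are retained (DC excluded) and, when `normalize = TRUE`, scaled to total
#' power 1 so magnitudes are comparable across cohorts.
#'
#' @param series numeric vector, length >= 20.
#' @param demean subtract the series mean first (default `TRUE`).
#' @param hamming apply the Hamming taper (default `TRUE`).
#' @param include_dc retain the k = 0 bin in the area normalization
#'   (sensitivity analysis; default `FALSE`).
#' @param normalize scale the retained power to sum to 1 (default `TRUE`).
#' @return object of class `Periodogram` with fields `freqs` (cycles/bp,
#'   `k/N`), `power`, `normalized`, `n_points` and `degenerate` (`TRUE` for a
#'   zero-variance input, which gets a flagged all-zero spectrum).
#' @export
periodogram <- function(series, demean = TRUE, hamming = TRUE,
                        include_dc = FALSE, normalize = TRUE) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 20) stop("series too short for spectral analysis (need >= 20)")
  if (anyNA(series)) stop("series contains NA")
  x <- if (demean) series - mean(series) else series
  if (hamming) x <- x * (0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1)))
  X <- stats::fft(x)
  k <- seq_len(n %/% 2)
  if (include_dc) k <- c(0L, k)
  power <- Mod(X[k + 1L])^2 / n
  degenerate <- FALSE
  if (normalize) {
    tot <- sum(power)
    if (tot <= 0) {
      degenerate <- TRUE
      power <- rep(0, length(power))
    } else power <- power / tot
  }
  structure(list(freqs = k / n, power = power, normalized = normalize,
                 n_points = n, k = k, degenerate = degenerate),
            class = "Periodogram")
}

#' Power at a target period
#'
#' Reads out the periodogram bin whose period `N/k` is closest to
#' `period_bp` (nearest bin, no interpolation). With the default 150-point
#' series, period 10 maps to bin k = 15 exactly.
#'
#' @param pg a [periodogram()].
#' @param period_bp target period in bp (default 10).
#' @return the power at that bin, with attributes `period_bin` (the exact
#'   period of the bin used) and `k` (its DFT index).
#' @export
magnitude_at_period <- function(pg, period_bp = 10) {
  stopifnot(inherits(pg, "Periodogram"))
  if (period_bp <= 2 || period_bp >= pg$n_points)
    stop("period must lie in (2, n_points)")
  ks <- pg$k[pg$k > 0]
  i <- which.min(abs(pg$n_points / ks - period_bp))
  k <- ks[i]
  val <- pg$power[match(k, pg$k)]
  attr(val, "period_bin") <- pg$n_points / k
  attr(val, "k") <- k
  val
}

## Fast path: magnitude at `period` of a raw mean-frequency series after
## 3-bp smoothing. Used by the resampling machinery where constructing
## profile objects per replicate would dominate.
series_magnitude <- function(series, smooth = 3L, period = 10) {
  s <- if (smooth > 1L) run_mean(series, smooth) else series
  pg <- periodogram(s)
  if (pg$degenerate) return(0)
  as.numeric(magnitude_at_period(pg, period))
}

#' The 10-bp periodicity statistic of a promoter set
#'
#' Composes the full measurement pipeline: dinucleotide-class mean frequency
#' profile, restriction to the downstream window (start offsets
#' `region_start .. region_start + series_len - 1`, i.e. +40..+189 by
#' default, covering bases +40..+190), 3-bp moving-average smoothing, Hamming
#' windowing, DFT, area normalization, and read-out at the target period.
#'
#' @param seqs an [aligned_seq_set()] covering the window.
#' @param cls dinucleotide class (default `"RR"`; see [dinuc_class()]).
#' @param region_start first dinucleotide start offset of the window
#'   (TSS-relative, default 40).
#' @param series_len number of consecutive start offsets (default 150, which
#'   makes period 10 an exact DFT bin).
#' @param smooth moving-average width in bp applied before the DFT
#'   (default 3).
#' @param period_bp target period (default 10).
#' @return object of class `PeriodicityStat`: `magnitude10`, `period_bin`,
#'   `region`, `feature`, plus the underlying `profile` and `periodogram`.
#' @export
periodicity_stat <- function(seqs, cls = "RR", region_start = 40L,
                             series_len = 150L, smooth = 3L, period_bp = 10) {
  offs <- region_start + 0:(series_len - 1L)
  ind <- dinuc_indicator(seqs, cls, offs)
  n_eff <- colSums(!is.na(ind))
  if (any(n_eff == 0))
    stop("no informative sequence at some window positions")
  series <- colSums(ind, na.rm = TRUE) / n_eff
  smoothed <- if (smooth > 1L) run_mean(series, smooth) else series
  pg <- periodogram(smoothed)
  mag <- if (pg$degenerate) structure(0, period_bin = NA_real_)
         else magnitude_at_period(pg, period_bp)
  structure(list(magnitude10 = as.numeric(mag),
                 period_bin = attr(mag, "period_bin"),
                 region = c(start = region_start,
                            end = region_start + series_len - 1L),
                 feature = if (length(cls) == 1L) cls
                           else paste(cls, collapse = "|"),
                 profile = new_position_profile(series, offs,
                                                paste0(cls, collapse = "|"),
                                                n_eff),
                 periodogram = pg),
            class = "PeriodicityStat")
}

#' @export
print.PeriodicityStat <- function(x, ...) {
  cat("PeriodicityStat [", x$feature, "]: magnitude at ",
      signif(x$period_bin, 4), " bp = ", signif(x$magnitude10, 4),
      " (window ", display_coord(x$region[["start"]]), "..",
      display_coord(x$region[["end"]]), ")\n", sep = "")
  invisible(x)
}

#' @export
print.Periodogram <- function(x, ...) {
  cat("Periodogram: N =", x$n_points, "|", length(x$power), "bins |",
      if (x$normalized) "area-normalized" else "raw power",
      if (x$degenerate) "| DEGENERATE (zero variance)" else "", "\n")
  invisible(x)
}

#' @export
as.data.frame.Periodogram <- function(x, ...) {
  data.frame(k = x$k, freq = x$freqs,
             period = ifelse(x$k > 0, x$n_points / x$k, Inf),
             power = x$power)
}

#' @export
plot.Periodogram <- function(x, xlab = "period (bp)",
                             ylab = "normalized power", type = "h",
                             xlim = c(2, 50), ...) {
  df <- as.data.frame(x)
  df <- df[is.finite(df$period), ]
  graphics::plot(df$period, df$power, type = type, xlab = xlab, ylab = ylab,
                 xlim = xlim, ...)
  graphics::abline(v = 10, lty = 3, col = "grey40")
  invisible(x)
}
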