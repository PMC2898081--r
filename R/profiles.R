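## Per-position composition profiles across an aligned promoter set.

new_position_profile <- function(values, coords, feature, n_effective,
                                 smoothed = FALSE) {
  structure(list(values = as.numeric(values), coords = as.integer(coords),
                 feature = feature, n_effective = as.integer(n_effective),
                 smoothed = smoothed),
            class = "PositionProfile")
}

#' Per-position nucleotide frequency profile
#'
#' Fraction of sequences carrying `base` at each TSS-relative offset. `N`
#' characters are excluded from the denominator, so `n_effective` can vary
#' along the profile (edge-padded sequences); positions where no sequence
#' informs the estimate are `NA`.
#'
#' @param seqs an [aligned_seq_set()].
#' @param base one of `"A"`, `"C"`, `"G"`, `"T"`.
#' @return a `PositionProfile` with one value per position.
#' @export
nucleotide_profile <- function(seqs, base = c("A", "C", "G", "T")) {
  base <- match.arg(base)
  if (length(seqs) == 0) stop("empty sequence set")
  code <- seq_code_matrix(seqs)
  hit <- code == match(base, BASES)
  n_eff <- colSums(!is.na(code))
  vals <- colSums(hit, na.rm = TRUE) / n_eff
  vals[n_eff == 0] <- NA_real_
  new_position_profile(vals, seq_len(ncol(code)) - 1L - seqs$offset_of_tss,
                       base, n_eff)
}

## Logical indicator matrix: does the dinucleotide starting at each requested
## TSS-relative offset belong to `cls`? NA where either base is N.
dinuc_indicator <- function(seqs, cls, offsets) {
  code <- seq_code_matrix(seqs)
  cols <- seqs$offset_of_tss + offsets + 1L
  if (any(cols < 1L) || any(cols + 1L > ncol(code)))
    stop("requested offsets fall outside the sequences")
  c1 <- code[, cols, drop = FALSE]
  c2 <- code[, cols + 1L, drop = FALSE]
  di <- (c1 - 1L) * 4L + c2
  ind <- matrix(di %in% dinuc_codes(cls), nrow = nrow(code))
  ind[is.na(di)] <- NA
  ind
}

#' Per-position dinucleotide class frequency profile
#'
#' Fraction of sequences whose dinucleotide starting at each offset (bases at
#' offsets `i` and `i + 1`, both non-N) belongs to `cls`. A dinucleotide "at
#' offset i" starts at `i` throughout the package.
#'
#' @param seqs an [aligned_seq_set()].
#' @param cls a class shorthand (see [dinuc_class()]) or explicit set of
#'   dinucleotides, e.g. `c("AA","AG","GA","GG")`.
#' @return a `PositionProfile` of length `L - 1`.
#' @export
dinucleotide_class_profile <- function(seqs, cls = "RR") {
  if (length(seqs) == 0) stop("empty sequence set")
  L <- seq_width(seqs)
  offs <- (0:(L - 2L)) - seqs$offset_of_tss
  ind <- dinuc_indicator(seqs, cls, offs)
  n_eff <- colSums(!is.na(ind))
  vals <- colSums(ind, na.rm = TRUE) / n_eff
  vals[n_eff == 0] <- NA_real_
  feature <- if (length(cls) == 1L) cls else paste(cls, collapse = "|")
  new_position_profile(vals, offs, feature, n_eff)
}

#' Moving-average smoothing of a profile
#'
#' Centered moving average of odd width; at the profile edges the window
#' shrinks to the available positions so the profile length is unchanged.
#'
#' @param p a `PositionProfile`.
#' @param window_bp odd window width in bp (default 3).
#' @return smoothed `PositionProfile`, feature label annotated `"smoothed"`.
#' @export
smooth_profile <- function(p, window_bp = 3L) {
  if (window_bp < 1 || window_bp %% 2 == 0)
    stop("window_bp must be odd and >= 1")
  out <- p
  out$values <- run_mean(p$values, window_bp)
  if (window_bp > 1L && !grepl("smoothed", p$feature))
    out$feature <- paste0(p$feature, " (smoothed ", window_bp, " bp)")
  out$smoothed <- TRUE
  out
}

#' Restrict a profile to a TSS-relative coordinate window
#'
#' @param p a `PositionProfile`.
#' @param from,to inclusive TSS-relative offsets.
#' @return the windowed `PositionProfile`.
#' @export
window_profile <- function(p, from, to) {
  keep <- p$coords >= from & p$coords <= to
  if (!any(keep)) stop("window [", from, ",", to, "] outside profile range")
  new_position_profile(p$values[keep], p$coords[keep], p$feature,
                       p$n_effective[keep], p$smoothed)
}

#' @export
print.PositionProfile <- function(x, ...) {
  cat("PositionProfile [", x$feature, "]: ", length(x$values),
      " positions, display span ", display_coord(min(x$coords)), "..",
      display_coord(max(x$coords)), ", mean ",
      signif(mean(x$values, na.rm = TRUE), 4), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.PositionProfile <- function(x, ...) {
  data.frame(offset = x$coords, position = display_coord(x$coords),
             value = x$values, n_effective = x$n_effective)
}

#' @export
plot.PositionProfile <- function(x, type = "l", xlab = "position (bp from TSS)",
                                 ylab = NULL, ...) {
  if (is.null(ylab)) ylab <- paste(x$feature, "frequency")
  graphics::plot(display_coord(x$coords), x$values, type = type,
                 xlab = xlab, ylab = ylab, ...)
  graphics::abline(v = 1, lty = 3, col = "grey40")
  invisible(x)
}
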