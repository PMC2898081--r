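## TSS ingestion, quality filtering and strand-aware promoter extraction.
##
## Coordinate conventions: genomic input is 1-based inclusive; internally a
## promoter is indexed by 0-based TSS-relative offsets where offset 0 is the
## first transcribed base (the "+1" base). The skip-zero display convention
## (..., -1, +1, ...) is applied only when printing or plotting.

#' Construct a TSS set
#'
#' A `TssSet` is a data frame of TSS records (one row per start site) with a
#' genome label attribute. Positions are 1-based genomic coordinates of the
#' first transcribed base; `support` counts the cDNAs mapping to that exact
#' position.
#'
#' @param id,chrom,pos,strand,support,gene_id record fields; `strand` must be
#'   `"+"` or `"-"`, `pos >= 1`, `support >= 0`.
#' @param genome_id label for the source assembly.
#' @return object of class `TssSet` (a data frame).
#' @export
tss_set <- function(id, chrom, pos, strand, support, gene_id = NA_character_,
                    genome_id = "unknown") {
  n <- length(id)
  if (n > 0) {
    if (anyDuplicated(id)) stop("TSS ids must be unique")
    if (!all(strand %in% c("+", "-")))
      stop("strand must be '+' or '-', got: ",
           paste(unique(strand[!strand %in% c("+", "-")]), collapse = ", "))
    if (any(pos < 1)) stop("positions must be >= 1")
    if (any(support < 0)) stop("support must be >= 0")
  }
  x <- data.frame(id = as.character(id), chrom = as.character(chrom),
                  pos = as.integer(pos), strand = as.character(strand),
                  support = as.integer(support),
                  gene_id = rep_len(as.character(gene_id), n),
                  stringsAsFactors = FALSE)
  attr(x, "genome_id") <- genome_id
  class(x) <- c("TssSet", "data.frame")
  x
}

#' Read a TSS table
#'
#' Reads a tab-separated TSS table (one row per start site). The column map
#' `dialect` names which input columns hold each field, so tables from
#' different databases can be ingested without reshaping.
#'
#' @param path path to a TSV file with a header line.
#' @param dialect named list mapping the internal fields `id`, `chrom`,
#'   `pos`, `strand`, `support`, `gene_id` to column names in the file.
#'   `gene_id` may be omitted.
#' @param genome_id label stored on the returned set.
#' @return a [tss_set()].
#' @export
read_tss_table <- function(path,
                           dialect = list(id = "id", chrom = "chrom",
                                          pos = "pos", strand = "strand",
                                          support = "support",
                                          gene_id = "gene_id"),
                           genome_id = "unknown") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", comment.char = "",
                          quote = "", check.names = FALSE)
  if (nrow(df) == 0)
    return(tss_set(character(), character(), integer(), character(),
                   integer(), genome_id = genome_id))
  need <- c("id", "chrom", "pos", "strand", "support")
  for (f in need) {
    col <- dialect[[f]]
    if (is.null(col) || !col %in% names(df))
      stop("dialect column for '", f, "' not found in ", path)
  }
  pos <- suppressWarnings(as.integer(df[[dialect$pos]]))
  support <- suppressWarnings(as.integer(df[[dialect$support]]))
  bad <- which(is.na(pos) | is.na(support))
  if (length(bad))
    stop("malformed row at line ", bad[1] + 1L, " of ", path)
  strand <- df[[dialect$strand]]
  badstr <- which(!strand %in% c("+", "-"))
  if (length(badstr))
    stop("unknown strand symbol '", strand[badstr[1]], "' at line ",
         badstr[1] + 1L, " of ", path)
  gid <- if (!is.null(dialect$gene_id) && dialect$gene_id %in% names(df))
    df[[dialect$gene_id]] else NA_character_
  tss_set(df[[dialect$id]], df[[dialect$chrom]], pos, strand, support,
          gid, genome_id = genome_id)
}

#' Read TSSs from a BED6 file
#'
#' Converts 0-based half-open BED intervals to 1-based TSS positions: the TSS
#' is `start + 1` on the plus strand and `end` on the minus strand. The BED
#' score column is interpreted as the cDNA support count.
#'
#' @inheritParams read_tss_table
#' @return a [tss_set()].
#' @export
read_tss_bed <- function(path, genome_id = "unknown") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          colClasses = "character", comment.char = "#",
                          quote = "")
  if (ncol(df) < 6) stop("BED6 requires 6 columns")
  strand <- df[[6]]
  pos <- ifelse(strand == "+", as.integer(df[[2]]) + 1L, as.integer(df[[3]]))
  tss_set(df[[4]], df[[1]], pos, strand, as.integer(df[[5]]),
          genome_id = genome_id)
}

#' Filter TSSs by support and proximity clustering
#'
#' Removes records supported by fewer than `min_support` cDNAs, then
#' collapses same-chromosome records linked by pairwise distance
#' `<= cluster_bp` (single-linkage, i.e. transitively) to the single record
#' with maximal support. Support ties are broken toward the smaller genomic
#' coordinate; remaining ties toward the lexicographically smaller id.
#'
#' @param tss a [tss_set()].
#' @param min_support minimum cDNA support to retain a record (default 2).
#' @param cluster_bp clustering distance in bp (default 200).
#' @return filtered `TssSet`; idempotent.
#' @export
filter_tss <- function(tss, min_support = 2L, cluster_bp = 200L) {
  x <- tss[tss$support >= min_support, , drop = FALSE]
  if (nrow(x) == 0) {
    class(x) <- c("TssSet", "data.frame")
    return(x)
  }
  keep <- unlist(lapply(split(seq_len(nrow(x)), x$chrom), function(ix) {
    sub <- x[ix, , drop = FALSE]
    o <- order(sub$pos)
    ix <- ix[o]; sub <- sub[o, , drop = FALSE]
    gap <- c(Inf, diff(sub$pos))
    grp <- cumsum(gap > cluster_bp)
    unlist(lapply(split(seq_along(ix), grp), function(j) {
      sel <- order(-sub$support[j], sub$pos[j], sub$id[j])[1]
      ix[j[sel]]
    }), use.names = FALSE)
  }), use.names = FALSE)
  out <- x[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("TssSet", "data.frame")
  attr(out, "genome_id") <- attr(tss, "genome_id")
  out
}

#' Construct an aligned promoter sequence set
#'
#' `N` equal-length sequences over `{A,C,G,T,N}` on a common TSS-relative
#' frame: the `+1` base of every sequence sits at 0-based string index
#' `offset_of_tss`, and increasing index is downstream of transcription
#' (minus-strand sources must already be reverse-complemented).
#'
#' @param sequences character vector of equal-length sequences.
#' @param offset_of_tss 0-based index of the `+1` base within each sequence.
#' @param source_ids ids of the source TSS records.
#' @return object of class `AlignedSeqSet`.
#' @export
aligned_seq_set <- function(sequences, offset_of_tss, source_ids = NULL) {
  sequences <- toupper(as.character(sequences))
  L <- unique(nchar(sequences))
  if (length(sequences) && length(L) != 1L)
    stop("all sequences must have identical length")
  if (length(sequences) == 0) L <- 0L
  if (length(sequences) && (offset_of_tss < 0 || offset_of_tss > L - 1))
    stop("offset_of_tss out of range")
  if (is.null(source_ids)) source_ids <- as.character(seq_along(sequences))
  structure(list(sequences = sequences,
                 offset_of_tss = as.integer(offset_of_tss),
                 source_ids = as.character(source_ids)),
            class = "AlignedSeqSet")
}

#' @export
length.AlignedSeqSet <- function(x) length(x$sequences)

seq_width <- function(seqs) if (length(seqs$sequences)) nchar(seqs$sequences[1]) else 0L

## N x L character matrix of an AlignedSeqSet.
seq_char_matrix <- function(seqs) {
  matrix(unlist(strsplit(seqs$sequences, "", fixed = TRUE), use.names = FALSE),
         nrow = length(seqs$sequences), byrow = TRUE)
}

## N x L integer code matrix (A=1,C=2,G=3,T=4, NA for anything else).
seq_code_matrix <- function(seqs) {
  m <- seq_char_matrix(seqs)
  matrix(match(m, BASES), nrow = nrow(m))
}

## Column index (1-based) of a TSS-relative offset within the sequences.
offset_col <- function(seqs, offset) seqs$offset_of_tss + offset + 1L

#' Extract TSS-aligned flanking sequences from a genome
#'
#' For each TSS the window covers `upstream` bases before and `downstream`
#' bases from the `+1` base (so every sequence has length
#' `upstream + downstream` and the `+1` base sits at 0-based offset
#' `upstream`). Minus-strand records are reverse-complemented so that
#' increasing offset is downstream of transcription. Windows overrunning a
#' contig edge are padded with `N`.
#'
#' @param tss a [tss_set()].
#' @param genome a `Biostrings::DNAStringSet` (e.g. from
#'   `Biostrings::readDNAStringSet`) or the path of a FASTA file.
#' @param upstream,downstream window extent in bp (defaults 1000/1000).
#' @return an [aligned_seq_set()].
#' @export
extract_flanks <- function(tss, genome, upstream = 1000L, downstream = 1000L) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  ## FASTA headers may carry descriptions; key on the first word.
  names(genome) <- sub("\\s.*$", "", names(genome))
  missing <- setdiff(unique(tss$chrom), names(genome))
  if (length(missing))
    stop("chromosomes missing from genome: ", paste(missing, collapse = ", "),
         " (ids: ",
         paste(tss$id[tss$chrom %in% missing], collapse = ", "), ")")
  L <- upstream + downstream
  out <- character(nrow(tss))
  for (i in seq_len(nrow(tss))) {
    chrom <- genome[[tss$chrom[i]]]
    clen <- length(chrom)
    p <- tss$pos[i]
    if (tss$strand[i] == "+") {
      from <- p - upstream; to <- p + downstream - 1L
    } else {
      ## mirrored about pos: upstream of transcription is higher coordinates
      from <- p - downstream + 1L; to <- p + upstream
    }
    lo <- max(from, 1L); hi <- min(to, clen)
    core <- if (lo <= hi) as.character(Biostrings::subseq(chrom, lo, hi)) else ""
    s <- paste0(strrep("N", lo - from), core, strrep("N", to - hi))
    if (tss$strand[i] == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    out[i] <- s
  }
  aligned_seq_set(out, offset_of_tss = upstream, source_ids = tss$id)
}

#' @export
print.TssSet <- function(x, ...) {
  cat("TssSet:", nrow(x), "records on", length(unique(x$chrom)),
      "chromosome(s); genome:", attr(x, "genome_id") %||% "unknown", "\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' @export
print.AlignedSeqSet <- function(x, ...) {
  L <- seq_width(x)
  cat("AlignedSeqSet:", length(x), "sequences of length", L,
      "| +1 base at offset", x$offset_of_tss,
      sprintf("(spanning %d..%+d in display coordinates)\n",
              -x$offset_of_tss, L - x$offset_of_tss))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
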