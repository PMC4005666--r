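# Structure-guided alignment conservation: per-column composition and
# information content (as drawn in sequence logos), and joint
# base-combination frequencies at designated k-turn positions.
#
# Conventions: T is normalised to U; IUPAC ambiguity codes are counted as
# gaps (reported separately), not fractionally; frequencies are over non-gap
# symbols with the gap fraction alongside, so both denominators are
# recoverable. Information content is 2 + sum(f * log2 f) bits, without
# small-sample correction by default.

#' Read a multiple sequence alignment
#'
#' Stockholm or aligned FASTA (sniffed from the file when `format = "auto"`).
#' Parsing is delegated to Biostrings; T is normalised to U and `.` gaps
#' to `-`.
#'
#' @param path alignment file.
#' @param format `"auto"`, `"stockholm"` or `"fasta"`.
#' @return a character matrix, sequences in rows (named when the file names
#'   them), alignment columns in columns.
#' @export
readAlignment <- function(path, format = c("auto", "stockholm", "fasta")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(errorCondition(sprintf("file not found: %s", path),
                        class = c("kjIOError", "error", "condition")))
  if (format == "auto") {
    head <- readLines(path, n = 1L, warn = FALSE)
    format <- if (grepl("^# STOCKHOLM", head)) "stockholm" else "fasta"
  }
  if (format == "stockholm") {
    ma <- tryCatch(
      Biostrings::readRNAMultipleAlignment(path, format = "stockholm"),
      error = function(e)
        Biostrings::readDNAMultipleAlignment(path, format = "stockholm"))
    seqs <- Biostrings::unmasked(ma)
    m <- do.call(rbind, strsplit(as.character(seqs), ""))
    rownames(m) <- names(seqs)
  } else {
    aln <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                    error = function(e) {
                      stop(errorCondition(
                        sprintf("cannot parse '%s' as aligned FASTA: %s",
                                path, conditionMessage(e)),
                        class = c("kjParseError", "error", "condition")))
                    })
    if (length(aln) == 0L)
      stop(errorCondition("empty alignment", class = c("kjParseError", "error", "condition")))
    w <- unique(Biostrings::width(aln))
    if (length(w) != 1L)
      stop(errorCondition("FASTA sequences have unequal aligned lengths",
                          class = c("kjParseError", "error", "condition")))
    m <- do.call(rbind, strsplit(as.character(aln), ""))
    rownames(m) <- names(aln)
  }
  m <- toupper(m)
  m[m == "T"] <- "U"
  m[m == "."] <- "-"
  m
}

#' Column mask: role labels to alignment columns
#'
#' @param mask named integer vector, role label -> 1-based alignment column.
#' @param alignment optional character matrix to validate ranges against.
#' @return the validated mask.
#' @export
columnMask <- function(mask, alignment = NULL) {
  if (is.null(names(mask)) || any(!nzchar(names(mask))))
    stop("mask must be a named integer vector (role -> column)")
  mask <- vapply(mask, as.integer, 0L)
  if (anyDuplicated(mask)) stop("mask must be injective (distinct columns)")
  if (any(mask < 1L)) stop("columns are 1-based")
  if (!is.null(alignment) && any(mask > ncol(alignment)))
    stop("mask column exceeds alignment width")
  mask
}

.GAPLIKE <- function(x) !(x %in% c("A", "C", "G", "U"))

#' Per-column composition and information content
#'
#' Counts A/C/G/U in one alignment column; everything else (gaps and IUPAC
#' ambiguity codes) counts toward the gap fraction. Frequencies are over the
#' non-gap symbols; the information content is `2 + sum(f log2 f)` bits
#' (0 for an even column, 2 for an invariant one). An all-gap column gets
#' `icDefined = FALSE` and `NA` content.
#'
#' @param alignment character matrix from [readAlignment()].
#' @param column 1-based column index.
#' @param smallSampleCorrection subtract the standard e_n = 3/(2 ln2 N)
#'   correction (off by default; intended for small alignments).
#' @return one-row data.frame: `column`, counts `nA..nU`, `gapFraction`,
#'   frequencies `fA..fU`, `informationContent`, `icDefined`.
#' @export
columnStats <- function(alignment, column, smallSampleCorrection = FALSE) {
  stopifnot(column >= 1L, column <= ncol(alignment))
  col <- alignment[, column]
  counts <- vapply(c("A", "C", "G", "U"), function(b) sum(col == b), 0L)
  nGap <- sum(.GAPLIKE(col))
  tot <- sum(counts)
  freqs <- if (tot > 0L) counts / tot else rep(NA_real_, 4L)
  ic <- NA_real_
  if (tot > 0L) {
    f <- freqs[freqs > 0]
    ic <- 2 + sum(f * log2(f))
    if (smallSampleCorrection) ic <- max(0, ic - 3 / (2 * log(2) * tot))
  }
  data.frame(column = as.integer(column),
             nA = counts[["A"]], nC = counts[["C"]],
             nG = counts[["G"]], nU = counts[["U"]],
             gapFraction = nGap / length(col),
             fA = freqs[[1L]], fC = freqs[[2L]], fG = freqs[[3L]], fU = freqs[[4L]],
             informationContent = ic, icDefined = tot > 0L)
}

#' Column statistics for a whole alignment
#'
#' @param alignment character matrix.
#' @param smallSampleCorrection see [columnStats()].
#' @return data.frame, one row per column (suitable for the positional
#'   entropy profile of a sequence logo).
#' @export
columnStatsAll <- function(alignment, smallSampleCorrection = FALSE) {
  do.call(rbind, lapply(seq_len(ncol(alignment)), columnStats,
                        alignment = alignment,
                        smallSampleCorrection = smallSampleCorrection))
}

#' Joint base-combination frequencies of two columns
#'
#' Joint counts over sequences ungapped at both columns (the 16 base
#' combinations), with percentages to 2 decimal places and gap-class counts.
#' Marginals of the joint table equal the single-column frequencies
#' restricted to the co-ungapped subset.
#'
#' @param alignment character matrix.
#' @param colI,colJ 1-based column indices (e.g. the 1b and 1n mask columns).
#' @return list with `counts` (4x4 integer matrix, rows = `colI` base),
#'   `percent` (4x4, to 2 dp), `nCoUngapped`, `gapClasses` (gap at i / at j /
#'   both), and `empty` (TRUE when no co-ungapped sequence exists).
#' @export
pairStats <- function(alignment, colI, colJ) {
  stopifnot(colI >= 1L, colI <= ncol(alignment),
            colJ >= 1L, colJ <= ncol(alignment))
  a <- alignment[, colI]; b <- alignment[, colJ]
  gi <- .GAPLIKE(a); gj <- .GAPLIKE(b)
  ok <- !gi & !gj
  bases <- c("A", "C", "G", "U")
  counts <- matrix(0L, 4L, 4L, dimnames = list(bases, bases))
  for (bi in bases) for (bj in bases)
    counts[bi, bj] <- sum(a[ok] == bi & b[ok] == bj)
  nOK <- sum(ok)
  list(counts = counts,
       percent = if (nOK > 0L) round(100 * counts / nOK, 2L) else counts * NA_real_,
       nCoUngapped = nOK,
       gapClasses = c(gapI = sum(gi & !gj), gapJ = sum(gj & !gi),
                      gapBoth = sum(gi & gj)),
       empty = nOK == 0L)
}
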