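#' Construct a protein multiple alignment
#'
#' @param ids Character vector of row identifiers.
#' @param seqs Character vector of equal-width gapped sequences
#'   (residues plus `'-'`).
#' @return An object of class `protein_alignment`: list with `ids`,
#'   `seqs`, `width` and an attribute `kept_columns` mapping current
#'   columns to the columns of the alignment it was derived from.
#' @export
protein_alignment <- function(ids, seqs) {
  stopifnot(is.character(ids), is.character(seqs),
            length(ids) == length(seqs))
  if (!length(seqs)) stop("alignment must have at least one row", call. = FALSE)
  w <- unique(nchar(seqs))
  if (length(w) != 1L)
    stop("ragged alignment: rows have different widths", call. = FALSE)
  bad <- grepl(sprintf("[^-%sX]", paste(AA20, collapse = "")), seqs)
  if (any(bad))
    stop(sprintf("invalid characters in alignment row %d", which(bad)[1L]),
         call. = FALSE)
  structure(list(ids = ids, seqs = seqs, width = w),
            class = "protein_alignment", kept_columns = seq_len(w))
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat(sprintf("<protein_alignment> %d rows x %d columns\n",
              length(x$ids), x$width))
  invisible(x)
}

aln_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
}

#' Remove gap-dominated alignment columns
#'
#' Columns whose gap fraction is strictly greater than `threshold` are
#' removed; a column with gap fraction exactly at the threshold is kept.
#'
#' @param aln A [protein_alignment()].
#' @param threshold Gap-fraction cutoff (default 0.5).
#' @return A `protein_alignment` whose `kept_columns` attribute gives, for
#'   each retained column, its index in `aln`.  Idempotent.
#' @examples
#' a <- protein_alignment(c("a", "b", "c"), c("A-C", "A-C", "AGC"))
#' filter_gap_columns(a)$width  # 2
#' @export
filter_gap_columns <- function(aln, threshold = 0.5) {
  stopifnot(inherits(aln, "protein_alignment"),
            threshold >= 0, threshold <= 1)
  m <- aln_matrix(aln)
  gap_frac <- colMeans(m == "-")
  keep <- which(gap_frac <= threshold)
  out <- protein_alignment(aln$ids, apply(m[, keep, drop = FALSE], 1L,
                                          paste, collapse = ""))
  attr(out, "kept_columns") <- attr(aln, "kept_columns")[keep]
  out
}

#' Per-column residue frequencies of an alignment
#'
#' @param aln A [protein_alignment()].
#' @return A list, one named proportion vector per column (gap `'-'`
#'   included as a category); each vector sums to 1.
#' @export
column_frequencies <- function(aln) {
  stopifnot(inherits(aln, "protein_alignment"))
  m <- aln_matrix(aln)
  lapply(seq_len(ncol(m)), function(j) {
    tab <- table(m[, j])
    stats::setNames(as.numeric(tab) / nrow(m), names(tab))
  })
}

#' Modal consensus of a multiple alignment
#'
#' Per column, the most frequent non-gap residue; ties are broken by the
#' lexicographically smallest residue.  Gaps count toward the column
#' frequency vectors but are never chosen as the consensus residue.  The
#' input is expected to be gap-filtered already; pass `gap_threshold` to
#' apply [filter_gap_columns()] first.
#'
#' @param aln A [protein_alignment()].
#' @param gap_threshold If non-`NULL`, gap-filter at this threshold before
#'   taking the consensus.
#' @return An object of class `consensus_result`: `consensus` (string),
#'   `kept_columns` (original column indices) and `column_freqs` (list of
#'   named frequency vectors for the kept columns).
#' @examples
#' a <- protein_alignment(c("a", "b", "c"), c("AC", "AC", "GC"))
#' modal_consensus(a)$consensus  # "AC"
#' @export
modal_consensus <- function(aln, gap_threshold = NULL) {
  stopifnot(inherits(aln, "protein_alignment"))
  if (!is.null(gap_threshold)) aln <- filter_gap_columns(aln, gap_threshold)
  if (aln$width == 0L)
    stop("alignment has no columns after gap filtering", call. = FALSE)
  m <- aln_matrix(aln)
  cons <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    col <- col[col != "-"]
    if (!length(col))
      stop(sprintf("column %d is all gaps; filter gap columns first", j),
           call. = FALSE)
    tab <- table(col)
    cands <- sort(names(tab)[tab == max(tab)])
    cands[1L]
  }, character(1L))
  structure(list(consensus = paste(cons, collapse = ""),
                 kept_columns = attr(aln, "kept_columns"),
                 column_freqs = column_frequencies(aln)),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> %d columns\n  %s\n",
              nchar(x$consensus), x$consensus))
  invisible(x)
}
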