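#' Read protein records from a FASTA file
#'
#' Sequences are uppercased; `'*'` stop characters are stripped with a
#' warning; duplicate identifiers are suffixed `_2`, `_3`, ... with a
#' warning.  An empty file or a malformed header produces an error naming
#' the offending line.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id`, `description`, `sequence`.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank))
    stop(sprintf("empty FASTA file: %s", path), call. = FALSE)
  if (!startsWith(trimws(lines[nonblank[1L]]), ">"))
    stop(sprintf("malformed FASTA: line %d does not start a record header",
                 nonblank[1L]), call. = FALSE)
  hdr <- which(startsWith(lines, ">"))
  ids <- character(length(hdr))
  descs <- character(length(hdr))
  seqs <- character(length(hdr))
  bounds <- c(hdr, length(lines) + 1L)
  for (i in seq_along(hdr)) {
    h <- sub("^>", "", lines[hdr[i]])
    if (!nzchar(trimws(h)))
      stop(sprintf("malformed FASTA: empty header at line %d", hdr[i]),
           call. = FALSE)
    parts <- strsplit(trimws(h), "\\s+")[[1L]]
    ids[i] <- parts[1L]
    descs[i] <- if (length(parts) > 1L)
      paste(parts[-1L], collapse = " ") else ""
    body <- lines[seq.int(hdr[i] + 1L, bounds[i + 1L] - 1L)]
    seqs[i] <- toupper(gsub("\\s", "", paste(body, collapse = "")))
  }
  if (any(grepl("*", seqs, fixed = TRUE))) {
    warning("'*' stop characters stripped from sequences")
    seqs <- gsub("*", "", seqs, fixed = TRUE)
  }
  if (!all(nzchar(seqs)))
    stop(sprintf("empty sequence for record %s", ids[!nzchar(seqs)][1L]),
         call. = FALSE)
  if (anyDuplicated(ids)) {
    warning("duplicate record ids; suffix-deduplicated")
    ids <- make.unique(ids, sep = "_")
  }
  data.frame(id = ids, description = descs, sequence = seqs)
}

#' Write protein records to a FASTA file
#'
#' @param records Data frame with `id`, `sequence` and optionally
#'   `description`.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  out <- unlist(lapply(seq_len(nrow(records)), function(i) {
    hdr <- paste0(">", records$id[i],
                  if (!is.null(records$description) &&
                      nzchar(records$description[i]))
                    paste0(" ", records$description[i]) else "")
    s <- records$sequence[i]
    c(hdr, substring(s, seq(1L, nchar(s), width),
                     pmin(nchar(s), seq(width, nchar(s) + width - 1L, width))))
  }))
  writeLines(out, path)
  invisible(path)
}

#' Read a multiple alignment in aligned-FASTA or Clustal format
#'
#' @param path Path to the alignment file.
#' @param format `"auto"` (sniff: a first line starting with `CLUSTAL`
#'   selects Clustal), `"fasta"` or `"clustal"`.  Clustal conservation
#'   lines are ignored and blocks concatenated.
#' @return A [protein_alignment()].  Ragged input is an error.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- trimws(readLines(path, n = 10L, warn = FALSE))
    first <- first[nzchar(first)]
    format <- if (length(first) && grepl("^CLUSTAL", first[1L],
                                         ignore.case = TRUE))
      "clustal" else "fasta"
  }
  if (format == "clustal") {
    aln <- seqinr::read.alignment(path, format = "clustal")
    ids <- aln$nam
    seqs <- toupper(unlist(aln$seq))
  } else {
    lines <- readLines(path, warn = FALSE)
    hdr <- which(startsWith(lines, ">"))
    if (!length(hdr))
      stop(sprintf("no FASTA headers in %s", path), call. = FALSE)
    bounds <- c(hdr, length(lines) + 1L)
    ids <- sub("^>", "", lines[hdr])
    ids <- vapply(strsplit(trimws(ids), "\\s+"), `[`, character(1L), 1L)
    seqs <- vapply(seq_along(hdr), function(i) {
      toupper(gsub("\\s", "",
                   paste(lines[seq.int(hdr[i] + 1L, bounds[i + 1L] - 1L)],
                         collapse = "")))
    }, character(1L))
  }
  seqs <- gsub("*", "", seqs, fixed = TRUE)
  protein_alignment(ids, seqs)
}
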