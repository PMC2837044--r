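# Brute-force pattern-matching oracle: enumerates every element placement
# (explicit start loop, per-element recursion with per-gap length loops,
# no segment collapsing or pruning) and returns the distinct anchor tuples
# as a sorted matrix.  Deliberately naive and structurally unlike the
# package matcher.
oracle_match <- function(pattern, seq) {
  if (is.character(pattern)) pattern <- parse_phi_pattern(pattern)
  elems <- unclass(pattern)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  hits <- list()
  place <- function(i, pos, anchors) {
    if (i > length(elems)) {
      hits[[length(hits) + 1L]] <<- anchors
      return(invisible())
    }
    e <- elems[[i]]
    if (e$kind == "literal") {
      if (pos <= n && (chars[pos] %in% e$set || chars[pos] == "X" ||
                       "X" %in% e$set))
        place(i + 1L, pos + 1L, c(anchors, pos))
    } else {
      for (len in e$min:e$max)
        if (pos + len - 1L <= n) place(i + 1L, pos + len, anchors)
    }
  }
  for (s in seq_len(n)) place(1L, s, integer())
  if (!length(hits)) return(matrix(integer(), ncol = 0L))
  m <- unique(do.call(rbind, hits))
  m[do.call(order, lapply(seq_len(ncol(m)), function(j) m[, j])), ,
    drop = FALSE]
}

anchors_matrix <- function(matches) {
  if (!nrow(matches)) return(matrix(integer(), ncol = 0L))
  m <- do.call(rbind, matches$anchors)
  m[do.call(order, lapply(seq_len(ncol(m)), function(j) m[, j])), ,
    drop = FALSE]
}

# all sequences of a given length over an alphabet, as strings
all_seqs <- function(len, alphabet) {
  grid <- do.call(expand.grid, c(rep(list(alphabet), len),
                                 stringsAsFactors = FALSE))
  apply(as.matrix(grid), 1L, paste, collapse = "")
}
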