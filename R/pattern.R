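#' PHI-BLAST search patterns for the tandem CWCH2 motif
#'
#' Returns the bounded-gap search pattern describing two CWCH2-type C2H2
#' zinc fingers joined by a linker.  The `strict` pattern is the original
#' survey pattern; `loose` widens the wildcard bounds (longer linker, wider
#' intra-cysteine and cysteine-histidine spacings) at the cost of
#' specificity.
#'
#' @param preset `"strict"` or `"loose"`.
#' @return A pattern string suitable for [parse_phi_pattern()].
#' @examples
#' parse_phi_pattern(tcwch2_pattern("strict"))
#' @export
tcwch2_pattern <- function(preset = c("strict", "loose")) {
  switch(match.arg(preset),
    strict = "xCxWx(2,35)Cx(5,15)Hx(2,5)Hx(5,25)CxWx(1,3)Cx(5,17)Hx(2,5)Hx",
    loose  = "xCxWx(1,35)Cx(5,15)Hx(2,5)Hx(5,42)CxWx(1,6)Cx(5,31)Hx(2,5)Hx")
}

#' The 64-residue tandem-CWCH2 consensus sequence
#'
#' Modal consensus over a multiple alignment of tandem CWCH2 motifs
#' (gap-heavy columns removed, most frequent residue per column).  Used
#' throughout the package as the worked example: it contains exactly one
#' tandem CWCH2 motif with an 8-residue linker.
#'
#' @return A 64-character amino-acid string.
#' @examples
#' annotate_tandems(tcwch2_consensus(), spacing_config("strict"))
#' @export
tcwch2_consensus <- function() {
  "LVCKWDGCSEKLFDSPEELVDHVCEDHVGTQLEYTCLWKGCDRFPFKSRYKLIRHIRSHTGEKP"
}

parse_error <- function(text, offset, why) {
  stop(sprintf("pattern parse error at offset %d in %s: %s",
               offset, dQuote(text), why), call. = FALSE)
}

#' Parse a PROSITE/PHI-BLAST-style motif pattern
#'
#' Accepted tokens: an uppercase residue letter (literal), a residue class
#' written `[KR]` or `(K/R)`, the wildcard `x` (one arbitrary residue), and
#' bounded wildcards `x(m)` / `x(m,n)` (between `m` and `n` arbitrary
#' residues).  `X` inside a literal or class stands for "unknown residue"
#' and matches anything.
#'
#' @param text Pattern string, e.g. `"xCxWx(2,35)Cx(5,15)Hx(2,5)Hx"`.
#' @return An object of class `phi_pattern`: a list of elements, each
#'   either `list(kind = "literal", set = <residues>)` or
#'   `list(kind = "gap", min =, max =)`, with attributes `source_text` and
#'   `n_literals`.
#' @seealso [match_pattern()], [render_phi_pattern()]
#' @examples
#' p <- parse_phi_pattern("xCxWx(2,35)C")
#' length(p)            # 5 elements
#' render_phi_pattern(p)
#' @export
parse_phi_pattern <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(text))
    stop("pattern text must be a single non-empty string", call. = FALSE)
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  elems <- list()
  i <- 1L
  ## err_at: offset reported for a malformed repeat spec (the "(" position)
  read_int <- function(i, err_at) {
    j <- i
    while (j <= n && chars[j] %in% as.character(0:9)) j <- j + 1L
    if (j == i)
      parse_error(text, err_at,
                  if (i > n) "unclosed parenthesis" else "expected a number")
    list(value = as.integer(paste(chars[i:(j - 1L)], collapse = "")), next_i = j)
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == "x") {
      if (i < n && chars[i + 1L] == "(") {
        j <- i + 2L
        r1 <- read_int(j, i + 1L)
        m <- r1$value
        j <- r1$next_i
        if (j > n) parse_error(text, i + 1L, "unclosed parenthesis")
        if (chars[j] == ",") {
          r2 <- read_int(j + 1L, i + 1L)
          mx <- r2$value
          j <- r2$next_i
        } else mx <- m
        if (j > n || chars[j] != ")")
          parse_error(text, i + 1L, "unclosed parenthesis")
        if (m < 1L || m > mx)
          parse_error(text, i + 1L,
                      sprintf("invalid repeat bounds (%d,%d)", m, mx))
        elems[[length(elems) + 1L]] <- list(kind = "gap", min = m, max = mx)
        i <- j + 1L
      } else {
        elems[[length(elems) + 1L]] <- list(kind = "gap", min = 1L, max = 1L)
        i <- i + 1L
      }
    } else if (ch %in% c(AA20, "X")) {
      elems[[length(elems) + 1L]] <- list(kind = "literal", set = ch)
      i <- i + 1L
    } else if (ch == "[" || ch == "(") {
      close <- if (ch == "[") "]" else ")"
      j <- i + 1L
      set <- character()
      while (j <= n && chars[j] != close) {
        if (chars[j] == "/" && ch == "(") { j <- j + 1L; next }
        if (!chars[j] %in% c(AA20, "X"))
          parse_error(text, j, sprintf("invalid residue code '%s'", chars[j]))
        set <- c(set, chars[j])
        j <- j + 1L
      }
      if (j > n) parse_error(text, i, "unclosed class")
      if (!length(set)) parse_error(text, i, "empty residue class")
      elems[[length(elems) + 1L]] <- list(kind = "literal", set = unique(set))
      i <- j + 1L
    } else {
      parse_error(text, i, sprintf("unexpected character '%s'", ch))
    }
  }
  if (!length(elems)) stop("pattern has no elements", call. = FALSE)
  structure(elems,
            class = "phi_pattern",
            source_text = text,
            n_literals = sum(vapply(elems, function(e) e$kind == "literal",
                                    logical(1L))))
}

#' Render a parsed pattern back to normalized text
#'
#' `parse_phi_pattern(render_phi_pattern(p))` reproduces `p` element for
#' element; `(K/R)`-style classes normalize to `[KR]`.
#'
#' @param pattern A `phi_pattern`.
#' @return A single pattern string.
#' @export
render_phi_pattern <- function(pattern) {
  stopifnot(inherits(pattern, "phi_pattern"))
  paste(vapply(unclass(pattern), function(e) {
    if (e$kind == "gap") {
      if (e$min == 1L && e$max == 1L) "x"
      else if (e$min == e$max) sprintf("x(%d)", e$min)
      else sprintf("x(%d,%d)", e$min, e$max)
    } else if (length(e$set) == 1L) e$set
    else paste0("[", paste(e$set, collapse = ""), "]")
  }, character(1L)), collapse = "")
}

#' @export
print.phi_pattern <- function(x, ...) {
  cat("<phi_pattern> ", render_phi_pattern(x), "\n", sep = "")
  cat(sprintf("  %d elements: %d literal(s), %d wildcard run(s)\n",
              length(x), attr(x, "n_literals"),
              length(x) - attr(x, "n_literals")))
  invisible(x)
}

## Collapse the element list into literal/gap-run form used by the matcher:
## candidate positions per literal plus cumulative wildcard bounds between
## consecutive literals (and before the first / after the last).
pattern_segments <- function(pattern) {
  kinds <- vapply(unclass(pattern), `[[`, character(1L), "kind")
  lit_idx <- which(kinds == "literal")
  gap_sum <- function(idx) {
    if (!length(idx)) return(c(0L, 0L))
    mins <- vapply(unclass(pattern)[idx], `[[`, integer(1L), "min")
    maxs <- vapply(unclass(pattern)[idx], `[[`, integer(1L), "max")
    c(sum(mins), sum(maxs))
  }
  if (!length(lit_idx)) {
    return(list(n_lit = 0L, total = gap_sum(seq_along(kinds))))
  }
  k <- length(lit_idx)
  lead <- gap_sum(seq_len(lit_idx[1L] - 1L))
  trail <- gap_sum(if (lit_idx[k] < length(kinds))
    (lit_idx[k] + 1L):length(kinds) else integer())
  between <- if (k > 1L) lapply(seq_len(k - 1L), function(j) {
    lo <- lit_idx[j] + 1L
    hi <- lit_idx[j + 1L] - 1L
    gap_sum(if (lo <= hi) lo:hi else integer())
  }) else list()
  sets <- lapply(unclass(pattern)[lit_idx], `[[`, "set")
  list(n_lit = k, sets = sets, lead = lead, trail = trail, between = between)
}

#' Match a bounded-gap pattern against a protein sequence
#'
#' Enumerates anchor placements of the pattern's literal elements.  A match
#' is identified by its anchor tuple (one subject position per literal
#' element); wildcard runs between literals may realize any length within
#' their cumulative bounds.  An `X` in the subject is treated as an unknown
#' residue and satisfies any literal.
#'
#' @param pattern A `phi_pattern` (or a pattern string, parsed on the fly).
#' @param seq Uppercase protein sequence string.
#' @param mode `"all"` returns every distinct anchor tuple, ordered by
#'   (start, anchor tuple); `"nonoverlapping"` greedily selects
#'   span-disjoint matches left to right, preferring the lexicographically
#'   smallest anchor tuple at each start.
#' @return A data frame with one row per match: `start`, `end` (1-based
#'   inclusive span using minimal wildcard context) and a list column
#'   `anchors` of 1-based literal positions.  Zero rows when no match.
#' @examples
#' m <- match_pattern(tcwch2_pattern(), tcwch2_consensus())
#' m$anchors[[1]]   # C, W, C, H, H anchor positions of both fingers
#' @export
match_pattern <- function(pattern, seq, mode = c("all", "nonoverlapping")) {
  mode <- match.arg(mode)
  if (is.character(pattern)) pattern <- parse_phi_pattern(pattern)
  stopifnot(inherits(pattern, "phi_pattern"),
            is.character(seq), length(seq) == 1L)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  seg <- pattern_segments(pattern)
  empty <- data.frame(start = integer(), end = integer())
  empty$anchors <- list()

  if (seg$n_lit == 0L) {
    ## degenerate all-wildcard pattern: one match per feasible span
    lens <- seq.int(seg$total[1L], min(seg$total[2L], n))
    if (!length(lens) || lens[1L] > n) return(empty)
    out <- do.call(rbind, lapply(lens, function(L)
      data.frame(start = seq_len(n - L + 1L), end = seq_len(n - L + 1L) + L - 1L)))
    out <- out[order(out$start, out$end), , drop = FALSE]
    out$anchors <- rep(list(integer()), nrow(out))
    rownames(out) <- NULL
    return(out)
  }

  cand <- lapply(seg$sets, function(s) {
    if ("X" %in% s) which(chars %in% c(s, "X"))
    else which(chars %in% s | chars == "X")
  })
  ## first literal must leave room for the leading wildcard run; last must
  ## leave room for the trailing run
  c1 <- cand[[1L]][cand[[1L]] - 1L >= seg$lead[1L]]
  if (!length(c1)) return(empty)

  k <- seg$n_lit
  acc <- vector("list", 256L)
  n_acc <- 0L
  stack <- integer(k)
  rec <- function(j, pos) {
    stack[j] <<- pos
    if (j == k) {
      if (n - pos >= seg$trail[1L]) {
        n_acc <<- n_acc + 1L
        if (n_acc > length(acc)) length(acc) <<- 2L * n_acc
        acc[[n_acc]] <<- stack[seq_len(k)]
      }
      return(invisible())
    }
    b <- seg$between[[j]]
    nxt <- cand[[j + 1L]]
    nxt <- nxt[nxt - pos - 1L >= b[1L] & nxt - pos - 1L <= b[2L]]
    for (q in nxt) rec(j + 1L, q)
  }
  for (p in c1) rec(1L, p)
  if (!n_acc) return(empty)

  anch <- unique(do.call(rbind, acc[seq_len(n_acc)]))
  start <- anch[, 1L] - seg$lead[1L]
  end <- anch[, k] + seg$trail[1L]
  ord <- do.call(order, c(list(start), lapply(seq_len(k), function(j) anch[, j])))
  anch <- anch[ord, , drop = FALSE]
  out <- data.frame(start = start[ord], end = end[ord])
  out$anchors <- lapply(seq_len(nrow(anch)), function(i) unname(anch[i, ]))
  rownames(out) <- NULL

  if (mode == "nonoverlapping") {
    keep <- logical(nrow(out))
    last_end <- 0L
    for (i in seq_len(nrow(out))) {
      if (out$start[i] > last_end) {
        keep[i] <- TRUE
        last_end <- out$end[i]
      }
    }
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}
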