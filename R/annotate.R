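#' Spacing bounds for C2H2/CWCH2 finger detection and tandem pairing
#'
#' Encodes the residue-count bounds of the tandem-CWCH2 search pattern as
#' per-finger constraints.  All bounds count residues strictly between the
#' two anchors they connect:
#' \describe{
#'   \item{`zf1_cc`, `zf2_cc`}{between the two cysteines of finger 1 / 2
#'     (strict: 4--37 and 3--5; the minimum of 4 corresponds to
#'     C-x-W-x-x-C with no insertion).}
#'   \item{`zf1_ch`, `zf2_ch`}{between the second cysteine and the first
#'     histidine (strict: 5--15 and 5--17).}
#'   \item{`hh`}{between the two histidines (2--5 for both fingers).}
#'   \item{`linker`}{between the last histidine of finger 1 and the first
#'     cysteine of finger 2 (strict: 5--25; loose: 5--42).}
#' }
#' The `loose` preset widens `zf1_cc` to 3--37, `zf2_cc` to 3--8,
#' `zf2_ch` to 5--31 and the linker to 5--42.
#'
#' @param preset `"strict"` or `"loose"`.
#' @param zf1_cc,zf1_ch,zf2_cc,zf2_ch,hh,linker Optional length-2
#'   `c(min, max)` overrides of individual bounds.
#' @return An object of class `spacing_config` (a named list of length-2
#'   integer bounds).
#' @examples
#' spacing_config("strict")
#' spacing_config("strict", linker = c(1, 41))  # widen only the linker
#' @export
spacing_config <- function(preset = c("strict", "loose"),
                           zf1_cc = NULL, zf1_ch = NULL,
                           zf2_cc = NULL, zf2_ch = NULL,
                           hh = NULL, linker = NULL) {
  preset <- match.arg(preset)
  cfg <- if (preset == "strict") {
    list(zf1_cc = c(4L, 37L), zf1_ch = c(5L, 15L),
         zf2_cc = c(3L, 5L),  zf2_ch = c(5L, 17L),
         hh = c(2L, 5L), linker = c(5L, 25L))
  } else {
    list(zf1_cc = c(3L, 37L), zf1_ch = c(5L, 15L),
         zf2_cc = c(3L, 8L),  zf2_ch = c(5L, 31L),
         hh = c(2L, 5L), linker = c(5L, 42L))
  }
  over <- list(zf1_cc = zf1_cc, zf1_ch = zf1_ch, zf2_cc = zf2_cc,
               zf2_ch = zf2_ch, hh = hh, linker = linker)
  for (nm in names(over)) {
    if (!is.null(over[[nm]])) {
      b <- as.integer(over[[nm]])
      if (length(b) != 2L || any(is.na(b)) || b[1L] > b[2L] || b[1L] < 0L)
        stop(sprintf("invalid bounds for %s", nm), call. = FALSE)
      cfg[[nm]] <- b
    }
  }
  structure(c(cfg, list(preset = preset)), class = "spacing_config")
}

#' @export
print.spacing_config <- function(x, ...) {
  cat(sprintf("<spacing_config> preset=%s\n", x$preset))
  for (nm in c("zf1_cc", "zf1_ch", "zf2_cc", "zf2_ch", "hh", "linker"))
    cat(sprintf("  %-7s %2d..%d\n", nm, x[[nm]][1L], x[[nm]][2L]))
  invisible(x)
}

as_residues <- function(seq) {
  if (is.character(seq) && length(seq) == 1L)
    strsplit(seq, "", fixed = TRUE)[[1L]]
  else if (is.character(seq)) seq
  else stop("sequence must be a character string", call. = FALSE)
}

seq_of <- function(x) {
  ## accept a bare sequence string or a record data frame row / list with
  ## a $sequence field
  if (is.list(x) && !is.null(x$sequence)) x$sequence else x
}

in_bounds <- function(gap, b) gap >= b[1L] & gap <= b[2L]

#' Detect C2H2 zinc fingers in a protein sequence
#'
#' Scans left to right for non-overlapping Cys-Xn-Cys-Xn-His-Xn-His units.
#' At each candidate first cysteine the lexicographically smallest feasible
#' `(c2, h1, h2)` assignment is taken; if none exists the scan moves to the
#' next cysteine.  Detection uses the per-position union of the ZF1 and ZF2
#' bounds in `cfg`; finger-specific bounds are enforced later, when pairing
#' (see [annotate_tandems()]).
#'
#' @param seq Protein sequence string (or a record with a `$sequence`
#'   field).
#' @param cfg A [spacing_config()].
#' @return A data frame with one row per finger: 1-based anchor positions
#'   `c1`, `c2`, `h1`, `h2` and logical `is_cwch2` (tryptophan at
#'   `c1 + 2`).
#' @examples
#' find_c2h2(tcwch2_consensus(), spacing_config("strict"))
#' @export
find_c2h2 <- function(seq, cfg = spacing_config("strict")) {
  stopifnot(inherits(cfg, "spacing_config"))
  ch <- as_residues(seq_of(seq))
  cc <- c(min(cfg$zf1_cc[1L], cfg$zf2_cc[1L]), max(cfg$zf1_cc[2L], cfg$zf2_cc[2L]))
  chb <- c(min(cfg$zf1_ch[1L], cfg$zf2_ch[1L]), max(cfg$zf1_ch[2L], cfg$zf2_ch[2L]))
  hhb <- cfg$hh
  cpos <- which(ch == "C")
  hpos <- which(ch == "H")
  res <- list()
  from <- 1L
  for (c1 in cpos) {
    if (c1 < from) next
    c2s <- cpos[in_bounds(cpos - c1 - 1L, cc)]
    hit <- NULL
    for (c2 in c2s) {
      h1s <- hpos[in_bounds(hpos - c2 - 1L, chb)]
      for (h1 in h1s) {
        h2s <- hpos[in_bounds(hpos - h1 - 1L, hhb)]
        if (length(h2s)) {
          hit <- c(c1, c2, h1, h2s[1L])
          break
        }
      }
      if (!is.null(hit)) break
    }
    if (!is.null(hit)) {
      res[[length(res) + 1L]] <- hit
      from <- hit[4L] + 1L
    }
  }
  if (!length(res)) {
    return(data.frame(c1 = integer(), c2 = integer(), h1 = integer(),
                      h2 = integer(), is_cwch2 = logical()))
  }
  m <- do.call(rbind, res)
  data.frame(c1 = m[, 1L], c2 = m[, 2L], h1 = m[, 3L], h2 = m[, 4L],
             is_cwch2 = m[, 1L] + 2L < m[, 2L] & ch[m[, 1L] + 2L] == "W")
}

#' Pair CWCH2 fingers into tandem CWCH2 motifs and extract their features
#'
#' Adjacent finger pairs from [find_c2h2()] are accepted as one tandem
#' motif when both fingers carry the CWCH2 tryptophan (unless
#' `require_w = FALSE`), each finger satisfies its finger-specific spacing
#' bounds, and the linker (residues strictly between the last histidine of
#' the first finger and the first cysteine of the second) is within the
#' configured bounds.  A finger joins at most one tandem; pairing is
#' resolved left to right.
#'
#' @param seq Protein sequence string (or record with `$sequence`).
#' @param cfg A [spacing_config()].
#' @param require_w If `FALSE`, pairing does not require the CWCH2
#'   tryptophans (used for conservation scoring, where the finger pair must
#'   be locatable even when a tryptophan has mutated away).
#' @return A data frame with one row per tandem: the eight anchor positions
#'   (`zf1_c1` ... `zf2_h2`, 1-based), per-finger tryptophan flags
#'   `zf1_cwch2`/`zf2_cwch2`, `linker_len`, `linker_seq`, the residues
#'   `phi1`/`phi2` immediately C-terminal of each finger's first histidine,
#'   intra-cysteine insertion lengths `extra1`/`extra2` (residues beyond the
#'   canonical four), and `has_tgekp` on the linker.
#' @examples
#' annotate_tandems(tcwch2_consensus(), spacing_config("strict"))
#' @export
annotate_tandems <- function(seq, cfg = spacing_config("strict"),
                             require_w = TRUE) {
  stopifnot(inherits(cfg, "spacing_config"))
  ch <- as_residues(seq_of(seq))
  f <- find_c2h2(ch, cfg)
  out <- list()
  i <- 1L
  while (i + 1L <= nrow(f)) {
    z1 <- f[i, ]
    z2 <- f[i + 1L, ]
    linker <- z2$c1 - z1$h2 - 1L
    ok <- (!require_w || (z1$is_cwch2 && z2$is_cwch2)) &&
      in_bounds(z1$c2 - z1$c1 - 1L, cfg$zf1_cc) &&
      in_bounds(z1$h1 - z1$c2 - 1L, cfg$zf1_ch) &&
      in_bounds(z2$c2 - z2$c1 - 1L, cfg$zf2_cc) &&
      in_bounds(z2$h1 - z2$c2 - 1L, cfg$zf2_ch) &&
      in_bounds(linker, cfg$linker)
    if (ok) {
      lseq <- if (linker > 0L)
        paste(ch[(z1$h2 + 1L):(z2$c1 - 1L)], collapse = "") else ""
      out[[length(out) + 1L]] <- data.frame(
        zf1_c1 = z1$c1, zf1_c2 = z1$c2, zf1_h1 = z1$h1, zf1_h2 = z1$h2,
        zf2_c1 = z2$c1, zf2_c2 = z2$c2, zf2_h1 = z2$h1, zf2_h2 = z2$h2,
        zf1_cwch2 = z1$is_cwch2, zf2_cwch2 = z2$is_cwch2,
        linker_len = linker, linker_seq = lseq,
        phi1 = ch[z1$h1 + 1L], phi2 = ch[z2$h1 + 1L],
        extra1 = max(0L, z1$c2 - z1$c1 - 1L - 4L),
        extra2 = max(0L, z2$c2 - z2$c1 - 1L - 4L),
        has_tgekp = has_tgekp(lseq))
      i <- i + 2L
    } else {
      i <- i + 1L
    }
  }
  if (!length(out)) {
    return(data.frame(zf1_c1 = integer(), zf1_c2 = integer(),
                      zf1_h1 = integer(), zf1_h2 = integer(),
                      zf2_c1 = integer(), zf2_c2 = integer(),
                      zf2_h1 = integer(), zf2_h2 = integer(),
                      zf1_cwch2 = logical(), zf2_cwch2 = logical(),
                      linker_len = integer(), linker_seq = character(),
                      phi1 = character(), phi2 = character(),
                      extra1 = integer(), extra2 = integer(),
                      has_tgekp = logical()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Test a segment for the canonical TGE(K/R)P linker
#'
#' The five-residue Thr-Gly-Glu-(Lys|Arg)-Pro linker is the canonical
#' inter-finger linker of DNA-binding C2H2 arrays; tandem-CWCH2 linkers
#' characteristically lack it.
#'
#' @param segment Character vector of sequence segments.
#' @return Logical vector: does each segment contain T,G,E,(K or R),P
#'   consecutively?
#' @examples
#' has_tgekp(c("HTGEKP", "TGERP", "TGEQP"))
#' @export
has_tgekp <- function(segment) {
  grepl("TGE[KR]P", segment, fixed = FALSE)
}

#' Parse PROSITE-style aligned-segment headers
#'
#' Headers of the form `"NAME/start-end"` (as in the PDOC00028 C2H2
#' alignment) carry the 1-based inclusive coordinates of each aligned
#' finger segment on its parent protein.
#'
#' @param x Character vector of headers.
#' @return A data frame with columns `id`, `start`, `end`.
#' @examples
#' parse_segment_headers(c("GLI1_HUMAN/301-330", "GLI1_HUMAN/337-366"))
#' @export
parse_segment_headers <- function(x) {
  m <- regmatches(x, regexec("^(.*)/([0-9]+)-([0-9]+)$", x))
  bad <- which(vapply(m, length, integer(1L)) != 4L)
  if (length(bad))
    stop(sprintf("malformed segment header: %s", dQuote(x[bad[1L]])),
         call. = FALSE)
  data.frame(id = vapply(m, `[`, character(1L), 2L),
             start = as.integer(vapply(m, `[`, character(1L), 3L)),
             end = as.integer(vapply(m, `[`, character(1L), 4L)))
}

#' Inter-finger linker lengths from aligned-segment coordinates
#'
#' For each pair of consecutive finger segments of one protein, the linker
#' length is the residue count strictly between them
#' (`next start - previous end - 1`).  Lengths above `max_len` (default 41)
#' are discarded as artifacts of missed intervening fingers; negative
#' lengths are discarded with a warning.
#'
#' @param segments A data frame with columns `start`, `end` (1-based
#'   inclusive) and optionally `id` (protein identifier; linkers are only
#'   formed within one protein).  See [parse_segment_headers()].
#' @param max_len Upper exclusion bound on reported lengths.
#' @return Integer vector of linker lengths, pooled over proteins.
#' @examples
#' linker_from_segment_headers(data.frame(start = c(301, 337),
#'                                        end = c(330, 366)))  # 6
#' @export
linker_from_segment_headers <- function(segments, max_len = 41L) {
  stopifnot(is.data.frame(segments),
            all(c("start", "end") %in% names(segments)))
  ids <- if ("id" %in% names(segments)) segments$id else rep("*", nrow(segments))
  lens <- integer()
  n_neg <- 0L
  for (g in split(segments[c("start", "end")], ids)) {
    if (nrow(g) < 2L) next
    if (is.unsorted(g$start, strictly = TRUE))
      stop("segments must be sorted by start within a protein", call. = FALSE)
    l <- g$start[-1L] - g$end[-nrow(g)] - 1L
    n_neg <- n_neg + sum(l < 0L)
    lens <- c(lens, l[l >= 0L & l <= max_len])
  }
  if (n_neg)
    warning(sprintf("%d negative linker length(s) discarded", n_neg))
  lens
}
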