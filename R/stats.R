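#' Residue frequency table
#'
#' @param x Character vector of single residues, or a named numeric vector
#'   of counts.
#' @return An object of class `freq_table`: list with `counts` (named
#'   integer), `n` (total) and `freq` (named proportions summing to 1).
#' @examples
#' freq_table(c("V", "I", "V", "L"))
#' @export
freq_table <- function(x) {
  counts <- if (is.character(x)) {
    tab <- table(x)
    stats::setNames(as.integer(tab), names(tab))
  } else if (is.numeric(x) && !is.null(names(x))) {
    stopifnot(all(x >= 0))
    x
  } else stop("x must be residues or named counts", call. = FALSE)
  n <- sum(counts)
  if (n <= 0) stop("frequency table needs at least one observation",
                   call. = FALSE)
  structure(list(counts = counts, n = n, freq = counts / n),
            class = "freq_table")
}

#' @export
print.freq_table <- function(x, digits = 3, ...) {
  cat(sprintf("<freq_table> n=%s\n", format(x$n)))
  print(round(sort(x$freq, decreasing = TRUE), digits))
  invisible(x)
}

#' Summarize a sample of linker lengths
#'
#' @param lengths Non-negative integer vector of linker lengths (residues).
#' @return An object of class `linker_stats`: `n`, sample `mean`, sample
#'   standard deviation `sd` (denominator n-1; `NA` when n < 2), `min`,
#'   `max`.
#' @examples
#' linker_summary(c(6, 8, 10))  # mean 8, sd 2
#' @export
linker_summary <- function(lengths) {
  if (!length(lengths)) stop("no linker lengths supplied", call. = FALSE)
  if (any(lengths < 0)) stop("linker lengths must be non-negative",
                             call. = FALSE)
  structure(list(n = length(lengths), mean = mean(lengths),
                 sd = if (length(lengths) > 1L) stats::sd(lengths) else NA_real_,
                 min = min(lengths), max = max(lengths)),
            class = "linker_stats")
}

#' @export
print.linker_stats <- function(x, ...) {
  cat(sprintf("<linker_stats> n=%d  mean=%.2f aa  sd=%s  range=%d..%d\n",
              x$n, x$mean,
              if (is.na(x$sd)) "NA" else sprintf("%.2f", x$sd),
              x$min, x$max))
  invisible(x)
}

format_p <- function(p) {
  if (p < 1e-300) "< 1e-300" else format(p, digits = 4)
}

motif_test <- function(method, statistic, p_value, extras = list()) {
  p_value <- min(1, max(0, p_value))
  structure(list(method = method, statistic = statistic,
                 p_value = p_value, p_string = format_p(p_value),
                 extras = extras),
            class = "motif_test")
}

#' @export
print.motif_test <- function(x, ...) {
  cat(sprintf("<motif_test> %s\n  statistic = %.4g, p = %s\n",
              x$method, x$statistic, x$p_string))
  invisible(x)
}

#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two samples.  When the pooled size is at most 12
#' and there are no ties, the two-sided p-value is computed by exact
#' enumeration of all rank assignments; otherwise a normal approximation
#' with tie correction and continuity correction is used.  The reported U
#' statistic is for sample `a`.
#'
#' @param a,b Numeric samples.
#' @param exact Force (`TRUE`) or suppress (`FALSE`) the exact branch;
#'   default `NULL` auto-selects as described.  `exact = TRUE` with ties
#'   or a pooled size over 12 is an error.
#' @return A `motif_test` with `statistic` = U(a); `extras` carries `U`,
#'   `mu` (null mean of U), `exact`, and `z` for the approximate branch.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(a, b, exact = NULL) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty",
                                     call. = FALSE)
  n1 <- length(a)
  n2 <- length(b)
  N <- n1 + n2
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  no_ties <- !anyDuplicated(pooled)
  if (isTRUE(exact) && (N > 12L || !no_ties))
    stop("exact enumeration requires pooled size <= 12 and no ties",
         call. = FALSE)
  use_exact <- if (is.null(exact)) N <= 12L && no_ties else exact
  if (use_exact) {
    ranks <- seq_len(N)
    combs <- utils::combn(N, n1)
    Uall <- colSums(matrix(ranks[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(Uall - mu) >= abs(U - mu) - 1e-9)
    return(motif_test("Mann-Whitney U (exact)", U, p,
                      extras = list(U = U, mu = mu, exact = TRUE)))
  }
  tie <- table(r)
  s2 <- n1 * n2 / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
  if (s2 <= 0) {
    return(motif_test("Mann-Whitney U (normal approximation)", U, 1,
                      extras = list(U = U, mu = mu, exact = FALSE, z = 0)))
  }
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(s2)
  if (U == mu) z <- 0
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  motif_test("Mann-Whitney U (normal approximation)", U, p,
             extras = list(U = U, mu = mu, exact = FALSE, z = z,
                           tie_correction = sum(tie^3 - tie)))
}

#' Two-sided F test for equality of variances
#'
#' @param a,b Numeric samples with at least two observations each.
#' @return A `motif_test` with `statistic` = `var(a)/var(b)` (sample
#'   variances) and a two-sided p-value from the F distribution with
#'   `(length(a)-1, length(b)-1)` degrees of freedom.
#' @examples
#' f_variance_test(rnorm(10), rnorm(10, sd = 3))
#' @export
f_variance_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least two observations", call. = FALSE)
  v1 <- stats::var(a)
  v2 <- stats::var(b)
  if (v2 == 0) stop("zero variance in denominator sample", call. = FALSE)
  F <- v1 / v2
  df1 <- length(a) - 1L
  df2 <- length(b) - 1L
  p <- min(1, 2 * min(stats::pf(F, df1, df2),
                      stats::pf(F, df1, df2, lower.tail = FALSE)))
  motif_test("F test of variances", F, p,
             extras = list(df1 = df1, df2 = df2, var_a = v1, var_b = v2))
}

#' Chi-squared test of residue composition against a background
#'
#' Collapses an observed residue frequency table into two categories --
#' inside versus outside a hydrophobic residue set -- and tests the counts
#' against expectations from a background frequency table (goodness of
#' fit, 1 degree of freedom).  The full per-residue goodness-of-fit test
#' over the background's residue set is returned as a secondary statistic
#' in `extras$per_residue`.
#'
#' @param observed A `freq_table` of observed residues.
#' @param background A `freq_table` of background residue frequencies; must
#'   cover every observed residue.
#' @param hydrophobic_set Residues forming the focal category (e.g.
#'   `c("V","L","I")`).
#' @return A `motif_test`.
#' @examples
#' obs <- freq_table(c(rep("V", 45), rep("I", 46), rep("A", 9)))
#' chi2_vs_background(obs, pdoc00028_phi_freqs(), c("V", "L", "I", "M"))
#' @export
chi2_vs_background <- function(observed, background,
                               hydrophobic_set = c("V", "L", "I")) {
  stopifnot(inherits(observed, "freq_table"),
            inherits(background, "freq_table"))
  uncovered <- setdiff(names(observed$counts)[observed$counts > 0],
                       names(background$freq)[background$freq > 0])
  if (length(uncovered))
    stop(sprintf("background has zero frequency for observed residue(s): %s",
                 paste(uncovered, collapse = ",")), call. = FALSE)
  obs_in <- sum(observed$counts[names(observed$counts) %in% hydrophobic_set])
  p_in <- sum(background$freq[names(background$freq) %in% hydrophobic_set])
  if (p_in <= 0 || p_in >= 1)
    stop("expected count of zero in a category", call. = FALSE)
  gof <- suppressWarnings(
    stats::chisq.test(c(obs_in, observed$n - obs_in), p = c(p_in, 1 - p_in)))
  full_counts <- stats::setNames(rep(0, length(background$freq)),
                                 names(background$freq))
  full_counts[names(observed$counts)] <- observed$counts
  per_res <- suppressWarnings(
    stats::chisq.test(full_counts, p = background$freq, rescale.p = TRUE))
  motif_test("chi-squared vs background (2-category)",
             unname(gof$statistic), unname(gof$p.value),
             extras = list(df = 1L, observed_in = obs_in,
                           expected_in = observed$n * p_in,
                           background_rate = p_in,
                           per_residue = list(
                             statistic = unname(per_res$statistic),
                             df = unname(per_res$parameter),
                             p_value = unname(per_res$p.value))))
}

#' Residue frequencies at the phi1 and phi2 positions
#'
#' The phi positions are the residues immediately C-terminal of the first
#' histidine of each finger of a tandem CWCH2 motif; they are strongly
#' biased toward the small hydrophobic residues V/L/I (and M at phi2).
#'
#' @param tandems A tandem annotation data frame from [annotate_tandems()]
#'   (rows possibly pooled over records); needs columns `phi1` and `phi2`.
#' @return A list with `freq_table` components `phi1` and `phi2`.
#' @export
phi_frequency <- function(tandems) {
  stopifnot(is.data.frame(tandems))
  if (!nrow(tandems)) stop("no tandem motifs supplied", call. = FALSE)
  list(phi1 = freq_table(tandems$phi1), phi2 = freq_table(tandems$phi2))
}

#' Background phi-position frequencies of general C2H2 fingers
#'
#' Frequencies of the residue following the first zinc-chelating histidine
#' in a large general-C2H2 alignment (the PROSITE PDOC00028 compilation):
#' V 4.2%, L 9.5%, I 5.3%, M 7.8%.  The remaining mass is spread uniformly
#' over the other 16 standard residues, since only the hydrophobic entries
#' of the compilation are tabulated.
#'
#' @return A `freq_table` (frequencies scaled to counts per 1000).
#' @export
pdoc00028_phi_freqs <- function() {
  f <- c(V = 0.042, L = 0.095, I = 0.053, M = 0.078)
  rest <- setdiff(AA20, names(f))
  f <- c(f, stats::setNames(rep((1 - sum(f)) / length(rest), length(rest)),
                            rest))
  freq_table(f * 1000)
}

#' Tryptophan conservation of a tandem CWCH2 motif across a gene family
#'
#' For each sequence, the finger pair is located with the CWCH2 tryptophan
#' requirement relaxed (so a pair whose tryptophan has mutated away is
#' still found) and scored as conserved when both fingers carry tryptophan
#' two residues after their first cysteine.  Sequences in which no finger
#' pair can be located are counted as non-conserved, with a warning.
#'
#' @param family Family name carried into the report.
#' @param records Data frame of protein records (columns `id`,
#'   `sequence`), or a character vector of sequences.
#' @param cfg A [spacing_config()].
#' @param pair_index Which tandem (in sequence order) to score, for
#'   families with more than one tandem motif per protein.
#' @return An object of class `conservation_report`: `family`, `n`,
#'   `conserved` (count) and `percent`.
#' @examples
#' recs <- c(tcwch2_consensus(), sub("W", "G", tcwch2_consensus()))
#' tryptophan_conservation("demo", recs)
#' @export
tryptophan_conservation <- function(family, records,
                                    cfg = spacing_config("strict"),
                                    pair_index = 1L) {
  seqs <- if (is.data.frame(records)) records$sequence else records
  if (!length(seqs)) stop("records must be non-empty", call. = FALSE)
  n_missing <- 0L
  conserved <- vapply(seqs, function(s) {
    td <- annotate_tandems(s, cfg, require_w = FALSE)
    if (nrow(td) < pair_index) {
      n_missing <<- n_missing + 1L
      return(FALSE)
    }
    td$zf1_cwch2[pair_index] && td$zf2_cwch2[pair_index]
  }, logical(1L), USE.NAMES = FALSE)
  if (n_missing)
    warning(sprintf("%d record(s) with no locatable finger pair counted as non-conserved",
                    n_missing))
  structure(list(family = family, n = length(seqs),
                 conserved = sum(conserved),
                 percent = 100 * sum(conserved) / length(seqs)),
            class = "conservation_report")
}

#' @export
print.conservation_report <- function(x, ...) {
  cat(sprintf("<conservation_report> %s: %d/%d sequences with both tryptophans (%.1f%%)\n",
              x$family, x$conserved, x$n, x$percent))
  invisible(x)
}
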