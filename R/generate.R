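## Discretized truncated-normal machinery for linker lengths.  The target
## mean/sd describe the *generated* lengths, so the underlying normal is
## moment-matched: with a hard lower bound near the mean, naive
## round-and-reject sampling at the nominal parameters would inflate the
## realized mean by ~0.5 aa, defeating parameter-recovery checks.
disc_trunc_pmf <- function(mu, sigma, lo, hi) {
  k <- lo:hi
  w <- stats::pnorm(k + 0.5, mu, sigma) - stats::pnorm(k - 0.5, mu, sigma)
  if (sum(w) <= 0) stop("degenerate linker distribution", call. = FALSE)
  w / sum(w)
}

match_linker_model <- function(mean, sd, lo, hi) {
  if (lo > hi) stop("linker model has min > max", call. = FALSE)
  k <- lo:hi
  obj <- function(par) {
    p <- disc_trunc_pmf(par[1L], exp(par[2L]), lo, hi)
    m <- sum(k * p)
    s <- sqrt(max(0, sum(k^2 * p) - m^2))
    (m - mean)^2 + (s - sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  pmf <- disc_trunc_pmf(fit$par[1L], exp(fit$par[2L]), lo, hi)
  list(mean = mean, sd = sd, min = lo, max = hi,
       mu = fit$par[1L], sigma = exp(fit$par[2L]),
       support = k, pmf = pmf,
       realized_mean = sum(k * pmf),
       realized_sd = sqrt(sum(k^2 * pmf) - sum(k * pmf)^2))
}

## phi-position frequency presets.  Printed values cover V/L/I (phi1) and
## V/L/I/M (phi2); the remainder is spread uniformly over the other
## standard residues excluding C and H, which the generator must not place
## at a phi position lest they create spurious zinc-finger anchors.
phi_table <- function(named) {
  rest <- setdiff(AA20, c(names(named), "C", "H"))
  p <- c(named, stats::setNames(rep((1 - sum(named)) / length(rest),
                                    length(rest)), rest))
  p
}

#' Phi-position residue frequency presets of the tandem CWCH2 motif
#'
#' Observed frequencies at the hydrophobic-biased positions following the
#' first histidine of finger 1 (`phi1`: V 34.1%, L 22.0%, I 35.3%) and
#' finger 2 (`phi2`: V 14.3%, L 14.3%, I 39.1%, M 24.2%); the untabulated
#' remainder is spread uniformly over the other residues (excluding C and
#' H, see [generator_config()]).
#'
#' @param position 1 or 2.
#' @return Named proportion vector summing to 1.
#' @export
phi_freq_preset <- function(position = 1L) {
  if (position == 1L) phi_table(c(V = 0.341, L = 0.220, I = 0.353))
  else if (position == 2L)
    phi_table(c(V = 0.143, L = 0.143, I = 0.391, M = 0.242))
  else stop("position must be 1 or 2", call. = FALSE)
}

decoy_kinds <- c("w_to_g", "spacing_violation", "single_finger")

#' Configuration of the synthetic zinc-finger protein generator
#'
#' Defines the study conditions the generator emulates: tandem-CWCH2
#' records whose linker lengths follow a discretized truncated normal
#' (preset `"tcwch2"`: mean 11.8, sd 4.4 aa on 5..37; preset
#' `"background"`: mean 8.1, sd 5.0 aa on 1..41, mimicking the general
#' C2H2 compilation), phi-position residues drawn from
#' [phi_freq_preset()], occasional intra-cysteine insertions, and --
#' for background linkers -- the canonical TGE(K/R)P pentamer present in a
#' configurable fraction of sequences (default 0.65 under the background
#' preset).  The underlying normal is moment-matched so that the generated
#' linker lengths have the stated mean and sd on the stated support.
#'
#' @param seed Integer seed; generation is fully reproducible given the
#'   configuration.
#' @param n_records Number of records.
#' @param linker_preset `"tcwch2"` or `"background"`.
#' @param linker_mean,linker_sd,linker_min,linker_max Override the linker
#'   model of the preset.
#' @param phi1_freqs,phi2_freqs Named proportion vectors over residues
#'   (defaults: [phi_freq_preset()]).
#' @param tgekp_rate Fraction of sequences whose linker carries TGE(K/R)P
#'   (default 0.65 under the background preset, else 0).  Insertion
#'   replaces the first five linker residues and is therefore only
#'   possible in linkers of length >= 5; the per-linker insertion odds are
#'   raised accordingly so the sequence-level rate matches.
#' @param extra1_probs Distribution of the ZF1 intra-cysteine insertion
#'   length over 0..30 (default: no insertion with probability 0.85,
#'   geometric tail beyond).
#' @param extra2_probs Distribution of the ZF2 insertion length over 0..1.
#' @param decoy_fractions Named proportions over
#'   `c("w_to_g", "spacing_violation", "single_finger")`; the remainder of
#'   records are intact (`"none"`).
#' @param flank_len Length-2 range of random flanking residues on each
#'   side.
#' @return An object of class `generator_config`.
#' @seealso [generate_dataset()], [generator_spacing()]
#' @export
generator_config <- function(seed,
                             n_records = 100L,
                             linker_preset = c("tcwch2", "background"),
                             linker_mean = NULL, linker_sd = NULL,
                             linker_min = NULL, linker_max = NULL,
                             phi1_freqs = phi_freq_preset(1L),
                             phi2_freqs = phi_freq_preset(2L),
                             tgekp_rate = NULL,
                             extra1_probs = NULL,
                             extra2_probs = c(`0` = 0.9, `1` = 0.1),
                             decoy_fractions = numeric(),
                             flank_len = c(3L, 15L)) {
  linker_preset <- match.arg(linker_preset)
  stopifnot(is.numeric(seed), length(seed) == 1L, seed == floor(seed),
            n_records >= 1L)
  def <- if (linker_preset == "tcwch2") c(11.8, 4.4, 5, 37)
         else c(8.1, 5.0, 1, 41)
  lm <- match_linker_model(
    if (is.null(linker_mean)) def[1L] else linker_mean,
    if (is.null(linker_sd)) def[2L] else linker_sd,
    as.integer(if (is.null(linker_min)) def[3L] else linker_min),
    as.integer(if (is.null(linker_max)) def[4L] else linker_max))
  if (is.null(tgekp_rate))
    tgekp_rate <- if (linker_preset == "background") 0.65 else 0
  stopifnot(tgekp_rate >= 0, tgekp_rate <= 1)
  for (p in list(phi1_freqs, phi2_freqs))
    stopifnot(abs(sum(p) - 1) < 1e-6, all(p >= 0), !is.null(names(p)))
  if (is.null(extra1_probs)) {
    extra1_probs <- c(0.85, 0.15 * 0.4 * 0.6^(0:29) / sum(0.4 * 0.6^(0:29)))
    names(extra1_probs) <- 0:30
  }
  stopifnot(abs(sum(extra1_probs) - 1) < 1e-6,
            abs(sum(extra2_probs) - 1) < 1e-6)
  if (length(decoy_fractions)) {
    stopifnot(all(names(decoy_fractions) %in% decoy_kinds),
              all(decoy_fractions >= 0), sum(decoy_fractions) <= 1)
  }
  stopifnot(length(flank_len) == 2L, flank_len[1L] >= 1L,
            flank_len[1L] <= flank_len[2L])
  structure(list(seed = as.integer(seed), n_records = as.integer(n_records),
                 linker_preset = linker_preset, linker_model = lm,
                 phi1_freqs = phi1_freqs, phi2_freqs = phi2_freqs,
                 tgekp_rate = tgekp_rate,
                 extra1_probs = extra1_probs, extra2_probs = extra2_probs,
                 decoy_fractions = decoy_fractions,
                 flank_len = as.integer(flank_len)),
            class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("<generator_config> seed=%d  n=%d  linker=%s(%.1f±%.1f aa on %d..%d)\n",
              x$seed, x$n_records, x$linker_preset, x$linker_model$mean,
              x$linker_model$sd, x$linker_model$min, x$linker_model$max))
  cat(sprintf("  tgekp_rate=%.2f  decoys: %s\n", x$tgekp_rate,
              if (length(x$decoy_fractions))
                paste(names(x$decoy_fractions), x$decoy_fractions,
                      sep = "=", collapse = ", ") else "none"))
  invisible(x)
}

#' Spacing configuration matched to a generator configuration
#'
#' The spacing under which generated records are guaranteed recoverable:
#' the strict preset, with the linker bounds widened to the generator's
#' linker support when that support extends outside the strict search
#' pattern (as the background preset's 1..41 does).  Under the `"tcwch2"`
#' preset this is exactly the strict preset; linker draws beyond its
#' pairing bound are resampled by the generator's self-check.
#'
#' @param cfg A [generator_config()].
#' @return A [spacing_config()].
#' @export
generator_spacing <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  strict <- spacing_config("strict")
  lo <- cfg$linker_model$min
  hi <- cfg$linker_model$max
  if (lo >= strict$linker[1L] && hi <= strict$linker[2L] ||
      cfg$linker_preset == "tcwch2")
    strict
  else spacing_config("strict", linker = c(min(lo, strict$linker[1L]),
                                           max(hi, strict$linker[2L])))
}

rand_res <- function(n) {
  if (n <= 0L) return(character())
  sample(FREE_AA, n, replace = TRUE)
}

sample_from <- function(probs, n = 1L) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

## assemble one record; returns list(seq = chr vector, truth = one-row df)
build_record <- function(cfg, id, linker_len, phi1, phi2, extra1, extra2,
                         tgekp) {
  f1 <- sample(cfg$flank_len[1L]:cfg$flank_len[2L], 1L)
  f2 <- sample(cfg$flank_len[1L]:cfg$flank_len[2L], 1L)
  make_zf <- function(extra, phi) {
    s_ch <- sample(5:15, 1L)
    spacer <- rand_res(s_ch)
    spacer[ceiling(s_ch / 2)] <- "F"   # the conserved hydrophobic F of C2H2
    c(
      "C", rand_res(1L), "W", rand_res(2L + extra), "C",
      spacer,
      "H", phi, rand_res(2L), "H")
  }
  zf1 <- make_zf(extra1, phi1)
  zf2 <- make_zf(extra2, phi2)
  linker <- rand_res(linker_len)
  if (tgekp) {
    stopifnot(linker_len >= 5L)
    linker[1:5] <- c("T", "G", "E", sample(c("K", "R"), 1L), "P")
  }
  ## truth records actual pentamer presence (insertion or, very rarely, a
  ## spontaneous occurrence in the random linker residues)
  tgekp <- has_tgekp(paste(linker, collapse = ""))
  seqv <- c(rand_res(f1), zf1, linker, zf2, rand_res(f2))
  ## planted anchor arithmetic
  zf1_c1 <- f1 + 1L
  zf1_c2 <- zf1_c1 + 4L + extra1 + 1L            # intra count 4+extra
  zf1_h1 <- f1 + which(zf1 == "H")[1L]
  zf1_h2 <- zf1_h1 + 4L
  base2 <- f1 + length(zf1) + linker_len
  zf2_c1 <- base2 + 1L
  zf2_c2 <- zf2_c1 + 4L + extra2 + 1L
  zf2_h1 <- base2 + which(zf2 == "H")[1L]
  zf2_h2 <- zf2_h1 + 4L
  truth <- data.frame(id = id,
                      zf1_c1 = zf1_c1, zf1_c2 = zf1_c2,
                      zf1_h1 = zf1_h1, zf1_h2 = zf1_h2,
                      zf2_c1 = zf2_c1, zf2_c2 = zf2_c2,
                      zf2_h1 = zf2_h1, zf2_h2 = zf2_h2,
                      linker_len = linker_len, phi1 = phi1, phi2 = phi2,
                      extra1 = extra1, extra2 = extra2,
                      has_tgekp = tgekp, decoy = "none")
  list(seq = seqv, truth = truth)
}

#' Apply a decoy mutation to a generated record
#'
#' @param record A one-row record data frame (`id`, `description`,
#'   `sequence`) or a list with `$sequence`.
#' @param truth The matching ground-truth row (see [generate_dataset()]).
#' @param kind One of `"w_to_g"` (the ZF1 tryptophan is replaced by
#'   glycine, mirroring the pathogenic W-to-G loss of function; fingers
#'   remain detectable but the tandem call is lost), `"spacing_violation"`
#'   (the linker is stretched beyond the pairing bound) or
#'   `"single_finger"` (the record is truncated after finger 1).
#' @param cfg The [generator_config()] that produced the record (supplies
#'   the residue alphabet and spacing bounds for the stretch).
#' @return A list with the mutated `record` and updated `truth`.
#' @export
mutate_decoy <- function(record, truth, kind, cfg) {
  if (!kind %in% decoy_kinds)
    stop(sprintf("unknown decoy kind %s", dQuote(kind)), call. = FALSE)
  seqv <- as_residues(seq_of(record))
  t <- truth
  if (kind == "w_to_g") {
    stopifnot(seqv[t$zf1_c1 + 2L] == "W")
    seqv[t$zf1_c1 + 2L] <- "G"
  } else if (kind == "spacing_violation") {
    sp <- generator_spacing(cfg)
    target <- sp$linker[2L] + 15L
    add <- target - t$linker_len
    if (add > 0L) {
      seqv <- append(seqv, rand_res(add), after = t$zf1_h2)
      shift <- add
      for (f in c("zf2_c1", "zf2_c2", "zf2_h1", "zf2_h2"))
        t[[f]] <- t[[f]] + shift
      t$linker_len <- target
    }
  } else if (kind == "single_finger") {
    keep <- min(length(seqv), t$zf1_h2 + 2L)
    seqv <- seqv[seq_len(keep)]
    t[c("zf2_c1", "zf2_c2", "zf2_h1", "zf2_h2")] <- NA_integer_
    t$linker_len <- NA_integer_
    t$phi2 <- NA_character_
  }
  t$decoy <- kind
  rec <- if (is.list(record) && !is.null(record$sequence)) {
    record$sequence <- paste(seqv, collapse = "")
    record
  } else paste(seqv, collapse = "")
  list(record = rec, truth = t)
}

check_record <- function(seqs, truth, spacing) {
  td <- annotate_tandems(seqs, spacing)
  if (truth$decoy == "none") {
    nrow(td) == 1L &&
      all(td[1L, c("zf1_c1", "zf1_c2", "zf1_h1", "zf1_h2",
                   "zf2_c1", "zf2_c2", "zf2_h1", "zf2_h2")] ==
            truth[1L, c("zf1_c1", "zf1_c2", "zf1_h1", "zf1_h2",
                        "zf2_c1", "zf2_c2", "zf2_h1", "zf2_h2")]) &&
      td$linker_len[1L] == truth$linker_len &&
      td$phi1[1L] == truth$phi1 && td$phi2[1L] == truth$phi2
  } else {
    nrow(td) == 0L
  }
}

#' Generate a seeded synthetic zinc-finger protein dataset with ground truth
#'
#' Each intact record is random flank + finger 1 (C-x-W-insertion-C,
#' spacer with a central F, H, phi1 + 2 residues, H) + linker + finger 2 +
#' random flank, with all free residues drawn from an alphabet excluding C
#' and H so the planted anchors are the only ones.  Sampled linker length,
#' phi residues, insertion lengths and TGE(K/R)P status are recorded as
#' ground truth.  Records designated as decoys are mutated via
#' [mutate_decoy()].  After assembly every record is re-scanned with
#' [generator_spacing()]; a record whose scan disagrees with its truth
#' (possible only for rare linker draws beyond the pairing bound, or decoy
#' edge cases) is redrawn, up to 25 attempts.
#'
#' @param cfg A [generator_config()].
#' @return A list with `records` (data frame: `id`, `description`,
#'   `sequence`) and `truth` (data frame: planted anchors, `linker_len`,
#'   `phi1`, `phi2`, `extra1`, `extra2`, `has_tgekp`, `decoy`).
#'   Deterministic given `cfg$seed`.
#' @examples
#' ds <- generate_dataset(generator_config(seed = 1, n_records = 5))
#' annotate_tandems(ds$records$sequence[1], generator_spacing(
#'   generator_config(seed = 1, n_records = 5)))
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  spacing <- generator_spacing(cfg)
  n <- cfg$n_records
  ## per-record decoy assignment
  kinds <- if (length(cfg$decoy_fractions)) {
    p <- c(cfg$decoy_fractions,
           none = 1 - sum(cfg$decoy_fractions))
    sample(names(p), n, replace = TRUE, prob = p)
  } else rep("none", n)
  ## TGE(K/R)P insertion: conditional odds among eligible (len >= 5)
  ## linkers chosen so the marginal sequence-level rate matches tgekp_rate
  p_ge5 <- sum(cfg$linker_model$pmf[cfg$linker_model$support >= 5L])
  p_ins <- if (cfg$tgekp_rate > 0) {
    if (cfg$tgekp_rate > p_ge5 + 1e-9)
      stop("tgekp_rate exceeds the fraction of linkers of length >= 5",
           call. = FALSE)
    min(1, cfg$tgekp_rate / p_ge5)
  } else 0
  records <- vector("list", n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("synth_%05d", i)
    ok <- FALSE
    for (attempt in seq_len(25L)) {
      linker_len <- as.integer(sample_from(
        stats::setNames(cfg$linker_model$pmf,
                        cfg$linker_model$support)))
      phi1 <- sample_from(cfg$phi1_freqs)
      phi2 <- sample_from(cfg$phi2_freqs)
      extra1 <- as.integer(sample_from(cfg$extra1_probs))
      extra2 <- as.integer(sample_from(cfg$extra2_probs))
      tgekp <- p_ins > 0 && linker_len >= 5L && stats::runif(1L) < p_ins
      br <- build_record(cfg, id, linker_len, phi1, phi2, extra1, extra2,
                         tgekp)
      seqv <- br$seq
      truth <- br$truth
      if (kinds[i] != "none") {
        md <- mutate_decoy(paste(seqv, collapse = ""), truth, kinds[i], cfg)
        seqv <- as_residues(md$record)
        truth <- md$truth
      }
      if (check_record(seqv, truth, spacing)) {
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop(sprintf("could not generate a self-consistent record for %s", id),
           call. = FALSE)
    records[[i]] <- data.frame(id = id,
                               description = sprintf("synthetic %s record",
                                                     truth$decoy),
                               sequence = paste(seqv, collapse = ""))
    truths[[i]] <- truth
  }
  list(records = do.call(rbind, records), truth = do.call(rbind, truths))
}

#' Perturb a template sequence into a synthetic multiple alignment
#'
#' Emulates an alignment of diverged motif instances: each row is the
#' template with independent residue substitutions at rate `sub_rate`
#' (uniform over the other residues), then each column receives a random
#' gap fraction drawn uniformly from `[0, max_gap_frac]`.  With moderate
#' rates the columnwise mode equals the template, so [modal_consensus()]
#' recovers it.
#'
#' @param template Ungapped residue string.
#' @param n_rows Number of alignment rows.
#' @param sub_rate Per-position substitution probability.
#' @param max_gap_frac Upper bound of the per-column gap fraction.
#' @return A [protein_alignment()].
#' @examples
#' set.seed(1)
#' a <- perturb_alignment(tcwch2_consensus(), n_rows = 50)
#' modal_consensus(a, gap_threshold = 0.5)$consensus == tcwch2_consensus()
#' @export
perturb_alignment <- function(template, n_rows = 200L, sub_rate = 0.1,
                              max_gap_frac = 0.4) {
  tmpl <- as_residues(template)
  w <- length(tmpl)
  stopifnot(w > 0L, n_rows >= 1L, sub_rate >= 0, sub_rate < 1,
            max_gap_frac >= 0, max_gap_frac <= 1)
  m <- matrix(rep(tmpl, each = n_rows), nrow = n_rows)
  subs <- which(matrix(stats::runif(n_rows * w) < sub_rate, nrow = n_rows))
  if (length(subs)) {
    m[subs] <- vapply(m[subs],
                      function(r) sample(setdiff(AA20, r), 1L),
                      character(1L))
  }
  for (j in seq_len(w)) {
    g <- floor(stats::runif(1L, 0, max_gap_frac) * n_rows)
    if (g > 0L) m[sample(n_rows, g), j] <- "-"
  }
  protein_alignment(sprintf("row_%04d", seq_len(n_rows)),
                    apply(m, 1L, paste, collapse = ""))
}
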