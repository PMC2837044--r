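TSV_VERSION <- "tcwch2 tsv v1"

write_tsv_report <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s", TSV_VERSION), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_report <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

read_background_freqs <- function(path) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("residue", "freq"),
                          stringsAsFactors = FALSE)
  freq_table(stats::setNames(df$freq, df$residue) * 1e6)
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(cfg), tmp)
  unname(tools::md5sum(tmp))
}

log_line <- function(con, fmt, ...) writeLines(sprintf(fmt, ...), con)

#' Run a pipeline stage
#'
#' Thin driver tying the package stages into file-to-file steps, also
#' exposed through the `inst/scripts/tcwch2` command-line wrapper.
#' Subcommands:
#' \describe{
#'   \item{scan}{FASTA in; per-record finger and tandem annotations out
#'     (`fingers.tsv`, `annotations.tsv`, `annotations.json`).  All
#'     coordinates are 1-based inclusive.}
#'   \item{stats}{a scan `annotations.tsv` in (plus an optional two-column
#'     residue/frequency background file); linker summary, phi frequency
#'     tables and tests out (`stats.json`, `linker_stats.tsv`,
#'     `phi_freqs.tsv`).}
#'   \item{consensus}{alignment in (aligned FASTA or Clustal);
#'     gap-filtered modal consensus out (`consensus.fasta`,
#'     `column_freqs.tsv`).}
#'   \item{simulate}{generator settings in; synthetic records and ground
#'     truth out (`records.fasta`, `truth.tsv`).}
#'   \item{conserve}{FASTA of one gene family in; tryptophan-conservation
#'     report out (`conservation.tsv`, `conservation.json`).}
#' }
#' Every run writes `run.log` (package version, seed, configuration hash).
#' Outputs are byte-stable given identical inputs and configuration.
#'
#' @param cfg A list: `subcommand` (one of the above), `input` (input
#'   path; unused for simulate), `outdir`, and optionally `preset`
#'   (`"strict"`/`"loose"`), `pattern` (pattern-string override used to
#'   report grammar-engine matches alongside the scan), `gap_threshold`,
#'   `seed`, `n_records`, `linker_preset`, `background_freqs` (path),
#'   `family`, `pair_index`.
#' @return Invisibly, a list with `status` (0) and the paths written.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(is.list(cfg), !is.null(cfg$subcommand))
  sub <- match.arg(cfg$subcommand,
                   c("scan", "stats", "consensus", "simulate", "conserve"))
  outdir <- cfg$outdir
  if (is.null(outdir)) stop("cfg$outdir is required", call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory", call. = FALSE)
  if (sub != "simulate") {
    if (is.null(cfg$input) || !file.exists(cfg$input))
      stop(sprintf("input file not found: %s",
                   if (is.null(cfg$input)) "<missing>" else cfg$input),
           call. = FALSE)
  }
  preset <- if (is.null(cfg$preset)) "strict" else cfg$preset
  files <- character()

  if (sub == "scan") {
    recs <- read_fasta(cfg$input)
    sp <- spacing_config(preset)
    fingers <- do.call(rbind, lapply(seq_len(nrow(recs)), function(i) {
      f <- find_c2h2(recs$sequence[i], sp)
      if (nrow(f)) cbind(id = recs$id[i], f) else NULL
    }))
    tandems <- do.call(rbind, lapply(seq_len(nrow(recs)), function(i) {
      td <- annotate_tandems(recs$sequence[i], sp)
      if (nrow(td)) cbind(id = recs$id[i], td) else NULL
    }))
    if (is.null(fingers)) fingers <- data.frame(id = character())
    if (is.null(tandems)) tandems <- data.frame(id = character())
    files <- c(write_tsv_report(fingers, file.path(outdir, "fingers.tsv")),
               write_tsv_report(tandems, file.path(outdir, "annotations.tsv")))
    jsonlite::write_json(list(format = TSV_VERSION, preset = preset,
                              coordinates = "1-based inclusive",
                              n_records = nrow(recs),
                              tandems = tandems),
                         file.path(outdir, "annotations.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, file.path(outdir, "annotations.json"))
    if (!is.null(cfg$pattern)) {
      pat <- parse_phi_pattern(cfg$pattern)
      pm <- do.call(rbind, lapply(seq_len(nrow(recs)), function(i) {
        m <- match_pattern(pat, recs$sequence[i], mode = "nonoverlapping")
        if (!nrow(m)) return(NULL)
        data.frame(id = recs$id[i], start = m$start, end = m$end,
                   anchors = vapply(m$anchors, paste, character(1L),
                                    collapse = ","))
      }))
      if (is.null(pm)) pm <- data.frame(id = character())
      files <- c(files, write_tsv_report(pm, file.path(outdir, "pattern_matches.tsv")))
    }
  } else if (sub == "stats") {
    ann <- read_tsv_report(cfg$input)
    if (!nrow(ann) || !"linker_len" %in% names(ann))
      stop("stats requires a scan annotations table with tandem rows",
           call. = FALSE)
    ls <- linker_summary(ann$linker_len)
    pf <- phi_frequency(ann)
    out <- list(linker = unclass(ls),
                phi1 = list(counts = as.list(pf$phi1$counts),
                            freq = as.list(pf$phi1$freq)),
                phi2 = list(counts = as.list(pf$phi2$counts),
                            freq = as.list(pf$phi2$freq)),
                tgekp_percent = 100 * mean(ann$has_tgekp))
    if (!is.null(cfg$background_freqs)) {
      bg <- read_background_freqs(cfg$background_freqs)
      t1 <- chi2_vs_background(pf$phi1, bg, c("V", "L", "I"))
      t2 <- chi2_vs_background(pf$phi2, bg, c("V", "L", "I", "M"))
      out$chi2_phi1 <- list(statistic = t1$statistic, p = t1$p_value,
                            p_string = t1$p_string)
      out$chi2_phi2 <- list(statistic = t2$statistic, p = t2$p_value,
                            p_string = t2$p_string)
    }
    jsonlite::write_json(out, file.path(outdir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    ls_df <- data.frame(n = ls$n, mean = ls$mean, sd = ls$sd,
                        min = ls$min, max = ls$max)
    phi_df <- rbind(
      data.frame(position = "phi1", residue = names(pf$phi1$freq),
                 count = as.integer(pf$phi1$counts),
                 freq = as.numeric(pf$phi1$freq)),
      data.frame(position = "phi2", residue = names(pf$phi2$freq),
                 count = as.integer(pf$phi2$counts),
                 freq = as.numeric(pf$phi2$freq)))
    files <- c(file.path(outdir, "stats.json"),
               write_tsv_report(ls_df, file.path(outdir, "linker_stats.tsv")),
               write_tsv_report(phi_df, file.path(outdir, "phi_freqs.tsv")))
  } else if (sub == "consensus") {
    aln <- read_alignment(cfg$input)
    thr <- if (is.null(cfg$gap_threshold)) 0.5 else cfg$gap_threshold
    cons <- modal_consensus(aln, gap_threshold = thr)
    write_fasta(data.frame(id = "consensus",
                           description = sprintf("modal consensus, %d columns",
                                                 nchar(cons$consensus)),
                           sequence = cons$consensus),
                file.path(outdir, "consensus.fasta"))
    freq_df <- do.call(rbind, lapply(seq_along(cons$column_freqs), function(j) {
      f <- cons$column_freqs[[j]]
      data.frame(column = j, original_column = cons$kept_columns[j],
                 residue = names(f), freq = as.numeric(f))
    }))
    files <- c(file.path(outdir, "consensus.fasta"),
               write_tsv_report(freq_df, file.path(outdir, "column_freqs.tsv")))
  } else if (sub == "simulate") {
    if (is.null(cfg$seed)) stop("simulate requires cfg$seed", call. = FALSE)
    gcfg <- generator_config(
      seed = cfg$seed,
      n_records = if (is.null(cfg$n_records)) 100L else cfg$n_records,
      linker_preset = if (is.null(cfg$linker_preset)) "tcwch2"
                      else cfg$linker_preset)
    ds <- generate_dataset(gcfg)
    files <- c(write_fasta(ds$records, file.path(outdir, "records.fasta")),
               write_tsv_report(ds$truth, file.path(outdir, "truth.tsv")))
  } else if (sub == "conserve") {
    recs <- read_fasta(cfg$input)
    fam <- if (is.null(cfg$family))
      sub("\\.[^.]*$", "", basename(cfg$input)) else cfg$family
    rep_ <- tryptophan_conservation(
      fam, recs, spacing_config(preset),
      pair_index = if (is.null(cfg$pair_index)) 1L else cfg$pair_index)
    df <- data.frame(family = rep_$family, n = rep_$n,
                     conserved = rep_$conserved, percent = rep_$percent)
    jsonlite::write_json(unclass(rep_), file.path(outdir, "conservation.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(write_tsv_report(df, file.path(outdir, "conservation.tsv")),
               file.path(outdir, "conservation.json"))
  }

  log_path <- file.path(outdir, "run.log")
  con <- file(log_path, "w")
  log_line(con, "tcwch2 version %s",
           as.character(utils::packageVersion("tcwch2")))
  log_line(con, "subcommand %s", sub)
  log_line(con, "seed %s", if (is.null(cfg$seed)) "NA" else cfg$seed)
  log_line(con, "config_hash %s", config_hash(cfg))
  close(con)
  invisible(list(status = 0L, files = c(files, log_path)))
}
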