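strict <- spacing_config("strict")
loose <- spacing_config("loose")

test_that("finger detection on the consensus recovers both CWCH2 fingers", {
  f <- find_c2h2(tcwch2_consensus(), strict)
  expect_equal(f$c1, c(3L, 36L))
  expect_equal(f$c2, c(8L, 41L))
  expect_equal(f$h1, c(22L, 55L))
  expect_equal(f$h2, c(27L, 59L))
  expect_true(all(f$is_cwch2))
})

test_that("sequences without anchors yield no fingers", {
  expect_equal(nrow(find_c2h2("AAAA", strict)), 0L)
  expect_equal(nrow(find_c2h2("", strict)), 0L)
})

test_that("tandem annotation of the consensus extracts the documented features", {
  td <- annotate_tandems(tcwch2_consensus(), strict)
  expect_equal(nrow(td), 1L)
  expect_equal(td$linker_len, 8L)
  expect_equal(td$linker_seq, "VGTQLEYT")
  expect_equal(td$phi1, "V")
  expect_equal(td$phi2, "I")
  expect_equal(c(td$extra1, td$extra2), c(0L, 0L))
  expect_false(td$has_tgekp)
})

test_that("loss of the second tryptophan abolishes the tandem but not the fingers", {
  mut <- tcwch2_consensus()
  substr(mut, 38, 38) <- "G"   # the ZF2 tryptophan
  f <- find_c2h2(mut, strict)
  expect_equal(nrow(f), 2L)
  expect_equal(f$is_cwch2, c(TRUE, FALSE))
  expect_equal(nrow(annotate_tandems(mut, strict)), 0L)
  # relaxed pairing still locates the pair (used for conservation scoring)
  td <- annotate_tandems(mut, strict, require_w = FALSE)
  expect_equal(nrow(td), 1L)
  expect_equal(td$zf2_cwch2, FALSE)
})

test_that("linker bounds separate the strict and loose presets", {
  # two CWCH2 fingers 40 residues apart: outside strict (5..25), inside
  # loose (5..42)
  zf <- "CAWLECGGFGGHAGLH"
  seqs <- paste0("AA", zf, strrep("G", 40), zf, "AA")
  expect_equal(nrow(annotate_tandems(seqs, strict)), 0L)
  expect_equal(nrow(annotate_tandems(seqs, loose)), 1L)
})

test_that("strict tandems are a subset of loose tandems", {
  set.seed(11)
  ds <- generate_dataset(generator_config(seed = 31, n_records = 60))
  for (s in ds$records$sequence) {
    td_s <- annotate_tandems(s, strict)
    td_l <- annotate_tandems(s, loose)
    if (nrow(td_s)) {
      key <- function(td) paste(td$zf1_c1, td$zf2_h2)
      expect_true(all(key(td_s) %in% key(td_l)))
    }
  }
})

test_that("reported fingers are span-disjoint, sorted and within bounds", {
  set.seed(12)
  ds <- generate_dataset(generator_config(seed = 32, n_records = 40))
  for (s in ds$records$sequence) {
    f <- find_c2h2(s, strict)
    expect_true(all(diff(f$c1) > 0))
    if (nrow(f) > 1L) expect_true(all(f$c1[-1L] > f$h2[-nrow(f)]))
    expect_true(all(f$c1 < f$c2 & f$c2 < f$h1 & f$h1 < f$h2))
    expect_true(all(f$h2 - f$h1 - 1L >= 2L & f$h2 - f$h1 - 1L <= 5L))
  }
})

test_that("TGE(K/R)P detection honors the K/R class only", {
  expect_true(has_tgekp("HTGEKP"))
  expect_true(has_tgekp("TGERP"))
  expect_false(has_tgekp("TGEQP"))
  expect_false(has_tgekp(""))
  expect_equal(has_tgekp(c("ATGEKPA", "AAAA")), c(TRUE, FALSE))
})

test_that("segment-header linker arithmetic applies the exclusion rules", {
  expect_equal(linker_from_segment_headers(
    data.frame(start = c(301, 337), end = c(330, 366))), 6L)
  # 46-residue gap excluded (> 41)
  expect_equal(linker_from_segment_headers(
    data.frame(start = c(1, 75), end = c(28, 102))), integer())
  # a single segment forms no pair
  expect_equal(linker_from_segment_headers(
    data.frame(start = 1, end = 28)), integer())
  # linkers never cross protein boundaries
  expect_equal(linker_from_segment_headers(
    data.frame(id = c("a", "a", "b", "b"),
               start = c(1, 40, 1, 50), end = c(28, 70, 30, 80))),
    c(11L, 19L))
  expect_error(linker_from_segment_headers(
    data.frame(start = c(40, 1), end = c(70, 28))), "sorted")
  expect_warning(
    out <- linker_from_segment_headers(
      data.frame(start = c(1, 20), end = c(25, 50))),
    "negative")
  expect_equal(out, integer())
})

test_that("PROSITE-style headers parse into coordinates", {
  df <- parse_segment_headers(c("GLI1_HUMAN/301-330", "GLI1_HUMAN/337-366"))
  expect_equal(df$start, c(301L, 337L))
  expect_equal(df$end, c(330L, 366L))
  expect_equal(df$id, rep("GLI1_HUMAN", 2))
  expect_error(parse_segment_headers("GLI1_HUMAN_301_330"), "malformed")
})
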