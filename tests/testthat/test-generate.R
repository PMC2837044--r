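test_that("the discretized linker model is moment-matched to its targets", {
  for (preset in c("tcwch2", "background")) {
    cfg <- generator_config(seed = 1, linker_preset = preset)
    lm <- cfg$linker_model
    expect_equal(lm$realized_mean, lm$mean, tolerance = 1e-4)
    expect_equal(lm$realized_sd, lm$sd, tolerance = 1e-4)
    expect_equal(sum(lm$pmf), 1, tolerance = 1e-12)
    expect_true(all(lm$support >= lm$min & lm$support <= lm$max))
  }
  expect_error(generator_config(seed = 1, linker_min = 10, linker_max = 5),
               "min > max")
})

test_that("generation is deterministic given the seed", {
  cfg <- generator_config(seed = 123, n_records = 30,
                          decoy_fractions = c(w_to_g = 0.2))
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$records, d2$records)
  expect_identical(d1$truth, d2$truth)
  d3 <- generate_dataset(generator_config(seed = 124, n_records = 30))
  expect_false(identical(d1$records$sequence, d3$records$sequence))
})

test_that("intact records round-trip through the annotator exactly", {
  cfg <- generator_config(seed = 55, n_records = 150)
  ds <- generate_dataset(cfg)
  sp <- generator_spacing(cfg)
  anchor_cols <- c("zf1_c1", "zf1_c2", "zf1_h1", "zf1_h2",
                   "zf2_c1", "zf2_c2", "zf2_h1", "zf2_h2")
  for (i in seq_len(nrow(ds$records))) {
    td <- annotate_tandems(ds$records$sequence[i], sp)
    expect_equal(nrow(td), 1L)
    expect_equal(unlist(td[1, anchor_cols]), unlist(ds$truth[i, anchor_cols]))
    expect_equal(td$linker_len, ds$truth$linker_len[i])
    expect_equal(td$phi1, ds$truth$phi1[i])
    expect_equal(td$phi2, ds$truth$phi2[i])
    expect_equal(td$extra1, ds$truth$extra1[i])
    expect_equal(td$extra2, ds$truth$extra2[i])
    expect_equal(td$has_tgekp, ds$truth$has_tgekp[i])
  }
})

test_that("empirical linker and phi distributions match the configuration", {
  cfg <- generator_config(seed = 77, n_records = 2000)
  ds <- generate_dataset(cfg)
  lm <- cfg$linker_model
  se_mean <- lm$sd / sqrt(nrow(ds$truth))
  expect_lt(abs(mean(ds$truth$linker_len) - lm$mean), 3 * se_mean + 0.02)
  for (res in c("V", "L", "I")) {
    p <- cfg$phi1_freqs[[res]]
    se <- sqrt(p * (1 - p) / nrow(ds$truth))
    expect_lt(abs(mean(ds$truth$phi1 == res) - p), 3 * se)
  }
  p_m <- cfg$phi2_freqs[["M"]]
  expect_lt(abs(mean(ds$truth$phi2 == "M") - p_m),
            3 * sqrt(p_m * (1 - p_m) / nrow(ds$truth)))
})

test_that("each decoy kind breaks detection in its documented way", {
  strict <- spacing_config("strict")
  loose <- spacing_config("loose")
  cfg <- generator_config(seed = 91, n_records = 20)
  ds <- generate_dataset(cfg)
  for (i in 1:5) {
    rec <- ds$records$sequence[i]
    tr <- ds$truth[i, ]
    wg <- mutate_decoy(rec, tr, "w_to_g", cfg)
    expect_equal(nrow(find_c2h2(wg$record, strict)), 2L)
    expect_equal(nrow(annotate_tandems(wg$record, strict)), 0L)
    sv <- mutate_decoy(rec, tr, "spacing_violation", cfg)
    expect_equal(sv$truth$linker_len, 40L)
    expect_equal(nrow(annotate_tandems(sv$record, strict)), 0L)
    expect_equal(nrow(annotate_tandems(sv$record, loose)), 1L)
    sf <- mutate_decoy(rec, tr, "single_finger", cfg)
    expect_equal(nrow(find_c2h2(sf$record, strict)), 1L)
    expect_equal(nrow(annotate_tandems(sf$record, strict)), 0L)
  }
  expect_error(mutate_decoy(ds$records$sequence[1], ds$truth[1, ],
                            "nonsense", cfg), "unknown decoy")
})

test_that("all-decoy datasets produce zero tandem calls", {
  cfg <- generator_config(seed = 99, n_records = 40,
                          decoy_fractions = c(w_to_g = 1))
  ds <- generate_dataset(cfg)
  expect_true(all(ds$truth$decoy == "w_to_g"))
  n_td <- sum(vapply(ds$records$sequence, function(s)
    nrow(annotate_tandems(s, generator_spacing(cfg))), integer(1)))
  expect_equal(n_td, 0L)
})

test_that("background generation hits the configured TGE(K/R)P rate", {
  cfg <- generator_config(seed = 101, n_records = 1500,
                          linker_preset = "background")
  ds <- generate_dataset(cfg)
  rate <- mean(ds$truth$has_tgekp)
  se <- sqrt(0.65 * 0.35 / nrow(ds$truth))
  expect_lt(abs(rate - 0.65), 3 * se)
  # detected pentamers agree with the planted flags
  td <- do.call(rbind, lapply(ds$records$sequence, annotate_tandems,
                              cfg = generator_spacing(cfg)))
  expect_equal(td$has_tgekp, ds$truth$has_tgekp)
  # an unsatisfiable rate errors out
  expect_error(
    generate_dataset(generator_config(seed = 1, n_records = 5,
                                      linker_preset = "background",
                                      linker_min = 1, linker_max = 3,
                                      linker_mean = 2, linker_sd = 1,
                                      tgekp_rate = 0.65)),
    "tgekp_rate")
})

test_that("strict tandem calls coincide with full-pattern matches anchor for anchor", {
  cfg <- generator_config(seed = 202, n_records = 250)
  ds <- generate_dataset(cfg)
  pat <- parse_phi_pattern(tcwch2_pattern("strict"))
  strict <- spacing_config("strict")
  for (s in ds$records$sequence) {
    td <- annotate_tandems(s, strict)
    pm <- match_pattern(pat, s, mode = "nonoverlapping")
    expect_equal(nrow(td), nrow(pm))
    if (nrow(td)) {
      td_anchors <- unlist(td[1, c("zf1_c1", "zf1_c2", "zf1_h1", "zf1_h2",
                                   "zf2_c1", "zf2_c2", "zf2_h1", "zf2_h2")])
      expect_equal(unname(pm$anchors[[1]][c(1, 3, 4, 5, 6, 8, 9, 10)]),
                   unname(td_anchors))
      # the pattern's tryptophan anchors sit two after each first cysteine
      expect_equal(pm$anchors[[1]][c(2, 7)], unname(td_anchors[c(1, 5)]) + 2L)
    }
  }
})

test_that("perturbed alignments recover their template consensus", {
  set.seed(303)
  a <- perturb_alignment(tcwch2_consensus(), n_rows = 120, sub_rate = 0.1,
                         max_gap_frac = 0.4)
  expect_equal(modal_consensus(a, gap_threshold = 0.5)$consensus,
               tcwch2_consensus())
})
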