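test_that("linker summaries use sample moments and flag degenerate input", {
  s1 <- linker_summary(8)
  expect_equal(s1$n, 1L)
  expect_equal(s1$mean, 8)
  expect_true(is.na(s1$sd))
  s3 <- linker_summary(c(6, 8, 10))
  expect_equal(s3$mean, 8)
  expect_equal(s3$sd, 2)
  expect_equal(c(s3$min, s3$max), c(6, 10))
  expect_error(linker_summary(numeric()), "no linker")
  expect_error(linker_summary(c(3, -1)), "non-negative")
})

test_that("Mann-Whitney U reproduces hand-enumerated exact cases", {
  # identical tied samples: U at its null mean, p ~ 1
  t_sym <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(t_sym$statistic, 4.5)
  expect_equal(t_sym$p_value, 1)
  # full separation: 2 of the 20 rank assignments are as extreme
  t_sep <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(t_sep$statistic, 0)
  expect_true(t_sep$extras$exact)
  expect_equal(t_sep$p_value, 0.1)
  expect_error(mann_whitney(numeric(), 1), "non-empty")
})

test_that("Mann-Whitney U is symmetric under sample swap", {
  set.seed(5)
  for (i in 1:20) {
    a <- rnorm(sample(3:30, 1))
    b <- rnorm(sample(3:30, 1), mean = runif(1, -1, 1))
    ta <- mann_whitney(a, b)
    tb <- mann_whitney(b, a)
    expect_equal(tb$statistic, length(a) * length(b) - ta$statistic)
    expect_equal(ta$p_value, tb$p_value)
  }
})

test_that("Mann-Whitney p-values agree with wilcox.test", {
  set.seed(6)
  for (i in 1:25) {
    a <- rnorm(sample(4:40, 1))
    b <- rnorm(sample(4:40, 1), mean = runif(1, -1, 1))
    ours <- mann_whitney(a, b)
    ref <- suppressWarnings(wilcox.test(a, b, exact = ours$extras$exact,
                                        correct = TRUE))
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-8)
  }
})

test_that("exact and approximate Mann-Whitney branches agree at the boundary", {
  # exhaustive over pooled size 12 at splits 4+8 .. 8+4, every achievable U
  # (at more extreme splits the normal approximation itself deviates from
  # the exact tail by up to 0.035, so agreement there is not attainable)
  set.seed(8)
  for (n1 in 4:8) {
    n2 <- 12L - n1
    vals <- sample(1000, 12)       # no ties by construction
    vals <- sort(vals)
    combs <- combn(12L, n1)
    for (k in sample(ncol(combs), 40)) {
      a <- vals[combs[, k]]
      b <- vals[-combs[, k]]
      pe <- mann_whitney(a, b, exact = TRUE)$p_value
      pa <- mann_whitney(a, b, exact = FALSE)$p_value
      expect_lt(abs(pe - pa), 0.02 + 1e-9)
    }
  }
  expect_error(mann_whitney(c(1, 1, 2), c(3, 4), exact = TRUE), "ties")
})

test_that("the variance F test matches its closed form and var.test", {
  t_eq <- f_variance_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(t_eq$statistic, 1)
  expect_equal(t_eq$p_value, 1)
  a <- c(0, 2, 4, 6, 8)            # var = 10
  b <- c(0, 1, 2, 3, 4)            # var = 2.5
  expect_equal(f_variance_test(a, b)$statistic, 4)
  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(sample(5:30, 1))
    y <- rnorm(sample(5:30, 1), sd = runif(1, 0.5, 2))
    ours <- f_variance_test(x, y)
    ref <- var.test(x, y)
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
  expect_error(f_variance_test(1:5, rep(2, 5)), "zero variance")
  expect_error(f_variance_test(1, 1:5), "at least two")
})

test_that("F-test p-values are uniform under the null", {
  set.seed(10)
  p <- replicate(400, f_variance_test(rnorm(20), rnorm(20))$p_value)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("chi-squared against background matches hand arithmetic", {
  bg <- pdoc00028_phi_freqs()
  # observed equal to background: statistic 0, p 1
  t0 <- chi2_vs_background(bg, bg, c("V", "L", "I", "M"))
  expect_equal(t0$statistic, 0, tolerance = 1e-12)
  expect_equal(t0$p_value, 1)
  # 91/100 hydrophobic against a 26.8% background rate
  obs <- freq_table(c(rep("V", 45), rep("I", 46), rep("A", 9)))
  t1 <- chi2_vs_background(obs, bg, c("V", "L", "I", "M"))
  expect_equal(t1$extras$background_rate, 0.268, tolerance = 1e-12)
  expect_equal(t1$statistic,
               (91 - 26.8)^2 / 26.8 + (9 - 73.2)^2 / 73.2,
               tolerance = 1e-10)
  expect_equal(t1$extras$df, 1L)
  # per-residue secondary statistic present and valid
  expect_true(t1$extras$per_residue$p_value >= 0 &&
                t1$extras$per_residue$p_value <= 1)
  # uncovered residue violates the precondition
  bad_bg <- freq_table(c(V = 1))
  expect_error(chi2_vs_background(obs, bad_bg, "V"), "zero frequency")
})

test_that("phi frequency tables come straight from the annotation", {
  td <- annotate_tandems(tcwch2_consensus())
  pf <- phi_frequency(td)
  expect_equal(unname(pf$phi1$freq["V"]), 1)
  expect_equal(unname(pf$phi2$freq["I"]), 1)
  two <- rbind(td, td)
  two$phi1 <- c("V", "I")
  pf2 <- phi_frequency(two)
  expect_equal(as.numeric(pf2$phi1$freq[c("I", "V")]), c(0.5, 0.5))
  expect_error(phi_frequency(td[0, ]), "no tandem")
})

test_that("frequency tables are closed under their invariants", {
  set.seed(13)
  for (i in 1:10) {
    x <- sample(c("V", "L", "I", "M", "A"), sample(5:50, 1), replace = TRUE)
    ft <- freq_table(x)
    expect_equal(sum(ft$freq), 1, tolerance = 1e-9)
    expect_equal(sum(ft$counts), ft$n)
  }
  expect_error(freq_table(character()), "at least one")
})

test_that("tryptophan conservation reproduces family percentages", {
  base <- tcwch2_consensus()
  w_mut <- base
  substr(w_mut, 5, 5) <- "G"       # ZF1 tryptophan lost
  fam16 <- c(rep(base, 14), rep(w_mut, 2))
  r16 <- tryptophan_conservation("Zfp106-like", fam16)
  expect_equal(r16$n, 16L)
  expect_equal(r16$percent, 87.5)
  fam40 <- c(rep(base, 37), rep(w_mut, 3))
  expect_equal(tryptophan_conservation("Mizf-like", fam40)$percent, 92.5)
  expect_equal(tryptophan_conservation("all", rep(base, 5))$percent, 100)
  # unlocatable pair counts as non-conserved, with a warning
  expect_warning(
    r <- tryptophan_conservation("broken", c(base, "AAAA")),
    "no locatable")
  expect_equal(r$percent, 50)
})

test_that("vanishing p-values are reported as bounded strings", {
  expect_equal(tcwch2:::format_p(0), "< 1e-300")
  expect_equal(tcwch2:::format_p(1e-320), "< 1e-300")
  expect_match(tcwch2:::format_p(0.05), "0.05")
})
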