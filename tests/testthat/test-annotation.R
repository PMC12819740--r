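test_that("direction summaries give percentages to one decimal", {
  res <- tibble::tibble(log2fc = c(rep(1, 428), rep(-1, 80)))
  out <- summarize_direction(res)
  expect_equal(out$n, 508L)
  expect_equal(out$pct_up, 84.3)
  expect_equal(out$pct_down, 15.7)
  expect_equal(out$pct_up + out$pct_down, 100, tolerance = 0.1)

  by_ct <- summarize_direction(tibble::tibble(
    cell_type = rep(c("EX", "ODC"), c(319, 165)),
    log2fc = c(rep(1, 303), rep(-1, 16), rep(1, 107), rep(-1, 58))),
    by = "cell_type")
  expect_equal(by_ct$pct_up[by_ct$cell_type == "EX"], 95.0)
  expect_equal(by_ct$pct_up[by_ct$cell_type == "ODC"], 64.8)
  expect_equal(by_ct$pct_down[by_ct$cell_type == "ODC"], 35.2)

  # zero log2fc rows are excluded and counted separately
  z <- summarize_direction(tibble::tibble(log2fc = c(0, 2, -2)))
  expect_equal(z$n_zero, 1L)
  expect_equal(z$n, 2L)
  # empty input: no division
  e <- summarize_direction(tibble::tibble(log2fc = numeric()))
  expect_true(is.na(e$pct_up))
})

test_that("class composition reproduces percentage arithmetic", {
  loci <- tibble::tibble(te_class = rep(c("SINE", "LINE", "LTR", "DNA"),
                                        c(319, 134, 37, 18)))
  out <- class_composition(loci)
  expect_equal(out$pct[match(c("SINE", "LINE", "LTR", "DNA"), out$te_class)],
               c(62.8, 26.4, 7.3, 3.5))
  expect_equal(sum(out$pct), 100, tolerance = 0.1)
  single <- class_composition(tibble::tibble(te_class = "LINE"))
  expect_equal(single$pct, 100.0)
  expect_equal(nrow(class_composition(tibble::tibble(te_class = character()))),
               0L)
})

test_that("age classes follow retrotransposon phylogeny rules", {
  cases <- c(L1HS = "Young", L1PA2 = "Young", L1PA4 = "Young",
             L1PA8 = "Young", L1PA9 = "Old", L1PA15 = "Old",
             L1PA17 = "Old", L1PB1 = "Old", L1M5 = "Very Old",
             L2a = "Ancient", L3 = "Ancient",
             AluY = "Young", AluYa5 = "Young", AluSx = "Old",
             AluJb = "Ancient", MIRb = "Ancient",
             `HERVK9-int` = "unclassified", Charlie1a = "unclassified")
  expect_equal(assign_age(names(cases)), unname(cases))
  # total and deterministic over generated subfamilies
  b <- simulate_te_dataset(small_config(seed = 13))
  a1 <- assign_age(b$te_loci$subfamily)
  expect_true(all(a1 %in% c("Young", "Old", "Very Old", "Ancient",
                            "unclassified")))
  expect_identical(a1, assign_age(b$te_loci$subfamily))
})

test_that("family enrichment reproduces fold and exact binomial tests", {
  obs <- c(Alu = 300, L1 = 100, L2 = 34, MIR = 19, ERV = 30, DNA = 10,
           other = 15)
  fe <- family_enrichment(obs)
  expect_equal(round(fe$families$fold[fe$families$family == "Alu"], 2), 1.31)
  expect_equal(sum(fe$families$n), 508L)
  # proportional observation: all folds 1, chi-square statistic 0
  base <- baseline_composition()
  prop <- family_enrichment(setNames(round(base * 1000), names(base)),
                            baseline = round(base * 1000) / 1000)
  expect_equal(prop$families$fold, rep(1, 7), tolerance = 1e-9)
  expect_equal(prop$chisq$statistic, 0, tolerance = 1e-9)
  # toy exact two-sided binomial: 8 of 10 against 0.5
  toy <- family_enrichment(c(Alu = 8, L1 = 2),
                           baseline = c(Alu = 0.5, L1 = 0.5))
  expect_equal(toy$families$p_value[toy$families$family == "Alu"],
               0.109375, tolerance = 1e-12)
})

test_that("binomial p-values match exhaustive enumeration for small N", {
  set.seed(61)
  for (i in 1:25) {
    n <- sample(2:20, 1)
    k <- sample(0:n, 1)
    p0 <- runif(1, 0.05, 0.95)
    ours <- binom.test(k, n, p0, alternative = "two.sided")$p.value
    expect_equal(ours, binom_two_sided_oracle(k, n, p0), tolerance = 1e-9)
  }
})

test_that("unknown families pool into 'other' and zero totals error", {
  fe <- family_enrichment(c(Alu = 5, WeirdFam = 3))
  expect_equal(fe$families$n[fe$families$family == "other"], 3L)
  expect_error(family_enrichment(c(Alu = 0)), "at least one")
})

test_that("chromosome enrichment normalises by chromosome length", {
  genome2 <- tibble::tibble(chrom = c("chr1", "chr2"), length = c(1e7, 1e7))
  loci <- tibble::tibble(chrom = rep(c("chr1", "chr2"), c(16, 4)))
  ce <- chromosome_enrichment(loci, genome2)
  expect_equal(ce$fold, c(1.6, 0.4))
  expect_equal(ce$enriched, c(TRUE, FALSE))
  expect_equal(sum(ce$expected), 20, tolerance = 1e-9)
  # uniform density: all folds 1, none flagged
  genome4 <- tibble::tibble(chrom = paste0("chr", 1:4), length = rep(1e7, 4))
  u <- chromosome_enrichment(
    tibble::tibble(chrom = rep(paste0("chr", 1:4), each = 5)), genome4)
  expect_equal(u$fold, rep(1, 4))
  expect_false(any(u$enriched))
  # single chromosome: fold exactly 1
  s <- chromosome_enrichment(tibble::tibble(chrom = rep("chr1", 7)),
                             tibble::tibble(chrom = "chr1", length = 1e6))
  expect_equal(s$fold, 1)
  expect_error(chromosome_enrichment(tibble::tibble(chrom = "chrX"), genome4),
               "genome table")
})

test_that("cluster-size diagnostics compute rates and correlations", {
  d <- tibble::tibble(
    cell_type = paste0("ct", 1:5),
    n_cells = c(100, 500, 1000, 2000, 4000),
    n_de_tes = c(1, 3, 5, 9, 20),
    mean_abs_log2fc = c(5, 4.5, 4, 3.5, 3))
  out <- cluster_size_diagnostics(d)
  expect_equal(out$rates$rate_per_1000[out$rates$n_cells == 2000], 4.5)
  sp <- out$cor$estimate[out$cor$metric == "spearman_cells_vs_n_de"]
  expect_equal(sp, 1.0)  # strictly monotone counts
  pe <- out$cor$estimate[out$cor$metric == "pearson_cells_vs_effect"]
  expect_lt(pe, 0)
  # zero-DE cell types stay in the table with rate 0
  d2 <- d
  d2$n_de_tes[1] <- 0
  expect_equal(cluster_size_diagnostics(d2)$rates$rate_per_1000[1], 0)
  # constant vector: correlation undefined, flagged as NA
  d3 <- d
  d3$n_de_tes <- 5
  expect_true(is.na(cluster_size_diagnostics(d3)$cor$estimate[1]))
  expect_error(cluster_size_diagnostics(d[1:2, ]), "at least 3")
})
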