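test_that("pair finding measures interval gaps with overlap giving zero", {
  te <- tibble::tibble(feature_id = "te1", chrom = "chr1",
                       start = 1000L, end = 1300L)
  gn <- tibble::tibble(
    gene_id = c("near", "inside", "far", "boundary", "beyond"),
    chrom = "chr1",
    start = c(1500L, 1100L, 900000L, 251300L, 251301L),
    end = c(3000L, 1200L, 950000L, 252000L, 252100L))
  pr <- find_pairs(te, gn, window = 250e3)
  expect_equal(pr$distance[pr$gene_id == "near"], 200L)
  expect_equal(pr$distance[pr$gene_id == "inside"], 0L)  # TE spans the gene
  expect_false("far" %in% pr$gene_id)
  # gap == window is included, window + 1 is not
  expect_true("boundary" %in% pr$gene_id)
  expect_equal(pr$distance[pr$gene_id == "boundary"], 250000L)
  expect_false("beyond" %in% pr$gene_id)
})

test_that("pair finding matches a brute-force scan on random instances", {
  for (i in 1:200) {
    inst <- random_toy_instance(7000 + i)
    got <- find_pairs(inst$te, inst$genes, inst$window)
    want <- brute_force_pairs(inst$te, inst$genes, inst$window)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      expect_equal(got$te_id, want$te_id)
      expect_equal(got$gene_id, want$gene_id)
      expect_equal(got$distance, want$distance)
    }
  }
})

test_that("windows nest and metrics are monotone in window size", {
  sc <- scenario_pipeline()
  windows <- c(50e3, 250e3, 500e3, 1e6)
  pairs <- sc$result$proximity$pairs
  key <- function(w) {
    pw <- pairs[pairs$window == w, ]
    paste(pw$te_id, pw$gene_id)
  }
  for (i in 1:3) {
    expect_true(all(key(windows[i]) %in% key(windows[i + 1])))
  }
  m <- sc$result$proximity$metrics |> dplyr::arrange(window)
  expect_true(all(diff(m$isolation_pct) <= 0))
  expect_true(all(diff(m$median_genes_per_te) >= 0))
})

test_that("window metrics compute isolation and median on a toy genome", {
  te <- tibble::tibble(feature_id = c("te1", "te2"), chrom = "chr1",
                       start = c(1000L, 40000L), end = c(1200L, 40200L))
  gn <- tibble::tibble(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
                       start = c(1500L, 2500L, 90000L),
                       end = c(2000L, 3000L, 95000L))
  pairs <- find_pairs(te, gn, window = 2000)
  m <- suppressWarnings(window_metrics(pairs, te, list(), gn$gene_id))
  expect_equal(m$isolation_pct, 50)  # te2 has no gene within 2 kb
  expect_equal(m$median_genes_per_te, 1)  # counts 2 and 0 -> median 1
  expect_equal(m$n_significant_gene_sets, 0L)
  # all genes beyond the window: isolation 100%
  m2 <- suppressWarnings(window_metrics(
    find_pairs(te, gn[3, ], window = 100), te, list(), gn$gene_id,
    windows = 100))
  expect_equal(m2$isolation_pct, 100)
  expect_equal(m2$median_genes_per_te, 0)
})

test_that("gene-set over-representation matches the hypergeometric tail", {
  background <- paste0("g", 1:40)
  query <- paste0("g", 1:10)
  sets <- list(hit = paste0("g", 1:8), miss = paste0("g", 30:39))
  ora <- ora_gene_sets(query, sets, background)
  expect_equal(ora$p_value[ora$set == "hit"],
               hyper_tail_oracle(8, 8, 40, 10), tolerance = 1e-12)
  expect_equal(ora$p_value[ora$set == "miss"],
               hyper_tail_oracle(length(intersect(query, sets$miss)),
                                 10, 40, 10), tolerance = 1e-12)
  # enumeration equivalence across random small instances
  set.seed(71)
  for (i in 1:30) {
    N <- sample(10:50, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 hyper_tail_oracle(k, K, N, n), tolerance = 1e-9)
  }
  # a set equal to the proximal union against a 10x background is detected
  big_bg <- paste0("g", 1:100)
  ora2 <- ora_gene_sets(paste0("g", 1:10),
                        list(exact = paste0("g", 1:10)), big_bg)
  expect_lt(ora2$q_value, 0.05)
})

test_that("window selection rewards specificity and functional signal", {
  dominant <- tibble::tibble(
    window = c(50e3, 250e3), isolation_pct = c(20, 5),
    median_genes_per_te = c(2, 6), n_significant_gene_sets = c(0L, 10L))
  expect_equal(select_window(dominant)$selected, 250e3)
  # ties break to the smaller window
  tie <- tibble::tibble(
    window = c(50e3, 250e3), isolation_pct = c(5, 5),
    median_genes_per_te = c(3, 3), n_significant_gene_sets = c(2L, 2L))
  expect_equal(select_window(tie)$selected, 50e3)
  # mixed table: second window maximises the composite
  mixed <- tibble::tibble(
    window = c(50e3, 250e3, 500e3, 1e6),
    isolation_pct = c(18.3, 3.3, 2.0, 1.0),
    median_genes_per_te = c(2, 6, 12, 21),
    n_significant_gene_sets = c(0L, 14L, 9L, 5L))
  sel <- select_window(mixed)
  expect_equal(sel$selected, 250e3)
  # composite equals the stated formula
  sc <- sel$scores
  expect_equal(sc$composite,
               (sc$s_specificity + sc$s_functional + sc$s_coverage) / 3,
               tolerance = 1e-12)
  # constant metric is neutralised at 0.5
  const <- tie
  const$n_significant_gene_sets <- c(0L, 5L)
  expect_true(all(select_window(const)$scores$s_specificity == 0.5))
})

test_that("AD gene tiers are cumulative with first-appearance counting", {
  te <- tibble::tibble(feature_id = "te1", chrom = "chr1",
                       start = 100000L, end = 100300L)
  gn <- tibble::tibble(
    gene_id = c("g40kb", "g200kb", "g800kb"), chrom = "chr1",
    start = c(140300L, 300300L, 900300L),
    end = c(150000L, 310000L, 910000L))
  windows <- c(50e3, 250e3, 500e3, 1e6)
  pairs <- purrr::map_dfr(windows, function(w) find_pairs(te, gn, w))
  ad <- ad_gene_proximity(pairs, gn$gene_id, windows = windows)
  expect_equal(ad$tiers$n_new_genes, c(1L, 1L, 0L, 1L))
  expect_equal(ad$tiers$n_cumulative, c(1L, 2L, 2L, 3L))
  # ranking by distinct TE count
  te2 <- tibble::tibble(feature_id = c("te1", "te2", "te3"), chrom = "chr1",
                        start = c(1000L, 5000L, 9000L),
                        end = c(1300L, 5300L, 9300L))
  gnr <- tibble::tibble(gene_id = c("multi", "single"), chrom = "chr1",
                        start = c(2000L, 700000L), end = c(3000L, 710000L))
  pairs2 <- purrr::map_dfr(windows, function(w) find_pairs(te2, gnr, w))
  ad2 <- ad_gene_proximity(pairs2, gnr$gene_id, windows = windows,
                           tally_window = 1e6)
  expect_equal(ad2$top_genes$gene_id[1], "multi")
  expect_equal(ad2$top_genes$n_tes, c(3L, 3L))
  # no AD genes in range: zero counts everywhere
  ad3 <- ad_gene_proximity(pairs2[0, ], "absent", windows = windows)
  expect_equal(ad3$tiers$n_cumulative, rep(0L, 4))
})

test_that("TE-derived gene test reproduces printed proportions", {
  prox <- paste0("gene", 1:2326)
  catalog <- paste0("gene", 1:12)
  out <- te_derived_gene_test(prox, catalog)
  expect_equal(out$pct, 0.52)
  expect_equal(out$direction, "depleted")
  expect_lt(out$p_value, 1e-6)
  # proportion at the genome rate is null
  null <- te_derived_gene_test(paste0("g", 1:100), paste0("g", 1:3))
  expect_gt(null$p_value, 0.5)
  # Fisher p matches exhaustive enumeration on a toy table
  toy <- fisher.test(matrix(c(1, 9, 3, 7), 2))$p.value
  expect_equal(toy, fisher_two_sided_oracle(matrix(c(1, 9, 3, 7), 2)),
               tolerance = 1e-9)
  set.seed(72)
  for (i in 1:20) {
    tab <- matrix(sample(0:12, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher.test(tab)$p.value, fisher_two_sided_oracle(tab),
                 tolerance = 1e-9)
  }
  expect_warning(te_derived_gene_test(character(0), "g1"), "no proximal")
})

test_that("genomic feature assignment is total with fixed precedence", {
  genes <- tibble::tibble(
    gene_id = "g1", chrom = "chr1", start = 10000L, end = 30000L,
    strand = "+", tss = 10000L)
  exons <- tibble::tibble(gene_id = "g1", chrom = "chr1",
                          start = 12000L, end = 13000L)
  enhancers <- tibble::tibble(chrom = "chr1", start = 20000L, end = 21000L)
  te <- tibble::tibble(
    feature_id = c("prom", "enh_in_intron", "exonic", "intronic",
                   "intergenic"),
    chrom = "chr1",
    start = c(8900L, 20400L, 12400L, 15000L, 5000000L),
    end = c(9100L, 20600L, 12600L, 15200L, 5000200L))
  out <- assign_genomic_feature(te, genes, exons, enhancers)
  expect_equal(out$genomic_feature,
               c("promoter", "enhancer", "exon", "intron", "intergenic"))
  # totality on a simulated bundle: categories sum to the TE count
  b <- simulate_te_dataset(small_config(seed = 14))
  f <- assign_genomic_feature(b$te_loci, b$genes, b$exons, b$enhancers)
  expect_equal(nrow(f), nrow(b$te_loci))
  expect_true(all(f$genomic_feature %in%
                    c("promoter", "enhancer", "exon", "intron",
                      "intergenic")))
})
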