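test_that("pseudobulk aggregation is additive and conserves counts", {
  counts <- Matrix::Matrix(matrix(
    c(3, 4, 1,
      0, 2, 5), nrow = 2, byrow = TRUE,
    dimnames = list(c("f1", "f2"), c("c1", "c2", "c3"))), sparse = TRUE)
  cells <- tibble::tibble(
    cell_id = c("c1", "c2", "c3"),
    sample_id = c("S1", "S1", "S2"),
    condition = c("AD", "AD", "control"),
    cell_type = "EX")
  # two cells of S1 with counts 3 and 4 -> pseudobulk 7; too few samples
  # per condition here, so aggregate via the internal path with a warning
  expect_warning(pb0 <- aggregate_pseudobulk(counts, cells, "EX"),
                 "fewer than 2 samples")
  expect_null(pb0)

  b <- simulate_te_dataset(small_config(seed = 12))
  pb <- aggregate_pseudobulk(b$counts, b$cells, "EX")
  ex_cells <- b$cells$cell_id[b$cells$cell_type == "EX"]
  expect_equal(sum(pb$counts), sum(b$counts[, ex_cells]))
  one_sample <- pb$samples$sample_id[1]
  contrib <- b$cells$cell_id[b$cells$cell_type == "EX" &
                               b$cells$sample_id == one_sample]
  expect_equal(unname(pb$counts[, one_sample]),
               unname(Matrix::rowSums(b$counts[, contrib, drop = FALSE])))
  # samples with zero cells of the type get no column
  cells_drop <- b$cells[!(b$cells$cell_type == "EX" &
                            b$cells$sample_id == one_sample), ]
  pb2 <- aggregate_pseudobulk(b$counts, cells_drop, "EX")
  expect_false(one_sample %in% colnames(pb2$counts))
  expect_true(one_sample %in% pb2$excluded_samples)
})

test_that("identical per-condition profiles give log2FC 0 and p near 1", {
  block <- matrix(c(5, 9, 13, 2,
                    0, 3, 7, 11), nrow = 2, byrow = TRUE)
  counts <- cbind(block, block)
  rownames(counts) <- c("f1", "f2")
  colnames(counts) <- paste0("s", 1:8)
  pb <- make_pseudobulk(counts, rep(c("AD", "control"), each = 4),
                        lib_size = rep(100, 8))
  de <- nb_lrt(pb, dispersion = 0.1)
  expect_equal(de$log2fc, c(0, 0), tolerance = 1e-8)
  expect_equal(de$p_value, c(1, 1), tolerance = 1e-6)
})

test_that("with dispersion 0 the test matches a closed-form Poisson LRT", {
  set.seed(31)
  n <- 20
  counts <- matrix(rpois(n * 10, lambda = rep(c(5, 40), 5)), nrow = n)
  rownames(counts) <- paste0("f", 1:n)
  cond <- rep(c("AD", "control"), each = 5)
  ls <- c(80, 120, 100, 90, 110, 95, 105, 115, 85, 100)
  pb <- make_pseudobulk(counts, cond, lib_size = ls)
  de <- nb_lrt(pb, dispersion = 0)
  is_case <- cond == "AD"
  for (i in seq_len(nrow(de))) {
    f <- de$feature_id[i]
    oracle <- poisson_lrt_oracle(counts[f, ], is_case, ls)
    expect_equal(de$p_value[i], oracle$p, tolerance = 1e-6)
    expect_equal(de$log2fc[i], oracle$log2fc, tolerance = 1e-6)
  }
})

test_that("the NB fit agrees with glm + MASS at a fixed dispersion", {
  skip_if_not_installed("MASS")
  set.seed(32)
  n <- 15
  counts <- matrix(rnbinom(n * 12, mu = 30, size = 5), nrow = n)
  rownames(counts) <- paste0("f", 1:n)
  cond <- factor(rep(c("control", "AD"), each = 6),
                 levels = c("control", "AD"))
  ls <- rlnorm(12, log(100), 0.2)
  pb <- make_pseudobulk(counts, as.character(cond), lib_size = ls)
  phi <- 0.2
  de <- nb_lrt(pb, dispersion = phi)
  off <- log(ls)
  for (i in seq_len(n)) {
    y <- counts[i, ]
    fam <- MASS::negative.binomial(theta = 1 / phi)
    full <- glm(y ~ cond + offset(off), family = fam)
    null <- glm(y ~ 1 + offset(off), family = fam)
    stat <- max(0, null$deviance - full$deviance)
    expect_lt(abs(de$log2fc[de$feature_id == rownames(counts)[i]] -
                    unname(coef(full)["condAD"]) / log(2)), 1e-5)
    expect_lt(abs(de$p_value[de$feature_id == rownames(counts)[i]] -
                    pchisq(stat, 1, lower.tail = FALSE)), 1e-5)
  }
})

test_that("the NB-LRT agrees with edgeR at matched dispersion and offsets", {
  skip_if_not_installed("edgeR")
  set.seed(33)
  n <- 40
  mu <- rep(c(10, 50, 200), length.out = n)
  counts <- matrix(rnbinom(n * 18, mu = mu, size = 1 / 0.1), nrow = n)
  rownames(counts) <- paste0("f", 1:n)
  cond <- rep(c("AD", "control"), c(11, 7))
  ls <- rlnorm(18, log(5000), 0.1)
  pb <- make_pseudobulk(counts, cond, lib_size = ls)
  phi <- 0.1
  de <- nb_lrt(pb, dispersion = phi)

  design <- model.matrix(~ factor(cond, levels = c("control", "AD")))
  fit <- edgeR::glmFit(counts, design, dispersion = phi,
                       offset = log(ls), prior.count = 0)
  lrt <- edgeR::glmLRT(fit, coef = 2)
  ord <- match(de$feature_id, rownames(lrt$table))
  expect_equal(de$log2fc, lrt$table$logFC[ord], tolerance = 1e-4)
  expect_equal(de$p_value, lrt$table$PValue[ord], tolerance = 1e-4)
})

test_that("swapping condition labels negates log2FC and keeps p-values", {
  set.seed(34)
  counts <- matrix(rnbinom(30 * 10, mu = 25, size = 4), nrow = 30)
  rownames(counts) <- paste0("f", 1:30)
  cond <- rep(c("AD", "control"), each = 5)
  ls <- rlnorm(10, log(100), 0.1)
  de1 <- nb_lrt(make_pseudobulk(counts, cond, lib_size = ls),
                dispersion = 0.1)
  swapped <- ifelse(cond == "AD", "control", "AD")
  de2 <- nb_lrt(make_pseudobulk(counts, swapped, lib_size = ls),
                dispersion = 0.1)
  expect_equal(de1$log2fc, -de2$log2fc, tolerance = 1e-9)
  expect_equal(de1$p_value, de2$p_value, tolerance = 1e-9)
})

test_that("BH adjustment matches the reference step-up procedure", {
  set.seed(35)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
  # and fdr in results is the BH transform of the p-values
  counts <- matrix(rnbinom(50 * 10, mu = 30, size = 4), nrow = 50)
  rownames(counts) <- paste0("f", 1:50)
  de <- nb_lrt(make_pseudobulk(counts, rep(c("AD", "control"), each = 5)),
               dispersion = 0.1)
  expect_equal(de$fdr, bh_oracle(de$p_value), tolerance = 1e-12)
})

test_that("candidate selection applies both thresholds strictly", {
  res <- tibble::tibble(
    feature_id = c("a", "b", "c", "d"),
    fdr = c(0.04, 0.04, 0.06, 0.049),
    log2fc = c(1.9, -2.5, 5, 2.0))
  out <- call_robust_candidates(res)
  expect_setequal(out$feature_id, c("b", "d"))
})

test_that("untestable features are excluded and counted", {
  counts <- matrix(0, nrow = 3, ncol = 8,
                   dimnames = list(c("ok", "sparse_case", "zero"),
                                   paste0("s", 1:8)))
  counts["ok", ] <- 5
  counts["sparse_case", ] <- c(4, 0, 0, 0, 2, 3, 1, 2)  # 1 nonzero AD sample
  de <- nb_lrt(make_pseudobulk(counts, rep(c("AD", "control"), each = 4),
                               lib_size = rep(50, 8)), dispersion = 0.1)
  expect_equal(de$feature_id, "ok")
  expect_equal(attr(de, "n_untestable"), 2L)
})
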