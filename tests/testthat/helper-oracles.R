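# Independent oracles (brute force / exhaustive enumeration / closed
# form) used to check the package's implementations.

# O(n*m) interval scan: gap between half-open intervals <= window.
brute_force_pairs <- function(te, genes, window) {
  out <- list()
  for (i in seq_len(nrow(te))) {
    for (j in seq_len(nrow(genes))) {
      if (te$chrom[i] != genes$chrom[j]) next
      gap <- max(0, genes$start[j] - te$end[i], te$start[i] - genes$end[j])
      if (gap <= window) {
        out[[length(out) + 1]] <- data.frame(
          te_id = te$feature_id[i], gene_id = genes$gene_id[j],
          distance = gap, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(te_id = character(), gene_id = character(),
                      distance = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$te_id, res$gene_id), , drop = FALSE]
}

# Exhaustive two-sided binomial p (minimum-likelihood convention).
binom_two_sided_oracle <- function(k, n, p) {
  probs <- dbinom(0:n, n, p)
  sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
}

# Hypergeometric upper tail P[X >= k] by direct summation of the pmf.
hyper_tail_oracle <- function(k, K, N, n) {
  kk <- max(0, k):min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Two-sided Fisher p for a 2x2 table by enumerating the hypergeometric
# support (minimum-likelihood convention).
fisher_two_sided_oracle <- function(tab) {
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); kcol <- sum(tab[, 1])
  support <- max(0, kcol - n2):min(m, kcol)
  probs <- dhyper(support, m, n2, kcol)
  obs <- dhyper(tab[1, 1], m, n2, kcol)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Closed-form two-group Poisson GLM LRT with library-size offsets:
# group MLE rate = sum(y_g) / sum(ls_g); deviance difference from exact
# log-likelihoods. Independent of any glm/Newton machinery.
poisson_lrt_oracle <- function(y, is_case, ls) {
  ll <- function(mu) sum(dpois(y, mu, log = TRUE))
  r_case <- sum(y[is_case]) / sum(ls[is_case])
  r_ctrl <- sum(y[!is_case]) / sum(ls[!is_case])
  r_null <- sum(y) / sum(ls)
  mu_full <- ifelse(is_case, r_case, r_ctrl) * ls
  stat <- max(0, 2 * (ll(mu_full) - ll(r_null * ls)))
  list(log2fc = log2(r_case / r_ctrl),
       p = pchisq(stat, 1, lower.tail = FALSE))
}

# Reference Benjamini-Hochberg step-up adjustment.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Build a te_pseudobulk directly from a counts matrix (for unit tests).
make_pseudobulk <- function(counts, condition, lib_size = NULL,
                            cell_type = "toy") {
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("f", seq_len(nrow(counts)))
  }
  structure(list(
    counts = counts,
    samples = tibble::tibble(
      sample_id = colnames(counts) %||% paste0("s", seq_len(ncol(counts))),
      condition = condition, n_cells = 1L,
      lib_size = lib_size %||% colSums(counts)),
    cell_type = cell_type, excluded_samples = character()
  ), class = "te_pseudobulk")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
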