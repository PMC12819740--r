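# Pseudobulk differential expression: sum cells to sample-level counts per
# cell type, then test AD vs control per feature with a negative-binomial
# GLM likelihood-ratio test (1 df) using log-library-size offsets.
#
# Dispersion is estimated per feature by maximum likelihood and shrunk on
# the log scale toward the common (all-feature) dispersion with a fixed
# weight (default 0.3 toward common) - a deliberately simple
# empirical-Bayes average; the calibration and recovery properties in the
# test suite are the contract, not any particular shrinkage recipe.

#' Aggregate single cells to sample-level pseudobulk for one cell type
#'
#' Entry (f, s) is the sum of counts of feature f over all cells of
#' `cell_type` in sample s. Samples contributing zero cells of the type
#' are excluded (and recorded); aggregation conserves total counts
#' exactly.
#'
#' @param counts Features x cells count matrix.
#' @param cells Cell metadata tibble (`cell_id`, `sample_id`, `condition`,
#'   `cell_type`).
#' @param cell_type Cell-type label to aggregate.
#' @return A `te_pseudobulk` list: `counts` (features x samples),
#'   `samples` tibble (`sample_id`, `condition`, `n_cells`, `lib_size`),
#'   `cell_type`, `excluded_samples`. `NULL` (with a warning) when fewer
#'   than 2 samples per condition remain.
#' @export
aggregate_pseudobulk <- function(counts, cells, cell_type) {
  stopifnot_cols(cells, c("cell_id", "sample_id", "condition", "cell_type"),
                 "cell metadata")
  sel <- cells[cells$cell_type == cell_type, ]
  if (nrow(sel) == 0) {
    warn(sprintf("no cells of type %s", cell_type))
    return(NULL)
  }
  sel <- sel[match(intersect(colnames(counts), sel$cell_id), sel$cell_id), ]
  sample_ids <- sort(unique(sel$sample_id))
  # indicator matrix cells x samples, then one sparse matrix product
  ind <- Matrix::sparseMatrix(
    i = match(sel$cell_id, colnames(counts)),
    j = match(sel$sample_id, sample_ids),
    x = 1, dims = c(ncol(counts), length(sample_ids))
  )
  pb <- as.matrix(counts %*% ind)
  colnames(pb) <- sample_ids

  cond <- sel$condition[match(sample_ids, sel$sample_id)]
  n_cells <- as.vector(table(factor(sel$sample_id, levels = sample_ids)))
  all_samples <- unique(cells[, c("sample_id", "condition")])
  excluded <- setdiff(all_samples$sample_id, sample_ids)

  samples <- tibble(sample_id = sample_ids, condition = cond,
                    n_cells = n_cells, lib_size = colSums(pb))
  if (sum(cond == "AD") < 2 || sum(cond == "control") < 2) {
    warn(sprintf("cell type %s: fewer than 2 samples per condition; skipped",
                 cell_type))
    return(NULL)
  }
  structure(list(counts = pb, samples = samples, cell_type = cell_type,
                 excluded_samples = excluded),
            class = "te_pseudobulk")
}

# Row-wise NB log-likelihood (features x samples), Poisson limit at
# phi ~ 0. `phi` is a per-feature vector.
nb_loglik_rows <- function(Y, mu, phi) {
  ll <- numeric(nrow(Y))
  pois <- phi <= 1e-12
  if (any(pois)) {
    ll[pois] <- rowSums(stats::dpois(Y[pois, , drop = FALSE],
                                     mu[pois, , drop = FALSE], log = TRUE))
  }
  if (any(!pois)) {
    sz <- matrix(1 / phi[!pois], sum(!pois), ncol(Y))
    ll[!pois] <- rowSums(stats::dnbinom(Y[!pois, , drop = FALSE],
                                        mu = mu[!pois, , drop = FALSE],
                                        size = sz, log = TRUE))
  }
  ll
}

# Newton-scoring fit of one log-rate per feature for a block of samples:
# mu_fj = exp(b_f) * ls_j. The score in b is sum_j (y - mu)/(1 + phi mu),
# strictly decreasing in b, so Newton with a step cap converges; the
# Poisson case (phi = 0) is exact after the first step.
newton_group_fit <- function(Y, ls, phi, max_iter = 100, tol = 1e-8) {
  b <- log(pmax(unname(rowSums(Y)), 0.25) / sum(ls))
  step <- rep(Inf, nrow(Y))
  for (it in seq_len(max_iter)) {
    mu <- exp(b) %o% ls
    denom <- 1 + phi * mu
    score <- rowSums((Y - mu) / denom)
    info <- rowSums(mu * (1 + phi * Y) / denom^2)
    step <- score / pmax(info, 1e-12)
    step <- pmin(pmax(step, -5), 5)
    b <- unname(b + step)
    if (max(abs(step)) < tol) break
  }
  list(b = b, converged = unname(abs(step) < 1e-4))
}

# Poisson MLE group means under a library-size offset (closed form),
# used as the fitted values when profiling the dispersion.
poisson_group_means <- function(Y, ls, cond) {
  mu <- matrix(0, nrow(Y), ncol(Y))
  for (g in levels(cond)) {
    in_g <- cond == g
    rate <- rowSums(Y[, in_g, drop = FALSE]) / sum(ls[in_g])
    mu[, in_g] <- rate %o% ls[in_g]
  }
  pmax(mu, 1e-8)
}

# Per-feature ML dispersion by profile likelihood over a log-spaced grid
# with one parabolic refinement, means held at the Poisson group fit.
estimate_dispersion_rows <- function(Y, mu, grid = exp(seq(log(1e-4), log(20),
                                                           length.out = 31))) {
  ll <- vapply(grid, function(phi) {
    nb_loglik_rows(Y, mu, rep(phi, nrow(Y)))
  }, numeric(nrow(Y)))
  ll <- matrix(ll, nrow = nrow(Y))
  best <- max.col(ll, ties.method = "first")
  lg <- log(grid)
  refine <- function(i) {
    j <- best[i]
    if (j == 1 || j == length(grid)) return(grid[j])
    y0 <- ll[i, j - 1]; y1 <- ll[i, j]; y2 <- ll[i, j + 1]
    den <- y0 - 2 * y1 + y2
    if (!is.finite(den) || den >= 0) return(grid[j])
    exp(lg[j] + 0.5 * (lg[j] - lg[j - 1]) * (y0 - y2) / den)
  }
  vapply(seq_len(nrow(Y)), refine, 0)
}

#' Negative-binomial likelihood-ratio test on a pseudobulk matrix
#'
#' Per feature, fits the NB log-linear model
#' `log mu = beta0 + beta1 * condition + log(lib_size)` and compares its
#' deviance against the intercept-only model (chi-square, 1 df).
#' `log2fc` is the condition coefficient divided by `ln 2` (AD over
#' control). Benjamini-Hochberg correction is applied across tested
#' features within the cell type. Features without nonzero counts in at
#' least 2 samples per condition are excluded before testing (recorded in
#' the `n_untestable` attribute); non-converged fits get `NA` p-values and
#' are excluded from the correction.
#'
#' @param pb A `te_pseudobulk` from [aggregate_pseudobulk()].
#' @param dispersion Optional fixed dispersion applied to every feature
#'   (0 gives an exact Poisson GLM LRT); `NULL` (default) estimates per
#'   feature with shrinkage.
#' @param shrink_weight Weight pulling per-feature log-dispersion toward
#'   the common dispersion (0 = none, 1 = fully common). Default 0.3.
#' @param fdr_threshold,lfc_threshold Thresholds recorded in the
#'   `significant` / `passes_effect` columns (defaults 0.05 and 2).
#' @return A `te_de` tibble: `feature_id`, `cell_type`, `base_mean`,
#'   `log2fc`, `p_value`, `fdr`, `significant`, `passes_effect`,
#'   `converged`, `dispersion`.
#' @export
nb_lrt <- function(pb, dispersion = NULL, shrink_weight = 0.3,
                   fdr_threshold = 0.05, lfc_threshold = 2) {
  stopifnot(inherits(pb, "te_pseudobulk"))
  counts <- pb$counts
  cond <- factor(pb$samples$condition, levels = c("control", "AD"))
  log_ls <- log(pmax(pb$samples$lib_size, 1))

  nz_case <- rowSums(counts[, cond == "AD", drop = FALSE] > 0)
  nz_ctrl <- rowSums(counts[, cond == "control", drop = FALSE] > 0)
  testable <- nz_case >= 2 & nz_ctrl >= 2
  n_untestable <- sum(!testable)
  counts <- counts[testable, , drop = FALSE]
  n <- nrow(counts)
  if (n == 0) {
    warn("no testable features")
    empty <- empty_de(pb$cell_type)
    attr(empty, "n_untestable") <- n_untestable
    return(empty)
  }

  ls <- exp(log_ls)
  if (is.null(dispersion)) {
    mu0 <- poisson_group_means(counts, ls, cond)
    phi_raw <- pmax(estimate_dispersion_rows(counts, mu0), 1e-6)
    common <- exp(mean(log(phi_raw)))
    phi <- exp((1 - shrink_weight) * log(phi_raw) +
                 shrink_weight * log(common))
  } else {
    phi <- rep(dispersion, n)
    common <- dispersion
  }

  is_case <- cond == "AD"
  fit_case <- newton_group_fit(counts[, is_case, drop = FALSE],
                               ls[is_case], phi)
  fit_ctrl <- newton_group_fit(counts[, !is_case, drop = FALSE],
                               ls[!is_case], phi)
  fit_null <- newton_group_fit(counts, ls, phi)
  mu_full <- matrix(0, n, ncol(counts))
  mu_full[, is_case] <- exp(fit_case$b) %o% ls[is_case]
  mu_full[, !is_case] <- exp(fit_ctrl$b) %o% ls[!is_case]
  mu_null <- exp(fit_null$b) %o% ls
  lrt <- unname(pmax(0, 2 * (nb_loglik_rows(counts, mu_full, phi) -
                               nb_loglik_rows(counts, mu_null, phi))))
  converged <- fit_case$converged & fit_ctrl$converged & fit_null$converged

  res <- tibble(
    feature_id = rownames(counts),
    cell_type = pb$cell_type,
    base_mean = unname(rowMeans(counts)),
    log2fc = ifelse(converged, (fit_case$b - fit_ctrl$b) / log(2), NA_real_),
    p_value = ifelse(converged, pchisq(lrt, 1, lower.tail = FALSE), NA_real_),
    converged = converged,
    dispersion = phi
  )
  res$fdr <- NA_real_
  ok <- !is.na(res$p_value)
  res$fdr[ok] <- p.adjust(res$p_value[ok], method = "BH")
  res$significant <- !is.na(res$fdr) & res$fdr < fdr_threshold
  res$passes_effect <- !is.na(res$log2fc) & abs(res$log2fc) >= lfc_threshold
  res <- res[, c("feature_id", "cell_type", "base_mean", "log2fc",
                 "p_value", "fdr", "significant", "passes_effect",
                 "converged", "dispersion")]
  res <- new_te_de(res)
  attr(res, "n_untestable") <- n_untestable
  attr(res, "n_nonconverged") <- sum(!res$converged)
  attr(res, "common_dispersion") <- common
  attr(res, "thresholds") <- c(fdr = fdr_threshold, lfc = lfc_threshold)
  res
}

empty_de <- function(cell_type) {
  new_te_de(tibble(
    feature_id = character(), cell_type = character(), base_mean = numeric(),
    log2fc = numeric(), p_value = numeric(), fdr = numeric(),
    significant = logical(), passes_effect = logical(), converged = logical(),
    dispersion = numeric()
  ))
}

new_te_de <- function(df) {
  class(df) <- c("te_de", class(df))
  df
}

#' Select candidate TEs passing both significance and effect thresholds
#'
#' Returns the rows with `fdr < fdr_threshold` and
#' `|log2fc| >= lfc_threshold` (defaults 0.05 and 2.0, the robust-TE
#' thresholds).
#'
#' @param results A `te_de` tibble (possibly several cell types bound
#'   together).
#' @param fdr_threshold,lfc_threshold Selection thresholds.
#' @return The filtered tibble.
#' @export
call_robust_candidates <- function(results, fdr_threshold = 0.05,
                                   lfc_threshold = 2) {
  stopifnot_cols(results, c("fdr", "log2fc"), "DE results")
  results[!is.na(results$fdr) & results$fdr < fdr_threshold &
            !is.na(results$log2fc) & abs(results$log2fc) >= lfc_threshold, ]
}
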