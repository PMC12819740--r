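# Balanced-downsampling robustness screen for imbalanced designs: repeat
# the DE test K times on random case subsets matched in size to the
# control group, and call a feature "highly robust" only if it is
# significant in the full data and in every iteration.

#' Draw balanced downsampling plans
#'
#' Draws `k` distinct, uniformly sampled subsets of the case samples, each
#' of size `length(control_ids)`; all controls are always retained.
#' Distinctness is enforced by rejection resampling.
#'
#' @param case_ids,control_ids Character vectors of sample ids.
#' @param k Number of iterations (default 10).
#' @param seed Integer seed making the plan list deterministic.
#' @return Tibble with `iteration` and list-column `retained_cases`.
#' @export
#' @examples
#' make_plans(paste0("AD", 1:11), paste0("CT", 1:7), k = 10, seed = 1)
make_plans <- function(case_ids, control_ids, k = 10, seed = 1) {
  n_case <- length(case_ids)
  n_keep <- length(control_ids)
  if (n_case < n_keep) abort("need at least as many cases as controls")
  n_subsets <- choose(n_case, n_keep)
  if (k > n_subsets) {
    abort(sprintf("k = %d exceeds the %d distinct subsets of size %d",
                  k, n_subsets, n_keep))
  }
  withr_seed(seed, {
    seen <- character(0)
    plans <- vector("list", k)
    i <- 1L
    while (i <= k) {
      keep <- sort(sample(case_ids, n_keep))
      key <- paste(keep, collapse = ",")
      if (!key %in% seen) {
        seen <- c(seen, key)
        plans[[i]] <- keep
        i <- i + 1L
      }
    }
  })
  tibble(iteration = seq_len(k), retained_cases = plans)
}

#' Run the DE test across balanced downsampling iterations
#'
#' For each plan, restricts the pseudobulk matrix to the retained case
#' samples plus all controls and reruns [nb_lrt()].
#'
#' @param pb A `te_pseudobulk`.
#' @param plans Tibble from [make_plans()].
#' @param ... Passed on to [nb_lrt()].
#' @return List of `te_de` tibbles, one per iteration.
#' @export
run_downsampled_de <- function(pb, plans, ...) {
  stopifnot(inherits(pb, "te_pseudobulk"))
  control_ids <- pb$samples$sample_id[pb$samples$condition == "control"]
  lapply(plans$retained_cases, function(keep_cases) {
    keep <- pb$samples$sample_id %in% c(keep_cases, control_ids)
    sub <- structure(list(
      counts = pb$counts[, keep, drop = FALSE],
      samples = pb$samples[keep, ],
      cell_type = pb$cell_type,
      excluded_samples = c(pb$excluded_samples,
                           setdiff(pb$samples$sample_id,
                                   pb$samples$sample_id[keep]))
    ), class = "te_pseudobulk")
    nb_lrt(sub, ...)
  })
}

#' Classify features by downsampling robustness
#'
#' A feature is "highly robust" iff it is significant (FDR below the
#' per-run threshold) in the full data **and** in all `K` balanced
#' iterations (100% detection). A feature absent from an iteration (for
#' example, filtered as untestable there) counts as not detected in it.
#'
#' @param full A `te_de` tibble from the full data.
#' @param per_iteration List of `te_de` tibbles, one per iteration.
#' @return Tibble with `feature_id`, `cell_type`, `significant_full`,
#'   `detection_count`, `k`, `highly_robust`.
#' @export
classify_robust <- function(full, per_iteration) {
  k <- length(per_iteration)
  detect <- lapply(per_iteration, function(res) {
    res$feature_id[res$significant]
  })
  detection_count <- vapply(full$feature_id, function(f) {
    sum(vapply(detect, function(d) f %in% d, TRUE))
  }, 0L)
  tibble(
    feature_id = full$feature_id,
    cell_type = full$cell_type,
    significant_full = full$significant,
    detection_count = unname(detection_count),
    k = k,
    highly_robust = full$significant & detection_count == k
  )
}
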