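# ATAC integration: accessibility profiles at TE loci and the weighted
# composite regulatory score for TE-gene pairs, with confidence tiers.

#' Chromatin accessibility profile of TE loci
#'
#' For each TE: whether it directly overlaps an ATAC peak, the number of
#' peaks within `window` bp, and - over those peaks' rows of the
#' accessibility matrix - the mean accessibility, the peak variance, and
#' the cell-type specificity index
#' `tau = sum(1 - x / max(x)) / (n - 1)` computed on per-cell-type mean
#' accessibility `x` (0 = uniform across cell types, 1 = confined to a
#' single type). TEs with no peak in the window get zero metrics and are
#' flagged.
#'
#' @param te_loci Tibble with `feature_id`, `chrom`, `start`, `end`.
#' @param peaks Tibble with `peak_id`, `chrom`, `start`, `end`.
#' @param peak_matrix Numeric matrix, peaks x cell types, rownames =
#'   `peak_id`.
#' @param window Search window in bp (default 250,000).
#' @return Tibble with `te_id`, `overlaps_peak`, `n_peaks_within_window`,
#'   `mean_accessibility`, `peak_variance`, `tau`, `no_peak_in_window`.
#' @export
accessibility_profile <- function(te_loci, peaks, peak_matrix,
                                  window = 250e3) {
  stopifnot_cols(te_loci, c("feature_id", "chrom", "start", "end"), "te_loci")
  stopifnot_cols(peaks, c("peak_id", "chrom", "start", "end"), "peaks")
  if (!all(peaks$peak_id %in% rownames(peak_matrix))) {
    abort("every peak must have a row in peak_matrix")
  }
  lvls <- unique(c(te_loci$chrom, peaks$chrom))
  hits <- GenomicRanges::findOverlaps(
    gr_from_halfopen(te_loci, lvls), gr_from_halfopen(peaks, lvls),
    maxgap = window, ignore.strand = TRUE
  )
  ti <- S4Vectors::queryHits(hits)
  pi <- S4Vectors::subjectHits(hits)
  gap <- interval_gap(te_loci$start[ti], te_loci$end[ti],
                      peaks$start[pi], peaks$end[pi])
  keep <- gap <= window
  ti <- ti[keep]; pi <- pi[keep]; gap <- gap[keep]

  purrr::map_dfr(seq_len(nrow(te_loci)), function(i) {
    p_idx <- pi[ti == i]
    g <- gap[ti == i]
    if (length(p_idx) == 0) {
      return(tibble(te_id = te_loci$feature_id[i], overlaps_peak = FALSE,
                    n_peaks_within_window = 0L, mean_accessibility = 0,
                    peak_variance = 0, tau = 0, no_peak_in_window = TRUE))
    }
    sub <- peak_matrix[peaks$peak_id[p_idx], , drop = FALSE]
    x <- colMeans(sub)
    tau <- if (max(x) > 0 && length(x) > 1) {
      sum(1 - x / max(x)) / (length(x) - 1)
    } else 0
    tibble(
      te_id = te_loci$feature_id[i],
      overlaps_peak = any(g == 0),
      n_peaks_within_window = length(p_idx),
      mean_accessibility = mean(sub),
      peak_variance = if (length(sub) > 1) var(as.vector(sub)) else 0,
      tau = tau,
      no_peak_in_window = FALSE
    )
  })
}

#' Default weights of the composite regulatory score
#'
#' Genomic distance 0.3, chromatin accessibility 0.3, DE effect size 0.2,
#' TE-gene expression correlation 0.2.
#'
#' @return Named numeric vector summing to 1.
#' @export
score_weights <- function() {
  c(distance = 0.3, accessibility = 0.3, effect = 0.2, correlation = 0.2)
}

#' TE-gene pseudobulk expression correlation
#'
#' Product-moment correlation between TE and gene expression across
#' sample-by-cell-type pseudobulk units, computed on log1p of
#' library-size-normalised counts. Used as the correlation component of
#' the regulatory score; externally supplied (e.g. simulated)
#' correlations can be injected instead via the `correlation` argument of
#' [score_pairs()].
#'
#' @param pairs Tibble with `te_id`, `gene_id`.
#' @param pseudobulks List of `te_pseudobulk` objects (one per cell
#'   type).
#' @return `pairs` with a `correlation` column (NA when either profile is
#'   constant).
#' @export
pair_expression_correlation <- function(pairs, pseudobulks) {
  pseudobulks <- Filter(Negate(is.null), pseudobulks)
  if (length(pseudobulks) == 0) abort("no pseudobulk matrices supplied")
  mats <- lapply(pseudobulks, function(pb) {
    cpm <- t(t(pb$counts) / pmax(pb$samples$lib_size, 1)) * 1e4
    log1p(cpm)
  })
  common <- Reduce(intersect, lapply(mats, rownames))
  expr <- do.call(cbind, lapply(mats, function(m) m[common, , drop = FALSE]))
  corr <- vapply(seq_len(nrow(pairs)), function(i) {
    te <- pairs$te_id[i]; gn <- pairs$gene_id[i]
    if (!te %in% common || !gn %in% common) return(NA_real_)
    x <- expr[te, ]; y <- expr[gn, ]
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, 0)
  mutate(pairs, correlation = corr)
}

#' Composite regulatory score for TE-gene pairs
#'
#' Combines four components in `[0, 1]`:
#' `s_dist = 1 - min(d, W)/W` (W = the scoring window),
#' `s_acc` = min-max normalised mean accessibility,
#' `s_eff` = min-max normalised |log2FC|, and
#' `s_corr = max(r, 0)` (negative correlations carry no regulatory
#' support). The composite is the weighted sum (weights
#' [score_weights()] by default). Min-max contexts are computed over the
#' scored set; a degenerate (constant) context is neutralised at 0.5
#' with a warning. Missing correlations score 0.
#'
#' @param pairs Tibble with `te_id`, `gene_id`, `distance` and optionally
#'   `correlation`.
#' @param profiles Accessibility profiles from [accessibility_profile()].
#' @param de `te_de` results supplying `log2fc` per `te_id` (the maximum
#'   |log2fc| across cell types is used when a TE was tested in several).
#' @param window Scoring window W in bp (default 250,000).
#' @param weights Named weights (`distance`, `accessibility`, `effect`,
#'   `correlation`), non-negative, summing to 1.
#' @param correlation Optional numeric vector overriding
#'   `pairs$correlation` (e.g. simulated correlations).
#' @return A `te_scores` tibble: pair columns plus `s_dist`, `s_acc`,
#'   `s_eff`, `s_corr`, `composite`, `overlaps_peak`.
#' @export
score_pairs <- function(pairs, profiles, de, window = 250e3,
                        weights = score_weights(), correlation = NULL) {
  stopifnot_cols(pairs, c("te_id", "gene_id", "distance"), "pairs")
  stopifnot(all(weights >= 0), abs(sum(weights) - 1) < 1e-9)
  if (!is.null(correlation)) pairs$correlation <- correlation
  if (!"correlation" %in% names(pairs)) pairs$correlation <- NA_real_

  prof <- profiles[match(pairs$te_id, profiles$te_id), ]
  de_eff <- de |>
    group_by(.data$feature_id) |>
    summarise(abs_lfc = max(abs(.data$log2fc), na.rm = TRUE),
              .groups = "drop")
  eff <- de_eff$abs_lfc[match(pairs$te_id, de_eff$feature_id)]
  eff[is.na(eff)] <- 0

  out <- pairs |>
    mutate(
      s_dist = 1 - pmin(.data$distance, window) / window,
      s_acc = minmax(prof$mean_accessibility, warn_constant = TRUE),
      s_eff = minmax(eff, warn_constant = TRUE),
      s_corr = pmax(dplyr::coalesce(.data$correlation, 0), 0),
      composite = weights[["distance"]] * .data$s_dist +
        weights[["accessibility"]] * .data$s_acc +
        weights[["effect"]] * .data$s_eff +
        weights[["correlation"]] * .data$s_corr,
      overlaps_peak = prof$overlaps_peak
    )
  class(out) <- c("te_scores", class(out))
  attr(out, "weights") <- weights
  attr(out, "normalization") <- list(
    accessibility_range = range(prof$mean_accessibility),
    effect_range = range(eff), window = window
  )
  out
}

#' Assign confidence tiers to scored pairs
#'
#' `high_confidence` requires direct peak overlap **and** a composite
#' above the set-wise median. Tiers: Very High = high confidence with
#' correlation support (`s_corr >= corr_support`); High = high confidence
#' without it; Medium = exactly one of peak overlap / above-median
#' composite; Low = neither.
#'
#' @param scores A `te_scores` tibble from [score_pairs()].
#' @param corr_support Correlation-support threshold (default 0.3).
#' @return `scores` with `high_confidence` and `tier` columns.
#' @export
classify_confidence <- function(scores, corr_support = 0.3) {
  stopifnot_cols(scores, c("composite", "overlaps_peak", "s_corr"), "scores")
  med <- median(scores$composite)
  above <- scores$composite > med
  hc <- scores$overlaps_peak & above
  tier <- dplyr::case_when(
    hc & scores$s_corr >= corr_support ~ "Very High",
    hc ~ "High",
    xor(scores$overlaps_peak, above) ~ "Medium",
    TRUE ~ "Low"
  )
  out <- mutate(scores, high_confidence = hc,
                tier = factor(tier, levels = c("Very High", "High",
                                               "Medium", "Low")))
  attr(out, "median_composite") <- med
  out
}
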