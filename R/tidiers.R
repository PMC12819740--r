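# broom-style accessors for fitted/result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a differential expression result
#'
#' @param x A `te_de` tibble.
#' @param ... Unused.
#' @return A plain tibble of per-feature results.
#' @method tidy te_de
#' @export
tidy.te_de <- function(x, ...) {
  as_tibble(unclass(x)[names(x)])
}

#' One-row summary of a differential expression result
#'
#' @param x A `te_de` tibble.
#' @param ... Unused.
#' @return Tibble with test counts, significance counts and the common
#'   dispersion.
#' @method glance te_de
#' @export
glance.te_de <- function(x, ...) {
  tibble(
    n_tested = nrow(x),
    n_significant = sum(x$significant, na.rm = TRUE),
    n_pass_effect = sum(x$significant & x$passes_effect, na.rm = TRUE),
    n_untestable = attr(x, "n_untestable") %||% NA_integer_,
    n_nonconverged = attr(x, "n_nonconverged") %||% NA_integer_,
    common_dispersion = attr(x, "common_dispersion") %||% NA_real_
  )
}

#' Tidy a regulatory score table
#'
#' @param x A `te_scores` tibble.
#' @param ... Unused.
#' @return A plain tibble of scored pairs.
#' @method tidy te_scores
#' @export
tidy.te_scores <- function(x, ...) {
  as_tibble(unclass(x)[names(x)])
}

#' One-row summary of a regulatory score table
#'
#' @param x A `te_scores` tibble.
#' @param ... Unused.
#' @return Tibble with pair counts, median composite and tier counts.
#' @method glance te_scores
#' @export
glance.te_scores <- function(x, ...) {
  out <- tibble(
    n_pairs = nrow(x),
    median_composite = median(x$composite),
    n_peak_overlap = sum(x$overlaps_peak)
  )
  if ("tier" %in% names(x)) {
    tier_n <- table(x$tier)
    out$n_very_high <- unname(tier_n["Very High"])
    out$n_high_confidence <- sum(x$high_confidence)
  }
  out
}

#' Tidy a full pipeline run
#'
#' @param x A `te_pipeline`.
#' @param ... Unused.
#' @return The robust DE TE table.
#' @method tidy te_pipeline
#' @export
tidy.te_pipeline <- function(x, ...) {
  tidy(x$robust_de)
}

#' One-row summary of a pipeline run
#'
#' @param x A `te_pipeline`.
#' @param ... Unused.
#' @return Tibble of headline counts (tests run, robust TEs, direction
#'   split, selected window, scored pairs).
#' @method glance te_pipeline
#' @export
glance.te_pipeline <- function(x, ...) {
  dirn <- x$annotation$direction_overall
  tibble(
    n_de_tests = nrow(x$de),
    n_robust_tes = nrow(x$robust_de),
    pct_up = if (nrow(dirn) > 0) dirn$pct_up else NA_real_,
    mean_te_pct = mean(x$te_fraction$te_pct, na.rm = TRUE),
    selected_window = x$manifest$selected_window,
    n_scored_pairs = x$manifest$stage_rows$pairs_selected_window
  )
}
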