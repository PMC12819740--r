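# ggplot2 views of the main result types.

#' Violin plot of per-cell TE transcript fractions by cell type
#'
#' @param te_fraction Tibble from [te_fraction_per_cell()] with
#'   `cell_type` joined.
#' @return A ggplot.
#' @export
plot_te_fraction <- function(te_fraction) {
  stopifnot_cols(te_fraction, c("te_pct", "cell_type"), "te_fraction")
  ggplot2::ggplot(te_fraction[!is.na(te_fraction$te_pct), ],
                  ggplot2::aes(x = .data$cell_type, y = .data$te_pct)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_boxplot(width = 0.12, outlier.size = 0.4) +
    ggplot2::labs(x = NULL, y = "TE-derived transcripts (% of cell total)") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential expression result
#'
#' @param object A `te_de` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot te_de
#' @export
autoplot.te_de <- function(object, ...) {
  df <- tidy(object)
  df <- df[!is.na(df$p_value), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(pmax(.data$p_value, 1e-300)),
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 0.7, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (AD / control)",
                  y = "-log10 p", colour = "FDR < threshold") +
    ggplot2::theme_minimal()
}

#' Bar chart of per-cell-type up/down direction of robust TEs
#'
#' @param direction Tibble from [summarize_direction()] with
#'   `by = "cell_type"`.
#' @return A ggplot.
#' @export
plot_direction_summary <- function(direction) {
  stopifnot_cols(direction, c("cell_type", "n_up", "n_down"), "direction")
  long <- tidyr::pivot_longer(direction[, c("cell_type", "n_up", "n_down")],
                              c("n_up", "n_down"),
                              names_to = "direction", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cell_type, y = .data$count,
                                     fill = .data$direction)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_manual(
      values = c(n_up = "firebrick", n_down = "steelblue"),
      labels = c(n_up = "up in AD", n_down = "down in AD")) +
    ggplot2::labs(x = NULL, y = "robust DE TEs", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Normalized window-selection matrix as a tile plot
#'
#' @param selection List from [select_window()].
#' @return A ggplot.
#' @export
plot_window_selection <- function(selection) {
  scores <- selection$scores
  long <- tidyr::pivot_longer(
    scores[, c("window", "s_specificity", "s_functional", "s_coverage",
               "composite")],
    -"window", names_to = "component", values_to = "score")
  long$window_kb <- factor(long$window / 1e3,
                           levels = sort(unique(long$window)) / 1e3)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$window_kb,
                                     y = .data$component,
                                     fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$score)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "darkgreen",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "window (kb)", y = NULL, fill = "score") +
    ggplot2::theme_minimal()
}

#' Composite-score distribution by confidence tier
#'
#' @param object A `te_scores` tibble (after [classify_confidence()]).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot te_scores
#' @export
autoplot.te_scores <- function(object, ...) {
  stopifnot_cols(object, c("composite", "tier"), "scores")
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$tier,
                                             y = .data$composite)) +
    ggplot2::geom_jitter(width = 0.15, size = 0.8, alpha = 0.6) +
    ggplot2::labs(x = "confidence tier", y = "composite regulatory score") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
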