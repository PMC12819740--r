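# TE annotation: direction summaries, class composition, evolutionary age
# classes, family enrichment against genomic baseline composition,
# chromosome-level enrichment, and cluster-size bias diagnostics.

#' Summarise up/down direction of DE TEs
#'
#' Counts up- and downregulated results (sign of `log2fc`) overall or per
#' cell type, with percentages to one decimal. Zero log2fc entries are
#' excluded from the up/down split and reported in `n_zero`.
#'
#' @param results Tibble with `log2fc` (and `cell_type` if
#'   `by = "cell_type"`).
#' @param by `"overall"` or `"cell_type"`.
#' @return Tibble with `n`, `n_up`, `n_down`, `n_zero`, `pct_up`,
#'   `pct_down` (one row per group).
#' @export
#' @examples
#' summarize_direction(tibble::tibble(log2fc = c(2, 3, -2.5)))
summarize_direction <- function(results, by = c("overall", "cell_type")) {
  by <- match.arg(by)
  stopifnot_cols(results, "log2fc", "results")
  grouped <- if (by == "cell_type") {
    stopifnot_cols(results, "cell_type", "results")
    group_by(results, .data$cell_type)
  } else results
  out <- summarise(
    grouped,
    n = sum(.data$log2fc != 0),
    n_up = sum(.data$log2fc > 0),
    n_down = sum(.data$log2fc < 0),
    n_zero = sum(.data$log2fc == 0),
    .groups = "drop"
  )
  out |>
    mutate(pct_up = ifelse(.data$n > 0, round(100 * .data$n_up / .data$n, 1),
                           NA_real_),
           pct_down = ifelse(.data$n > 0,
                             round(100 * .data$n_down / .data$n, 1),
                             NA_real_))
}

#' TE class composition
#'
#' Counts and percentages (one decimal) per TE class over
#' \{SINE, LINE, LTR, DNA, other\}; classes with zero members are dropped.
#'
#' @param te_loci Tibble with a `te_class` column.
#' @return Tibble with `te_class`, `n`, `pct`, sorted by descending count.
#' @export
class_composition <- function(te_loci) {
  stopifnot_cols(te_loci, "te_class", "te_loci")
  if (nrow(te_loci) == 0) {
    return(tibble(te_class = character(), n = integer(), pct = numeric()))
  }
  te_loci |>
    count(.data$te_class, name = "n") |>
    mutate(pct = round(100 * .data$n / sum(.data$n), 1)) |>
    arrange(desc(.data$n))
}

#' Evolutionary age classification rules
#'
#' Pattern rules mapping TE subfamilies to age classes following
#' established retrotransposon phylogeny: LINE-1 subfamilies are Young
#' (<6 Mya: L1HS, L1PA2-L1PA8), Old (6-40 Mya: L1PA9-L1PA17, L1PB),
#' Very Old (40-80 Mya: L1M) or Ancient (>80 Mya: L2, L3); Alu
#' subfamilies are Young (<25 Mya: AluY), Old (25-50 Mya: AluS) or
#' Ancient (>50 Mya: AluJ, MIR). Anything unmatched is "unclassified".
#'
#' @return Tibble with `pattern` (regular expression), `age` - applied in
#'   order, first match wins.
#' @export
age_class_rules <- function() {
  tibble(
    pattern = c("^L1HS", "^L1PA([2-8])($|[^0-9])", "^L1PA(9|1[0-7])",
                "^L1PB", "^L1M", "^L2", "^L3",
                "^AluY", "^AluS", "^AluJ", "^MIR"),
    age = c("Young", "Young", "Old", "Old", "Very Old", "Ancient", "Ancient",
            "Young", "Old", "Ancient", "Ancient")
  )
}

#' Assign an evolutionary age class to TE subfamilies
#'
#' Deterministic first-match lookup against [age_class_rules()];
#' subfamilies matching no rule return `"unclassified"`.
#'
#' @param subfamily Character vector of subfamily names (e.g. "L1PA4").
#' @param rules Rules tibble (default [age_class_rules()]).
#' @return Character vector of age classes.
#' @export
#' @examples
#' assign_age(c("L1PA4", "AluSx", "MIRb", "HERVK9-int"))
assign_age <- function(subfamily, rules = age_class_rules()) {
  out <- rep("unclassified", length(subfamily))
  undecided <- rep(TRUE, length(subfamily))
  for (i in seq_len(nrow(rules))) {
    hit <- undecided & grepl(rules$pattern[i], subfamily)
    out[hit] <- rules$age[i]
    undecided[hit] <- FALSE
  }
  out
}

#' TE family enrichment against a genomic baseline
#'
#' Tests whether the family composition of a TE set deviates from genomic
#' baseline proportions: an overall chi-square goodness-of-fit test plus
#' per-family exact two-sided binomial tests (minimum-likelihood
#' convention) with Benjamini-Hochberg correction. Families observed but
#' absent from the baseline are pooled into `"other"`. Fold is
#' `(k_f / N) / pi_f` (reported to full precision; round to 2 decimals
#' for display).
#'
#' @param observed Named integer vector (or tibble with `family`, `n`) of
#'   observed family counts.
#' @param baseline Named proportions (default [baseline_composition()]).
#' @return A list with `families` (tibble: `family`, `n`, `prop`,
#'   `baseline`, `fold`, `p_value`, `q_value`) and `chisq` (tibble:
#'   `statistic`, `df`, `p_value`).
#' @export
family_enrichment <- function(observed, baseline = baseline_composition()) {
  if (is.data.frame(observed)) {
    stopifnot_cols(observed, c("family", "n"), "observed")
    observed <- setNames(observed$n, observed$family)
  }
  if (abs(sum(baseline) - 1) > 1e-9) abort("baseline must sum to 1")
  fam <- names(observed)
  fam[!fam %in% names(baseline)] <- "other"
  counts <- tapply(as.integer(observed), fam, sum)
  # full baseline support, zero-filling unobserved families
  k <- setNames(rep(0L, length(baseline)), names(baseline))
  k[names(counts)] <- counts
  N <- sum(k)
  if (N < 1) abort("need at least one observed TE")

  fold <- (k / N) / baseline
  p <- vapply(seq_along(k), function(i) {
    binom.test(k[i], N, baseline[i], alternative = "two.sided")$p.value
  }, 0)
  chisq <- suppressWarnings(chisq.test(k, p = baseline))
  list(
    families = tibble(
      family = names(k), n = unname(k), prop = unname(k / N),
      baseline = unname(baseline), fold = unname(fold),
      p_value = p, q_value = p.adjust(p, "BH")
    ),
    chisq = tibble(statistic = unname(chisq$statistic),
                   df = unname(chisq$parameter),
                   p_value = chisq$p.value)
  )
}

#' Chromosome-level TE enrichment normalised for chromosome size
#'
#' Expected counts are proportional to chromosome length
#' (`N * L_c / sum(L)`); fold is observed/expected and chromosomes with
#' fold above `fold_threshold` (default 1.5) are flagged as enriched.
#'
#' @param te_loci Tibble with a `chrom` column.
#' @param genome Tibble with `chrom`, `length` covering every locus.
#' @param fold_threshold Enrichment flag threshold.
#' @return Tibble with `chrom`, `observed`, `expected`, `fold`,
#'   `enriched`.
#' @export
chromosome_enrichment <- function(te_loci, genome, fold_threshold = 1.5) {
  stopifnot_cols(te_loci, "chrom", "te_loci")
  stopifnot_cols(genome, c("chrom", "length"), "genome")
  if (!all(te_loci$chrom %in% genome$chrom)) {
    abort("every locus chromosome must appear in the genome table")
  }
  N <- nrow(te_loci)
  obs <- table(factor(te_loci$chrom, levels = genome$chrom))
  expected <- N * genome$length / sum(genome$length)
  tibble(
    chrom = genome$chrom,
    observed = as.integer(obs),
    expected = expected,
    fold = as.integer(obs) / expected,
    enriched = as.integer(obs) / expected > fold_threshold
  )
}

#' Cluster-size bias diagnostics
#'
#' Checks whether apparent TE dysregulation simply tracks cell-type
#' abundance: per-1,000-cell DE rates, the Spearman rank correlation of
#' cell count vs number of DE TEs, and the Pearson correlation of cell
#' count vs mean absolute effect size. Spearman p-values are exact for
#' small cell-type counts (no ties); a constant input vector makes the
#' corresponding correlation `NA` (flagged).
#'
#' @param per_cell_type Tibble with `cell_type`, `n_cells`, `n_de_tes`,
#'   `mean_abs_log2fc` (NA allowed where no DE TEs).
#' @return A list with `rates` (input plus `rate_per_1000`) and `cor`
#'   (tibble: `metric`, `estimate`, `p_value`).
#' @export
cluster_size_diagnostics <- function(per_cell_type) {
  stopifnot_cols(per_cell_type,
                 c("cell_type", "n_cells", "n_de_tes", "mean_abs_log2fc"),
                 "per_cell_type")
  if (nrow(per_cell_type) < 3) abort("need at least 3 cell types")
  rates <- per_cell_type |>
    mutate(rate_per_1000 = 1000 * .data$n_de_tes / .data$n_cells)

  safe_cor <- function(x, y, method) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3 || length(unique(x[ok])) < 2 ||
          length(unique(y[ok])) < 2) {
      return(c(NA_real_, NA_real_))
    }
    ct <- suppressWarnings(
      cor.test(x[ok], y[ok], method = method,
               exact = if (method == "spearman") sum(ok) <= 10 else NULL))
    c(unname(ct$estimate), ct$p.value)
  }
  sp <- safe_cor(per_cell_type$n_cells, per_cell_type$n_de_tes, "spearman")
  pe <- safe_cor(per_cell_type$n_cells, per_cell_type$mean_abs_log2fc,
                 "pearson")
  list(
    rates = rates,
    cor = tibble(
      metric = c("spearman_cells_vs_n_de", "pearson_cells_vs_effect"),
      estimate = c(sp[1], pe[1]),
      p_value = c(sp[2], pe[2])
    )
  )
}

#' Subfamily-to-family prefix map
#'
#' RepeatMasker-style prefix rules mapping TE subfamily names to families
#' and classes, shipped as an editable TSV
#' (`system.file("extdata", "te_family_map.tsv", package = "tescape")`).
#' Longest matching prefix wins; unmatched subfamilies fall to
#' `"other"`/`"other"`.
#'
#' @param path Optional path to an alternative map TSV (columns `prefix`,
#'   `family`, `te_class`).
#' @return Tibble with `prefix`, `family`, `te_class`.
#' @export
te_family_map <- function(path = NULL) {
  path <- path %||% system.file("extdata", "te_family_map.tsv",
                                package = "tescape")
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Infer TE family and class from a subfamily name
#'
#' Adapter for feature naming dialects that carry only the subfamily:
#' looks the subfamily up in the prefix map ([te_family_map()]), longest
#' prefix first.
#'
#' @param subfamily Character vector of subfamily names.
#' @param map Prefix map tibble.
#' @return Tibble with `subfamily`, `family`, `te_class`.
#' @export
#' @examples
#' subfamily_to_family(c("AluYa5", "L1PA4", "MER41B"))
subfamily_to_family <- function(subfamily, map = te_family_map()) {
  map <- map[order(-nchar(map$prefix)), ]
  idx <- vapply(subfamily, function(s) {
    hit <- which(startsWith(s, map$prefix))
    if (length(hit) == 0) NA_integer_ else hit[1]
  }, 0L)
  tibble(
    subfamily = unname(subfamily),
    family = unname(ifelse(is.na(idx), "other", map$family[idx])),
    te_class = unname(ifelse(is.na(idx), "other", map$te_class[idx]))
  )
}
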