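# TE-gene proximity: pair finding at multiple genomic windows, the
# normalized window-selection matrix, gene-set over-representation,
# AD-risk-gene and TE-derived-gene analyses, and genomic feature
# assignment.
#
# Distances are interval gaps between the TE and the gene body (0 on
# overlap), strand-agnostic, in 0-based half-open coordinates. GRanges is
# used for the overlap engine; the 1-based conversion happens only here.

gr_from_halfopen <- function(df, seqlevels = unique(df$chrom)) {
  GenomicRanges::GRanges(
    seqnames = factor(df$chrom, levels = seqlevels),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

#' Find TE-gene pairs within a genomic window
#'
#' A pair is included iff the gap between the TE interval and the gene
#' anchor interval is at most `window` base pairs (gap 0 on overlap).
#' The anchor is the gene body by default; `anchor = "tss"` measures to
#' the transcription start site instead.
#'
#' @param te_loci Tibble with `feature_id`, `chrom`, `start`, `end` (and
#'   optionally `family`, `te_class`, carried through).
#' @param genes Tibble with `gene_id`, `chrom`, `start`, `end` (and `tss`
#'   when `anchor = "tss"`).
#' @param window Window size in bp (> 0).
#' @param anchor `"body"` (default) or `"tss"`.
#' @return Tibble with `te_id`, `gene_id`, `distance`, `window` plus any
#'   `family` / `te_class` columns present in `te_loci`.
#' @export
#' @examples
#' te <- tibble::tibble(feature_id = "te1", chrom = "chr1",
#'   start = 1000L, end = 1300L)
#' gn <- tibble::tibble(gene_id = "g1", chrom = "chr1",
#'   start = 1500L, end = 3000L)
#' find_pairs(te, gn, window = 250e3)
find_pairs <- function(te_loci, genes, window, anchor = c("body", "tss")) {
  anchor <- match.arg(anchor)
  stopifnot(window > 0)
  stopifnot_cols(te_loci, c("feature_id", "chrom", "start", "end"), "te_loci")
  stopifnot_cols(genes, c("gene_id", "chrom", "start", "end"), "genes")
  gdf <- genes
  if (anchor == "tss") {
    stopifnot_cols(genes, "tss", "genes")
    gdf$start <- gdf$tss
    gdf$end <- gdf$tss + 1L
  }
  if (nrow(te_loci) == 0 || nrow(gdf) == 0) {
    return(empty_pairs(window, te_loci))
  }
  lvls <- unique(c(te_loci$chrom, gdf$chrom))
  hits <- GenomicRanges::findOverlaps(
    gr_from_halfopen(te_loci, lvls), gr_from_halfopen(gdf, lvls),
    maxgap = window, ignore.strand = TRUE
  )
  ti <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  d <- interval_gap(te_loci$start[ti], te_loci$end[ti],
                    gdf$start[gi], gdf$end[gi])
  keep <- d <= window
  out <- tibble(
    te_id = te_loci$feature_id[ti][keep],
    gene_id = gdf$gene_id[gi][keep],
    distance = as.integer(d[keep]),
    window = as.integer(window)
  )
  for (col in intersect(c("family", "te_class"), names(te_loci))) {
    out[[col]] <- te_loci[[col]][ti][keep]
  }
  arrange(out, .data$te_id, .data$gene_id)
}

empty_pairs <- function(window, te_loci) {
  out <- tibble(te_id = character(), gene_id = character(),
                distance = integer(), window = as.integer(window)[0])
  for (col in intersect(c("family", "te_class"), names(te_loci))) {
    out[[col]] <- character()
  }
  out
}

#' One-sided hypergeometric over-representation of gene sets
#'
#' Tests each gene set for over-representation of `query` genes against a
#' `background` universe (one-sided hypergeometric upper tail), with
#' Benjamini-Hochberg correction across sets. Genes outside the
#' background are ignored.
#'
#' @param query Character vector of genes of interest.
#' @param gene_sets Named list of character vectors.
#' @param background Character vector, the gene universe.
#' @return Tibble with `set`, `k`, `set_size`, `query_size`, `p_value`,
#'   `q_value`, sorted by p-value.
#' @export
ora_gene_sets <- function(query, gene_sets, background) {
  if (length(gene_sets) == 0) {
    warn("empty gene-set collection")
    return(tibble(set = character(), k = integer(), set_size = integer(),
                  query_size = integer(), p_value = numeric(),
                  q_value = numeric()))
  }
  bg <- unique(background)
  q <- intersect(unique(query), bg)
  res <- purrr::imap_dfr(gene_sets, function(genes, set_name) {
    s <- intersect(unique(genes), bg)
    k <- length(intersect(q, s))
    tibble(set = set_name, k = k, set_size = length(s),
           query_size = length(q),
           p_value = hyper_tail(k, length(s), length(bg), length(q)))
  })
  res$q_value <- p.adjust(res$p_value, "BH")
  arrange(res, .data$p_value)
}

#' Per-window proximity metrics
#'
#' For each window: the TE isolation percentage (TEs with zero genes in
#' the window), the median number of genes per TE (zeros included), and
#' the number of gene sets significantly over-represented (BH q < 0.05)
#' among the union of proximal genes.
#'
#' @param pairs Tibble of pairs over one or more windows (a `window`
#'   column, as produced by binding [find_pairs()] results).
#' @param te_loci The TE set every window was computed on.
#' @param gene_sets Named list of gene sets (may be empty).
#' @param background Gene universe for over-representation.
#' @param windows Window sizes to report (default: those present in
#'   `pairs`; pass explicitly when a window produced no pairs at all).
#' @return Tibble with `window`, `isolation_pct`, `median_genes_per_te`,
#'   `n_significant_gene_sets`.
#' @export
window_metrics <- function(pairs, te_loci, gene_sets, background,
                           windows = sort(unique(pairs$window))) {
  stopifnot_cols(pairs, c("te_id", "gene_id", "window"), "pairs")
  n_te <- nrow(te_loci)
  purrr::map_dfr(sort(windows), function(w) {
    pw <- pairs[pairs$window == w, ]
    genes_per_te <- table(factor(pw$te_id, levels = te_loci$feature_id))
    n_sig <- if (length(gene_sets) == 0) {
      warn("empty gene-set collection: n_significant_gene_sets = 0")
      0L
    } else {
      sum(ora_gene_sets(unique(pw$gene_id), gene_sets,
                        background)$q_value < 0.05)
    }
    tibble(
      window = w,
      isolation_pct = 100 * sum(genes_per_te == 0) / n_te,
      median_genes_per_te = median(as.integer(genes_per_te)),
      n_significant_gene_sets = n_sig
    )
  })
}

#' Select the analysis window from a normalized selection matrix
#'
#' Each metric is min-max normalised across windows, oriented so that
#' lower isolation (specificity without starvation), more significant
#' gene sets (functional signal) and *lower* median genes per TE
#' (penalising indiscriminate coverage) score higher; the composite is
#' the weighted mean of the three oriented scores and the window with the
#' highest composite wins (ties break to the smaller window). A metric
#' constant across windows is neutralised at 0.5.
#'
#' @param metrics Tibble from [window_metrics()] (>= 2 windows).
#' @param weights Length-3 non-negative weights for
#'   (isolation, gene sets, coverage); default equal.
#' @return A list with `selected` (window, bp) and `scores` (the metrics
#'   tibble plus the three oriented components and `composite`).
#' @export
select_window <- function(metrics, weights = c(1, 1, 1)) {
  stopifnot_cols(metrics, c("window", "isolation_pct", "median_genes_per_te",
                            "n_significant_gene_sets"), "metrics")
  if (nrow(metrics) < 2) abort("need at least 2 windows to select from")
  stopifnot(length(weights) == 3, all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)
  scores <- metrics |>
    arrange(.data$window) |>
    mutate(
      s_specificity = 1 - minmax(.data$isolation_pct),
      s_functional = minmax(.data$n_significant_gene_sets),
      s_coverage = 1 - minmax(.data$median_genes_per_te),
      composite = w[1] * .data$s_specificity + w[2] * .data$s_functional +
        w[3] * .data$s_coverage
    )
  best <- which(scores$composite == max(scores$composite))[1]
  list(selected = scores$window[best], scores = scores)
}

#' AD risk gene proximity across windows
#'
#' Tiers each AD risk gene by the smallest window in which it first
#' acquires a proximal TE, tallies TE families over AD-gene pairs, and
#' ranks AD genes by their number of distinct proximal TEs (both at
#' `tally_window`).
#'
#' @param pairs Pair tibble covering all `windows` (a `window` column).
#' @param ad_genes Character vector of risk gene ids (nonempty).
#' @param windows Increasing window sizes used (default the pairs'
#'   windows).
#' @param tally_window Window at which family and per-gene tallies are
#'   computed (default the largest).
#' @return List with `tiers` (window, n_new_genes, n_cumulative),
#'   `family_counts`, `top_genes`.
#' @export
ad_gene_proximity <- function(pairs, ad_genes,
                              windows = sort(unique(pairs$window)),
                              tally_window = max(windows)) {
  if (length(ad_genes) == 0) abort("ad_genes must be nonempty")
  stopifnot_cols(pairs, c("te_id", "gene_id", "distance", "window"), "pairs")
  wmax <- max(windows)
  ad_pairs <- pairs[pairs$window == wmax & pairs$gene_id %in% ad_genes, ]
  first_window <- if (nrow(ad_pairs) > 0) {
    ad_pairs |>
      group_by(.data$gene_id) |>
      summarise(min_d = min(.data$distance), .groups = "drop") |>
      mutate(tier = vapply(.data$min_d,
                           function(d) min(windows[windows >= d]), 0))
  } else {
    tibble(gene_id = character(), min_d = integer(), tier = numeric())
  }
  tiers <- tibble(window = windows) |>
    mutate(n_new_genes = vapply(.data$window,
                                function(w) sum(first_window$tier == w), 0L),
           n_cumulative = cumsum(.data$n_new_genes))

  tp <- pairs[pairs$window == tally_window & pairs$gene_id %in% ad_genes, ]
  family_counts <- if ("family" %in% names(tp)) {
    tp |> count(.data$family, name = "n") |> arrange(desc(.data$n))
  } else {
    tibble(family = character(), n = integer())
  }
  top_genes <- tp |>
    group_by(.data$gene_id) |>
    summarise(n_tes = dplyr::n_distinct(.data$te_id), .groups = "drop") |>
    arrange(desc(.data$n_tes), .data$gene_id)
  list(tiers = tiers, family_counts = family_counts, top_genes = top_genes)
}

#' Test the TE-derived fraction of proximal genes
#'
#' Compares the proportion of TE-derived genes among genes proximal to DE
#' TEs with the genome-wide expectation (default ~3% of a 20,000-gene
#' background) by a two-sided Fisher's exact test on the 2x2 table.
#'
#' @param proximal_genes Character vector of distinct proximal genes.
#' @param catalog Character vector, the TE-derived gene catalog.
#' @param genome_rate Genome-wide TE-derived fraction (default 0.03).
#' @param genome_size Genome-wide gene count for the comparison column
#'   (default 20000).
#' @return Tibble with `n_proximal`, `n_te_derived`, `pct`, `odds_ratio`,
#'   `p_value`, `direction` ("depleted"/"enriched"/"undefined").
#' @export
te_derived_gene_test <- function(proximal_genes, catalog,
                                 genome_rate = 0.03, genome_size = 20000) {
  if (length(catalog) == 0) abort("catalog must be nonempty")
  prox <- unique(proximal_genes)
  n <- length(prox)
  if (n == 0) {
    warn("no proximal genes: TE-derived test undefined")
    return(tibble(n_proximal = 0L, n_te_derived = 0L, pct = NA_real_,
                  odds_ratio = NA_real_, p_value = NA_real_,
                  direction = "undefined"))
  }
  k <- length(intersect(prox, catalog))
  expected <- round(genome_rate * genome_size)
  tab <- matrix(c(k, n - k, expected, genome_size - expected), nrow = 2)
  ft <- fisher.test(tab, alternative = "two.sided")
  pct <- round(100 * k / n, 2)
  tibble(
    n_proximal = n, n_te_derived = k, pct = pct,
    odds_ratio = unname(ft$estimate), p_value = ft$p.value,
    direction = if (pct < 100 * genome_rate) "depleted" else "enriched"
  )
}

#' Assign each TE to a genomic feature category
#'
#' Classifies the TE midpoint into promoter, enhancer, exon, intron or
#' intergenic with that precedence. Promoters span `promoter_upstream` bp
#' upstream to `promoter_downstream` bp downstream of the TSS
#' (strand-aware; defaults 2,000 and 500).
#'
#' @param te_loci Tibble with `feature_id`, `chrom`, `start`, `end`.
#' @param genes Gene models (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss`).
#' @param exons Exon intervals (`chrom`, `start`, `end`).
#' @param enhancers Enhancer intervals (`chrom`, `start`, `end`).
#' @param promoter_upstream,promoter_downstream Promoter span around the
#'   TSS, bp.
#' @return `te_loci` with a `genomic_feature` column.
#' @export
assign_genomic_feature <- function(te_loci, genes, exons, enhancers,
                                   promoter_upstream = 2000,
                                   promoter_downstream = 500) {
  stopifnot_cols(genes, c("chrom", "start", "end", "strand", "tss"), "genes")
  mid <- floor((te_loci$start + te_loci$end) / 2)
  pts <- tibble(chrom = te_loci$chrom, start = mid, end = mid + 1L)

  promoters <- tibble(
    chrom = genes$chrom,
    start = pmax(0L, as.integer(ifelse(genes$strand == "-",
                                       genes$tss - promoter_downstream,
                                       genes$tss - promoter_upstream))),
    end = as.integer(ifelse(genes$strand == "-",
                            genes$tss + promoter_upstream,
                            genes$tss + promoter_downstream))
  )
  hit_any <- function(track) {
    if (nrow(track) == 0) return(rep(FALSE, nrow(pts)))
    lvls <- unique(c(pts$chrom, track$chrom))
    GenomicRanges::countOverlaps(gr_from_halfopen(pts, lvls),
                                 gr_from_halfopen(track, lvls)) > 0
  }
  in_promoter <- hit_any(promoters)
  in_enhancer <- hit_any(enhancers)
  in_exon <- hit_any(exons)
  in_body <- hit_any(genes)
  feature <- dplyr::case_when(
    in_promoter ~ "promoter",
    in_enhancer ~ "enhancer",
    in_exon ~ "exon",
    in_body ~ "intron",
    TRUE ~ "intergenic"
  )
  mutate(te_loci, genomic_feature = feature)
}
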