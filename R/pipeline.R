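# End-to-end orchestration: filter -> pseudobulk DE per cell type ->
# balanced-downsampling robustness -> annotation/enrichment -> proximity
# -> ATAC scoring, as one pure function of (bundle, parameters, seed),
# plus a file-based runner driven by a YAML config that writes every
# result table and a reproducibility manifest.

bundle_genome <- function(bundle) {
  if (!is.null(bundle$config) && !is.null(bundle$config$genome)) {
    return(bundle$config$genome)
  }
  bind_rows(
    bundle$te_loci[, c("chrom", "end")],
    bundle$genes[, c("chrom", "end")]
  ) |>
    group_by(.data$chrom) |>
    summarise(length = max(.data$end) + 1e5, .groups = "drop")
}

#' Run the full TE dysregulation pipeline on a bundle
#'
#' Executes every stage in order on an in-memory `te_bundle`:
#' low-expression filtering, per-cell TE fractions, per-cell-type
#' pseudobulk NB-LRT differential expression of TE loci, the balanced
#' downsampling robustness screen, direction/class/family/age/chromosome
#' annotation of the robust set, multi-window TE-gene proximity with
#' window selection, AD-risk and TE-derived gene analyses, genomic
#' feature assignment, and ATAC-weighted regulatory scoring. The result
#' is a pure function of the bundle, the parameters and `seed`.
#'
#' @param bundle A `te_bundle` ([simulate_te_dataset()] or
#'   [read_bundle()]).
#' @param min_cells Low-expression filter threshold (default 10 cells).
#' @param fdr_threshold,lfc_threshold Significance and effect thresholds
#'   (defaults 0.05 and 2.0).
#' @param k_downsample Balanced downsampling iterations (default 10; 0
#'   disables the screen and every significant feature keeps detection
#'   count 0 with `highly_robust = significant_full`).
#' @param windows Proximity window sizes in bp.
#' @param seed Root seed for the downsampling plans.
#' @param shrink_weight Dispersion shrinkage weight for [nb_lrt()].
#' @return A `te_pipeline` list of result tables (see the individual
#'   stage functions) plus `manifest`.
#' @export
run_te_pipeline <- function(bundle,
                            min_cells = 10,
                            fdr_threshold = 0.05,
                            lfc_threshold = 2,
                            k_downsample = 10,
                            windows = c(50e3, 250e3, 500e3, 1e6),
                            seed = 1,
                            shrink_weight = 0.3) {
  stopifnot(inherits(bundle, "te_bundle"))
  genome <- bundle_genome(bundle)

  counts <- filter_low_expression(bundle$counts, min_cells = min_cells)
  features <- bundle$features[match(rownames(counts),
                                    bundle$features$feature_id), ]
  te_fraction <- te_fraction_per_cell(counts, features, bundle$cells)

  cell_types <- sort(unique(bundle$cells$cell_type))
  sample_cond <- distinct(bundle$cells, .data$sample_id, .data$condition)
  case_ids <- sort(sample_cond$sample_id[sample_cond$condition == "AD"])
  control_ids <- sort(sample_cond$sample_id[sample_cond$condition == "control"])
  plans <- if (k_downsample > 0) {
    make_plans(case_ids, control_ids, k = k_downsample,
               seed = derive_seed(seed, "downsample"))
  } else NULL

  te_ids <- features$feature_id[features$kind == "TE"]
  pseudobulks <- list()
  de_full <- list()
  robustness <- list()
  for (ct in cell_types) {
    pb <- suppressWarnings(aggregate_pseudobulk(counts, bundle$cells, ct))
    if (is.null(pb)) next
    pseudobulks[[ct]] <- pb
    pb_te <- pb
    pb_te$counts <- pb$counts[intersect(rownames(pb$counts), te_ids), ,
                              drop = FALSE]
    full <- suppressWarnings(
      nb_lrt(pb_te, shrink_weight = shrink_weight,
             fdr_threshold = fdr_threshold, lfc_threshold = lfc_threshold))
    de_full[[ct]] <- full
    if (!is.null(plans)) {
      per_iter <- suppressWarnings(
        run_downsampled_de(pb_te, plans, shrink_weight = shrink_weight,
                           fdr_threshold = fdr_threshold,
                           lfc_threshold = lfc_threshold))
      robustness[[ct]] <- classify_robust(full, per_iter)
    } else {
      robustness[[ct]] <- classify_robust(full, list())
    }
  }
  de <- bind_rows(de_full)
  robust_records <- bind_rows(robustness)

  # effect-size filter applied after robustness classification, on
  # full-data estimates
  de_key <- paste(de$feature_id, de$cell_type)
  rb_key <- paste(robust_records$feature_id, robust_records$cell_type)
  robust_records$passes_effect <- de$passes_effect[match(rb_key, de_key)]
  robust_de <- de[de_key %in% rb_key[robust_records$highly_robust &
                                       robust_records$passes_effect], ]

  robust_te_loci <- bundle$te_loci[
    bundle$te_loci$feature_id %in% unique(robust_de$feature_id), ]
  robust_te_loci$age <- assign_age(robust_te_loci$subfamily)

  annotation <- list(
    direction_overall = summarize_direction(robust_de, by = "overall"),
    direction_by_cell_type = summarize_direction(robust_de,
                                                 by = "cell_type"),
    class_composition = class_composition(robust_te_loci),
    family_enrichment = if (nrow(robust_te_loci) > 0) {
      family_enrichment(table(robust_te_loci$family))
    } else NULL,
    chromosome_enrichment = if (nrow(robust_te_loci) > 0) {
      chromosome_enrichment(robust_te_loci, genome)
    } else NULL
  )

  cells_per_type <- count(bundle$cells, .data$cell_type, name = "n_cells")
  de_per_type <- robust_de |>
    group_by(.data$cell_type) |>
    summarise(n_de_tes = n(),
              mean_abs_log2fc = mean(abs(.data$log2fc)), .groups = "drop")
  diag_input <- left_join(cells_per_type, de_per_type, by = "cell_type") |>
    mutate(n_de_tes = dplyr::coalesce(.data$n_de_tes, 0L))
  diagnostics <- if (nrow(diag_input) >= 3) {
    cluster_size_diagnostics(diag_input)
  } else NULL

  proximity <- NULL
  scores <- NULL
  if (nrow(robust_te_loci) > 0) {
    pairs <- purrr::map_dfr(windows, function(w) {
      find_pairs(robust_te_loci, bundle$genes, window = w)
    })
    metrics <- suppressWarnings(
      window_metrics(pairs, robust_te_loci, bundle$gene_sets,
                     bundle$genes$gene_id))
    selection <- select_window(metrics)
    sel_pairs <- pairs[pairs$window == selection$selected, ]
    ad <- ad_gene_proximity(pairs, bundle$ad_genes, windows = windows,
                            tally_window = selection$selected)
    td <- te_derived_gene_test(unique(sel_pairs$gene_id),
                               bundle$te_derived_genes)
    feat <- assign_genomic_feature(robust_te_loci, bundle$genes,
                                   bundle$exons, bundle$enhancers)
    proximity <- list(pairs = pairs, metrics = metrics,
                      selection = selection, ad = ad,
                      te_derived = td, genomic_features = feat)

    profiles <- accessibility_profile(robust_te_loci, bundle$peaks,
                                      bundle$peak_matrix,
                                      window = selection$selected)
    sel_pairs <- pair_expression_correlation(sel_pairs, pseudobulks)
    scores <- suppressWarnings(
      score_pairs(sel_pairs, profiles, robust_de,
                  window = selection$selected))
    scores <- classify_confidence(scores)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("tescape")),
    seed = seed,
    config_hash = rlang::hash(bundle$config),
    thresholds = list(min_cells = min_cells, fdr = fdr_threshold,
                      lfc = lfc_threshold, k_downsample = k_downsample),
    windows = windows,
    selected_window = if (!is.null(proximity)) proximity$selection$selected
                      else NA,
    stage_rows = list(
      features_after_filter = nrow(counts),
      cells = ncol(counts),
      de_tests = nrow(de),
      robust_tes = nrow(robust_de),
      pairs_selected_window = if (!is.null(scores)) nrow(scores) else 0L
    )
  )

  structure(list(
    te_fraction = te_fraction, pseudobulks = pseudobulks, de = de,
    robustness = robust_records, robust_de = robust_de,
    robust_te_loci = robust_te_loci, annotation = annotation,
    diagnostics = diagnostics, proximity = proximity, scores = scores,
    manifest = manifest
  ), class = "te_pipeline")
}

#' @export
print.te_pipeline <- function(x, ...) {
  m <- x$manifest
  cat("<te_pipeline>\n")
  cat(sprintf("  features tested: %d | robust DE TEs: %d\n",
              m$stage_rows$de_tests, m$stage_rows$robust_tes))
  if (!is.na(m$selected_window)) {
    cat(sprintf("  selected window: %g kb | scored pairs: %d\n",
                m$selected_window / 1e3, m$stage_rows$pairs_selected_window))
  }
  invisible(x)
}

config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  to_tbl <- function(x) if (is.null(x)) NULL else as_tibble(as.data.frame(x))
  simulation_config(
    seed = raw$seed %||% 1L,
    n_samples_case = raw$n_samples_case %||% 11L,
    n_samples_control = raw$n_samples_control %||% 7L,
    cell_types = to_tbl(raw$cell_types) %||% default_cell_types(),
    n_genes = raw$n_genes %||% 400L,
    n_te_loci = raw$n_te_loci %||% 400L,
    family_mix = unlist(raw$family_mix) %||% baseline_composition(),
    target_te_fraction = raw$target_te_fraction %||% 0.12,
    planted_effects = to_tbl(raw$planted_effects),
    nb_dispersion = raw$nb_dispersion %||% 0.15,
    genome = to_tbl(raw$genome) %||% default_genome(),
    planted_floor = raw$planted_floor %||% 0.5,
    n_peaks = raw$n_peaks %||% 300L,
    n_enhancers = raw$n_enhancers %||% 150L,
    n_gene_sets = raw$n_gene_sets %||% 30L,
    ad_gene_count = raw$ad_gene_count %||% 40L,
    te_derived_frac = raw$te_derived_frac %||% 0.03,
    peak_overlap_frac = raw$peak_overlap_frac %||% 0.6
  )
}

#' Run the pipeline from a config file and write all outputs
#'
#' File-based front end: reads a YAML simulation config (or a previously
#' written bundle directory), runs [run_te_pipeline()], and writes every
#' result table as TSV plus a JSON manifest to `outdir`. Re-running with
#' the same config and seed reproduces the output files byte for byte.
#'
#' @param config Path to a YAML simulation config (ignored when
#'   `input_dir` is given).
#' @param outdir Output directory (created).
#' @param seed Root seed; overrides the config seed when supplied.
#' @param input_dir Optional directory from [write_bundle()] to analyse
#'   instead of simulating.
#' @param n_planted_effects Number of disease-like effects planted when
#'   simulating (default 60; 0 gives a null run).
#' @param ... Passed to [run_te_pipeline()].
#' @return The `te_pipeline` object, invisibly.
#' @export
run_pipeline <- function(config = NULL, outdir, seed = NULL,
                         input_dir = NULL, n_planted_effects = 60L, ...) {
  if (!is.null(input_dir)) {
    bundle <- read_bundle(input_dir)
    seed <- seed %||% 1L
  } else {
    cfg <- if (is.null(config)) simulation_config() else
      config_from_yaml(config)
    if (!is.null(seed)) cfg$seed <- as.integer(seed)
    seed <- cfg$seed
    if (nrow(cfg$planted_effects) == 0 && n_planted_effects > 0) {
      cfg <- plant_ad_scenario(cfg, n_effects = n_planted_effects)
    }
    bundle <- simulate_te_dataset(cfg)
  }
  result <- run_te_pipeline(bundle, seed = seed, ...)
  write_pipeline_outputs(result, outdir)
  invisible(result)
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  tsv <- function(df, name) if (!is.null(df)) readr::write_tsv(df, p(name))

  tsv(result$te_fraction, "te_fraction.tsv")
  tsv(result$de, "de_results.tsv")
  tsv(result$robustness, "robustness.tsv")
  tsv(result$robust_de, "robust_tes.tsv")
  tsv(result$annotation$direction_overall, "direction_overall.tsv")
  tsv(result$annotation$direction_by_cell_type, "direction_by_cell_type.tsv")
  tsv(result$annotation$class_composition, "class_composition.tsv")
  if (!is.null(result$annotation$family_enrichment)) {
    tsv(result$annotation$family_enrichment$families, "family_enrichment.tsv")
    tsv(result$annotation$family_enrichment$chisq, "family_chisq.tsv")
  }
  tsv(result$annotation$chromosome_enrichment, "chromosome_enrichment.tsv")
  if (!is.null(result$diagnostics)) {
    tsv(result$diagnostics$rates, "cluster_rates.tsv")
    tsv(result$diagnostics$cor, "cluster_correlations.tsv")
  }
  if (!is.null(result$proximity)) {
    tsv(result$proximity$pairs, "te_gene_pairs.tsv")
    tsv(result$proximity$metrics, "window_metrics.tsv")
    tsv(result$proximity$selection$scores, "window_selection.tsv")
    tsv(result$proximity$ad$tiers, "ad_gene_tiers.tsv")
    tsv(result$proximity$ad$family_counts, "ad_family_counts.tsv")
    tsv(result$proximity$ad$top_genes, "ad_top_genes.tsv")
    tsv(result$proximity$te_derived, "te_derived_test.tsv")
    tsv(result$proximity$genomic_features, "genomic_features.tsv")
  }
  if (!is.null(result$scores)) {
    tsv(as_tibble(result$scores), "regulatory_scores.tsv")
  }
  jsonlite::write_json(result$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
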