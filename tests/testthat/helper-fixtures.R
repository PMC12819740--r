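# Shared desk-scale fixtures, built in code at test time.

# A small but complete simulation config; planted effects optional.
small_config <- function(seed = 1, planted_effects = NULL, n_genes = 120L,
                         n_te_loci = 100L, ...) {
  simulation_config(
    seed = seed,
    cell_types = tibble::tibble(
      cell_type = c("ASC", "EX", "INH", "MG", "ODC", "OPC", "PER.END"),
      min_cells = c(6L, 20L, 6L, 5L, 25L, 5L, 3L),
      max_cells = c(12L, 32L, 12L, 10L, 40L, 10L, 6L)),
    n_genes = n_genes, n_te_loci = n_te_loci,
    n_peaks = 80L, n_enhancers = 50L, n_gene_sets = 10L,
    ad_gene_count = 20L,
    planted_effects = planted_effects, ...
  )
}

# Uniform-size cell types for variance-sensitive generator checks.
flat_cell_types <- function(n_min = 25L, n_max = 35L) {
  tibble::tibble(
    cell_type = c("ASC", "EX", "INH", "MG", "ODC", "OPC", "PER.END"),
    min_cells = rep(n_min, 7), max_cells = rep(n_max, 7))
}

# Cache a planted-scenario bundle + pipeline run across test files.
scenario_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- plant_ad_scenario(simulation_config(seed = 42), n_effects = 60)
      bundle <- simulate_te_dataset(cfg)
      cache <<- list(config = cfg, bundle = bundle,
                     result = run_te_pipeline(bundle, seed = 42))
    }
    cache
  }
})

random_toy_instance <- function(seed) {
  set.seed(seed)
  n_te <- sample(2:12, 1)
  n_gn <- sample(2:12, 1)
  chroms <- c("chrA", "chrB")
  L <- 50000
  te_start <- sample(0:(L - 500), n_te)
  gn_start <- sample(0:(L - 500), n_gn)
  list(
    te = tibble::tibble(
      feature_id = sprintf("te%02d", seq_len(n_te)),
      chrom = sample(chroms, n_te, replace = TRUE),
      start = te_start, end = te_start + sample(100:400, n_te, TRUE)),
    genes = tibble::tibble(
      gene_id = sprintf("g%02d", seq_len(n_gn)),
      chrom = sample(chroms, n_gn, replace = TRUE),
      start = gn_start, end = gn_start + sample(200:2000, n_gn, TRUE)),
    window = sample(c(100L, 500L, 2000L, 10000L), 1)
  )
}
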