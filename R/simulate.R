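# Synthetic-data generator: a complete desk-scale stand-in for a
# case/control single-nucleus RNA-seq + ATAC study with locus-level TE
# quantification. Everything downstream (pseudobulk DE, robustness,
# annotation, proximity, ATAC scoring) runs on the bundle it produces.

te_subfamily_pool <- list(
  Alu   = c("AluY", "AluYa5", "AluSx", "AluSg", "AluJb", "AluJo"),
  L1    = c("L1HS", "L1PA2", "L1PA4", "L1PA7", "L1PA11", "L1PA15", "L1PB1",
            "L1M2", "L1M5"),
  L2    = c("L2a", "L2b", "L2c"),
  MIR   = c("MIR", "MIRb", "MIRc"),
  ERV   = c("HERVK9-int", "HERVH-int", "LTR7", "MER41B"),
  DNA   = c("Charlie1a", "MER5A", "Tigger1", "MER20"),
  other = c("SVA_D", "UCON4", "Eulor1")
)

te_family_class <- c(Alu = "SINE", MIR = "SINE", L1 = "LINE", L2 = "LINE",
                     ERV = "LTR", DNA = "DNA", other = "other")

te_class_length_range <- list(
  SINE = c(150L, 400L), LINE = c(500L, 6000L), LTR = c(300L, 5000L),
  DNA = c(200L, 3000L), other = c(200L, 2000L)
)

default_cell_types <- function() {
  tibble(
    cell_type = c("ASC", "EX", "INH", "MG", "ODC", "OPC", "PER.END"),
    min_cells = c(10L, 40L, 10L, 8L, 50L, 8L, 4L),
    max_cells = c(25L, 70L, 25L, 20L, 90L, 20L, 12L)
  )
}

default_genome <- function() {
  tibble(chrom = paste0("chr", 1:4), length = rep(10e6, 4))
}

#' Genomic baseline TE family composition
#'
#' Reference proportions of TE families genome-wide, used as the null for
#' family enrichment testing and as the family mix the simulator draws from:
#' 45% Alu, 17% L1, 8% L2, 5% MIR, 8% ERV, 3% DNA transposons, 14% other.
#'
#' @return Named numeric vector of family proportions summing to 1.
#' @export
baseline_composition <- function() {
  c(Alu = 0.45, L1 = 0.17, L2 = 0.08, MIR = 0.05, ERV = 0.08, DNA = 0.03,
    other = 0.14)
}

#' Build a simulation configuration
#'
#' Defines the conditions for the synthetic study: a case/control design of
#' 11 vs 7 samples, seven brain cell types, negative-binomial counts for
#' genes and locus-level TEs on a toy genome of four 10-Mb chromosomes, a
#' per-cell TE transcript fraction around 12%, and optional planted
#' cell-type-specific TE effects (see [plant_ad_scenario()]).
#'
#' @param seed Integer root seed; all randomness in generation derives from it.
#' @param n_samples_case,n_samples_control Number of biological samples per
#'   condition (defaults 11 and 7, the imbalanced design the robustness
#'   screen is built for).
#' @param cell_types Tibble with columns `cell_type`, `min_cells`,
#'   `max_cells` giving the per-sample cell-count range of each population.
#' @param n_genes,n_te_loci Number of gene and TE features.
#' @param family_mix Named proportions of TE families (must sum to 1).
#' @param target_te_fraction Desired dataset-wide mean per-cell TE transcript
#'   fraction, in (0, 0.5). Default 0.12 (the 10--15% regime typical of
#'   locus-level TE quantification in brain nuclei).
#' @param planted_effects Tibble with columns `te_index` (1-based),
#'   `cell_type`, `log2fc`; each row multiplies the case-condition mean of
#'   that TE in that cell type by `2^log2fc`.
#' @param nb_dispersion Shared negative-binomial dispersion (1/size).
#' @param genome Tibble with columns `chrom`, `length`.
#' @param planted_floor Minimum per-cell baseline mean (post-scaling)
#'   imposed on planted TEs so planted effects act on a measurable
#'   baseline; the default 0.1 counts/cell gives roughly 5+ pseudobulk
#'   counts per sample in the larger cell types.
#' @param n_peaks,n_enhancers Number of ATAC peaks / enhancer intervals.
#' @param n_gene_sets Number of random gene sets (three seeded "enriched"
#'   sets are added when effects are planted).
#' @param ad_gene_count Size of the synthetic AD-risk gene list.
#' @param te_derived_frac Fraction of genes placed in the synthetic
#'   TE-derived gene catalog (genome-wide expectation ~3%).
#' @param peak_overlap_frac Fraction of planted TEs given an overlapping
#'   high-accessibility peak (positive controls for regulatory scoring).
#' @return A `te_sim_config` list.
#' @export
#' @examples
#' cfg <- simulation_config(seed = 1, n_genes = 50, n_te_loci = 40)
simulation_config <- function(seed = 1L,
                              n_samples_case = 11L,
                              n_samples_control = 7L,
                              cell_types = default_cell_types(),
                              n_genes = 400L,
                              n_te_loci = 400L,
                              family_mix = baseline_composition(),
                              target_te_fraction = 0.12,
                              planted_effects = NULL,
                              nb_dispersion = 0.15,
                              genome = default_genome(),
                              planted_floor = 0.1,
                              n_peaks = 300L,
                              n_enhancers = 150L,
                              n_gene_sets = 30L,
                              ad_gene_count = 40L,
                              te_derived_frac = 0.03,
                              peak_overlap_frac = 0.6) {
  if (abs(sum(family_mix) - 1) > 1e-9) {
    abort("family_mix proportions must sum to 1")
  }
  if (!(target_te_fraction > 0 && target_te_fraction < 0.5)) {
    abort("target_te_fraction must lie in (0, 0.5)")
  }
  counts <- c(n_samples_case, n_samples_control, n_genes, n_te_loci,
              n_peaks, n_enhancers)
  if (any(counts <= 0)) abort("all size parameters must be positive")
  if (nb_dispersion <= 0) abort("nb_dispersion must be positive")
  stopifnot_cols(cell_types, c("cell_type", "min_cells", "max_cells"),
                 "cell_types")
  stopifnot_cols(genome, c("chrom", "length"), "genome")
  if (is.null(planted_effects)) {
    planted_effects <- tibble(te_index = integer(), cell_type = character(),
                              log2fc = numeric())
  }
  stopifnot_cols(planted_effects, c("te_index", "cell_type", "log2fc"),
                 "planted_effects")
  if (nrow(planted_effects) > 0) {
    if (any(planted_effects$te_index < 1 | planted_effects$te_index > n_te_loci)) {
      abort("planted te_index out of range [1, n_te_loci]")
    }
    if (any(abs(planted_effects$log2fc) > 10)) {
      abort("|log2fc| of planted effects must be <= 10")
    }
    if (!all(planted_effects$cell_type %in% cell_types$cell_type)) {
      abort("planted cell_type not in configured cell types")
    }
  }
  structure(list(
    seed = as.integer(seed),
    n_samples_case = as.integer(n_samples_case),
    n_samples_control = as.integer(n_samples_control),
    cell_types = as_tibble(cell_types),
    n_genes = as.integer(n_genes),
    n_te_loci = as.integer(n_te_loci),
    family_mix = family_mix,
    target_te_fraction = target_te_fraction,
    planted_effects = as_tibble(planted_effects),
    nb_dispersion = nb_dispersion,
    genome = as_tibble(genome),
    planted_floor = planted_floor,
    n_peaks = as.integer(n_peaks),
    n_enhancers = as.integer(n_enhancers),
    n_gene_sets = as.integer(n_gene_sets),
    ad_gene_count = as.integer(ad_gene_count),
    te_derived_frac = te_derived_frac,
    peak_overlap_frac = peak_overlap_frac
  ), class = "te_sim_config")
}

#' Plant a disease-like TE dysregulation scenario
#'
#' Adds planted effects reproducing, at reduced scale, the direction
#' structure seen in AD cortex: effects concentrated in two populations,
#' with ~63% of effects in an excitatory-neuron-like population (almost all
#' upregulated), ~32% in an oligodendrocyte-like population (about
#' two-thirds upregulated), and the remainder scattered over other cell
#' types. Effect magnitudes are drawn uniformly in \[2.2, 6.5\] log2 units.
#'
#' @param config A `te_sim_config`.
#' @param n_effects Total number of planted effects (0 returns `config`
#'   unchanged).
#' @param populations Length-2 character vector naming the dominant and
#'   secondary cell types (default `c("EX", "ODC")`).
#' @return The config with `planted_effects` replaced.
#' @export
plant_ad_scenario <- function(config, n_effects = 60L,
                              populations = c("EX", "ODC")) {
  stopifnot(inherits(config, "te_sim_config"))
  if (!all(populations %in% config$cell_types$cell_type)) {
    abort("both populations must be configured cell types")
  }
  n_effects <- as.integer(n_effects)
  if (n_effects == 0L) return(config)
  if (n_effects > config$n_te_loci) {
    abort("cannot plant more effects than TE loci")
  }

  n_a <- round(0.63 * n_effects)
  n_b <- round(0.32 * n_effects)
  n_rest <- n_effects - n_a - n_b
  other_types <- setdiff(config$cell_types$cell_type, populations)

  withr_seed(derive_seed(config$seed, "plant_ad_scenario"), {
    te_index <- sample.int(config$n_te_loci, n_effects)
    cell_type <- c(rep(populations[1], n_a), rep(populations[2], n_b),
                   sample(other_types, n_rest, replace = TRUE))
    sign_block <- function(n, p_up) {
      n_up <- round(p_up * n)
      sample(c(rep(1, n_up), rep(-1, n - n_up)))
    }
    signs <- c(sign_block(n_a, 0.95), sign_block(n_b, 0.65),
               sign_block(n_rest, 0.84))
    magnitude <- runif(n_effects, 2.2, 6.5)
  })

  config$planted_effects <- tibble(
    te_index = te_index, cell_type = cell_type, log2fc = signs * magnitude
  )
  config
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  eval(expr, envir = parent.frame())
}

random_intervals <- function(n, genome, len_min, len_max) {
  chrom <- sample(genome$chrom, n, replace = TRUE,
                  prob = genome$length / sum(genome$length))
  chrom_len <- genome$length[match(chrom, genome$chrom)]
  len <- as.integer(round(runif(n, len_min, len_max)))
  if (any(len >= chrom_len)) {
    abort("impossible geometry: interval longer than its chromosome")
  }
  start <- as.integer(floor(runif(n, 0, chrom_len - len)))
  tibble(chrom = chrom, start = start, end = start + len)
}

#' Generate a complete synthetic dataset
#'
#' Draws negative-binomial counts for genes and locus-level TEs across
#' cells of a case/control design, places every feature on the toy genome,
#' and emits all the side tables the pipeline consumes: cell metadata, TE
#' and gene interval tracks, enhancers, an ATAC peak track with a
#' peak-by-cell-type accessibility matrix, an AD-risk gene list, a
#' TE-derived gene catalog, and a gene-set collection. TE feature means are
#' rescaled so the dataset-wide mean per-cell TE transcript fraction hits
#' `target_te_fraction`; planted effects multiply the case-condition mean
#' of their TE in their cell type by `2^log2fc`. Identical configs give
#' bit-identical bundles.
#'
#' @param config A `te_sim_config` from [simulation_config()].
#' @return A `te_bundle` list: `counts` (sparse features x cells),
#'   `features`, `cells`, `te_loci`, `genes`, `exons`, `enhancers`,
#'   `peaks`, `peak_matrix`, `ad_genes`, `te_derived_genes`, `gene_sets`,
#'   and the generating `config`.
#' @export
#' @examples
#' bundle <- simulate_te_dataset(simulation_config(seed = 1, n_genes = 60,
#'   n_te_loci = 40))
#' dim(bundle$counts)
simulate_te_dataset <- function(config) {
  stopifnot(inherits(config, "te_sim_config"))
  set.seed(config$seed)
  genome <- config$genome

  ## --- samples and cells ------------------------------------------------
  samples <- tibble(
    sample_id = c(sprintf("AD%02d", seq_len(config$n_samples_case)),
                  sprintf("CT%02d", seq_len(config$n_samples_control))),
    condition = c(rep("AD", config$n_samples_case),
                  rep("control", config$n_samples_control))
  )
  cells <- purrr::pmap_dfr(samples, function(sample_id, condition) {
    purrr::pmap_dfr(config$cell_types, function(cell_type, min_cells, max_cells) {
      n <- sample(seq.int(min_cells, max_cells), 1)
      tibble(sample_id = sample_id, condition = condition,
             cell_type = cell_type, idx = seq_len(n))
    })
  })
  cells <- cells |>
    mutate(cell_id = sprintf("%s_%s_%03d", .data$sample_id, .data$cell_type,
                             .data$idx)) |>
    select("cell_id", "sample_id", "condition", "cell_type")

  ## --- features ---------------------------------------------------------
  genes_iv <- random_intervals(config$n_genes, genome, 2e3, 6e4)
  genes <- genes_iv |>
    mutate(gene_id = sprintf("G%04d", seq_len(config$n_genes)),
           strand = sample(c("+", "-"), config$n_genes, replace = TRUE),
           tss = ifelse(.data$strand == "+", .data$start, .data$end)) |>
    select("gene_id", "chrom", "start", "end", "strand", "tss")

  exons <- purrr::pmap_dfr(genes, function(gene_id, chrom, start, end, strand, tss) {
    n_ex <- sample(1:4, 1)
    width <- end - start
    ex_start <- sort(as.integer(floor(runif(n_ex, start, end - 200))))
    ex_end <- pmin(ex_start + as.integer(round(runif(n_ex, 100, 2000))), end)
    tibble(gene_id = gene_id, chrom = chrom, start = ex_start, end = ex_end)
  })

  family <- sample(names(config$family_mix), config$n_te_loci, replace = TRUE,
                   prob = config$family_mix)
  subfamily <- vapply(family, function(f) sample(te_subfamily_pool[[f]], 1), "")
  te_class <- unname(te_family_class[family])
  te_len_rng <- te_class_length_range[te_class]
  te_len <- vapply(te_len_rng, function(r) round(runif(1, r[1], r[2])), 0)
  te_chrom <- sample(genome$chrom, config$n_te_loci, replace = TRUE,
                     prob = genome$length / sum(genome$length))
  te_chrom_len <- genome$length[match(te_chrom, genome$chrom)]
  if (any(te_len >= te_chrom_len)) {
    abort("impossible geometry: TE longer than its chromosome")
  }
  te_start <- as.integer(floor(runif(config$n_te_loci, 0, te_chrom_len - te_len)))
  te_loci <- tibble(
    chrom = te_chrom, start = te_start, end = te_start + as.integer(te_len),
    subfamily = unname(subfamily), family = family, te_class = te_class,
    strand = sample(c("+", "-"), config$n_te_loci, replace = TRUE)
  ) |>
    mutate(feature_id = format_te_name(.data$chrom, .data$start, .data$end,
                                       .data$subfamily, .data$family,
                                       .data$te_class, .data$strand)) |>
    select("feature_id", dplyr::everything())

  features <- tibble(
    feature_id = c(genes$gene_id, te_loci$feature_id),
    kind = rep(c("gene", "TE"), c(config$n_genes, config$n_te_loci))
  )

  ## --- expression means -------------------------------------------------
  # Gene budget dominates the per-cell library (as in real nuclei), so
  # planted TE effects perturb sample library sizes only marginally.
  gene_mu <- rlnorm(config$n_genes, meanlog = log(1.0), sdlog = 1.2)
  te_mu0 <- rlnorm(config$n_te_loci, meanlog = log(0.2), sdlog = 1.2)
  n_feat <- config$n_genes + config$n_te_loci

  ct_labels <- config$cell_types$cell_type
  ct_factor <- matrix(rlnorm(n_feat * length(ct_labels), 0, 0.25),
                      nrow = n_feat, dimnames = list(NULL, ct_labels))

  # Scale the TE baseline so the expected dataset-wide mean per-cell TE
  # transcript fraction hits the target, accounting for planted
  # case-condition effects and the post-scaling floor on planted TEs.
  planted <- config$planted_effects
  floor_vec <- rep(0, config$n_te_loci)
  if (nrow(planted) > 0) {
    floor_vec[unique(planted$te_index)] <- config$planted_floor
  }
  ctf_gene <- ct_factor[seq_len(config$n_genes), , drop = FALSE]
  ctf_te <- ct_factor[config$n_genes + seq_len(config$n_te_loci), ,
                      drop = FALSE]
  group_n <- cells |> count(.data$cell_type, .data$condition, name = "n")
  expected_fraction <- function(s) {
    te_s <- pmax(s * te_mu0, floor_vec)
    fr <- purrr::pmap_dbl(group_n, function(cell_type, condition, n) {
      fc <- rep(1, config$n_te_loci)
      if (condition == "AD" && nrow(planted) > 0) {
        pl <- planted[planted$cell_type == cell_type, ]
        fc[pl$te_index] <- 2^pl$log2fc
      }
      te_w <- sum(te_s * ctf_te[, cell_type] * fc)
      gene_w <- sum(gene_mu * ctf_gene[, cell_type])
      te_w / (te_w + gene_w)
    })
    sum(fr * group_n$n) / sum(group_n$n)
  }
  tf <- config$target_te_fraction
  if (expected_fraction(1e-9) > tf) {
    warn("planted floor alone exceeds the target TE fraction; target not met")
    s_hat <- 1e-9
  } else {
    s_hat <- stats::uniroot(function(s) expected_fraction(s) - tf,
                            lower = 1e-9, upper = 1e3, tol = 1e-10)$root
  }
  te_mu <- pmax(s_hat * te_mu0, floor_vec)
  base_mu <- c(gene_mu, te_mu)
  sample_factor <- setNames(rlnorm(nrow(samples), 0, 0.1), samples$sample_id)
  cell_size <- rlnorm(nrow(cells), 0, 0.3)

  te_offset <- config$n_genes

  counts <- matrix(0L, nrow = n_feat, ncol = nrow(cells))
  for (ct in ct_labels) {
    cols <- which(cells$cell_type == ct)
    if (length(cols) == 0) next
    mu_ct <- base_mu * ct_factor[, ct]
    fc <- rep(1, n_feat)
    if (nrow(planted) > 0) {
      pl <- planted[planted$cell_type == ct, ]
      fc[te_offset + pl$te_index] <- 2^pl$log2fc
    }
    is_case <- cells$condition[cols] == "AD"
    scale_cells <- cell_size[cols] * sample_factor[cells$sample_id[cols]]
    mu_mat <- outer(mu_ct, scale_cells)
    if (any(is_case) && nrow(planted) > 0) {
      mu_mat[, is_case] <- mu_mat[, is_case] * fc
    }
    counts[, cols] <- rnbinom(length(mu_mat), mu = mu_mat,
                              size = 1 / config$nb_dispersion)
  }
  dimnames(counts) <- list(features$feature_id, cells$cell_id)
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE),
                        "CsparseMatrix")

  ## --- regulatory tracks ------------------------------------------------
  enhancers <- random_intervals(config$n_enhancers, genome, 500, 2000)

  peaks <- random_intervals(config$n_peaks, genome, 400, 1200)
  planted_peak_of <- integer(0)
  if (nrow(planted) > 0) {
    target_tes <- unique(planted$te_index)
    n_overlap <- ceiling(config$peak_overlap_frac * length(target_tes))
    chosen <- sort(sample(target_tes, min(n_overlap, length(target_tes))))
    # overwrite the first peaks so they sit on top of planted TEs
    for (i in seq_along(chosen)) {
      te <- te_loci[chosen[i], ]
      mid <- floor((te$start + te$end) / 2)
      half <- as.integer(round(runif(1, 200, 600)))
      peaks$chrom[i] <- te$chrom
      peaks$start[i] <- max(0L, mid - half)
      peaks$end[i] <- mid + half
      planted_peak_of[i] <- chosen[i]
    }
  }
  peaks <- peaks |>
    mutate(peak_id = sprintf("peak%04d", dplyr::row_number())) |>
    select("peak_id", "chrom", "start", "end")

  peak_matrix <- matrix(rgamma(config$n_peaks * length(ct_labels),
                               shape = 2, scale = 1),
                        nrow = config$n_peaks,
                        dimnames = list(peaks$peak_id, ct_labels))
  if (length(planted_peak_of) > 0) {
    for (i in seq_along(planted_peak_of)) {
      pl_ct <- planted$cell_type[planted$te_index == planted_peak_of[i]][1]
      peak_matrix[i, ] <- peak_matrix[i, ] * 2
      peak_matrix[i, pl_ct] <- peak_matrix[i, pl_ct] * 4
    }
  }

  ## --- gene lists and sets ----------------------------------------------
  proximal_to_planted <- character(0)
  if (nrow(planted) > 0) {
    pl_te <- te_loci[unique(planted$te_index), ]
    near <- find_pairs(pl_te, genes, window = 250e3)
    proximal_to_planted <- unique(near$gene_id)
  }
  n_biased <- min(length(proximal_to_planted), config$ad_gene_count %/% 2)
  ad_genes <- unique(c(
    if (n_biased > 0) sample(proximal_to_planted, n_biased),
    sample(genes$gene_id, config$ad_gene_count)
  ))[seq_len(config$ad_gene_count)]

  n_derived <- max(1L, round(config$te_derived_frac * config$n_genes))
  te_derived_genes <- sort(sample(genes$gene_id, n_derived))

  gene_sets <- lapply(seq_len(config$n_gene_sets), function(i) {
    sort(sample(genes$gene_id, sample(15:40, 1)))
  })
  names(gene_sets) <- sprintf("set%03d", seq_len(config$n_gene_sets))
  if (length(proximal_to_planted) >= 10) {
    for (j in 1:3) {
      k <- min(length(proximal_to_planted), sample(15:30, 1))
      core <- sample(proximal_to_planted, ceiling(0.7 * k))
      pad <- sample(setdiff(genes$gene_id, core), k - length(core))
      gene_sets[[sprintf("enriched%02d", j)]] <- sort(c(core, pad))
    }
  }

  structure(list(
    counts = counts, features = features, cells = cells,
    te_loci = te_loci, genes = genes, exons = exons,
    enhancers = enhancers, peaks = peaks, peak_matrix = peak_matrix,
    ad_genes = ad_genes, te_derived_genes = te_derived_genes,
    gene_sets = gene_sets, config = config
  ), class = "te_bundle")
}

#' @export
print.te_bundle <- function(x, ...) {
  cat(sprintf(
    "<te_bundle> %d features (%d genes, %d TE loci) x %d cells; %d samples; %d peaks\n",
    nrow(x$counts), sum(x$features$kind == "gene"),
    sum(x$features$kind == "TE"), ncol(x$counts),
    length(unique(x$cells$sample_id)), nrow(x$peaks)))
  invisible(x)
}

write_bed <- function(df, path, name = NULL, score = 0, strand = NULL) {
  out <- tibble(
    chrom = df$chrom, start = df$start, end = df$end,
    name = name %||% ".", score = score,
    strand = strand %||% "."
  )
  readr::write_tsv(out, path, col_names = FALSE)
}

#' Write a synthetic bundle to disk
#'
#' Emits the standard on-disk form the readers in this package (and common
#' external tools) consume: MatrixMarket counts with feature/barcode TSVs,
#' a cell-metadata TSV, BED6 tracks for TE loci, gene bodies, exons,
#' enhancers and ATAC peaks, a gene-model TSV (with TSS), a peak
#' accessibility TSV, plain-text gene lists, a JSON gene-set collection,
#' and the generating config as YAML.
#'
#' @param bundle A `te_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "te_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)

  Matrix::writeMM(bundle$counts, p("matrix.mtx"))
  readr::write_tsv(bundle$features, p("features.tsv"), col_names = TRUE)
  readr::write_tsv(tibble(cell_id = colnames(bundle$counts)),
                   p("barcodes.tsv"), col_names = TRUE)
  readr::write_tsv(bundle$cells, p("cell_metadata.tsv"))

  write_bed(bundle$te_loci, p("te_loci.bed"),
            name = bundle$te_loci$feature_id, strand = bundle$te_loci$strand)
  write_bed(bundle$genes, p("gene_bodies.bed"),
            name = bundle$genes$gene_id, strand = bundle$genes$strand)
  write_bed(bundle$exons, p("exons.bed"), name = bundle$exons$gene_id)
  write_bed(bundle$enhancers, p("enhancers.bed"))
  write_bed(bundle$peaks, p("atac_peaks.bed"), name = bundle$peaks$peak_id)
  readr::write_tsv(bundle$genes, p("gene_models.tsv"))
  readr::write_tsv(
    as_tibble(bundle$peak_matrix, rownames = "peak_id"),
    p("peak_accessibility.tsv"))
  writeLines(bundle$ad_genes, p("ad_risk_genes.txt"))
  writeLines(bundle$te_derived_genes, p("te_derived_genes.txt"))
  jsonlite::write_json(bundle$gene_sets, p("gene_sets.json"))
  cfg <- bundle$config
  cfg_list <- lapply(unclass(cfg), function(x) {
    if (inherits(x, "tbl_df")) as.data.frame(x) else x
  })
  yaml::write_yaml(cfg_list, p("config.yaml"))
  invisible(dir)
}
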