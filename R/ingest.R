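# Ingest: locus-encoded TE feature names, matrix/metadata/track readers,
# the low-expression feature filter, and per-cell TE transcript fractions.
#
# All coordinates are 0-based half-open (BED convention) throughout the
# package; conversion to the 1-based closed convention happens only at the
# GenomicRanges boundary inside proximity/ATAC helpers.

te_class_vocabulary <- c("SINE", "LINE", "LTR", "DNA", "other")

#' Format a locus-encoded TE feature name
#'
#' The canonical grammar is
#' `TE|<chrom>|<start>|<end>|<subfamily>:<family>:<class>|<strand>` with
#' 0-based half-open coordinates, e.g.
#' `TE|chr1|1000|1300|AluY:Alu:SINE|+`. Matrices produced by locus-level
#' TE quantifiers can be adapted to this form by renaming features.
#'
#' @param chrom,start,end,subfamily,family,te_class,strand Vectorised
#'   locus fields.
#' @return Character vector of feature names.
#' @export
format_te_name <- function(chrom, start, end, subfamily, family, te_class,
                           strand = "+") {
  sprintf("TE|%s|%d|%d|%s:%s:%s|%s", chrom, as.integer(start),
          as.integer(end), subfamily, family, te_class, strand)
}

#' Parse locus-encoded TE feature names
#'
#' Inverse of [format_te_name()]. Unknown classes are normalised to
#' `"other"`; malformed names raise an error naming the offending token.
#'
#' @param name Character vector of TE feature names.
#' @return Tibble with columns `feature_id`, `chrom`, `start`, `end`,
#'   `subfamily`, `family`, `te_class`, `strand`.
#' @export
#' @examples
#' parse_te_name("TE|chr1|1000|1300|AluY:Alu:SINE|+")
parse_te_name <- function(name) {
  parts <- stringr::str_split(name, stringr::fixed("|"))
  bad <- lengths(parts) != 6 | !vapply(parts, function(p) p[1] == "TE", TRUE)
  if (any(bad)) {
    abort(sprintf("malformed TE name (expected 6 '|'-separated fields starting 'TE'): %s",
                  name[bad][1]))
  }
  m <- do.call(rbind, parts)
  start <- suppressWarnings(as.integer(m[, 3]))
  end <- suppressWarnings(as.integer(m[, 4]))
  if (anyNA(start) || anyNA(end)) {
    i <- which(is.na(start) | is.na(end))[1]
    abort(sprintf("malformed TE name: non-integer coordinate in %s", name[i]))
  }
  if (any(start >= end)) {
    i <- which(start >= end)[1]
    abort(sprintf("malformed TE name: start >= end in %s", name[i]))
  }
  tax <- stringr::str_split(m[, 5], stringr::fixed(":"))
  if (any(lengths(tax) != 3)) {
    i <- which(lengths(tax) != 3)[1]
    abort(sprintf("malformed TE name: taxonomy field '%s' is not subfamily:family:class",
                  m[i, 5]))
  }
  taxm <- do.call(rbind, tax)
  if (any(taxm[, 1] == "")) abort("malformed TE name: empty subfamily")
  if (!all(m[, 6] %in% c("+", "-", "."))) {
    i <- which(!m[, 6] %in% c("+", "-", "."))[1]
    abort(sprintf("malformed TE name: strand '%s'", m[i, 6]))
  }
  te_class <- ifelse(taxm[, 3] %in% te_class_vocabulary, taxm[, 3], "other")
  tibble(
    feature_id = name, chrom = m[, 2], start = start, end = end,
    subfamily = taxm[, 1], family = taxm[, 2], te_class = te_class,
    strand = m[, 6]
  )
}

#' Read a counts bundle from disk
#'
#' Reads the MTX + features/barcodes/metadata layout written by
#' [write_bundle()] together with the interval tracks, gene lists and
#' gene-set collection, returning a `te_bundle` equivalent to the one that
#' was written. Duplicate feature or cell ids are rejected.
#'
#' @param dir Directory produced by [write_bundle()].
#' @return A `te_bundle`.
#' @export
read_bundle <- function(dir) {
  p <- function(...) file.path(dir, ...)
  counts <- methods::as(Matrix::readMM(p("matrix.mtx")), "CsparseMatrix")
  features <- readr::read_tsv(p("features.tsv"), show_col_types = FALSE)
  barcodes <- readr::read_tsv(p("barcodes.tsv"), show_col_types = FALSE)
  if (anyDuplicated(features$feature_id)) abort("duplicate feature ids")
  if (anyDuplicated(barcodes$cell_id)) abort("duplicate cell ids")
  dimnames(counts) <- list(features$feature_id, barcodes$cell_id)
  cells <- read_cell_metadata(p("cell_metadata.tsv"))
  te_loci <- parse_te_name(features$feature_id[features$kind == "TE"])
  genes <- readr::read_tsv(p("gene_models.tsv"), show_col_types = FALSE)
  exons <- read_bed(p("exons.bed"))
  exons <- tibble(gene_id = exons$name, chrom = exons$chrom,
                  start = exons$start, end = exons$end)
  enhancers <- read_bed(p("enhancers.bed"))[, c("chrom", "start", "end")]
  peaks_bed <- read_bed(p("atac_peaks.bed"))
  peaks <- tibble(peak_id = peaks_bed$name, chrom = peaks_bed$chrom,
                  start = peaks_bed$start, end = peaks_bed$end)
  pm <- readr::read_tsv(p("peak_accessibility.tsv"), show_col_types = FALSE)
  peak_matrix <- as.matrix(pm[, -1])
  rownames(peak_matrix) <- pm$peak_id
  gene_sets <- jsonlite::read_json(p("gene_sets.json"),
                                   simplifyVector = TRUE)
  gene_sets <- lapply(gene_sets, as.character)
  structure(list(
    counts = counts, features = features, cells = cells, te_loci = te_loci,
    genes = genes, exons = exons, enhancers = enhancers, peaks = peaks,
    peak_matrix = peak_matrix,
    ad_genes = readLines(p("ad_risk_genes.txt")),
    te_derived_genes = readLines(p("te_derived_genes.txt")),
    gene_sets = gene_sets, config = NULL
  ), class = "te_bundle")
}

#' Read cell metadata
#'
#' Requires columns `cell_id`, `sample_id`, `condition`, `cell_type`;
#' rejects duplicate cell ids and conditions outside \{AD, control\}.
#'
#' @param path TSV file path.
#' @return Tibble of cell annotations.
#' @export
read_cell_metadata <- function(path) {
  cells <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot_cols(cells, c("cell_id", "sample_id", "condition", "cell_type"),
                 "cell metadata")
  if (anyDuplicated(cells$cell_id)) abort("duplicate cell ids in metadata")
  if (!all(cells$condition %in% c("AD", "control"))) {
    abort("condition must be 'AD' or 'control'")
  }
  cells
}

#' Read a BED file (BED3/BED6)
#'
#' 0-based half-open intervals; columns beyond the sixth are ignored.
#'
#' @param path BED file path.
#' @return Tibble with `chrom`, `start`, `end` and, when present, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  if (ncol(bed) < 3) abort("BED file must have at least 3 columns")
  nm <- c("chrom", "start", "end", "name", "score", "strand")
  names(bed)[seq_len(min(6, ncol(bed)))] <- nm[seq_len(min(6, ncol(bed)))]
  as_tibble(bed[, seq_len(min(6, ncol(bed)))])
}

#' Drop features detected in too few cells
#'
#' Retains features with a nonzero count in at least `min_cells` cells
#' (default 10), applied uniformly to genes and TE loci. Cells are never
#' removed. The operation is idempotent and monotone in `min_cells`.
#'
#' @param counts Sparse or dense features x cells count matrix.
#' @param min_cells Minimum number of cells with nonzero counts.
#' @return The filtered count matrix (possibly with zero rows, with a
#'   warning).
#' @export
filter_low_expression <- function(counts, min_cells = 10) {
  stopifnot(min_cells >= 1)
  n_cells_detected <- Matrix::rowSums(counts > 0)
  keep <- n_cells_detected >= min_cells
  if (!any(keep)) warn("no features pass the low-expression filter")
  counts[keep, , drop = FALSE]
}

#' Per-cell TE transcript fraction
#'
#' For each cell, the percentage of total counts carried by TE features:
#' `100 * sum(TE counts) / sum(all counts)`. Cells with zero total counts
#' get `NA` and are flagged.
#'
#' @param counts Features x cells count matrix.
#' @param features Tibble with `feature_id`, `kind` ("gene" or "TE")
#'   matching the matrix rows.
#' @param cells Optional cell metadata to join (adds `cell_type`,
#'   `condition`).
#' @return Tibble with `cell_id`, `te_pct`, `total_counts`, `zero_total`.
#' @export
te_fraction_per_cell <- function(counts, features, cells = NULL) {
  stopifnot_cols(features, c("feature_id", "kind"), "features")
  if (nrow(features) != nrow(counts)) {
    abort("features table must match matrix rows")
  }
  te_rows <- features$kind == "TE"
  total <- unname(Matrix::colSums(counts))
  te_total <- unname(Matrix::colSums(counts[te_rows, , drop = FALSE]))
  out <- tibble(
    cell_id = colnames(counts) %||% as.character(seq_along(total)),
    te_pct = ifelse(total > 0, 100 * te_total / total, NA_real_),
    total_counts = total,
    zero_total = total == 0
  )
  if (!is.null(cells)) out <- left_join(out, cells, by = "cell_id")
  out
}
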