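#' Construct a count matrix container
#'
#' Bundles a sparse genes x cells integer count matrix with gene/cell
#' metadata and per-gene class flags. Mitochondrial and ribosomal genes
#' are flagged by name pattern (10x naming convention); pseudogenes by an
#' explicit ID list.
#'
#' @param counts Sparse (`dgCMatrix`) or dense non-negative integer
#'   matrix, genes in rows, cells in columns.
#' @param gene_ids,gene_names Character vectors of length `nrow(counts)`.
#' @param barcodes Character vector of unique cell barcodes, length
#'   `ncol(counts)`.
#' @param mito_pattern,ribo_pattern Regular expressions applied to
#'   `gene_names` to flag mitochondrial and ribosomal genes.
#' @param pseudogene_ids Optional character vector of gene IDs flagged as
#'   pseudogenes.
#' @return An object of class `count_matrix`: list with `counts`
#'   (dgCMatrix, dimnames = gene names x barcodes), `gene_ids`,
#'   `gene_names`, `barcodes` and `gene_flags` (data.frame with logical
#'   columns `mitochondrial`, `ribosomal`, `pseudogene`).
#' @export
count_matrix <- function(counts, gene_ids, gene_names = gene_ids,
                         barcodes,
                         mito_pattern = "^mt-|^MT-",
                         ribo_pattern = "^Rps|^Rpl|^RPS|^RPL",
                         pseudogene_ids = NULL) {
  counts <- as(as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"),
               "CsparseMatrix")
  if (length(gene_ids) != nrow(counts))
    stop("gene_ids length does not match gene count", call. = FALSE)
  if (length(gene_names) != nrow(counts))
    stop("gene_names length does not match gene count", call. = FALSE)
  if (length(barcodes) != ncol(counts))
    stop("barcodes length does not match cell count", call. = FALSE)
  if (anyDuplicated(barcodes))
    stop("duplicate cell barcodes", call. = FALSE)
  if (any(counts@x < 0))
    stop("counts must be non-negative", call. = FALSE)
  dimnames(counts) <- list(gene_names, barcodes)
  flags <- data.frame(
    mitochondrial = grepl(mito_pattern, gene_names),
    ribosomal = grepl(ribo_pattern, gene_names),
    pseudogene = if (is.null(pseudogene_ids)) rep(FALSE, length(gene_ids))
                 else gene_ids %in% pseudogene_ids,
    row.names = NULL
  )
  structure(list(counts = counts, gene_ids = gene_ids,
                 gene_names = gene_names, barcodes = barcodes,
                 gene_flags = flags),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells (%d mito, %d ribo, %d pseudo)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$gene_flags$mitochondrial), sum(x$gene_flags$ribosomal),
              sum(x$gene_flags$pseudogene)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Load a 10x-style sparse count matrix
#'
#' Reads `matrix.mtx` + `barcodes.tsv` + `features.tsv` (gene id, gene
#' name) from a directory, checking that the MatrixMarket header agrees
#' with the TSV line counts, and derives gene-class flags from name
#' patterns and an optional pseudogene ID list (a `pseudogenes.tsv` in
#' the directory is picked up automatically).
#'
#' @param directory Directory containing the triplet files.
#' @param matrix_file,barcodes_file,features_file Override individual file
#'   paths.
#' @param pseudogene_ids Optional pseudogene ID vector; defaults to the
#'   contents of `pseudogenes.tsv` when present.
#' @inheritParams count_matrix
#' @return A [count_matrix()].
#' @export
load_counts <- function(directory = NULL,
                        matrix_file = file.path(directory, "matrix.mtx"),
                        barcodes_file = file.path(directory, "barcodes.tsv"),
                        features_file = file.path(directory, "features.tsv"),
                        mito_pattern = "^mt-|^MT-",
                        ribo_pattern = "^Rps|^Rpl|^RPS|^RPL",
                        pseudogene_ids = NULL) {
  for (f in c(matrix_file, barcodes_file, features_file))
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
  m <- as(as(Matrix::readMM(matrix_file), "generalMatrix"), "CsparseMatrix")
  barcodes <- readLines(barcodes_file)
  feats <- read.delim(features_file, header = FALSE,
                      stringsAsFactors = FALSE)
  if (nrow(feats) != nrow(m))
    stop(sprintf("dimension mismatch: %s declares %d genes but %s has %d lines",
                 matrix_file, nrow(m), features_file, nrow(feats)),
         call. = FALSE)
  if (length(barcodes) != ncol(m))
    stop(sprintf("dimension mismatch: %s declares %d cells but %s has %d lines",
                 matrix_file, ncol(m), barcodes_file, length(barcodes)),
         call. = FALSE)
  if (is.null(pseudogene_ids) && !is.null(directory)) {
    pf <- file.path(directory, "pseudogenes.tsv")
    if (file.exists(pf)) pseudogene_ids <- readLines(pf)
  }
  count_matrix(m, gene_ids = feats[[1L]],
               gene_names = if (ncol(feats) >= 2L) feats[[2L]] else feats[[1L]],
               barcodes = barcodes,
               mito_pattern = mito_pattern, ribo_pattern = ribo_pattern,
               pseudogene_ids = pseudogene_ids)
}

#' Quality-control parameters
#'
#' Default thresholds are the strict filters for droplet scRNA-seq of
#' thymocytes: cells with fewer than 500 or more than 4500 detected genes
#' or with a mitochondrial count fraction exceeding 40% are removed, and
#' genes detected in fewer than three remaining cells are dropped. All
#' comparisons are strict inequalities.
#'
#' @param min_genes,max_genes Detected-gene count bounds per cell
#'   (`detected` means raw count > 0).
#' @param max_mito_fraction Maximum tolerated mitochondrial count
#'   fraction, computed on the matrix before gene-class removal.
#' @param min_cells_per_gene Minimum number of remaining cells a gene
#'   must be detected in.
#' @return An object of class `qc_params`.
#' @export
qc_params <- function(min_genes = 500L, max_genes = 4500L,
                      max_mito_fraction = 0.40, min_cells_per_gene = 3L) {
  if (min_genes >= max_genes)
    stop("min_genes must be below max_genes", call. = FALSE)
  if (max_mito_fraction < 0 || max_mito_fraction > 1)
    stop("max_mito_fraction must lie in [0, 1]", call. = FALSE)
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 max_mito_fraction = max_mito_fraction,
                 min_cells_per_gene = min_cells_per_gene),
            class = "qc_params")
}

#' Apply quality-control filters to a count matrix
#'
#' Filtering proceeds in the order: (1) remove flagged gene classes
#' (mitochondrial, ribosomal, pseudogenes); (2) remove cells whose
#' detected-gene count lies outside (`min_genes`, `max_genes`) or whose
#' mitochondrial count fraction — computed on the matrix *before*
#' gene-class removal — exceeds `max_mito_fraction`; (3) remove genes
#' detected in fewer than `min_cells_per_gene` of the remaining cells.
#' The three cell rules are independent (OR-ed); the report counts each
#' rule separately so overlapping removals can be audited.
#'
#' @param m A [count_matrix()] with populated gene flags.
#' @param params A [qc_params()] object.
#' @return A list of class `qc_result`: `matrix` (filtered
#'   [count_matrix()]) and `report`, a data.frame of removal counts per
#'   rule (`genes_class_removed`, `cells_low_genes`, `cells_high_genes`,
#'   `cells_high_mito`, `cells_removed`, `genes_low_cells`).
#' @export
qc_filter <- function(m, params = qc_params()) {
  if (!inherits(m, "count_matrix"))
    stop("'m' must be a count_matrix", call. = FALSE)
  if (!inherits(params, "qc_params"))
    stop("'params' must be a qc_params object", call. = FALSE)
  counts <- m$counts
  flags <- m$gene_flags

  # mito fraction on the pre-removal matrix
  total <- Matrix::colSums(counts)
  mito_frac <- if (any(flags$mitochondrial))
    Matrix::colSums(counts[flags$mitochondrial, , drop = FALSE]) /
      pmax(total, 1)
  else rep(0, ncol(counts))

  class_remove <- flags$mitochondrial | flags$ribosomal | flags$pseudogene
  kept_genes <- !class_remove
  sub <- counts[kept_genes, , drop = FALSE]

  detected <- Matrix::colSums(sub > 0)
  low <- detected < params$min_genes
  high <- detected > params$max_genes
  himito <- mito_frac > params$max_mito_fraction
  drop_cell <- low | high | himito
  if (all(drop_cell))
    stop("empty after QC: every cell was removed", call. = FALSE)
  sub <- sub[, !drop_cell, drop = FALSE]

  gene_cells <- Matrix::rowSums(sub > 0)
  low_gene <- gene_cells < params$min_cells_per_gene
  sub <- sub[!low_gene, , drop = FALSE]

  keep_gene_idx <- which(kept_genes)[!low_gene]
  out <- count_matrix(sub,
                      gene_ids = m$gene_ids[keep_gene_idx],
                      gene_names = m$gene_names[keep_gene_idx],
                      barcodes = m$barcodes[!drop_cell],
                      pseudogene_ids = m$gene_ids[m$gene_flags$pseudogene])
  report <- data.frame(
    genes_class_removed = sum(class_remove),
    cells_low_genes = sum(low),
    cells_high_genes = sum(high),
    cells_high_mito = sum(himito),
    cells_removed = sum(drop_cell),
    genes_low_cells = sum(low_gene)
  )
  structure(list(matrix = out, report = report,
                 removed_cells = m$barcodes[drop_cell]),
            class = "qc_result")
}

#' Quantile-normalize expression across cells
#'
#' Classical quantile normalization: each cell's values are replaced by
#' the across-cell mean of the rank-ordered values at each rank, so that
#' after normalization every cell shares one sorted value distribution.
#' Ties within a cell receive the mean of the rank values they span.
#' Computation is delegated to \code{limma::normalizeQuantiles}.
#'
#' @param m A [count_matrix()] or a numeric genes x cells matrix.
#' @return Dense numeric genes x cells matrix of normalized values, with
#'   dimnames preserved.
#' @export
quantile_normalize <- function(m) {
  x <- if (inherits(m, "count_matrix")) as_expr_matrix(m$counts)
       else as_expr_matrix(m)
  if (ncol(x) < 2L)
    stop("quantile normalization is undefined for a single cell",
         call. = FALSE)
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}
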