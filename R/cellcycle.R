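#' Overall cell-cycle score per cell
#'
#' The mean normalized expression over all cell-cycle-associated genes
#' (e.g. a GO cell-cycle list). Genes absent from the matrix are dropped
#' with a warning; an empty intersection is an error.
#'
#' @param expr Normalized genes x cells matrix.
#' @param gene_set Character vector of cell-cycle gene names.
#' @return Named numeric vector, one score per cell.
#' @export
cellcycle_score <- function(expr, gene_set) {
  x <- as_expr_matrix(expr)
  present <- intersect(gene_set, rownames(x))
  if (!length(present))
    stop("none of the cell-cycle genes are present in the matrix: ",
         paste(head(gene_set, 5L), collapse = ", "),
         if (length(gene_set) > 5L) ", ...", call. = FALSE)
  if (length(present) < length(unique(gene_set)))
    warning(length(unique(gene_set)) - length(present),
            " cell-cycle gene(s) absent from the matrix were dropped",
            call. = FALSE)
  colMeans(x[present, , drop = FALSE])
}

#' Per-phase cell-cycle scores
#'
#' For each of the five phases (G1/S, S, G2/M, M, M/G1) the phase score
#' of a cell is the mean normalized expression of that phase's periodic
#' genes.
#'
#' @param expr Normalized genes x cells matrix.
#' @param sets Named list of five gene vectors; names must be exactly
#'   the phases of [phase_names()].
#' @return Numeric cells x 5 matrix of phase scores.
#' @export
phase_scores <- function(expr, sets) {
  if (!setequal(names(sets), phase_names()))
    stop("'sets' must be named exactly ",
         paste(phase_names(), collapse = ", "), call. = FALSE)
  out <- vapply(phase_names(), function(ph) cellcycle_score(expr, sets[[ph]]),
                numeric(ncol(expr)))
  rownames(out) <- colnames(expr)
  out
}

#' Assign each cell a cell-cycle phase by the z > 1 rule
#'
#' Phase scores are standardized across cells (per phase, z =
#' (score - mean) / sd). A cell is classified into the phase of its
#' maximal z among phases with z above `z_threshold`; if no phase
#' exceeds the threshold the cell is not considered to be in the cell
#' cycle (`"none"`). A z exactly equal to the threshold does not count
#' as cycling. A zero-variance phase has its z set to 0 with a warning.
#'
#' @param scores Cells x 5 matrix from [phase_scores()].
#' @param z_threshold Exceedance threshold in standard-deviation units
#'   (default 1).
#' @return A data.frame of class `phase_assignment`: the five z-score
#'   columns (prefixed `z.`) and `label` (factor with levels
#'   `phase_names()` plus `"none"`).
#' @export
assign_phase <- function(scores, z_threshold = 1) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2L)
    stop("z-scores are undefined for fewer than two cells", call. = FALSE)
  if (ncol(scores) != 5L)
    stop("'scores' must have five phase columns", call. = FALSE)
  if (is.null(colnames(scores))) colnames(scores) <- phase_names()
  z <- scale(scores)
  zero_var <- attr(z, "scaled:scale") == 0 | !is.finite(attr(z, "scaled:scale"))
  if (any(zero_var)) {
    warning("zero-variance phase score(s): ",
            paste(colnames(scores)[zero_var], collapse = ", "),
            "; z set to 0", call. = FALSE)
    z[, zero_var] <- 0
  }
  z <- z[, , drop = FALSE]
  best <- max.col(z, ties.method = "first")
  best_z <- z[cbind(seq_len(nrow(z)), best)]
  label <- ifelse(best_z > z_threshold, colnames(scores)[best], "none")
  out <- data.frame(z, check.names = FALSE)
  colnames(out) <- paste0("z.", colnames(scores))
  out$label <- factor(label, levels = c(colnames(scores), "none"))
  rownames(out) <- rownames(scores)
  class(out) <- c("phase_assignment", "data.frame")
  out
}

#' Cell-cycle phase composition per group
#'
#' Fraction of cells in each phase label (including `"none"`) per group
#' of cells (cluster or developmental stage); fractions within a group
#' sum to 1. Groups with no cells are dropped with a warning.
#'
#' @param assignment A [assign_phase()] result (or a label vector).
#' @param groups Group label per cell.
#' @return Numeric groups x labels matrix of fractions.
#' @export
phase_composition <- function(assignment, groups) {
  label <- if (inherits(assignment, "phase_assignment")) assignment$label
           else factor(assignment, levels = c(phase_names(), "none"))
  if (length(label) != length(groups))
    stop("'groups' must align with cells", call. = FALSE)
  if (!is.factor(groups)) groups <- factor(groups)
  empty <- tabulate(groups, nbins = nlevels(groups)) == 0L
  if (any(empty)) {
    warning("empty group(s) dropped: ",
            paste(levels(groups)[empty], collapse = ", "), call. = FALSE)
    groups <- droplevels(groups)
  }
  tab <- table(groups, label)
  prop <- sweep(as.matrix(tab), 1L, rowSums(tab), "/")
  prop
}

#' Phase strip along the cell order
#'
#' Returns the per-cell (order, label) table sorted by order — the strip
#' plot used to inspect whether cycle phases run sequentially along
#' development — together with, per stage, the Spearman rank correlation
#' between the order and the phase ordinal (G1/S = 1 ... M/G1 = 5)
#' among cycling cells. A sequential proliferation regime gives a
#' positive within-stage correlation; randomly ordered phases give a
#' correlation near zero; stages with fewer than two cycling cells (or
#' tied values) report NA.
#'
#' @param assignment A [assign_phase()] result.
#' @param order Named per-cell order in \[0, 1\].
#' @param stages Optional per-cell stage labels (aligned to
#'   `assignment` rows); when omitted all cells form one stage.
#' @return A list of class `phase_strip`: `strip` (data.frame cell,
#'   order, label, stage sorted by order) and `stage_correlation`
#'   (named numeric).
#' @export
phase_strip <- function(assignment, order, stages = NULL) {
  cells <- rownames(assignment)
  order <- order[cells]
  if (anyNA(order)) stop("'order' does not cover all cells", call. = FALSE)
  if (is.null(stages)) stages <- rep("all", length(cells))
  strip <- data.frame(cell = cells, order = unname(order),
                      label = assignment$label, stage = stages,
                      stringsAsFactors = FALSE)
  strip <- strip[base::order(strip$order), ]
  ordinal <- match(as.character(strip$label), phase_names())  # NA for none
  corr <- vapply(unique(stages), function(st) {
    idx <- strip$stage == st & !is.na(ordinal)
    if (sum(idx) < 2L) return(NA_real_)
    suppressWarnings(cor(strip$order[idx], ordinal[idx],
                         method = "spearman"))
  }, numeric(1L))
  structure(list(strip = strip, stage_correlation = corr),
            class = "phase_strip")
}

#' Remove cell-cycle-related genes from an expression matrix
#'
#' Drops the given cell-cycle genes so that the trajectory can be
#' recomputed without them — the control for whether pseudotime and
#' subpopulation structure are driven by cell-cycle transcription.
#'
#' @param expr Normalized genes x cells matrix.
#' @param gene_set Cell-cycle gene names to remove (non-empty; names
#'   absent from the matrix are ignored).
#' @return The matrix without the given genes.
#' @export
strip_cellcycle_genes <- function(expr, gene_set) {
  if (!length(gene_set)) stop("'gene_set' is empty", call. = FALSE)
  x <- as_expr_matrix(expr)
  keep <- !rownames(x) %in% gene_set
  if (!any(keep))
    stop("removing the gene set would empty the matrix", call. = FALSE)
  x[keep, , drop = FALSE]
}

#' Overlap ratio between two cell partitions
#'
#' For each subpopulation of the reference partition, the maximum
#' Jaccard index against the subpopulations of the comparison partition
#' — the statistic used to check that subpopulations persist after
#' cell-cycle gene removal.
#'
#' @param reference,comparison Cluster/stage label vectors over the same
#'   cells.
#' @return Named numeric vector: per reference subpopulation, its best
#'   Jaccard overlap.
#' @export
partition_overlap <- function(reference, comparison) {
  if (length(reference) != length(comparison))
    stop("partitions must cover the same cells", call. = FALSE)
  ref_sets <- split(seq_along(reference), reference)
  cmp_sets <- split(seq_along(comparison), comparison)
  vapply(ref_sets, function(rs) {
    max(vapply(cmp_sets, function(cs)
      length(intersect(rs, cs)) / length(union(rs, cs)), numeric(1L)))
  }, numeric(1L))
}
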