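#' Bundle one species' expression data for cross-species comparison
#'
#' @param species Species name (e.g. `"human"`, `"mouse"`).
#' @param expr Normalized genes x cells matrix; row names are homolog
#'   ids shared across species (see [align_homologs()]).
#' @param stages Per-cell developmental stage labels.
#' @return An object of class `species_expression`.
#' @export
species_expression <- function(species, expr, stages) {
  x <- as_expr_matrix(expr)
  if (anyDuplicated(rownames(x)))
    stop("duplicate homolog ids in '", species, "' matrix", call. = FALSE)
  if (length(stages) != ncol(x))
    stop("'stages' must align with cells", call. = FALSE)
  structure(list(species = species, expr = x,
                 stages = as.character(stages)),
            class = "species_expression")
}

#' Restrict two species' matrices to one-to-one homologs
#'
#' Applies a two-column homolog mapping table to a pair of expression
#' matrices, dropping many-to-many pairs (reported) and renaming rows to
#' a shared homolog id (the first species' gene name).
#'
#' @param a_expr,b_expr Genes x cells matrices with species-native gene
#'   names.
#' @param map Data.frame whose first column holds genes of `a_expr` and
#'   second column genes of `b_expr`.
#' @return List with matrices `a` and `b` on shared homolog row names,
#'   and `dropped` (rows of `map` discarded as many-to-many).
#' @export
align_homologs <- function(a_expr, b_expr, map) {
  a_expr <- as_expr_matrix(a_expr); b_expr <- as_expr_matrix(b_expr)
  map <- map[, 1:2]
  names(map) <- c("a", "b")
  one2one <- !(duplicated(map$a) | duplicated(map$a, fromLast = TRUE) |
               duplicated(map$b) | duplicated(map$b, fromLast = TRUE))
  dropped <- map[!one2one, , drop = FALSE]
  map <- map[one2one & map$a %in% rownames(a_expr) &
               map$b %in% rownames(b_expr), , drop = FALSE]
  a <- a_expr[map$a, , drop = FALSE]
  b <- b_expr[map$b, , drop = FALSE]
  rownames(b) <- map$a
  list(a = a, b = b, dropped = dropped)
}

#' Species-exclusive genes (step 1 of the cross-species comparison)
#'
#' A homolog gene is species-exclusive when it is expressed in one
#' species (detected, count > 0, in strictly more than
#' `expressed_min_cells` cells) but not the other (detected in strictly
#' fewer than `absent_max_cells` cells). Genes absent from one species'
#' annotation are skipped and reported.
#'
#' @param a,b [species_expression()] objects on shared homolog ids.
#' @param expressed_min_cells Detection count above which a gene counts
#'   as expressed (default 20, strict).
#' @param absent_max_cells Detection count below which a gene counts as
#'   not expressed (default 3, strict).
#' @return Data.frame (gene, n_cells_a, n_cells_b, direction) where
#'   direction is `"<species a>-high"` or `"<species b>-high"`;
#'   attribute `skipped` lists genes absent from one annotation.
#' @export
species_exclusive_genes <- function(a, b, expressed_min_cells = 20L,
                                    absent_max_cells = 3L) {
  shared <- intersect(rownames(a$expr), rownames(b$expr))
  skipped <- union(setdiff(rownames(a$expr), shared),
                   setdiff(rownames(b$expr), shared))
  na <- rowSums(a$expr[shared, , drop = FALSE] > 0)
  nb <- rowSums(b$expr[shared, , drop = FALSE] > 0)
  a_only <- na > expressed_min_cells & nb < absent_max_cells
  b_only <- nb > expressed_min_cells & na < absent_max_cells
  flag <- a_only | b_only
  out <- data.frame(gene = shared[flag],
                    n_cells_a = unname(na[flag]),
                    n_cells_b = unname(nb[flag]),
                    direction = ifelse(a_only[flag],
                                       paste0(a$species, "-high"),
                                       paste0(b$species, "-high")),
                    stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

# natural-log fold change of means with pseudocount 1
ln_fc <- function(mean_in, mean_out) log(mean_in + 1) - log(mean_out + 1)

#' Stage marker genes within one species
#'
#' Wilcoxon rank-sum test of each gene in the stage's cells against all
#' other cells; markers must have a natural-log fold change (of
#' pseudocount-1 means) above `fc_threshold` and a mean background
#' (non-stage) expression below `background_max`. Results are ranked by
#' p-value.
#'
#' @param se A [species_expression()] object.
#' @param stage Stage label to test (must have at least `min_cells`
#'   cells; otherwise skipped with a warning and an empty result).
#' @param fc_threshold Natural-log fold-change threshold (default 0.2,
#'   strict).
#' @param background_max Maximum mean expression outside the stage
#'   (default 1, strict).
#' @param min_cells Minimum stage size (default 3).
#' @return Data.frame (gene, ln_fc, background, p) sorted by p.
#' @export
stage_marker_genes <- function(se, stage, fc_threshold = 0.2,
                               background_max = 1, min_cells = 3L) {
  if (length(unique(se$stages)) < 2L)
    stop("marker detection needs at least two stages", call. = FALSE)
  in_stage <- se$stages == stage
  empty <- data.frame(gene = character(), ln_fc = numeric(),
                      background = numeric(), p = numeric())
  if (sum(in_stage) < min_cells) {
    warning("stage '", stage, "' has fewer than ", min_cells,
            " cells; skipped", call. = FALSE)
    return(empty)
  }
  x <- se$expr
  m_in <- rowMeans(x[, in_stage, drop = FALSE])
  m_out <- rowMeans(x[, !in_stage, drop = FALSE])
  fc <- ln_fc(m_in, m_out)
  cand <- which(fc > fc_threshold & m_out < background_max)
  if (!length(cand)) return(empty)
  p <- vapply(cand, function(gi)
    suppressWarnings(wilcox.test(x[gi, in_stage], x[gi, !in_stage],
                                 alternative = "greater")$p.value),
    numeric(1L))
  out <- data.frame(gene = rownames(x)[cand], ln_fc = fc[cand],
                    background = m_out[cand], p = p,
                    stringsAsFactors = FALSE)
  out <- out[base::order(out$p, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Combine two species' marker lists with a size cap
#'
#' Union of the per-stage marker lists of both species; when the
#' combined list exceeds `cap` genes, only the top `cap` most
#' significant (smallest p across species) are kept.
#'
#' @param a_markers,b_markers [stage_marker_genes()] results.
#' @param cap Maximum combined list size (default 400).
#' @return Character vector of marker genes.
#' @export
combine_marker_lists <- function(a_markers, b_markers, cap = 400L) {
  all <- rbind(a_markers[, c("gene", "p")], b_markers[, c("gene", "p")])
  if (!nrow(all)) return(character())
  best <- tapply(all$p, all$gene, min)
  genes <- names(base::sort(best))
  head(genes, cap)
}

#' Per-stage cross-species differential genes (step 2)
#'
#' Within one developmental stage, each combined marker gene is tested
#' for a cross-species expression shift: the natural-log fold change of
#' the stage-mean expression between species must exceed `fc_threshold`
#' in absolute value (strict).
#'
#' @param a,b [species_expression()] objects on shared homolog ids.
#' @param marker_union Genes to test (see [combine_marker_lists()]).
#' @param stage Stage label.
#' @param fc_threshold Natural-log fold-change threshold (default 0.25).
#' @return Data.frame (gene, stage, ln_fc, direction).
#' @export
cross_stage_de <- function(a, b, marker_union, stage,
                           fc_threshold = 0.25) {
  genes <- intersect(marker_union, intersect(rownames(a$expr),
                                             rownames(b$expr)))
  a_idx <- a$stages == stage
  b_idx <- b$stages == stage
  if (!any(a_idx) || !any(b_idx) || !length(genes))
    return(data.frame(gene = character(), stage = character(),
                      ln_fc = numeric(), direction = character()))
  m_a <- rowMeans(a$expr[genes, a_idx, drop = FALSE])
  m_b <- rowMeans(b$expr[genes, b_idx, drop = FALSE])
  fc <- ln_fc(m_a, m_b)
  flag <- abs(fc) > fc_threshold
  data.frame(gene = genes[flag], stage = rep(stage, sum(flag)),
             ln_fc = unname(fc[flag]),
             direction = ifelse(fc[flag] > 0,
                                paste0(a$species, "-high"),
                                paste0(b$species, "-high")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Two-step cross-species differential expression
#'
#' Runs the full comparison: (1) species-exclusive genes
#' ([species_exclusive_genes()]); (2) per developmental stage, combined
#' species marker genes ([stage_marker_genes()],
#' [combine_marker_lists()]) tested for a cross-species fold change
#' ([cross_stage_de()]). Genes flagged by either step form the
#' differential set.
#'
#' @param a,b [species_expression()] objects on shared homolog ids with
#'   identical stage vocabularies.
#' @param stages Stages to test (default: all shared stage labels).
#' @param exclusive_params,marker_params,de_params Named lists of
#'   threshold overrides for the three steps.
#' @return A list of class `cross_species_de`: `set1` (exclusive),
#'   `set2` (per-stage differential), `union` (gene, direction),
#'   `params`.
#' @export
cross_species_de <- function(a, b, stages = NULL,
                             exclusive_params = list(),
                             marker_params = list(),
                             de_params = list()) {
  if (is.null(stages)) stages <- intersect(unique(a$stages),
                                           unique(b$stages))
  set1 <- do.call(species_exclusive_genes,
                  c(list(a = a, b = b), exclusive_params))
  set2 <- do.call(rbind, lapply(stages, function(st) {
    am <- do.call(stage_marker_genes,
                  c(list(se = a, stage = st), marker_params))
    bm <- do.call(stage_marker_genes,
                  c(list(se = b, stage = st), marker_params))
    mu <- combine_marker_lists(am, bm)
    do.call(cross_stage_de,
            c(list(a = a, b = b, marker_union = mu, stage = st), de_params))
  }))
  uni <- rbind(data.frame(gene = set1$gene, direction = set1$direction,
                          stringsAsFactors = FALSE),
               data.frame(gene = set2$gene, direction = set2$direction,
                          stringsAsFactors = FALSE))
  uni <- uni[!duplicated(uni$gene), , drop = FALSE]
  rownames(uni) <- NULL
  structure(list(set1 = set1, set2 = set2, union = uni,
                 params = list(exclusive = exclusive_params,
                               marker = marker_params, de = de_params)),
            class = "cross_species_de")
}

#' Driver-TF enrichment among cross-species differential genes
#'
#' For each transcription factor, a one-sided Fisher exact test of the
#' overlap between its target gene set and the cross-species
#' differential genes within a gene universe (2x2 table: target vs
#' non-target, differential vs not). P-values are BH-adjusted across
#' TFs. TFs whose target set is empty after intersection with the
#' universe are skipped.
#'
#' @param de_genes Character vector of differential genes.
#' @param tf_targets Named list of target gene sets per TF.
#' @param universe Character vector of all tested genes (must contain
#'   the differential genes).
#' @return Data.frame of class `driver_tf_result`: tf, n_targets,
#'   overlap, odds_ratio (sample estimate), p (one-sided), q (BH).
#' @export
driver_tf_enrichment <- function(de_genes, tf_targets, universe) {
  universe <- unique(universe)
  de_genes <- intersect(unique(de_genes), universe)
  if (!length(de_genes))
    stop("no differential genes inside the universe", call. = FALSE)
  rows <- lapply(names(tf_targets), function(tf) {
    targets <- intersect(unique(tf_targets[[tf]]), universe)
    if (!length(targets)) return(NULL)
    a11 <- length(intersect(targets, de_genes))
    a12 <- length(targets) - a11
    a21 <- length(de_genes) - a11
    a22 <- length(universe) - a11 - a12 - a21
    tab <- matrix(c(a11, a21, a12, a22), 2L)
    p <- fisher.test(tab, alternative = "greater")$p.value
    or <- if (a11 == 0) 0
          else if (a12 == 0 || a21 == 0) Inf
          else (a11 * a22) / (a12 * a21)
    data.frame(tf = tf, n_targets = length(targets), overlap = a11,
               odds_ratio = or, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop("no TF has targets inside the universe", call. = FALSE)
  out$q <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  class(out) <- c("driver_tf_result", "data.frame")
  out
}

#' Bulk RNA-seq cross-species differential test
#'
#' Depth-normalizes both species' bulk count matrices to counts per
#' million, runs a per-gene two-sample Welch t-test on the CPM values,
#' and flags genes with |log2 fold change| > `lfc_threshold` and
#' p < `p_threshold` (both strict) as significantly differential.
#'
#' @param a_bulk,b_bulk Genes x replicates count matrices on shared
#'   homolog row names (at least two replicates each).
#' @param lfc_threshold log2 fold-change threshold (default 1).
#' @param p_threshold p-value threshold (default 0.01).
#' @return Data.frame (gene, log2_fc, p, significant).
#' @export
bulk_de <- function(a_bulk, b_bulk, lfc_threshold = 1,
                    p_threshold = 0.01) {
  a_bulk <- as_expr_matrix(a_bulk); b_bulk <- as_expr_matrix(b_bulk)
  if (ncol(a_bulk) < 2L || ncol(b_bulk) < 2L)
    stop("the t-test needs at least two replicates per species",
         call. = FALSE)
  shared <- intersect(rownames(a_bulk), rownames(b_bulk))
  if (!length(shared)) stop("no shared genes", call. = FALSE)
  cpm <- function(m) sweep(m, 2L, colSums(m), "/") * 1e6
  ca <- cpm(a_bulk)[shared, , drop = FALSE]
  cb <- cpm(b_bulk)[shared, , drop = FALSE]
  lfc <- log2(rowMeans(ca) + 1) - log2(rowMeans(cb) + 1)
  p <- vapply(seq_along(shared), function(gi) {
    va <- ca[gi, ]; vb <- cb[gi, ]
    if (sd(va) == 0 && sd(vb) == 0) return(1)
    tryCatch(t.test(va, vb)$p.value, error = function(e) 1)
  }, numeric(1L))
  data.frame(gene = shared, log2_fc = unname(lfc), p = p,
             significant = abs(lfc) > lfc_threshold & p < p_threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}
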