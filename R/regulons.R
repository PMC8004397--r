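#' Binarize a TF enrichment matrix and filter ubiquitous/rare TFs
#'
#' Post-processing of a SCENIC-style regulon enrichment score matrix
#' (cells x TFs, e.g. AUCell output). Scores below a TF's binarization
#' threshold are set to 0; a cell is "assigned" to a TF when its score
#' is at or above the threshold. TFs assigned in fewer than 10% or more
#' than 90% of cells (strict inequalities) are removed — too rare to be
#' informative or too ubiquitous to be stage-specific.
#'
#' @param scores Cells x TFs numeric matrix of enrichment scores.
#' @param thresholds Named per-TF thresholds (SCENIC exports these).
#'   When `NULL`, a fallback global threshold is used: the
#'   `fallback_quantile` quantile of all nonzero scores.
#' @param min_fraction,max_fraction Assigned-cell fraction bounds
#'   (defaults 0.10 and 0.90).
#' @param fallback_quantile Quantile for the fallback threshold
#'   (default 0.05).
#' @return A list of class `tf_filter_result`: `scores` (thresholded
#'   matrix restricted to kept TFs), `assigned_fraction` (all TFs),
#'   `kept`, `dropped`, `thresholds`.
#' @export
binarize_and_filter_tfs <- function(scores, thresholds = NULL,
                                    min_fraction = 0.10,
                                    max_fraction = 0.90,
                                    fallback_quantile = 0.05) {
  scores <- as.matrix(scores)
  tfs <- colnames(scores)
  if (is.null(tfs)) stop("'scores' must have TF column names",
                         call. = FALSE)
  if (is.null(thresholds)) {
    nz <- scores[scores > 0]
    if (!length(nz)) stop("all scores are zero", call. = FALSE)
    thresholds <- setNames(rep(quantile(nz, fallback_quantile), length(tfs)),
                           tfs)
  }
  if (anyNA(thresholds[tfs]))
    stop("missing threshold for TF(s): ",
         paste(setdiff(tfs, names(thresholds)), collapse = ", "),
         call. = FALSE)
  thr <- thresholds[tfs]
  assigned <- sweep(scores, 2L, thr, ">=")
  frac <- colMeans(assigned)
  keep <- frac >= min_fraction & frac <= max_fraction
  filtered <- scores
  filtered[!assigned] <- 0
  structure(list(scores = filtered[, keep, drop = FALSE],
                 assigned_fraction = frac,
                 kept = tfs[keep], dropped = tfs[!keep],
                 thresholds = thr),
            class = "tf_filter_result")
}

#' Stage-specific transcription factors
#'
#' Per TF, the mean enrichment score of each cell subgroup (cluster or
#' developmental stage) is computed; TFs whose largest between-subgroup
#' difference (max mean - min mean) exceeds `min_difference` are
#' retained and each is assigned to its argmax subgroup.
#'
#' @param scores Cells x TFs matrix (typically the filtered scores from
#'   [binarize_and_filter_tfs()]).
#' @param clusters Subgroup label per cell (at least two subgroups).
#' @param min_difference Retention threshold on the between-subgroup
#'   spread (default 0.4, strict).
#' @return Data.frame (tf, stage, difference) of retained TFs, with the
#'   full subgroup-mean matrix as attribute `cluster_means`.
#' @export
stage_specific_tfs <- function(scores, clusters, min_difference = 0.4) {
  scores <- as.matrix(scores)
  clusters <- factor(clusters)
  if (length(clusters) != nrow(scores))
    stop("'clusters' must align with the score matrix rows", call. = FALSE)
  if (nlevels(clusters) < 2L)
    stop("between-subgroup differences need at least two subgroups",
         call. = FALSE)
  means <- apply(scores, 2L, function(col) tapply(col, clusters, mean))
  diffs <- apply(means, 2L, function(m) max(m) - min(m))
  peak <- rownames(means)[apply(means, 2L, which.max)]
  keep <- diffs > min_difference
  out <- data.frame(tf = colnames(scores)[keep], stage = peak[keep],
                    difference = unname(diffs[keep]),
                    stringsAsFactors = FALSE)
  attr(out, "cluster_means") <- means
  out
}

#' Filter TF-target links by expression correlation and assign stages
#'
#' Retains candidate regulatory links whose TF and target gene
#' expression correlate (Pearson, strictly above `min_correlation`)
#' across cells, and assigns each retained link to a developmental
#' stage: the target gene's (or, optionally, the TF's) expression is
#' smoothed along the cell order ([bin_and_smooth()]) and the link is
#' labeled with the stage most common among the cells of the
#' peak-expression bin. Zero-variance genes have undefined correlation
#' and are dropped with a warning.
#'
#' @param links Data.frame with columns `tf` and `gene` (candidate
#'   regulon links, e.g. SCENIC TF-target pairs).
#' @param expr Normalized genes x cells matrix containing both TFs and
#'   target genes.
#' @param order Per-cell order in \[0, 1\] (named).
#' @param stages Per-cell stage labels (named or aligned to columns).
#' @param min_correlation Retention threshold (default 0.4, strict).
#' @param assign_by `"gene"` (default) or `"tf"`: whose expression peak
#'   determines the stage label.
#' @param n_bins,poly_degree Passed to [bin_and_smooth()].
#' @return Data.frame of class `regulon_links`: tf, gene, correlation,
#'   stage.
#' @export
filter_links_by_correlation <- function(links, expr, order, stages,
                                        min_correlation = 0.4,
                                        assign_by = c("gene", "tf"),
                                        n_bins = 100L, poly_degree = 10L) {
  assign_by <- match.arg(assign_by)
  x <- as_expr_matrix(expr)
  if (!all(c("tf", "gene") %in% names(links)))
    stop("'links' needs columns 'tf' and 'gene'", call. = FALSE)
  if (!is.null(names(order))) order <- order[colnames(x)]
  if (!is.null(names(stages))) stages <- stages[colnames(x)]

  present <- links$tf %in% rownames(x) & links$gene %in% rownames(x)
  if (any(!present))
    warning(sum(!present), " link(s) with TF or gene absent from the ",
            "matrix were skipped", call. = FALSE)
  links <- links[present, , drop = FALSE]

  corr <- vapply(seq_len(nrow(links)), function(i) {
    tf_e <- x[links$tf[i], ]
    g_e <- x[links$gene[i], ]
    if (sd(tf_e) == 0 || sd(g_e) == 0) return(NA_real_)
    cor(tf_e, g_e)
  }, numeric(1L))
  if (anyNA(corr))
    warning(sum(is.na(corr)),
            " link(s) with zero-variance expression were dropped",
            call. = FALSE)
  keep <- !is.na(corr) & corr > min_correlation
  links <- links[keep, , drop = FALSE]
  corr <- corr[keep]
  if (!nrow(links))
    return(structure(data.frame(tf = character(), gene = character(),
                                correlation = numeric(),
                                stage = character()),
                     class = c("regulon_links", "data.frame")))

  # stage of each bin = most common stage among its cells
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  bin <- findInterval(order, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  bin_stage <- rep(NA_character_, n_bins)
  for (bi in seq_len(n_bins)) {
    s <- stages[bin == bi]
    if (length(s)) bin_stage[bi] <- names(which.max(table(s)))
  }
  if (anyNA(bin_stage)) {     # empty bins inherit the nearest labeled bin
    lab <- which(!is.na(bin_stage))
    for (bi in which(is.na(bin_stage)))
      bin_stage[bi] <- bin_stage[lab[which.min(abs(lab - bi))]]
  }
  key_genes <- if (assign_by == "gene") links$gene else links$tf
  prof <- bin_and_smooth(x[unique(key_genes), , drop = FALSE], order,
                         n_bins = n_bins, poly_degree = poly_degree)
  peak_bin <- apply(prof$fitted, 1L, which.max)
  out <- data.frame(tf = links$tf, gene = links$gene, correlation = corr,
                    stage = bin_stage[peak_bin[key_genes]],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("regulon_links", "data.frame")
  out
}
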