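#' Co-clustering consistency across a grid of clustering settings
#'
#' Given cluster labels of the same cells under several clustering
#' settings (e.g. the 5 resolutions x 5 neighbor counts grid), the
#' consistency of a cell pair is the fraction of settings in which the
#' two cells share a cluster. The clustering engine is deliberately
#' pluggable: any label table works.
#'
#' @param labels Cells x settings matrix (or data.frame) of cluster ids;
#'   rows are cells, columns are settings. Row/column names are kept.
#' @return A list of class `consistency_matrix`: `consistency` (cells x
#'   cells symmetric matrix of fractions, diagonal 1), `counts` (raw
#'   co-occurrence counts), `n_settings`.
#' @export
pairwise_consistency <- function(labels) {
  labels <- as.matrix(labels)
  if (ncol(labels) < 2L)
    stop("at least two settings are required", call. = FALSE)
  if (anyNA(labels)) {
    idx <- which(is.na(labels), arr.ind = TRUE)[1L, ]
    cellname <- if (!is.null(rownames(labels))) rownames(labels)[idx[1L]]
                else idx[1L]
    setting <- if (!is.null(colnames(labels))) colnames(labels)[idx[2L]]
               else idx[2L]
    stop(sprintf("missing cluster label for cell '%s' in setting '%s'",
                 cellname, setting), call. = FALSE)
  }
  n <- nrow(labels)
  counts <- matrix(0L, n, n, dimnames = list(rownames(labels),
                                             rownames(labels)))
  for (s in seq_len(ncol(labels))) {
    ind <- outer(labels[, s], labels[, s], "==")
    counts <- counts + ind
  }
  structure(list(consistency = counts / ncol(labels), counts = counts,
                 n_settings = ncol(labels)),
            class = "consistency_matrix")
}

#' Summarize co-clustering consistency against a reference partition
#'
#' Per reference cluster, the mean pairwise consistency among its cells
#' (within) and between its cells and all others (between), plus
#' pair-count-weighted overall means. High within and low between
#' consistency indicate that the reference clusters are robust to the
#' clustering settings.
#'
#' @param cm A [pairwise_consistency()] result.
#' @param reference_labels Cluster label per cell (aligned to the
#'   consistency matrix).
#' @return A list of class `consistency_summary`: `per_cluster`
#'   (data.frame cluster, n_cells, within, between; within is NA for
#'   singletons) and `overall` (within, between).
#' @export
summarize_consistency <- function(cm, reference_labels) {
  C <- cm$consistency
  n <- nrow(C)
  if (length(reference_labels) != n)
    stop("'reference_labels' must align with the consistency matrix",
         call. = FALSE)
  ref <- factor(reference_labels)
  per <- lapply(levels(ref), function(cl) {
    idx <- which(ref == cl)
    within <- if (length(idx) < 2L) NA_real_ else {
      block <- C[idx, idx, drop = FALSE]
      mean(block[upper.tri(block)])
    }
    between <- if (length(idx) == n) NA_real_ else
      mean(C[idx, -idx, drop = FALSE])
    data.frame(cluster = cl, n_cells = length(idx),
               within = within, between = between,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  w_pairs <- choose(per$n_cells, 2L)
  b_pairs <- per$n_cells * (n - per$n_cells)
  overall <- c(
    within = if (any(w_pairs > 0))
      sum(per$within * w_pairs, na.rm = TRUE) / sum(w_pairs) else NA_real_,
    between = if (any(b_pairs > 0))
      sum(per$between * b_pairs, na.rm = TRUE) / sum(b_pairs) else NA_real_
  )
  structure(list(per_cluster = per, overall = overall),
            class = "consistency_summary")
}
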