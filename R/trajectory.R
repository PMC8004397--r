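#' Build a k-nearest-neighbor graph of cells
#'
#' Cells are embedded by PCA of the log-transformed (`log1p`) normalized
#' expression; Euclidean k-nearest neighbors are computed in the top
#' principal components and symmetrized by edge union (an edge exists if
#' either endpoint lists the other among its k neighbors). Only the
#' largest connected component is retained; dropped cells are reported.
#'
#' @param expr Normalized genes x cells matrix (see
#'   [quantile_normalize()]).
#' @param k Number of neighbors per cell (default 20).
#' @param n_pcs Number of principal components for the embedding
#'   (default 20); must not exceed the matrix rank.
#' @return An object of class `knn_graph`: `adjacency` (binary symmetric
#'   sparse matrix over retained cells), `cells` (retained barcodes),
#'   `dropped` (barcodes outside the largest component), `k`, `n_pcs`.
#' @export
build_knn_graph <- function(expr, k = 20L, n_pcs = 20L) {
  x <- as_expr_matrix(expr)
  n_cells <- ncol(x)
  if (k <= 0) stop("'k' must be positive", call. = FALSE)
  if (k >= n_cells) stop("'k' must be below the number of cells",
                         call. = FALSE)
  max_rank <- min(n_cells - 1L, nrow(x))
  if (n_pcs > max_rank)
    stop(sprintf("n_pcs = %d exceeds the matrix rank bound %d",
                 n_pcs, max_rank), call. = FALSE)
  emb <- t(log1p(x))
  pcs <- prcomp(emb, center = TRUE, scale. = FALSE, rank. = n_pcs)$x
  d <- as.matrix(stats::dist(pcs))
  diag(d) <- Inf
  nn <- apply(d, 1L, function(row) order(row)[seq_len(k)])
  i <- rep(seq_len(n_cells), each = k)
  j <- as.vector(nn)
  adj <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                              dims = c(n_cells, n_cells))
  adj@x[] <- 1                                  # union, binary weights
  barcodes <- colnames(x)
  if (is.null(barcodes)) barcodes <- sprintf("cell%05d", seq_len(n_cells))
  dimnames(adj) <- list(barcodes, barcodes)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  keep <- comp$membership == which.max(comp$csize)
  structure(list(adjacency = adj[keep, keep, drop = FALSE],
                 cells = barcodes[keep],
                 dropped = barcodes[!keep],
                 k = as.integer(k), n_pcs = as.integer(n_pcs)),
            class = "knn_graph")
}

#' @export
print.knn_graph <- function(x, ...) {
  cat(sprintf("knn_graph: %d cells (k = %d, %d PCs), %d dropped\n",
              length(x$cells), x$k, x$n_pcs, length(x$dropped)))
  invisible(x)
}

#' Construct the PBA source/sink rate vector R
#'
#' Population balance analysis models development at steady state, where
#' per-cell net rates R sum to zero. Per sink group (e.g. the CD4sp and
#' CD8sp fates), cells are scored by the mean normalized expression of
#' that group's marker genes, and the top `n_sinks` cells receive
#' R = -1; all remaining cells share a uniform positive rate chosen to
#' enforce `sum(R) = 0`. Ties in the marker score are broken by barcode
#' so the sink choice is deterministic; cells claimed by more than one
#' group are kept by the group that ranks them first (with a warning).
#'
#' @param expr Normalized genes x cells matrix.
#' @param sink_marker_genes Named list: one character vector of marker
#'   genes per sink group.
#' @param n_sinks Sinks per group (default 10).
#' @param cells Optional barcode subset (e.g. a graph's retained cells).
#' @return An object of class `source_sink_spec`: `R` (named rate
#'   vector), `sink_cells` (barcodes), `sink_groups` (group label per
#'   sink cell).
#' @export
construct_R <- function(expr, sink_marker_genes, n_sinks = 10L,
                        cells = colnames(expr)) {
  x <- as_expr_matrix(expr)[, cells, drop = FALSE]
  if (is.null(names(sink_marker_genes)) || length(sink_marker_genes) < 1L)
    stop("'sink_marker_genes' must be a named list of gene vectors",
         call. = FALSE)
  n <- ncol(x)
  sink_cells <- character()
  sink_groups <- character()
  for (grp in names(sink_marker_genes)) {
    genes <- intersect(sink_marker_genes[[grp]], rownames(x))
    if (!length(genes))
      stop("no marker genes of sink group '", grp, "' present in matrix",
           call. = FALSE)
    score <- Matrix::colMeans(x[genes, , drop = FALSE])
    ranked <- cells[order(-score, cells)]
    if (any(head(ranked, n_sinks) %in% sink_cells))
      warning("sink group '", grp,
              "' overlapped a previous group's top cells; ",
              "next-ranked cells used", call. = FALSE)
    chosen <- head(setdiff(ranked, sink_cells), n_sinks)
    sink_cells <- c(sink_cells, chosen)
    sink_groups <- c(sink_groups, rep(grp, length(chosen)))
  }
  n_sink_total <- length(sink_cells)
  if (n_sink_total >= n)
    stop("all cells would become sinks", call. = FALSE)
  R <- setNames(rep(n_sink_total / (n - n_sink_total), n), cells)
  R[sink_cells] <- -1
  structure(list(R = R, sink_cells = sink_cells,
                 sink_groups = setNames(sink_groups, sink_cells)),
            class = "source_sink_spec")
}

#' Solve the PBA potential on the cell graph
#'
#' The developmental potential V solves the graph-Laplacian system
#' `L V = R`, where `L = D - A` is the combinatorial Laplacian of the
#' kNN graph and R the source/sink rate vector. Since L is singular with
#' null space spanned by the constant vector and `sum(R) = 0`, the
#' system is solved by grounding one node and the result is shifted so
#' `min(V) = 0`. V is large at the undifferentiated source and zero at
#' the deepest sink, playing the role of a pseudotime measured from the
#' mature end.
#'
#' @param g A [build_knn_graph()] object (must be connected on the cells
#'   of `s`).
#' @param s A [construct_R()] specification.
#' @param tol Tolerance on `sum(R)` (default 1e-8).
#' @return An object of class `pba_potential`: `V` (named, min 0) and
#'   `residual` (max abs of `L V - R`).
#' @export
solve_potential <- function(g, s, tol = 1e-8) {
  if (!inherits(g, "knn_graph")) stop("'g' must be a knn_graph",
                                      call. = FALSE)
  R <- s$R[g$cells]
  if (anyNA(R))
    stop("rate vector does not cover all graph cells", call. = FALSE)
  if (abs(sum(R)) > tol)
    stop(sprintf("sum(R) = %.3g violates the steady-state condition",
                 sum(R)), call. = FALSE)
  A <- g$adjacency
  gg <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  comp <- igraph::components(gg)
  if (comp$no > 1L)
    stop("graph is disconnected (component sizes: ",
         paste(comp$csize, collapse = ", "), ")", call. = FALSE)
  n <- nrow(A)
  L <- Matrix::Diagonal(x = Matrix::rowSums(A)) - A
  V <- numeric(n)
  if (n > 1L)
    V[-1L] <- as.vector(Matrix::solve(L[-1L, -1L, drop = FALSE], R[-1L]))
  V <- V - min(V)
  names(V) <- g$cells
  residual <- max(abs(as.vector(L %*% V) - R))
  structure(list(V = V, residual = residual), class = "pba_potential")
}

#' Fate probabilities by an absorbing descending random walk
#'
#' A random walk on the kNN graph restricted to edges oriented toward
#' strictly lower potential V, with uniform transitions over admissible
#' neighbors and the sink cells absorbing (labeled by sink group).
#' Absorption probabilities are solved exactly from the linear system of
#' the absorbing chain. A non-sink cell with no descending neighbor is
#' assigned probability 1 for its nearest sink group by unweighted graph
#' distance and flagged.
#'
#' @param g A [build_knn_graph()] object.
#' @param s A [construct_R()] specification.
#' @param V The potential from [solve_potential()] (object or named
#'   vector).
#' @return Matrix cells x sink groups of absorption probabilities (rows
#'   sum to 1), with attribute `dead_end_cells` listing flagged cells.
#' @export
compute_fate_probabilities <- function(g, s, V) {
  if (inherits(V, "pba_potential")) V <- V$V
  V <- V[g$cells]
  groups <- unique(unname(s$sink_groups))
  if (length(groups) < 2L)
    stop("at least two sink groups are required", call. = FALSE)
  n <- length(g$cells)
  A <- g$adjacency
  is_sink <- g$cells %in% s$sink_cells
  sink_grp <- s$sink_groups[g$cells[is_sink]]

  # descending neighbor lists from the triplet representation
  At <- as(A, "TsparseMatrix")
  nb_all <- split(At@j + 1L, factor(At@i + 1L, levels = seq_len(n)))
  adj_idx <- lapply(seq_len(n), function(i) {
    nb <- nb_all[[i]]
    nb[V[nb] < V[i]]
  })
  dead_end <- !is_sink & vapply(adj_idx, length, 1L) == 0L

  probs <- matrix(0, n, length(groups),
                  dimnames = list(g$cells, groups))
  probs[cbind(which(is_sink), match(sink_grp, groups))] <- 1

  if (any(dead_end)) {
    gg <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    dmat <- igraph::distances(gg, v = which(dead_end), to = which(is_sink))
    nearest <- apply(dmat, 1L, which.min)
    probs[cbind(which(dead_end),
                match(sink_grp[nearest], groups))] <- 1
  }

  transient <- which(!is_sink & !dead_end)
  if (length(transient)) {
    absorbing <- which(is_sink | dead_end)
    tmap <- match(seq_len(n), transient)
    nt <- length(transient)
    trips <- vector("list", nt)
    Sstep <- matrix(0, nt, length(groups))
    for (ti in seq_len(nt)) {
      i <- transient[ti]
      nb <- adj_idx[[i]]
      p <- 1 / length(nb)
      to_t <- nb[!is.na(tmap[nb])]
      to_a <- nb[is.na(tmap[nb])]
      if (length(to_t))
        trips[[ti]] <- cbind(ti, tmap[to_t], p)
      if (length(to_a))
        Sstep[ti, ] <- p * colSums(probs[to_a, , drop = FALSE])
    }
    trips <- do.call(rbind, trips)
    Q <- if (is.null(trips))
      Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                           dims = c(nt, nt))
    else
      Matrix::sparseMatrix(i = trips[, 1L], j = trips[, 2L],
                           x = trips[, 3L], dims = c(nt, nt))
    B <- as.matrix(Matrix::solve(Matrix::Diagonal(nt) - Q, Sstep))
    probs[transient, ] <- B
  }
  attr(probs, "dead_end_cells") <- g$cells[dead_end]
  probs
}

#' Scale the potential to a cell order in [0, 1]
#'
#' Cells are ranked by decreasing potential (the earliest source first,
#' the deepest sink last) and the ranks mapped linearly onto \[0, 1\];
#' ties share their mean rank. The order is invariant to any positive
#' rescaling of the rate vector R.
#'
#' @param V Potential (object from [solve_potential()] or named vector).
#' @return Named numeric vector of orders in \[0, 1\].
#' @export
scale_cell_order <- function(V) {
  if (inherits(V, "pba_potential")) V <- V$V
  if (any(!is.finite(V))) stop("'V' must be finite", call. = FALSE)
  n <- length(V)
  if (n == 1L) return(setNames(0.5, names(V)))
  (rank(-V, ties.method = "average") - 1) / (n - 1)
}

#' Bin expression along the cell order and fit a smooth profile
#'
#' Cells are partitioned into `n_bins` equal-width bins of the order
#' axis; per-gene bin means are computed (empty bins filled by linear
#' interpolation between neighboring bins and flagged) and a
#' least-squares polynomial of degree `poly_degree` is fitted over the
#' bin centers.
#'
#' @param expr Normalized genes x cells matrix.
#' @param order Per-cell order in \[0, 1\] (named, aligned to columns).
#' @param n_bins Number of bins (default 100).
#' @param poly_degree Polynomial degree (default 10).
#' @return A list of class `binned_profiles`: `bin_centers`, `bin_means`
#'   and `fitted` (genes x bins matrices), `empty_bins` (indices filled
#'   by interpolation).
#' @export
bin_and_smooth <- function(expr, order, n_bins = 100L, poly_degree = 10L) {
  x <- as_expr_matrix(expr)
  order <- order[colnames(x)]
  if (anyNA(order)) stop("'order' does not cover all cells", call. = FALSE)
  if (any(order < 0 | order > 1))
    stop("'order' must lie in [0, 1]", call. = FALSE)
  if (poly_degree >= n_bins)
    stop("'poly_degree' must be below 'n_bins'", call. = FALSE)
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  bin <- findInterval(order, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  centers <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  bin_means <- matrix(NA_real_, nrow(x), n_bins,
                      dimnames = list(rownames(x), NULL))
  for (bi in seq_len(n_bins)) {
    idx <- which(bin == bi)
    if (length(idx))
      bin_means[, bi] <- rowMeans(x[, idx, drop = FALSE])
  }
  empty <- which(is.na(bin_means[1L, ]))
  if (length(empty)) {
    filled <- setdiff(seq_len(n_bins), empty)
    for (gi in seq_len(nrow(bin_means)))
      bin_means[gi, empty] <- approx(centers[filled],
                                     bin_means[gi, filled],
                                     xout = centers[empty],
                                     rule = 2)$y
  }
  basis <- cbind(1, stats::poly(centers, degree = poly_degree))
  qrb <- qr(basis)
  fitted <- t(basis %*% qr.coef(qrb, t(bin_means)))
  dimnames(fitted) <- dimnames(bin_means)
  structure(list(bin_centers = centers, bin_means = bin_means,
                 fitted = fitted, empty_bins = empty),
            class = "binned_profiles")
}

#' Run the full PBA trajectory pipeline
#'
#' Convenience wrapper: builds the kNN graph, constructs the rate vector
#' from terminal-fate marker genes, solves the potential, computes fate
#' probabilities and the scaled cell order.
#'
#' @inheritParams build_knn_graph
#' @inheritParams construct_R
#' @return A list of class `pba_result`: `graph`, `spec`, `V`,
#'   `residual`, `order`, `fate_probs`.
#' @export
pba_trajectory <- function(expr, sink_marker_genes, k = 20L, n_pcs = 20L,
                           n_sinks = 10L) {
  g <- build_knn_graph(expr, k = k, n_pcs = n_pcs)
  s <- construct_R(expr, sink_marker_genes, n_sinks = n_sinks,
                   cells = g$cells)
  pot <- solve_potential(g, s)
  structure(list(graph = g, spec = s, V = pot$V,
                 residual = pot$residual,
                 order = scale_cell_order(pot$V),
                 fate_probs = compute_fate_probabilities(g, s, pot)),
            class = "pba_result")
}
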