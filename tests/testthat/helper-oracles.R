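# Independent brute-force oracles used to check the implementation.

# Quantile normalization by explicit sort-and-average, no tie handling
# (callers use tie-free inputs).
brute_quantile_normalize <- function(x) {
  sorted <- apply(x, 2L, sort)
  target <- rowMeans(sorted)
  apply(x, 2L, function(col) target[rank(col, ties.method = "first")])
}

# PBA potential by dense Moore-Penrose pseudoinverse of the Laplacian.
brute_potential <- function(adjacency, R) {
  A <- as.matrix(adjacency)
  L <- diag(rowSums(A)) - A
  V <- as.vector(MASS::ginv(L) %*% R)
  V - min(V)
}

# All sliding-window means by explicit enumeration.
brute_window_means <- function(x, n_window) {
  n <- length(x)
  vapply(seq_len(n - n_window + 1L), function(s)
    mean(x[s:(s + n_window - 1L)]), numeric(1L))
}

# One-sided (over-representation) Fisher p by hypergeometric enumeration.
brute_fisher_greater <- function(overlap, n_targets, n_de, n_universe) {
  ks <- overlap:min(n_targets, n_de)
  sum(stats::dhyper(ks, n_de, n_universe - n_de, n_targets))
}

# Random connected undirected graph (retries until connected).
random_connected_graph <- function(n, p = 0.15) {
  repeat {
    A <- matrix(stats::rbinom(n * n, 1L, p), n, n)
    A[lower.tri(A, diag = TRUE)] <- 0
    A <- A + t(A)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    if (igraph::is_connected(g)) return(A)
  }
}

# knn_graph object from an explicit adjacency matrix (for solver tests).
graph_from_adjacency <- function(A, cells = sprintf("c%03d", seq_len(nrow(A)))) {
  adj <- methods::as(methods::as(Matrix::Matrix(A, sparse = TRUE),
                                 "generalMatrix"), "CsparseMatrix")
  dimnames(adj) <- list(cells, cells)
  structure(list(adjacency = adj, cells = cells, dropped = character(),
                 k = NA_integer_, n_pcs = NA_integer_),
            class = "knn_graph")
}

# source_sink_spec from explicit values.
spec_from_R <- function(R, sink_cells, sink_groups) {
  structure(list(R = R, sink_cells = sink_cells,
                 sink_groups = stats::setNames(sink_groups, sink_cells)),
            class = "source_sink_spec")
}
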