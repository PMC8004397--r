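test_that("kNN graph edges match brute-force distances", {
  # three collinear cells, k = 1: middle cell bridges the ends
  expr <- matrix(c(0, 1, 2.5), nrow = 1,
                 dimnames = list("g1", c("a", "b", "c")))
  g <- build_knn_graph(expr, k = 1, n_pcs = 1)
  A <- as.matrix(g$adjacency)
  # brute force in the same embedding
  emb <- log1p(as.vector(expr))
  d <- abs(outer(emb, emb, "-")); diag(d) <- Inf
  nn <- apply(d, 1, which.min)
  B <- matrix(0, 3, 3)
  for (i in 1:3) { B[i, nn[i]] <- 1; B[nn[i], i] <- 1 }
  expect_equal(unname(A), B)
  expect_equal(unname(sort(which(A["b", ] > 0))), c(1L, 3L))
})

test_that("k = n-1 yields the complete graph and bad inputs error", {
  set.seed(21)
  expr <- matrix(rpois(50, 5), 5, 10,
                 dimnames = list(NULL, letters[1:10]))
  g <- build_knn_graph(expr, k = 9, n_pcs = 3)
  A <- as.matrix(g$adjacency)
  expect_true(all(A[upper.tri(A)] == 1))
  expect_true(all(diag(A) == 0))
  expect_error(build_knn_graph(expr, k = 0, n_pcs = 2), "positive")
  expect_error(build_knn_graph(expr, k = 10, n_pcs = 2), "below")
  expect_error(build_knn_graph(expr, k = 3, n_pcs = 50), "rank")
})

test_that("construct_R enforces the steady-state condition", {
  # 110 cells, one sink group of 10 at -1 -> 100 sources at +0.1
  set.seed(31)
  expr <- matrix(rpois(110, 2), 1, 110,
                 dimnames = list("mk", sprintf("c%03d", 1:110)))
  expr[1, 1:10] <- 100
  s <- construct_R(expr, list(end = "mk"), n_sinks = 10)
  expect_equal(sum(s$R), 0, tolerance = 1e-12)
  expect_setequal(s$sink_cells, sprintf("c%03d", 1:10))
  expect_equal(unname(s$R[s$sink_cells]), rep(-1, 10))
  expect_equal(unname(s$R[setdiff(names(s$R), s$sink_cells)]),
               rep(0.1, 100))
})

test_that("chosen sinks carry the terminal ground-truth labels", {
  p <- small_pipeline()
  sink_stages <- p$truth[p$res$spec$sink_cells, "stage"]
  expect_true(all(sink_stages %in% c("CD4sp", "CD8sp")))
  grp <- p$res$spec$sink_groups
  expect_identical(unname(grp), unname(sink_stages))
})

test_that("solve_potential reproduces the dense path-graph solution", {
  A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- 1
  g <- graph_from_adjacency(A)
  s <- spec_from_R(setNames(c(1, 0, -1), g$cells), g$cells[3], "end")
  pot <- solve_potential(g, s)
  expect_equal(unname(pot$V), c(2, 1, 0))
  expect_lt(pot$residual, 1e-8)
  # R = 0 everywhere -> constant potential 0
  s0 <- spec_from_R(setNames(rep(0, 3), g$cells), character(), character())
  expect_equal(unname(solve_potential(g, s0)$V), rep(0, 3))
})

test_that("solve_potential validates R and connectivity", {
  A <- matrix(0, 4, 4); A[1, 2] <- A[2, 1] <- A[3, 4] <- A[4, 3] <- 1
  g <- graph_from_adjacency(A)
  s <- spec_from_R(setNames(c(1, -1, 0, 0), g$cells), g$cells[2], "end")
  expect_error(solve_potential(g, s), "component sizes: 2, 2")
  gc <- graph_from_adjacency(rbind(c(0, 1), c(1, 0)))
  sbad <- spec_from_R(setNames(c(1, -0.5), gc$cells), gc$cells[2], "end")
  expect_error(solve_potential(gc, sbad), "steady-state")
})

test_that("solver agrees with the pseudoinverse oracle on random graphs", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    A <- random_connected_graph(n)
    g <- graph_from_adjacency(A)
    R <- rnorm(n); R <- R - mean(R)
    names(R) <- g$cells
    s <- spec_from_R(R, character(), character())
    V <- solve_potential(g, s)$V
    expect_lt(max(abs(V - brute_potential(A, R))), 1e-8)
  }
})

test_that("potential is equivariant to rescaling R; order is invariant", {
  set.seed(43)
  A <- random_connected_graph(30)
  g <- graph_from_adjacency(A)
  R <- rnorm(30); R <- R - mean(R); names(R) <- g$cells
  V1 <- solve_potential(g, spec_from_R(R, character(), character()))$V
  V2 <- solve_potential(g, spec_from_R(R * 7, character(), character()))$V
  expect_equal(V2, V1 * 7, tolerance = 1e-9)
  expect_equal(scale_cell_order(V2), scale_cell_order(V1))
})

test_that("fate probabilities solve the absorbing chain exactly", {
  # symmetric path of 5, sinks at both ends, source at the center
  n <- 5
  A <- matrix(0, n, n)
  for (i in 1:(n - 1)) { A[i, i + 1] <- 1; A[i + 1, i] <- 1 }
  g <- graph_from_adjacency(A)
  R <- setNames(c(-1, 0, 2, 0, -1), g$cells)
  s <- spec_from_R(R, g$cells[c(1, 5)], c("L", "R"))
  V <- solve_potential(g, s)
  fp <- compute_fate_probabilities(g, s, V)
  expect_equal(unname(fp[3, ]), c(0.5, 0.5))
  expect_equal(unname(fp[1, ]), c(1, 0))     # sink: its own group
  expect_equal(unname(fp[5, ]), c(0, 1))
  expect_equal(max(abs(rowSums(fp) - 1)), 0, tolerance = 1e-10)
})

test_that("dead-end cells fall back to the nearest sink group", {
  # V dips at the middle of a path whose ends are the sinks
  n <- 5
  A <- matrix(0, n, n)
  for (i in 1:(n - 1)) { A[i, i + 1] <- 1; A[i + 1, i] <- 1 }
  g <- graph_from_adjacency(A)
  s <- spec_from_R(setNames(c(-1, 0.5, 1, 0.5, -1), g$cells),
                   g$cells[c(1, 5)], c("L", "R"))
  V <- setNames(c(0, 1, 0.5, 1.2, 0), g$cells)   # node 3 is a dead end
  fp <- compute_fate_probabilities(g, s, V)
  expect_identical(attr(fp, "dead_end_cells"), g$cells[3])
  expect_equal(sum(fp[3, ]), 1)
  expect_equal(max(abs(rowSums(fp) - 1)), 0, tolerance = 1e-10)
})

test_that("terminal-branch cells commit to their true branch", {
  p <- small_pipeline()
  fp <- p$res$fate_probs
  term <- p$truth$stage %in% c("CD4sp", "CD8sp")
  maj <- colnames(fp)[max.col(fp)]
  expect_gt(mean(maj[term] == p$truth$stage[term]), 0.9)
  expect_equal(max(abs(rowSums(fp) - 1)), 0, tolerance = 1e-10)
})

test_that("scale_cell_order is the tie-averaged rank map", {
  expect_equal(unname(scale_cell_order(c(a = 2, b = 1, c = 0))),
               c(0, 0.5, 1))
  expect_equal(unname(scale_cell_order(rep(3, 4))), rep(0.5, 4))
  expect_error(scale_cell_order(c(1, NA)), "finite")
})

test_that("stage means of the recovered order increase along the chain", {
  p <- small_pipeline()
  m <- tapply(p$res$order, p$truth$stage, mean)
  chain <- c("DN", "ISP", "DPbla", "DPre", "DPsel")
  expect_true(all(diff(m[chain]) > 0))
  expect_true(all(m[c("CD4sp", "CD8sp")] > m[["DPsel"]]))
  expect_gt(cor(p$res$order, p$truth$true_order, method = "spearman"), 0.9)
})

test_that("bin_and_smooth reproduces exactly representable profiles", {
  n <- 400
  ord <- setNames((seq_len(n) - 0.5) / n, sprintf("c%03d", seq_len(n)))
  expr <- rbind(const = rep(2, n), lin = 5 * ord)
  colnames(expr) <- names(ord)
  bs <- bin_and_smooth(expr, ord, n_bins = 100, poly_degree = 10)
  expect_equal(unname(bs$fitted["const", ]), rep(2, 100), tolerance = 1e-9)
  # equally spaced cells: bin means are linear in the centers
  expect_equal(unname(bs$fitted["lin", ]), unname(bs$bin_means["lin", ]),
               tolerance = 1e-6)
  expect_lt(max(abs(bs$fitted["lin", ] - 5 * bs$bin_centers)), 1e-6)
})

test_that("bin_and_smooth recovers a sigmoid's half-maximum position", {
  set.seed(51)
  n <- 1000
  ord <- setNames(runif(n), sprintf("c%04d", seq_len(n)))
  true_switch <- 0.55
  y <- 10 * plogis((ord - true_switch) / 0.03) + rnorm(n, sd = 0.3)
  expr <- matrix(y, 1, dimnames = list("sig", names(ord)))
  bs <- bin_and_smooth(expr, ord)
  f <- bs$fitted[1, ]
  half <- (max(f) + min(f)) / 2
  cross <- bs$bin_centers[min(which(f >= half))]
  expect_lt(abs(cross - true_switch), 0.05)
})

test_that("empty bins are interpolated and flagged", {
  ord <- setNames(c(seq(0, 0.4, length.out = 30),
                    seq(0.6, 1, length.out = 30)),
                  sprintf("c%02d", 1:60))
  expr <- matrix(c(rep(1, 30), rep(3, 30)), 1,
                 dimnames = list("g", names(ord)))
  bs <- bin_and_smooth(expr, ord, n_bins = 20, poly_degree = 3)
  expect_gt(length(bs$empty_bins), 0)
  expect_false(anyNA(bs$bin_means))
  mid <- bs$bin_means[1, bs$empty_bins]
  expect_true(all(mid >= 1 & mid <= 3))
})
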