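detect_matrix <- function(n_cells_detected, total_cells, genes) {
  # genes x cells matrix where gene i is detected in exactly
  # n_cells_detected[i] cells
  m <- matrix(0, length(genes), total_cells,
              dimnames = list(genes, sprintf("c%03d", seq_len(total_cells))))
  for (i in seq_along(genes))
    if (n_cells_detected[i] > 0) m[i, seq_len(n_cells_detected[i])] <- 5
  m
}

test_that("species-exclusive calls follow the strict nCells bounds", {
  genes <- c("gA", "gB", "gC", "gD")
  hu <- species_expression("human",
                           detect_matrix(c(25, 25, 20, 2), 40, genes),
                           rep(c("DP", "SP"), 20))
  mo <- species_expression("mouse",
                           detect_matrix(c(2, 25, 0, 25), 40, genes),
                           rep(c("DP", "SP"), 20))
  ex <- species_exclusive_genes(hu, mo)
  # gA: 25 vs 2 -> human-high; gB: 25 vs 25 -> no; gC: 20 vs 0 -> no
  # (20 is not > 20); gD: 2 vs 25 -> mouse-high
  expect_setequal(ex$gene, c("gA", "gD"))
  expect_identical(ex$direction[ex$gene == "gA"], "human-high")
  expect_identical(ex$direction[ex$gene == "gD"], "mouse-high")
  # boundary just above: 21 vs 2 flags
  hu2 <- species_expression("human", detect_matrix(21, 40, "gX"), rep("DP", 40))
  mo2 <- species_expression("mouse", detect_matrix(2, 40, "gX"), rep("DP", 40))
  expect_identical(species_exclusive_genes(hu2, mo2)$gene, "gX")
})

test_that("swapping species flips directions, not membership", {
  set.seed(95)
  genes <- sprintf("g%02d", 1:30)
  a <- species_expression("human",
                          detect_matrix(sample(0:40, 30, TRUE), 40, genes),
                          rep("DP", 40))
  b <- species_expression("mouse",
                          detect_matrix(sample(0:40, 30, TRUE), 40, genes),
                          rep("DP", 40))
  ab <- species_exclusive_genes(a, b)
  ba <- species_exclusive_genes(b, a)
  expect_setequal(ab$gene, ba$gene)
  # direction labels carry species names, so the call order must not
  # change which species a gene is attributed to
  expect_identical(ba$direction[match(ab$gene, ba$gene)], ab$direction)
  # positionally, every first-argument-high call flips to second-high
  a_high <- ab$direction == "human-high"
  expect_identical(ba$n_cells_a[match(ab$gene, ba$gene)], ab$n_cells_b)
})

test_that("homolog alignment keeps only one-to-one pairs", {
  a <- matrix(1, 4, 3, dimnames = list(c("A1", "A2", "A3", "A4"), NULL))
  b <- matrix(1, 4, 3, dimnames = list(c("B1", "B2", "B3", "B4"), NULL))
  map <- data.frame(a = c("A1", "A2", "A2", "A3"),
                    b = c("B1", "B2", "B3", "B3"))
  al <- align_homologs(a, b, map)
  expect_identical(rownames(al$a), "A1")     # A2 and B3 are many-to-many
  expect_identical(rownames(al$b), "A1")
  expect_equal(nrow(al$dropped), 3)
})

test_that("stage markers require fold change and low background", {
  set.seed(96)
  n <- 60
  stages <- rep(c("DP", "SP", "DN"), each = n / 3)
  expr <- rbind(
    mk = ifelse(stages == "DP", 8, 0.05) + runif(n, 0, 0.01),
    uni = rep(4, n) + runif(n, 0, 0.01),        # uniform: no marker
    hibg = ifelse(stages == "DP", 9, 5))        # background >= 1 fails
  colnames(expr) <- sprintf("c%02d", seq_len(n))
  se <- species_expression("mouse", expr, stages)
  mk <- stage_marker_genes(se, "DP")
  expect_identical(mk$gene, "mk")
  # a stage with fewer than three cells is skipped with a warning
  st2 <- c("DP", "DP", rep("SP", n - 2))
  expect_warning(out <- stage_marker_genes(
    species_expression("mouse", expr, st2), "DP"), "fewer than")
  expect_equal(nrow(out), 0L)
})

test_that("combined marker lists are capped at the top 400", {
  a <- data.frame(gene = sprintf("a%03d", 1:300), p = seq(0, 0.3, length.out = 300))
  b <- data.frame(gene = sprintf("b%03d", 1:101), p = seq(0, 0.1, length.out = 101))
  comb <- combine_marker_lists(a, b)           # 401 qualifying genes
  expect_identical(length(comb), 400L)
  # the weakest gene by p is the one excluded
  worst <- "a300"
  expect_false(worst %in% comb)
  expect_identical(length(combine_marker_lists(a[1:10, ], b[1:5, ])), 15L)
})

test_that("per-stage cross-species fold changes are strict", {
  n <- 30
  stages <- rep("DP", n)
  base <- matrix(rep(c(2, 2, 5), n), 3, n,
                 dimnames = list(c("g1", "g2", "g3"), sprintf("c%02d", 1:n)))
  a <- species_expression("human", base * c(1, 2, 1), stages)
  b <- species_expression("mouse", base, stages)
  de <- cross_stage_de(a, b, c("g1", "g2", "g3"), "DP")
  # identical g1/g3 never flagged; doubled g2 flagged human-high
  expect_identical(de$gene, "g2")
  expect_identical(de$direction, "human-high")
  # fold change exactly at the threshold is not flagged
  fc2 <- log(2 * 2 + 1) - log(2 + 1)
  de2 <- cross_stage_de(a, b, "g2", "DP", fc_threshold = fc2)
  expect_equal(nrow(de2), 0L)
  # identical matrices: nothing flagged
  expect_equal(nrow(cross_stage_de(b, b, c("g1", "g2", "g3"), "DP")), 0L)
})

test_that("the two-step union carries direction labels", {
  set.seed(97)
  n <- 50
  stages <- rep(c("DP", "SP"), each = n / 2)
  genes <- c("excl", "shift", "flat")
  ha <- rbind(excl = c(rep(5, 30), rep(0, 20)),
              shift = ifelse(stages == "DP", 6, 0.1),
              flat = rep(2, n))
  mb <- rbind(excl = rep(0, n),
              shift = ifelse(stages == "DP", 2, 0.1),
              flat = rep(2, n))
  colnames(ha) <- colnames(mb) <- sprintf("c%02d", 1:n)
  a <- species_expression("human", ha, stages)
  b <- species_expression("mouse", mb, stages)
  res <- cross_species_de(a, b)
  expect_true("excl" %in% res$set1$gene)
  expect_true("shift" %in% res$set2$gene)
  expect_false("flat" %in% res$union$gene)
  expect_setequal(res$union$gene, c("excl", "shift"))
  expect_true(all(res$union$direction == "human-high"))
})

test_that("driver-TF Fisher test equals the hypergeometric oracle", {
  set.seed(98)
  for (i in 1:25) {
    n_uni <- sample(50:2000, 1)
    universe <- sprintf("u%04d", seq_len(n_uni))
    targets <- sample(universe, sample(5:50, 1))
    de <- sample(universe, sample(5:100, 1))
    res <- driver_tf_enrichment(de, list(TF = targets), universe)
    p_oracle <- brute_fisher_greater(res$overlap, res$n_targets,
                                     length(de), n_uni)
    expect_lt(abs(res$p - p_oracle), 1e-10)
  }
  # worked 2x2 example: universe 1000, targets 50, DE 100, overlap 20
  universe <- sprintf("u%04d", 1:1000)
  targets <- universe[1:50]
  de <- c(universe[1:20], universe[51:130])
  res <- driver_tf_enrichment(de, list(TF = targets), universe)
  expect_equal(res$overlap, 20)
  expect_lt(abs(res$p - brute_fisher_greater(20, 50, 100, 1000)), 1e-10)
  expect_equal(res$odds_ratio, (20 * 870) / (30 * 80))
})

test_that("degenerate overlaps give OR 0 (p 1) and OR near 1 at random", {
  universe <- sprintf("u%03d", 1:500)
  targets <- universe[1:50]
  de_disjoint <- universe[51:150]
  res <- driver_tf_enrichment(de_disjoint, list(TF = targets), universe)
  expect_equal(res$odds_ratio, 0)
  expect_equal(res$p, 1)
  # overlap at expectation: OR approximately 1
  de_exp <- c(universe[1:10], universe[51:140])   # 10 = 50*100/500
  res2 <- driver_tf_enrichment(de_exp, list(TF = targets), universe)
  expect_lt(abs(res2$odds_ratio - 1), 0.15)
})

test_that("a planted species-specific regulon attains the smallest q", {
  set.seed(99)
  universe <- sprintf("u%04d", 1:800)
  de <- sample(universe, 80)
  tf_targets <- c(
    list(planted = c(sample(de, 30), sample(setdiff(universe, de), 20))),
    lapply(setNames(1:20, sprintf("bg%02d", 1:20)),
           function(i) sample(universe, 50)))
  res <- driver_tf_enrichment(de, tf_targets, universe)
  expect_identical(res$tf[which.min(res$q)], "planted")
})

test_that("bulk differential test applies CPM, t-test and strict cuts", {
  set.seed(100)
  genes <- sprintf("g%02d", 1:20)
  base <- matrix(rnbinom(20 * 3, mu = 100, size = 50), 20, 3,
                 dimnames = list(genes, NULL))
  # identical replicate matrices: nothing significant
  expect_true(all(!bulk_de(base, base)$significant))
  # planted 4x gene across 3 vs 3 replicates
  hi <- base
  hi["g05", ] <- hi["g05", ] * 4
  h1 <- hi + matrix(rpois(60, 3), 20)
  b1 <- base + matrix(rpois(60, 3), 20)
  res <- bulk_de(h1, b1)
  expect_true(res$significant[res$gene == "g05"])
  # |log2 FC| exactly at the threshold is not significant (strict >)
  r5 <- res[res$gene == "g05", ]
  res2 <- bulk_de(h1, b1, lfc_threshold = abs(r5$log2_fc))
  expect_false(res2$significant[res2$gene == "g05"])
  expect_error(bulk_de(base[, 1, drop = FALSE], base), "two replicates")
})
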