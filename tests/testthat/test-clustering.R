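test_that("modularity matches closed forms", {
  g <- two_cliques_graph()
  one <- single_partition(g$ids)
  expect_equal(modularity(g, one), 0, tolerance = 1e-12)
  # clique partition of two 3-cliques: Q = 1/2
  cliq <- istgreg:::new_partition(g$ids, c(1, 1, 1, 2, 2, 2), "manual")
  expect_equal(modularity(g, cliq), 0.5, tolerance = 1e-12)
  # all-singletons: Q = -sum (k_i / 2m)^2
  sing <- istgreg:::new_partition(g$ids, 1:6, "manual")
  k <- rowSums(g$weights)
  expect_equal(modularity(g, sing), -sum((k / sum(k))^2), tolerance = 1e-12)
})

test_that("modularity agrees with igraph on random weighted graphs", {
  skip_if_not_installed("igraph")
  set.seed(21)
  for (rep in 1:3) {
    n <- 7
    W <- matrix(runif(n * n), n, n)
    W <- (W + t(W)) / 2
    diag(W) <- 0
    g <- sim_graph_from_matrix(W)
    lab <- sample(1:3, n, replace = TRUE)
    part <- istgreg:::new_partition(g$ids, lab, "manual")
    ig <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                              weighted = TRUE)
    expect_equal(modularity(g, part),
                 igraph::modularity(ig, match(lab, sort(unique(lab))),
                                    weights = igraph::E(ig)$weight),
                 tolerance = 1e-10)
  }
})

test_that("Louvain recovers clique structure and respects brute-force bounds", {
  g <- two_cliques_graph()
  p <- louvain_partition(g, seed = 1)
  expect_equal(length(unique(p$labels)), 2L)
  expect_equal(length(unique(p$labels[1:3])), 1L)
  expect_equal(length(unique(p$labels[4:6])), 1L)
  expect_equal(p$modularity, 0.5, tolerance = 1e-12)
  expect_equal(p$modularity, brute_force_best_q(g$weights), tolerance = 1e-12)

  # complete graph K3 -> single community, Q = 0
  W3 <- matrix(1, 3, 3); diag(W3) <- 0
  g3 <- sim_graph_from_matrix(W3)
  p3 <- louvain_partition(g3, seed = 1)
  expect_equal(length(unique(p3$labels)), 1L)
  expect_equal(p3$modularity, 0, tolerance = 1e-12)
  expect_equal(brute_force_best_q(W3), 0, tolerance = 1e-12)

  # assorted n <= 8 fixtures: Louvain never exceeds the brute-force maximum
  set.seed(8)
  fixtures <- list(
    two_cliques = g$weights,
    k3 = W3,
    planted8 = {
      W <- matrix(0.1, 8, 8)
      W[1:4, 1:4] <- 1; W[5:8, 5:8] <- 1
      diag(W) <- 0
      W
    },
    random7 = {
      W <- matrix(runif(49), 7, 7); W <- (W + t(W)) / 2; diag(W) <- 0; W
    })
  for (W in fixtures) {
    q_best <- brute_force_best_q(W)
    p <- louvain_partition(sim_graph_from_matrix(W), seed = 3)
    expect_lte(p$modularity, q_best + 1e-10)
  }
  # and attains it on the planted two-block fixture
  p8 <- louvain_partition(sim_graph_from_matrix(fixtures$planted8), seed = 3)
  expect_equal(p8$modularity, brute_force_best_q(fixtures$planted8),
               tolerance = 1e-10)
})

test_that("planted weighted three-block graphs are recovered for many seeds", {
  set.seed(123)
  n_block <- 10
  W <- matrix(0.1, 3 * n_block, 3 * n_block)
  for (b in 0:2) {
    idx <- b * n_block + seq_len(n_block)
    W[idx, idx] <- 1
  }
  diag(W) <- 0
  g <- sim_graph_from_matrix(W)
  truth <- rep(0:2, each = n_block)
  for (seed in 1:10) {
    p <- louvain_partition(g, seed = seed)
    tab <- table(p$labels, truth)
    expect_equal(length(unique(p$labels)), 3L)
    expect_true(all(colSums(tab > 0) == 1) && all(rowSums(tab > 0) == 1))
  }
})

test_that("Louvain is deterministic given the seed", {
  set.seed(77)
  W <- matrix(runif(144), 12, 12); W <- (W + t(W)) / 2; diag(W) <- 0
  g <- sim_graph_from_matrix(W)
  p1 <- louvain_partition(g, seed = 5)
  p2 <- louvain_partition(g, seed = 5)
  expect_identical(p1$labels, p2$labels)
  expect_identical(p1$modularity, p2$modularity)
})

test_that("no single-node move can improve the final Louvain partition", {
  set.seed(31)
  W <- matrix(runif(100), 10, 10); W <- (W + t(W)) / 2; diag(W) <- 0
  g <- sim_graph_from_matrix(W)
  p <- louvain_partition(g, seed = 2)
  q0 <- p$modularity
  lab <- p$labels
  for (i in seq_along(lab)) {
    for (target in unique(lab)) {
      cand <- lab
      cand[i] <- target
      part <- istgreg:::new_partition(g$ids, cand + 1L, "manual")
      expect_lte(modularity(g, part), q0 + 1e-9)
    }
  }
})

test_that("age partitioning applies half-open bins with stated boundaries", {
  ids <- paste0("s", 1:6)
  ages <- stats::setNames(c(1.2, 2.9, 3.0, 5.9, 6.0, 7.1), ids)
  p <- partition_by_age(ids, ages)
  expect_equal(unname(p$labels[ids]), c(0L, 0L, 1L, 1L, 2L, 2L))
  # age exactly 3.0 belongs to the middle bin
  expect_equal(unname(p$labels["s3"]), 1L)
  expect_warning(p1 <- partition_by_age(ids[1:2], ages[1:2]), "empty")
  expect_equal(length(unique(p1$labels)), 1L)
  expect_error(partition_by_age(c(ids, "s7"), ages), "missing age")
})

test_that("the single-group partition labels everything zero", {
  p <- single_partition(paste0("s", 1:5))
  expect_true(all(p$labels == 0L))
  expect_equal(single_partition("only")$labels[["only"]], 0L)
  expect_equal(length(unique(single_partition(letters[1:9])$labels)), 1L)
})
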