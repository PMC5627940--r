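toys <- make_toy_graphs()

test_that("graph measures equal exhaustive brute-force values on the toy library", {
  for (nm in names(toys)) {
    W <- toys[[nm]]$W
    truth <- toys[[nm]]$truth
    expect_equal(weighted_clustering(W)$clustering, truth$clustering,
                 tolerance = 1e-12, info = nm)
    expect_equal(algebraic_connectivity(W), truth$lambda2,
                 tolerance = 1e-9, info = nm)
    # a single truth value means the maximal tree is unique; a set means
    # ties, and the computed tree must realize one of its leaf counts
    expect_true(mst_leaf_number(W)$leaf_number %in% truth$mst_leaf_number,
                info = nm)
  }
  # bridged cliques: Louvain recovers the exhaustively best 2-partition
  W <- toys$two_clique_bridge$W
  gm <- graph_modularity(W, seed = 4, n_restarts = 10)
  expect_equal(gm$modularity_q, toys$two_clique_bridge$truth$modularity_q,
               tolerance = 1e-9)
  expect_equal(unname(vapply(split(seq_len(10), gm$membership), length,
                             integer(1))), c(5L, 5L))
})

test_that("named small graphs hit their closed-form values", {
  expect_equal(weighted_clustering(toys$triangle$W)$clustering, rep(1, 3))
  expect_equal(weighted_clustering(toys$star6$W)$clustering, rep(0, 6))
  expect_equal(algebraic_connectivity(toys$path3$W), 1, tolerance = 1e-9)
  expect_equal(algebraic_connectivity(toys$k5$W), 5, tolerance = 1e-9)
  expect_equal(mst_leaf_number(toys$star6$W)$leaf_number, 5)
  chain <- toys$path3$W
  expect_equal(mst_leaf_number(chain)$leaf_number, 2)
  # complete uniform graph has no community structure
  expect_lt(abs(graph_modularity(toys$k5$W, seed = 1)$modularity_q), 1e-9)
  # two disconnected components: algebraic connectivity is exactly 0
  W2 <- matrix(0, 4, 4); W2[1, 2] <- W2[2, 1] <- W2[3, 4] <- W2[4, 3] <- 1
  expect_equal(algebraic_connectivity(W2), 0)
  expect_error(mst_leaf_number(W2), "2 components")
})

test_that("gamma normalization behaves as a surrogate-referenced ratio", {
  set.seed(21)
  n <- 30
  U <- matrix(runif(n^2), n); U[lower.tri(U, diag = TRUE)] <- 0
  W <- (U > 0.5) * 0.7; W <- W + t(W)
  g1 <- normalized_gamma(W, n_surrogates = 100, seed = 5)
  # one random realization against its own surrogate ensemble: unity up to
  # the realization's clustering fluctuation
  expect_equal(g1, 1, tolerance = 0.12)
  # scaling all weights leaves gamma unchanged (same surrogate seed)
  expect_equal(normalized_gamma(3 * W, n_surrogates = 100, seed = 5), g1,
               tolerance = 1e-12)
  # a clique-of-cliques is more clustered than its shuffled surrogates
  expect_gt(normalized_gamma(toys$two_clique_bridge$W, n_surrogates = 100,
                             seed = 5), 1)
})

test_that("measures are invariant under node relabeling", {
  W <- toys$random8$W
  base_c <- sort(weighted_clustering(W)$clustering)
  base_l2 <- algebraic_connectivity(W)
  base_leaf <- mst_leaf_number(W)$leaf_number
  base_q <- graph_modularity(W, seed = 3, n_restarts = 10)$modularity_q
  base_g <- normalized_gamma(W, n_surrogates = 400, seed = 3)
  set.seed(99)
  for (i in 1:20) {
    pm <- sample(nrow(W))
    Wp <- W[pm, pm]
    expect_equal(sort(weighted_clustering(Wp)$clustering), base_c,
                 tolerance = 1e-12)
    expect_equal(algebraic_connectivity(Wp), base_l2, tolerance = 1e-10)
    expect_equal(mst_leaf_number(Wp)$leaf_number, base_leaf)
  }
  pm <- sample(nrow(W))
  expect_equal(graph_modularity(W[pm, pm], seed = 3,
                                n_restarts = 10)$modularity_q,
               base_q, tolerance = 1e-9)
  # gamma is invariant only in distribution: relabeling reorders the weight
  # multiset, so the seeded surrogate draws differ; compare at the
  # surrogate-ensemble standard error
  expect_equal(normalized_gamma(W[pm, pm], n_surrogates = 400, seed = 3),
               base_g, tolerance = 0.1)
})

test_that("algebraic connectivity never decreases when a weight is raised", {
  W <- toys$random8$W
  set.seed(14)
  l2 <- algebraic_connectivity(W)
  for (i in 1:50) {
    idx <- sample(8, 2)
    Wp <- W
    Wp[idx[1], idx[2]] <- Wp[idx[2], idx[1]] <- Wp[idx[1], idx[2]] + runif(1)
    expect_gte(algebraic_connectivity(Wp), l2 - 1e-12)
  }
})

test_that("fixtures regenerate identically and bundle their ground truths", {
  again <- make_toy_graphs()
  expect_identical(toys$random8$W, again$random8$W)
  expect_identical(toys$two_clique_bridge$truth, again$two_clique_bridge$truth)
  expect_named(toys$triangle$truth,
               c("clustering", "mean_clustering", "lambda2",
                 "mst_leaf_number"))
  # graph_metrics bundles all four measures into one row
  gm <- graph_metrics(toys$random8$W, n_surrogates = 20, seed = 2)
  expect_s3_class(gm, "tbl_df")
  expect_named(gm, c("gamma", "modularity_q", "algebraic_connectivity",
                     "mst_leaf_number", "mst_leaf_fraction"))
})
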