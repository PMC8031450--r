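test_that("adjacency normalization reproduces hand-computed cases", {
  # single isolated node: self-loop of degree 1
  expect_equal(normalize_adjacency(matrix(0, 1, 1)), matrix(1, 1, 1))

  # two connected nodes: degrees (2,2) after self-loops
  A2 <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(normalize_adjacency(A2), matrix(0.5, 2, 2))

  # 3-node path: degrees (2,3,2); entry (0,1) = 1/sqrt(6)
  A3 <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3)
  got <- normalize_adjacency(A3)
  At <- A3 + diag(3)
  Dm <- diag(1 / sqrt(c(2, 3, 2)))
  expect_equal(got, Dm %*% At %*% Dm)
  expect_equal(got[1, 2], 1 / sqrt(6))

  expect_error(normalize_adjacency(matrix(c(0, 1, 0, 0), 2)), "symmetric")
  expect_error(normalize_adjacency(matrix(c(1, 0, 0, 0), 2)), "diagonal")
})

test_that("normalized adjacency has spectral radius at most 1", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(3:25, 1)
    A <- matrix(rbinom(n * n, 1, 0.3), n, n)
    A[lower.tri(A)] <- t(A)[lower.tri(A)]
    diag(A) <- 0
    ev <- eigen(normalize_adjacency(A), symmetric = TRUE,
                only.values = TRUE)$values
    expect_lte(max(abs(ev)), 1 + 1e-10)
  }
})

test_that("graph convolution matches the per-node brute-force sum", {
  # identity-weight 2-node case
  ah <- normalize_adjacency(matrix(c(0, 1, 1, 0), 2))
  out <- graph_conv(matrix(c(1, 0), 2, 1), ah, matrix(1, 1, 1))
  expect_equal(out, matrix(0.5, 2, 1))

  # zero features stay zero
  expect_true(all(graph_conv(matrix(0, 4, 3), diag(4),
                             matrix(rnorm(6), 3, 2)) == 0))

  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(2:20, 1)
    f_in <- sample(2:6, 1)
    f_out <- sample(1:5, 1)
    A <- matrix(rbinom(n * n, 1, 0.4), n, n)
    A[lower.tri(A)] <- t(A)[lower.tri(A)]
    diag(A) <- 0
    ah <- normalize_adjacency(A)
    F_mat <- matrix(rnorm(n * f_in), n)
    W <- matrix(rnorm(f_in * f_out), f_in)
    got <- graph_conv(F_mat, ah, W)
    manual <- matrix(0, n, f_out)
    for (i in seq_len(n)) {
      acc <- numeric(f_out)
      for (j in seq_len(n)) acc <- acc + ah[i, j] * (F_mat[j, ] %*% W)
      manual[i, ] <- pmax(acc, 0)
    }
    expect_equal(got, manual, tolerance = 1e-6)
  }
})

test_that("graph gather sums the first n_nodes rows only", {
  F_mat <- matrix(c(1, 3, 2, 4), 2)
  expect_equal(graph_gather(F_mat, 2), c(4, 6))
  expect_equal(graph_gather(rbind(F_mat, matrix(0, 50, 2)), 2), c(4, 6))
  expect_equal(graph_gather(F_mat, 1), c(1, 2))
  expect_error(graph_gather(F_mat, 3), "exceeds")
})

test_that("network construction follows the configured architecture", {
  cfg <- network_config(n_bins = 2, seed = 5)
  net <- build_network(cfg)
  expect_length(net$weights$blocks, 2)
  # concatenated readout: 2 blocks x (16 x 2) = 64
  expect_equal(nrow(net$weights$w_fc), 64)
  expect_equal(dim(net$weights$blocks[[1]]$wg3), c(128, 32))
  expect_equal(dim(net$weights$blocks[[1]]$wf3), c(32, 32))

  # same seed, same weights; different seed, different weights
  net2 <- build_network(cfg)
  expect_identical(net$weights, net2$weights)
  net3 <- build_network(network_config(n_bins = 2, seed = 6))
  expect_false(identical(net$weights$w_in, net3$weights$w_in))

  # bin counts change only the block list and the readout width
  n1 <- build_network(network_config(n_bins = 1, seed = 5))
  n8 <- build_network(network_config(n_bins = 8, seed = 5))
  expect_length(n1$weights$blocks, 1)
  expect_length(n8$weights$blocks, 8)
  expect_equal(nrow(n1$weights$w_fc), 1 * 16 * 1)
  expect_equal(nrow(n8$weights$w_fc), 8 * 16 * 8)

  expect_error(network_config(n_bins = 3), "n_bins")
})

test_that("the two-FC block layout is switchable and gathers width 32", {
  cfg <- network_config(n_bins = 2, block_layout = "two_fc", seed = 5)
  net <- build_network(cfg)
  expect_null(net$weights$blocks[[1]]$wf3)
  expect_equal(nrow(net$weights$w_fc), 2 * 32)
  g <- synthetic_graphs(5)[[1]]
  expect_length(forward(net, g), 1)
})

test_that("eval-mode forward is deterministic and ignores padding", {
  params <- synth_params(seed = 17)
  net <- build_network(network_config(n_bins = 2, seed = 2))
  for (i in 1:10) {
    pocket <- as_pocket(generate_complex(params, i))
    g <- featurize_pocket(pocket, n_bins = 2)
    p1 <- forward(net, g)
    expect_identical(forward(net, g), p1)
    # featurize the same pocket with 100 extra padding rows: unchanged
    wide <- featurize_pocket(pocket, n_bins = 2, max_nodes = 300)
    expect_equal(forward(net, wide), p1, tolerance = 1e-10)
  }
})

test_that("forward is invariant under node permutation", {
  graphs <- synthetic_graphs(60)
  net <- build_network(network_config(n_bins = 2, seed = 3))
  for (k in seq_along(graphs)) {
    g <- graphs[[k]]
    set.seed(k)
    perm <- sample(g$n_nodes)
    gp <- g
    gp$features[seq_len(g$n_nodes), ] <- g$features[perm, ]
    for (b in seq_len(g$n_bins)) {
      sub <- as.matrix(g$adjacency[[b]][seq_len(g$n_nodes), seq_len(g$n_nodes)])
      ps <- sub[perm, perm]
      m <- matrix(0, g$max_nodes, g$max_nodes)
      m[seq_len(g$n_nodes), seq_len(g$n_nodes)] <- ps
      gp$adjacency[[b]] <- Matrix::Matrix(m, sparse = TRUE)
      gp$a_hat[[b]] <- normalize_adjacency(Matrix::Matrix(ps, sparse = TRUE))
    }
    expect_equal(forward(net, gp), forward(net, g), tolerance = 1e-5)
  }
})

test_that("train-mode dropout is stochastic but seeded", {
  g <- synthetic_graphs(5)[[1]]
  net <- build_network(network_config(n_bins = 2, seed = 2))
  set.seed(9); a <- forward(net, g, train_mode = TRUE)
  set.seed(9); b <- forward(net, g, train_mode = TRUE)
  set.seed(10); d <- forward(net, g, train_mode = TRUE)
  expect_identical(a, b)
  expect_false(identical(a, d))
})

test_that("bin-count mismatches are rejected", {
  g <- synthetic_graphs(5)[[1]]
  net <- build_network(network_config(n_bins = 4, seed = 2))
  expect_error(forward(net, g), "bin count")
})
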