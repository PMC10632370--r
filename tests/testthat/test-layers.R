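test_that("GCN layer matches hand-derived toy cases", {
  # isolated node with identity weights: self-loop only, degree 1
  uni <- gene_universe(c("a", "b", "c"))
  rec <- data.frame(source = "a", target = "b", network = "ppi", directed = FALSE)
  g <- assemble_graph(rec, uni)
  X <- diag(3)
  out <- layer_gcn(X, g, diag(3))
  expect_equal(out[3, ], c(0, 0, 1))                  # isolated node c
  expect_equal(out[1, ], c(0.5, 0.5, 0))              # A_hat rows [[.5,.5],[.5,.5]]
  expect_equal(out[2, ], c(0.5, 0.5, 0))
  # empty graph: A_hat = I so output = XW
  g0 <- structure(list(universe = uni, edge_sets = list(), directed_flags = logical(0)),
                  class = "gene_graph")
  W <- matrix(rnorm(9), 3)
  expect_equal(layer_gcn(X, g0, W), X %*% W)
  expect_error(layer_gcn(X, g, matrix(0, 2, 2)), "shape mismatch")
})

test_that("TAG layer reduces to a dense layer at K = 0 and sums hops on edge-free graphs", {
  uni <- gene_universe(paste0("g", 1:4))
  g0 <- structure(list(universe = uni, edge_sets = list(), directed_flags = logical(0)),
                  class = "gene_graph")
  X <- matrix(rnorm(8), 4)
  W0 <- matrix(rnorm(4), 2)
  expect_equal(layer_tag(X, g0, list(W0)), X %*% W0)
  # no edges, K = 3, identity weights: four identical terms
  expect_equal(layer_tag(X, g0, rep(list(diag(2)), 4)), 4 * X)
})

test_that("RGCN layer follows the mean-aggregation update", {
  uni <- gene_universe(paste0("g", 1:4))
  rec <- data.frame(source = c("g2", "g3"), target = c("g1", "g1"),
                    network = "r1", directed = TRUE)
  g <- assemble_graph(rec, uni)
  X <- matrix(rnorm(8), 4)
  Wr <- list(r1 = diag(2))
  # no neighbors: root projection only
  out <- layer_rgcn(X, g, Wr, W_root = 2 * diag(2))
  expect_equal(out[4, ], 2 * X[4, ])
  # two neighbors, zero root: plain neighbor mean
  out0 <- layer_rgcn(X, g, Wr, W_root = matrix(0, 2, 2))
  expect_equal(out0[1, ], colMeans(X[2:3, ]))
  expect_equal(out0[2, ], c(0, 0))
  # single neighbor normalizes by 1
  rec1 <- data.frame(source = "g2", target = "g1", network = "r1", directed = TRUE)
  g1 <- assemble_graph(rec1, uni)
  expect_equal(layer_rgcn(X, g1, Wr, matrix(0, 2, 2))[1, ], X[2, ])
})

test_that("FiLM layer applies receiver-conditioned modulation with a rectifier", {
  uni <- gene_universe(paste0("g", 1:3))
  rec <- data.frame(source = "g2", target = "g1", network = "r1", directed = TRUE)
  g <- assemble_graph(rec, uni)
  X <- matrix(abs(rnorm(6)), 3)     # non-negative features
  h <- 2
  Wr <- list(r1 = diag(h))
  # hypernetwork forced to gamma = 1, beta = 0 via zero weights + bias
  Wg <- list(r1 = matrix(0, h, 2 * h))
  bg <- list(r1 = c(rep(0, h), rep(1, h)))
  out <- layer_film(X, g, Wr, Wg, bg)
  expect_equal(out[1, ], X[2, ])                    # rectifier passthrough
  expect_equal(out[2, ], c(0, 0))                   # no in-neighbors
  expect_equal(out[3, ], c(0, 0))
  # gamma = 0, beta = 0: sigma(0) = 0 everywhere
  bg0 <- list(r1 = rep(0, 2 * h))
  expect_equal(layer_film(X, g, Wr, Wg, bg0), matrix(0, 3, h))
})

test_that("all layer kinds agree with dense brute-force oracles on random graphs", {
  for (case in 1:25) {
    set.seed(case)
    n <- sample(3:10, 1)
    n_rel <- sample(1:3, 1)
    g <- rand_graph(n, n_rel = n_rel, p_edge = 0.4, seed = case + 100)
    X <- matrix(rnorm(n * 3), n, 3)
    W <- matrix(rnorm(9), 3)
    expect_equal(layer_gcn(X, g, W), dense_gcn_oracle(X, g, W), tolerance = 1e-5)
    Wl <- replicate(3, matrix(rnorm(9), 3), simplify = FALSE)
    expect_equal(layer_tag(X, g, Wl), dense_tag_oracle(X, g, Wl), tolerance = 1e-5)
    Wr <- lapply(g$edge_sets, function(e) matrix(rnorm(9), 3))
    Wroot <- matrix(rnorm(9), 3)
    expect_equal(layer_rgcn(X, g, Wr, Wroot), dense_rgcn_oracle(X, g, Wr, Wroot),
                 tolerance = 1e-5)
    Wg <- lapply(g$edge_sets, function(e) matrix(rnorm(3 * 6), 3))
    bg <- lapply(g$edge_sets, function(e) rnorm(6))
    expect_equal(layer_film(X, g, Wr, Wg, bg), dense_film_oracle(X, g, Wr, Wg, bg),
                 tolerance = 1e-5)
  }
})

test_that("GCN and TAG are equivariant under node relabeling", {
  for (case in 1:5) {
    n <- 7
    g <- rand_graph(n, seed = case)
    X <- matrix(rnorm(n * 2), n, 2)
    W <- matrix(rnorm(4), 2)
    perm <- sample(n)
    # relabel the graph with the same permutation
    uni <- g$universe
    e <- g$edge_sets$net1
    rec <- data.frame(source = uni$genes[order(perm)[e[, 1]]],
                      target = uni$genes[order(perm)[e[, 2]]],
                      network = "net1", directed = FALSE)
    gp <- assemble_graph(rec, uni)
    expect_equal(layer_gcn(X, g, W)[perm, ], layer_gcn(X[perm, ], gp, W),
                 tolerance = 1e-10)
    Wl <- replicate(3, matrix(rnorm(4), 2), simplify = FALSE)
    expect_equal(layer_tag(X, g, Wl)[perm, ], layer_tag(X[perm, ], gp, Wl),
                 tolerance = 1e-10)
  }
})

test_that("FiLM with one relation and identity modulation reduces to an unnormalized sum", {
  g <- rand_graph(6, seed = 31)
  X <- matrix(abs(rnorm(12)), 6, 2)
  h <- 2
  Wg <- list(net1 = matrix(0, h, 2 * h))
  bg <- list(net1 = c(rep(0, h), rep(1, h)))
  out <- layer_film(X, g, list(net1 = diag(h)), Wg, bg)
  # plain A %*% X (messages summed without degree normalization)
  e <- g$edge_sets$net1
  A <- matrix(0, 6, 6); A[cbind(e[, 2], e[, 1])] <- 1
  expect_equal(out, A %*% X, tolerance = 1e-10)
})

test_that("instance normalization standardizes channels and survives constants", {
  set.seed(5)
  X <- cbind(rnorm(100, 3, 5), rnorm(100), rep(2, 100))
  Z <- normalize_instance(X)
  expect_true(all(abs(colMeans(Z)) < 1e-6))
  v <- apply(Z[, 1:2], 2, function(x) mean(x^2) - mean(x)^2)
  expect_true(all(abs(v - 1) < 1e-4))
  expect_equal(Z[, 3], rep(0, 100))               # eps guard, no division error
  expect_error(normalize_instance(X[1, , drop = FALSE]), ">= 2 nodes")
})
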