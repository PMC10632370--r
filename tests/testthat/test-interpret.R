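test_that("integrated gradients are exact for linear models and vanish on the baseline", {
  w <- c(1.5, -2, 0.3)
  grad_fun <- function(x) w                              # F(x) = w . x
  x <- c(2, 1, -4)
  attr_ <- integrated_gradients(grad_fun, x, steps = 16)
  expect_equal(attr_, w * x, tolerance = 1e-12)
  expect_equal(integrated_gradients(grad_fun, x, baseline = x), rep(0, 3))
  expect_error(integrated_gradients(grad_fun, x, steps = 1), "steps >= 2")
})

test_that("completeness holds on a trained model and attributions converge in steps", {
  cfg <- sim_config(n_genes = 60, effect_size = 3, core_fraction = 0.15,
                    label_frequency_slope = 0, seed = 31,
                    networks = list(list(name = "ppi", model = "erdos-renyi",
                                         mean_degree = 4, directed = FALSE)))
  sim <- simulate_pu_data(cfg)
  feats <- scale_features_robust(sim$features)
  pos <- sim$labels$positives
  mod <- build_model(classifier_spec("mlp", hidden_dim = 8), sim$graph,
                     ncol(feats$values), seed = 2)
  fit <- fit_model(mod, feats$values, pos[-1], pos[1], setdiff(1:60, pos),
                   max_epochs = 60, patience = 60, seed = 2)
  mod <- fit$model
  gene <- pos[2]
  A <- attribute_features(mod, feats$values, gene, steps = 64)
  s1 <- forward_classifier(mod, feats$values)[gene]
  s0 <- forward_classifier(mod, feats$values * 0)[gene]
  expect_lt(abs(sum(A) - (s1 - s0)) / max(abs(s1 - s0), 1e-8), 1e-3)
  # doubling the resolution barely moves the attributions
  A2 <- attribute_features(mod, feats$values, gene, steps = 128)
  expect_lt(max(abs(A - A2)) / max(abs(A) + 1e-12), 1e-3)
})

test_that("edge attributions are zero for graph-free models and sign-consistent for GCN", {
  # single-edge toy: removing the edge changes the score
  uni <- gene_universe(c("a", "b", "c"))
  rec <- data.frame(source = "a", target = "b", network = "ppi", directed = FALSE)
  g <- assemble_graph(rec, uni)
  X <- matrix(c(3, -1, 0.5, 1, 2, -2), 3, 2)
  gcn <- build_model(classifier_spec("gcn", hidden_dim = 5, mp_layers = 1), g, 2, seed = 6)
  e_attr <- attribute_edges(gcn, X, gene = 2, steps = 64)
  expect_length(e_attr, 2L)
  # finite-difference sign oracle on the edge a -> b (position of (1 -> 2))
  et <- gcn$ctx$edge_table
  idx <- which(et$source == 1 & et$target == 2)
  s_with <- forward_classifier(gcn, X, rep(1, 2))[2]
  w0 <- rep(1, 2); w0[idx] <- 0
  s_without <- forward_classifier(gcn, X, w0)[2]
  expect_gt(abs(s_with - s_without), 1e-8)
  expect_equal(sign(e_attr[idx]), sign(s_with - s_without))
  # attribution is query-specific
  e_other <- attribute_edges(gcn, X, gene = 3, steps = 64)
  expect_false(isTRUE(all.equal(e_attr, e_other)))
  # graph-free MLP: no edge dependence, all attributions exactly zero
  mlp <- build_model(classifier_spec("mlp", hidden_dim = 5), g, 2, seed = 6)
  expect_equal(attribute_edges(mlp, X, gene = 2), rep(0, 2))
})

test_that("ensemble aggregation minmax-scales per model, averages, and respects bounds", {
  # single model: its top-|attribution| edge gets importance exactly 1
  e1 <- c(0.2, -0.9, 0.1)
  f1 <- matrix(c(1, -2, 0.5, 0.1), 2, 2)
  rep1 <- aggregate_ensemble_importance(list(e1), list(f1), gene = 1)
  expect_equal(rep1$edge[2], 1)
  expect_equal(min(rep1$edge), 0)
  # edge top in half the models, bottom in the other half: importance 0.5
  eA <- c(1, 0); eB <- c(0, 1)
  repAB <- aggregate_ensemble_importance(list(eA, eB), list(f1, f1), gene = 1)
  expect_equal(repAB$edge, c(0.5, 0.5))
  # aggregation order-invariant
  repBA <- aggregate_ensemble_importance(list(eB, eA), list(f1, f1), gene = 1)
  expect_equal(repAB$edge, repBA$edge)
  # bounds after aggregation
  set.seed(7)
  eds <- replicate(5, rnorm(6), simplify = FALSE)
  fts <- replicate(5, matrix(rnorm(12), 4, 3), simplify = FALSE)
  rp <- aggregate_ensemble_importance(eds, fts, gene = 2)
  expect_true(all(rp$edge >= 0 & rp$edge <= 1))
  expect_true(all(rp$node >= 0 & rp$node <= 1))
  expect_true(all(rp$self >= -1 & rp$self <= 1))
  # self features keep their sign
  fpos <- matrix(c(2, -3, 0.5, -0.1, 1, 4), 2, 3)
  rs <- aggregate_ensemble_importance(list(c(1, 0)), list(fpos), gene = 1)
  expect_equal(sign(rs$self), sign(fpos[1, ]) * (abs(fpos[1, ]) > min(abs(fpos[1, ]))))
})

test_that("interpret_ensemble produces ranked edge and feature tables", {
  cfg <- sim_config(n_genes = 40, effect_size = 3, core_fraction = 0.2,
                    label_frequency_slope = 0, seed = 41,
                    networks = list(list(name = "ppi", model = "erdos-renyi",
                                         mean_degree = 3, directed = FALSE)))
  sim <- simulate_pu_data(cfg)
  fit <- pu_ensemble(sim$graph, sim$features, sim$labels, classifier = "gcn",
                     m = 2, n = 2, B = 50, max_epochs = 30, patience = 30,
                     seed = 41, keep_models = TRUE)
  out <- interpret_ensemble(fit, gene = sim$graph$universe$genes[1], steps = 16)
  expect_true(all(c("source", "target", "network", "importance") %in% names(out$edges)))
  expect_true(all(out$edges$importance >= 0 & out$edges$importance <= 1))
  expect_equal(nrow(out$features), ncol(sim$features$values))
  expect_true(all(abs(out$features$importance) <= 1))
})
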