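test_that("fold plan partitions positives with balanced sizes", {
  pos <- 1:110
  plan <- plan_nested_folds(pos, m = 11, n = 10, seed = 1)
  expect_length(plan$test, 11L)
  expect_true(all(lengths(plan$test) == 10L))
  expect_setequal(unlist(plan$test), pos)                    # test sets partition positives
  for (j in 1:11) {
    expect_true(all(lengths(plan$val[[j]]) == 10L))
    expect_setequal(unlist(plan$val[[j]]), setdiff(pos, plan$test[[j]]))
    train_ji <- setdiff(setdiff(pos, plan$test[[j]]), plan$val[[j]][[1]])
    expect_length(train_ji, 90L)
  }
  expect_error(plan_nested_folds(1:5, m = 11, n = 10), "at least m")
})

test_that("fold-plan invariants hold for arbitrary sizes and seeds", {
  set.seed(20)
  for (case in 1:20) {
    npos <- sample(12:200, 1)
    m <- sample(3:11, 1)
    n <- sample(2:10, 1)
    if (npos < m) next
    pos <- sample(1000, npos)
    plan <- plan_nested_folds(pos, m, n, seed = case)
    expect_setequal(unlist(plan$test), pos)
    expect_equal(sum(lengths(plan$test)), npos)              # disjoint by construction
    expect_true(max(lengths(plan$test)) - min(lengths(plan$test)) <= 1L)
    j <- sample(m, 1)
    expect_setequal(unlist(plan$val[[j]]), setdiff(pos, plan$test[[j]]))
    expect_true(max(lengths(plan$val[[j]])) - min(lengths(plan$val[[j]])) <= 1L)
  }
})

test_that("concordance counts agreeing models per gene", {
  calls <- list(c(1, 0, 1), c(1, 0, 0), c(1, 0, 1))
  expect_equal(concordance(calls), c(3L, 0L, 2L))
  expect_equal(concordance(matrix(1, 4, 10)), rep(10L, 4))
  expect_equal(concordance(matrix(0, 4, 10)), rep(0L, 4))
})

test_that("background concordance matches its null model", {
  # no calls anywhere: all-zero background
  bg0 <- background_concordance(rep(0L, 5), 100, 10, B = 20, seed = 1)
  expect_true(all(bg0 == 0))
  expect_equal(dim(bg0), c(20L, 5L))
  # expected overlap at concordance exactly 1 matches the closed form
  # P(gene hit by model i) = k_i / N; overlap_1 = T * sum_i p_i prod_{j!=i}(1-p_j)
  counts <- c(30L, 50L, 20L)
  N <- 200L; Tn <- 20L; B <- 3000L
  bg <- background_concordance(counts, N, Tn, B = B, seed = 2)
  p <- counts / N
  expected1 <- Tn * sum(vapply(1:3, function(i) p[i] * prod(1 - p[-i]), numeric(1)))
  se <- sd(bg[, 1]) / sqrt(B)
  expect_lt(abs(mean(bg[, 1]) - expected1), 4 * se + 1e-9)
  # agreement with a naive full-universe draw (independent implementation)
  set.seed(3)
  naive <- t(replicate(3000, {
    conc <- integer(Tn)
    for (i in seq_along(counts)) {
      marked <- sample.int(N, counts[i])
      hit <- marked[marked <= Tn]
      conc[hit] <- conc[hit] + 1L
    }
    tabulate(conc, nbins = length(counts))
  }))
  for (c_ in 1:3) {
    se_c <- sqrt(var(bg[, c_]) / B + var(naive[, c_]) / 3000)
    expect_lt(abs(mean(bg[, c_]) - mean(naive[, c_])), 5 * se_c + 0.01)
  }
})

test_that("threshold selection follows the FDR and sparse-background branches", {
  # null: observed equals the background mean everywhere, means >= 0.1 -> none
  set.seed(4)
  bg <- matrix(rpois(1000 * 5, 2), 1000, 5)
  obs <- round(colMeans(bg))
  sel <- select_inner_threshold(obs, bg)
  expect_true(is.na(sel$threshold))
  # sparse branch: observed 4 at bin 9 with background mean 0.05
  bg2 <- matrix(0, 1000, 10)
  bg2[, 1:8] <- matrix(rpois(1000 * 8, 3), 1000)
  bg2[sample(1000, 50), 9] <- 1                      # mean 0.05 < 0.1
  obs2 <- c(round(colMeans(bg2[, 1:8])), 4, 0)
  sel2 <- select_inner_threshold(obs2, bg2)
  expect_equal(sel2$threshold, 9L)
  expect_true(sel2$diagnostics$chosen[9])
  # significance branch picks the minimal significant bin
  bg3 <- matrix(rpois(1000 * 4, 1), 1000, 4) + 1     # means ~2, all >= 0.1
  obs3 <- c(2, 30, 30, 2)
  sel3 <- select_inner_threshold(obs3, bg3)
  expect_equal(sel3$threshold, 2L)
  # zero-variance background with observed <= mean: p = 1 by convention
  bgz <- matrix(2, 500, 3)
  selz <- select_inner_threshold(c(2, 2, 2), bgz)
  expect_true(all(selz$diagnostics$p == 1))
  expect_true(is.na(selz$threshold))
})

test_that("candidate extraction respects the threshold and excludes known positives", {
  conc <- c(10L, 9L, 5L, 0L, 10L, 7L)
  pos <- c(5L)                                      # a test positive with full agreement
  expect_equal(fold_candidates(conc, 10L, pos), 1L)  # unanimous unlabeled only
  expect_equal(fold_candidates(conc, 7L, pos), c(1L, 2L, 6L))
  expect_equal(fold_candidates(conc, NA_integer_, pos), integer(0))
  # monotonicity: raising the threshold never enlarges the candidate set
  for (c1 in 1:9) {
    expect_true(all(fold_candidates(conc, c1 + 1L, pos) %in% fold_candidates(conc, c1, pos)))
  }
})

test_that("consensus scores count selecting folds and flag gene classes", {
  sets <- list(c(1L, 2L), c(2L), c(2L, 7L))
  cr <- consensus_score(sets, n_universe = 8, known_positives = 4L)
  expect_equal(cr$cs[2], 3L)
  expect_equal(cr$cs[1], 1L)
  expect_equal(cr$cs[3], 0L)
  expect_true(is.na(cr$cs[4]))
  expect_equal(as.character(cr$flag[c(1, 3, 4)]),
               c("candidate", "non-candidate", "positive-label"))
  full <- consensus_score(rep(list(5L), 11), 6, integer(0))
  expect_equal(full$cs[5], 11L)
  part <- consensus_score(list(3L, integer(0), 3L, integer(0), 3L), 4, integer(0))
  expect_equal(part$cs[3], 3L)
})

test_that("a small ensemble runs end to end, never scores known positives and is deterministic", {
  cfg <- sim_config(n_genes = 150, effect_size = 3, core_fraction = 0.12,
                    label_frequency_slope = 1, seed = 23)
  sim <- simulate_pu_data(cfg)
  fit <- pu_ensemble(sim$graph, sim$features, sim$labels, classifier = "mlp",
                     m = 3, n = 3, B = 100, max_epochs = 80, patience = 80,
                     seed = 23, keep_models = FALSE)
  expect_s3_class(fit, "pu_ensemble")
  expect_true(all(is.na(fit$consensus$cs[sim$labels$positives])))
  expect_true(all(fit$consensus$cs[!is.na(fit$consensus$cs)] <= 3L))
  cons <- predict(fit, type = "consensus")
  expect_equal(nrow(cons), 150L)
  fit2 <- pu_ensemble(sim$graph, sim$features, sim$labels, classifier = "mlp",
                      m = 3, n = 3, B = 100, max_epochs = 80, patience = 80,
                      seed = 23, keep_models = FALSE)
  expect_identical(fit$consensus$cs, fit2$consensus$cs)
  expect_output(print(fit), "ensemble")
  s <- summary(fit)
  expect_equal(sum(s$cs_table), 150L - length(sim$labels$positives))
})
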