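test_that("fisher enrichment reports the cross-product odds ratio and exact p", {
  ann <- geneset_annotation(membership = 1:20, background = 1:1000)
  # a=10, b=90, c=10, d=890 -> OR = (10*890)/(90*10) = 9.888...
  test_set <- c(11:20, 101:190)
  e <- fisher_enrichment(test_set, ann)
  expect_equal(c(e$a, e$b, e$c, e$d), c(10, 90, 10, 890))
  expect_equal(e$odds_ratio, (10 * 890) / (90 * 10), tolerance = 1e-9)
  expect_equal(e$p, fisher_p_enumeration(10, 90, 10, 890), tolerance = 1e-9)
  # symmetric null table
  ann2 <- geneset_annotation(1:50, 1:100)
  e2 <- fisher_enrichment(c(1:25, 51:75), ann2)
  expect_equal(e2$odds_ratio, 1)
  expect_equal(e2$p, 1)
  # empty cell: Haldane correction keeps the OR finite and flags it
  ann3 <- geneset_annotation(1:10, 1:100)
  e3 <- fisher_enrichment(11:30, ann3)
  expect_equal(e3$a, 0)
  expect_true(e3$corrected)
  expect_true(is.finite(e3$odds_ratio))
  # exclusions empty the test set
  expect_error(fisher_enrichment(1:5, ann2, exclusions = 1:5), "empty")
})

test_that("fisher p-values match hypergeometric enumeration on small tables", {
  set.seed(11)
  for (case in 1:30) {
    m1 <- sample(1:15, 1); m2 <- sample(1:15, 1); k <- sample(1:(m1 + m2), 1)
    a <- sample(max(0, k - m2):min(k, m1), 1)
    b <- m1 - a; c_ <- k - a; d <- m2 - c_
    p_pkg <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value
    expect_equal(p_pkg, fisher_p_enumeration(a, b, c_, d), tolerance = 1e-9)
  }
})

test_that("CS-bin enrichment uses cumulative bins and controls FDR under the null", {
  set.seed(12)
  cs <- sample(0:5, 500, replace = TRUE, prob = c(0.7, 0.1, 0.08, 0.06, 0.04, 0.02))
  pos <- sample(which(cs == 0), 20)
  cs[pos] <- NA
  # annotation equals exactly the top bin: maximal (corrected) OR at k = max
  ann_top <- geneset_annotation(which(!is.na(cs) & cs == 5), which(!is.na(cs)))
  e_top <- enrichment_by_cs_bin(cs, ann_top, known_positives = pos)
  expect_equal(e_top$b[5], 0)
  expect_gt(e_top$odds_ratio[5], e_top$odds_ratio[1])
  # bin 1 is the candidates-vs-non-candidates split
  cand <- which(!is.na(cs) & cs >= 1)
  nonc <- which(!is.na(cs) & cs == 0)
  e1_direct <- fisher_enrichment(cand, geneset_annotation(ann_top$membership, c(cand, nonc)))
  expect_equal(e_top$odds_ratio[1], e1_direct$odds_ratio)
  # CS-independent annotation: few significant bins across seeds
  n_sig <- 0L; n_tot <- 0L
  for (s in 1:20) {
    set.seed(s + 100)
    ann_null <- geneset_annotation(sample(which(!is.na(cs)), 60), which(!is.na(cs)))
    en <- enrichment_by_cs_bin(cs, ann_null, known_positives = pos)
    n_sig <- n_sig + sum(en$significant, na.rm = TRUE)
    n_tot <- n_tot + sum(!is.na(en$significant))
  }
  expect_lte(n_sig / n_tot, 0.10)
})

test_that("simulated validation sets are recovered as enriched at the planted odds ratio", {
  cfg <- sim_config(n_genes = 5000, core_fraction = 0.1, validation_or = 5, seed = 3)
  z <- simulate_coreness(cfg)
  truth <- assign_pu_labels(cfg, z)
  v <- simulate_validation_geneset(cfg, truth)
  # pretend a perfect classifier: candidates = true cores (minus labels)
  cs <- integer(5000)
  cs[truth$true_cores] <- 1L
  cs[truth$labeled_positives] <- NA
  ann <- geneset_annotation(v, seq_len(5000))
  e <- enrichment_by_cs_bin(cs, ann, known_positives = truth$labeled_positives)
  expect_gt(e$odds_ratio[1], 2.5)
  expect_true(e$significant[1])
})

test_that("Tukey HSD group comparisons match studentized-range expectations", {
  # three identical groups: no pair significant
  v0 <- rep(c(1, 2, 3), 3)
  g0 <- rep(c("a", "b", "c"), each = 3)
  t0 <- tukey_groups(v0, g0)
  expect_true(all(t0$p_adj > 0.9))
  expect_true(all(abs(t0$diff) < 1e-12))
  # groups centered at 0 / 5 / 10, sd 0.1: differences {5, 10, 5}, all tiny p
  set.seed(14)
  v1 <- c(rnorm(3, 0, 0.1), rnorm(3, 5, 0.1), rnorm(3, 10, 0.1))
  g1 <- rep(c("lo", "mid", "hi"), each = 3)
  t1 <- tukey_groups(v1, g1)
  expect_equal(sort(round(abs(t1$diff))), c(5, 5, 10))
  expect_true(all(t1$p_adj < 1e-6))
  # two groups: Tukey p equals the pooled two-sample t-test p (q = t * sqrt(2))
  set.seed(15)
  x <- rnorm(8); y <- rnorm(8, 1)
  t2 <- tukey_groups(c(x, y), rep(c("a", "b"), each = 8))
  expect_equal(t2$p_adj, t.test(y, x, var.equal = TRUE)$p.value, tolerance = 1e-9)
  expect_error(tukey_groups(1:4, rep("a", 4)), ">= 2 groups")
})

test_that("drug-degree rank-sum tests report median ratios", {
  set.seed(16)
  nonc <- rpois(200, 4) + 1
  cand <- nonc * 2                                   # exact doubling
  counts <- c(cand, nonc)
  grp <- rep(c("candidate", "non-candidate"), c(200, 200))
  r <- drug_degree_ranksum(counts, grp)
  row <- r[r$group1 == "candidate" & r$group2 == "non-candidate", ]
  expect_equal(row$xdc, 2)
  expect_lt(row$fdr, 0.05)
  # identical distributions: ratio 1, large p
  r0 <- drug_degree_ranksum(c(nonc, nonc), grp)
  expect_equal(r0$xdc[1], 1)
  expect_gt(r0$p[1], 0.05)
  # genes without interactions are excluded; empty group skipped with warning
  counts2 <- c(rep(0, 5), rpois(50, 3) + 1, rpois(50, 3) + 1)
  grp2 <- c(rep("positive", 5), rep(c("candidate", "non-candidate"), c(50, 50)))
  expect_warning(r2 <- drug_degree_ranksum(counts2, grp2), "positive")
  expect_equal(nrow(r2), 1L)
})

test_that("druggability-excluding-targets removes targets before testing", {
  set.seed(17)
  bgu <- 1:600
  targets <- sample(bgu, 100)
  druggable <- sample(setdiff(bgu, targets), 80)
  test_set <- c(sample(druggable, 30), sample(setdiff(bgu, c(druggable, targets)), 30))
  e <- druggable_excluding_targets(druggable, targets, test_set, bgu)
  expect_gt(e$odds_ratio, 1)
  expect_equal(e$a + e$b, 60)                        # no targets left in the test set
  expect_error(druggable_excluding_targets(druggable, targets,
                                           test_set = targets[1:10], bgu), "empty")
  # independence: OR near 1
  test_null <- sample(setdiff(bgu, targets), 100)
  e0 <- druggable_excluding_targets(druggable, targets, test_null, bgu)
  expect_lt(abs(log(e0$odds_ratio)), log(3))
})

test_that("two-proportion z-test matches its closed form", {
  z0 <- compare_rates_ztest(30, 100, 30, 100)
  expect_equal(z0$z, 0)
  expect_equal(z0$p, 1)
  # 50/100 vs 10/100 with pooled p_hat = 0.3
  z1 <- compare_rates_ztest(50, 100, 10, 100)
  se <- sqrt(0.3 * 0.7 * (1 / 100 + 1 / 100))
  expect_equal(z1$z, 0.4 / se, tolerance = 1e-12)
  expect_error(compare_rates_ztest(1, 10, 0, 0), "trials > 0")
})

test_that("BH adjustment reproduces the step-up formula and is permutation-invariant", {
  expect_equal(adjust_fdr(0.03), 0.03)
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  set.seed(18)
  p <- runif(20)
  perm <- sample(20)
  expect_equal(adjust_fdr(p)[perm], adjust_fdr(p[perm]))
})
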