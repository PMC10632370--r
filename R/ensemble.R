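# Nested cross-validation ensemble: fold planning, model agreement,
# statistically selected inner threshold, and per-gene consensus scores.

#' Plan the nested cross-validation folds
#'
#' Partitions the positives into `m` outer test sets; within each outer
#' fold, the remaining positives are partitioned into `n` inner validation
#' sets (one per inner model), so every inner model trains on
#' `positives - test_j - val_{j,i}`. All set sizes are balanced within one.
#'
#' @param positives integer positions of the known positives.
#' @param m number of outer folds (default 11).
#' @param n number of inner models per fold (default 10).
#' @param seed integer seed.
#' @return object of class `fold_plan`: list with `m`, `n`, `test` (list of
#'   m integer vectors), `val` (list of m lists of n integer vectors).
#' @export
plan_nested_folds <- function(positives, m = 11L, n = 10L, seed = 1L) {
  positives <- sort(unique(as.integer(positives)))
  if (length(positives) < m) stop("need at least m = ", m, " positives to form outer folds")
  set.seed(seed)
  shuffled <- sample(positives)
  test <- unname(split(shuffled, rep_len(seq_len(m), length(shuffled))))
  val <- vector("list", m)
  for (j in seq_len(m)) {
    rest <- sample(setdiff(positives, test[[j]]))
    val[[j]] <- unname(split(rest, rep_len(seq_len(n), length(rest))))
  }
  structure(list(m = as.integer(m), n = as.integer(n), positives = positives,
                 test = test, val = val, seed = seed),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat("<fold_plan> ", x$m, " outer folds x ", x$n, " inner models, ",
      length(x$positives), " positives\n", sep = "")
  invisible(x)
}

#' Concordance of inner-model predictions
#'
#' Counts, per gene, how many of the `n` inner models call it positive.
#'
#' @param fold_predictions list (or matrix columns) of n binary call
#'   vectors over the same gene universe.
#' @return integer vector of per-gene concordance counts in `0..n`.
#' @export
concordance <- function(fold_predictions) {
  if (is.list(fold_predictions)) fold_predictions <- do.call(cbind, fold_predictions)
  as.integer(rowSums(fold_predictions))
}

#' Background concordance of random classifiers
#'
#' Null model for the inner-threshold statistic: `n` random classifiers
#' each mark as many genes as the corresponding real model did, uniformly
#' without replacement within the scored universe. The overlap of their
#' concordance bins with the held-out test positives is recorded; this is
#' repeated `B` times. The draw restricted to the test positives is
#' realized exactly: each random classifier hits `h ~ Hypergeometric`
#' test positives, which then form a uniform subset.
#'
#' @param call_counts integer vector (length n) of positive-call counts of
#'   the real models within the scored universe.
#' @param scored_universe_size size of the scored universe (unlabeled genes
#'   plus the fold's test positives).
#' @param test_positive_count number of held-out test positives.
#' @param B number of background repetitions (default 1000).
#' @param seed integer seed.
#' @return integer matrix `B x n`; entry `[b, c]` is the number of test
#'   positives with concordance exactly `c` in repetition `b`.
#' @export
background_concordance <- function(call_counts, scored_universe_size,
                                   test_positive_count, B = 1000L, seed = 1L) {
  n <- length(call_counts)
  N <- scored_universe_size
  Tn <- test_positive_count
  stopifnot(all(call_counts >= 0L), all(call_counts <= N), Tn <= N, Tn >= 0L)
  set.seed(seed)
  out <- matrix(0L, B, n)
  if (Tn == 0L) return(out)
  for (b in seq_len(B)) {
    conc <- integer(Tn)
    for (i in seq_len(n)) {
      h <- stats::rhyper(1L, Tn, N - Tn, call_counts[i])
      if (h > 0L) {
        hit <- sample.int(Tn, h)
        conc[hit] <- conc[hit] + 1L
      }
    }
    tab <- tabulate(conc, nbins = n)
    out[b, ] <- tab
  }
  out
}

#' Select the inner agreement threshold
#'
#' For every agreement level `c* in 1..n` the observed number of test
#' positives at that concordance is compared against the `B` background
#' overlaps with a one-sided t-statistic on the background scale,
#' `t = (observed - mean(background)) / sd(background)` with `B - 1`
#' degrees of freedom (small p when the observation exceeds what a random
#' background draw would reach; using the background standard deviation,
#' not the standard error of its mean, keeps the per-bin type-I rate at
#' the nominal level under a null observation). P-values are
#' Benjamini-Hochberg corrected across the `n` levels. The chosen threshold is the minimal bin with
#' FDR below `fdr_level`, or the minimal bin whose background mean falls
#' below `min_background` while at least one test positive is observed
#' there -- whichever is smaller. `NA` if no bin qualifies.
#'
#' @param observed integer vector (length n): test positives with
#'   concordance exactly `c*`.
#' @param background matrix from [background_concordance()].
#' @param fdr_level FDR cutoff (default 0.05).
#' @param min_background background-mean cutoff for the sparse branch
#'   (default 0.1).
#' @return list with `threshold` (integer or `NA`) and `diagnostics`
#'   (data.frame: bin, observed, bg_mean, bg_sd, p, fdr, chosen).
#' @export
select_inner_threshold <- function(observed, background, fdr_level = 0.05,
                                   min_background = 0.1) {
  n <- length(observed)
  stopifnot(ncol(background) == n)
  p <- numeric(n)
  bg_mean <- colMeans(background)
  bg_sd <- apply(background, 2L, stats::sd)
  B <- nrow(background)
  for (c_ in seq_len(n)) {
    if (bg_sd[c_] == 0) {
      # degenerate background: significant only if strictly below the observation
      p[c_] <- if (bg_mean[c_] < observed[c_]) 0 else 1
    } else {
      p[c_] <- stats::pt((bg_mean[c_] - observed[c_]) / bg_sd[c_], df = B - 1)
    }
  }
  fdr <- stats::p.adjust(p, method = "BH")
  sig_bins <- which(fdr < fdr_level & observed > bg_mean)
  low_bins <- which(bg_mean < min_background & observed >= 1)
  cand <- c(sig_bins, low_bins)
  threshold <- if (length(cand) > 0L) min(cand) else NA_integer_
  diagnostics <- data.frame(bin = seq_len(n), observed = observed,
                            bg_mean = bg_mean, bg_sd = bg_sd, p = p, fdr = fdr,
                            chosen = !is.na(threshold) & seq_len(n) == threshold)
  list(threshold = threshold, diagnostics = diagnostics)
}

#' Candidate genes of one outer fold
#'
#' All unlabeled genes whose concordance reaches at least the inner
#' threshold; known positives (including the fold's own test positives)
#' are never candidates.
#'
#' @param conc per-gene concordance vector over the whole universe.
#' @param threshold chosen inner threshold (`NA` gives an empty set).
#' @param known_positives integer positions of all known positives.
#' @return sorted integer vector of candidate gene positions.
#' @export
fold_candidates <- function(conc, threshold, known_positives) {
  if (is.na(threshold)) return(integer(0))
  sort(setdiff(which(conc >= threshold), known_positives))
}

#' Consensus score across outer folds
#'
#' `CS(g)` counts the outer folds whose candidate set contains gene `g`;
#' it ranges from 0 (non-candidate) to `m` (selected by every fold).
#' Known positives receive no consensus score (`NA`) and are flagged
#' `"positive-label"`.
#'
#' @param candidate_sets list of m integer vectors of candidate positions.
#' @param n_universe number of genes in the universe.
#' @param known_positives integer positions of the known positives.
#' @return object of class `consensus_result`: list with `cs` (integer
#'   vector, `NA` for positives), `flag` (factor: positive-label /
#'   candidate / non-candidate), `m`, `candidate_sets`.
#' @export
consensus_score <- function(candidate_sets, n_universe, known_positives = integer(0)) {
  m <- length(candidate_sets)
  cs <- integer(n_universe)
  for (set in candidate_sets) cs[set] <- cs[set] + 1L
  flag <- ifelse(seq_len(n_universe) %in% known_positives, "positive-label",
                 ifelse(cs > 0L, "candidate", "non-candidate"))
  cs[known_positives] <- NA_integer_
  structure(list(cs = cs, flag = factor(flag, levels = c("positive-label", "candidate", "non-candidate")),
                 m = m, candidate_sets = candidate_sets),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("<consensus_result> m = ", x$m, " folds; ",
      sum(x$flag == "candidate"), " candidates, ",
      sum(x$flag == "non-candidate"), " non-candidates, ",
      sum(x$flag == "positive-label"), " known positives\n", sep = "")
  invisible(x)
}

#' Fit a positive-unlabeled nested cross-validation ensemble
#'
#' The main fitting function. Positive labels are split into `m` outer test
#' sets; within every outer fold, `n` base classifiers are trained (each
#' with its own positives-only early-stopping holdout) on all unlabeled
#' genes as class 0 -- the fold's test positives included -- plus the
#' remaining positives as class 1. Model agreement on the held-out test
#' positives is compared against a simulated random background to select
#' the fold's inner agreement threshold; unlabeled genes at or above the
#' threshold become the fold's candidates, and the per-gene consensus
#' score counts selecting folds.
#'
#' @param graph a `gene_graph`.
#' @param features a `feature_matrix` (robust-scaled automatically if not
#'   yet scaled).
#' @param labels a `label_set` of known positives.
#' @param classifier method name for [classifier_spec()] or an
#'   [arch_spec()].
#' @param m,n ensemble shape: outer folds and inner models (defaults 11, 10).
#' @param cfg a [loss_config()].
#' @param B background repetitions for the inner threshold (default 1000).
#' @param fdr_level FDR level of the threshold test (default 0.05).
#' @param score_threshold binarization cutoff on scores (default 0.7).
#' @param embedding optional embedding table for embedding-consuming
#'   classifiers; computed via [embed_networks_randomwalk()] defaults when
#'   required but missing.
#' @param embedding_control a [n2v_control()] list.
#' @param lr,max_epochs,patience training controls, see [fit_model()].
#' @param seed global seed; per-model seeds are derived as
#'   `seed + 97 * j + i`.
#' @param keep_models retain the trained inner models (needed for
#'   interpretation; default `TRUE`).
#' @param verbose print per-fold progress.
#' @return object of class `pu_ensemble`; see [print.pu_ensemble()],
#'   [summary.pu_ensemble()], [predict.pu_ensemble()], [plot.pu_ensemble()].
#' @export
pu_ensemble <- function(graph, features, labels, classifier = "mlp",
                        m = 11L, n = 10L, cfg = loss_config(), B = 1000L,
                        fdr_level = 0.05, score_threshold = 0.7,
                        embedding = NULL, embedding_control = n2v_control(),
                        lr = 1e-3, max_epochs = 1000L, patience = 100L,
                        seed = 1L, keep_models = TRUE, verbose = FALSE) {
  stopifnot(inherits(graph, "gene_graph"), inherits(features, "feature_matrix"),
            inherits(labels, "label_set"))
  spec <- if (inherits(classifier, "arch_spec")) classifier else classifier_spec(classifier)
  if (is.null(features$scaling)) features <- scale_features_robust(features)
  X <- features$values
  if (spec$needs_embedding) {
    if (is.null(embedding)) {
      embedding <- embed_networks_randomwalk(graph, embedding_control, seed = seed)
    }
    X <- augment_features(X, embedding)
  }
  nuni <- n_genes(graph)
  pos <- labels$positives
  unlabeled <- setdiff(seq_len(nuni), pos)
  plan <- plan_nested_folds(pos, m = m, n = n, seed = seed)
  fold_sets <- vector("list", m)
  diagnostics <- vector("list", m)
  thresholds <- integer(m)
  models <- if (keep_models) vector("list", m) else NULL
  for (j in seq_len(m)) {
    test_j <- plan$test[[j]]
    train_j <- setdiff(pos, test_j)
    negatives <- sort(c(unlabeled, test_j))     # option (2): test positives train as class 0
    scored <- sort(c(unlabeled, test_j))        # unlabeled genes plus the fold's test positives
    calls <- matrix(0L, nuni, n)
    call_counts <- integer(n)
    if (keep_models) models[[j]] <- vector("list", n)
    for (i in seq_len(n)) {
      val_ji <- plan$val[[j]][[i]]
      train_ji <- setdiff(train_j, val_ji)
      mseed <- seed + 97L * j + i
      model <- build_model(spec, graph, ncol(X), seed = mseed)
      fit <- fit_model(model, X, train_ji, val_ji, negatives, cfg = cfg, lr = lr,
                       max_epochs = max_epochs, patience = patience,
                       score_threshold = score_threshold, seed = mseed)
      s <- forward_classifier(fit$model, X)
      calls[, i] <- binarize_predictions(s, score_threshold)
      call_counts[i] <- sum(calls[scored, i])
      if (keep_models) models[[j]][[i]] <- fit$model
    }
    conc <- concordance(calls)
    observed <- tabulate(conc[test_j], nbins = n)
    bg <- background_concordance(call_counts, length(scored), length(test_j),
                                 B = B, seed = seed + 7919L * j)
    sel <- select_inner_threshold(observed, bg, fdr_level = fdr_level)
    thresholds[j] <- sel$threshold
    fold_sets[[j]] <- fold_candidates(conc, sel$threshold, pos)
    diagnostics[[j]] <- cbind(fold = j, sel$diagnostics)
    if (verbose) {
      message("fold ", j, "/", m, ": inner threshold ",
              ifelse(is.na(sel$threshold), "none", sel$threshold), ", ",
              length(fold_sets[[j]]), " candidates")
    }
  }
  consensus <- consensus_score(fold_sets, nuni, pos)
  structure(list(consensus = consensus, plan = plan,
                 thresholds = thresholds,
                 diagnostics = do.call(rbind, diagnostics),
                 universe = graph$universe, labels = labels, spec = spec,
                 cfg = cfg, models = models, score_threshold = score_threshold,
                 B = B, fdr_level = fdr_level, seed = seed,
                 features_scaled = features, embedding = embedding,
                 graph = graph, X_input = X),
            class = "pu_ensemble")
}

#' @export
print.pu_ensemble <- function(x, ...) {
  cat("Positive-unlabeled nested cross-validation ensemble\n")
  cat("  classifier:      ", x$spec$mp_kind,
      if (x$spec$needs_embedding) " (+ random-walk embeddings)", "\n", sep = "")
  cat("  ensemble shape:  m = ", x$plan$m, " outer folds x n = ", x$plan$n,
      " inner models\n", sep = "")
  cat("  positives:       ", length(x$labels$positives), "\n", sep = "")
  cat("  candidates:      ", sum(x$consensus$flag == "candidate"),
      " of ", sum(x$consensus$flag != "positive-label"), " unlabeled genes\n", sep = "")
  cat("  inner thresholds:", paste(ifelse(is.na(x$thresholds), "none", x$thresholds),
                                   collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.pu_ensemble <- function(object, ...) {
  cs <- object$consensus$cs
  tab <- table(factor(cs[!is.na(cs)], levels = 0:object$plan$m))
  out <- list(cs_table = tab, thresholds = object$thresholds,
              n_candidates = sum(object$consensus$flag == "candidate"),
              m = object$plan$m, n = object$plan$n)
  class(out) <- "summary.pu_ensemble"
  out
}

#' @export
print.summary.pu_ensemble <- function(x, ...) {
  cat("Consensus score distribution (unlabeled genes):\n")
  print(x$cs_table)
  cat("Inner thresholds per fold:",
      paste(ifelse(is.na(x$thresholds), "none", x$thresholds), collapse = " "), "\n")
  invisible(x)
}

#' Extract per-gene predictions from a fitted ensemble
#'
#' @param object a `pu_ensemble`.
#' @param type `"consensus"` for a data.frame of gene, consensus score and
#'   flag; `"score"` for the mean raw classifier score across all inner
#'   models.
#' @param ... unused.
#' @return data.frame (`"consensus"`) or numeric vector (`"score"`).
#' @export
predict.pu_ensemble <- function(object, type = c("consensus", "score"), ...) {
  type <- match.arg(type)
  if (type == "consensus") {
    return(data.frame(gene = object$universe$genes,
                      cs = object$consensus$cs,
                      flag = object$consensus$flag))
  }
  if (is.null(object$models)) stop("ensemble was fitted with keep_models = FALSE")
  s <- rowMeans(vapply(unlist(object$models, recursive = FALSE),
                       function(mod) forward_classifier(mod, object$X_input),
                       numeric(length(object$universe$genes))))
  stats::setNames(s, object$universe$genes)
}

#' Plot threshold diagnostics of a fitted ensemble
#'
#' Observed test-positive overlap per concordance bin against the
#' background mean (+/- one standard deviation), one panel row per fold.
#'
#' @param x a `pu_ensemble`.
#' @param folds which outer folds to show (default first).
#' @param ... passed to [graphics::barplot()].
#' @export
plot.pu_ensemble <- function(x, folds = 1L, ...) {
  d <- x$diagnostics
  old <- graphics::par(mfrow = c(length(folds), 1L), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (j in folds) {
    dj <- d[d$fold == j, ]
    hh <- rbind(observed = dj$observed, background = dj$bg_mean)
    bp <- graphics::barplot(hh, beside = TRUE, names.arg = dj$bin,
                            legend.text = rownames(hh),
                            xlab = "inner concordance bin",
                            ylab = "test positives", main = paste("fold", j), ...)
    graphics::arrows(bp[2L, ], pmax(dj$bg_mean - dj$bg_sd, 0),
                     bp[2L, ], dj$bg_mean + dj$bg_sd,
                     angle = 90, code = 3, length = 0.02)
  }
  invisible(x)
}
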