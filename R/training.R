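# Positive-unlabeled training: loss, dilution sampling, fitting with early
# stopping, binarization, and the method-selection cross-validation harness.

#' Loss configuration
#'
#' Two PU-specific loss modifications: *dilution* downsamples the unlabeled
#' "negatives" each epoch to `|P_train| * d` genes drawn uniformly with
#' replacement, and *amplification* multiplies the positive binary
#' cross-entropy by `a`, making false negatives `a` times more costly than
#' false positives.
#'
#' @param d dilution factor (positive integer, default 10).
#' @param a amplification factor (positive real, default 2).
#' @return object of class `loss_config`.
#' @export
loss_config <- function(d = 10L, a = 2) {
  stopifnot(d >= 1, a > 0)
  structure(list(d = as.integer(d), a = a), class = "loss_config")
}

#' Sample the diluted unlabeled multiset
#'
#' Draws `P_train_size * d` unlabeled genes uniformly with replacement; a
#' fresh draw is taken every training epoch so that every unlabeled gene
#' contributes occasionally without dominating the loss.
#'
#' @param unlabeled integer vector of unlabeled gene positions.
#' @param P_train_size number of training positives.
#' @param d dilution factor.
#' @param seed optional seed (omit inside a training loop that manages its
#'   own RNG stream).
#' @return integer vector of length `P_train_size * d` (duplicates allowed).
#' @export
sample_diluted_unlabeled <- function(unlabeled, P_train_size, d, seed = NULL) {
  if (length(unlabeled) == 0L) stop("unlabeled set must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  unlabeled[sample.int(length(unlabeled), P_train_size * d, replace = TRUE)]
}

clamp_scores <- function(s, eps = 1e-7) pmin(pmax(s, eps), 1 - eps)

#' L1 penalty of a LINKX model
#'
#' `l1_alpha * ||W||_1` over the first adjacency-branch weight matrix;
#' added to the training loss to curb overfitting of the large first
#' layer. Zero for any other architecture.
#'
#' @param model a `pu_model`.
#' @return non-negative scalar.
#' @export
linkx_l1_penalty <- function(model) {
  if (model$spec$mp_kind != "linkx") return(0)
  model$spec$l1_alpha * sum(abs(model$params$A1_W))
}

#' Positive-unlabeled loss
#'
#' `L = sum_u BCE(0, s_u) / d + a * sum_p BCE(1, s_p)` over the sampled
#' unlabeled multiset and the training positives. Scores are clamped to
#' `[1e-7, 1 - 1e-7]` to keep the cross-entropy finite.
#'
#' @param pos_scores scores of the training positives, in (0, 1).
#' @param sampled_unlabeled_scores scores of the diluted unlabeled sample.
#' @param cfg a [loss_config()].
#' @return non-negative scalar loss.
#' @export
pu_loss <- function(pos_scores, sampled_unlabeled_scores, cfg = loss_config()) {
  if (length(pos_scores) == 0L) stop("pu_loss requires a non-empty positive set")
  sp <- clamp_scores(pos_scores)
  su <- clamp_scores(sampled_unlabeled_scores)
  sum(-log(1 - su)) / cfg$d + cfg$a * sum(-log(sp))
}

#' Binarize prediction scores
#'
#' A gene is called positive iff its score strictly exceeds the threshold
#' (a score of exactly 0.7 maps to 0).
#'
#' @param scores numeric scores in `[0, 1]`.
#' @param threshold decision threshold (default 0.7).
#' @return integer vector of 0/1 calls.
#' @export
binarize_predictions <- function(scores, threshold = 0.7) {
  as.integer(scores > threshold)
}

#' Area under the ROC curve
#'
#' Rank-statistic form (equivalent to the normalized Wilcoxon statistic);
#' ties share ranks.
#'
#' @param scores numeric scores.
#' @param labels 0/1 vector, 1 = positive.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0L || nn == 0L) stop("auroc needs both classes")
  r <- rank(scores)
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

#' Fit a single base classifier
#'
#' Full-batch gradient training of the PU objective with the Adam optimizer
#' (learning rate 1e-3). Every epoch resamples the diluted unlabeled set.
#' Overfitting is monitored with `f1 = 2 * pr * rec / (pr + rec)` combining
#' precision on the training pool (train positives plus all training
#' negatives, binarized at the score threshold) with recall on the
#' positives-only holdout; the weights of the best epoch are retained, and
#' training stops after `patience` epochs without strict improvement or at
#' `max_epochs`.
#'
#' @param model a [build_model()] result (its weights are the starting point).
#' @param X input feature matrix.
#' @param train_positives integer positions of training positives.
#' @param holdout_positives integer positions of the positives-only early
#'   stopping holdout (disjoint from `train_positives`).
#' @param negatives integer positions treated as class 0 (all unlabeled
#'   genes; under the nested CV this includes the outer test positives).
#' @param cfg a [loss_config()].
#' @param lr learning rate (default 1e-3).
#' @param max_epochs epoch cap (default 1000).
#' @param patience early-stopping patience (default 100).
#' @param score_threshold binarization threshold for the monitor.
#' @param seed seed fixing the weight-independent sampling stream.
#' @param edge_weights optional fixed edge weights during training.
#' @return list with `model` (best weights), `state` (epochs run, best
#'   epoch, best monitor value, loss history).
#' @export
fit_model <- function(model, X, train_positives, holdout_positives, negatives,
                      cfg = loss_config(), lr = 1e-3, max_epochs = 1000L,
                      patience = 100L, score_threshold = 0.7, seed = 1L,
                      edge_weights = NULL) {
  stopifnot(length(intersect(train_positives, holdout_positives)) == 0L,
            length(train_positives) > 0L, length(negatives) > 0L)
  set.seed(seed)
  P <- model$params
  opt <- adam_init(P)
  best <- list(f1 = -Inf, epoch = 0L, params = P)
  loss_hist <- numeric(0)
  train_pool <- c(train_positives, negatives)
  n_pos <- length(train_positives)
  for (epoch in seq_len(max_epochs)) {
    u_sampled <- sample_diluted_unlabeled(negatives, n_pos, cfg$d)
    fw <- model_forward(model, X, edge_weights, want_cache = TRUE)
    s <- fw$score
    loss <- pu_loss(s[train_positives], s[u_sampled], cfg) + linkx_l1_penalty(model)
    if (!is.finite(loss)) {
      stop("fit_model: divergent (non-finite) loss at epoch ", epoch,
           "; consider lowering the learning rate")
    }
    loss_hist[epoch] <- loss
    # d BCE / d logit = (score - label), weighted per Eq-style dilution/amplification
    dlogit <- numeric(length(s))
    dlogit[train_positives] <- dlogit[train_positives] + cfg$a * (s[train_positives] - 1)
    tab <- tabulate(u_sampled, nbins = length(s))
    dlogit <- dlogit + tab * s / cfg$d
    bw <- model_backward(model, fw$cache, dlogit)
    if (model$spec$mp_kind == "linkx") {
      bw$grads$A1_W <- bw$grads$A1_W + model$spec$l1_alpha * sign(model$params$A1_W)
    }
    step <- adam_step(model$params, bw$grads, opt, lr = lr)
    model$params <- step$params
    opt <- step$state
    calls <- binarize_predictions(s, score_threshold)
    called_pool <- sum(calls[train_pool])
    pr <- if (called_pool == 0L) 0 else sum(calls[train_positives]) / called_pool
    rec <- if (length(holdout_positives) == 0L) 1 else mean(calls[holdout_positives])
    f1 <- if (pr + rec == 0) 0 else 2 * pr * rec / (pr + rec)
    if (f1 > best$f1) {
      best <- list(f1 = f1, epoch = epoch, params = model$params)
    }
    if (epoch - best$epoch >= patience) break
  }
  model$params <- best$params
  list(model = model,
       state = list(epochs = epoch, best_epoch = best$epoch, best_f1 = best$f1,
                    loss = loss_hist))
}

#' Method-selection cross-validation
#'
#' Benchmarks a base classifier by `folds`-fold cross-validation with
#' `repeats` repetitions per fold (default 4 x 4 = 16 models). Each fold
#' holds out 25% of both positive and unlabeled genes; unlabeled genes are
#' assumed negative and performance is the AUROC of the held-out positives
#' against the held-out unlabeled genes. A tenth of the training positives
#' is carved out per model as the positives-only early-stopping holdout.
#'
#' @param spec an [arch_spec()] (or [classifier_spec()] result).
#' @param graph a `gene_graph`.
#' @param X input feature matrix (already scaled, embedding concatenated if
#'   the method needs it).
#' @param labels a `label_set`.
#' @param folds,repeats cross-validation shape (defaults 4 and 4).
#' @param cfg a [loss_config()].
#' @param seed integer seed.
#' @param ... passed on to [fit_model()] (e.g. `max_epochs`, `patience`).
#' @return list with `mean_auroc` and `results` (data.frame: fold, repeat,
#'   auroc).
#' @export
crossval_auroc <- function(spec, graph, X, labels, folds = 4L, repeats = 4L,
                           cfg = loss_config(), seed = 1L, ...) {
  n <- n_genes(graph)
  pos <- labels$positives
  unl <- setdiff(seq_len(n), pos)
  if (length(pos) < folds) stop("need at least one positive per fold")
  set.seed(seed)
  fold_pos <- split(sample(pos), rep_len(seq_len(folds), length(pos)))
  fold_unl <- split(sample(unl), rep_len(seq_len(folds), length(unl)))
  res <- NULL
  for (f in seq_len(folds)) {
    test_pos <- fold_pos[[f]]
    test_unl <- fold_unl[[f]]
    train_pos_all <- setdiff(pos, test_pos)
    train_unl <- setdiff(unl, test_unl)
    for (r in seq_len(repeats)) {
      mseed <- seed + 1000L * f + r
      set.seed(mseed)
      n_val <- max(1L, floor(length(train_pos_all) / 10))
      val_pos <- sample(train_pos_all, n_val)
      tr_pos <- setdiff(train_pos_all, val_pos)
      model <- build_model(spec, graph, ncol(X), seed = mseed)
      fit <- fit_model(model, X, tr_pos, val_pos, train_unl, cfg = cfg,
                       seed = mseed, ...)
      s <- forward_classifier(fit$model, X)
      hold <- c(test_pos, test_unl)
      a <- auroc(s[hold], c(rep(1L, length(test_pos)), rep(0L, length(test_unl))))
      res <- rbind(res, data.frame(fold = f, rep = r, auroc = a))
    }
  }
  list(mean_auroc = mean(res$auroc), results = res)
}
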