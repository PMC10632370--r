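# Model interpretation: integrated-gradients attributions for the edges and
# node features behind a query gene's prediction, aggregated over all models
# of the ensemble by per-model minmax scaling and averaging.

#' Integrated gradients along a straight path
#'
#' Approximates `(x_i - baseline_i) * integral_0^1 dF/dx_i(baseline +
#' alpha (x - baseline)) d alpha` with a midpoint Riemann sum. Satisfies
#' the completeness axiom (`sum(attribution) = F(x) - F(baseline)`) up to
#' discretization error, exactly for linear `F`.
#'
#' @param grad_fun function taking an input like `x` and returning the
#'   gradient of the scalar model output at that point (same shape as `x`).
#' @param x input point (numeric vector or matrix).
#' @param baseline contrast point (default: zeros).
#' @param steps Riemann-sum resolution (default 64; must be >= 2).
#' @return attributions with the shape of `x`.
#' @export
integrated_gradients <- function(grad_fun, x, baseline = NULL, steps = 64L) {
  if (steps < 2L) stop("integrated_gradients requires steps >= 2")
  if (is.null(baseline)) baseline <- x * 0
  stopifnot(length(baseline) == length(x))
  diff <- x - baseline
  acc <- x * 0
  for (k in seq_len(steps)) {
    alpha <- (k - 0.5) / steps
    acc <- acc + grad_fun(baseline + alpha * diff)
  }
  diff * acc / steps
}

# gradient of the query gene's *score* wrt the input feature matrix
score_grad_features <- function(model, gene, edge_weights = NULL) {
  function(Xp) {
    fw <- model_forward(model, Xp, edge_weights, want_cache = TRUE)
    dlogit <- numeric(length(fw$score))
    dlogit[gene] <- fw$score[gene] * (1 - fw$score[gene])
    model_backward(model, fw$cache, dlogit, want_input = TRUE)$dX
  }
}

# gradient of the query gene's score wrt the global edge-weight vector
score_grad_edges <- function(model, gene, X) {
  function(w) {
    fw <- model_forward(model, X, w, want_cache = TRUE)
    dlogit <- numeric(length(fw$score))
    dlogit[gene] <- fw$score[gene] * (1 - fw$score[gene])
    bw <- model_backward(model, fw$cache, dlogit, want_edges = TRUE)
    if (is.null(bw$dw)) numeric(length(w)) else bw$dw
  }
}

#' Attribute a prediction to node features
#'
#' Integrated gradients of the query gene's score with respect to the full
#' input feature matrix, against an all-zero baseline.
#'
#' @param model a `pu_model`.
#' @param X input feature matrix used by the model.
#' @param gene query gene position.
#' @param steps Riemann-sum resolution.
#' @return attribution matrix (n x p): row `gene` carries the gene's own
#'   feature attributions, other rows those of its (multi-hop) neighbors.
#' @export
attribute_features <- function(model, X, gene, steps = 64L) {
  integrated_gradients(score_grad_features(model, gene), as.matrix(X), steps = steps)
}

#' Attribute a prediction to edges
#'
#' Every edge carries a multiplicative weight: 1 leaves message passing
#' unchanged, 0 removes the edge. Integrated gradients of the query gene's
#' score with respect to all edge weights against the zero (edge-free)
#' contrast. Graph-free classifiers yield all-zero attributions.
#'
#' @param model a `pu_model`.
#' @param X input feature matrix used by the model.
#' @param gene query gene position.
#' @param steps Riemann-sum resolution.
#' @return numeric vector of per-edge attributions (global edge order,
#'   see `model$ctx$edge_table`).
#' @export
attribute_edges <- function(model, X, gene, steps = 64L) {
  nE <- model$ctx$n_edges
  if (nE == 0L) return(numeric(0))
  integrated_gradients(score_grad_edges(model, gene, as.matrix(X)),
                       rep(1, nE), baseline = rep(0, nE), steps = steps)
}

# minmax to [0,1]; a zero range maps to all zeros
minmax01 <- function(x) {
  r <- range(x)
  if (r[2L] - r[1L] == 0) return(x * 0)
  (x - r[1L]) / (r[2L] - r[1L])
}

# signed minmax to [-1,1]: scale |x| to [0,1], reapply the sign
minmax_signed <- function(x) minmax01(abs(x)) * sign(x)

#' Aggregate per-model attributions into ensemble importances
#'
#' Per model, absolute edge attributions are minmax-scaled across the full
#' edge set and absolute per-node attributions (summed over each node's
#' feature dimensions) across the node set; the ensemble importance is the
#' mean of the scaled values, so an edge ranked top by every model scores
#' near 1 and one ranked bottom near 0. The query gene's own feature
#' attributions keep their sign and are minmax-scaled across its p
#' dimensions into `[-1, 1]`.
#'
#' @param edge_attr list (one per model) of per-edge attribution vectors.
#' @param feature_attr list (one per model) of n x p attribution matrices
#'   from [attribute_features()].
#' @param gene query gene position.
#' @return object of class `importance_report`: list with `edge` (per-edge
#'   importance in `[0, 1]`), `node` (per-node neighbor importance in
#'   `[0, 1]`), `self` (signed per-feature importance in `[-1, 1]`).
#' @export
aggregate_ensemble_importance <- function(edge_attr, feature_attr, gene) {
  stopifnot(length(edge_attr) == length(feature_attr), length(edge_attr) >= 1L)
  k <- length(edge_attr)
  edge <- if (length(edge_attr[[1L]]) > 0L) {
    Reduce(`+`, lapply(edge_attr, function(a) minmax01(abs(a)))) / k
  } else numeric(0)
  node <- Reduce(`+`, lapply(feature_attr, function(A) minmax01(rowSums(abs(A))))) / k
  self <- Reduce(`+`, lapply(feature_attr, function(A) minmax_signed(A[gene, ]))) / k
  structure(list(edge = edge, node = node, self = self, gene = gene,
                 n_models = k),
            class = "importance_report")
}

#' @export
print.importance_report <- function(x, ...) {
  cat("<importance_report> query gene position ", x$gene, ", ", x$n_models,
      " models; ", length(x$edge), " edges, ", length(x$node), " nodes\n", sep = "")
  invisible(x)
}

#' Interpret an ensemble prediction for one gene
#'
#' Runs integrated gradients for every trained inner model of a fitted
#' ensemble and aggregates edge and feature importances.
#'
#' @param fit a [pu_ensemble()] result fitted with `keep_models = TRUE`.
#' @param gene gene identifier or position to interpret.
#' @param steps Riemann-sum resolution per model (default 64).
#' @return list with `edges` (data.frame: source, target, network,
#'   importance), `features` (data.frame: feature, importance, value) and
#'   the raw `importance_report`.
#' @export
interpret_ensemble <- function(fit, gene, steps = 64L) {
  stopifnot(inherits(fit, "pu_ensemble"))
  if (is.null(fit$models)) stop("ensemble was fitted with keep_models = FALSE")
  if (is.character(gene)) {
    gi <- unname(fit$universe$index[gene])
    if (is.na(gi)) stop("unknown gene: ", gene)
  } else gi <- as.integer(gene)
  models <- unlist(fit$models, recursive = FALSE)
  X <- fit$X_input
  edge_attr <- lapply(models, function(m) attribute_edges(m, X, gi, steps))
  feat_attr <- lapply(models, function(m) attribute_features(m, X, gi, steps))
  rep_ <- aggregate_ensemble_importance(edge_attr, feat_attr, gi)
  et <- models[[1L]]$ctx$edge_table
  edges <- if (nrow(et) > 0L) {
    data.frame(source = fit$universe$genes[et$source],
               target = fit$universe$genes[et$target],
               network = et$network, importance = rep_$edge)
  } else data.frame(source = character(0), target = character(0),
                    network = character(0), importance = numeric(0))
  features <- data.frame(feature = colnames(X), importance = rep_$self,
                         value = X[gi, ])
  list(edges = edges[order(-abs(edges$importance)), , drop = FALSE],
       features = features[order(-abs(features$importance)), , drop = FALSE],
       report = rep_)
}
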