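# Message-passing layers and their supporting graph operators.
#
# All layers operate on a node-feature matrix X (n x h, rows = genes) and a
# gene_graph. Edges carry a multiplicative weight (1 by default) so that the
# interpretation machinery can differentiate a model's output with respect to
# edge presence; degree normalizations are always computed on the unweighted
# graph, so a weight of 1 reproduces the textbook layer exactly and a weight
# of 0 removes the edge's message.

#' Merge all edge sets of a graph into one relation
#'
#' @param graph a `gene_graph`.
#' @return integer matrix (edges x 2) of directed source -> target pairs.
#' @export
merged_edges <- function(graph) {
  if (length(graph$edge_sets) == 0L) return(matrix(integer(0), ncol = 2L,
                                                  dimnames = list(NULL, c("source", "target"))))
  do.call(rbind, unname(graph$edge_sets))
}

# Symmetrically normalized adjacency with self-loops:
# S = D^{-1/2} (A + I) D^{-1/2}, D = degree matrix of (A + I).
# S[v, u] carries the message u -> v. Entries belonging to real edges are
# scaled by `weights`; the self-loop entries are fixed at 1 (they encode the
# layer's own skip, not an input edge).
gcn_operator <- function(n, edges, weights = NULL) {
  nE <- nrow(edges)
  if (is.null(weights)) weights <- rep(1, nE)
  stopifnot(length(weights) == nE)
  src <- edges[, 1L]; tgt <- edges[, 2L]
  # binary (A + I), duplicate typed edges collapse for degree purposes
  ii <- c(tgt, seq_len(n)); jj <- c(src, seq_len(n))
  A1 <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  A1@x[] <- pmin(A1@x, 1)
  deg <- Matrix::rowSums(A1)
  dinv <- 1 / sqrt(pmax(deg, 1))
  norm_edge <- dinv[tgt] * dinv[src]
  norm_self <- dinv * dinv
  S <- Matrix::sparseMatrix(i = ii, j = jj,
                            x = c(norm_edge * weights, norm_self),
                            dims = c(n, n))
  list(S = S, edges = edges, norm_edge = norm_edge, weights = weights)
}

# Mean-normalized per-relation operator for RGCN: S_r[v, u] = w_e / |N_r(v)|,
# no self-loop (the root weight handles the node itself).
rgcn_operator <- function(n, edges, weights = NULL) {
  nE <- nrow(edges)
  if (is.null(weights)) weights <- rep(1, nE)
  src <- edges[, 1L]; tgt <- edges[, 2L]
  indeg <- tabulate(tgt, nbins = n)
  norm_edge <- 1 / pmax(indeg[tgt], 1)
  S <- Matrix::sparseMatrix(i = tgt, j = src, x = norm_edge * weights, dims = c(n, n))
  list(S = S, edges = edges, norm_edge = norm_edge, weights = weights)
}

#' Graph convolution (GCN) layer
#'
#' Computes `S X W` with `S = D^{-1/2}(A + I)D^{-1/2}`, the symmetrically
#' normalized adjacency with self-loops; `D` is the degree matrix of
#' `(A + I)`. Isolated nodes keep a self-loop of weight 1 and therefore map
#' to their own projected features.
#'
#' @param X numeric node-feature matrix (n x h_in).
#' @param graph a `gene_graph`; all its edge sets are merged into a single
#'   relation (GCN is not edge-type aware).
#' @param W weight matrix (h_in x h_out).
#' @param edge_weights optional per-edge multiplicative weights aligned with
#'   the rows of [merged_edges()].
#' @return numeric matrix (n x h_out).
#' @export
layer_gcn <- function(X, graph, W, edge_weights = NULL) {
  X <- as.matrix(X)
  if (nrow(X) != n_genes(graph)) stop("X rows must match the graph's universe")
  if (nrow(W) != ncol(X)) stop("shape mismatch: ncol(X) != nrow(W)")
  op <- gcn_operator(nrow(X), merged_edges(graph), edge_weights)
  as.matrix(op$S %*% X %*% W)
}

#' Topology-adaptive graph convolution (TAG) layer
#'
#' Computes `sum_{k=0..K} S^k X W_k` with the same normalized operator `S`
#' as [layer_gcn()]. The k = 0 term is the skip connection (`S^0 = I`), so a
#' graph without edges reduces to a sum of dense projections.
#'
#' @param X numeric node-feature matrix.
#' @param graph a `gene_graph` (edge sets merged).
#' @param W_list list of K + 1 weight matrices, one per hop `k = 0..K`.
#' @param edge_weights optional per-edge weights.
#' @return numeric matrix (n x h_out).
#' @export
layer_tag <- function(X, graph, W_list, edge_weights = NULL) {
  X <- as.matrix(X)
  K <- length(W_list) - 1L
  if (K < 0L) stop("W_list must contain at least the k = 0 weight")
  op <- gcn_operator(nrow(X), merged_edges(graph), edge_weights)
  P <- X
  out <- P %*% W_list[[1L]]
  if (K > 0L) for (k in seq_len(K)) {
    P <- as.matrix(op$S %*% P)
    out <- out + P %*% W_list[[k + 1L]]
  }
  out
}

#' Relational graph convolution (RGCN) layer
#'
#' `x_v' = W_root x_v + sum_r sum_{u in N_r(v)} W_r x_u / |N_r(v)|`.
#' Relations with an empty neighborhood contribute zero; a node with no
#' neighbors in any relation keeps only its root projection.
#'
#' @param X numeric node-feature matrix.
#' @param graph a `gene_graph`; each named edge set is one relation.
#' @param W_r named list of per-relation weight matrices (h_in x h_out).
#' @param W_root root weight matrix (h_in x h_out).
#' @param edge_weights optional named list of per-edge weights per relation.
#' @return numeric matrix (n x h_out).
#' @export
layer_rgcn <- function(X, graph, W_r, W_root, edge_weights = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  out <- X %*% W_root
  for (nw in names(graph$edge_sets)) {
    e <- graph$edge_sets[[nw]]
    if (nrow(e) == 0L) next
    op <- rgcn_operator(n, e, edge_weights[[nw]])
    out <- out + as.matrix(op$S %*% X %*% W_r[[nw]])
  }
  out
}

#' Feature-wise linear modulation (FiLM) layer
#'
#' `x_v' = sum_r sum_{u in N_r(v)} relu(gamma_{r,v} * (W_r x_u) + beta_{r,v})`,
#' with the per-receiver, per-relation modulation `(beta, gamma)` produced by
#' a single-linear-layer hypernetwork `[beta gamma] = x_v W_{g,r} + b_{g,r}`.
#' The neighborhood aggregation is a plain (unnormalized) sum and the inner
#' nonlinearity is the rectifier, following the layer's defining equation;
#' ELU is only applied between stacked layers.
#'
#' @param X numeric node-feature matrix.
#' @param graph a `gene_graph`; each named edge set is one relation.
#' @param W_r named list of message weights (h_in x h_out).
#' @param W_g named list of hypernetwork weights (h_in x 2 h_out); columns
#'   `1..h_out` produce beta, columns `h_out+1..2 h_out` produce gamma.
#' @param b_g optional named list of hypernetwork biases (length 2 h_out).
#' @param edge_weights optional named list of per-edge weights per relation.
#' @return numeric matrix (n x h_out).
#' @export
layer_film <- function(X, graph, W_r, W_g, b_g = NULL, edge_weights = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  h_out <- ncol(W_r[[1L]])
  out <- matrix(0, n, h_out)
  for (nw in names(graph$edge_sets)) {
    e <- graph$edge_sets[[nw]]
    if (nrow(e) == 0L) next
    w <- edge_weights[[nw]]
    if (is.null(w)) w <- rep(1, nrow(e))
    BG <- X %*% W_g[[nw]]
    if (!is.null(b_g[[nw]])) BG <- sweep(BG, 2L, b_g[[nw]], "+")
    beta <- BG[, seq_len(h_out), drop = FALSE]
    gamma <- BG[, h_out + seq_len(h_out), drop = FALSE]
    src <- e[, 1L]; tgt <- e[, 2L]
    M <- X[src, , drop = FALSE] %*% W_r[[nw]]
    Z <- gamma[tgt, , drop = FALSE] * M + beta[tgt, , drop = FALSE]
    R <- pmax(Z, 0) * w
    agg <- Matrix::sparseMatrix(i = tgt, j = seq_along(tgt), x = 1, dims = c(n, length(tgt)))
    out <- out + as.matrix(agg %*% R)
  }
  out
}

#' Instance normalization across nodes
#'
#' Centers and scales every feature channel across the node dimension to
#' mean 0 and variance 1 (population variance, epsilon-guarded). No learned
#' affine transform. Constant channels map to zeros.
#'
#' @param X numeric node-feature matrix (>= 2 rows).
#' @param eps variance guard (default 1e-5).
#' @return normalized matrix of the same shape.
#' @export
normalize_instance <- function(X, eps = 1e-5) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("instance normalization needs >= 2 nodes")
  mu <- colMeans(X)
  v <- colMeans(X^2) - mu^2
  sweep(sweep(X, 2L, mu, "-"), 2L, sqrt(pmax(v, 0) + eps), "/")
}

#' Exponential linear unit
#' @param x numeric input.
#' @return elementwise ELU: `x` for positive entries, `exp(x) - 1` otherwise.
#' @export
elu <- function(x) pmax(x, 0) + expm1(pmin(x, 0))

sigmoid <- function(x) 1 / (1 + exp(-x))
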