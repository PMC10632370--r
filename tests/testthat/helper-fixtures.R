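# Shared fixtures and independent brute-force oracles.

# random multi-relation gene_graph on n nodes
rand_graph <- function(n, n_rel = 1L, p_edge = 0.3, directed = FALSE, seed = 1L) {
  set.seed(seed)
  uni <- gene_universe(paste0("g", seq_len(n)))
  records <- NULL
  for (r in seq_len(n_rel)) {
    pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    keep <- stats::runif(nrow(pairs)) < p_edge
    pr <- pairs[keep, , drop = FALSE]
    if (nrow(pr) > 0L) {
      records <- rbind(records, data.frame(
        source = paste0("g", pr[, 1L]), target = paste0("g", pr[, 2L]),
        network = paste0("net", r), directed = directed))
    } else {
      records <- rbind(records, data.frame(
        source = "g1", target = "g2", network = paste0("net", r), directed = directed))
    }
  }
  assemble_graph(records, uni)
}

# dense normalized operator D^{-1/2}(A+I)D^{-1/2} with multiplicative
# edge weights on the off-diagonal entries (degrees from the binary graph)
dense_gcn_operator <- function(n, edges, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(edges))
  Abin <- diag(n)
  for (e in seq_len(nrow(edges))) Abin[edges[e, 2L], edges[e, 1L]] <- 1
  deg <- rowSums(Abin)
  Dm <- diag(1 / sqrt(deg))
  # weighted (A + I): self-loops fixed at 1; parallel typed edges each add
  # their own message (degrees still from the binary union)
  Aw <- diag(n)
  for (e in seq_len(nrow(edges))) {
    Aw[edges[e, 2L], edges[e, 1L]] <- Aw[edges[e, 2L], edges[e, 1L]] + weights[e]
  }
  Dm %*% Aw %*% Dm
}

dense_gcn_oracle <- function(X, graph, W, weights = NULL) {
  e <- merged_edges(graph)
  S <- dense_gcn_operator(nrow(X), e, weights)
  S %*% X %*% W
}

dense_tag_oracle <- function(X, graph, W_list, weights = NULL) {
  e <- merged_edges(graph)
  S <- dense_gcn_operator(nrow(X), e, weights)
  out <- matrix(0, nrow(X), ncol(W_list[[1L]]))
  P <- diag(nrow(X))
  for (k in seq_along(W_list)) {
    out <- out + P %*% X %*% W_list[[k]]
    P <- S %*% P
  }
  out
}

dense_rgcn_oracle <- function(X, graph, W_r, W_root) {
  n <- nrow(X)
  out <- X %*% W_root
  for (nw in names(graph$edge_sets)) {
    e <- graph$edge_sets[[nw]]
    if (nrow(e) == 0L) next
    for (v in seq_len(n)) {
      nb <- e[e[, 2L] == v, 1L]
      if (length(nb) == 0L) next
      acc <- 0
      for (u in nb) acc <- acc + X[u, ] %*% W_r[[nw]]
      out[v, ] <- out[v, ] + acc / length(nb)
    }
  }
  out
}

dense_film_oracle <- function(X, graph, W_r, W_g, b_g = NULL) {
  n <- nrow(X)
  h <- ncol(W_r[[1L]])
  out <- matrix(0, n, h)
  for (nw in names(graph$edge_sets)) {
    e <- graph$edge_sets[[nw]]
    if (nrow(e) == 0L) next
    for (v in seq_len(n)) {
      bg <- drop(X[v, ] %*% W_g[[nw]])
      if (!is.null(b_g[[nw]])) bg <- bg + b_g[[nw]]
      beta <- bg[seq_len(h)]; gamma <- bg[h + seq_len(h)]
      nb <- e[e[, 2L] == v, 1L]
      for (u in nb) {
        out[v, ] <- out[v, ] + pmax(gamma * drop(X[u, ] %*% W_r[[nw]]) + beta, 0)
      }
    }
  }
  out
}

# two-sided Fisher p by full hypergeometric enumeration of tables with the
# observed margins (probability-mass comparison, as in the exact test)
fisher_p_enumeration <- function(a, b, c_, d) {
  m1 <- a + b; m2 <- c_ + d; k <- a + c_
  lo <- max(0L, k - m2); hi <- min(k, m1)
  probs <- stats::dhyper(lo:hi, m1, m2, k)
  p_obs <- stats::dhyper(a, m1, m2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# tiny deterministic two-clique graph for embedding tests
two_clique_graph <- function() {
  uni <- gene_universe(paste0("g", 1:10))
  pairs <- rbind(t(utils::combn(1:5, 2L)), t(utils::combn(6:10, 2L)), c(5L, 6L))
  records <- data.frame(source = paste0("g", pairs[, 1L]),
                        target = paste0("g", pairs[, 2L]),
                        network = "ppi", directed = FALSE)
  assemble_graph(records, uni)
}
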