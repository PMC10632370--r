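# Unsupervised random-walk node embeddings (node2vec-style).
#
# All networks are merged into one untyped edge set, unbiased random walks
# (return and in-out parameters both 1) are started from every node, and a
# skip-gram model with negative sampling is trained on the (center, context)
# pairs. Isolated nodes take part in no walk and receive zero vectors.

#' Control parameters for the random-walk embedding
#'
#' Defaults mirror the conventional setting for gene networks: context
#' window 5, 100 dimensions, walk length 100 and 500 training epochs.
#' Shrink `epochs`/`walk_length`/`d_emb` for small graphs and tests.
#'
#' @param d_emb embedding dimension.
#' @param walk_length steps per walk.
#' @param context skip-gram window size.
#' @param epochs training epochs (one walk per node per epoch).
#' @param negative negative samples per positive pair.
#' @param lr skip-gram learning rate.
#' @return list of control parameters.
#' @export
n2v_control <- function(d_emb = 100L, walk_length = 100L, context = 5L,
                        epochs = 500L, negative = 5L, lr = 0.025) {
  stopifnot(d_emb >= 1, walk_length >= 1, context >= 1, epochs >= 1, negative >= 1)
  list(d_emb = as.integer(d_emb), walk_length = as.integer(walk_length),
       context = as.integer(context), epochs = as.integer(epochs),
       negative = as.integer(negative), lr = lr)
}

# adjacency list of out-neighbors over the merged edge set
merged_adjlist <- function(graph) {
  e <- merged_edges(graph)
  n <- n_genes(graph)
  if (nrow(e) == 0L) return(rep(list(integer(0)), n))
  unname(split(e[, 2L], factor(e[, 1L], levels = seq_len(n))))
}

random_walks <- function(adj, walk_length) {
  n <- length(adj)
  starts <- which(lengths(adj) > 0L)
  lapply(starts, function(v) {
    walk <- integer(walk_length)
    walk[1L] <- v
    cur <- v
    for (s in seq_len(walk_length - 1L)) {
      nb <- adj[[cur]]
      if (length(nb) == 0L) return(walk[seq_len(s)])
      cur <- nb[sample.int(length(nb), 1L)]
      walk[s + 1L] <- cur
    }
    walk
  })
}

walk_pairs <- function(walk, context) {
  L <- length(walk)
  if (L < 2L) return(NULL)
  out <- vector("list", context)
  for (off in seq_len(min(context, L - 1L))) {
    out[[off]] <- cbind(center = c(walk[seq_len(L - off)], walk[-seq_len(off)]),
                        ctx = c(walk[-seq_len(off)], walk[seq_len(L - off)]))
  }
  do.call(rbind, out)
}

#' Random-walk network embedding
#'
#' Embeds the merged (untyped) union of all networks of a graph into
#' `d_emb`-dimensional vectors by skip-gram with negative sampling over
#' unbiased random walks. Deterministic under `seed`; isolated nodes
#' receive zero vectors, and a graph with no edges at all yields an
#' all-zero table with a warning.
#'
#' @param graph a `gene_graph`.
#' @param control a [n2v_control()] list.
#' @param seed integer seed.
#' @return numeric matrix (genes x `d_emb`), rows named by gene.
#' @export
embed_networks_randomwalk <- function(graph, control = n2v_control(), seed = 1L) {
  n <- n_genes(graph)
  E <- matrix(0, n, control$d_emb, dimnames = list(graph$universe$genes, NULL))
  adj <- merged_adjlist(graph)
  if (all(lengths(adj) == 0L)) {
    warning("graph has no edges; returning an all-zero embedding table")
    return(E)
  }
  set.seed(seed)
  d <- control$d_emb
  active <- which(lengths(adj) > 0L)
  # input (center) and output (context) vectors, small random init
  W_in <- matrix(stats::runif(n * d, -0.5, 0.5) / d, n, d)
  W_out <- matrix(0, n, d)
  # negative-sampling distribution: unigram over walkable nodes
  neg_pool <- active
  k <- control$negative
  for (ep in seq_len(control$epochs)) {
    walks <- random_walks(adj, control$walk_length)
    pairs <- do.call(rbind, lapply(walks, walk_pairs, context = control$context))
    if (is.null(pairs) || nrow(pairs) == 0L) next
    pairs <- pairs[sample.int(nrow(pairs)), , drop = FALSE]
    ctr <- pairs[, 1L]; ctx <- pairs[, 2L]
    neg <- matrix(neg_pool[sample.int(length(neg_pool), nrow(pairs) * k, replace = TRUE)],
                  nrow(pairs), k)
    # sequential SGD in chunks: within a chunk, updates are accumulated
    chunk <- 512L
    idx <- split(seq_len(nrow(pairs)), ceiling(seq_len(nrow(pairs)) / chunk))
    for (ii in idx) {
      c_i <- ctr[ii]; x_i <- ctx[ii]
      Vc <- W_in[c_i, , drop = FALSE]
      Vx <- W_out[x_i, , drop = FALSE]
      g_pos <- sigmoid(rowSums(Vc * Vx)) - 1
      dVc <- g_pos * Vx
      dVx <- g_pos * Vc
      for (j in seq_len(k)) {
        nj <- neg[ii, j]
        Vn <- W_out[nj, , drop = FALSE]
        g_neg <- sigmoid(rowSums(Vc * Vn))
        dVc <- dVc + g_neg * Vn
        dVn <- g_neg * Vc
        W_out[nj, ] <- W_out[nj, , drop = FALSE] - control$lr * dVn
      }
      W_in[c_i, ] <- W_in[c_i, , drop = FALSE] - control$lr * dVc
      W_out[x_i, ] <- W_out[x_i, , drop = FALSE] - control$lr * dVx
    }
  }
  E[active, ] <- W_in[active, , drop = FALSE]
  E
}

#' Concatenate features with an embedding table
#'
#' Input augmentation for embedding-consuming classifiers (`"n2v+mlp"`):
#' the network topology enters as extra columns of the feature matrix.
#'
#' @param X numeric feature matrix (genes x p).
#' @param embedding matrix from [embed_networks_randomwalk()].
#' @return matrix with `p + d_emb` columns.
#' @export
augment_features <- function(X, embedding) {
  stopifnot(nrow(X) == nrow(embedding))
  cbind(as.matrix(X), embedding)
}
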