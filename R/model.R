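# Trainable classifier models.
#
# A model is a plain list: architecture spec, parameter list, and a
# precomputed graph context (per-relation edge sets and their offsets in the
# global edge-weight vector). Forward and backward passes are written out
# explicitly; the backward pass returns gradients with respect to the
# parameters and, on request, the input features and the edge weights (the
# latter two feed the integrated-gradients interpretation).

#' Architecture specification for a base classifier
#'
#' The shared architecture is pre message passing -> message passing ->
#' post message passing: dense layers interspersed with ELU activations
#' around a stack of graph layers, each graph layer followed by ELU and
#' instance normalization, and a single sigmoid output unit.
#'
#' @param mp_kind message-passing core: one of `"none"` (plain MLP),
#'   `"gcn"`, `"tag"`, `"rgcn"`, `"film"`, or `"linkx"` (a non-message
#'   passing method with its own two-branch architecture).
#' @param hidden_dim width of the hidden layers (default 50).
#' @param pre_layers number of hidden dense layers before message passing.
#' @param post_layers number of hidden dense layers after message passing.
#' @param mp_layers number of graph layers (ignored for `"none"`/`"linkx"`).
#' @param tag_k number of hops per TAG layer (default 3).
#' @param l1_alpha L1 penalty on the first adjacency-branch weight matrix
#'   (LINKX only, default 1e-2).
#' @param needs_embedding if `TRUE` the classifier consumes random-walk
#'   node embeddings concatenated to the input features.
#' @return object of class `arch_spec`.
#' @export
arch_spec <- function(mp_kind = c("none", "gcn", "tag", "rgcn", "film", "linkx"),
                      hidden_dim = 50, pre_layers = 2, post_layers = 2,
                      mp_layers = 2, tag_k = 3, l1_alpha = 1e-2,
                      needs_embedding = FALSE) {
  mp_kind <- match.arg(mp_kind)
  stopifnot(hidden_dim > 0, pre_layers >= 1, post_layers >= 1,
            mp_layers >= 0, tag_k >= 0, l1_alpha >= 0)
  structure(list(mp_kind = mp_kind, hidden_dim = as.integer(hidden_dim),
                 pre_layers = as.integer(pre_layers),
                 post_layers = as.integer(post_layers),
                 mp_layers = as.integer(mp_layers), tag_k = as.integer(tag_k),
                 l1_alpha = l1_alpha, needs_embedding = needs_embedding),
            class = "arch_spec")
}

#' Classifier registry
#'
#' Maps a method name to its [arch_spec()]. Available methods: `"mlp"`,
#' `"gcn"`, `"tag"`, `"rgcn"`, `"film"`, `"n2v+mlp"` (MLP over features
#' concatenated with random-walk embeddings) and `"linkx"`.
#'
#' @param name method name.
#' @param ... overrides passed on to [arch_spec()].
#' @return an `arch_spec`.
#' @export
classifier_spec <- function(name, ...) {
  dots <- list(...)
  base <- switch(name,
    "mlp" = list(mp_kind = "none"),
    "gcn" = list(mp_kind = "gcn"),
    "tag" = list(mp_kind = "tag"),
    "rgcn" = list(mp_kind = "rgcn"),
    "film" = list(mp_kind = "film"),
    "n2v+mlp" = list(mp_kind = "none", needs_embedding = TRUE),
    "linkx" = list(mp_kind = "linkx"),
    stop("unknown classifier: ", name)
  )
  do.call(arch_spec, utils::modifyList(base, dots))
}

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

# Graph context shared by all forward calls: relation edge sets plus their
# offsets into the global edge-weight vector (concatenated in relation order).
graph_context <- function(graph) {
  rel <- graph$edge_sets
  sizes <- vapply(rel, nrow, integer(1L))
  offsets <- c(0L, cumsum(sizes))[seq_along(sizes)]
  names(offsets) <- names(rel)
  list(n = n_genes(graph), relations = rel, offsets = offsets,
       n_edges = sum(sizes),
       edge_table = if (sum(sizes) > 0)
         data.frame(source = unlist(lapply(rel, function(e) e[, 1L]), use.names = FALSE),
                    target = unlist(lapply(rel, function(e) e[, 2L]), use.names = FALSE),
                    network = rep(names(rel), sizes))
       else data.frame(source = integer(0), target = integer(0), network = character(0)))
}

#' Build a classifier model
#'
#' Initializes all trainable weights (Glorot-uniform, zero biases) for the
#' requested architecture on a given graph and input dimensionality.
#'
#' @param spec an [arch_spec()].
#' @param graph a `gene_graph`.
#' @param p_in input feature dimension (after any embedding concatenation).
#' @param seed integer seed for the weight draw.
#' @return object of class `pu_model`.
#' @export
build_model <- function(spec, graph, p_in, seed = 1L) {
  stopifnot(inherits(spec, "arch_spec"))
  set.seed(seed)
  h <- spec$hidden_dim
  ctx <- graph_context(graph)
  params <- list()
  if (spec$mp_kind == "linkx") {
    n <- ctx$n
    params$A1_W <- glorot(n, h); params$A1_b <- numeric(h)
    params$A2_W <- glorot(h, h); params$A2_b <- numeric(h)
    params$X1_W <- glorot(p_in, h); params$X1_b <- numeric(h)
    params$X2_W <- glorot(h, h); params$X2_b <- numeric(h)
    params$F1_W <- glorot(2L * h, h); params$F1_b <- numeric(h)
    params$out_W <- glorot(h, 1L); params$out_b <- numeric(1L)
  } else {
    dims_in <- p_in
    for (i in seq_len(spec$pre_layers)) {
      params[[paste0("pre", i, "_W")]] <- glorot(dims_in, h)
      params[[paste0("pre", i, "_b")]] <- numeric(h)
      dims_in <- h
    }
    if (spec$mp_kind != "none") {
      for (t in seq_len(spec$mp_layers)) {
        key <- paste0("mp", t, "_")
        if (spec$mp_kind == "gcn") {
          params[[paste0(key, "W")]] <- glorot(h, h)
        } else if (spec$mp_kind == "tag") {
          params[[paste0(key, "W")]] <- lapply(0:spec$tag_k, function(k) glorot(h, h))
        } else if (spec$mp_kind == "rgcn") {
          params[[paste0(key, "Wroot")]] <- glorot(h, h)
          params[[paste0(key, "Wr")]] <- lapply(ctx$relations, function(e) glorot(h, h))
        } else if (spec$mp_kind == "film") {
          params[[paste0(key, "Wr")]] <- lapply(ctx$relations, function(e) glorot(h, h))
          params[[paste0(key, "Wg")]] <- lapply(ctx$relations, function(e) glorot(h, 2L * h))
          params[[paste0(key, "bg")]] <- lapply(ctx$relations, function(e) numeric(2L * h))
        }
      }
    }
    for (i in seq_len(spec$post_layers)) {
      params[[paste0("post", i, "_W")]] <- glorot(h, h)
      params[[paste0("post", i, "_b")]] <- numeric(h)
    }
    params$out_W <- glorot(h, 1L)
    params$out_b <- numeric(1L)
  }
  structure(list(spec = spec, params = params, ctx = ctx, p_in = p_in),
            class = "pu_model")
}

#' @export
print.pu_model <- function(x, ...) {
  np <- sum(vapply(rapply(x$params, length, how = "unlist"), sum, numeric(1L)))
  cat("<pu_model> ", x$spec$mp_kind, " core, ", x$p_in, " inputs, ",
      format(np, big.mark = ","), " parameters\n", sep = "")
  invisible(x)
}

# split the global edge-weight vector into per-relation pieces
split_edge_weights <- function(ctx, edge_weights) {
  if (is.null(edge_weights)) return(NULL)
  stopifnot(length(edge_weights) == ctx$n_edges)
  out <- list()
  for (nw in names(ctx$relations)) {
    nE <- nrow(ctx$relations[[nw]])
    out[[nw]] <- edge_weights[ctx$offsets[[nw]] + seq_len(nE)]
  }
  out
}

# dense adjacency input for LINKX: row v holds the weights of edges into v
linkx_adjacency <- function(ctx, ew_split) {
  A <- matrix(0, ctx$n, ctx$n)
  for (nw in names(ctx$relations)) {
    e <- ctx$relations[[nw]]
    if (nrow(e) == 0L) next
    w <- ew_split[[nw]]
    if (is.null(w)) w <- rep(1, nrow(e))
    A[cbind(e[, 2L], e[, 1L])] <- A[cbind(e[, 2L], e[, 1L])] + w
  }
  A
}

#' Forward pass of a classifier
#'
#' Runs the full architecture and returns per-gene scores in (0, 1).
#'
#' @param model a [build_model()] result.
#' @param X input feature matrix (n x p_in).
#' @param edge_weights optional global edge-weight vector (length = total
#'   directed edges across relations, in relation order); default all 1.
#' @param want_cache keep intermediate activations for a backward pass.
#' @return list with `score` (n-vector), `logit`, and `cache`.
#' @export
model_forward <- function(model, X, edge_weights = NULL, want_cache = FALSE) {
  X <- as.matrix(X)
  spec <- model$spec; P <- model$params; ctx <- model$ctx
  ew <- split_edge_weights(ctx, edge_weights)
  cache <- list(input = X, ew = ew)
  dense_fwd <- function(H, W, b) {
    Z <- H %*% W
    Z + rep(b, each = nrow(Z))
  }
  if (spec$mp_kind == "linkx") {
    A <- linkx_adjacency(ctx, ew)
    a1 <- dense_fwd(A, P$A1_W, P$A1_b); a1e <- elu(a1)
    a2 <- dense_fwd(a1e, P$A2_W, P$A2_b); a2e <- elu(a2)
    x1 <- dense_fwd(X, P$X1_W, P$X1_b); x1e <- elu(x1)
    x2 <- dense_fwd(x1e, P$X2_W, P$X2_b); x2e <- elu(x2)
    J <- cbind(a2e, x2e)
    f1 <- dense_fwd(J, P$F1_W, P$F1_b); f1e <- elu(f1)
    logit <- drop(dense_fwd(f1e, P$out_W, P$out_b))
    if (want_cache) cache <- c(cache, list(A = A, a1 = a1, a1e = a1e, a2 = a2, a2e = a2e,
                                           x1 = x1, x1e = x1e, x2 = x2, x2e = x2e,
                                           J = J, f1 = f1, f1e = f1e))
    return(list(score = sigmoid(logit), logit = logit, cache = if (want_cache) cache))
  }
  H <- X
  acts <- list()
  for (i in seq_len(spec$pre_layers)) {
    Z <- dense_fwd(H, P[[paste0("pre", i, "_W")]], P[[paste0("pre", i, "_b")]])
    acts[[paste0("pre", i, "_in")]] <- H
    acts[[paste0("pre", i, "_z")]] <- Z
    H <- elu(Z)
  }
  if (spec$mp_kind != "none") {
    for (t in seq_len(spec$mp_layers)) {
      key <- paste0("mp", t, "_")
      acts[[paste0(key, "in")]] <- H
      mp <- mp_forward(spec, P, ctx, key, H, ew)
      acts[[paste0(key, "cache")]] <- mp$cache
      Z <- mp$out
      acts[[paste0(key, "z")]] <- Z
      E <- elu(Z)
      acts[[paste0(key, "e")]] <- E
      norm <- instnorm_fwd(E)
      acts[[paste0(key, "norm")]] <- norm
      H <- norm$out
    }
  }
  for (i in seq_len(spec$post_layers)) {
    Z <- dense_fwd(H, P[[paste0("post", i, "_W")]], P[[paste0("post", i, "_b")]])
    acts[[paste0("post", i, "_in")]] <- H
    acts[[paste0("post", i, "_z")]] <- Z
    H <- elu(Z)
  }
  acts$out_in <- H
  logit <- drop(dense_fwd(H, P$out_W, P$out_b))
  if (want_cache) cache$acts <- acts
  list(score = sigmoid(logit), logit = logit, cache = if (want_cache) cache)
}

instnorm_fwd <- function(X, eps = 1e-5) {
  mu <- colMeans(X)
  v <- colMeans(X^2) - mu^2
  inv_std <- 1 / sqrt(pmax(v, 0) + eps)
  xhat <- sweep(sweep(X, 2L, mu, "-"), 2L, inv_std, "*")
  list(out = xhat, inv_std = inv_std)
}

instnorm_bwd <- function(G, norm) {
  n <- nrow(G)
  xhat <- norm$out
  s1 <- colMeans(G)
  s2 <- colMeans(G * xhat)
  sweep(G - sweep(xhat, 2L, s2, "*") - matrix(s1, n, length(s1), byrow = TRUE),
        2L, norm$inv_std, "*")
}

# message-passing forward for one layer; returns out + cache for backward
mp_forward <- function(spec, P, ctx, key, H, ew) {
  n <- nrow(H)
  if (spec$mp_kind == "gcn") {
    edges <- do.call(rbind, unname(ctx$relations))
    if (is.null(edges)) edges <- matrix(integer(0), ncol = 2L)
    w <- if (is.null(ew)) NULL else unlist(ew, use.names = FALSE)
    op <- gcn_operator(n, edges, w)
    Hs <- as.matrix(op$S %*% H)
    out <- Hs %*% P[[paste0(key, "W")]]
    list(out = out, cache = list(op = op, H = H, Hs = Hs))
  } else if (spec$mp_kind == "tag") {
    edges <- do.call(rbind, unname(ctx$relations))
    if (is.null(edges)) edges <- matrix(integer(0), ncol = 2L)
    w <- if (is.null(ew)) NULL else unlist(ew, use.names = FALSE)
    op <- gcn_operator(n, edges, w)
    W <- P[[paste0(key, "W")]]
    Pk <- H
    Ps <- list(Pk)
    out <- Pk %*% W[[1L]]
    for (k in seq_len(spec$tag_k)) {
      Pk <- as.matrix(op$S %*% Pk)
      Ps[[k + 1L]] <- Pk
      out <- out + Pk %*% W[[k + 1L]]
    }
    list(out = out, cache = list(op = op, Ps = Ps))
  } else if (spec$mp_kind == "rgcn") {
    Wr <- P[[paste0(key, "Wr")]]
    out <- H %*% P[[paste0(key, "Wroot")]]
    ops <- list(); Hs <- list()
    for (nw in names(ctx$relations)) {
      e <- ctx$relations[[nw]]
      if (nrow(e) == 0L) next
      op <- rgcn_operator(n, e, ew[[nw]])
      Hr <- as.matrix(op$S %*% H)
      out <- out + Hr %*% Wr[[nw]]
      ops[[nw]] <- op; Hs[[nw]] <- Hr
    }
    list(out = out, cache = list(ops = ops, Hs = Hs, H = H))
  } else if (spec$mp_kind == "film") {
    Wr <- P[[paste0(key, "Wr")]]; Wg <- P[[paste0(key, "Wg")]]; bg <- P[[paste0(key, "bg")]]
    h_out <- ncol(Wr[[1L]])
    out <- matrix(0, n, h_out)
    rc <- list()
    for (nw in names(ctx$relations)) {
      e <- ctx$relations[[nw]]
      if (nrow(e) == 0L) next
      w <- ew[[nw]]; if (is.null(w)) w <- rep(1, nrow(e))
      BG <- sweep(H %*% Wg[[nw]], 2L, bg[[nw]], "+")
      beta <- BG[, seq_len(h_out), drop = FALSE]
      gamma <- BG[, h_out + seq_len(h_out), drop = FALSE]
      src <- e[, 1L]; tgt <- e[, 2L]
      M <- H[src, , drop = FALSE] %*% Wr[[nw]]
      Z <- gamma[tgt, , drop = FALSE] * M + beta[tgt, , drop = FALSE]
      R <- pmax(Z, 0)
      agg <- Matrix::sparseMatrix(i = tgt, j = seq_along(tgt), x = 1, dims = c(n, length(tgt)))
      out <- out + as.matrix(agg %*% (R * w))
      rc[[nw]] <- list(M = M, Z = Z, R = R, gamma = gamma, src = src, tgt = tgt,
                       w = w, agg = agg)
    }
    list(out = out, cache = list(rc = rc, H = H))
  }
}

# backward through one message-passing layer; returns grad wrt input H,
# parameter gradients (named like the params) and edge-weight gradients
mp_backward <- function(spec, P, ctx, key, G, cache, want_edges = FALSE) {
  grads <- list(); ew_grad <- NULL
  n <- nrow(G)
  if (want_edges && ctx$n_edges > 0L) ew_grad <- numeric(ctx$n_edges)
  edge_slice <- function(nw) ctx$offsets[[nw]] + seq_len(nrow(ctx$relations[[nw]]))
  if (spec$mp_kind == "gcn") {
    W <- P[[paste0(key, "W")]]
    grads[[paste0(key, "W")]] <- crossprod(cache$Hs, G)
    M <- G %*% t(W)
    Gin <- as.matrix(Matrix::t(cache$op$S) %*% M)
    if (want_edges && nrow(cache$op$edges) > 0L) {
      e <- cache$op$edges
      dw <- cache$op$norm_edge *
        rowSums(M[e[, 2L], , drop = FALSE] * cache$H[e[, 1L], , drop = FALSE])
      ew_grad <- dw  # merged order equals global order
    }
  } else if (spec$mp_kind == "tag") {
    W <- P[[paste0(key, "W")]]
    Ps <- cache$Ps
    K <- length(W) - 1L
    grads[[paste0(key, "W")]] <- lapply(seq_along(W), function(k) crossprod(Ps[[k]], G))
    St <- Matrix::t(cache$op$S)
    e <- cache$op$edges
    Gin <- G %*% t(W[[1L]])
    if (K > 0L) for (k in seq_len(K)) {
      Q <- G %*% t(W[[k + 1L]])
      for (j in 0:(k - 1L)) {
        if (want_edges && nrow(e) > 0L) {
          Pprev <- Ps[[k - j]]  # P_{k-1-j} (1-based: Ps[[i+1]] = P_i)
          ew_grad <- ew_grad + cache$op$norm_edge *
            rowSums(Q[e[, 2L], , drop = FALSE] * Pprev[e[, 1L], , drop = FALSE])
        }
        Q <- as.matrix(St %*% Q)
      }
      Gin <- Gin + Q
    }
  } else if (spec$mp_kind == "rgcn") {
    Wr <- P[[paste0(key, "Wr")]]
    Wroot <- P[[paste0(key, "Wroot")]]
    grads[[paste0(key, "Wroot")]] <- crossprod(cache$H, G)
    gWr <- lapply(Wr, function(w) array(0, dim = dim(w)))
    Gin <- G %*% t(Wroot)
    for (nw in names(cache$ops)) {
      op <- cache$ops[[nw]]
      gWr[[nw]] <- crossprod(cache$Hs[[nw]], G)
      M <- G %*% t(Wr[[nw]])
      Gin <- Gin + as.matrix(Matrix::t(op$S) %*% M)
      if (want_edges) {
        e <- op$edges
        ew_grad[edge_slice(nw)] <- op$norm_edge *
          rowSums(M[e[, 2L], , drop = FALSE] * cache$H[e[, 1L], , drop = FALSE])
      }
    }
    grads[[paste0(key, "Wr")]] <- gWr
  } else if (spec$mp_kind == "film") {
    Wr <- P[[paste0(key, "Wr")]]; Wg <- P[[paste0(key, "Wg")]]
    h_out <- ncol(Wr[[1L]])
    gWr <- lapply(Wr, function(w) array(0, dim = dim(w)))
    gWg <- lapply(Wg, function(w) array(0, dim = dim(w)))
    gbg <- lapply(Wg, function(w) numeric(2L * h_out))
    Gin <- matrix(0, n, nrow(Wr[[1L]]))
    H <- cache$H
    for (nw in names(cache$rc)) {
      c_ <- cache$rc[[nw]]
      Gt <- G[c_$tgt, , drop = FALSE]
      if (want_edges) ew_grad[edge_slice(nw)] <- rowSums(Gt * c_$R)
      gR <- Gt * c_$w
      gZ <- gR * (c_$Z > 0)
      dGamma_e <- gZ * c_$M
      dBG <- cbind(as.matrix(c_$agg %*% gZ), as.matrix(c_$agg %*% dGamma_e))
      gWg[[nw]] <- crossprod(H, dBG)
      gbg[[nw]] <- colSums(dBG)
      Gin <- Gin + dBG %*% t(Wg[[nw]])
      dM <- gZ * c_$gamma[c_$tgt, , drop = FALSE]
      gWr[[nw]] <- crossprod(H[c_$src, , drop = FALSE], dM)
      srcagg <- Matrix::sparseMatrix(i = c_$src, j = seq_along(c_$src), x = 1,
                                     dims = c(n, length(c_$src)))
      Gin <- Gin + as.matrix(srcagg %*% (dM %*% t(Wr[[nw]])))
    }
    grads[[paste0(key, "Wr")]] <- gWr
    grads[[paste0(key, "Wg")]] <- gWg
    grads[[paste0(key, "bg")]] <- gbg
  }
  list(Gin = Gin, grads = grads, ew_grad = ew_grad)
}

#' Backward pass of a classifier
#'
#' Backpropagates a gradient on the logits through the cached forward pass.
#'
#' @param model a `pu_model`.
#' @param cache cache from [model_forward()] with `want_cache = TRUE`.
#' @param dlogit numeric n-vector: gradient of the objective wrt each logit.
#' @param want_input also return the gradient wrt the input features.
#' @param want_edges also return the gradient wrt the edge weights.
#' @return list with `grads` (named like `model$params`), and optionally
#'   `dX` and `dw`.
#' @export
model_backward <- function(model, cache, dlogit, want_input = FALSE, want_edges = FALSE) {
  spec <- model$spec; P <- model$params; ctx <- model$ctx
  grads <- list()
  # d elu / dz = 1 for z > 0, exp(z) otherwise = exp(min(z, 0))
  elu_bwd <- function(G, Z) G * exp(pmin(Z, 0))
  if (spec$mp_kind == "linkx") {
    G <- matrix(dlogit, ncol = 1L)
    grads$out_W <- crossprod(cache$f1e, G); grads$out_b <- colSums(G)
    G <- elu_bwd(G %*% t(P$out_W), cache$f1)
    grads$F1_W <- crossprod(cache$J, G); grads$F1_b <- colSums(G)
    GJ <- G %*% t(P$F1_W)
    h <- ncol(cache$a2e)
    Ga <- elu_bwd(GJ[, seq_len(h), drop = FALSE], cache$a2)
    Gx <- elu_bwd(GJ[, h + seq_len(h), drop = FALSE], cache$x2)
    grads$A2_W <- crossprod(cache$a1e, Ga); grads$A2_b <- colSums(Ga)
    grads$X2_W <- crossprod(cache$x1e, Gx); grads$X2_b <- colSums(Gx)
    Ga <- elu_bwd(Ga %*% t(P$A2_W), cache$a1)
    Gx <- elu_bwd(Gx %*% t(P$X2_W), cache$x1)
    grads$A1_W <- crossprod(cache$A, Ga); grads$A1_b <- colSums(Ga)
    grads$X1_W <- crossprod(cache$input, Gx); grads$X1_b <- colSums(Gx)
    out <- list(grads = grads)
    if (want_input) out$dX <- Gx %*% t(P$X1_W)
    if (want_edges) {
      dA <- Ga %*% t(P$A1_W)
      dw <- numeric(ctx$n_edges)
      for (nw in names(ctx$relations)) {
        e <- ctx$relations[[nw]]
        if (nrow(e) == 0L) next
        dw[ctx$offsets[[nw]] + seq_len(nrow(e))] <- dA[cbind(e[, 2L], e[, 1L])]
      }
      out$dw <- dw
    }
    return(out)
  }
  acts <- cache$acts
  G <- matrix(dlogit, ncol = 1L)
  grads$out_W <- crossprod(acts$out_in, G)
  grads$out_b <- colSums(G)
  G <- G %*% t(P$out_W)
  for (i in rev(seq_len(spec$post_layers))) {
    G <- elu_bwd(G, acts[[paste0("post", i, "_z")]])
    grads[[paste0("post", i, "_W")]] <- crossprod(acts[[paste0("post", i, "_in")]], G)
    grads[[paste0("post", i, "_b")]] <- colSums(G)
    G <- G %*% t(P[[paste0("post", i, "_W")]])
  }
  dw <- if (want_edges && ctx$n_edges > 0L) numeric(ctx$n_edges) else NULL
  if (spec$mp_kind != "none") {
    for (t in rev(seq_len(spec$mp_layers))) {
      key <- paste0("mp", t, "_")
      G <- instnorm_bwd(G, acts[[paste0(key, "norm")]])
      G <- elu_bwd(G, acts[[paste0(key, "z")]])
      mb <- mp_backward(spec, P, ctx, key, G, acts[[paste0(key, "cache")]],
                        want_edges = want_edges)
      grads <- c(grads, mb$grads)
      if (want_edges && !is.null(mb$ew_grad)) dw <- dw + mb$ew_grad
      G <- mb$Gin
    }
  }
  for (i in rev(seq_len(spec$pre_layers))) {
    G <- elu_bwd(G, acts[[paste0("pre", i, "_z")]])
    grads[[paste0("pre", i, "_W")]] <- crossprod(acts[[paste0("pre", i, "_in")]], G)
    grads[[paste0("pre", i, "_b")]] <- colSums(G)
    G <- G %*% t(P[[paste0("pre", i, "_W")]])
  }
  out <- list(grads = grads)
  if (want_input) out$dX <- G
  if (want_edges) out$dw <- dw
  out
}

#' Score genes with a classifier
#'
#' Convenience wrapper: forward pass returning only the per-gene scores.
#'
#' @param model a `pu_model`.
#' @param X input feature matrix.
#' @param edge_weights optional global edge-weight vector.
#' @return numeric vector of scores in (0, 1).
#' @export
forward_classifier <- function(model, X, edge_weights = NULL) {
  model_forward(model, X, edge_weights)$score
}

# elementwise Adam update; params/grads are (possibly nested) lists of arrays
adam_init <- function(params) {
  zero <- function(p) if (is.list(p)) lapply(p, zero) else array(0, dim = if (is.null(dim(p))) length(p) else dim(p))
  list(m = zero(params), v = zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      res <- Map(upd, p, g, m, v)
      return(list(p = lapply(res, `[[`, "p"), m = lapply(res, `[[`, "m"),
                  v = lapply(res, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  res <- Map(upd, params, grads[names(params)], state$m, state$v)
  list(params = lapply(res, `[[`, "p"),
       state = list(m = lapply(res, `[[`, "m"), v = lapply(res, `[[`, "v"), t = t))
}
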