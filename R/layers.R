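# Message-passing layers implemented from their defining update rules, each
# with an explicit reverse-mode gradient. All layers operate on an edge list
# (src -> dst means u sends its message to v) plus per-graph auxiliary
# structures precomputed once in `graph_aux()`.

relu <- function(x) pmax(x, 0)
relu_grad <- function(x) (x > 0) * 1
leaky_relu <- function(x, slope = 0.2) pmax(x, 0) + slope * pmin(x, 0)
leaky_relu_grad <- function(x, slope = 0.2) slope + (1 - slope) * (x > 0)

act_fun <- function(name) {
  switch(name,
         relu = list(f = relu, grad = relu_grad),
         elu = list(
           f = function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1),
           grad = function(x) ifelse(x > 0, 1, exp(pmin(x, 0)))),
         identity = list(f = identity, grad = function(x) 1),
         stop(sprintf("unknown activation `%s`", name)))
}

# scatter-add of edge-wise rows into node rows (C++ kernel)
scatter_add <- function(vals, idx, n) cpp_scatter_add(vals, idx, n)

scatter_add_vec <- function(vals, idx, n) cpp_scatter_add_vec(vals, idx, n)

#' Precompute per-graph structures for a layer type
#'
#' Self-loops are added for `gcn`, `gat` and `gatv2` (every node then has a
#' defined in-neighborhood, including isolated singleton patients); `sage`
#' uses its explicit self term and `gin` its `(1+eps)` term instead.
#'
#' @param graph A `cbc_graph`.
#' @param layer_type One of sage, gcn, gat, gatv2, gin.
#' @return Internal auxiliary list (edge lists, degrees, normalizations,
#'   per-target edge groups for attention softmax).
#' @keywords internal
graph_aux <- function(graph, layer_type) {
  n <- n_nodes(graph)
  aux <- list(n = n, src = graph$src, dst = graph$dst,
              deg = tabulate(graph$dst, nbins = n))
  if (layer_type %in% c("gcn", "gat", "gatv2")) {
    aux$src_sl <- c(graph$src, seq_len(n))
    aux$dst_sl <- c(graph$dst, seq_len(n))
    if (layer_type == "gcn") {
      dhat <- aux$deg + 1
      aux$gcn_coef <- 1 / sqrt(dhat[aux$src_sl] * dhat[aux$dst_sl])
    }
  }
  aux
}

# numerically stable softmax over each target's in-edge group
edge_softmax <- function(e, aux) {
  m <- cpp_group_max(e, aux$dst_sl, aux$n)
  ex <- exp(e - m[aux$dst_sl])
  denom <- scatter_add_vec(ex, aux$dst_sl, aux$n)
  ex / denom[aux$dst_sl]
}

# d(loss)/d(e) given d(loss)/d(alpha), through the per-target softmax
edge_softmax_backward <- function(dalpha, alpha, aux) {
  s <- scatter_add_vec(alpha * dalpha, aux$dst_sl, aux$n)
  alpha * (dalpha - s[aux$dst_sl])
}

glorot <- function(nin, nout) {
  r <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -r, r), nin, nout)
}

# ---- layer constructors ----------------------------------------------------

init_layer <- function(type, f_in, f_out, n_heads = 1L, combine = "concat") {
  l <- list(type = type, f_in = f_in, f_out = f_out,
            n_heads = as.integer(n_heads), combine = combine)
  p <- list()
  if (type == "sage") {
    p$W_self <- glorot(f_in, f_out)
    p$W_neigh <- glorot(f_in, f_out)
    p$b <- numeric(f_out)
  } else if (type == "gcn") {
    p$W <- glorot(f_in, f_out)
    p$b <- numeric(f_out)
  } else if (type %in% c("gat", "gatv2")) {
    d <- head_dim(type, f_out, n_heads, combine)
    p$heads <- lapply(seq_len(n_heads), function(h) {
      if (type == "gat") {
        list(W = glorot(f_in, d),
             a_src = stats::runif(d, -sqrt(3 / d), sqrt(3 / d)),
             a_dst = stats::runif(d, -sqrt(3 / d), sqrt(3 / d)))
      } else {
        list(Wl = glorot(f_in, d), Wr = glorot(f_in, d),
             a = stats::runif(d, -sqrt(3 / d), sqrt(3 / d)))
      }
    })
    p$b <- numeric(f_out)
  } else if (type == "gin") {
    p$W1 <- glorot(f_in, f_out)
    p$b1 <- numeric(f_out)
    p$W2 <- glorot(f_out, f_out)
    p$b2 <- numeric(f_out)
    l$eps <- 0
  } else stop(sprintf("unknown layer type `%s`", type))
  l$params <- p
  l
}

# heads are concatenated in hidden layers (f_out must split evenly) and
# averaged at the output layer (each head emits the full f_out)
head_dim <- function(type, f_out, n_heads, combine = "concat") {
  if (combine == "mean") return(f_out)
  if (f_out %% n_heads != 0) {
    stop(sprintf("hidden dim %d not divisible by %d heads", f_out, n_heads))
  }
  f_out %/% n_heads
}

# ---- forward / backward ----------------------------------------------------

layer_forward <- function(layer, H, aux, act_name = "identity",
                          combine = layer$combine) {
  if (is.null(combine)) combine <- "concat"
  act <- act_fun(act_name)
  type <- layer$type
  p <- layer$params
  n <- aux$n
  cache <- list(H = H, act = act, combine = combine)

  if (type == "sage") {
    M <- cpp_gather_scatter(H, aux$src, aux$dst, NULL, n) / pmax(aux$deg, 1)
    Z <- H %*% p$W_self + M %*% p$W_neigh +
      matrix(p$b, n, layer$f_out, byrow = TRUE)
    cache$M <- M; cache$Z <- Z
    return(list(out = act$f(Z), cache = cache))
  }
  if (type == "gcn") {
    HW <- H %*% p$W
    Z <- cpp_gather_scatter(HW, aux$src_sl, aux$dst_sl, aux$gcn_coef, n) +
      matrix(p$b, n, layer$f_out, byrow = TRUE)
    cache$Z <- Z
    return(list(out = act$f(Z), cache = cache))
  }
  if (type == "gat") {
    heads <- vector("list", layer$n_heads)
    for (h in seq_len(layer$n_heads)) {
      hp <- p$heads[[h]]
      Wh <- H %*% hp$W
      s <- as.vector(Wh %*% hp$a_src)
      t <- as.vector(Wh %*% hp$a_dst)
      z <- s[aux$src_sl] + t[aux$dst_sl]
      alpha <- edge_softmax(leaky_relu(z), aux)
      out_h <- cpp_gather_scatter(Wh, aux$src_sl, aux$dst_sl, alpha, n)
      heads[[h]] <- list(Wh = Wh, z = z, alpha = alpha, out = out_h)
    }
    comb <- combine_heads(heads, combine)
    Z <- comb + matrix(p$b, n, layer$f_out, byrow = TRUE)
    cache$heads <- heads; cache$Z <- Z
    return(list(out = act$f(Z), cache = cache,
                attention = lapply(heads, `[[`, "alpha")))
  }
  if (type == "gatv2") {
    heads <- vector("list", layer$n_heads)
    for (h in seq_len(layer$n_heads)) {
      hp <- p$heads[[h]]
      L <- H %*% hp$Wl
      R <- H %*% hp$Wr
      z <- cpp_edge_pair_sum(L, R, aux$src_sl, aux$dst_sl)
      q <- leaky_relu(z)
      e <- as.vector(q %*% hp$a)
      alpha <- edge_softmax(e, aux)
      out_h <- cpp_gather_scatter(L, aux$src_sl, aux$dst_sl, alpha, n)
      heads[[h]] <- list(L = L, R = R, z = z, q = q, alpha = alpha,
                         out = out_h)
    }
    comb <- combine_heads(heads, combine)
    Z <- comb + matrix(p$b, n, layer$f_out, byrow = TRUE)
    cache$heads <- heads; cache$Z <- Z
    return(list(out = act$f(Z), cache = cache,
                attention = lapply(heads, `[[`, "alpha")))
  }
  if (type == "gin") {
    S <- (1 + layer$eps) * H + cpp_gather_scatter(H, aux$src, aux$dst, NULL, n)
    Z1 <- S %*% p$W1 + matrix(p$b1, n, layer$f_out, byrow = TRUE)
    A1 <- relu(Z1)
    Z2 <- A1 %*% p$W2 + matrix(p$b2, n, layer$f_out, byrow = TRUE)
    cache$S <- S; cache$Z1 <- Z1; cache$A1 <- A1; cache$Z <- Z2
    return(list(out = act$f(Z2), cache = cache))
  }
  stop("unreachable")
}

combine_heads <- function(heads, combine) {
  outs <- lapply(heads, `[[`, "out")
  if (combine == "concat") do.call(cbind, outs)
  else Reduce(`+`, outs) / length(outs)
}

layer_backward <- function(layer, dOut, cache, aux) {
  type <- layer$type
  p <- layer$params
  n <- aux$n
  dZ <- dOut * cache$act$grad(cache$Z)
  grads <- list()

  if (type == "sage") {
    grads$W_self <- crossprod(cache$H, dZ)
    grads$W_neigh <- crossprod(cache$M, dZ)
    grads$b <- colSums(dZ)
    dM <- dZ %*% t(p$W_neigh)
    dH <- dZ %*% t(p$W_self) +
      cpp_gather_scatter(dM, aux$dst, aux$src,
                         1 / pmax(aux$deg, 1)[aux$dst], n)
    return(list(dH = dH, grads = grads))
  }
  if (type == "gcn") {
    dHW <- cpp_gather_scatter(dZ, aux$dst_sl, aux$src_sl, aux$gcn_coef, n)
    grads$W <- crossprod(cache$H, dHW)
    grads$b <- colSums(dZ)
    return(list(dH = dHW %*% t(p$W), grads = grads))
  }
  if (type %in% c("gat", "gatv2")) {
    # grads must mirror the params structure (heads first, then b): Adam
    # pairs parameter and gradient leaves by position
    grads$heads <- vector("list", layer$n_heads)
    dH <- matrix(0, n, layer$f_in)
    d <- ncol(cache$heads[[1]]$out)
    for (h in seq_len(layer$n_heads)) {
      dOh <- if (cache$combine == "concat") {
        dZ[, ((h - 1) * d + 1):(h * d), drop = FALSE]
      } else dZ / layer$n_heads
      hc <- cache$heads[[h]]
      hp <- p$heads[[h]]
      if (type == "gat") {
        g_e <- cpp_edge_dot(dOh, hc$Wh, aux$src_sl, aux$dst_sl)
        de <- edge_softmax_backward(g_e, hc$alpha, aux)
        dz <- de * leaky_relu_grad(hc$z)
        ds <- scatter_add_vec(dz, aux$src_sl, n)
        dt <- scatter_add_vec(dz, aux$dst_sl, n)
        dWh <- cpp_gather_scatter(dOh, aux$dst_sl, aux$src_sl, hc$alpha, n) +
          tcrossprod(ds, hp$a_src) + tcrossprod(dt, hp$a_dst)
        grads$heads[[h]] <- list(
          W = crossprod(cache$H, dWh),
          a_src = as.vector(crossprod(hc$Wh, ds)),
          a_dst = as.vector(crossprod(hc$Wh, dt)))
        dH <- dH + dWh %*% t(hp$W)
      } else {
        g_e <- cpp_edge_dot(dOh, hc$L, aux$src_sl, aux$dst_sl)
        de <- edge_softmax_backward(g_e, hc$alpha, aux)
        dq <- tcrossprod(de, hp$a)
        dz <- dq * leaky_relu_grad(hc$z)
        dL <- cpp_gather_scatter(dOh, aux$dst_sl, aux$src_sl, hc$alpha, n) +
          scatter_add(dz, aux$src_sl, n)
        dR <- scatter_add(dz, aux$dst_sl, n)
        grads$heads[[h]] <- list(
          Wl = crossprod(cache$H, dL),
          Wr = crossprod(cache$H, dR),
          a = as.vector(crossprod(hc$q, de)))
        dH <- dH + dL %*% t(hp$Wl) + dR %*% t(hp$Wr)
      }
    }
    grads$b <- colSums(dZ)
    return(list(dH = dH, grads = grads))
  }
  if (type == "gin") {
    dA1 <- dZ %*% t(p$W2)
    dZ1 <- dA1 * relu_grad(cache$Z1)
    grads$W1 <- crossprod(cache$S, dZ1)
    grads$b1 <- colSums(dZ1)
    grads$W2 <- crossprod(cache$A1, dZ)
    grads$b2 <- colSums(dZ)
    dS <- dZ1 %*% t(p$W1)
    dH <- (1 + layer$eps) * dS +
      cpp_gather_scatter(dS, aux$dst, aux$src, NULL, n)
    return(list(dH = dH, grads = grads))
  }
  stop("unreachable")
}
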