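# Independent brute-force oracles: dense-matrix implementations of the layer
# update rules, pairwise AUROC, and O(n^3) average-linkage clustering. These
# deliberately avoid the package's edge-list/scatter code paths.

dense_adj <- function(n, src, dst, self_loops = FALSE) {
  A <- matrix(0, n, n)
  if (length(src)) A[cbind(src, dst)] <- 1
  if (self_loops) diag(A) <- 1
  A
}

oracle_sage <- function(H, src, dst, p, act = identity) {
  n <- nrow(H)
  A <- dense_adj(n, src, dst)
  deg <- pmax(colSums(A), 1)
  M <- t(A) %*% H / deg
  act(H %*% p$W_self + M %*% p$W_neigh +
        matrix(p$b, n, length(p$b), byrow = TRUE))
}

oracle_gcn <- function(H, src, dst, p, act = identity) {
  n <- nrow(H)
  A <- dense_adj(n, src, dst, self_loops = TRUE)
  dhat <- colSums(A)
  out <- matrix(0, n, ncol(p$W))
  HW <- H %*% p$W
  for (v in seq_len(n)) {
    for (u in which(A[, v] > 0)) {
      out[v, ] <- out[v, ] + HW[u, ] / sqrt(dhat[u] * dhat[v])
    }
  }
  act(out + matrix(p$b, n, length(p$b), byrow = TRUE))
}

oracle_gin <- function(H, src, dst, p, eps = 0, act = identity) {
  n <- nrow(H)
  A <- dense_adj(n, src, dst)
  S <- (1 + eps) * H + t(A) %*% H
  A1 <- pmax(S %*% p$W1 + matrix(p$b1, n, length(p$b1), byrow = TRUE), 0)
  act(A1 %*% p$W2 + matrix(p$b2, n, length(p$b2), byrow = TRUE))
}

lrelu <- function(x, s = 0.2) ifelse(x > 0, x, s * x)

# per-node softmax attention, explicit loops; self-loops included
oracle_gat_head <- function(H, src, dst, hp, variant = "gat") {
  n <- nrow(H)
  A <- dense_adj(n, src, dst, self_loops = TRUE)
  if (variant == "gat") {
    Wh <- H %*% hp$W
    msg <- Wh
    score <- function(u, v) {
      lrelu(sum(Wh[u, ] * hp$a_src) + sum(Wh[v, ] * hp$a_dst))
    }
  } else {
    L <- H %*% hp$Wl
    R <- H %*% hp$Wr
    msg <- L
    score <- function(u, v) sum(lrelu(L[u, ] + R[v, ]) * hp$a)
  }
  out <- matrix(0, n, ncol(msg))
  for (v in seq_len(n)) {
    nb <- which(A[, v] > 0)
    e <- vapply(nb, function(u) score(u, v), numeric(1))
    a <- exp(e - max(e)); a <- a / sum(a)
    for (i in seq_along(nb)) out[v, ] <- out[v, ] + a[i] * msg[nb[i], ]
  }
  out
}

oracle_attention_layer <- function(H, src, dst, params, variant, combine,
                                   act = identity) {
  outs <- lapply(params$heads, function(hp) {
    oracle_gat_head(H, src, dst, hp, variant)
  })
  comb <- if (combine == "concat") do.call(cbind, outs)
          else Reduce(`+`, outs) / length(outs)
  act(comb + matrix(params$b, nrow(H), length(params$b), byrow = TRUE))
}

# exhaustive pairwise AUROC
oracle_auroc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

oracle_mcc <- function(labels, pred) {
  tp <- sum(labels == 1 & pred == 1); tn <- sum(labels == 0 & pred == 0)
  fp <- sum(labels == 0 & pred == 1); fn <- sum(labels == 1 & pred == 0)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
}

# O(n^3) agglomerative average linkage; returns sorted merge heights
oracle_average_linkage_heights <- function(m) {
  d <- as.matrix(stats::dist(m))
  clusters <- as.list(seq_len(nrow(m)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, j, i)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# random small graph for layer tests
random_graph <- function(n = 8, f = 3, p_edge = 0.35,
                         with_isolated = FALSE) {
  x <- matrix(stats::rnorm(n * f), n, f)
  M <- matrix(stats::runif(n * n) < p_edge, n, n)
  diag(M) <- FALSE
  if (with_isolated) M[, 1] <- FALSE
  pr <- which(M, arr.ind = TRUE)
  new_graph(x, pr[, 1], pr[, 2],
            labels = sample(0:1, n, replace = TRUE),
            split = sample(c("train", "validation"), n, replace = TRUE))
}

# hand-built 4-patient toy cohort (fractions enumerated by hand in the tests)
toy_cohort <- function() {
  df <- data.frame(
    patient_id = c("A", "B", "B", "B", "C", "D", "D"),
    position = c(1L, 1L, 2L, 3L, 1L, 1L, 2L),
    age = 60, sex = 0L, hemoglobin = 8, rbc = 4.5, wbc = 7, mcv = 90,
    platelets = 250,
    label = c(1L, 0L, 0L, 1L, 0L, 0L, 1L),
    split = "train", stringsAsFactors = FALSE
  )
  class(df) <- c("cbc_cohort", "data.frame")
  df
}

small_cohort <- function(n_patients = 400, seed = 11, ...) {
  generate_cohort(cohort_config(n_patients = n_patients, seed = seed, ...))
}

# one-layer forward through the package path, for oracle comparisons
forward_layer <- function(type, g, f_out = 5, n_heads = 1, act = "relu",
                          seed = 1) {
  set.seed(seed)
  l <- cbcgnn:::init_layer(type, ncol(g$x), f_out, n_heads = n_heads)
  aux <- cbcgnn:::graph_aux(g, type)
  list(layer = l, out = cbcgnn:::layer_forward(l, g$x, aux, act))
}

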