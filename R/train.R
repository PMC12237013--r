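# ---- specifications --------------------------------------------------------

#' Architecture specification for a node classifier
#'
#' Two message-passing layers with 128 hidden neurons are the reference
#' configuration; attention variants support 1 or 2 heads (heads are
#' concatenated in hidden layers and averaged at the output layer).
#'
#' @param layer_type One of `"sage"`, `"gcn"`, `"gat"`, `"gatv2"`, `"gin"`.
#' @param n_layers Number of message-passing layers (default 2).
#' @param hidden_dim Hidden width (default 128).
#' @param n_heads Attention heads for gat/gatv2.
#' @param activation Hidden activation (`"relu"` or `"elu"`).
#' @return A `cbc_model_spec`.
#' @export
model_spec <- function(layer_type = c("sage", "gcn", "gat", "gatv2", "gin"),
                       n_layers = 2L, hidden_dim = 128L, n_heads = 1L,
                       activation = "relu") {
  layer_type <- match.arg(layer_type)
  if (hidden_dim < 1 || n_heads < 1 || n_layers < 1) {
    stop("hidden_dim, n_heads and n_layers must be >= 1")
  }
  structure(list(layer_type = layer_type, n_layers = as.integer(n_layers),
                 hidden_dim = as.integer(hidden_dim),
                 n_heads = as.integer(n_heads), activation = activation),
            class = "cbc_model_spec")
}

#' Training specification
#'
#' Defaults follow the reference protocol: learning rate 0.0003, up to
#' 10,000 epochs, early stopping after `patience` consecutive increases of
#' the validation loss (10 for similarity graphs; 5 is the patient-centric
#' protocol), full-graph training whenever the node count does not exceed
#' `batch_size` (50,000), otherwise patient-complete node batches.
#'
#' @param learning_rate Adam learning rate.
#' @param max_epochs Epoch cap.
#' @param patience Consecutive validation-loss increases before stopping.
#' @param batch_size Maximum nodes per full-graph pass.
#' @param seed Seed for parameter initialization (and batch shuffling).
#' @param class_weight Weight classes inversely to frequency in the loss
#'   (off by default).
#' @param restore_best Return the parameters from the epoch with minimum
#'   validation loss rather than the last epoch.
#' @return A `cbc_train_spec`.
#' @export
train_spec <- function(learning_rate = 3e-4, max_epochs = 10000L,
                       patience = 10L, batch_size = 50000L, seed = 1L,
                       class_weight = FALSE, restore_best = TRUE) {
  if (patience < 1) stop("patience must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 class_weight = class_weight, restore_best = restore_best),
            class = "cbc_train_spec")
}

# ---- model assembly --------------------------------------------------------

#' Initialize an untrained node classifier
#'
#' @param spec A [model_spec()].
#' @param n_features Input feature width of the graph.
#' @param seed Seed for Glorot initialization.
#' @return A `cbc_gnn_model` (untrained; `predict_proba()` works on it).
#' @export
init_gnn_model <- function(spec, n_features, seed = 1L) {
  set.seed(seed)
  layers <- vector("list", spec$n_layers)
  f_in <- n_features
  for (i in seq_len(spec$n_layers)) {
    last <- i == spec$n_layers
    layers[[i]] <- init_layer(spec$layer_type, f_in,
                              if (last) 2L else spec$hidden_dim,
                              n_heads = spec$n_heads,
                              combine = if (last) "mean" else "concat")
    f_in <- spec$hidden_dim
  }
  structure(list(spec = spec, layers = layers, n_features = n_features,
                 history = NULL, stopped_epoch = 0L),
            class = "cbc_gnn_model")
}

model_forward <- function(model, x, aux, keep_cache = FALSE) {
  H <- x
  caches <- list()
  attn <- list()
  for (i in seq_along(model$layers)) {
    last <- i == length(model$layers)
    fw <- layer_forward(model$layers[[i]], H, aux,
                        act_name = if (last) "identity" else model$spec$activation)
    H <- fw$out
    if (keep_cache) caches[[i]] <- fw$cache
    if (!is.null(fw$attention)) attn[[i]] <- fw$attention
  }
  list(logits = H, caches = caches, attention = attn)
}

model_backward <- function(model, dLogits, caches, aux) {
  grads <- vector("list", length(model$layers))
  dH <- dLogits
  for (i in rev(seq_along(model$layers))) {
    bw <- layer_backward(model$layers[[i]], dH, caches[[i]], aux)
    grads[[i]] <- bw$grads
    dH <- bw$dH
  }
  grads
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

# cross-entropy on masked nodes; returns loss and gradient wrt logits
masked_ce <- function(logits, labels, mask, weights = NULL) {
  idx <- which(mask)
  p <- softmax_rows(logits[idx, , drop = FALSE])
  y <- labels[idx]
  w <- if (is.null(weights)) rep(1, length(idx)) else weights[y + 1L]
  w <- w / sum(w)
  ll <- -sum(w * log(pmax(p[cbind(seq_along(idx), y + 1L)], 1e-12)))
  dLogits <- matrix(0, nrow(logits), 2)
  Y <- matrix(0, length(idx), 2)
  Y[cbind(seq_along(idx), y + 1L)] <- 1
  dLogits[idx, ] <- w * (p - Y)
  list(loss = ll, dLogits = dLogits)
}

# ---- Adam over nested parameter lists --------------------------------------

adam_init <- function(params) {
  walk <- function(p) {
    if (is.list(p)) lapply(p, walk)
    else list(m = p * 0, v = p * 0)
  }
  lapply(params, walk)
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, s) {
    if (is.list(p)) {
      out <- Map(walk, p, g, s)
      return(list(p = lapply(out, `[[`, "p"), s = lapply(out, `[[`, "s")))
    }
    m <- beta1 * s$m + (1 - beta1) * g
    v <- beta2 * s$v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), s = list(m = m, v = v))
  }
  out <- Map(walk, params, grads, state)
  list(params = lapply(out, `[[`, "p"), state = lapply(out, `[[`, "s"))
}

model_params <- function(model) lapply(model$layers, `[[`, "params")

set_model_params <- function(model, params) {
  for (i in seq_along(model$layers)) model$layers[[i]]$params <- params[[i]]
  model
}

# ---- training loop ---------------------------------------------------------

#' Train a node classifier with validation-loss early stopping
#'
#' Optimizes masked cross-entropy on the train-split nodes with Adam,
#' monitoring the loss on the validation-split nodes each epoch. Training
#' stops at `max_epochs` or once the validation loss has increased for
#' `patience` consecutive epochs; by default the parameters from the epoch
#' with minimum validation loss are restored. Test-split labels are never
#' read. When the graph exceeds `batch_size` nodes, gradient steps run on
#' patient-complete node batches (a patient's subgraph is never split).
#'
#' @param graph A `cbc_graph` with train and validation nodes.
#' @param spec A [model_spec()].
#' @param tspec A [train_spec()].
#' @return A trained `cbc_gnn_model` with `history` (per-epoch train/val
#'   loss) and `stopped_epoch`.
#' @export
train_node_classifier <- function(graph, spec = model_spec("sage"),
                                  tspec = train_spec()) {
  train_mask <- !is.na(graph$split) & graph$split == "train"
  val_mask <- !is.na(graph$split) & graph$split == "validation"
  if (!any(train_mask) || !any(val_mask)) {
    stop("graph needs non-empty train and validation masks")
  }
  y_train <- graph$labels[train_mask]
  if (length(unique(y_train)) < 2) {
    stop("training mask contains a single class; cannot fit a classifier")
  }
  weights <- if (isTRUE(tspec$class_weight)) {
    cnt <- tabulate(y_train + 1L, 2)
    sum(cnt) / (2 * cnt)
  } else NULL

  model <- init_gnn_model(spec, ncol(graph$x), seed = tspec$seed)
  aux <- graph_aux(graph, spec$layer_type)
  params <- model_params(model)
  state <- adam_init(params)
  batches <- make_batches(graph, tspec$batch_size)
  if (!is.null(batches)) {
    batches <- lapply(batches, function(b) {
      b$aux <- graph_aux(b$graph, spec$layer_type)
      b
    })
  }

  history <- matrix(NA_real_, tspec$max_epochs, 2,
                    dimnames = list(NULL, c("train_loss", "val_loss")))
  best_val <- Inf; best_params <- params
  prev_val <- Inf; n_increase <- 0L; stopped <- tspec$max_epochs
  step <- 0L

  for (epoch in seq_len(tspec$max_epochs)) {
    model <- set_model_params(model, params)
    if (is.null(batches)) {
      fw <- model_forward(model, graph$x, aux, keep_cache = TRUE)
      ce <- masked_ce(fw$logits, graph$labels, train_mask, weights)
      if (!is.finite(ce$loss)) {
        stop(sprintf("non-finite training loss at epoch %d; try a lower learning rate", epoch))
      }
      grads <- model_backward(model, ce$dLogits, fw$caches, aux)
      step <- step + 1L
      upd <- adam_step(params, grads, state, tspec$learning_rate, step)
      params <- upd$params; state <- upd$state
      train_loss <- ce$loss
      logits_full <- fw$logits
    } else {
      losses <- numeric(length(batches))
      for (b in seq_along(batches)) {
        sub <- batches[[b]]
        model <- set_model_params(model, params)
        fw <- model_forward(model, sub$graph$x, sub$aux, keep_cache = TRUE)
        ce <- masked_ce(fw$logits, sub$graph$labels,
                        !is.na(sub$graph$split) & sub$graph$split == "train",
                        weights)
        if (!is.finite(ce$loss)) {
          stop(sprintf("non-finite training loss at epoch %d", epoch))
        }
        grads <- model_backward(model, ce$dLogits, fw$caches, sub$aux)
        step <- step + 1L
        upd <- adam_step(params, grads, state, tspec$learning_rate, step)
        params <- upd$params; state <- upd$state
        losses[b] <- ce$loss
      }
      train_loss <- mean(losses)
      model <- set_model_params(model, params)
      logits_full <- model_forward(model, graph$x, aux)$logits
    }
    val_loss <- masked_ce(logits_full, graph$labels, val_mask, weights)$loss
    history[epoch, ] <- c(train_loss, val_loss)

    if (val_loss < best_val) {
      best_val <- val_loss
      best_params <- params
    }
    if (val_loss > prev_val) n_increase <- n_increase + 1L else n_increase <- 0L
    prev_val <- val_loss
    if (n_increase >= tspec$patience) {
      stopped <- epoch
      break
    }
  }

  final <- if (isTRUE(tspec$restore_best)) best_params else params
  model <- set_model_params(model, final)
  model$history <- data.frame(epoch = seq_len(stopped),
                              history[seq_len(stopped), , drop = FALSE])
  model$stopped_epoch <- stopped
  model$train_spec <- tspec
  model
}

# patient-complete node batches; NULL when the full graph fits one batch
make_batches <- function(graph, batch_size) {
  n <- n_nodes(graph)
  if (n <= batch_size) return(NULL)
  pat <- graph$patient
  pat[is.na(pat)] <- paste0(".node", which(is.na(pat)))
  groups <- split(seq_len(n), pat)
  batches <- list(); cur <- integer(0)
  out <- list()
  for (g in groups) {
    if (length(cur) && length(cur) + length(g) > batch_size) {
      out[[length(out) + 1L]] <- cur
      cur <- integer(0)
    }
    cur <- c(cur, g)
  }
  if (length(cur)) out[[length(out) + 1L]] <- cur
  lapply(out, function(nodes) {
    nodes <- sort(nodes)
    inset <- logical(n); inset[nodes] <- TRUE
    remap <- integer(n); remap[nodes] <- seq_along(nodes)
    keep <- inset[graph$src] & inset[graph$dst]
    sub <- new_graph(graph$x[nodes, , drop = FALSE],
                     remap[graph$src[keep]], remap[graph$dst[keep]],
                     labels = graph$labels[nodes],
                     split = graph$split[nodes],
                     patient = graph$patient[nodes],
                     node_type = graph$node_type[nodes])
    list(graph = sub, aux = NULL)
  })
}

# ---- prediction & attention ------------------------------------------------

#' Per-node class probabilities
#'
#' Generic `predict_proba` contract shared by every model in the package:
#' returns an `n x 2` matrix of class probabilities (columns: control,
#' sepsis) summing to 1 per row.
#'
#' @param model A trained model.
#' @param newdata A `cbc_graph` (GNN models) or feature matrix (tabular
#'   models).
#' @param ... Unused.
#' @return Numeric matrix with columns `control`, `sepsis`.
#' @export
predict_proba <- function(model, newdata, ...) UseMethod("predict_proba")

#' @rdname predict_proba
#' @export
predict_proba.cbc_gnn_model <- function(model, newdata, ...) {
  if (!inherits(newdata, "cbc_graph")) stop("GNN models predict on a cbc_graph")
  if (ncol(newdata$x) != model$n_features) {
    stop(sprintf("graph has %d features but model expects %d",
                 ncol(newdata$x), model$n_features))
  }
  aux <- graph_aux(newdata, model$spec$layer_type)
  p <- softmax_rows(model_forward(model, newdata$x, aux)$logits)
  colnames(p) <- c("control", "sepsis")
  p
}

#' Extract attention weights from a trained attention model
#'
#' Re-runs the forward pass and returns one record per (layer, head, arc),
#' self-loops included. Within each (layer, head, target) the weights sum
#' to 1.
#'
#' @param model A trained `cbc_gnn_model` with `layer_type` gat or gatv2.
#' @param graph The graph to run on.
#' @return data.frame with columns `layer`, `head`, `source`, `target`,
#'   `weight`.
#' @export
extract_attention <- function(model, graph) {
  if (!model$spec$layer_type %in% c("gat", "gatv2")) {
    stop("attention weights exist only for gat/gatv2 models")
  }
  aux <- graph_aux(graph, model$spec$layer_type)
  fw <- model_forward(model, graph$x, aux)
  recs <- list()
  for (l in seq_along(fw$attention)) {
    for (h in seq_along(fw$attention[[l]])) {
      recs[[length(recs) + 1L]] <- data.frame(
        layer = l, head = h, source = aux$src_sl, target = aux$dst_sl,
        weight = fw$attention[[l]][[h]])
    }
  }
  do.call(rbind, recs)
}

# ---- checkpoints -----------------------------------------------------------

serialize_params <- function(p) {
  if (is.list(p)) return(lapply(p, serialize_params))
  list(dim = dim(p), values = as.vector(p))
}

deserialize_params <- function(p) {
  if (!is.null(p$values) || (is.list(p) && identical(sort(names(p)),
                                                     c("dim", "values")))) {
    v <- as.numeric(p$values)
    if (length(p$dim)) v <- array(v, dim = unlist(p$dim))
    return(v)
  }
  lapply(p, deserialize_params)
}

#' Save / load a trained model checkpoint
#'
#' Writes a directory with `model_spec.json`, `params.json` (full-precision
#' parameter values) and `history.csv`.
#'
#' @param model A `cbc_gnn_model`.
#' @param dir Checkpoint directory.
#' @return `dir` (resp. the restored model).
#' @export
write_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    c(unclass(model$spec), list(n_features = model$n_features,
                                stopped_epoch = model$stopped_epoch)),
    file.path(dir, "model_spec.json"), auto_unbox = TRUE)
  jsonlite::write_json(serialize_params(model_params(model)),
                       file.path(dir, "params.json"), auto_unbox = FALSE,
                       digits = NA, null = "null")
  if (!is.null(model$history)) {
    utils::write.csv(model$history, file.path(dir, "history.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_model
#' @export
read_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model_spec.json"),
                              simplifyVector = TRUE)
  spec <- model_spec(meta$layer_type, n_layers = meta$n_layers,
                     hidden_dim = meta$hidden_dim, n_heads = meta$n_heads,
                     activation = meta$activation)
  model <- init_gnn_model(spec, meta$n_features, seed = 1L)
  raw <- jsonlite::read_json(file.path(dir, "params.json"))
  model <- set_model_params(model, deserialize_params(raw))
  model$stopped_epoch <- meta$stopped_epoch
  hist_path <- file.path(dir, "history.csv")
  if (file.exists(hist_path)) model$history <- utils::read.csv(hist_path)
  model
}

#' Dump attention records as TSV
#'
#' Columns: layer, head, source, target, weight.
#'
#' @param records Output of [extract_attention()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_attention <- function(records, path) {
  utils::write.table(records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
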