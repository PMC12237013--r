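separable_graph <- function(n_per = 60, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * 2, -2), n_per, 2),
             matrix(rnorm(n_per * 2, 2), n_per, 2))
  new_graph(x, labels = rep(0:1, each = n_per),
            split = rep(c("train", "validation"), length.out = 2 * n_per))
}

fast_tspec <- function(max_epochs = 200, ...) {
  train_spec(learning_rate = 0.05, max_epochs = max_epochs, patience = 10, ...)
}

test_that("a linearly separable toy reaches training AUROC 1", {
  g <- separable_graph()
  for (type in c("sage", "gat")) {
    m <- train_node_classifier(g, model_spec(type, hidden_dim = 8),
                               fast_tspec(seed = 2))
    p <- predict_proba(m, g)[, "sepsis"]
    expect_equal(auroc(g$labels, p), 1)
    expect_lte(m$stopped_epoch, 200)
    expect_equal(nrow(m$history), m$stopped_epoch)
  }
})

test_that("training is deterministic for a fixed seed", {
  g <- separable_graph()
  m1 <- train_node_classifier(g, model_spec("gin", hidden_dim = 8),
                              fast_tspec(seed = 5, max_epochs = 60))
  m2 <- train_node_classifier(g, model_spec("gin", hidden_dim = 8),
                              fast_tspec(seed = 5, max_epochs = 60))
  expect_identical(m1$history, m2$history)
  expect_identical(predict_proba(m1, g), predict_proba(m2, g))
})

test_that("early stopping fires after `patience` consecutive increases", {
  g <- separable_graph(n_per = 30)
  # an aggressive learning rate makes the validation loss oscillate
  m <- train_node_classifier(g, model_spec("sage", hidden_dim = 4),
                             train_spec(learning_rate = 1.5,
                                        max_epochs = 400, patience = 2,
                                        seed = 3))
  expect_lte(m$stopped_epoch, 400)
  if (m$stopped_epoch < 400) {
    v <- m$history$val_loss
    k <- m$stopped_epoch
    expect_true(all(diff(v[(k - 2):k]) > 0))  # the 2 final increases
  }
  # restored parameters come from the best-validation epoch
  expect_lte(min(m$history$val_loss),
             m$history$val_loss[m$stopped_epoch])
})

test_that("single-class training masks are rejected", {
  g <- separable_graph(n_per = 20)
  g$labels[g$split == "train"] <- 0L
  expect_error(train_node_classifier(g, model_spec("sage", hidden_dim = 4),
                                     fast_tspec(seed = 1)),
               "single class")
})

test_that("probabilities sum to one and zeroed output weights give 0.5", {
  g <- separable_graph(n_per = 25)
  m <- init_gnn_model(model_spec("sage", hidden_dim = 8), 2, seed = 1)
  p <- predict_proba(m, g)
  expect_lt(max(abs(rowSums(p) - 1)), 1e-6)
  # zero the final layer -> logits are all equal -> [0.5, 0.5]
  m$layers[[2]]$params <- lapply(m$layers[[2]]$params, function(x) x * 0)
  p0 <- predict_proba(m, g)
  expect_equal(unname(p0), matrix(0.5, nrow(p0), 2))
})

test_that("predictions are invariant to a consistent node permutation", {
  set.seed(6)
  g <- random_graph(n = 10, f = 3)
  g$split <- rep(c("train", "validation"), 5)
  g$labels <- rep(c(0L, 1L, 1L, 0L), length.out = 10)
  m <- train_node_classifier(g, model_spec("gat", hidden_dim = 8),
                             fast_tspec(seed = 4, max_epochs = 40))
  p <- predict_proba(m, g)
  perm <- sample(10); inv <- order(perm)
  gp <- new_graph(g$x[perm, ], inv[g$src], inv[g$dst],
                  labels = g$labels[perm], split = g$split[perm])
  expect_lt(max(abs(predict_proba(m, gp) - p[perm, ])), 1e-10)
})

test_that("feature-width mismatches are caught", {
  g <- separable_graph(n_per = 15)
  m <- init_gnn_model(model_spec("sage", hidden_dim = 4), 2, seed = 1)
  g$x <- cbind(g$x, 1)
  expect_error(predict_proba(m, g), "features")
})

test_that("training never reads test-split labels", {
  co <- small_cohort(250, seed = 21)
  std <- fit_standardizer(co)
  g <- build_patient_graph(co, "reversed", std)
  spec <- model_spec("sage", hidden_dim = 8)
  ts <- fast_tspec(seed = 7, max_epochs = 50)
  m1 <- train_node_classifier(g, spec, ts)
  g2 <- g
  test_rows <- g2$split %in% c("internal_test", "external_test")
  g2$labels[test_rows] <- 1L - g2$labels[test_rows]
  m2 <- train_node_classifier(g2, spec, ts)
  expect_identical(m1$history, m2$history)
  expect_identical(cbcgnn:::model_params(m1), cbcgnn:::model_params(m2))
})

test_that("patient-complete mini-batches never split a patient", {
  co <- small_cohort(120, seed = 22)
  g <- build_patient_graph(co, "directed", fit_standardizer(co))
  batches <- cbcgnn:::make_batches(g, batch_size = 40)
  expect_gt(length(batches), 1)
  pats <- lapply(batches, function(b) unique(b$graph$patient))
  expect_equal(sum(lengths(pats)), length(unique(co$patient_id)))
  expect_false(any(duplicated(unlist(pats))))
  # batched training runs end to end
  m <- train_node_classifier(g, model_spec("sage", hidden_dim = 4),
                             train_spec(learning_rate = 0.01,
                                        max_epochs = 5, patience = 2,
                                        batch_size = 40, seed = 1))
  expect_true(all(is.finite(m$history$val_loss)))
})

test_that("attention extraction is complete and reconstructs the forward pass", {
  set.seed(9)
  g <- random_graph(n = 8, f = 3)
  g$split <- rep(c("train", "validation"), 4)
  g$labels <- rep(c(0L, 1L, 1L, 0L), 2)
  m <- train_node_classifier(g, model_spec("gat", hidden_dim = 6, n_heads = 2),
                             fast_tspec(seed = 2, max_epochs = 30))
  rec <- extract_attention(m, g)
  n_arcs <- length(g$src) + nrow(g$x)  # self-loops included
  expect_equal(nrow(rec), 2 * 2 * n_arcs)  # layers x heads x arcs
  # per-(layer, head, target) normalization
  sums <- aggregate(weight ~ layer + head + target, rec, sum)
  expect_lt(max(abs(sums$weight - 1)), 1e-6)
  # single-node graph: one record per layer/head, weight 1
  g1 <- new_graph(matrix(rnorm(3), 1, 3))
  rec1 <- extract_attention(m, g1)
  expect_equal(rec1$weight, rep(1, 4))
  # reconstruction oracle: layer-1 head outputs rebuilt from the records
  aux <- cbcgnn:::graph_aux(g, "gat")
  fw <- cbcgnn:::model_forward(m, g$x, aux, keep_cache = TRUE)
  for (h in 1:2) {
    hp <- m$layers[[1]]$params$heads[[h]]
    Wh <- g$x %*% hp$W
    r <- rec[rec$layer == 1 & rec$head == h, ]
    out <- matrix(0, nrow(g$x), ncol(Wh))
    for (i in seq_len(nrow(r))) {
      out[r$target[i], ] <- out[r$target[i], ] + r$weight[i] * Wh[r$source[i], ]
    }
    expect_lt(max(abs(out - fw$caches[[1]]$heads[[h]]$out)), 1e-6)
  }
  # non-attention models refuse
  ms <- train_node_classifier(g, model_spec("sage", hidden_dim = 4),
                              fast_tspec(seed = 2, max_epochs = 10))
  expect_error(extract_attention(ms, g), "gat")
})

test_that("model checkpoints round-trip through the directory format", {
  g <- separable_graph(n_per = 20)
  m <- train_node_classifier(g, model_spec("gat", hidden_dim = 6, n_heads = 2),
                             fast_tspec(seed = 3, max_epochs = 15))
  dir <- withr::local_tempdir()
  write_model(m, dir)
  expect_setequal(list.files(dir),
                  c("model_spec.json", "params.json", "history.csv"))
  back <- read_model(dir)
  expect_equal(predict_proba(back, g), predict_proba(m, g))
  expect_equal(back$stopped_epoch, m$stopped_epoch)
  # attention dump
  path <- withr::local_tempfile(fileext = ".tsv")
  write_attention(extract_attention(m, g), path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_named(tab, c("layer", "head", "source", "target", "weight"))
})
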