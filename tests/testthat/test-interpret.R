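test_that("sex sweeps only its observed unique values", {
  co <- small_cohort(200, seed = 15)
  pd <- partial_dependence(function(co) rep(0.3, nrow(co)), co, "sex")
  expect_equal(pd$grid, c(0, 1))
  expect_equal(pd$avg_prediction, c(0.3, 0.3))
})

test_that("continuous features use a 100-point grid between P5 and P95", {
  co <- small_cohort(300, seed = 16)
  pd <- partial_dependence(function(co) rep(0.5, nrow(co)), co, "wbc")
  expect_equal(nrow(pd), 100)
  expect_equal(range(pd$grid), unname(quantile(co$wbc, c(0.05, 0.95))))
  expect_true(all(diff(pd$grid) > 0))
})

test_that("a closed-form sigmoid predictor reproduces its analytic curve", {
  co <- small_cohort(250, seed = 17)
  mu <- mean(co$wbc); s <- sd(co$wbc); beta <- 1.7
  fn <- function(co) plogis(beta * (co$wbc - mu) / s)
  pd <- partial_dependence(fn, co, "wbc")
  expect_lt(max(abs(pd$avg_prediction - plogis(beta * (pd$grid - mu) / s))),
            1e-8)
})

test_that("pdp of a predictor that ignores the feature is flat", {
  co <- small_cohort(150, seed = 18)
  fn <- function(co) plogis((co$platelets - 200) / 100)
  pd <- partial_dependence(fn, co, "wbc")
  expect_equal(diff(range(pd$avg_prediction)), 0)
})

test_that("pdp rejects unknown features and invalid probabilities", {
  co <- small_cohort(50, seed = 19)
  expect_error(partial_dependence(function(co) rep(0.1, nrow(co)), co,
                                  "creatinine"), "unknown feature")
  expect_error(partial_dependence(function(co) rep(1.5, nrow(co)), co,
                                  "wbc"), "outside")
})

test_that("importance is the normalized curve variance", {
  grid <- 1:10
  curve <- function(f, v) {
    structure(data.frame(feature = f, grid = grid, avg_prediction = v),
              class = c("cbc_pdp_curve", "data.frame"))
  }
  # dependence on one feature only
  cs <- list(wbc = curve("wbc", seq(0.1, 0.9, length.out = 10)),
             age = curve("age", rep(0.4, 10)))
  imp <- importance_from_pdp(cs)
  expect_equal(unname(imp), c(1, 0))
  # identical variances split evenly
  cs2 <- list(a = curve("a", seq(0, 1, length.out = 10)),
              b = curve("b", rev(seq(0, 1, length.out = 10))))
  expect_equal(unname(importance_from_pdp(cs2)), c(0.5, 0.5))
  # random curves match the direct variance-ratio oracle and sum to 1
  set.seed(50)
  cs3 <- lapply(1:5, function(i) curve(paste0("f", i), runif(10)))
  names(cs3) <- paste0("f", 1:5)
  imp3 <- importance_from_pdp(cs3)
  v <- vapply(cs3, function(cu) var(cu$avg_prediction), numeric(1))
  expect_equal(imp3, v / sum(v))
  expect_equal(sum(imp3), 1, tolerance = 1e-9)
  # all-constant curves are an error, not silent zeros
  cs4 <- list(a = curve("a", rep(0.2, 10)), b = curve("b", rep(0.7, 10)))
  expect_error(importance_from_pdp(cs4), "undefined")
})

test_that("model clustering is average-linkage on Euclidean distances", {
  m <- rbind(a = c(0.5, 0.5, 0), b = c(0.5, 0.5, 0), c = c(0, 0, 1))
  hc <- cluster_models(m)
  expect_equal(hc$height[1], 0)  # identical rows merge at height 0
  expect_setequal(abs(hc$merge[1, ]), 1:2)  # and merge first
  set.seed(51)
  m5 <- matrix(runif(20), 5, 4)
  hc5 <- cluster_models(m5)
  expect_equal(sort(hc5$height), oracle_average_linkage_heights(m5))
  expect_error(cluster_models(m5[1, , drop = FALSE]), "at least 2")
})

test_that("attention summaries group arcs by label concordance", {
  recs <- data.frame(layer = c(1, 1, 1), head = 1,
                     source = c(1, 2, 3), target = c(2, 3, 3),
                     weight = c(0.25, 0.75, 0.5))
  labels <- c(0, 0, 1)
  s <- summarize_attention_by_label(recs, labels)
  expect_equal(s$mean[s$group == "same_label"], 0.25)      # arc 1->2 (0,0)
  expect_equal(s$mean[s$group == "different_label"], 0.75) # arc 2->3 (0,1)
  expect_equal(s$mean[s$group == "self_loop"], 0.5)        # arc 3->3
  expect_equal(sum(s$n), nrow(recs))
  # all-same-label graphs flag the empty group instead of erroring
  s2 <- summarize_attention_by_label(recs, c(0, 0, 0))
  expect_true("different_label" %in% attr(s2, "empty_groups"))
  expect_error(summarize_attention_by_label(recs, c(0, NA, 1)),
               "without a label")
})

test_that("attention summary statistics match a direct grouping oracle", {
  set.seed(52)
  n <- 30
  src <- sample(n, 120, replace = TRUE)
  dst <- sample(n, 120, replace = TRUE)
  recs <- data.frame(layer = sample(1:2, 120, replace = TRUE), head = 1,
                     source = src, target = dst, weight = runif(120))
  labels <- sample(0:1, n, replace = TRUE)
  s <- summarize_attention_by_label(recs, labels)
  same <- recs$source != recs$target &
    labels[recs$source] == labels[recs$target]
  for (l in 1:2) {
    w <- recs$weight[same & recs$layer == l]
    expect_equal(s$mean[s$layer == l & s$group == "same_label"], mean(w))
    expect_equal(s$q50[s$layer == l & s$group == "same_label"],
                 unname(median(w)))
  }
})

test_that("pdp predict-fn factory substitutes features on graphs", {
  co <- small_cohort(150, seed = 23)
  std <- fit_standardizer(co)
  g <- build_knn_similarity_graph(std_transform(std, co), 3,
                                  labels = co$label, split = co$split)
  m <- train_node_classifier(g, model_spec("sage", hidden_dim = 8),
                             train_spec(learning_rate = 0.05,
                                        max_epochs = 30, patience = 5,
                                        seed = 1))
  fn <- pdp_predict_fn(m, std, graph_template = g)
  p <- fn(co)
  expect_equal(length(p), nrow(co))
  expect_true(all(p >= 0 & p <= 1))
  pd <- partial_dependence(fn, co, "wbc", grid_resolution = 5)
  expect_equal(nrow(pd), 5)
})

test_that("the sensitivity flag rebuilds the similarity graph per call", {
  co <- small_cohort(80, seed = 24)
  std <- fit_standardizer(co)
  g <- build_knn_similarity_graph(std_transform(std, co), 2,
                                  labels = co$label, split = co$split)
  m <- train_node_classifier(g, model_spec("sage", hidden_dim = 4),
                             train_spec(learning_rate = 0.05,
                                        max_epochs = 10, patience = 5,
                                        seed = 1))
  fn <- pdp_predict_fn(m, std, graph_template = g, rebuild_knn = TRUE)
  co2 <- co
  co2$wbc <- rep(mean(co$wbc), nrow(co))  # substitution changes neighborhoods
  p <- fn(co2)
  expect_equal(length(p), nrow(co))
  expect_true(all(p >= 0 & p <= 1))
})
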