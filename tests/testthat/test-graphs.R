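test_that("standardizer centers the fitting split and round-trips", {
  co <- small_cohort(300, seed = 4)
  std <- fit_standardizer(co)
  Xs <- std_transform(std, co)
  tr <- co$split == "train"
  expect_lt(max(abs(colMeans(Xs[tr, ]))), 1e-8)
  expect_lt(max(abs(apply(Xs[tr, ], 2, sd) - 1)), 1e-8)
  # algebraic round trip
  expect_lt(max(abs(std_inverse(std, Xs) - cohort_features(co))), 1e-10)
  # leakage contract: external rows transform with train moments, no refit
  ext <- Xs[co$split == "external_test", ]
  expect_true(all(is.finite(ext)))
  expect_gt(max(abs(colMeans(ext))), 1e-8)
})

test_that("a constant feature is rejected by name", {
  co <- small_cohort(50, seed = 1)
  co$sex <- 0L
  expect_error(fit_standardizer(co), "sex")
})

test_that("simple standardizer example: values 1,2,3", {
  co <- toy_cohort()[1:3, ]
  for (f in cbc_feature_names()) co[[f]] <- c(1, 2, 3)
  std <- fit_standardizer(co)
  expect_equal(unname(std$mean["age"]), 2)
  expect_equal(unname(std$sd["age"]), 1)
  expect_equal(std_transform(std, co)[2, "age"], 0)
})

test_that("k-NN graph matches the hand-computed 3-point example", {
  g <- build_knn_similarity_graph(matrix(c(0, 1, 10), ncol = 1), k = 1)
  got <- cbind(g$src, g$dst)
  expect_setequal(paste(got[, 1], got[, 2]), c("2 1", "1 2", "2 3"))
})

test_that("k = N-1 produces the complete digraph and k >= N warns", {
  X <- matrix(rnorm(12), 6, 2)
  g <- build_knn_similarity_graph(X, k = 5)
  expect_equal(length(g$src), 30)
  expect_true(all(g$src != g$dst))
  expect_warning(g2 <- build_knn_similarity_graph(X, k = 10), "k = 10")
  expect_equal(length(g2$src), 30)
  expect_error(build_knn_similarity_graph(X[1, , drop = FALSE], k = 1),
               "at least 2")
})

test_that("duplicated points tie-break by node index reproducibly", {
  X <- matrix(0, 4, 2)  # all identical
  g1 <- build_knn_similarity_graph(X, k = 2)
  g2 <- build_knn_similarity_graph(X, k = 2)
  expect_identical(g1$src, g2$src)
  # each node picks the two lowest other indices
  expect_equal(sort(g1$src[g1$dst == 4]), c(1, 2))
  expect_equal(sort(g1$src[g1$dst == 1]), c(2, 3))
})

test_that("k-NN neighborhoods equal a brute-force distance-sort oracle", {
  set.seed(20)
  for (rep in 1:8) {
    n <- sample(10:60, 1)
    k <- sample(1:5, 1)
    X <- matrix(rnorm(n * 3), n, 3)
    g <- build_knn_similarity_graph(X, k)
    D <- as.matrix(dist(X))
    for (v in seq_len(n)) {
      nn <- setdiff(order(D[v, ]), v)[seq_len(k)]
      expect_setequal(g$src[g$dst == v], nn)
    }
    expect_true(all(tabulate(g$dst, n) == min(k, n - 1)))
  }
})

test_that("patient graph arc counts follow the closed forms", {
  co <- small_cohort(200, seed = 8)
  std <- fit_standardizer(co)
  lens <- as.vector(table(co$patient_id))
  expect_true(any(lens == 1) && any(lens >= 3))  # singletons and sequences
  gd <- build_patient_graph(co, "directed", std)
  gr <- build_patient_graph(co, "reversed", std)
  gu <- build_patient_graph(co, "undirected", std)
  expect_equal(length(gd$src), sum(lens * (lens - 1) / 2))
  expect_equal(length(gr$src), sum(lens * (lens - 1) / 2))
  expect_equal(length(gu$src), sum(lens * (lens - 1)))
  # no arc crosses patients; directions respect positions
  expect_true(all(co$patient_id[gd$src] == co$patient_id[gd$dst]))
  expect_true(all(co$position[gd$src] < co$position[gd$dst]))
  expect_true(all(co$position[gr$src] > co$position[gr$dst]))
  # undirected arc set is closed under reversal
  expect_setequal(paste(gu$src, gu$dst), paste(gu$dst, gu$src))
  # reversed graph is the directed graph with arcs flipped
  expect_setequal(paste(gr$src, gr$dst), paste(gd$dst, gd$src))
})

test_that("a 5-measurement patient yields 10 directed arcs", {
  df <- toy_cohort()[rep(1, 5), ]
  df$position <- 1:5
  df$wbc <- c(5, 6, 7, 8, 9)  # avoid constant features
  df$age <- c(50, 55, 60, 65, 70)
  std <- list(mean = colMeans(cohort_features(df)),
              sd = apply(cohort_features(df), 2, function(x) max(sd(x), 1)))
  class(std) <- "cbc_standardizer"
  g <- build_patient_graph(df, "directed", std)
  expect_equal(length(g$src), 10)
  one <- toy_cohort()[1, ]
  expect_equal(length(build_patient_graph(one, "directed", std)$src), 0)
})

test_that("positional encodings behave per scheme", {
  co <- small_cohort(150, seed = 9)
  std <- fit_standardizer(co)
  g <- build_patient_graph(co, "directed", std)
  f0 <- ncol(g$x)
  ge <- add_positional_encoding(g, co, "scalar")
  expect_equal(ncol(ge$x), f0 + 1)
  # monotone in position, and equal positions share encodings across patients
  enc <- ge$x[, "pos_enc"]
  expect_true(all(diff(sort(unique(co$position))) > 0))
  expect_equal(order(tapply(enc, co$position, unique)),
               seq_along(unique(co$position)))
  expect_true(all(tapply(enc, co$position,
                         function(v) max(v) - min(v)) < 1e-12))
  expect_identical(add_positional_encoding(g, co, "none"), g)
  expect_error(add_positional_encoding(g, co, "fourier"), "unknown")
  gs <- add_positional_encoding(g, co, "sinusoidal", dim = 4)
  expect_equal(ncol(gs$x), f0 + 4)
})

test_that("graphs serialize to a directory and back", {
  co <- small_cohort(60, seed = 10)
  g <- build_patient_graph(co, "undirected", fit_standardizer(co))
  dir <- withr::local_tempdir()
  write_graph(g, dir)
  back <- read_graph(dir)
  expect_equal(back$x, g$x, ignore_attr = TRUE)
  expect_identical(back$src, g$src)
  expect_identical(back$labels, g$labels)
  expect_identical(back$split, g$split)
})

test_that("symmetric closure makes the k-NN arc set reversal-closed", {
  set.seed(33)
  X <- matrix(rnorm(40), 20, 2)
  g <- build_knn_similarity_graph(X, 3, symmetric = TRUE)
  expect_setequal(paste(g$src, g$dst), paste(g$dst, g$src))
  expect_gte(length(g$src), 60)
})
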