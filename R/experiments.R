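# Orchestration of the four experiment families on synthetic cohorts:
# similarity-graph benchmarking, patient-centric graph comparison, noise
# robustness, and the interpretability report. Experiments run over a seed
# list and report per-seed rows plus seed-mean summaries.

#' Configuration for the experiment runner
#'
#' @param cohort A [cohort_config()]; its seed is replaced by each entry of
#'   `seeds` in turn.
#' @param seeds Integer vector of run seeds (>= 1 entry).
#' @param k Neighbors for the k-NN similarity graph.
#' @param m Percentile bins per blood parameter.
#' @param pe_schemes Positional-encoding schemes for the patient-centric
#'   grid (subset of `"none"`, `"scalar"`, `"sinusoidal"`).
#' @param baseline_models Tabular baselines to run.
#' @param gnn_models Layer types for the homogeneous similarity graph.
#' @param hetero_models Layer types for the heterogeneous graph.
#' @param patient_models Layer types for the patient-centric grid.
#' @param graph_modes Patient-centric graph modes.
#' @param noise_levels Noise-feature counts for [run_noise_robustness()].
#' @param hidden_dim,n_heads Architecture settings for all GNNs.
#' @param max_epochs,learning_rate Training settings; patience follows the
#'   protocol (10 for similarity graphs, 5 for patient-centric).
#' @param threshold Probability threshold for F1/MCC.
#' @param out_dir Optional output directory for reports and a manifest.
#' @return A `cbc_experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_config(),
                              seeds = 1L,
                              k = 5L, m = 10L,
                              pe_schemes = c("none", "scalar"),
                              baseline_models = c("logistic_regression",
                                                  "decision_tree",
                                                  "random_forest", "mlp"),
                              gnn_models = c("sage", "gat", "gatv2", "gin"),
                              hetero_models = c("sage", "gin"),
                              patient_models = c("gat", "sage", "gcn"),
                              graph_modes = c("directed", "reversed",
                                              "undirected"),
                              noise_levels = c(0L, 10L, 100L),
                              hidden_dim = 128L, n_heads = 1L,
                              max_epochs = 10000L, learning_rate = 3e-4,
                              threshold = 0.5, out_dir = NULL) {
  if (length(seeds) < 1) stop("need at least one seed")
  structure(list(cohort = cohort, seeds = as.integer(seeds), k = as.integer(k),
                 m = as.integer(m), pe_schemes = pe_schemes,
                 baseline_models = baseline_models, gnn_models = gnn_models,
                 hetero_models = hetero_models,
                 patient_models = patient_models, graph_modes = graph_modes,
                 noise_levels = as.integer(noise_levels),
                 hidden_dim = as.integer(hidden_dim),
                 n_heads = as.integer(n_heads),
                 max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate, threshold = threshold,
                 out_dir = out_dir),
            class = "cbc_experiment_config")
}

seeded_cohort <- function(config, seed) {
  cc <- config$cohort
  cc$seed <- as.integer(seed)
  generate_cohort(cc)
}

eval_splits <- function(labels, scores, split, threshold) {
  out <- list()
  for (s in c("internal_test", "external_test")) {
    mask <- !is.na(split) & split == s
    r <- metric_report(labels[mask], scores[mask], threshold)
    out[[s]] <- data.frame(split = s, auroc = r$auroc, f1_macro = r$f1_macro,
                           mcc = r$mcc)
  }
  do.call(rbind, out)
}

baseline_matrix <- function(cohort, std, name) {
  # linear/NN models see standardized features, trees raw ones
  if (name %in% c("logistic_regression", "mlp")) std_transform(std, cohort)
  else cohort_features(cohort)
}

fit_eval_baseline <- function(name, cohort, std, seed, threshold,
                              X_all = NULL, max_epochs = 10000L) {
  X <- if (is.null(X_all)) baseline_matrix(cohort, std, name) else X_all
  tr <- cohort$split == "train"
  va <- cohort$split == "validation"
  model <- train_tabular_baseline(
    name, X[tr, , drop = FALSE], cohort$label[tr], seed = seed,
    X_val = if (name == "mlp") X[va, , drop = FALSE] else NULL,
    y_val = if (name == "mlp") cohort$label[va] else NULL,
    mlp_tspec = if (name == "mlp") train_spec(patience = 10L, seed = seed,
                                              max_epochs = max_epochs)
                else NULL)
  scores <- predict_proba(model, X)[, "sepsis"]
  list(model = model,
       rows = eval_splits(cohort$label, scores, cohort$split, threshold))
}

fit_eval_gnn <- function(graph, layer_type, config, seed, patience,
                         labels = graph$labels, split = graph$split) {
  spec <- model_spec(layer_type, hidden_dim = config$hidden_dim,
                     n_heads = config$n_heads)
  tspec <- train_spec(learning_rate = config$learning_rate,
                      max_epochs = config$max_epochs, patience = patience,
                      seed = seed)
  model <- train_node_classifier(graph, spec, tspec)
  scores <- predict_proba(model, graph)[, "sepsis"]
  list(model = model,
       rows = eval_splits(labels, scores, split, config$threshold))
}

#' Benchmark models on similarity graphs
#'
#' Trains the tabular baselines and the graph models on the homogeneous
#' k-NN and heterogeneous percentile-bin similarity graphs of a synthetic
#' cohort (one transductive graph over all splits; the loss only ever sees
#' train-split labels) and evaluates AUROC / F1-macro / MCC on the internal
#' and external test splits.
#'
#' @param config An [experiment_config()].
#' @return List with per-seed `results` rows, a seed-mean `summary`, and
#'   the `manifest`.
#' @export
run_similarity_benchmark <- function(config = experiment_config()) {
  rows <- list()
  for (seed in config$seeds) {
    cohort <- seeded_cohort(config, seed)
    std <- fit_standardizer(cohort)
    for (nm in config$baseline_models) {
      r <- fit_eval_baseline(nm, cohort, std, seed, config$threshold,
                             max_epochs = config$max_epochs)$rows
      rows[[length(rows) + 1L]] <- cbind(seed = seed, model = nm,
                                         graph = "tabular", r)
    }
    if (length(config$gnn_models)) {
      g <- build_knn_similarity_graph(std_transform(std, cohort), config$k,
                                      labels = cohort$label,
                                      split = cohort$split,
                                      patient = cohort$patient_id)
      for (lt in config$gnn_models) {
        r <- fit_eval_gnn(g, lt, config, seed, patience = 10L)$rows
        rows[[length(rows) + 1L]] <- cbind(seed = seed, model = lt,
                                           graph = "knn", r)
      }
    }
    if (length(config$hetero_models)) {
      hg <- as_homogeneous(build_hetero_similarity_graph(cohort, config$m,
                                                         std))
      for (lt in config$hetero_models) {
        r <- fit_eval_gnn(hg, lt, config, seed, patience = 10L)$rows
        rows[[length(rows) + 1L]] <- cbind(seed = seed, model = lt,
                                           graph = "hetero", r)
      }
    }
  }
  finish_report(rows, config, "similarity_benchmark")
}

#' Benchmark GNNs on patient-centric graphs
#'
#' Runs the full grid of graph modes (directed / reversed / undirected) x
#' positional-encoding schemes x layer types, with the patient-centric
#' training protocol (patience 5), and reports per-seed and seed-mean AUROC
#' on both test splits.
#'
#' @param config An [experiment_config()].
#' @return List with `results`, `summary`, `manifest`.
#' @export
run_patient_centric_benchmark <- function(config = experiment_config()) {
  rows <- list()
  for (seed in config$seeds) {
    cohort <- seeded_cohort(config, seed)
    std <- fit_standardizer(cohort)
    for (mode in config$graph_modes) {
      g0 <- build_patient_graph(cohort, mode, std)
      for (pe in config$pe_schemes) {
        g <- add_positional_encoding(g0, cohort, pe)
        for (lt in config$patient_models) {
          r <- fit_eval_gnn(g, lt, config, seed, patience = 5L)$rows
          rows[[length(rows) + 1L]] <- cbind(seed = seed, model = lt,
                                             graph = mode, pe = pe, r)
        }
      }
    }
  }
  finish_report(rows, config, "patient_centric_benchmark")
}

#' Noise-robustness experiment
#'
#' Appends 0 / 10 / 100 uniform noise features to the input matrix, retrains
#' every model at each noise level, and reports the metric deltas relative
#' to the noise-free run.
#'
#' @param config An [experiment_config()]; `noise_levels` defines the grid.
#'   GraphSAGE on the k-NN graph represents the GNNs (the graph is rebuilt
#'   from the noisy standardized features).
#' @return List with `results`, `summary` (including `delta_auroc`),
#'   `manifest`.
#' @export
run_noise_robustness <- function(config = experiment_config()) {
  rows <- list()
  for (seed in config$seeds) {
    cohort <- seeded_cohort(config, seed)
    for (n_noise in config$noise_levels) {
      Xraw <- add_noise_features(cohort_features(cohort), n_noise,
                                 seed = seed + 1000L)
      tr <- cohort$split == "train"
      mu <- colMeans(Xraw[tr, , drop = FALSE])
      sd <- apply(Xraw[tr, , drop = FALSE], 2, stats::sd)
      Xstd <- sweep(sweep(Xraw, 2, mu), 2, sd, "/")
      for (nm in config$baseline_models) {
        X <- if (nm %in% c("logistic_regression", "mlp")) Xstd else Xraw
        r <- fit_eval_baseline(nm, cohort, NULL, seed, config$threshold,
                               X_all = X, max_epochs = config$max_epochs)$rows
        rows[[length(rows) + 1L]] <- cbind(seed = seed, model = nm,
                                           n_noise = n_noise, r)
      }
      for (lt in intersect(config$gnn_models, "sage")) {
        g <- build_knn_similarity_graph(Xstd, config$k,
                                        labels = cohort$label,
                                        split = cohort$split,
                                        patient = cohort$patient_id)
        r <- fit_eval_gnn(g, lt, config, seed, patience = 10L)$rows
        rows[[length(rows) + 1L]] <- cbind(seed = seed, model = lt,
                                           n_noise = n_noise, r)
      }
    }
  }
  rep <- finish_report(rows, config, "noise_robustness")
  res <- rep$results
  base <- res[res$n_noise == 0, c("seed", "model", "split", "auroc")]
  names(base)[4] <- "auroc0"
  res <- merge(res, base, by = c("seed", "model", "split"), sort = FALSE)
  res$delta_auroc <- res$auroc - res$auroc0
  rep$results <- res
  rep
}

#' Interpretability report
#'
#' Trains the configured models, computes partial-dependence curves for all
#' seven input features on the internal-test split, derives the
#' normalized-variance importance table, clusters the models by their
#' importance rows, and (for attention models on a patient-centric graph)
#' summarizes attention weights by label concordance.
#'
#' @param config An [experiment_config()]; the first seed is used.
#' @param attention_mode Patient-graph mode for the attention summary.
#' @return List with `pdp` (long data.frame), `importance` (models x
#'   features matrix), `clustering` (hclust or NULL), `attention_summary`,
#'   `manifest`.
#' @export
run_interpretability_report <- function(config = experiment_config(),
                                        attention_mode = "reversed") {
  seed <- config$seeds[1]
  cohort <- seeded_cohort(config, seed)
  std <- fit_standardizer(cohort)
  eval_rows <- cohort$split == "internal_test"

  fns <- list()
  for (nm in config$baseline_models) {
    fit <- fit_eval_baseline(nm, cohort, std, seed, config$threshold,
                             max_epochs = config$max_epochs)$model
    uses_std <- nm %in% c("logistic_regression", "mlp")
    fns[[nm]] <- pdp_predict_fn(fit, if (uses_std) std else NULL,
                                rows = eval_rows)
  }
  if (length(config$gnn_models)) {
    lt <- config$gnn_models[1]
    g <- build_knn_similarity_graph(std_transform(std, cohort), config$k,
                                    labels = cohort$label,
                                    split = cohort$split,
                                    patient = cohort$patient_id)
    fit <- fit_eval_gnn(g, lt, config, seed, patience = 10L)$model
    fns[[paste0(lt, "_knn")]] <- pdp_predict_fn(fit, std, graph_template = g,
                                                rows = eval_rows)
  }

  pdp_rows <- list(); imp <- list()
  for (mdl in names(fns)) {
    curves <- lapply(cbc_feature_names(), function(f) {
      partial_dependence(fns[[mdl]], cohort, f)
    })
    names(curves) <- cbc_feature_names()
    imp[[mdl]] <- importance_from_pdp(curves)
    for (cu in curves) {
      pdp_rows[[length(pdp_rows) + 1L]] <- cbind(model = mdl, cu)
    }
  }
  importance <- do.call(rbind, imp)
  clustering <- if (nrow(importance) >= 2) cluster_models(importance) else NULL

  attention_summary <- NULL
  if (any(config$patient_models %in% c("gat", "gatv2"))) {
    lt <- intersect(config$patient_models, c("gat", "gatv2"))[1]
    pg <- build_patient_graph(cohort, attention_mode, std)
    fit <- fit_eval_gnn(pg, lt, config, seed, patience = 5L)$model
    recs <- extract_attention(fit, pg)
    attention_summary <- summarize_attention_by_label(recs, pg$labels)
  }

  out <- list(pdp = do.call(rbind, pdp_rows), importance = importance,
              clustering = clustering, attention_summary = attention_summary,
              manifest = build_manifest(config, "interpretability_report"))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out$pdp, file.path(config$out_dir, "pdp_curves.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(model = rownames(importance), importance),
                     file.path(config$out_dir, "importance.csv"),
                     row.names = FALSE)
    if (!is.null(attention_summary)) {
      jsonlite::write_json(attention_summary,
                           file.path(config$out_dir, "attention_summary.json"),
                           dataframe = "rows", na = "null")
    }
    jsonlite::write_json(out$manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, null = "null")
  }
  out
}

# ---- report plumbing -------------------------------------------------------

finish_report <- function(rows, config, experiment) {
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  by_cols <- intersect(c("model", "graph", "pe", "n_noise", "split"),
                       names(results))
  agg <- stats::aggregate(results[, c("auroc", "f1_macro", "mcc")],
                          results[by_cols], function(x) mean(x))
  sdv <- stats::aggregate(results[, "auroc", drop = FALSE],
                          results[by_cols], stats::sd)
  names(sdv)[names(sdv) == "auroc"] <- "auroc_sd"
  summary <- merge(agg, sdv, by = by_cols, sort = FALSE)
  manifest <- build_manifest(config, experiment)
  out <- list(results = results, summary = summary, manifest = manifest)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(results,
                     file.path(config$out_dir, paste0(experiment, ".csv")),
                     row.names = FALSE)
    jsonlite::write_json(summary,
                         file.path(config$out_dir,
                                   paste0(experiment, "_summary.json")),
                         dataframe = "rows", digits = NA)
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, null = "null")
  }
  out
}

# 32-bit FNV-1a over the deparsed configuration
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit modular multiply in exact double arithmetic
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

build_manifest <- function(config, experiment) {
  list(experiment = experiment,
       package_version = tryCatch(
         as.character(utils::packageVersion("cbcgnn")),
         error = function(e) "dev"),
       r_version = as.character(getRversion()),
       seeds = config$seeds,
       config_hash = config_hash(config),
       timestamp = format(Sys.time(), tz = "UTC"))
}
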