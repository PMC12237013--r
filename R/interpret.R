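# Model-agnostic partial dependence (graph-compatible), normalized-variance
# feature importance, model clustering, and attention-weight summaries.

#' Build a prediction closure for partial dependence
#'
#' Wraps a trained model into a function mapping a full raw-scale cohort to
#' per-row sepsis probabilities, applying the required transformations
#' (train-split standardization, feature-matrix extraction, graph feature
#' substitution). For graph models the edges of `graph_template` are held
#' fixed while node features are substituted; the similarity graph is not
#' rebuilt per grid value (rebuilding would change the estimand and is far
#' more expensive; see the methods vignette).
#'
#' @param model A `cbc_gnn_model` or `cbc_tabular_model`.
#' @param standardizer The train-split [fit_standardizer()] used by the
#'   model (`NULL` for models trained on raw features, e.g. trees).
#' @param graph_template For graph models, the graph whose edges (and any
#'   positional-encoding columns) are reused.
#' @param rows Optional row filter (e.g. an evaluation-split mask) applied
#'   to the returned probabilities.
#' @param rebuild_knn Sensitivity-analysis flag: rebuild the k-NN similarity
#'   graph from the substituted features on every call instead of keeping
#'   the template's edges fixed (changes the estimand; much slower). Uses
#'   the template's `k`.
#' @return `function(cohort) -> numeric` of sepsis probabilities.
#' @export
pdp_predict_fn <- function(model, standardizer = NULL, graph_template = NULL,
                           rows = NULL, rebuild_knn = FALSE) {
  force(model); force(standardizer); force(graph_template); force(rows)
  force(rebuild_knn)
  function(cohort) {
    if (inherits(model, "cbc_gnn_model")) {
      stopifnot(!is.null(graph_template))
      g <- graph_template
      X <- if (is.null(standardizer)) cohort_features(cohort)
           else std_transform(standardizer, cohort)
      if (rebuild_knn) {
        stopifnot(identical(g$meta$kind, "knn_similarity"))
        g <- build_knn_similarity_graph(X, g$meta$k, labels = g$labels,
                                        split = g$split, patient = g$patient,
                                        symmetric = isTRUE(g$meta$symmetric))
      }
      meas <- which(g$node_type == "measurement")
      g$x[meas, colnames(X)] <- X
      p <- predict_proba(model, g)[meas, "sepsis"]
    } else {
      X <- if (is.null(standardizer)) cohort_features(cohort)
           else std_transform(standardizer, cohort)
      p <- predict_proba(model, X)[, "sepsis"]
    }
    if (!is.null(rows)) p <- p[rows]
    p
  }
}

#' Partial dependence of a predictor on one feature
#'
#' Sweeps the feature over a grid of `grid_resolution` evenly spaced values
#' between its 5% and 95% percentiles (or over the unique observed values
#' when there are fewer than `grid_resolution`, e.g. binary sex), replacing
#' every row's value by each grid point, re-running the predictor, and
#' averaging the predicted sepsis probabilities.
#'
#' @param predict_fn Function mapping a cohort-shaped data.frame to per-row
#'   sepsis probabilities (see [pdp_predict_fn()]).
#' @param cohort Raw-scale `cbc_cohort` providing the feature distribution
#'   and the background rows.
#' @param feature One of the 7 input features.
#' @param grid_resolution Maximum number of grid values (default 100).
#' @param quantile_range Grid endpoints as feature quantiles.
#' @return A `cbc_pdp_curve` data.frame: `feature`, `grid`, `avg_prediction`.
#' @export
partial_dependence <- function(predict_fn, cohort, feature,
                               grid_resolution = 100L,
                               quantile_range = c(0.05, 0.95)) {
  if (!feature %in% cbc_feature_names()) {
    stop(sprintf("unknown feature `%s`", feature))
  }
  v <- cohort[[feature]]
  uniq <- sort(unique(v))
  grid <- if (length(uniq) < grid_resolution) uniq else {
    qs <- stats::quantile(v, quantile_range, names = FALSE)
    seq(qs[1], qs[2], length.out = grid_resolution)
  }
  avg <- vapply(grid, function(g) {
    co <- cohort
    co[[feature]] <- rep(g, nrow(co))
    p <- predict_fn(co)
    if (any(p < -1e-9 | p > 1 + 1e-9)) {
      stop("predict_fn returned probabilities outside [0, 1]")
    }
    mean(p)
  }, numeric(1))
  structure(data.frame(feature = feature, grid = grid, avg_prediction = avg),
            class = c("cbc_pdp_curve", "data.frame"))
}

#' Normalized-variance feature importance from PDP curves
#'
#' The importance of a feature is the variance of its partial-dependence
#' curve divided by the sum of those variances over all features of the same
#' model; values lie in `[0, 1]` and sum to 1.
#'
#' @param curves Named list of [partial_dependence()] curves for one model.
#' @return Named numeric vector of importances summing to 1.
#' @export
importance_from_pdp <- function(curves) {
  if (length(curves) < 2) stop("need curves for at least 2 features")
  v <- vapply(curves, function(cu) stats::var(cu$avg_prediction), numeric(1))
  if (is.null(names(v)) || any(!nzchar(names(v)))) {
    names(v) <- vapply(curves, function(cu) cu$feature[1], character(1))
  }
  total <- sum(v)
  if (total == 0) {
    stop("all PDP curves are constant; importance is undefined (0/0)")
  }
  v / total
}

#' Hierarchically cluster models by their importance profiles
#'
#' Agglomerative clustering with average linkage on the Euclidean distances
#' between the models' normalized-variance importance rows.
#'
#' @param importance_matrix models x features numeric matrix.
#' @return An [stats::hclust] dendrogram.
#' @export
cluster_models <- function(importance_matrix) {
  m <- as.matrix(importance_matrix)
  if (nrow(m) < 2) stop("need at least 2 models to cluster")
  stats::hclust(stats::dist(m, method = "euclidean"), method = "average")
}

#' Summarize attention weights by label concordance
#'
#' Splits every non-self-loop arc into `same_label` / `different_label` by
#' the labels of its endpoints (self-loops are reported separately) and
#' computes mean, SD and the \{5, 25, 50, 75, 95\}% quantiles of the
#' attention weights per layer and group. Arcs whose endpoints lack labels
#' raise an error; an empty group yields an `NA` row rather than an error.
#'
#' @param records Attention records from [extract_attention()].
#' @param labels Per-node labels covering all arc endpoints.
#' @return data.frame with one row per (layer, group).
#' @export
summarize_attention_by_label <- function(records, labels) {
  if (nrow(records) == 0) stop("no attention records")
  ls <- labels[records$source]
  lt <- labels[records$target]
  non_self <- records$source != records$target
  if (any(is.na(ls[non_self])) || any(is.na(lt[non_self]))) {
    stop("arc endpoint without a label")
  }
  grp <- ifelse(!non_self, "self_loop",
                ifelse(ls == lt, "same_label", "different_label"))
  qs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  out <- list()
  for (l in sort(unique(records$layer))) {
    for (g in c("same_label", "different_label", "self_loop")) {
      w <- records$weight[records$layer == l & grp == g]
      row <- data.frame(layer = l, group = g, n = length(w),
                        mean = if (length(w)) mean(w) else NA_real_,
                        sd = if (length(w) > 1) stats::sd(w) else NA_real_)
      qv <- if (length(w)) stats::quantile(w, qs, names = FALSE)
            else rep(NA_real_, length(qs))
      row[paste0("q", qs * 100)] <- as.list(qv)
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  attr(res, "empty_groups") <- res$group[res$n == 0 & res$group != "self_loop"]
  res
}
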