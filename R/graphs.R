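# ---- standardization -------------------------------------------------------

#' Extract the 7-column feature matrix from a cohort
#'
#' Column order is fixed: age, sex, hemoglobin, rbc, wbc, mcv, platelets.
#'
#' @param cohort A `cbc_cohort`.
#' @return Numeric matrix with one row per measurement.
#' @export
cohort_features <- function(cohort) {
  as.matrix(cohort[, cbc_feature_names()])
}

#' Fit a feature standardizer on one split
#'
#' Means and standard deviations are estimated on the given split only
#' (train by default) and then applied unchanged to all other splits, so no
#' test information leaks into the scaling.
#'
#' @param cohort A `cbc_cohort`.
#' @param split Split tag to fit on.
#' @return A `cbc_standardizer` with `mean` and `sd` vectors.
#' @export
fit_standardizer <- function(cohort, split = "train") {
  rows <- cohort$split == split
  if (!any(rows)) stop(sprintf("split `%s` is empty", split))
  X <- cohort_features(cohort[rows, , drop = FALSE])
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  const <- names(sd)[sd == 0 | !is.finite(sd)]
  if (length(const)) {
    stop(sprintf("constant feature(s) on fitting split: %s",
                 paste(const, collapse = ", ")))
  }
  structure(list(mean = mu, sd = sd, split = split),
            class = "cbc_standardizer")
}

#' Apply / invert a fitted standardizer
#'
#' @param std A `cbc_standardizer`.
#' @param x A `cbc_cohort` or a numeric matrix whose columns match the fitted
#'   features.
#' @return Standardized (resp. raw-scale) matrix.
#' @export
std_transform <- function(std, x) {
  X <- if (inherits(x, "cbc_cohort")) cohort_features(x) else as.matrix(x)
  sweep(sweep(X, 2, std$mean[colnames(X)]), 2, std$sd[colnames(X)], "/")
}

#' @rdname std_transform
#' @export
std_inverse <- function(std, x) {
  X <- as.matrix(x)
  sweep(sweep(X, 2, std$sd[colnames(X)], "*"), 2, std$mean[colnames(X)], "+")
}

# ---- graph container -------------------------------------------------------

#' Construct a graph object
#'
#' Arcs are directed `(src -> dst)` pairs over 1-based node indices; message
#' passing sends information from `src` to `dst`. Self-arcs are not stored;
#' layers that need them add them internally.
#'
#' @param x Node feature matrix (N x F).
#' @param src,dst Integer endpoint vectors of equal length.
#' @param labels Per-node integer labels in \{0, 1\} (NA for unlabeled nodes).
#' @param split Per-node split tags (NA for auxiliary nodes).
#' @param patient Per-node patient ids (NA where not applicable).
#' @param node_type Per-node type tag.
#' @param meta Free-form metadata list.
#' @return A `cbc_graph`.
#' @export
new_graph <- function(x, src = integer(), dst = integer(), labels = NULL,
                      split = NULL, patient = NULL, node_type = NULL,
                      meta = list()) {
  x <- as.matrix(x)
  n <- nrow(x)
  src <- as.integer(src); dst <- as.integer(dst)
  if (length(src) != length(dst)) stop("src/dst length mismatch")
  if (length(src)) {
    if (min(c(src, dst)) < 1L || max(c(src, dst)) > n) {
      stop("edge endpoint outside [1, N]")
    }
    if (any(src == dst)) stop("self-arcs must not be stored explicitly")
    if (anyDuplicated(cbind(src, dst))) stop("duplicate arcs")
  }
  g <- list(x = x, src = src, dst = dst,
            labels = if (is.null(labels)) rep(NA_integer_, n) else as.integer(labels),
            split = if (is.null(split)) rep(NA_character_, n) else as.character(split),
            patient = if (is.null(patient)) rep(NA_character_, n) else as.character(patient),
            node_type = if (is.null(node_type)) rep("measurement", n) else as.character(node_type),
            meta = meta)
  class(g) <- "cbc_graph"
  g
}

#' @export
print.cbc_graph <- function(x, ...) {
  cat(sprintf("<cbc_graph> %d nodes, %d arcs, %d features\n",
              nrow(x$x), length(x$src), ncol(x$x)))
  invisible(x)
}

n_nodes <- function(graph) nrow(graph$x)

# ---- k-NN similarity graph -------------------------------------------------

#' Build a k-nearest-neighbor similarity graph
#'
#' Each measurement node receives one arc from each of its `k` nearest
#' neighbors (Euclidean distance on the standardized features, self
#' excluded), i.e. neighbors send messages to the query node. Distance ties
#' are broken by node index, so construction is deterministic.
#'
#' @param X_std Standardized N x F feature matrix.
#' @param k Number of neighbors (>= 1). If `k >= N` a warning is issued and
#'   all other nodes are used.
#' @param labels,split,patient Optional per-node metadata passed through to
#'   the graph.
#' @param symmetric Add the reverse of every arc (symmetric closure), so
#'   neighbors also receive messages from their query nodes.
#' @return A `cbc_graph` with `min(k, N - 1) * N` arcs (more under
#'   `symmetric = TRUE`).
#' @export
build_knn_similarity_graph <- function(X_std, k, labels = NULL, split = NULL,
                                       patient = NULL, symmetric = FALSE) {
  X <- as.matrix(X_std)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 nodes for a k-NN graph")
  if (k < 1) stop("k must be >= 1")
  if (k >= n) {
    warning(sprintf("k = %d >= N = %d; connecting to all other nodes", k, n))
    k <- n - 1L
  }
  sq <- rowSums(X^2)
  src <- vector("list", ceiling(n / 512))
  dst <- vector("list", ceiling(n / 512))
  chunk_id <- 0L
  for (start in seq(1L, n, by = 512L)) {
    chunk_id <- chunk_id + 1L
    idx <- start:min(start + 511L, n)
    D2 <- outer(sq[idx], rep(1, n)) + outer(rep(1, length(idx)), sq) -
      2 * tcrossprod(X[idx, , drop = FALSE], X)
    nb <- matrix(0L, length(idx), k)
    # order() is stable, so equal distances resolve to the lower node index;
    # the self is dropped by removing the query index explicitly (duplicated
    # points make "self" ambiguous by distance alone)
    for (r in seq_along(idx)) {
      o <- order(D2[r, ])
      o <- o[o != idx[r]]
      nb[r, ] <- o[seq_len(k)]
    }
    src[[chunk_id]] <- as.integer(t(nb))
    dst[[chunk_id]] <- rep(idx, each = k)
  }
  src <- unlist(src); dst <- unlist(dst)
  if (symmetric) {
    e <- unique(rbind(cbind(src, dst), cbind(dst, src)))
    src <- e[, 1]; dst <- e[, 2]
  }
  new_graph(X, src, dst, labels = labels, split = split,
            patient = patient,
            meta = list(kind = "knn_similarity", k = k,
                        symmetric = symmetric))
}

# ---- patient-centric graphs ------------------------------------------------

#' Build a patient-centric temporal graph
#'
#' Arcs connect measurements of the same patient only. In `directed` mode
#' every earlier measurement sends an arc to every later one (past ->
#' present message flow); `reversed` sends arcs from later to earlier
#' measurements (future -> present); `undirected` contains both arcs of
#' every pair. A patient with n measurements contributes n(n-1)/2, n(n-1)/2
#' and n(n-1) arcs respectively; singleton patients are isolated nodes.
#'
#' @param cohort A `cbc_cohort`.
#' @param mode One of `"directed"`, `"reversed"`, `"undirected"`.
#' @param standardizer A fitted [fit_standardizer()]; fitted on the train
#'   split when `NULL`.
#' @return A `cbc_graph` whose node order matches the cohort rows.
#' @export
build_patient_graph <- function(cohort,
                                mode = c("directed", "reversed", "undirected"),
                                standardizer = NULL) {
  mode <- match.arg(mode)
  if (is.null(standardizer)) standardizer <- fit_standardizer(cohort)
  X <- std_transform(standardizer, cohort)
  by_pat <- split(seq_len(nrow(cohort)), cohort$patient_id)
  src <- integer(0); dst <- integer(0)
  srcs <- list(); dsts <- list(); i <- 0L
  for (rows in by_pat) {
    if (length(rows) < 2) next
    rows <- rows[order(cohort$position[rows])]
    pairs <- utils::combn(rows, 2)  # column: (earlier, later)
    i <- i + 1L
    if (mode == "directed") {
      srcs[[i]] <- pairs[1, ]; dsts[[i]] <- pairs[2, ]
    } else if (mode == "reversed") {
      srcs[[i]] <- pairs[2, ]; dsts[[i]] <- pairs[1, ]
    } else {
      srcs[[i]] <- c(pairs[1, ], pairs[2, ])
      dsts[[i]] <- c(pairs[2, ], pairs[1, ])
    }
  }
  new_graph(X, unlist(srcs), unlist(dsts), labels = cohort$label,
            split = cohort$split, patient = cohort$patient_id,
            meta = list(kind = paste0("patient_", mode), mode = mode))
}

# ---- positional encodings --------------------------------------------------

#' Append positional encodings to a graph
#'
#' Encodes each measurement's 1-based position within its patient's sequence
#' as extra node features. The default `scalar` scheme appends a single
#' column: the position index standard-normalized over the train split, so
#' later measurements carry strictly higher values. `sinusoidal` appends
#' `sin/cos` pairs at geometric wavelengths; `none` returns the graph
#' unchanged.
#'
#' @param graph A `cbc_graph` whose nodes align with `cohort` rows.
#' @param cohort The cohort the graph was built from.
#' @param scheme `"scalar"`, `"sinusoidal"` or `"none"`.
#' @param dim Encoding width for the sinusoidal scheme (even).
#' @return The graph with `F + width` features.
#' @export
add_positional_encoding <- function(graph, cohort, scheme = "scalar",
                                    dim = 4L) {
  if (!scheme %in% c("scalar", "sinusoidal", "none")) {
    stop(sprintf("unknown positional encoding scheme `%s`", scheme))
  }
  if (scheme == "none") return(graph)
  pos <- cohort$position
  if (length(pos) != n_nodes(graph)) stop("graph/cohort size mismatch")
  if (scheme == "scalar") {
    tr <- pos[cohort$split == "train"]
    s <- stats::sd(tr)
    if (!is.finite(s) || s == 0) s <- 1
    enc <- matrix((pos - mean(tr)) / s, ncol = 1,
                  dimnames = list(NULL, "pos_enc"))
  } else {
    half <- as.integer(dim) %/% 2L
    freq <- 1 / (10^(2 * (seq_len(half) - 1) / max(1, dim)))
    enc <- cbind(
      sapply(freq, function(f) sin(pos * f)),
      sapply(freq, function(f) cos(pos * f))
    )
    colnames(enc) <- c(paste0("pos_sin", seq_len(half)),
                       paste0("pos_cos", seq_len(half)))
  }
  graph$x <- cbind(graph$x, enc)
  graph$meta$positional_encoding <- scheme
  graph
}

# ---- serialization ---------------------------------------------------------

#' Serialize a graph to a directory
#'
#' Writes `nodes.csv` (features plus label/split/patient/node_type),
#' `edges.tsv` (`source<TAB>target<TAB>edge_type`, 1-based indices) and
#' `meta.json`.
#'
#' @param graph A `cbc_graph`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_graph <- function(graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nodes <- data.frame(graph$x, check.names = FALSE)
  nodes$label <- graph$labels
  nodes$split <- graph$split
  nodes$patient <- graph$patient
  nodes$node_type <- graph$node_type
  utils::write.csv(nodes, file.path(dir, "nodes.csv"), row.names = FALSE)
  edges <- data.frame(source = graph$src, target = graph$dst,
                      edge_type = rep("arc", length(graph$src)))
  utils::write.table(edges, file.path(dir, "edges.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(graph$meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(dir)
}

#' Read a graph serialized by [write_graph()]
#'
#' @param dir Directory containing `nodes.csv`, `edges.tsv`, `meta.json`.
#' @return A `cbc_graph`.
#' @export
read_graph <- function(dir) {
  nodes <- utils::read.csv(file.path(dir, "nodes.csv"), check.names = FALSE)
  edges <- utils::read.table(file.path(dir, "edges.tsv"), sep = "\t",
                             header = TRUE)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  aux <- c("label", "split", "patient", "node_type")
  new_graph(as.matrix(nodes[, setdiff(names(nodes), aux), drop = FALSE]),
            edges$source, edges$target, labels = nodes$label,
            split = nodes$split, patient = nodes$patient,
            node_type = nodes$node_type, meta = as.list(meta))
}
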