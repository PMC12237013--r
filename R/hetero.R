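# ---- percentile discretization --------------------------------------------

#' Discretize one blood parameter into percentile bins
#'
#' Boundaries sit at the i/m quantiles of the training values, giving m
#' non-overlapping intervals that cover the observed training range.
#' Percentile (rather than equal-width) bins are robust to outliers. Each bin
#' carries three features: its minimum and maximum absolute value and its
#' upper percentile.
#'
#' @param values Training values of one parameter.
#' @param m Number of bins (>= 2; needs at least `m` distinct values).
#' @return A data.frame with columns `lower_value`, `upper_value`,
#'   `upper_percentile` (class `cbc_percentile_bins`).
#' @export
compute_percentile_bins <- function(values, m = 10L) {
  m <- as.integer(m)
  if (m < 2) stop("m must be >= 2")
  values <- values[is.finite(values)]
  if (length(unique(values)) < m) {
    stop(sprintf(
      "only %d distinct values but m = %d bins requested; use a smaller m",
      length(unique(values)), m))
  }
  qs <- stats::quantile(values, probs = seq_len(m) / m, names = FALSE)
  bins <- data.frame(
    lower_value = c(min(values), qs[-m]),
    upper_value = qs,
    upper_percentile = seq_len(m) / m
  )
  if (any(diff(bins$upper_value) <= 0)) {
    stop("degenerate percentile boundaries; use a smaller m")
  }
  class(bins) <- c("cbc_percentile_bins", "data.frame")
  bins
}

#' Map values to percentile bins
#'
#' Intervals are right-closed, `(lower, upper]`, with the first bin closed on
#' both sides; values outside the training range clamp to the first/last bin,
#' so every value maps to exactly one bin.
#'
#' @param bins A [compute_percentile_bins()] result.
#' @param x Numeric values.
#' @return Integer bin indices in `1..m`.
#' @export
assign_bins <- function(bins, x) {
  idx <- findInterval(x, bins$upper_value, left.open = TRUE) + 1L
  pmin(pmax(idx, 1L), nrow(bins))
}

# ---- heterogeneous similarity graph ----------------------------------------

#' Build the heterogeneous percentile-interval similarity graph
#'
#' Measurement nodes (standardized 7-feature vectors) connect to one
#' percentile-bin node per blood parameter, so measurements with similar
#' blood values are indirectly connected through shared bins. Bins are fitted
#' on the train split; out-of-range values from other splits clamp to the
#' boundary bins. Edges are emitted in both directions so that two
#' message-passing layers let measurements exchange information through bins.
#'
#' @param cohort A `cbc_cohort`.
#' @param m Bins per blood parameter (default 10 percentiles).
#' @param standardizer Optional pre-fitted [fit_standardizer()].
#' @return A `cbc_hetero_graph`: measurement features/labels/splits, a
#'   `bins` list (one `cbc_percentile_bins` per parameter) and an `edges`
#'   list of `(measurement, bin)` index pairs per parameter.
#' @export
build_hetero_similarity_graph <- function(cohort, m = 10L,
                                          standardizer = NULL) {
  if (is.null(standardizer)) standardizer <- fit_standardizer(cohort)
  X <- std_transform(standardizer, cohort)
  params <- c("hemoglobin", "rbc", "wbc", "mcv", "platelets")
  train <- cohort$split == "train"
  bins <- list(); edges <- list()
  for (p in params) {
    b <- compute_percentile_bins(cohort[[p]][train], m)
    bins[[p]] <- b
    edges[[p]] <- data.frame(measurement = seq_len(nrow(cohort)),
                             bin = assign_bins(b, cohort[[p]]))
  }
  hg <- list(x = X, labels = cohort$label, split = cohort$split,
             patient = cohort$patient_id, bins = bins, edges = edges,
             m = as.integer(m), standardizer = standardizer)
  class(hg) <- "cbc_hetero_graph"
  hg
}

#' @export
print.cbc_hetero_graph <- function(x, ...) {
  cat(sprintf("<cbc_hetero_graph> %d measurements, %d parameters x %d bins\n",
              nrow(x$x), length(x$bins), x$m))
  invisible(x)
}

#' Flatten a heterogeneous graph into one homogeneous feature space
#'
#' Measurement and bin nodes are embedded in a shared feature matrix by
#' zero-padding: measurement rows carry the 7 standardized CBC features, bin
#' rows carry their 3 interval features (bounds rescaled with the parameter's
#' train standardizer so they are on a comparable scale), and a one-hot
#' node-type block distinguishes measurements from each parameter's bin set.
#' Measurement-bin arcs are emitted in both directions. This lets the
#' homogeneous message-passing layers run on the typed graph through a
#' single, shared code path.
#'
#' @param hg A `cbc_hetero_graph`.
#' @return A `cbc_graph`; bin nodes have `NA` labels and splits so they never
#'   enter a loss mask.
#' @export
as_homogeneous <- function(hg) {
  params <- names(hg$bins)
  n_meas <- nrow(hg$x)
  n_bin <- sum(vapply(hg$bins, nrow, integer(1)))
  types <- c("measurement", params)
  f_names <- c(colnames(hg$x), "bin_lower", "bin_upper", "bin_pct",
               paste0("is_", types))
  x <- matrix(0, n_meas + n_bin, length(f_names),
              dimnames = list(NULL, f_names))
  x[seq_len(n_meas), colnames(hg$x)] <- hg$x
  x[seq_len(n_meas), "is_measurement"] <- 1

  node_type <- c(rep("measurement", n_meas), character(n_bin))
  src <- list(); dst <- list()
  offset <- n_meas
  for (p in params) {
    b <- hg$bins[[p]]
    rows <- offset + seq_len(nrow(b))
    mu <- hg$standardizer$mean[[p]]; s <- hg$standardizer$sd[[p]]
    x[rows, "bin_lower"] <- (b$lower_value - mu) / s
    x[rows, "bin_upper"] <- (b$upper_value - mu) / s
    x[rows, "bin_pct"] <- b$upper_percentile
    x[rows, paste0("is_", p)] <- 1
    node_type[rows] <- p
    e <- hg$edges[[p]]
    src[[p]] <- c(e$measurement, offset + e$bin)
    dst[[p]] <- c(offset + e$bin, e$measurement)
    offset <- offset + nrow(b)
  }
  new_graph(x, unlist(src), unlist(dst),
            labels = c(hg$labels, rep(NA_integer_, n_bin)),
            split = c(hg$split, rep(NA_character_, n_bin)),
            patient = c(hg$patient, rep(NA_character_, n_bin)),
            node_type = node_type,
            meta = list(kind = "hetero_similarity", m = hg$m))
}
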