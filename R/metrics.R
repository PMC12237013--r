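# ---- evaluation metrics ----------------------------------------------------

#' Area under the ROC curve (rank / Mann-Whitney formulation)
#'
#' Equals the probability that a uniformly random positive outscores a
#' uniformly random negative, with ties counted 1/2. Threshold-independent,
#' hence robust under heavy class imbalance.
#'
#' @param labels Binary labels in \{0, 1\}.
#' @param scores Numeric scores (higher = more positive).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(labels, scores) {
  if (length(labels) != length(scores)) stop("labels/scores length mismatch")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUROC needs both classes present")
  r <- rank(scores)  # midranks handle ties as 1/2 wins
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

confusion <- function(labels, predictions) {
  c(tp = sum(labels == 1 & predictions == 1),
    tn = sum(labels == 0 & predictions == 0),
    fp = sum(labels == 0 & predictions == 1),
    fn = sum(labels == 1 & predictions == 0))
}

#' Macro-averaged F1 score
#'
#' Mean of the two per-class F1 scores; a class with zero precision+recall
#' denominator contributes F1 = 0.
#'
#' @param labels,predictions Binary vectors in \{0, 1\}.
#' @return F1-macro in `[0, 1]`.
#' @export
f1_macro <- function(labels, predictions) {
  if (length(labels) != length(predictions)) stop("length mismatch")
  cm <- confusion(labels, predictions)
  f1_pos <- {
    den <- 2 * cm["tp"] + cm["fp"] + cm["fn"]
    if (den == 0) 0 else 2 * cm["tp"] / den
  }
  f1_neg <- {
    den <- 2 * cm["tn"] + cm["fn"] + cm["fp"]
    if (den == 0) 0 else 2 * cm["tn"] / den
  }
  unname((f1_pos + f1_neg) / 2)
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; defined as 0 when
#' any factor of the denominator is 0.
#'
#' @param labels,predictions Binary vectors in \{0, 1\}.
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(labels, predictions) {
  if (length(labels) != length(predictions)) stop("length mismatch")
  cm <- as.numeric(confusion(labels, predictions))
  tp <- cm[1]; tn <- cm[2]; fp <- cm[3]; fn <- cm[4]
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Full metric report for probabilistic predictions
#'
#' @param labels Binary labels.
#' @param scores Predicted sepsis probabilities.
#' @param threshold Probability cut for the thresholded metrics (F1/MCC).
#' @return List with `auroc`, `f1_macro`, `mcc`, `threshold`.
#' @export
metric_report <- function(labels, scores, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  list(auroc = auroc(labels, scores),
       f1_macro = f1_macro(labels, pred),
       mcc = mcc(labels, pred),
       threshold = threshold)
}

# ---- noise injection -------------------------------------------------------

#' Append uniform noise features
#'
#' Adds `n_noise` i.i.d. Uniform[0,1) columns to a feature matrix, leaving
#' the original columns untouched; used for noise-robustness experiments.
#'
#' @param X Feature matrix.
#' @param n_noise Number of noise columns (>= 0).
#' @param seed Seed for the noise draws.
#' @return Matrix with `ncol(X) + n_noise` columns.
#' @export
add_noise_features <- function(X, n_noise, seed = 1L) {
  if (n_noise < 0) stop("n_noise must be >= 0")
  X <- as.matrix(X)
  if (n_noise == 0) return(X)
  set.seed(seed)
  noise <- matrix(stats::runif(nrow(X) * n_noise), nrow(X), n_noise,
                  dimnames = list(NULL, paste0("noise", seq_len(n_noise))))
  cbind(X, noise)
}
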