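# Core uncertainty and calibration statistics.

#' Confidence score of probabilistic predictions
#'
#' The confidence score of a prediction is the largest element of its
#' class-probability vector, i.e. the probability assigned to the predicted
#' class. Confidence approximates the probability of being correct and is the
#' statistic binned by [ece()].
#'
#' @param probs Numeric matrix (samples x classes) of row-stochastic class
#'   probabilities, or a single probability vector.
#' @return Numeric vector with one confidence value in `[0, 1]` per sample.
#' @seealso [shannon_entropy()], [ece()]
#' @export
#' @examples
#' confidence(rbind(c(0.2, 0.5, 0.3), c(1, 0, 0)))
confidence <- function(probs) {
  probs <- as_prob_matrix(probs)
  apply(probs, 1L, max)
}

#' Shannon entropy of probabilistic predictions
#'
#' Total predictive uncertainty of each probability vector,
#' \eqn{H(p) = -\sum_k p_k \log p_k}, in nats (natural logarithm). Zero for a
#' one-hot vector, and maximal at \eqn{\log K} for the uniform distribution
#' over K classes. The convention \eqn{0 \log 0 = 0} applies.
#'
#' @inheritParams confidence
#' @return Numeric vector of per-sample entropies in `[0, log K]` nats.
#' @export
#' @examples
#' shannon_entropy(rbind(c(1, 0, 0), c(1, 1, 1) / 3))
shannon_entropy <- function(probs) {
  probs <- as_prob_matrix(probs)
  plogp <- probs * log(probs)
  plogp[probs == 0] <- 0
  -rowSums(plogp)
}

# Coerce to a matrix of valid probability rows; shared validation for the
# row-wise statistics.
as_prob_matrix <- function(probs) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  probs <- as.matrix(probs)
  if (!is.numeric(probs)) stop("probabilities must be numeric")
  if (anyNA(probs) || any(probs < 0)) {
    stop("probability entries must be non-negative and non-missing")
  }
  sums <- rowSums(probs)
  if (any(abs(sums - 1) > 1e-6)) {
    bad <- which(abs(sums - 1) > 1e-6)[1L]
    stop(sprintf("row %d does not sum to 1 (sum = %.8f)", bad, sums[bad]))
  }
  probs
}

#' Micro-averaged F1 score for single-label multiclass predictions
#'
#' For single-label multiclass classification, micro-F1 equals plain accuracy:
#' the fraction of samples whose predicted label matches the true label.
#' Samples whose true label was never part of the training label set
#' ("unseen" classes) can never be predicted correctly and therefore always
#' count as errors.
#'
#' @param predicted_label Vector of predicted class labels.
#' @param true_label Vector of true class labels, same length.
#' @return Scalar in `[0, 1]`.
#' @export
#' @examples
#' micro_f1(c("a", "b", "b", "c"), c("a", "b", "c", "c"))
micro_f1 <- function(predicted_label, true_label) {
  if (length(predicted_label) != length(true_label)) {
    stop("predicted and true label vectors must have equal length")
  }
  if (length(true_label) == 0L) stop("cannot compute micro-F1 of an empty set")
  mean(as.character(predicted_label) == as.character(true_label))
}

#' Expected calibration error
#'
#' Bins predictions into `M` equal-width confidence bins on `[0, 1]` and
#' returns the count-weighted mean absolute gap between each bin's accuracy
#' and its mean confidence:
#' \deqn{ECE = \sum_{m=1}^{M} \frac{|B_m|}{n}\,|acc(B_m) - conf(B_m)|.}
#' A positive gap (confidence above accuracy) indicates overconfidence.
#'
#' Bin m covers the half-open interval `((m-1)/M, m/M]`; a confidence of
#' exactly 0 falls in the first bin.
#'
#' @param conf Numeric vector of per-sample confidence scores in `[0, 1]`.
#' @param correct Logical vector: was each prediction correct?
#' @param bins Number of equal-width bins M (default 10).
#' @return An object of class `"shiftbench_ece"`: a list with `ece` (scalar),
#'   `bins` (data frame with one row per bin: `bin`, `lower`, `upper`,
#'   `count`, `accuracy`, `mean_confidence`), and `n`.
#' @seealso [samplewise_calibration_error()]
#' @export
#' @examples
#' ece(conf = rep(0.9, 10), correct = rep(c(TRUE, FALSE), c(6, 4)))$ece
ece <- function(conf, correct, bins = 10L) {
  stopifnot(length(conf) == length(correct), bins >= 1L)
  if (anyNA(conf) || any(conf < 0 | conf > 1)) {
    stop("confidence scores must lie in [0, 1]")
  }
  correct <- as.logical(correct)
  if (anyNA(correct)) stop("correctness indicators must be TRUE/FALSE")
  n <- length(conf)
  if (n == 0L) stop("cannot compute ECE of an empty set")
  M <- as.integer(bins)
  idx <- pmax(1L, ceiling(conf * M))          # bin ((m-1)/M, m/M], 0 -> bin 1
  count <- tabulate(idx, nbins = M)
  acc <- vapply(seq_len(M), function(m) {
    if (count[m] == 0L) NA_real_ else mean(correct[idx == m])
  }, numeric(1))
  mconf <- vapply(seq_len(M), function(m) {
    if (count[m] == 0L) NA_real_ else mean(conf[idx == m])
  }, numeric(1))
  occ <- count > 0L
  value <- sum((count[occ] / n) * abs(acc[occ] - mconf[occ]))
  structure(
    list(
      ece = value,
      bins = data.frame(
        bin = seq_len(M),
        lower = (seq_len(M) - 1) / M,
        upper = seq_len(M) / M,
        count = count,
        accuracy = acc,
        mean_confidence = mconf
      ),
      n = n
    ),
    class = "shiftbench_ece"
  )
}

#' @export
print.shiftbench_ece <- function(x, ...) {
  cat(sprintf("Expected calibration error: %.4f (%d samples, %d bins, %d occupied)\n",
              x$ece, x$n, nrow(x$bins), sum(x$bins$count > 0)))
  invisible(x)
}

#' Per-sample absolute calibration error
#'
#' Assigns each sample the absolute accuracy-vs-confidence gap of its ECE bin,
#' `|acc(B_m) - conf(B_m)|`, giving a per-sample view of (over)confidence whose
#' plain mean over all samples reproduces the ECE exactly. Distributions of
#' these values are what the rank-sum model comparisons operate on.
#'
#' @inheritParams ece
#' @return Numeric vector, one non-negative value per sample.
#' @export
samplewise_calibration_error <- function(conf, correct, bins = 10L) {
  res <- ece(conf, correct, bins = bins)
  M <- nrow(res$bins)
  idx <- pmax(1L, ceiling(conf * M))
  gap <- abs(res$bins$accuracy - res$bins$mean_confidence)
  gap[idx]
}

#' Relative percent decrease between the best and worst model
#'
#' Summarises how much worse the bottom-ranked model is than the top-ranked
#' one on a metric, as a percentage of the reference value. For a
#' higher-is-better metric (e.g. F1-AUC) the reference is the better (larger)
#' value and the decrease is `(top - bottom) / top * 100`. For a
#' lower-is-better metric (e.g. ADP) the reference is the worse (larger)
#' value and the improvement of the top model is `(bottom - top) / bottom * 100`.
#'
#' This is a *relative* comparison between models; it is distinct from the
#' percentage-point F1 decreases that enter the ADP itself.
#'
#' @param top Metric value of the top-ranked model.
#' @param bottom Metric value of the bottom-ranked model.
#' @param direction `"higher_is_better"` or `"lower_is_better"`.
#' @return Scalar percentage.
#' @export
#' @examples
#' percent_decrease(4.28, 9.24, "lower_is_better")    # 53.68
#' percent_decrease(93.67, 93.25, "higher_is_better") # 0.45
percent_decrease <- function(top, bottom,
                             direction = c("higher_is_better", "lower_is_better")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(top), is.numeric(bottom),
            length(top) == 1L, length(bottom) == 1L)
  ref <- if (direction == "higher_is_better") top else bottom
  if (ref == 0) stop("reference value is zero; percent decrease undefined")
  if (direction == "higher_is_better") {
    (top - bottom) / ref * 100
  } else {
    (bottom - top) / ref * 100
  }
}
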