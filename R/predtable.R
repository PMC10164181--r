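# Prediction tables: the universal input of all evaluation metrics.

#' Construct a prediction table
#'
#' A prediction table holds, for n samples, the true class label and the
#' predicted class-probability vector over K classes, together with the
#' derived per-sample statistics every metric in this package consumes:
#' the predicted label (row argmax), the confidence score (row maximum) and
#' the Shannon entropy in nats. True labels may include classes outside the
#' probability columns ("unseen" classes absent from training); such samples
#' can never be predicted correctly.
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param true_label Character vector of true class labels.
#' @param probs Numeric matrix (n x K) of row-stochastic class probabilities
#'   with column names giving the class labels (column order is preserved and
#'   meaningful).
#' @param tol Maximum allowed absolute deviation of each row sum from 1
#'   (default `1e-9`).
#' @param renormalise If `TRUE`, divide each row by its sum after the
#'   tolerance check passes.
#' @return An object of class `"prediction_table"`: a list with elements
#'   `sample_id`, `true_label`, `classes`, `probs`, `predicted_label`,
#'   `confidence`, `entropy`, `n`.
#' @export
#' @examples
#' p <- matrix(c(0.2, 0.5, 0.3, 1, 0, 0), 2, byrow = TRUE,
#'             dimnames = list(NULL, c("a", "b", "c")))
#' tab <- prediction_table(c("s1", "s2"), c("b", "a"), p)
#' tab$confidence
prediction_table <- function(sample_id, true_label, probs,
                             tol = 1e-9, renormalise = FALSE) {
  probs <- as.matrix(probs)
  n <- nrow(probs)
  if (n < 1L) stop("a prediction table needs at least one sample")
  if (is.null(colnames(probs)) || anyDuplicated(colnames(probs))) {
    stop("probability columns must carry unique class names")
  }
  sample_id <- as.character(sample_id)
  true_label <- as.character(true_label)
  if (length(sample_id) != n || length(true_label) != n) {
    stop("sample_id, true_label and probs must agree on the number of samples")
  }
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  }
  if (anyNA(probs) || any(probs < 0)) {
    stop("probabilities must be non-negative and non-missing")
  }
  sums <- rowSums(probs)
  off <- abs(sums - 1) > tol
  if (any(off)) {
    stop(sprintf("probability row for sample '%s' sums to %.8f (tolerance %g)",
                 sample_id[which(off)[1L]], sums[which(off)[1L]], tol))
  }
  if (renormalise) probs <- probs / sums
  classes <- colnames(probs)
  pred_idx <- max.col(probs, ties.method = "first")
  structure(
    list(
      sample_id = sample_id,
      true_label = true_label,
      classes = classes,
      probs = probs,
      predicted_label = classes[pred_idx],
      confidence = confidence(probs),
      entropy = shannon_entropy(probs),
      n = n
    ),
    class = "prediction_table"
  )
}

#' @export
print.prediction_table <- function(x, ...) {
  cat(sprintf("Prediction table: %d samples, %d classes (%s)\n", x$n,
              length(x$classes), paste(utils::head(x$classes, 5), collapse = ", ")))
  cat(sprintf("  micro-F1 %.4f | mean confidence %.4f | mean entropy %.4f nats\n",
              micro_f1(x$predicted_label, x$true_label),
              mean(x$confidence), mean(x$entropy)))
  invisible(x)
}

#' Fraction of correct predictions, per sample
#'
#' @param table A [prediction_table()].
#' @return Logical vector: predicted label equals true label.
#' @export
is_correct <- function(table) {
  stopifnot(inherits(table, "prediction_table"))
  table$predicted_label == table$true_label
}

# Resolve the per-sample uncertainty statistic used for sorting/thresholding.
# "entropy" uses Shannon entropy; "confidence" uses 1 - confidence so that
# larger values always mean more uncertain. A numeric vector is used as-is.
resolve_uncertainty <- function(table, uncertainty) {
  if (is.numeric(uncertainty)) {
    if (length(uncertainty) != table$n) {
      stop("uncertainty vector length does not match the table")
    }
    return(uncertainty)
  }
  switch(match.arg(uncertainty, c("entropy", "confidence")),
         entropy = table$entropy,
         confidence = 1 - table$confidence)
}

#' Read a prediction table from a delimited file
#'
#' Expects a header `sample_id, label, p_<class1>, ..., p_<classK>`; class
#' labels and their order are taken from the header. Derived columns
#' (predicted label, confidence, entropy) are recomputed on read.
#'
#' @param path File path.
#' @param dialect `"tsv"` or `"csv"`; defaults from the file extension
#'   (`.csv` implies csv, anything else tsv).
#' @param renormalise Rows whose probabilities sum within `1e-6` of 1 are
#'   accepted as-is; set `renormalise = TRUE` to rescale them to sum exactly
#'   to 1. Rows outside the tolerance are always an error.
#' @return A [prediction_table()].
#' @export
read_prediction_table <- function(path, dialect = NULL, renormalise = FALSE) {
  dialect <- resolve_dialect(path, dialect)
  sep <- if (dialect == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  need <- c("sample_id", "label")
  if (!all(need %in% names(df))) {
    stop("prediction table must have 'sample_id' and 'label' columns")
  }
  pcols <- grep("^p_", names(df), value = TRUE)
  if (length(pcols) < 2L) {
    stop("prediction table needs at least two probability columns 'p_<class>'")
  }
  probs <- matrix(NA_real_, nrow(df), length(pcols),
                  dimnames = list(NULL, sub("^p_", "", pcols)))
  for (j in seq_along(pcols)) {
    v <- suppressWarnings(as.numeric(df[[pcols[j]]]))
    if (anyNA(v)) {
      stop(sprintf("malformed probability in column '%s', line %d",
                   pcols[j], which(is.na(v))[1L] + 1L))
    }
    probs[, j] <- v
  }
  tab <- prediction_table(df$sample_id, df$label, probs,
                          tol = 1e-6, renormalise = renormalise)
  # Derived columns, if stored in the file, must match the recomputed ones.
  if ("predicted_label" %in% names(df) &&
      !identical(df$predicted_label, tab$predicted_label)) {
    stop("stored predicted_label column disagrees with the row argmax")
  }
  for (col in c("confidence", "entropy")) {
    if (col %in% names(df)) {
      stored <- suppressWarnings(as.numeric(df[[col]]))
      if (anyNA(stored) || any(abs(stored - tab[[col]]) > 1e-9)) {
        stop(sprintf("stored %s column disagrees with the recomputed values", col))
      }
    }
  }
  tab
}

#' Write a prediction table to a delimited file
#'
#' Writes the header `sample_id, label, p_<class>...` with probabilities at
#' full double precision, so that reading the file back reproduces the table
#' exactly.
#'
#' @param table A [prediction_table()].
#' @param path Output path.
#' @param dialect `"tsv"` or `"csv"`; defaults from the file extension.
#' @return Invisibly, `path`.
#' @export
write_prediction_table <- function(table, path, dialect = NULL) {
  stopifnot(inherits(table, "prediction_table"))
  dialect <- resolve_dialect(path, dialect)
  sep <- if (dialect == "csv") "," else "\t"
  header <- c("sample_id", "label", paste0("p_", table$classes))
  body <- cbind(table$sample_id, table$true_label,
                matrix(sprintf("%.17g", table$probs), nrow = table$n))
  lines <- c(paste(header, collapse = sep),
             apply(body, 1L, paste, collapse = sep))
  writeLines(lines, path)
  invisible(path)
}

resolve_dialect <- function(path, dialect) {
  if (!is.null(dialect)) return(match.arg(dialect, c("tsv", "csv")))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
}
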