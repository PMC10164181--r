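# Strata datasets: features + labels partitioned by (batch,
# state-of-metastases, seen) keys into one IID development stratum and
# several shifted production strata.

#' Construct a strata dataset
#'
#' @param X Numeric feature matrix (n x D) with sample ids as row names.
#' @param y Character vector of class labels.
#' @param strata Data frame with columns `sample_id`, `batch`,
#'   `state_of_metastases` (`"Primary"`/`"Metastatic"`, case-insensitive) and
#'   `seen` (logical), aligned with the rows of `X`.
#' @param iid_batch Batch label of the stratum designated IID; the IID
#'   stratum is `(iid_batch, Primary, seen = TRUE)` and supplies the training
#'   and validation data.
#' @return Object of class `"strata_dataset"`: list with `X`, `y`, `strata`,
#'   `iid_batch`, `stratum_key` (one `"batch/state/seen"` string per sample)
#'   and `classes` (the IID = trainable label set).
#' @export
strata_dataset <- function(X, y, strata, iid_batch) {
  X <- as.matrix(X)
  n <- nrow(X)
  y <- as.character(y)
  stopifnot(length(y) == n, nrow(strata) == n)
  need <- c("sample_id", "batch", "state_of_metastases", "seen")
  if (!all(need %in% names(strata))) {
    stop("strata table needs columns: ", paste(need, collapse = ", "))
  }
  if (is.null(rownames(X))) rownames(X) <- strata$sample_id
  if (!identical(rownames(X), as.character(strata$sample_id))) {
    stop("sample ids of features and strata table do not match")
  }
  if (anyDuplicated(strata$sample_id)) stop("duplicate sample ids")
  # case-normalise the strata keys
  batch <- toupper(as.character(strata$batch))
  state_raw <- tolower(as.character(strata$state_of_metastases))
  if (!all(state_raw %in% c("primary", "metastatic"))) {
    stop("state_of_metastases must be 'Primary' or 'Metastatic', got: ",
         paste(setdiff(unique(strata$state_of_metastases),
                       c("Primary", "Metastatic")), collapse = ", "))
  }
  state <- ifelse(state_raw == "primary", "Primary", "Metastatic")
  seen <- as.logical(strata$seen)
  if (anyNA(seen)) stop("seen must be TRUE/FALSE")
  iid_batch <- toupper(iid_batch)
  is_iid <- batch == iid_batch & state == "Primary" & seen
  if (!any(is_iid)) {
    stop(sprintf("no samples in the designated IID stratum (%s, Primary, TRUE)",
                 iid_batch))
  }
  classes <- sort(unique(y[is_iid]))
  seen_labels <- unique(y[seen])
  if (!all(seen_labels %in% classes)) {
    stop("label(s) marked seen but absent from the IID stratum: ",
         paste(setdiff(seen_labels, classes), collapse = ", "))
  }
  unseen_labels <- unique(y[!seen])
  if (any(unseen_labels %in% classes)) {
    stop("label(s) marked unseen but present in the IID stratum: ",
         paste(intersect(unseen_labels, classes), collapse = ", "))
  }
  strata_norm <- data.frame(sample_id = as.character(strata$sample_id),
                            batch = batch, state_of_metastases = state,
                            seen = seen, stringsAsFactors = FALSE)
  structure(
    list(X = X, y = y, strata = strata_norm, iid_batch = iid_batch,
         stratum_key = paste(batch, state, seen, sep = "/"),
         classes = classes),
    class = "strata_dataset"
  )
}

#' @export
print.strata_dataset <- function(x, ...) {
  cat(sprintf("Strata dataset: %d samples, %d features, %d trainable classes\n",
              nrow(x$X), ncol(x$X), length(x$classes)))
  tab <- table(x$stratum_key)
  iid <- paste(x$iid_batch, "Primary", TRUE, sep = "/")
  for (k in names(tab)) {
    cat(sprintf("  %-28s n = %4d%s\n", k, tab[[k]],
                if (k == iid) "  [IID]" else ""))
  }
  invisible(x)
}

#' Logical mask of the IID development stratum
#' @param dataset A [strata_dataset()].
#' @return Logical vector over samples.
#' @export
iid_mask <- function(dataset) {
  stopifnot(inherits(dataset, "strata_dataset"))
  with(dataset$strata,
       batch == dataset$iid_batch & state_of_metastases == "Primary" & seen)
}

#' Read a strata dataset from its three delimited files
#'
#' @param features_path TSV with header `sample_id` then one column per
#'   feature.
#' @param labels_path TSV with columns `sample_id`, `label`.
#' @param strata_path TSV with columns `sample_id`, `batch`,
#'   `state_of_metastases`, `seen`.
#' @param iid_batch Batch designating the IID stratum; defaults to the batch
#'   of the first row of the strata table.
#' @return A [strata_dataset()]; per-stratum counts are reported via
#'   `message()`.
#' @export
read_strata_dataset <- function(features_path, labels_path, strata_path,
                                iid_batch = NULL) {
  feats <- utils::read.table(features_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, check.names = FALSE)
  labels <- utils::read.table(labels_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  strata <- utils::read.table(strata_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  ids <- as.character(feats$sample_id)
  if (!setequal(ids, labels$sample_id) || !setequal(ids, strata$sample_id)) {
    stop("sample ids differ between the features, labels and strata files")
  }
  labels <- labels[match(ids, labels$sample_id), ]
  strata <- strata[match(ids, strata$sample_id), ]
  X <- as.matrix(feats[, setdiff(names(feats), "sample_id"), drop = FALSE])
  rownames(X) <- ids
  if (is.null(iid_batch)) iid_batch <- strata$batch[1L]
  ds <- strata_dataset(X, labels$label, strata, iid_batch = iid_batch)
  counts <- table(ds$stratum_key)
  message("strata: ",
          paste(sprintf("%s (n=%d)", names(counts), counts), collapse = "; "))
  ds
}

#' Write a strata dataset to its three delimited files
#'
#' Inverse of [read_strata_dataset()]; features are written at full double
#' precision so the round trip is lossless.
#'
#' @param dataset A [strata_dataset()].
#' @inheritParams read_strata_dataset
#' @return Invisibly, the three paths.
#' @export
write_strata_dataset <- function(dataset, features_path, labels_path,
                                 strata_path) {
  stopifnot(inherits(dataset, "strata_dataset"))
  ids <- rownames(dataset$X)
  fnames <- colnames(dataset$X)
  if (is.null(fnames)) fnames <- sprintf("f%d", seq_len(ncol(dataset$X)))
  fheader <- c("sample_id", fnames)
  fbody <- cbind(ids, matrix(sprintf("%.17g", dataset$X),
                             nrow = nrow(dataset$X)))
  writeLines(c(paste(fheader, collapse = "\t"),
               apply(fbody, 1L, paste, collapse = "\t")), features_path)
  utils::write.table(data.frame(sample_id = ids, label = dataset$y),
                     labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$strata, strata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(features_path, labels_path, strata_path))
}

#' Stratified development split of the IID stratum
#'
#' Splits the IID stratum — and only the IID stratum — into training and
#' validation sets, stratified by class so that class proportions are
#' preserved within rounding. Shifted (production) strata never enter
#' development.
#'
#' @param dataset A [strata_dataset()].
#' @param val_fraction Fraction of each class assigned to validation
#'   (default 0.15).
#' @param seed Split seed.
#' @return List with elements `train` and `validation`, each a list of `X`,
#'   `y`, `sample_id`.
#' @export
split_development <- function(dataset, val_fraction = 0.15, seed = 1L) {
  stopifnot(inherits(dataset, "strata_dataset"),
            val_fraction > 0, val_fraction < 1)
  mask <- iid_mask(dataset)
  ids <- which(mask)
  y <- dataset$y[ids]
  set.seed(as.integer(seed))
  val_idx <- integer(0)
  for (cl in unique(y)) {
    members <- ids[y == cl]
    if (length(members) < 2L) {
      stop(sprintf("class '%s' has fewer than 2 IID samples; cannot split", cl))
    }
    n_val <- max(1L, round(length(members) * val_fraction))
    val_idx <- c(val_idx, sample(members, n_val))
  }
  train_idx <- setdiff(ids, val_idx)
  pick <- function(idx) list(X = dataset$X[idx, , drop = FALSE],
                             y = dataset$y[idx],
                             sample_id = rownames(dataset$X)[idx])
  list(train = pick(train_idx), validation = pick(sort(val_idx)))
}
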