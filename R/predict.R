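# Predictive inference for the four benchmark variants.

predictive_output <- function(mean_probs, n_draws, draws = NULL) {
  structure(list(mean_probs = mean_probs, n_draws = n_draws, draws = draws),
            class = "predictive_output")
}

#' @export
print.predictive_output <- function(x, ...) {
  cat(sprintf("Predictive output: %d samples x %d classes, %d Monte Carlo draw(s)\n",
              nrow(x$mean_probs), ncol(x$mean_probs), x$n_draws))
  invisible(x)
}

#' Pointwise (deterministic) prediction
#'
#' A single deterministic forward pass: dropout disabled, batch-norm frozen
#' at its running statistics, mean head only. This is the inference mode of
#' the baseline resnet; its probability vector is a single point in function
#' space, so its uncertainty reflects only the softmax shape.
#'
#' @param network A trained [build_network()] object.
#' @param X Feature matrix (n x D).
#' @return A `predictive_output` with `n_draws = 1`.
#' @export
predict_pointwise <- function(network, X) {
  stopifnot(inherits(network, "shiftbench_network"))
  X <- as.matrix(X)
  if (ncol(X) != network$D) stop("feature dimension mismatch")
  P <- softmax_rows(forward_eval(network, X, dropout = FALSE, sample = FALSE))
  colnames(P) <- network$classes
  predictive_output(P, 1L)
}

#' Monte Carlo dropout prediction
#'
#' Keeps dropout active at inference and, for a heteroscedastic network,
#' draws one Gaussian logit sample per pass from the data-dependent
#' N(f_t(x), diag s_t^2(x)). Each of the `T` stochastic passes yields one
#' probability vector; their average is the Monte Carlo estimate of the
#' posterior predictive distribution.
#'
#' @param network A trained heteroscedastic [build_network()] object.
#' @param X Feature matrix.
#' @param T_draws Number of Monte Carlo draws (default `spec$mc_samples`).
#' @param seed Seed for the dropout masks and Gaussian samples.
#' @param keep_draws Also return the per-draw probabilities as a
#'   `T x n x K` array.
#' @return A `predictive_output`.
#' @export
predict_mcd <- function(network, X, T_draws = network$spec$mc_samples,
                        seed = network$spec$seed, keep_draws = FALSE) {
  stopifnot(inherits(network, "shiftbench_network"), T_draws >= 1L)
  X <- as.matrix(X)
  if (ncol(X) != network$D) stop("feature dimension mismatch")
  set.seed(as.integer(seed))
  n <- nrow(X); K <- network$K
  acc <- matrix(0, n, K)
  draws <- if (keep_draws) array(NA_real_, c(T_draws, n, K)) else NULL
  for (t in seq_len(T_draws)) {
    P <- softmax_rows(forward_eval(network, X, dropout = TRUE,
                                   sample = network$variance_head))
    acc <- acc + P
    if (keep_draws) draws[t, , ] <- P
  }
  P <- acc / T_draws
  colnames(P) <- network$classes
  predictive_output(P, as.integer(T_draws), draws)
}

#' Deep-ensemble prediction
#'
#' Pools the Monte Carlo draws of several independently trained bi-Lipschitz
#' members (`ensemble_size x per_member_T` draws in total) and averages them.
#' Independent initialisations place the members at different modes of the
#' parameter posterior, so the pooled predictive distribution is
#' multi-modal — the property the single-network variants cannot express.
#'
#' @param members List (>= 2) of trained heteroscedastic networks sharing one
#'   class set.
#' @param X Feature matrix.
#' @param per_member_T Draws per member (default `spec$per_member_samples`).
#' @param seed Base seed; member m uses `seed + m`.
#' @return A `predictive_output` with `n_draws = length(members) * per_member_T`.
#' @export
predict_ensemble <- function(members, X,
                             per_member_T = members[[1L]]$spec$per_member_samples,
                             seed = members[[1L]]$spec$seed) {
  stopifnot(is.list(members), length(members) >= 2L, per_member_T >= 1L)
  K <- members[[1L]]$K
  classes <- members[[1L]]$classes
  for (m in members) {
    if (!inherits(m, "shiftbench_network") || m$K != K ||
        !identical(m$classes, classes)) {
      stop("ensemble members must share one class set")
    }
  }
  outs <- lapply(seq_along(members), function(i) {
    predict_mcd(members[[i]], X, T_draws = per_member_T,
                seed = as.integer(seed) + i)$mean_probs
  })
  P <- Reduce(`+`, outs) / length(outs)
  colnames(P) <- classes
  predictive_output(P, as.integer(length(members) * per_member_T))
}

#' Fit one benchmark variant
#'
#' Builds and trains one of the four controlled constructions from a shared
#' [model_spec()]:
#' * `"resnet"` — the pointwise baseline: trained with dropout as a
#'   regulariser, no variance head, deterministic inference;
#' * `"mcd"` — adds the heteroscedastic variance head and keeps dropout on
#'   at inference (Monte Carlo dropout);
#' * `"bilipschitz"` — MCD plus the spectral-normalisation constraint after
#'   every optimisation step;
#' * `"ensemble"` — `ensemble_size` independently initialised bi-Lipschitz
#'   members.
#'
#' @param spec A [model_spec()].
#' @param X,y,X_val,y_val Training and validation data; labels define the
#'   class set (validation labels must be a subset).
#' @param variant One of `"resnet"`, `"mcd"`, `"bilipschitz"`, `"ensemble"`.
#' @param classes Optional explicit class order; defaults to the sorted
#'   unique training labels.
#' @return Object of class `"shiftbench_model"` wrapping the trained
#'   network(s); use [predict_table()] to obtain prediction tables.
#' @export
fit_variant <- function(spec, X, y, X_val, y_val,
                        variant = c("resnet", "mcd", "bilipschitz", "ensemble"),
                        classes = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(spec, "model_spec"))
  if (is.null(classes)) classes <- sort(unique(as.character(y)))
  D <- ncol(as.matrix(X)); K <- length(classes)
  fit_one <- function(seed, sn, vh) {
    net <- build_network(spec, D, K, classes = classes,
                         variance_head = vh, seed = seed)
    train_network(net, X, y, X_val, y_val, spectral_norm = sn, seed = seed)
  }
  nets <- switch(variant,
    resnet = list(fit_one(spec$seed, sn = FALSE, vh = FALSE)),
    mcd = list(fit_one(spec$seed, sn = FALSE, vh = TRUE)),
    bilipschitz = list(fit_one(spec$seed, sn = TRUE, vh = TRUE)),
    ensemble = lapply(seq_len(spec$ensemble_size), function(m) {
      fit_one(spec$seed * 100L + m, sn = TRUE, vh = TRUE)
    })
  )
  structure(list(variant = variant, spec = spec, networks = nets,
                 classes = classes),
            class = "shiftbench_model")
}

#' @export
print.shiftbench_model <- function(x, ...) {
  cat(sprintf("shiftbench model '%s': %d network(s), %d classes\n",
              x$variant, length(x$networks), length(x$classes)))
  invisible(x)
}

#' Predict a prediction table from a fitted benchmark variant
#'
#' Runs the variant's canonical inference mode (deterministic for the
#' baseline, `T` Monte Carlo draws for MCD/bi-Lipschitz, pooled
#' `ensemble_size x T/10` draws for the ensemble) and wraps the averaged
#' probabilities with the true labels into a [prediction_table()].
#'
#' @param model A [fit_variant()] object.
#' @param X Feature matrix with row names as sample ids (generated when
#'   absent).
#' @param y True labels (may include unseen classes).
#' @param seed Seed for the Monte Carlo draws.
#' @return A [prediction_table()].
#' @export
predict_table <- function(model, X, y, seed = model$spec$seed) {
  stopifnot(inherits(model, "shiftbench_model"))
  X <- as.matrix(X)
  out <- switch(model$variant,
    resnet = predict_pointwise(model$networks[[1L]], X),
    mcd = predict_mcd(model$networks[[1L]], X, seed = seed),
    bilipschitz = predict_mcd(model$networks[[1L]], X, seed = seed),
    ensemble = predict_ensemble(model$networks, X, seed = seed)
  )
  ids <- rownames(X)
  if (is.null(ids)) ids <- sprintf("sample_%05d", seq_len(nrow(X)))
  prediction_table(ids, as.character(y), out$mean_probs, tol = 1e-6)
}
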