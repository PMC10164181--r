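# Synthetic strata generator: controllable development-to-production shift.
#
# Emulates the structure of a multi-dataset cancer-type prediction design:
# class signatures in an abstract expression-like feature space, an additive
# per-batch offset (batch effect), metastatic samples whose signature is
# blended toward the nearest other class (metastatic drift), and held-out
# unseen classes placed at a controllable blend distance from a related seen
# class. Gaussian class-conditional features are used deliberately: the
# evaluated machinery consumes continuous post-preprocessing features, and
# the benchmark needs controllable shift, not marginal realism.

#' Configuration of the synthetic shift benchmark
#'
#' @param K_seen Number of classes present in development (>= 2).
#' @param K_unseen Number of production-only classes (0 disables the unseen
#'   stratum).
#' @param D Feature dimension.
#' @param n_per_stratum Samples per stratum.
#' @param signature_scale Standard deviation of the class-signature
#'   coordinates; inter-class separation grows with it.
#' @param noise_sd Within-class feature noise standard deviation.
#' @param batch_shift_sd Per-coordinate standard deviation of the additive
#'   offset of the second batch (the development batch has no offset).
#' @param blend_alpha Metastatic interpolation weight in `[0, 1]`: metastatic
#'   samples of class k are centred at
#'   `(1 - alpha) * mu_k + alpha * mu_nearest(k)`. 0 recovers the primary
#'   distribution.
#' @param unseen_blend Blend weights of the unseen classes toward a fresh
#'   signature: unseen class u is centred at
#'   `(1 - w_u) * mu_related(u) + w_u * mu_fresh`. Small weights make an
#'   unseen class nearly indistinguishable from its related seen class.
#'   Default: evenly spaced in `[0.15, 0.55]`.
#' @param related_map Integer vector mapping each unseen class to a seen
#'   class index; default pairs unseen class u with seen class u (recycled).
#' @param seed Generator seed; everything (signatures, offsets, noise) is
#'   derived from it.
#' @return Object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(K_seen = 8L, K_unseen = 3L, D = 64L,
                             n_per_stratum = 400L, signature_scale = 1,
                             noise_sd = 1.5, batch_shift_sd = 0.5,
                             blend_alpha = 0.3, unseen_blend = NULL,
                             related_map = NULL, seed = 1L) {
  stopifnot(K_seen >= 2L, K_unseen >= 0L, D >= 2L, n_per_stratum >= K_seen,
            signature_scale > 0, noise_sd > 0, batch_shift_sd >= 0,
            blend_alpha >= 0, blend_alpha <= 1)
  if (K_unseen > 0L) {
    if (is.null(unseen_blend)) {
      unseen_blend <- if (K_unseen == 1L) 0.35 else
        seq(0.15, 0.55, length.out = K_unseen)
    }
    unseen_blend <- rep_len(unseen_blend, K_unseen)
    stopifnot(all(unseen_blend >= 0), all(unseen_blend <= 1))
    if (is.null(related_map)) {
      related_map <- ((seq_len(K_unseen) - 1L) %% K_seen) + 1L
    }
    related_map <- rep_len(as.integer(related_map), K_unseen)
    stopifnot(all(related_map >= 1L), all(related_map <= K_seen))
  } else {
    unseen_blend <- numeric(0)
    related_map <- integer(0)
  }
  structure(
    list(K_seen = as.integer(K_seen), K_unseen = as.integer(K_unseen),
         D = as.integer(D), n_per_stratum = as.integer(n_per_stratum),
         signature_scale = signature_scale, noise_sd = noise_sd,
         batch_shift_sd = batch_shift_sd, blend_alpha = blend_alpha,
         unseen_blend = unseen_blend, related_map = related_map,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Generate a synthetic strata dataset
#'
#' Draws one signature vector per class from a zero-mean spherical Gaussian
#' scaled by `signature_scale`, then assembles four strata (three when
#' `K_unseen = 0`), each of `n_per_stratum` samples with classes balanced:
#'
#' * `(SITE_A, Primary, seen)` — the IID development stratum;
#' * `(SITE_B, Primary, seen)` — batch shift only: features receive the
#'   additive SITE_B offset;
#' * `(SITE_A, Metastatic, seen)` — metastatic drift: class centres blended
#'   toward the nearest other seen signature with weight `blend_alpha`;
#' * `(SITE_B, Metastatic, unseen)` — classes absent from development,
#'   centred between a related seen signature and a fresh signature.
#'
#' Features are `centre + N(0, noise_sd^2 I) + batch offset`. With all shift
#' knobs at zero (and `K_unseen = 0`) the production strata are
#' distributionally identical to the IID stratum — the null-shift control.
#'
#' @param config A [synthetic_config()].
#' @return A [strata_dataset()]; the generating signatures and offsets are
#'   attached as the `"generator"` attribute.
#' @export
generate_strata <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  K <- config$K_seen; D <- config$D; n <- config$n_per_stratum
  seen_classes <- sprintf("C%d", seq_len(K))
  mu <- matrix(rnorm(K * D, sd = config$signature_scale), K, D,
               dimnames = list(seen_classes, NULL))
  offset_b <- rnorm(D, sd = config$batch_shift_sd)
  # nearest other seen signature, for metastatic blending
  dmat <- as.matrix(stats::dist(mu))
  diag(dmat) <- Inf
  nearest <- apply(dmat, 1L, which.min)
  # unseen-class centres
  if (config$K_unseen > 0L) {
    unseen_classes <- sprintf("U%d", seq_len(config$K_unseen))
    fresh <- matrix(rnorm(config$K_unseen * D, sd = config$signature_scale),
                    config$K_unseen, D)
    mu_unseen <- (1 - config$unseen_blend) * mu[config$related_map, , drop = FALSE] +
      config$unseen_blend * fresh
    rownames(mu_unseen) <- unseen_classes
  }

  balanced <- function(labels, n_total) {
    rep_len(rep(labels, each = ceiling(n_total / length(labels))), n_total)
  }
  make_stratum <- function(tag, centres, labels, offset, batch, state, seen) {
    y <- balanced(labels, n)
    X <- centres[y, , drop = FALSE] +
      matrix(rnorm(n * D, sd = config$noise_sd), n, D) +
      rep(offset, each = n)
    ids <- sprintf("%s_%04d", tag, seq_len(n))
    rownames(X) <- ids
    list(X = X, y = y,
         strata = data.frame(sample_id = ids, batch = batch,
                             state_of_metastases = state, seen = seen))
  }

  parts <- list(
    make_stratum("iid", mu, seen_classes, numeric(D),
                 "SITE_A", "Primary", TRUE),
    make_stratum("batch", mu, seen_classes, offset_b,
                 "SITE_B", "Primary", TRUE),
    make_stratum("met", (1 - config$blend_alpha) * mu +
                   config$blend_alpha * mu[nearest, , drop = FALSE],
                 seen_classes, numeric(D), "SITE_A", "Metastatic", TRUE)
  )
  if (config$K_unseen > 0L) {
    parts <- c(parts, list(
      make_stratum("unseen", mu_unseen, unseen_classes, offset_b,
                   "SITE_B", "Metastatic", FALSE)))
  }
  X <- do.call(rbind, lapply(parts, `[[`, "X"))
  colnames(X) <- sprintf("f%d", seq_len(D))
  y <- unlist(lapply(parts, `[[`, "y"), use.names = FALSE)
  strata <- do.call(rbind, lapply(parts, `[[`, "strata"))
  ds <- strata_dataset(X, y, strata, iid_batch = "SITE_A")
  attr(ds, "generator") <- list(
    mu = mu, offset_b = offset_b, nearest = nearest,
    mu_unseen = if (config$K_unseen > 0L) mu_unseen else NULL,
    config = config)
  ds
}
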