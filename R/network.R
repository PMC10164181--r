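# Residual multilayer perceptron shared by all four benchmark variants.
#
# Implemented directly on BLAS matrix operations: an input affine layer
# projecting D features to the hidden width, three residual hidden blocks
# U^(l) = g(BN(U^(l-1) W + b)) + U^(l-1) with Mish activations and batch
# normalisation, a linear mean head to K logits, and (for the heteroscedastic
# variants) a variance head sharing the last hidden representation.

#' Model specification shared by all benchmark variants
#'
#' A single specification bundle constructed once and reused to build every
#' model variant, so that the pointwise baseline, the Monte Carlo dropout
#' model, the bi-Lipschitz model and the deep ensemble differ *only* by their
#' canonical extension (dropout kept on at inference, spectral normalisation,
#' ensembling) and never by architecture or optimisation settings.
#'
#' @param width Neurons per hidden layer. Default 128, sized for CPU-scale
#'   benchmarking; set 1024 to match large-scale use.
#' @param n_hidden_layers Hidden layers (input projection + residual blocks);
#'   fixed at 4 in this architecture family.
#' @param activation Activation name; `"mish"` only.
#' @param dropout_rate Dropout probability after each hidden block's
#'   activation, in (0, 1).
#' @param spectral_bound Upper bound c on every weight matrix's largest
#'   singular value; enforced after each optimisation step in the
#'   bi-Lipschitz variant only.
#' @param mc_samples T, Monte Carlo draws for single Bayesian models
#'   (default 250).
#' @param ensemble_size Members in the deep ensemble (default 8).
#' @param per_member_samples Draws per ensemble member (default
#'   `mc_samples / 10` = 25), pooled so the ensemble's draw budget stays
#'   comparable to the single models.
#' @param learning_rate,batch_size,max_epochs,patience Optimisation settings
#'   (Adam, minibatch, early stopping on validation NLL).
#' @param literal_output_activation Apply the hidden-layer activation to the
#'   output heads as well. Off by default: a linear logit head is standard
#'   softmax-classifier practice.
#' @param seed Base seed for weight initialisation and training.
#' @return Object of class `"model_spec"`.
#' @export
model_spec <- function(width = 128L, n_hidden_layers = 4L, activation = "mish",
                       dropout_rate = 0.1, spectral_bound = 0.5,
                       mc_samples = 250L, ensemble_size = 8L,
                       per_member_samples = as.integer(mc_samples / 10),
                       learning_rate = 1e-3, batch_size = 64L,
                       max_epochs = 200L, patience = 10L,
                       literal_output_activation = FALSE, seed = 1L) {
  stopifnot(width >= 2L, n_hidden_layers == 4L, activation == "mish",
            dropout_rate > 0, dropout_rate < 1, spectral_bound > 0,
            mc_samples >= 1L, ensemble_size >= 2L, per_member_samples >= 1L)
  structure(
    list(width = as.integer(width), n_hidden_layers = 4L,
         activation = "mish", batch_norm = TRUE, residual = TRUE,
         dropout_rate = dropout_rate, spectral_bound = spectral_bound,
         mc_samples = as.integer(mc_samples),
         ensemble_size = as.integer(ensemble_size),
         per_member_samples = as.integer(per_member_samples),
         learning_rate = learning_rate, batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs), patience = as.integer(patience),
         literal_output_activation = literal_output_activation,
         seed = as.integer(seed)),
    class = "model_spec"
  )
}

#' Architecture signature of a specification or network
#'
#' Canonical string over the architectural fields only (layer count, width,
#' activation, normalisation, residual wiring). All four benchmark variants
#' built from one [model_spec()] share the same signature; this is the
#' controlled-benchmark contract made checkable.
#'
#' @param x A `model_spec` or a network built by [build_network()].
#' @return Character scalar.
#' @export
architecture_signature <- function(x) {
  spec <- if (inherits(x, "shiftbench_network")) x$spec else x
  stopifnot(inherits(spec, "model_spec"))
  sprintf("mlp/hidden=%d/width=%d/act=%s/bn=%s/residual=%s",
          spec$n_hidden_layers, spec$width, spec$activation,
          spec$batch_norm, spec$residual)
}

# --- numerics ---------------------------------------------------------------

softplus <- function(x) log1p(exp(-abs(x))) + pmax(x, 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Mish activation
#'
#' `mish(x) = x * tanh(softplus(x))`, a smooth self-regularising activation.
#'
#' @param x Numeric vector or matrix.
#' @return Same shape as `x`.
#' @export
mish <- function(x) x * tanh(softplus(x))

mish_grad <- function(x) {
  t <- tanh(softplus(x))
  t + x * (1 - t^2) * sigmoid(x)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Add a per-column bias vector to an n x H matrix (column-major broadcast).
add_bias <- function(Z, b) Z + rep(b, each = nrow(Z))

#' Spectrally normalise a weight matrix
#'
#' If the largest singular value of `W` exceeds the bound `c`, the whole
#' matrix is rescaled by `c / sigma_max` so that the bound holds exactly;
#' otherwise the matrix is returned unchanged. Applied to every affine weight
#' after each optimisation step in the bi-Lipschitz variant, this upper-bounds
#' the Lipschitz constant of each layer and hence controls the smoothness
#' half of the bi-Lipschitz constraint (sensitivity being supplied by the
#' residual connections).
#'
#' @param W Numeric weight matrix.
#' @param c Positive spectral bound.
#' @return The (possibly rescaled) matrix.
#' @export
#' @examples
#' spectral_normalise(diag(c(3, 1)), 1)   # diag(1, 1/3)
spectral_normalise <- function(W, c) {
  stopifnot(is.matrix(W), is.numeric(W), c > 0)
  if (!all(is.finite(W))) stop("weight matrix has non-finite entries")
  smax <- norm(W, type = "2")
  if (smax > c) W * (c / smax) else W
}

# --- network construction ---------------------------------------------------

#' Build a residual network
#'
#' Instantiates the shared architecture for `D` input features and `K`
#' classes: input affine projection to the hidden width, three residual
#' hidden blocks, a linear mean head, and optionally a variance head (used by
#' the heteroscedastic Monte Carlo dropout variants) whose output is mapped
#' through softplus to guarantee positive variances.
#'
#' @param spec A [model_spec()].
#' @param D Input feature dimension (>= 2).
#' @param K Number of classes (>= 2).
#' @param classes Optional character vector of K class labels carried through
#'   to prediction tables.
#' @param variance_head Add the heteroscedastic variance head.
#' @param seed Initialisation seed; defaults to `spec$seed`.
#' @return Object of class `"shiftbench_network"`.
#' @export
build_network <- function(spec, D, K, classes = NULL, variance_head = FALSE,
                          seed = spec$seed) {
  stopifnot(inherits(spec, "model_spec"), D >= 2L, K >= 2L)
  if (!is.null(classes) && length(classes) != K) {
    stop("classes must have length K")
  }
  set.seed(as.integer(seed))
  H <- spec$width
  he <- function(fan_in, fan_out) {
    matrix(rnorm(fan_in * fan_out, sd = sqrt(2 / fan_in)), fan_in, fan_out)
  }
  params <- list(
    W0 = he(D, H), b0 = numeric(H),
    W1 = he(H, H), b1 = numeric(H),
    W2 = he(H, H), b2 = numeric(H),
    W3 = he(H, H), b3 = numeric(H),
    Wmu = matrix(rnorm(H * K, sd = sqrt(1 / H)), H, K), bmu = numeric(K),
    g0 = rep(1, H), be0 = numeric(H),
    g1 = rep(1, H), be1 = numeric(H),
    g2 = rep(1, H), be2 = numeric(H),
    g3 = rep(1, H), be3 = numeric(H)
  )
  if (variance_head) {
    params$Ws <- matrix(rnorm(H * K, sd = 1e-3), H, K)
    # softplus(-3) ~ 0.049: start with modest logit noise
    params$bs <- rep(-3, K)
  }
  running <- list(mean = replicate(4, numeric(H), simplify = FALSE),
                  var = replicate(4, rep(1, H), simplify = FALSE))
  structure(
    list(spec = spec, D = as.integer(D), K = as.integer(K), classes = classes,
         variance_head = variance_head, params = params, running = running,
         sn_state = NULL, trained = FALSE),
    class = "shiftbench_network"
  )
}

#' @export
print.shiftbench_network <- function(x, ...) {
  cat(sprintf("Residual network: D = %d -> %d x %d hidden -> K = %d%s%s\n",
              x$D, x$spec$n_hidden_layers, x$spec$width, x$K,
              if (x$variance_head) " (+ variance head)" else "",
              if (x$trained) " [trained]" else " [untrained]"))
  cat(" ", architecture_signature(x), "\n")
  invisible(x)
}

# Count of trainable parameters (weights, biases, batch-norm scale/shift).
n_parameters <- function(net) {
  sum(vapply(net$params, length, integer(1)))
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1
VAR_FLOOR <- 1e-6

# Forward pass for inference. Batch-norm always uses the frozen running
# statistics; stochasticity (dropout masks, the single Gaussian logit sample)
# is only injected when requested, so the same code path serves the pointwise
# baseline (deterministic) and the MC-dropout draws.
forward_eval <- function(net, X, dropout = FALSE, sample = FALSE) {
  p <- net$params
  spec <- net$spec
  drop_mask <- function(nr, nc) {
    if (!dropout) return(NULL)
    matrix(stats::rbinom(nr * nc, 1L, 1 - spec$dropout_rate), nr, nc) /
      (1 - spec$dropout_rate)
  }
  bn_eval <- function(Z, l) {
    m <- net$running$mean[[l + 1L]]
    v <- net$running$var[[l + 1L]]
    g <- p[[paste0("g", l)]]
    be <- p[[paste0("be", l)]]
    Zc <- add_bias(Z, -m)
    Zc <- Zc * rep(1 / sqrt(v + BN_EPS), each = nrow(Z))
    add_bias(Zc * rep(g, each = nrow(Z)), be)
  }
  n <- nrow(X)
  U <- mish(bn_eval(add_bias(X %*% p$W0, p$b0), 0L))
  if (dropout) U <- U * drop_mask(n, ncol(U))
  for (l in 1:3) {
    Z <- add_bias(U %*% p[[paste0("W", l)]], p[[paste0("b", l)]])
    A <- mish(bn_eval(Z, l))
    if (dropout) A <- A * drop_mask(n, ncol(A))
    U <- A + U
  }
  f <- add_bias(U %*% p$Wmu, p$bmu)
  if (spec$literal_output_activation) f <- mish(f)
  if (sample && net$variance_head) {
    s2raw <- add_bias(U %*% p$Ws, p$bs)
    if (spec$literal_output_activation) s2raw <- mish(s2raw)
    s2 <- softplus(s2raw) + VAR_FLOOR
    f <- f + sqrt(s2) * matrix(rnorm(length(f)), nrow(f), ncol(f))
  }
  f
}

# Forward + backward + loss on one training minibatch. Returns the gradient
# list (same names as params) and the NLL. Heteroscedastic networks draw one
# Gaussian logit sample per pass (reparameterised, so the variance head gets
# gradients); batch-norm uses batch statistics and updates the running ones.
train_step_grad <- function(net, X, Yidx) {
  p <- net$params
  spec <- net$spec
  n <- nrow(X)
  H <- spec$width
  keep <- 1 - spec$dropout_rate
  grads <- list()
  caches <- list()

  bn_train <- function(Z, l) {
    mu <- colMeans(Z)
    Zc <- add_bias(Z, -mu)
    v <- colMeans(Zc^2)
    istd <- 1 / sqrt(v + BN_EPS)
    xhat <- Zc * rep(istd, each = n)
    g <- p[[paste0("g", l)]]
    out <- add_bias(xhat * rep(g, each = n), p[[paste0("be", l)]])
    net$running$mean[[l + 1L]] <<-
      (1 - BN_MOMENTUM) * net$running$mean[[l + 1L]] + BN_MOMENTUM * mu
    net$running$var[[l + 1L]] <<-
      (1 - BN_MOMENTUM) * net$running$var[[l + 1L]] + BN_MOMENTUM * v
    list(out = out, xhat = xhat, istd = istd, g = g)
  }
  bn_backward <- function(dout, cache) {
    dxhat <- dout * rep(cache$g, each = n)
    mean1 <- rep(colMeans(dxhat), each = n)
    mean2 <- rep(colMeans(dxhat * cache$xhat), each = n)
    dZ <- rep(cache$istd, each = n) * (dxhat - mean1 - cache$xhat * mean2)
    list(dZ = dZ, dg = colSums(dout * cache$xhat), dbe = colSums(dout))
  }

  # forward
  Z0 <- add_bias(X %*% p$W0, p$b0)
  bn0 <- bn_train(Z0, 0L)
  A0 <- mish(bn0$out)
  M0 <- matrix(stats::rbinom(n * H, 1L, keep), n, H) / keep
  U0 <- A0 * M0
  Us <- vector("list", 4L); Us[[1L]] <- U0
  bns <- list(bn0); As <- list(A0); Ms <- list(M0)
  for (l in 1:3) {
    Z <- add_bias(Us[[l]] %*% p[[paste0("W", l)]], p[[paste0("b", l)]])
    bn <- bn_train(Z, l)
    A <- mish(bn$out)
    M <- matrix(stats::rbinom(n * H, 1L, keep), n, H) / keep
    Us[[l + 1L]] <- A * M + Us[[l]]
    bns[[l + 1L]] <- bn; As[[l + 1L]] <- A; Ms[[l + 1L]] <- M
  }
  UL <- Us[[4L]]
  Fpre <- add_bias(UL %*% p$Wmu, p$bmu)
  f <- if (spec$literal_output_activation) mish(Fpre) else Fpre
  if (net$variance_head) {
    S2raw <- add_bias(UL %*% p$Ws, p$bs)
    s2 <- softplus(S2raw) + VAR_FLOOR
    E <- matrix(rnorm(n * net$K), n, net$K)
    logits <- f + sqrt(s2) * E
  } else {
    logits <- f
  }
  P <- softmax_rows(logits)
  picked <- P[cbind(seq_len(n), Yidx)]
  nll <- -mean(log(pmax(picked, 1e-12)))

  # backward
  Y <- matrix(0, n, net$K); Y[cbind(seq_len(n), Yidx)] <- 1
  dlogits <- (P - Y) / n
  df <- dlogits
  if (net$variance_head) {
    ds2 <- dlogits * E * 0.5 / sqrt(s2)
    dS2raw <- ds2 * sigmoid(S2raw)
    dFpre <- if (spec$literal_output_activation) df * mish_grad(Fpre) else df
    grads$Ws <- crossprod(UL, dS2raw); grads$bs <- colSums(dS2raw)
    dUL <- dFpre %*% t(p$Wmu) + dS2raw %*% t(p$Ws)
  } else {
    dFpre <- if (spec$literal_output_activation) df * mish_grad(Fpre) else df
    dUL <- dFpre %*% t(p$Wmu)
  }
  grads$Wmu <- crossprod(UL, dFpre); grads$bmu <- colSums(dFpre)

  dU <- dUL
  for (l in 3:1) {
    dA <- dU * Ms[[l + 1L]]
    dBNout <- dA * mish_grad(bns[[l + 1L]]$out)
    bb <- bn_backward(dBNout, bns[[l + 1L]])
    grads[[paste0("W", l)]] <- crossprod(Us[[l]], bb$dZ)
    grads[[paste0("b", l)]] <- colSums(bb$dZ)
    grads[[paste0("g", l)]] <- bb$dg
    grads[[paste0("be", l)]] <- bb$dbe
    dU <- dU + bb$dZ %*% t(p[[paste0("W", l)]])
  }
  dA0 <- dU * Ms[[1L]]
  dBN0 <- dA0 * mish_grad(bns[[1L]]$out)
  bb <- bn_backward(dBN0, bns[[1L]])
  grads$W0 <- crossprod(X, bb$dZ)
  grads$b0 <- colSums(bb$dZ)
  grads$g0 <- bb$dg
  grads$be0 <- bb$dbe

  list(grads = grads, nll = nll, running = net$running)
}
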