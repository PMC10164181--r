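# Training loop: minibatch Adam on the negative log likelihood with early
# stopping on validation NLL (best weights restored). The bi-Lipschitz
# variant additionally projects every affine weight back inside the spectral
# bound after each optimisation step.

#' Train a network by negative log likelihood
#'
#' Minimises the multiclass NLL with Adam. After every epoch the validation
#' NLL (computed deterministically: dropout off, frozen batch-norm
#' statistics, mean head only) and validation micro-F1 are recorded; training
#' stops when the validation NLL has not improved for `patience` epochs, or
#' at `max_epochs`, and the best-validation weights are restored. All models
#' in a controlled benchmark are stopped by the same rule so their
#' validation-set losses stay comparable.
#'
#' @param network A [build_network()] object.
#' @param X,y Training features (n x D matrix) and labels (character vector,
#'   levels drawn from `network$classes`).
#' @param X_val,y_val Validation features and labels for early stopping.
#' @param spectral_norm Enforce `sigma_max <= spectral_bound` on every affine
#'   weight after each optimisation step (the bi-Lipschitz constraint).
#' @param target_val_nll Optional: stop at the first epoch whose validation
#'   NLL is at or below this shared target, mirroring a benchmark design that
#'   equalises validation loss across models instead of using patience.
#' @param seed Seed governing minibatch order, dropout masks and Gaussian
#'   logit samples; a fixed seed makes training bit-reproducible.
#' @param verbose Print one line per epoch.
#' @return The trained network, with a `history` data frame (`epoch`,
#'   `train_nll`, `val_nll`, `val_f1`) and `best_epoch` attached.
#' @export
train_network <- function(network, X, y, X_val, y_val,
                          spectral_norm = FALSE, target_val_nll = NULL,
                          seed = network$spec$seed, verbose = FALSE) {
  stopifnot(inherits(network, "shiftbench_network"))
  spec <- network$spec
  classes <- network$classes
  if (is.null(classes)) stop("network must carry its class labels to train")
  yidx <- match(as.character(y), classes)
  yvidx <- match(as.character(y_val), classes)
  if (anyNA(yidx) || anyNA(yvidx)) {
    stop("training/validation labels outside the network's class set")
  }
  X <- as.matrix(X); X_val <- as.matrix(X_val)
  n <- nrow(X)

  set.seed(as.integer(seed))
  adam_m <- lapply(network$params, function(p) p * 0)
  adam_v <- adam_m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t_step <- 0L
  sn_names <- c("W0", "W1", "W2", "W3", "Wmu",
                if (network$variance_head) "Ws")

  val_nll <- function(net) {
    f <- forward_eval(net, X_val, dropout = FALSE, sample = FALSE)
    P <- softmax_rows(f)
    picked <- pmax(P[cbind(seq_along(yvidx), yvidx)], 1e-12)
    list(nll = -mean(log(picked)),
         f1 = mean(max.col(P, ties.method = "first") == yvidx))
  }

  history <- data.frame(epoch = integer(), train_nll = numeric(),
                        val_nll = numeric(), val_f1 = numeric())
  best <- list(nll = Inf, params = network$params,
               running = network$running, epoch = 0L)
  wait <- 0L
  for (epoch in seq_len(spec$max_epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = spec$batch_size)
    epoch_nll <- 0
    for (s in starts) {
      idx <- ord[s:min(s + spec$batch_size - 1L, n)]
      step <- train_step_grad(network, X[idx, , drop = FALSE], yidx[idx])
      if (!is.finite(step$nll)) {
        stop(sprintf("non-finite training loss at epoch %d (nll = %g); %s",
                     epoch, step$nll, "training aborted"))
      }
      network$running <- step$running
      t_step <- t_step + 1L
      corr1 <- 1 - b1^t_step; corr2 <- 1 - b2^t_step
      for (nm in names(step$grads)) {
        g <- step$grads[[nm]]
        adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * g
        adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * g^2
        network$params[[nm]] <- network$params[[nm]] -
          spec$learning_rate * (adam_m[[nm]] / corr1) /
            (sqrt(adam_v[[nm]] / corr2) + eps)
      }
      if (spectral_norm) {
        for (nm in sn_names) {
          network$params[[nm]] <-
            spectral_normalise(network$params[[nm]], spec$spectral_bound)
        }
      }
      epoch_nll <- epoch_nll + step$nll * length(idx)
    }
    v <- val_nll(network)
    history <- rbind(history, data.frame(
      epoch = epoch, train_nll = epoch_nll / n,
      val_nll = v$nll, val_f1 = v$f1))
    if (verbose) {
      message(sprintf("epoch %3d | train NLL %.4f | val NLL %.4f | val F1 %.4f",
                      epoch, epoch_nll / n, v$nll, v$f1))
    }
    if (v$nll < best$nll) {
      best <- list(nll = v$nll, params = network$params,
                   running = network$running, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
    }
    if (!is.null(target_val_nll) && v$nll <= target_val_nll) break
    if (wait >= spec$patience) break
  }
  network$params <- best$params
  network$running <- best$running
  network$trained <- TRUE
  network$history <- history
  network$best_epoch <- best$epoch
  network$spectral_norm <- spectral_norm
  network
}
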