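# Fixtures and independent brute-force oracles. The oracles deliberately
# share no code with the package: every F1 is recomputed from scratch with
# mean(), every sweep is an explicit loop.

# Random prediction table: Dirichlet-ish rows (normalised gamma draws),
# labels drawn from the class set plus optionally an unseen label.
random_table <- function(n, K = 4L, unseen_frac = 0, concentration = 0.8) {
  classes <- letters[seq_len(K)]
  probs <- matrix(rgamma(n * K, shape = concentration), n, K)
  probs <- probs / rowSums(probs)
  colnames(probs) <- classes
  true <- sample(classes, n, replace = TRUE)
  if (unseen_frac > 0) {
    flip <- runif(n) < unseen_frac
    true[flip] <- "zz_unseen"
  }
  prediction_table(sprintf("s%03d", seq_len(n)), true, probs)
}

# Table with prescribed per-sample correctness and uncertainty: sample i is
# forced correct/incorrect with confidence 1 - u[i] spread over the rest.
table_with <- function(correct, u, K = 3L) {
  n <- length(correct)
  classes <- letters[seq_len(K)]
  true <- rep(classes, length.out = n)
  probs <- matrix(0, n, K, dimnames = list(NULL, classes))
  for (i in seq_len(n)) {
    top <- 0.5 + (1 - u[i]) * 0.49          # in (0.5, 0.99]: always argmax
    target <- if (correct[i]) true[i] else classes[(match(true[i], classes)) %% K + 1L]
    probs[i, ] <- (1 - top) / (K - 1)
    probs[i, target] <- top
  }
  prediction_table(sprintf("s%03d", seq_len(n)), true, probs)
}

# Brute-force F1-AUC: explicit replacement sweep, F1 via mean() each step,
# trapezoid written out longhand.
oracle_f1_auc <- function(predicted, true, u) {
  n <- length(true)
  ord <- order(-u, method = "radix")
  labels <- predicted
  xs <- numeric(0); ys <- numeric(0)
  for (i in seq_len(n)) {
    xs <- c(xs, (n - i + 1) / n)
    ys <- c(ys, mean(labels == true))
    labels[ord[i]] <- true[ord[i]]
  }
  xs <- c(0, rev(xs)); ys <- c(1, rev(ys))    # ascending retention with terminus at 0
  auc <- 0
  for (i in seq_len(length(xs) - 1L)) {
    auc <- auc + (xs[i + 1L] - xs[i]) * (ys[i] + ys[i + 1L]) / 2
  }
  auc
}

# Brute-force ADP: dev curve by explicit discard loop; for every grid point,
# scan all dev points for the most permissive qualifying threshold, then
# evaluate both dev and prod as plain means over the accepted sets.
oracle_adp <- function(dev_correct, dev_u, prod_correct, prod_u,
                       f1_min = 0.975, f1_max = 0.990, step = 1e-5) {
  ordd <- order(-dev_u, method = "radix")
  thr <- numeric(0); f1s <- numeric(0)
  remaining <- ordd
  while (length(remaining) > 0L) {
    thr <- c(thr, dev_u[remaining[1L]])
    f1s <- c(f1s, mean(dev_correct[remaining]))
    remaining <- remaining[-1L]
  }
  grid <- f1_min + step * (0:round((f1_max - f1_min) / step))
  stopifnot(max(f1s) >= f1_max - 1e-9)
  decreases <- vapply(grid, function(t) {
    ok <- which(f1s >= t - 1e-9)
    ua <- max(thr[ok])
    f1_dev <- mean(dev_correct[dev_u <= ua])
    accepted <- prod_u <= ua
    if (!any(accepted)) stop("empty production set")
    (f1_dev - mean(prod_correct[accepted])) * 100
  }, numeric(1))
  mean(decreases)
}
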