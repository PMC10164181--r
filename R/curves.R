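# Selective-prediction curves and the ADP statistic.

# Stable descending order: ties keep their original row order, so curve
# shapes at tied uncertainties are reproducible and row-permutation invariant
# given identical (uncertainty, correctness) pairs.
discard_order <- function(u) order(-u, method = "radix")

#' F1-retention curve and its area (F1-AUC)
#'
#' Sorts predictions by descending uncertainty and sweeps over them once: at
#' each step the micro-F1 and the retention fraction (initially 100%) are
#' recorded, then the current most-uncertain prediction is replaced by its
#' ground-truth label, decreasing the retention. Replacing with ground truth
#' (rather than discarding) means F1 can only rise as retention falls, and
#' rises fastest when uncertainty correlates with the error rate. The area
#' under the curve (trapezoidal, including the terminal point F1 = 1 at
#' retention 0) summarises accuracy and the uncertainty-error-rate
#' correlation in one number.
#'
#' @param table A [prediction_table()].
#' @param uncertainty `"entropy"` (default), `"confidence"` (used as
#'   `1 - confidence`), or a numeric per-sample vector; larger = more
#'   uncertain.
#' @return Object of class `"f1_retention_curve"`: list with `retention` and
#'   `f1` (aligned vectors, retention decreasing from 1), `auc`, `n`.
#' @export
f1_retention_curve <- function(table, uncertainty = "entropy") {
  stopifnot(inherits(table, "prediction_table"))
  u <- resolve_uncertainty(table, uncertainty)
  n <- table$n
  ord <- discard_order(u)
  correct <- is_correct(table)
  # After i replacements the number of correct predictions is
  # n_correct0 + number of initially-wrong among the first i replaced.
  gains <- cumsum(!correct[ord])
  ncorrect <- c(sum(correct), sum(correct) + gains[-n])
  retention <- (n - seq_len(n) + 1) / n
  f1 <- ncorrect / n
  xs <- c(0, rev(retention))          # ascending retention incl. terminus
  ys <- c(1, rev(f1))
  auc <- sum(diff(xs) * (utils::head(ys, -1) + ys[-1]) / 2)
  structure(list(retention = retention, f1 = f1, auc = auc, n = n),
            class = "f1_retention_curve")
}

#' @export
print.f1_retention_curve <- function(x, ...) {
  cat(sprintf("F1-retention curve: n = %d, F1 at full retention %.4f, F1-AUC %.4f\n",
              x$n, x$f1[1L], x$auc))
  invisible(x)
}

#' F1-uncertainty curve
#'
#' Sorts predictions by descending uncertainty and iteratively *discards*
#' (does not replace) them: before each discard the pair (threshold = the
#' uncertainty of the sample about to be discarded, micro-F1 of the currently
#' retained set) is recorded. The retained set at the point with threshold u
#' is exactly the set of samples with uncertainty <= u. The development
#' flavour of this curve is what an uncertainty threshold is read off; the
#' production flavour measures what that threshold actually delivers after
#' deployment.
#'
#' @inheritParams f1_retention_curve
#' @param flavour `"development"` (IID validation data) or `"production"`
#'   (shifted data); a label carried along for reporting.
#' @return Object of class `"f1_uncertainty_curve"`: list with `threshold`
#'   (non-increasing), `f1`, `n_retained` (decreasing), `flavour`, `n`.
#' @export
f1_uncertainty_curve <- function(table, uncertainty = "entropy",
                                 flavour = c("development", "production")) {
  stopifnot(inherits(table, "prediction_table"))
  flavour <- match.arg(flavour)
  if (table$n < 2L) stop("an F1-uncertainty curve needs at least two samples")
  u <- resolve_uncertainty(table, uncertainty)
  n <- table$n
  ord <- discard_order(u)
  correct <- is_correct(table)[ord]
  # F1 of the retained suffix ord[i..n] for each i.
  suffix_correct <- rev(cumsum(rev(correct)))
  n_retained <- n - seq_len(n) + 1L
  structure(
    list(threshold = u[ord], f1 = suffix_correct / n_retained,
         n_retained = n_retained, flavour = flavour, n = n),
    class = "f1_uncertainty_curve"
  )
}

#' @export
print.f1_uncertainty_curve <- function(x, ...) {
  cat(sprintf("F1-uncertainty curve (%s): n = %d, F1 range [%.4f, %.4f]\n",
              x$flavour, x$n, min(x$f1), max(x$f1)))
  invisible(x)
}

# Largest development threshold whose development F1 meets each nominal
# target. Vectorised over the grid: sort dev points by F1 descending, take
# the running maximum of their thresholds, and for each target count how many
# points reach it. The 1e-9 slack only absorbs floating-point representation
# of the grid; F1 values are multiples of 1/n, far coarser.
dev_accept_thresholds <- function(dev, f1_targets) {
  ord <- order(-dev$f1, method = "radix")
  f1_sorted <- dev$f1[ord]
  thr_cummax <- cummax(dev$threshold[ord])
  count_ge <- length(f1_sorted) -
    findInterval(f1_targets - 1e-9, rev(f1_sorted), left.open = TRUE)
  ifelse(count_ge >= 1L, thr_cummax[pmax(count_ge, 1L)], NA_real_)
}

# Production F1 at each accepted threshold: the retained set is all samples
# with uncertainty <= u_accept, i.e. a suffix of the production discard
# order. Returns NA where the retained set is empty.
prod_f1_at <- function(prod, u_accept) {
  rev_thr <- rev(prod$threshold)                 # non-decreasing
  j <- findInterval(u_accept, rev_thr)           # retained count
  ifelse(j >= 1L, prod$f1[prod$n - pmin(j, prod$n) + 1L], NA_real_)
}

#' Area between the development and production curve (ADP)
#'
#' Quantifies the expected accuracy loss of uncertainty thresholding at
#' deployment. For each nominal F1 target on a grid, the most permissive
#' development threshold achieving that F1 is read off the development
#' F1-uncertainty curve; production predictions with uncertainty at or below
#' that threshold are accepted and their micro-F1 recorded. The per-target
#' decrease in percentage points is `(F1_dev - F1_production) * 100`, where
#' `F1_dev` is the *realised* development F1 at the accepted threshold (the
#' development curve evaluated at `u_accept`, exactly as the production
#' curve is) — a finite development set cannot promise an F1 its curve never
#' attains, and measuring both curves at the same threshold makes the ADP of
#' identical development and production data exactly zero. The ADP is the
#' arithmetic mean of the decreases over the grid. An ADP of 4.3 reads:
#' "expect to lose about 4.3 percentage points of accuracy when the
#' thresholds promised in development are applied in production".
#'
#' The default grid spans nominal F1 targets 0.975 to 0.990 in steps of 1e-5
#' (1501 points). The development curve must attain `f1_max` somewhere,
#' otherwise the nominal range is not supported by the development data and
#' an error is raised; see [adp_range_checks()] for the accompanying support
#' diagnostics.
#'
#' @param dev Development [f1_uncertainty_curve()].
#' @param prod Production [f1_uncertainty_curve()].
#' @param f1_min,f1_max Bounds of the nominal F1 target grid.
#' @param step Grid increment on the F1 fraction scale (default `1e-5`).
#' @return Object of class `"shiftbench_adp"`: list with `adp` (mean decrease,
#'   percentage points), `grid` (data frame: `f1_nominal`, `u_accept`,
#'   `f1_dev` (realised), `f1_prod`, `decrease`), `f1_min`, `f1_max`, `step`,
#'   and `ci` (`NULL` until filled by [adp_bootstrap_ci()]).
#' @export
adp <- function(dev, prod, f1_min = 0.975, f1_max = 0.990, step = 1e-5) {
  stopifnot(inherits(dev, "f1_uncertainty_curve"),
            inherits(prod, "f1_uncertainty_curve"))
  if (f1_max < f1_min || step <= 0) stop("invalid nominal F1 grid")
  if (max(dev$f1) < f1_max - 1e-9) {
    stop(sprintf(paste0(
      "development F1-uncertainty curve never attains f1_max = %g ",
      "(maximum %.6f): the retained sample size at max(F1_dev) is not ",
      "sufficiently large to support the nominal target range"),
      f1_max, max(dev$f1)))
  }
  grid <- f1_min + step * (0:round((f1_max - f1_min) / step))
  u_accept <- dev_accept_thresholds(dev, grid)
  f1_dev <- prod_f1_at(dev, u_accept)       # realised dev F1 at the threshold
  f1_prod <- prod_f1_at(prod, u_accept)
  if (anyNA(f1_prod)) {
    stop(sprintf(paste0(
      "no production prediction has uncertainty <= %.6g (grid point ",
      "F1_nominal = %.6f): production F1 is undefined on an empty set"),
      u_accept[which(is.na(f1_prod))[1L]], grid[which(is.na(f1_prod))[1L]]))
  }
  decrease <- (f1_dev - f1_prod) * 100
  structure(
    list(adp = mean(decrease),
         grid = data.frame(f1_nominal = grid, u_accept = u_accept,
                           f1_dev = f1_dev, f1_prod = f1_prod,
                           decrease = decrease),
         f1_min = f1_min, f1_max = f1_max, step = step, ci = NULL),
    class = "shiftbench_adp"
  )
}

#' @export
print.shiftbench_adp <- function(x, ...) {
  cat(sprintf("ADP: %.4f percentage points (grid [%g, %g], %d points)\n",
              x$adp, x$f1_min, x$f1_max, nrow(x$grid)))
  if (!is.null(x$ci)) {
    cat(sprintf("  bootstrap %g%% CI: [%.4f, %.4f]\n",
                100 * (1 - x$ci_level), x$ci[1L], x$ci[2L]))
  }
  invisible(x)
}

#' Bootstrap confidence interval for the ADP
#'
#' Resamples the production table with replacement, recomputes the ADP
#' against the fixed development curve for each resample, and returns the
#' percentile interval. Degenerate resamples — all samples from one true
#' class, or resamples on which the ADP is undefined (no production sample
#' retained at some grid threshold) — are redrawn, up to a cap per resample,
#' with a warning if any redraw was needed.
#'
#' @param dev_table Development [prediction_table()].
#' @param prod_table Production [prediction_table()].
#' @param B Number of bootstrap resamples (>= 100, default 1000).
#' @param alpha Interval level is `1 - alpha` (default 0.05).
#' @param uncertainty As in [f1_uncertainty_curve()].
#' @param f1_min,f1_max,step As in [adp()].
#' @param seed Integer seed; fixed seed gives an identical interval.
#' @param max_redraws Redraw cap per resample (default 50).
#' @return Object of class `"shiftbench_adp"` as from [adp()] on the full
#'   tables, with `ci = c(low, high)`, `ci_level = alpha`, and the bootstrap
#'   replicate values in `boot_values`.
#' @export
adp_bootstrap_ci <- function(dev_table, prod_table, B = 1000L, alpha = 0.05,
                             uncertainty = "entropy",
                             f1_min = 0.975, f1_max = 0.990, step = 1e-5,
                             seed = 1L, max_redraws = 50L) {
  stopifnot(inherits(dev_table, "prediction_table"),
            inherits(prod_table, "prediction_table"))
  if (B < 100L) stop("use at least 100 bootstrap resamples")
  dev <- f1_uncertainty_curve(dev_table, uncertainty, "development")
  prod <- f1_uncertainty_curve(prod_table, uncertainty, "production")
  point <- adp(dev, prod, f1_min = f1_min, f1_max = f1_max, step = step)
  u_accept <- point$grid$u_accept
  f1_dev <- point$grid$f1_dev

  u_all <- resolve_uncertainty(prod_table, uncertainty)
  correct_all <- is_correct(prod_table)
  labels_all <- prod_table$true_label
  n <- prod_table$n

  adp_of_resample <- function(idx) {
    u <- u_all[idx]
    correct <- correct_all[idx]
    ord <- discard_order(u)
    thr <- u[ord]
    suffix_correct <- rev(cumsum(rev(correct[ord])))
    n_retained <- n - seq_len(n) + 1L
    rev_thr <- rev(thr)
    j <- findInterval(u_accept, rev_thr)
    if (any(j < 1L)) return(NULL)               # undefined on this resample
    f1_prod <- (suffix_correct / n_retained)[n - j + 1L]
    mean((f1_dev - f1_prod) * 100)
  }

  set.seed(as.integer(seed))
  values <- numeric(B)
  redraws <- 0L
  for (b in seq_len(B)) {
    val <- NULL
    tries <- 0L
    while (is.null(val)) {
      idx <- sample.int(n, n, replace = TRUE)
      degenerate <- length(unique(labels_all[idx])) < 2L
      val <- if (degenerate) NULL else adp_of_resample(idx)
      if (is.null(val)) {
        tries <- tries + 1L
        redraws <- redraws + 1L
        if (tries > max_redraws) {
          stop("bootstrap resample remained degenerate after ", max_redraws,
               " redraws")
        }
      }
    }
    values[b] <- val
  }
  if (redraws > 0L) {
    warning(sprintf("%d degenerate bootstrap resample(s) were redrawn", redraws))
  }
  point$ci <- unname(stats::quantile(values, c(alpha / 2, 1 - alpha / 2)))
  point$ci_level <- alpha
  point$boot_values <- values
  point
}
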