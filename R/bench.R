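# Controlled four-model benchmark over IID and OOD strata.

#' Wilcoxon rank-sum comparison of per-sample uncertainty values
#'
#' Compares two per-sample distributions (entropies, calibration errors, ...)
#' with the rank-sum test at the requested sidedness and attaches the
#' conventional star code: `*` for p < 0.05, `**` for p < 0.01, `***` for
#' p < 0.001, `ns` otherwise. All-tied inputs are degenerate; they return
#' `ns` with a warning rather than a spurious p-value.
#'
#' @param a,b Numeric vectors (e.g. model A's and model B's OOD entropies).
#' @param sidedness `"two.sided"`, `"greater"` (a shifted above b) or
#'   `"less"`.
#' @return List with `statistic` (rank-sum W), `p_value`, `stars`.
#' @export
compare_uncertainties <- function(a, b,
                                  sidedness = c("two.sided", "greater", "less")) {
  sidedness <- match.arg(sidedness)
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  if (length(unique(c(a, b))) == 1L) {
    warning("all values tied; rank-sum comparison is degenerate")
    return(list(statistic = NA_real_, p_value = 1, stars = "ns"))
  }
  ht <- stats::wilcox.test(a, b, alternative = sidedness, exact = FALSE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       stars = p_stars(ht$p.value))
}

p_stars <- function(p) {
  if (is.na(p)) return("ns")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Support checks for the ADP nominal range
#'
#' The nominal F1 range of the ADP must be backed by the development curve:
#' the retained sample count at the threshold achieving `f1_max` should be
#' large enough for the F1 estimate to be stable, and `f1_min` should not
#' fall below what production use can tolerate. Violations are reported as
#' warnings (character vector), not errors — the judgement is the analyst's.
#'
#' @param dev_curve Development [f1_uncertainty_curve()].
#' @param f1_min,f1_max Nominal range bounds.
#' @param min_support Minimum retained-sample count at `f1_max` (default 30).
#' @param production_floor Optional minimally acceptable production F1; warns
#'   when `f1_min` lies below it.
#' @return Character vector of warnings; empty when all checks pass.
#' @export
adp_range_checks <- function(dev_curve, f1_min = 0.975, f1_max = 0.990,
                             min_support = 30L, production_floor = NULL) {
  stopifnot(inherits(dev_curve, "f1_uncertainty_curve"))
  warnings <- character(0)
  reach <- dev_curve$f1 >= f1_max - 1e-9
  if (!any(reach)) {
    warnings <- c(warnings, sprintf(
      "development curve never attains f1_max = %g (maximum %.6f)",
      f1_max, max(dev_curve$f1)))
  } else {
    support <- max(dev_curve$n_retained[reach])
    if (support < min_support) {
      warnings <- c(warnings, sprintf(
        "only %d samples retained at the threshold achieving f1_max = %g (minimum %d): the upper nominal target is weakly supported",
        support, f1_max, min_support))
    }
  }
  if (!is.null(production_floor) && f1_min < production_floor) {
    warnings <- c(warnings, sprintf(
      "f1_min = %g lies below the production floor %g: the lower nominal targets may not satisfy production needs",
      f1_min, production_floor))
  }
  warnings
}

#' Benchmark configuration
#'
#' Bundles everything one benchmark run needs: the shared [model_spec()]
#' (applied unchanged to all four variants — the controlled-benchmark
#' design), the [synthetic_config()] describing the data conditions, metric
#' settings and the seed list.
#'
#' @param spec Shared [model_spec()].
#' @param synth A [synthetic_config()]; its seed field is overridden by each
#'   benchmark seed.
#' @param seeds Nonempty integer vector; the benchmark is repeated per seed.
#' @param variants Subset of
#'   `c("resnet", "mcd", "bilipschitz", "ensemble")`.
#' @param uncertainty Uncertainty statistic driving sorting and thresholds:
#'   `"entropy"` (default) or `"confidence"`.
#' @param bins ECE bin count.
#' @param f1_min,f1_max,step ADP nominal grid.
#' @param bootstrap_B Bootstrap resamples for the ADP interval; 0 disables
#'   the interval.
#' @param alpha Bootstrap interval level is `1 - alpha`.
#' @param val_fraction Development validation fraction.
#' @return Object of class `"benchmark_config"`.
#' @export
benchmark_config <- function(spec = model_spec(), synth = synthetic_config(),
                             seeds = 0:4,
                             variants = c("resnet", "mcd", "bilipschitz",
                                          "ensemble"),
                             uncertainty = "entropy", bins = 10L,
                             f1_min = 0.975, f1_max = 0.990, step = 1e-5,
                             bootstrap_B = 0L, alpha = 0.05,
                             val_fraction = 0.15) {
  stopifnot(inherits(spec, "model_spec"), inherits(synth, "synthetic_config"),
            length(seeds) >= 1L)
  variants <- match.arg(variants, several.ok = TRUE)
  structure(
    list(spec = spec, synth = synth, seeds = as.integer(seeds),
         variants = variants, uncertainty = uncertainty,
         bins = as.integer(bins), f1_min = f1_min, f1_max = f1_max,
         step = step, bootstrap_B = as.integer(bootstrap_B), alpha = alpha,
         val_fraction = val_fraction),
    class = "benchmark_config"
  )
}

#' Run the controlled development-to-production benchmark
#'
#' For every seed: generate the strata dataset, split its IID stratum into
#' training and validation, train every requested variant from the one
#' shared specification, predict on the IID validation set and on every
#' production stratum, and compute the full metric set — micro-F1, mean
#' entropy, ECE and per-sample calibration error, F1-AUC on pooled OOD data,
#' and the ADP between the development and production F1-uncertainty curves
#' (with a bootstrap interval when `bootstrap_B > 0`). Rank-sum comparisons
#' of each Bayesian variant against the pointwise baseline (one-sided: higher
#' entropy, lower calibration error) are recorded per seed with star codes
#' and Holm-adjusted p-values. F1-AUC and ADP pool the seen and unseen
#' production strata; F1 and ECE are additionally reported per stratum.
#'
#' A variant whose training fails on some seed is recorded in the report's
#' `failures` table; the remaining cells are still produced.
#'
#' @param config A [benchmark_config()].
#' @param verbose Progress messages.
#' @return Object of class `"benchmark_report"`: list of data frames
#'   `metrics` (seed, model, stratum, metric, value), `comparisons`,
#'   `adp`, `failures`, plus `provenance`.
#' @export
run_benchmark <- function(config = benchmark_config(), verbose = FALSE) {
  stopifnot(inherits(config, "benchmark_config"))
  metrics <- list(); comparisons <- list(); adp_rows <- list()
  failures <- list()
  say <- function(...) if (verbose) message(sprintf(...))

  for (s in config$seeds) {
    synth <- config$synth; synth$seed <- s
    ds <- generate_strata(synth)
    splits <- split_development(ds, val_fraction = config$val_fraction,
                                seed = s)
    ood_mask <- !iid_mask(ds)
    ood_keys <- unique(ds$stratum_key[ood_mask])
    spec <- config$spec; spec$seed <- s

    seed_tables <- list()   # per-model: list(dev = ..., prod = ...)
    for (variant in config$variants) {
      say("seed %d: training %s", s, variant)
      res <- tryCatch({
        model <- fit_variant(spec, splits$train$X, splits$train$y,
                             splits$validation$X, splits$validation$y,
                             variant = variant)
        dev_tab <- predict_table(model, splits$validation$X,
                                 splits$validation$y, seed = s)
        prod_tab <- predict_table(model, ds$X[ood_mask, , drop = FALSE],
                                  ds$y[ood_mask], seed = s + 1L)
        list(model = model, dev = dev_tab, prod = prod_tab)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <-
          data.frame(seed = s, model = variant,
                     error = conditionMessage(res))
        next
      }
      seed_tables[[variant]] <- res

      add <- function(stratum, metric, value) {
        metrics[[length(metrics) + 1L]] <<-
          data.frame(seed = s, model = variant, stratum = stratum,
                     metric = metric, value = value)
      }
      dev_tab <- res$dev; prod_tab <- res$prod
      add("IID", "f1", micro_f1(dev_tab$predicted_label, dev_tab$true_label))
      add("IID", "mean_entropy", mean(dev_tab$entropy))
      add("IID", "ece", ece(dev_tab$confidence, is_correct(dev_tab),
                            config$bins)$ece)
      add("OOD", "f1", micro_f1(prod_tab$predicted_label, prod_tab$true_label))
      add("OOD", "mean_entropy", mean(prod_tab$entropy))
      add("OOD", "ece", ece(prod_tab$confidence, is_correct(prod_tab),
                            config$bins)$ece)
      # per-stratum F1 and ECE
      prod_keys <- ds$stratum_key[ood_mask]
      for (k in ood_keys) {
        sel <- prod_keys == k
        sub_pred <- prod_tab$predicted_label[sel]
        sub_true <- prod_tab$true_label[sel]
        add(paste0("OOD:", k), "f1", micro_f1(sub_pred, sub_true))
        add(paste0("OOD:", k), "ece",
            ece(prod_tab$confidence[sel], sub_pred == sub_true,
                config$bins)$ece)
        add(paste0("OOD:", k), "mean_entropy", mean(prod_tab$entropy[sel]))
      }
      rc <- f1_retention_curve(prod_tab, config$uncertainty)
      add("OOD", "f1_auc", rc$auc)
      dev_curve <- f1_uncertainty_curve(dev_tab, config$uncertainty,
                                        "development")
      prod_curve <- f1_uncertainty_curve(prod_tab, config$uncertainty,
                                         "production")
      adp_res <- tryCatch({
        if (config$bootstrap_B > 0L) {
          adp_bootstrap_ci(dev_tab, prod_tab, B = config$bootstrap_B,
                           alpha = config$alpha,
                           uncertainty = config$uncertainty,
                           f1_min = config$f1_min, f1_max = config$f1_max,
                           step = config$step, seed = s)
        } else {
          adp(dev_curve, prod_curve, f1_min = config$f1_min,
              f1_max = config$f1_max, step = config$step)
        }
      }, error = function(e) e)
      if (inherits(adp_res, "error")) {
        failures[[length(failures) + 1L]] <-
          data.frame(seed = s, model = variant,
                     error = paste("adp:", conditionMessage(adp_res)))
      } else {
        add("OOD", "adp", adp_res$adp)
        adp_rows[[length(adp_rows) + 1L]] <- data.frame(
          seed = s, model = variant, adp = adp_res$adp,
          ci_low = if (is.null(adp_res$ci)) NA_real_ else adp_res$ci[1L],
          ci_high = if (is.null(adp_res$ci)) NA_real_ else adp_res$ci[2L],
          range_warnings = paste(
            adp_range_checks(dev_curve, config$f1_min, config$f1_max),
            collapse = " | "))
      }
    }

    # rank-sum comparisons against the pointwise baseline
    if ("resnet" %in% names(seed_tables)) {
      base <- seed_tables[["resnet"]]
      for (variant in setdiff(names(seed_tables), "resnet")) {
        other <- seed_tables[[variant]]
        for (side in list(
          list(metric = "entropy_ood", a = other$prod$entropy,
               b = base$prod$entropy, alt = "greater"),
          list(metric = "entropy_iid", a = other$dev$entropy,
               b = base$dev$entropy, alt = "greater"),
          list(metric = "calibration_error_ood",
               a = samplewise_calibration_error(
                 base$prod$confidence, is_correct(base$prod), config$bins),
               b = samplewise_calibration_error(
                 other$prod$confidence, is_correct(other$prod), config$bins),
               alt = "greater"))) {
          cmp <- suppressWarnings(
            compare_uncertainties(side$a, side$b, side$alt))
          comparisons[[length(comparisons) + 1L]] <- data.frame(
            seed = s, metric = side$metric, model = variant,
            baseline = "resnet", sidedness = side$alt,
            statistic = cmp$statistic, p_value = cmp$p_value,
            stars = cmp$stars)
        }
      }
    }
  }

  comparisons <- if (length(comparisons)) do.call(rbind, comparisons) else
    data.frame(seed = integer(), metric = character(), model = character(),
               baseline = character(), sidedness = character(),
               statistic = numeric(), p_value = numeric(),
               stars = character())
  if (nrow(comparisons)) {
    # Holm adjustment within each seed's comparison family, clearly labelled
    # as an addition to the unadjusted per-comparison stars.
    comparisons$p_holm <- stats::ave(comparisons$p_value, comparisons$seed,
                                     FUN = function(p) stats::p.adjust(p, "holm"))
  } else {
    comparisons$p_holm <- numeric(0)
  }

  report <- structure(
    list(
      metrics = if (length(metrics)) do.call(rbind, metrics) else
        data.frame(seed = integer(), model = character(),
                   stratum = character(), metric = character(),
                   value = numeric()),
      comparisons = comparisons,
      adp = if (length(adp_rows)) do.call(rbind, adp_rows) else
        data.frame(seed = integer(), model = character(), adp = numeric(),
                   ci_low = numeric(), ci_high = numeric(),
                   range_warnings = character()),
      failures = if (length(failures)) do.call(rbind, failures) else
        data.frame(seed = integer(), model = character(),
                   error = character()),
      provenance = list(seeds = config$seeds,
                        config_hash = config_hash(config),
                        uncertainty = config$uncertainty,
                        models = config$variants)
    ),
    class = "benchmark_report"
  )
  report
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("Benchmark report: %d seed(s), models: %s\n",
              length(x$provenance$seeds),
              paste(x$provenance$models, collapse = ", ")))
  if (nrow(x$metrics)) {
    agg <- stats::aggregate(value ~ model + stratum + metric,
                            data = x$metrics, FUN = mean)
    show <- agg[agg$stratum %in% c("IID", "OOD") &
                  agg$metric %in% c("f1", "mean_entropy", "ece", "f1_auc",
                                    "adp"), ]
    print(stats::reshape(show, idvar = c("model", "stratum"),
                         timevar = "metric", direction = "wide"),
          row.names = FALSE)
  }
  if (nrow(x$failures)) {
    cat("Failures:\n"); print(x$failures, row.names = FALSE)
  }
  invisible(x)
}

# Cheap deterministic content hash for provenance (not cryptographic):
# polynomial rolling hash of the JSON rendering, mod 2^31 - 1.
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
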