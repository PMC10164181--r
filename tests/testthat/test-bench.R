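test_that("rank-sum comparison stars follow the printed significance cut-offs", {
  expect_equal(shiftbench:::p_stars(0.049), "*")
  expect_equal(shiftbench:::p_stars(0.05), "ns")
  expect_equal(shiftbench:::p_stars(0.009), "**")
  expect_equal(shiftbench:::p_stars(0.0009), "***")

  set.seed(23)
  a <- rnorm(50)
  same <- compare_uncertainties(a, a)
  expect_gte(same$p_value, 0.05)
  expect_equal(same$stars, "ns")
  # complete separation at n = 50 each, one-sided
  sep <- compare_uncertainties(a + 10, a, "greater")
  expect_equal(sep$stars, "***")
  expect_equal(sep$statistic, 2500)     # every pairwise comparison won
  expect_warning(res <- compare_uncertainties(rep(1, 5), rep(1, 5)), "tied")
  expect_equal(res$stars, "ns")
})

test_that("ADP range checks warn on weak support and low floors", {
  big <- structure(list(threshold = seq(1, 0.01, length.out = 100),
                        f1 = seq(0.9, 1, length.out = 100),
                        n_retained = 1000:901, flavour = "development",
                        n = 1000L),
                   class = "f1_uncertainty_curve")
  expect_length(adp_range_checks(big), 0L)
  weak <- structure(list(threshold = c(0.9, 0.5, 0.1), f1 = c(0.5, 0.7, 1),
                         n_retained = c(5L, 4L, 3L), flavour = "development",
                         n = 5L),
                    class = "f1_uncertainty_curve")
  w <- adp_range_checks(weak, min_support = 30)
  expect_match(w, "3 samples retained", all = FALSE)
  w2 <- adp_range_checks(big, f1_min = 0.5, production_floor = 0.9)
  expect_match(w2, "production floor", all = FALSE)
})

# One miniature end-to-end benchmark serves the shape, determinism and
# serialisation contracts together.
mini_report <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) {
      cfg <- benchmark_config(
        spec = model_spec(width = 16L, max_epochs = 15L, patience = 4L,
                          mc_samples = 20L, ensemble_size = 2L,
                          per_member_samples = 5L),
        synth = synthetic_config(K_seen = 3L, K_unseen = 1L, D = 8L,
                                 n_per_stratum = 120L, noise_sd = 1),
        seeds = 0L, variants = c("resnet", "mcd"),
        f1_min = 0.9, f1_max = 0.95)
      cached <<- list(cfg = cfg, report = run_benchmark(cfg))
    }
    cached
  }
})

test_that("the benchmark report grid is complete for every model and stratum", {
  rb <- mini_report()
  rep <- rb$report
  expect_s3_class(rep, "benchmark_report")
  expect_equal(nrow(rep$failures), 0L)
  got <- unique(rep$metrics[rep$metrics$metric == "f1", c("model", "stratum")])
  expect_equal(nrow(got), 2L * 5L)     # 2 models x (IID, OOD, 3 OOD strata)
  for (m in c("f1", "ece", "mean_entropy")) {
    expect_true(all(c("IID", "OOD") %in%
                      rep$metrics$stratum[rep$metrics$metric == m]))
  }
  expect_true(all(c("f1_auc", "adp") %in% rep$metrics$metric))
  expect_true(all(rep$comparisons$stars %in% c("ns", "*", "**", "***")))
  expect_true(all(c("p_value", "p_holm") %in% names(rep$comparisons)))
})

test_that("identical configuration and seeds reproduce the report exactly", {
  rb <- mini_report()
  again <- run_benchmark(rb$cfg)
  expect_identical(again$metrics, rb$report$metrics)
  expect_identical(again$adp, rb$report$adp)
  expect_identical(again$comparisons, rb$report$comparisons)
})

test_that("reports round-trip through JSON and render a rounded TSV", {
  rb <- mini_report()
  path <- file.path(tempdir(), "report.json")
  write_report(rb$report, path, tsv_digits = 3L)
  back <- read_report(path)
  expect_equal(back$metrics, rb$report$metrics)
  expect_equal(back$adp$adp, rb$report$adp$adp)        # unrounded in JSON
  expect_equal(back$provenance$config_hash,
               rb$report$provenance$config_hash)
  tsv <- utils::read.table(sub("\\.json$", ".tsv", path), header = TRUE,
                           sep = "\t")
  expect_true(all(round(tsv$value, 3) == tsv$value))   # rounded per config
})

test_that("an empty report serialises to valid JSON with an empty model list", {
  empty <- structure(
    list(metrics = data.frame(seed = integer(), model = character(),
                              stratum = character(), metric = character(),
                              value = numeric()),
         comparisons = data.frame(seed = integer(), metric = character(),
                                  model = character(), baseline = character(),
                                  sidedness = character(),
                                  statistic = numeric(), p_value = numeric(),
                                  stars = character(), p_holm = numeric()),
         adp = data.frame(seed = integer(), model = character(),
                          adp = numeric(), ci_low = numeric(),
                          ci_high = numeric(), range_warnings = character()),
         failures = data.frame(seed = integer(), model = character(),
                               error = character()),
         provenance = list(seeds = integer(), config_hash = "0",
                           uncertainty = "entropy", models = character())),
    class = "benchmark_report")
  path <- file.path(tempdir(), "empty.json")
  write_report(empty, path)
  back <- read_report(path)
  expect_equal(nrow(back$metrics), 0L)
  expect_length(back$provenance$models, 0L)
})
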