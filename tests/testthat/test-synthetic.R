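test_that("generation is seed-deterministic and respects the strata design", {
  cfg <- synthetic_config(seed = 3)
  d1 <- generate_strata(cfg)
  d2 <- generate_strata(cfg)
  expect_identical(d1$X, d2$X)
  expect_identical(d1$y, d2$y)

  expect_equal(sort(unique(d1$stratum_key)),
               sort(c("SITE_A/Primary/TRUE", "SITE_B/Primary/TRUE",
                      "SITE_A/Metastatic/TRUE", "SITE_B/Metastatic/FALSE")))
  expect_true(all(table(d1$stratum_key) == 400L))
  expect_equal(length(d1$classes), 8L)
  # unseen labels never appear in the IID stratum
  unseen <- unique(d1$y[!d1$strata$seen])
  expect_length(intersect(unseen, d1$classes), 0L)
  expect_equal(ncol(d1$X), 64L)
})

test_that("null-shift configuration makes all strata distributionally identical", {
  cfg <- synthetic_config(K_unseen = 0L, batch_shift_sd = 0, blend_alpha = 0,
                          n_per_stratum = 600L, seed = 5)
  ds <- generate_strata(cfg)
  expect_equal(length(unique(ds$stratum_key)), 3L)
  gen <- attr(ds, "generator")
  # per-class centroids of every stratum agree with the signature within
  # sampling error (~ noise_sd / sqrt(n_class) per coordinate)
  for (key in unique(ds$stratum_key)) {
    sel <- ds$stratum_key == key
    for (cl in ds$classes) {
      rows <- sel & ds$y == cl
      centroid <- colMeans(ds$X[rows, , drop = FALSE])
      se <- cfg$noise_sd / sqrt(sum(rows))
      expect_lt(max(abs(centroid - gen$mu[cl, ])), 6 * se)
    }
  }
})

test_that("shift knobs move the strata as designed", {
  cfg <- synthetic_config(seed = 7, batch_shift_sd = 1, blend_alpha = 0.4)
  ds <- generate_strata(cfg)
  gen <- attr(ds, "generator")
  # batch stratum centroids sit at signature + offset
  sel <- ds$stratum_key == "SITE_B/Primary/TRUE"
  cl <- ds$classes[1L]
  rows <- sel & ds$y == cl
  centroid <- colMeans(ds$X[rows, , drop = FALSE])
  se <- cfg$noise_sd / sqrt(sum(rows))
  expect_lt(max(abs(centroid - (gen$mu[cl, ] + gen$offset_b))), 6 * se)
  # metastatic stratum centred at the blend toward the nearest signature
  sel <- ds$stratum_key == "SITE_A/Metastatic/TRUE"
  rows <- sel & ds$y == cl
  blend <- 0.6 * gen$mu[cl, ] + 0.4 * gen$mu[gen$nearest[1L], ]
  expect_lt(max(abs(colMeans(ds$X[rows, , drop = FALSE]) - blend)),
            6 * cfg$noise_sd / sqrt(sum(rows)))
})

test_that("development split is stratified, leak-free and correctly sized", {
  cfg <- synthetic_config(n_per_stratum = 1000L, seed = 11)
  ds <- generate_strata(cfg)
  sp <- split_development(ds, val_fraction = 0.15, seed = 11)
  n_val <- length(sp$validation$y)
  expect_lte(abs(n_val - 150L), 8L)          # +-1 per class rounding
  expect_equal(length(sp$train$y) + n_val, 1000L)
  # class proportions preserved within rounding
  expect_true(all(abs(table(sp$validation$y) - 150 / 8) <= 1))
  # no leakage: validation and train disjoint, and no OOD ids anywhere
  expect_length(intersect(sp$train$sample_id, sp$validation$sample_id), 0L)
  ood_ids <- rownames(ds$X)[!iid_mask(ds)]
  expect_length(intersect(ood_ids, c(sp$train$sample_id,
                                     sp$validation$sample_id)), 0L)
})

test_that("strata datasets round-trip through their three files", {
  cfg <- synthetic_config(K_seen = 3L, K_unseen = 1L, D = 5L,
                          n_per_stratum = 30L, seed = 13)
  ds <- generate_strata(cfg)
  paths <- file.path(tempdir(), c("X.tsv", "y.tsv", "strata.tsv"))
  write_strata_dataset(ds, paths[1], paths[2], paths[3])
  back <- suppressMessages(
    read_strata_dataset(paths[1], paths[2], paths[3], iid_batch = "SITE_A"))
  expect_equal(back$X, ds$X)
  expect_identical(back$y, ds$y)
  expect_identical(back$strata, ds$strata)
  expect_identical(back$classes, ds$classes)
})

test_that("strata validation catches inconsistent label/seen combinations", {
  X <- matrix(rnorm(6 * 3), 6, 3,
              dimnames = list(sprintf("s%d", 1:6), NULL))
  strata <- data.frame(
    sample_id = sprintf("s%d", 1:6),
    batch = c("A", "A", "A", "B", "B", "B"),
    state_of_metastases = "Primary",
    seen = TRUE)
  # label 'x' marked seen but absent from the IID stratum
  expect_error(strata_dataset(X, c("a", "b", "a", "a", "b", "x"),
                              strata, iid_batch = "A"),
               "absent from the IID stratum")
  # label marked unseen but present in the IID stratum
  strata$seen[6] <- FALSE
  expect_error(strata_dataset(X, c("a", "b", "a", "a", "b", "a"),
                              strata, iid_batch = "A"),
               "unseen but present")
  strata$state_of_metastases[2] <- "weird"
  expect_error(strata_dataset(X, c("a", "b", "a", "a", "b", "c"),
                              strata, iid_batch = "A"),
               "Primary.*Metastatic")
  # strata keys are case-normalised
  ok <- strata_dataset(X, c("a", "b", "a", "a", "b", "b"),
                       data.frame(sample_id = sprintf("s%d", 1:6),
                                  batch = "a", state_of_metastases = "PRIMARY",
                                  seen = TRUE),
                       iid_batch = "a")
  expect_equal(unique(ok$strata$state_of_metastases), "Primary")
  expect_equal(ok$iid_batch, "A")
})

test_that("unseen classes closer to a seen signature attract lower predictive entropy", {
  cfg <- synthetic_config(seed = 19)
  ds <- generate_strata(cfg)
  sp <- split_development(ds, seed = 19)
  spec <- model_spec(width = 32L, max_epochs = 60L, seed = 19L)
  m <- fit_variant(spec, sp$train$X, sp$train$y,
                   sp$validation$X, sp$validation$y, "resnet")
  sel <- !ds$strata$seen
  tab <- predict_table(m, ds$X[sel, , drop = FALSE], ds$y[sel], seed = 19)
  mean_h <- tapply(tab$entropy, tab$true_label, mean)
  blend <- cfg$unseen_blend[match(names(mean_h), sprintf("U%d", 1:3))]
  expect_gt(cor(blend, mean_h, method = "spearman"), 0)
})
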