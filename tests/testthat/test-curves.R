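test_that("F1-retention curve reproduces the four-sample replacement sweep", {
  # two most-uncertain predictions wrong
  tab <- table_with(correct = c(TRUE, TRUE, FALSE, FALSE),
                    u = c(0.1, 0.2, 0.8, 0.9))
  rc <- f1_retention_curve(tab, 1 - tab$confidence)
  expect_equal(rc$retention, c(1, 0.75, 0.5, 0.25))
  expect_equal(rc$f1, c(0.5, 0.75, 1, 1))
  expect_equal(rc$auc, 0.875)   # trapezoid incl. terminus (0, 1), by hand
})

test_that("all-correct tables give a flat retention curve with unit area", {
  tab <- table_with(correct = rep(TRUE, 6), u = runif(6))
  rc <- f1_retention_curve(tab, "entropy")
  expect_true(all(rc$f1 == 1))
  expect_equal(rc$auc, 1)
})

test_that("retention F1 is monotone non-decreasing as retention falls", {
  set.seed(41)
  for (i in 1:25) {
    tab <- random_table(sample(5:40, 1), K = sample(3:6, 1),
                        unseen_frac = 0.15)
    rc <- f1_retention_curve(tab)
    expect_true(all(diff(rc$f1) >= 0))   # points ordered by falling retention
    expect_gte(min(rc$f1), 0)
    expect_lte(rc$auc, 1)
  }
})

test_that("tied uncertainties are broken by stable original order", {
  # identical correctness pattern at the tie: any permutation of tied rows
  # with the same correctness sequence gives the same area
  correct <- c(TRUE, FALSE, TRUE, FALSE, TRUE)
  u <- c(0.5, 0.5, 0.5, 0.2, 0.1)
  tab <- table_with(correct, u)
  base <- f1_retention_curve(tab, u)$auc
  perms <- list(c(3, 2, 1, 4, 5), c(1, 3, 2, 4, 5))  # permute tied block only
  for (pm in perms) {
    tab2 <- table_with(correct[pm], u[pm])
    expect_equal(f1_retention_curve(tab2, u[pm])$auc,
                 oracle_f1_auc(tab2$predicted_label, tab2$true_label, u[pm]))
  }
})

test_that("F1-AUC agrees with the brute-force replacement oracle", {
  set.seed(51)
  for (i in 1:30) {
    tab <- random_table(20, K = 4, unseen_frac = 0.1)
    expect_equal(f1_retention_curve(tab)$auc,
                 oracle_f1_auc(tab$predicted_label, tab$true_label,
                               tab$entropy),
                 tolerance = 1e-13)
  }
})

test_that("F1-uncertainty curve records F1 of each retained suffix", {
  # single wrong prediction is the most uncertain of three
  tab <- table_with(correct = c(TRUE, TRUE, FALSE), u = c(0.1, 0.2, 0.9))
  uc <- f1_uncertainty_curve(tab, 1 - tab$confidence, "development")
  expect_equal(uc$f1, c(2 / 3, 1, 1))
  expect_equal(uc$n_retained, c(3L, 2L, 1L))
  expect_true(all(diff(uc$threshold) <= 0))

  all_ok <- table_with(rep(TRUE, 4), runif(4))
  expect_true(all(f1_uncertainty_curve(all_ok)$f1 == 1))
  expect_error(f1_uncertainty_curve(table_with(TRUE, 0.5)), "two samples")
})

test_that("F1-uncertainty curves are invariant to row shuffling", {
  set.seed(61)
  tab <- random_table(30, K = 5)
  u <- tab$entropy
  perm <- sample(30)
  tab2 <- prediction_table(tab$sample_id[perm], tab$true_label[perm],
                           tab$probs[perm, ])
  c1 <- f1_uncertainty_curve(tab)
  c2 <- f1_uncertainty_curve(tab2)
  expect_equal(c1$threshold, c2$threshold)
  expect_equal(c1$f1, c2$f1)
})

test_that("ADP is exactly zero when production equals development", {
  set.seed(71)
  # needs a dev curve attaining 0.99: most-uncertain samples carry the errors
  tab <- table_with(correct = c(rep(TRUE, 30), FALSE, FALSE),
                    u = c(runif(30, 0, 0.5), 0.9, 0.95))
  dev <- f1_uncertainty_curve(tab, 1 - tab$confidence, "development")
  prod <- f1_uncertainty_curve(tab, 1 - tab$confidence, "production")
  expect_identical(adp(dev, prod)$adp, 0)
})

test_that("ADP closed form holds for a constant production curve", {
  # synthetic curves: dev attains every grid value exactly; prod constant 0.95
  grid <- 0.975 + 1e-5 * (0:1500)
  dev <- structure(list(threshold = rev(seq(0.1, 0.9, length.out = 1501)),
                        f1 = grid, n_retained = 1501:1,
                        flavour = "development", n = 1501L),
                   class = "f1_uncertainty_curve")
  prod <- structure(list(threshold = c(0.95, 0.05), f1 = c(0.95, 0.95),
                         n_retained = c(2L, 1L), flavour = "production",
                         n = 2L),
                    class = "f1_uncertainty_curve")
  res <- adp(dev, prod)
  expect_equal(res$adp, 3.25, tolerance = 1e-10)
  expect_equal(res$grid$decrease, (grid - 0.95) * 100, tolerance = 1e-10)
})

test_that("ADP matches the brute-force grid oracle on random tables", {
  set.seed(81)
  for (i in 1:10) {
    # dev: errors concentrated at high uncertainty so the curve reaches 0.99
    n_dev <- 40
    dev_correct <- c(rep(TRUE, 34), runif(6) < 0.3)
    dev_u <- c(runif(34, 0, 0.6), runif(6, 0.7, 1))
    prod_correct <- runif(25) < 0.8
    prod_u <- runif(25, 0, 0.9)
    dev_tab <- table_with(dev_correct, dev_u)
    prod_tab <- table_with(prod_correct, prod_u)
    dev <- f1_uncertainty_curve(dev_tab, dev_u, "development")
    prod <- f1_uncertainty_curve(prod_tab, prod_u, "production")
    expect_equal(adp(dev, prod)$adp,
                 oracle_adp(dev_correct, dev_u, prod_correct, prod_u),
                 tolerance = 1e-12)
  }
})

test_that("ADP is invariant to monotone rescaling of the uncertainty scale", {
  set.seed(91)
  dev_correct <- c(rep(TRUE, 25), rep(FALSE, 3))
  dev_u <- c(runif(25, 0, 0.5), runif(3, 0.6, 1))
  prod_correct <- runif(20) < 0.75
  prod_u <- runif(20)
  mk <- function(f) {
    dev <- f1_uncertainty_curve(table_with(dev_correct, dev_u), f(dev_u),
                                "development")
    prod <- f1_uncertainty_curve(table_with(prod_correct, prod_u), f(prod_u),
                                 "production")
    adp(dev, prod)$adp
  }
  base <- mk(identity)
  expect_equal(mk(function(u) exp(3 * u)), base)
  expect_equal(mk(function(u) u^3 + 10), base)
})

test_that("ADP errors are explicit for unreachable targets and empty retained sets", {
  # the least uncertain prediction is wrong: no retained suffix reaches 0.99
  lowdev <- table_with(correct = c(rep(c(TRUE, FALSE), 9), TRUE, FALSE),
                       u = seq(0.95, 0.05, length.out = 20))
  dev <- f1_uncertainty_curve(lowdev, "confidence", "development")
  prod <- f1_uncertainty_curve(lowdev, "confidence", "production")
  expect_error(adp(dev, prod), "never attains")

  # production uncertainties all above every accepted threshold
  dev_tab <- table_with(rep(TRUE, 10), runif(10, 0, 0.2))
  prod_tab <- table_with(rep(TRUE, 10), runif(10, 0.5, 1))
  d <- f1_uncertainty_curve(dev_tab, 1 - dev_tab$confidence, "development")
  p <- f1_uncertainty_curve(prod_tab, 1 - prod_tab$confidence, "production")
  expect_error(adp(d, p), "empty set")
})

test_that("bootstrap CI collapses to (0, 0) for an all-correct shared table", {
  tab <- table_with(rep(TRUE, 25), runif(25))
  res <- adp_bootstrap_ci(tab, tab, B = 200, seed = 5,
                          uncertainty = "confidence")
  expect_equal(res$ci, c(0, 0))
  expect_equal(res$adp, 0)
})

test_that("bootstrap CI brackets the point estimate and is seed-reproducible", {
  set.seed(101)
  dev_tab <- table_with(c(rep(TRUE, 40), rep(FALSE, 4)),
                        c(runif(40, 0, 0.5), runif(4, 0.7, 1)))
  prod_tab <- table_with(runif(60) < 0.85, runif(60))
  r1 <- adp_bootstrap_ci(dev_tab, prod_tab, B = 300, seed = 9)
  r2 <- adp_bootstrap_ci(dev_tab, prod_tab, B = 300, seed = 9)
  expect_identical(r1$ci, r2$ci)
  expect_lte(r1$ci[1], r1$adp + 1e-9)
  expect_gte(r1$ci[2], r1$adp - 1e-9)
})
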