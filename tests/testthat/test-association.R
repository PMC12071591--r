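test_that("or_per_sd recovers a known effect and handles null/separation", {
  d <- simulate_liability_scores(4000, 4000, gamma = log(1.5),
                                 prevalence = 0.1, seed = 42)
  res <- or_per_sd(d, pc_cols = character())
  expect_true(res$ci_low <= 1.5 && 1.5 <= res$ci_high)
  expect_gt(res$pseudo_r2[["nagelkerke"]], 0)
  # null: scores independent of status
  null <- withr::with_seed(7, tibble::tibble(
    standardized = rnorm(3000),
    status = rep(c("case", "control"), length.out = 3000)))
  rn <- or_per_sd(null, pc_cols = character())
  expect_true(rn$ci_low <= 1 && 1 <= rn$ci_high)
  # perfect separation errors with a diagnostic
  sep <- tibble::tibble(standardized = c(rnorm(50, -3), rnorm(50, 3)),
                        status = rep(c("control", "case"), each = 50))
  expect_error(or_per_sd(sep, pc_cols = character()), "separation")
})

test_that("binning is left-open right-closed with documented boundaries", {
  d <- tibble::tibble(standardized = 1:10 / 10,
                      status = rep(c("case", "control"), 5))
  b <- make_bins(d, boundary_source = "all")
  expect_equal(sort(table(b$bin)), sort(table(1:10)))  # one per decile
  expect_equal(attr(b, "reference_bins"), c(5L, 6L))
  # a value exactly at a boundary falls in the lower bin
  bounds <- attr(b, "boundaries")
  d2 <- tibble::tibble(standardized = c(d$standardized, bounds[4]),
                       status = c(d$status, "case"))
  b2 <- make_bins(d2, boundary_source = "all")
  x <- b2$bin[11]
  expect_equal(x, sum(attr(b2, "boundaries") < bounds[4]) + 1L)
  # massive ties keep the partition exhaustive
  d3 <- tibble::tibble(standardized = c(rep(0.5, 400), rnorm(100)),
                       status = rep(c("case", "control"), 250))
  b3 <- make_bins(d3, boundary_source = "all")
  expect_equal(sum(table(b3$bin)), 500)
  # percentile scheme: reference is the single (40,60] interval
  bp <- make_bins(d3, kind = "percentile", boundary_source = "all")
  expect_equal(attr(bp, "reference_bins"), 6L)
  expect_length(attr(bp, "boundaries"), 10)
})

test_that("bin_or equals the closed-form 2x2 OR without covariates", {
  withr::with_seed(31, {
    for (i in 1:25) {
      a <- sample(20:80, 1); b <- sample(20:80, 1)
      c <- sample(50:150, 1); d <- sample(50:150, 1)
      bo <- bin_or(binned_from_counts(a, b, c, d), 10, pc_cols = character())
      expect_equal(bo$or, (a * d) / (b * c), tolerance = 1e-8)
    }
  })
  # the documented example: (60,40) vs (100,100) -> OR 1.5
  bo <- bin_or(binned_from_counts(60, 40, 100, 100), 10, pc_cols = character())
  expect_equal(bo$or, 1.5, tolerance = 1e-8)
  # reference vs reference is exactly 1
  self <- bin_or(binned_from_counts(60, 40, 100, 100), c(5, 6))
  expect_identical(self$or, 1)
  expect_equal(self$flag, "self-comparison")
})

test_that("2x2 odds ratios match hand-computed Wald arithmetic", {
  r <- or_from_table(60, 40, 100, 100)
  expect_equal(r$or, 1.5)
  expect_equal(r$ci_low, 0.9219647, tolerance = 1e-6)
  expect_equal(r$ci_high, 2.4404405, tolerance = 1e-6)
  # identical exposure rates -> OR 1
  expect_equal(or_from_table(30, 30, 70, 70)$or, 1)
  # zero cell -> Haldane-Anscombe correction, finite and flagged
  z <- or_from_table(0, 10, 50, 50)
  expect_true(is.finite(z$or) && z$or > 0)
  expect_equal(z$flag, "haldane-anscombe")
  # data-frame interface
  df <- tibble::tibble(status = rep(c("case", "control"), c(160, 140)),
                       BRCA1 = c(rep(TRUE, 60), rep(FALSE, 100),
                                 rep(TRUE, 40), rep(FALSE, 100)))
  expect_equal(two_by_two_or(df, "BRCA1")$or, 1.5)
})

test_that("AUC behaves as a rank statistic on holdout and CV", {
  d <- tibble::tibble(standardized = rep(c(0, 1), each = 200),
                      status = rep(c("control", "case"), each = 200))
  expect_equal(auc_holdout(d, seed = 1), 1)
  # null scores: AUC near 1/2
  dn <- withr::with_seed(5, tibble::tibble(
    standardized = rnorm(20000),
    status = rep(c("case", "control"), 10000)))
  expect_lt(abs(auc_holdout(dn, seed = 2) - 0.5), 0.02)
  # invariance under strictly monotone transforms
  ds <- simulate_liability_scores(500, 700, seed = 9)
  a1 <- auc_holdout(ds, seed = 3)
  ds$standardized <- exp(3 * ds$standardized)
  expect_equal(auc_holdout(ds, seed = 3), a1)
  cv <- auc_cv(ds, folds = 10, seed = 3)
  expect_equal(nrow(cv$folds), 10)
  expect_equal(cv$mean_auc, mean(cv$folds$auc))
  expect_equal(sum(cv$folds$n), nrow(ds))
})

test_that("Bonferroni caps and scales as min(1, m p)", {
  expect_equal(bonferroni(0.01, m = 9), 0.09)
  expect_equal(bonferroni(0.5, m = 9), 1)
  expect_equal(bonferroni(c(0.2, 0.04)), c(0.4, 0.08))
  expect_equal(bonferroni(0.03, m = 1), 0.03)
  expect_error(bonferroni(c(0.1, 0.2), m = 1), "family size")
})

test_that("tidy and glance return broom-shaped tibbles", {
  r <- or_from_table(60, 40, 100, 100, contrast = "demo")
  td <- tidy(r)
  expect_equal(names(td), c("contrast", "or", "ci_low", "ci_high", "p_value",
                            "n_case", "n_control", "flag"))
  expect_equal(td$contrast, "demo")
  d <- simulate_liability_scores(500, 700, seed = 2)
  g <- glance(or_per_sd(d, pc_cols = character()))
  expect_equal(g$n, 1200)
  expect_true(g$pseudo_r2_nagelkerke >= g$pseudo_r2_mcfadden)
})
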