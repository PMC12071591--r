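test_that("configuration validates its invariants", {
  expect_error(sim_config(n_cases = 10, n_controls = 10), "seed")
  expect_error(sim_config(n_cases = 10, n_controls = 10, seed = 1,
                          prevalence = 1.5))
  bad_carriers <- default_carrier_spec()
  bad_carriers$freq[1] <- 0
  expect_error(sim_config(n_cases = 10, n_controls = 10, seed = 1,
                          carrier_spec = bad_carriers), "carrier frequencies")
  cfg <- sim_config(n_cases = 10, n_controls = 10, seed = 1)
  expect_equal(cfg$gamma, log(1.43))
  expect_equal(names(cfg$dirichlet_alpha), c("EUR", "AFR", "EAS", "AMR"))
})

test_that("generator marginals match the admixture-mixture allele frequencies", {
  co <- simulate_cohort(sim_config(n_cases = 500, n_controls = 500,
                                   n_variants = 120, prevalence = 0.5,
                                   gamma = 0, seed = 77))
  # with gamma = 0 and prevalence 1/2 the sampled cohort is a population draw
  P <- attr(co$truth, "ancestral_afs")
  q <- as.matrix(co$truth[ANCESTRIES])
  expected <- colMeans(q %*% P)
  observed <- colMeans(co$genotypes$dosages) / 2
  n <- nrow(co$samples)
  se <- sqrt(expected * (1 - expected) / (2 * n))
  expect_lt(mean(abs(observed - expected) > 3 * se), 0.05)
})

test_that("EUR-majority skew matches the targeted cohort composition", {
  co <- simulate_cohort(sim_config(n_cases = 400, n_controls = 600,
                                   n_variants = 50, seed = 19))
  expect_gt(median(co$truth$EUR), 0.8)
  g <- assign_ancestry_groups(co$samples)
  tab <- table(g$ancestry_group)
  expect_gt(tab[["EUR-majority"]], 0.8 * nrow(co$samples))
})

test_that("HWE holds within a near-single-ancestry stratum", {
  co <- simulate_cohort(sim_config(
    n_cases = 300, n_controls = 700, n_variants = 150, seed = 23,
    dirichlet_alpha = c(EUR = 500, AFR = 1, EAS = 1, AMR = 1),
    gamma = 0, prevalence = 0.3))
  g <- co$genotypes$dosages
  pvals <- apply(g, 2, function(col) {
    p <- mean(col) / 2
    if (p < 0.05 || p > 0.95) return(NA_real_)
    exp_counts <- length(col) * c((1 - p)^2, 2 * p * (1 - p), p^2)
    obs <- tabulate(col + 1, 3)
    suppressWarnings(stats::chisq.test(obs, p = exp_counts / sum(exp_counts))$p.value)
  })
  pvals <- pvals[!is.na(pvals)]
  expect_lt(mean(pvals < 0.05), 0.12)   # not enriched far beyond nominal 5%
})

test_that("a null effect yields a null per-SD odds ratio", {
  # a single 95% CI misses the truth 1 time in 20 by construction, so the
  # null check asks for coverage in a majority of three independent cohorts
  covered <- vapply(c(31, 32, 33), function(seed) {
    co <- simulate_cohort(sim_config(n_cases = 600, n_controls = 900,
                                     n_variants = 150, gamma = 0, seed = seed))
    ctrl <- co$samples$sample_id[co$samples$status == "control"]
    s <- compute_scores(match_alleles(co$scoring, co$genotypes),
                        co$genotypes, ctrl)
    d <- dplyr::left_join(co$samples, s, by = "sample_id")
    r <- or_per_sd(d, pc_cols = character())
    r$ci_low <= 1 && 1 <= r$ci_high
  }, logical(1))
  expect_gte(sum(covered), 2)
})

test_that("the genotype-level pipeline recovers the simulated per-SD effect", {
  co <- simulate_cohort(sim_config(n_cases = 2000, n_controls = 3000,
                                   n_variants = 300, gamma = log(1.5),
                                   seed = 57))
  ctrl <- co$samples$sample_id[co$samples$status == "control"]
  s <- compute_scores(match_alleles(co$scoring, co$genotypes),
                      co$genotypes, ctrl)
  d <- dplyr::left_join(co$samples, s, by = "sample_id")
  r <- or_per_sd(d, pc_cols = character())
  expect_true(r$ci_low <= 1.5 && 1.5 <= r$ci_high)
})

test_that("families carry the expected pedigree structure", {
  cfg <- sim_config(n_cases = 10, n_controls = 10, n_variants = 2000,
                    n_families = 8, family_size = 4, seed = 13)
  fam <- simulate_families(cfg)
  # each child links to both parents and its sib: >= 2 first-degree edges
  kin <- fam$kinship
  child_ids <- fam$pedigree$child
  for (ch in child_ids[1:4]) {
    deg <- sum(kin$sample_a == ch | kin$sample_b == ch)
    expect_gte(deg, 2)
  }
  # trio bookkeeping: 2 parent-child edges per child + sib edges
  n_child <- 2
  expect_equal(nrow(kin), 8 * (2 * n_child + choose(n_child, 2)))
  # zero families -> empty kinship
  fam0 <- simulate_families(sim_config(n_cases = 5, n_controls = 5,
                                       n_families = 0, seed = 1))
  expect_equal(nrow(fam0$kinship), 0)
})

test_that("sibling genotype correlation is near one half", {
  cfg <- sim_config(n_cases = 10, n_controls = 10, n_variants = 4000,
                    n_families = 6, family_size = 4, seed = 29,
                    dirichlet_alpha = c(EUR = 200, AFR = 1, EAS = 1, AMR = 1),
                    fst = 0.05)
  fam <- simulate_families(cfg)
  g <- fam$genotypes$dosages
  af <- fam$family_afs
  cors <- vapply(seq_len(6), function(f) {
    i1 <- (f - 1) * 4 + 3; i2 <- i1 + 1       # the two sibs of family f
    p <- af[i1, ]
    z1 <- (g[i1, ] - 2 * p) / sqrt(2 * p * (1 - p))
    z2 <- (g[i2, ] - 2 * p) / sqrt(2 * p * (1 - p))
    cor(z1, z2)
  }, numeric(1))
  expect_lt(abs(mean(cors) - 0.5), 0.05)
})

test_that("imputation noise interpolates between identity and independence", {
  co <- simulate_cohort(sim_config(n_cases = 1200, n_controls = 1800,
                                   n_variants = 300, seed = 41))
  ctrl <- co$samples$sample_id[co$samples$status == "control"]
  score_of <- function(gm) compute_scores(match_alleles(co$scoring, gm),
                                          gm, ctrl)$normalized
  base <- score_of(co$genotypes)
  # epsilon = 0: untouched
  n0 <- add_imputation_noise(co, epsilon = 0, seed = 2)
  expect_equal(score_of(n0$genotypes), base)
  expect_equal(n0$achieved_rho, 1)
  # epsilon = 1: full redraw, correlation collapses
  n1 <- add_imputation_noise(co, epsilon = 1, seed = 2)
  expect_lt(abs(cor(base, score_of(n1$genotypes), method = "spearman")), 0.05)
  # achieved rho decreases monotonically over an epsilon grid
  rhos <- vapply(c(0.05, 0.2, 0.5, 0.8), function(e)
    add_imputation_noise(co, epsilon = e, seed = 2)$achieved_rho, numeric(1))
  expect_true(all(diff(rhos) < 0))
  expect_error(add_imputation_noise(co, seed = 1), "exactly one")
})
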