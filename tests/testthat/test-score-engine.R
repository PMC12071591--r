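test_that("variant filters drop by reason and keep a ledger", {
  sc <- admixprs:::new_prs_scoring(tibble::tibble(
    variant_id = paste0("v", 1:5), chrom = "1",
    pos = c(1000L, 1190L, 5000L, 1100L, 3000L),
    effect_allele = "G", other_allele = "A",
    beta = c(0, 0.2, 0.3, 0.1, 0.4)))
  targets <- tibble::tibble(chrom = "1", start = 900L, end = 1180L)
  maf <- tibble::tibble(variant_id = paste0("v", 1:5),
                        maf = c(0.3, 0.3, 0.3, 0.0001, 0.3))
  res <- filter_scoring_variants(sc, targets = targets, max_distance_bp = 200,
                                 maf = maf, maf_min = 0.001,
                                 exclusion_ids = "v5")
  drops <- tibble::deframe(res$drops[, c("variant_id", "reason")])
  expect_equal(unname(drops["v1"]), "null-beta")
  expect_equal(unname(drops["v3"]), "off-target")   # 3820 bp away
  expect_equal(unname(drops["v4"]), "maf-filtered")
  expect_equal(unname(drops["v5"]), "exclusion-list")
  # v2 sits 10 bp outside the target, within the 200 bp allowance
  expect_equal(res$scoring$variant_id, "v2")
  expect_error(
    filter_scoring_variants(sc, exclusion_ids = paste0("v", 1:5)),
    "no scorable variants")
})

test_that("allele matching resolves orientation and exclusions", {
  gm <- genotype_matrix(matrix(1, 1, 4),
                        samples = "S1",
                        variants = tibble::tibble(
                          variant_id = paste0("g", 1:4), chrom = "1",
                          pos = c(100L, 200L, 300L, 400L),
                          ref = c("A", "A", "A", "C"),
                          alt = c("G", "G", "T", "G")))
  sc <- admixprs:::new_prs_scoring(tibble::tibble(
    variant_id = paste0("v", 1:5), chrom = "1",
    pos = c(100L, 200L, 300L, 400L, 999L),
    effect_allele = c("G", "A", "A", "T", "G"),
    other_allele  = c("A", "G", "T", "C", "A"),
    beta = rep(0.1, 5)))
  m <- match_alleles(sc, gm)
  expect_equal(m$orientation,
               c("effect-is-alt", "effect-is-ref", "ambiguous-strand",
                 "allele-mismatch", "not-found"))
  expect_equal(m$genotype_column[1:2], c(1L, 2L))
  expect_true(all(is.na(m$genotype_column[3:5])))
  # ambiguity exclusion can be lifted
  m2 <- match_alleles(sc, gm, include_ambiguous = TRUE)
  expect_equal(m2$orientation[3], "effect-is-ref")   # A/T pair, A is REF... T is ALT
})

test_that("scores follow the weighted-sum formula and its normalization", {
  sc <- tiny_scoring(beta = c(0.2, -0.1))
  # derived example: betas {0.2, -0.1}, dosages {1, 2} -> raw 0, normalized 1/3
  gm <- tiny_gm(rbind(c(1, 2), c(0, 2), c(2, 0)), scoring = sc)
  m <- match_alleles(sc, gm)
  s <- compute_scores(m, gm, controls = c("S02", "S03"))
  expect_equal(s$raw[1], 0)
  expect_equal(s$normalized[1], 1 / 3)
  # boundary configurations: all effect dosage at positive betas only -> 1;
  # zero at positives, full at negatives -> 0
  expect_equal(s$normalized[3], 1)   # d = (2, 0): 0.4 - (-0.2) over 0.6
  expect_equal(s$normalized[2], (0 - 0.2 - (-0.2)) / 0.6)
  # all-zero dosages with all-positive betas -> normalized 0
  sc2 <- tiny_scoring(beta = c(0.2, 0.5))
  gm2 <- tiny_gm(rbind(c(0, 0), c(1, 1), c(2, 2)), scoring = sc2)
  s2 <- compute_scores(match_alleles(sc2, gm2), gm2, controls = c("S02", "S03"))
  expect_equal(s2$normalized[1], 0)
  expect_equal(s2$normalized[3], 1)
  # controls are standardized exactly
  ctrl <- s2$standardized[2:3]
  expect_equal(mean(ctrl), 0, tolerance = 1e-12)
  expect_equal(sd(ctrl), 1, tolerance = 1e-12)
})

test_that("missing dosages are imputed with twice the effect-allele frequency", {
  sc <- tiny_scoring(beta = c(0.5))
  gm <- tiny_gm(matrix(c(2, 1, NA, 0), ncol = 1), scoring = sc)
  s <- compute_scores(match_alleles(sc, gm), gm, controls = c("S01", "S02"))
  eaf <- mean(c(2, 1, 0)) / 2
  expect_equal(s$raw[3], 0.5 * 2 * eaf)
  # degenerate controls
  gm3 <- tiny_gm(matrix(c(1, 1, 2), ncol = 1), scoring = sc)
  expect_error(compute_scores(match_alleles(sc, gm3), gm3,
                              controls = c("S01", "S02")),
               "standard deviation is zero")
})

test_that("vectorized scoring equals the explicit-loop oracle", {
  for (seed in c(3, 17, 91)) {
    inst <- random_instance(n = 40, m = 60, seed = seed)
    oracle <- oracle_scores(inst$scoring, inst$gm, inst$eff_is_alt)
    m <- match_alleles(inst$scoring, inst$gm)
    s <- compute_scores(m, inst$gm, controls = inst$gm$samples[1:20])
    expect_lt(max(abs(s$raw - oracle$raw)), 1e-10)
    expect_lt(max(abs(s$normalized - oracle$normalized)), 1e-10)
  }
})

test_that("allele flip with beta negation leaves normalized scores unchanged", {
  inst <- random_instance(n = 30, m = 40, seed = 8)
  m <- match_alleles(inst$scoring, inst$gm)
  base <- compute_scores(m, inst$gm, controls = inst$gm$samples[1:15])
  flip <- withr::with_seed(8, sample(40, 15))
  sc2 <- inst$scoring
  tmp <- sc2$effect_allele[flip]
  sc2$effect_allele[flip] <- sc2$other_allele[flip]
  sc2$other_allele[flip] <- tmp
  sc2$beta[flip] <- -sc2$beta[flip]
  s2 <- compute_scores(match_alleles(sc2, inst$gm), inst$gm,
                       controls = inst$gm$samples[1:15])
  expect_equal(s2$normalized, base$normalized, tolerance = 1e-12)
  expect_equal(s2$standardized, base$standardized, tolerance = 1e-10)
  expect_true(all(base$normalized >= 0 & base$normalized <= 1))
})
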