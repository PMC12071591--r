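#' Simulation configuration for the admixed case-control generator
#'
#' Collects every knob of the cohort generator with defaults emulating the
#' study conditions of a large Brazilian breast-cancer validation cohort:
#' ~5.6k cases and ~8.8k controls, four-way EUR/AFR/EAS/AMR admixture with
#' a strong European-majority skew, a per-SD log-odds effect of ln(1.43),
#' rare monogenic carriers with gene-specific odds ratios between ~2 and
#' 14, first-degree family clusters, and an imputation-noise model
#' calibrated to a score-level Spearman correlation of 0.74.
#'
#' @param n_cases,n_controls Target case/control sample sizes.
#' @param n_variants Number of independent scoring variants.
#' @param dirichlet_alpha Named Dirichlet concentration per ancestry; the
#'   default gives median EUR proportion near 0.84 with SD near 0.18.
#' @param fst Balding-Nichols divergence of per-ancestry allele
#'   frequencies from the shared ancestral frequency.
#' @param gamma True log-odds per population-SD of the normalized score.
#' @param prevalence Target disease prevalence in the simulated population.
#' @param carrier_spec Tibble `gene`, `freq`, `or`: carrier frequency and
#'   multiplicative odds effect per monogenic gene.
#' @param n_families,family_size First-degree family clusters appended to
#'   the cohort (each family = 2 parents + `family_size - 2` offspring).
#' @param target_rho Score-level Spearman correlation targeted by the
#'   imputation-noise calibration ([add_imputation_noise()]).
#' @param seed Mandatory integer seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 5598L, n_controls = 8767L,
                       n_variants = 500L,
                       dirichlet_alpha = c(EUR = 2.5, AFR = 0.2,
                                           EAS = 0.05, AMR = 0.25),
                       fst = 0.1, gamma = log(1.43), prevalence = 0.1,
                       carrier_spec = default_carrier_spec(),
                       n_families = 0L, family_size = 3L,
                       target_rho = 0.74, seed) {
  if (missing(seed) || is.null(seed)) stopf("sim_config() requires a seed")
  stopifnot(n_cases >= 1, n_controls >= 1, n_variants >= 2,
            is.finite(gamma), prevalence > 0, prevalence < 1,
            fst > 0, fst < 1, family_size >= 3)
  if (!setequal(names(dirichlet_alpha), ANCESTRIES))
    stopf("dirichlet_alpha must be named %s", paste(ANCESTRIES, collapse = ", "))
  if (any(carrier_spec$freq <= 0 | carrier_spec$freq >= 1))
    stopf("carrier frequencies must lie in (0, 1)")
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_variants = as.integer(n_variants),
                 dirichlet_alpha = dirichlet_alpha[ANCESTRIES], fst = fst,
                 gamma = gamma, prevalence = prevalence,
                 carrier_spec = carrier_spec,
                 n_families = as.integer(n_families),
                 family_size = as.integer(family_size),
                 target_rho = target_rho, seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_carrier_spec <- function() {
  tibble(gene = CARRIER_GENES,
         freq = c(0.003, 0.004, 0.0005, 0.0015, 0.0005, 0.004, 0.005, 0.001),
         or   = c(13.4,  8.8,   14,     5,      5,      2.5,   2.1,   5))
}

rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

# Balding-Nichols per-ancestry allele frequencies around a shared ancestral AF
ancestral_afs <- function(m, K, fst) {
  p0 <- stats::runif(m, 0.05, 0.95)
  a <- p0 * (1 - fst) / fst
  b <- (1 - p0) * (1 - fst) / fst
  P <- vapply(seq_len(K), function(k) stats::rbeta(m, a, b), numeric(m))
  pmin(pmax(t(P), 0.01), 0.99)            # K x m
}

# non-strand-ambiguous REF/ALT pairs only, so the generated scoring file is
# fully scorable under the default ambiguity exclusion
sim_variant_table <- function(m) {
  pairs <- rbind(c("A", "G"), c("A", "C"), c("G", "A"), c("C", "A"),
                 c("T", "G"), c("T", "C"), c("G", "T"), c("C", "T"))
  pick <- sample(nrow(pairs), m, replace = TRUE)
  tibble(variant_id = sprintf("rs%06d", seq_len(m)),
         chrom = as.character(rep_len(1:22, m)),
         pos = seq_len(m) * 1000L + sample.int(999L, m, replace = TRUE),
         ref = pairs[pick, 1], alt = pairs[pick, 2])
}

# intercept for a target prevalence given the non-intercept linear predictor
solve_intercept <- function(eta, prevalence) {
  f <- function(a) mean(stats::plogis(a + eta)) - prevalence
  if (f(-30) > 0 || f(30) < 0) stopf("target prevalence unattainable")
  stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
}

#' Simulate an admixed case-control cohort with known ground truth
#'
#' Generates, under a single seed: (1) a scoring file of independent
#' variants with Gaussian effect weights and randomized effect-allele
#' orientation; (2) per-sample admixture proportions `q ~ Dirichlet(alpha)`
#' and genotypes `g ~ Binomial(2, q' p)` (Hardy-Weinberg within each
#' individual's ancestry mixture, Balding-Nichols divergence across
#' ancestries); (3) monogenic carrier flags per gene; (4) disease status
#' from the logistic liability model
#' `P(case) = expit(alpha0 + gamma z + sum(carrier ln OR))`, where `z` is
#' the population-standardized true score and `alpha0` is solved for the
#' target prevalence; (5) case-control sampling down to the requested
#' sizes; and optionally (6) first-degree family clusters appended for
#' relatedness-pruning tests.
#'
#' @param config A [sim_config()].
#' @return A list of class `prs_cohort`: `scoring` (a `prs_scoring`
#'   tibble), `genotypes` (`genotype_matrix` of ALT dosages), `samples`
#'   (metadata tibble with status, sex, carrier flags and true ancestry
#'   proportions), `kinship` (first-degree pair tibble), and `truth`
#'   (per-sample tibble `z_true`, `eta`, plus attributes `alpha0`,
#'   `ancestral_afs`, `q`, `config`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    m <- config$n_variants
    vt <- sim_variant_table(m)
    eff_is_alt <- stats::runif(m) < 0.5
    scoring <- new_prs_scoring(tibble(
      variant_id = vt$variant_id, chrom = vt$chrom, pos = vt$pos,
      effect_allele = ifelse(eff_is_alt, vt$alt, vt$ref),
      other_allele = ifelse(eff_is_alt, vt$ref, vt$alt),
      beta = stats::rnorm(m, 0, 0.1)),
      prs_name = "sim_prs", provenance = "simulate_cohort")

    P <- ancestral_afs(m, length(ANCESTRIES), config$fst)   # ALT AF, K x m

    # population sized so the expected case/control yields clear the requested
    # counts by several binomial SDs even for small cohorts
    n_pop <- ceiling(max(
      (config$n_cases + 4 * sqrt(config$n_cases) + 20) / config$prevalence,
      (config$n_controls + 4 * sqrt(config$n_controls) + 20) /
        (1 - config$prevalence)))
    pop <- sim_population(n_pop, P, config, scoring, eff_is_alt)

    is_case <- pop$status == 1L
    if (sum(is_case) < config$n_cases || sum(!is_case) < config$n_controls)
      stopf("simulated population yielded too few %s; raise prevalence or sizes",
            if (sum(is_case) < config$n_cases) "cases" else "controls")
    take <- c(sample(which(is_case), config$n_cases),
              sample(which(!is_case), config$n_controls))
    take <- sort(take)

    fam <- if (config$n_families > 0)
      sim_families_internal(config, P, scoring, eff_is_alt) else NULL

    assemble_cohort(pop, take, fam, vt, scoring, P, config)
  })
}

# population draw: ancestry, genotypes, carriers, liability, status
sim_population <- function(n, P, config, scoring, eff_is_alt,
                           q = NULL, g = NULL) {
  m <- ncol(P)
  if (is.null(q)) q <- rdirichlet(n, config$dirichlet_alpha)
  p_ind <- q %*% P                                   # individual ALT AF
  if (is.null(g)) {
    g <- matrix(stats::rbinom(n * m, 2L, as.vector(p_ind)), nrow = n)
  }
  d_eff <- g
  if (any(!eff_is_alt)) d_eff[, !eff_is_alt] <- 2 - d_eff[, !eff_is_alt]
  raw <- as.vector(d_eff %*% scoring$beta)
  z <- (raw - mean(raw)) / stats::sd(raw)

  cs <- config$carrier_spec
  carriers <- matrix(stats::runif(n * nrow(cs)) < rep(cs$freq, each = n),
                     nrow = n, dimnames = list(NULL, cs$gene))
  eta <- config$gamma * z + as.vector(carriers %*% log(cs$or))
  alpha0 <- solve_intercept(eta, config$prevalence)
  status <- as.integer(stats::runif(n) < stats::plogis(alpha0 + eta))
  list(q = q, g = g, z = z, eta = eta, alpha0 = alpha0,
       carriers = carriers, status = status)
}

assemble_cohort <- function(pop, take, fam, vt, scoring, P, config) {
  ids <- sprintf("S%05d", seq_along(take))
  g <- pop$g[take, , drop = FALSE]
  q <- pop$q[take, , drop = FALSE]
  carriers <- pop$carriers[take, , drop = FALSE]
  status <- pop$status[take]
  z <- pop$z[take]; eta <- pop$eta[take]
  kin <- tibble(sample_a = character(), sample_b = character(),
                degree = integer())
  if (!is.null(fam)) {
    ids <- c(ids, fam$ids)
    g <- rbind(g, fam$g); q <- rbind(q, fam$q)
    carriers <- rbind(carriers, fam$carriers)
    status <- c(status, fam$status); z <- c(z, fam$z); eta <- c(eta, fam$eta)
    kin <- fam$kinship
  }
  colnames(q) <- ANCESTRIES
  samples <- bind_cols(
    tibble(sample_id = ids,
           status = ifelse(status == 1L, "case", "control"),
           sex = ifelse(status == 1L, "F",
                        ifelse(stats::runif(length(ids)) < 0.48, "F", "M")),
           age = NA_real_),
    as_tibble(carriers), as_tibble(q))
  gm <- genotype_matrix(g, ids, vt)
  truth <- bind_cols(tibble(sample_id = ids, z_true = z, eta = eta,
                            status = status), as_tibble(q))
  attr(truth, "alpha0") <- pop$alpha0
  attr(truth, "ancestral_afs") <- P
  attr(truth, "config") <- config
  structure(list(scoring = scoring, genotypes = gm, samples = samples,
                 kinship = kin, truth = truth),
            class = "prs_cohort")
}

#' @export
print.prs_cohort <- function(x, ...) {
  cat(sprintf("<prs_cohort> %d sample(s) (%d cases / %d controls), %d variant(s), %d kinship pair(s)\n",
              nrow(x$samples), sum(x$samples$status == "case"),
              sum(x$samples$status == "control"), nrow(x$scoring),
              nrow(x$kinship)))
  invisible(x)
}

# families: 2 founder parents each, offspring by Mendelian transmission
sim_families_internal <- function(config, P, scoring, eff_is_alt) {
  nf <- config$n_families
  n_child <- config$family_size - 2L
  m <- ncol(P)
  q_par <- rdirichlet(2L * nf, config$dirichlet_alpha)
  p_par <- q_par %*% P
  g_par <- matrix(stats::rbinom(2L * nf * m, 2L, as.vector(p_par)),
                  nrow = 2L * nf)
  transmit <- function(gp) {                 # one gamete per parent genotype row
    pr <- gp / 2
    matrix(stats::rbinom(length(gp), 1L, as.vector(pr)), nrow = nrow(gp))
  }
  ids <- character(); g <- NULL; q <- NULL
  kin <- list(); ped <- list()
  for (f in seq_len(nf)) {
    fa <- g_par[2L * f - 1L, , drop = FALSE]
    mo <- g_par[2L * f, , drop = FALSE]
    kids <- do.call(rbind, lapply(seq_len(n_child), function(i)
      transmit(fa) + transmit(mo)))
    fam_ids <- c(sprintf("F%03d_P1", f), sprintf("F%03d_P2", f),
                 sprintf("F%03d_C%d", f, seq_len(n_child)))
    ids <- c(ids, fam_ids)
    g <- rbind(g, fa, mo, kids)
    q_kid <- (q_par[2L * f - 1L, ] + q_par[2L * f, ]) / 2
    q <- rbind(q, q_par[2L * f - 1L, , drop = FALSE],
               q_par[2L * f, , drop = FALSE],
               matrix(rep(q_kid, n_child), ncol = length(q_kid), byrow = TRUE))
    child_ids <- fam_ids[-(1:2)]
    po <- expand.grid(p = fam_ids[1:2], c = child_ids,
                      stringsAsFactors = FALSE)
    kin[[f]] <- tibble(sample_a = c(po$p, if (n_child >= 2)
                         utils::combn(child_ids, 2)[1, ]),
                       sample_b = c(po$c, if (n_child >= 2)
                         utils::combn(child_ids, 2)[2, ]),
                       degree = 1L)
    ped[[f]] <- tibble(family = f, father = fam_ids[1], mother = fam_ids[2],
                       child = child_ids)
  }
  n_tot <- length(ids)
  # status/liability for family members under the same disease model
  d_eff <- g
  if (any(!eff_is_alt)) d_eff[, !eff_is_alt] <- 2 - d_eff[, !eff_is_alt]
  raw <- as.vector(d_eff %*% scoring$beta)
  z <- (raw - mean(raw)) / stats::sd(raw)
  cs <- config$carrier_spec
  carriers <- matrix(stats::runif(n_tot * nrow(cs)) < rep(cs$freq, each = n_tot),
                     nrow = n_tot, dimnames = list(NULL, cs$gene))
  eta <- config$gamma * z + as.vector(carriers %*% log(cs$or))
  alpha0 <- solve_intercept(eta, config$prevalence)
  status <- as.integer(stats::runif(n_tot) < stats::plogis(alpha0 + eta))
  list(ids = ids, g = g, q = q, carriers = carriers, status = status,
       z = z, eta = eta, kinship = bind_rows(kin),
       pedigree = bind_rows(ped),
       parent_afs = q_par %*% P)
}

#' Simulate first-degree family clusters
#'
#' Standalone family generator for relatedness tests: `n_families`
#' families of two founder parents and `family_size - 2` offspring drawn
#' by Mendelian transmission per variant; the kinship table lists every
#' parent-offspring and full-sibling pair with degree 1.
#'
#' @param config A [sim_config()] (uses `n_families`, `family_size`,
#'   `n_variants`, admixture and frequency settings, `seed`).
#' @return A list: `genotypes` (`genotype_matrix`), `kinship`,
#'   `pedigree`, `samples` (ids + status), and `family_afs` (per-member
#'   expected ALT AF matrix, for Mendelian-correlation checks).
#' @export
simulate_families <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_families == 0L)
    return(list(genotypes = NULL,
                kinship = tibble(sample_a = character(),
                                 sample_b = character(), degree = integer()),
                pedigree = tibble(), samples = tibble(), family_afs = NULL))
  withr::with_seed(config$seed, {
    m <- config$n_variants
    vt <- sim_variant_table(m)
    eff_is_alt <- stats::runif(m) < 0.5
    scoring <- new_prs_scoring(tibble(
      variant_id = vt$variant_id, chrom = vt$chrom, pos = vt$pos,
      effect_allele = ifelse(eff_is_alt, vt$alt, vt$ref),
      other_allele = ifelse(eff_is_alt, vt$ref, vt$alt),
      beta = stats::rnorm(m, 0, 0.1)), prs_name = "sim_prs_fam")
    P <- ancestral_afs(m, length(ANCESTRIES), config$fst)
    fam <- sim_families_internal(config, P, scoring, eff_is_alt)
    n_child <- config$family_size - 2L
    # per-member expected AF: parents their own, children the parental average
    child_af <- (fam$parent_afs[seq(1, nrow(fam$parent_afs), 2), , drop = FALSE] +
                 fam$parent_afs[seq(2, nrow(fam$parent_afs), 2), , drop = FALSE]) / 2
    member_afs <- NULL
    for (f in seq_len(config$n_families)) {
      member_afs <- rbind(member_afs,
                          fam$parent_afs[2L * f - 1L, , drop = FALSE],
                          fam$parent_afs[2L * f, , drop = FALSE],
                          child_af[rep(f, n_child), , drop = FALSE])
    }
    list(genotypes = genotype_matrix(fam$g, fam$ids, vt),
         kinship = fam$kinship, pedigree = fam$pedigree,
         samples = tibble(sample_id = fam$ids,
                          status = ifelse(fam$status == 1L, "case", "control")),
         family_afs = member_afs)
  })
}

#' Inject genotype-level imputation noise, optionally calibrated to a
#' target score correlation
#'
#' Each genotype is, with probability `epsilon`, replaced by a fresh
#' `Binomial(2, p_i)` draw at the individual's own allele frequency
#' (`p_i = q' p` from the cohort truth), emulating imputation error that
#' degrades score concordance without shifting allele-frequency marginals.
#' When `target_rho` is given instead of `epsilon`, the replacement
#' probability is found by bisection on the Spearman correlation between
#' original and noisy normalized scores; replacement draws are generated
#' once and thresholded, so the correlation is monotone in `epsilon` and
#' the bisection is well-posed.
#'
#' @param cohort A `prs_cohort` from [simulate_cohort()].
#' @param epsilon Per-genotype replacement probability in `[0, 1]`.
#' @param target_rho Target Spearman correlation (mutually exclusive with
#'   `epsilon`).
#' @param seed Integer seed for the noise draws.
#' @param tol Bisection tolerance on epsilon.
#' @return A list: `genotypes` (noisy `genotype_matrix`), `epsilon`
#'   (the value used/achieved), `achieved_rho`.
#' @export
add_imputation_noise <- function(cohort, epsilon = NULL, target_rho = NULL,
                                 seed = 1L, tol = 1e-4) {
  stopifnot(inherits(cohort, "prs_cohort"))
  if (is.null(epsilon) == is.null(target_rho))
    stopf("give exactly one of epsilon or target_rho")
  gm <- cohort$genotypes
  q <- as.matrix(cohort$truth[ANCESTRIES])
  P <- attr(cohort$truth, "ancestral_afs")
  p_ind <- q %*% P
  g0 <- gm$dosages
  withr::local_seed(seed)
  u <- matrix(stats::runif(length(g0)), nrow = nrow(g0))
  redraw <- matrix(stats::rbinom(length(g0), 2L, as.vector(p_ind)),
                   nrow = nrow(g0))

  score_of <- function(g) {
    gm2 <- gm; gm2$dosages <- g
    matched <- match_alleles(cohort$scoring, gm2)
    controls <- cohort$samples$sample_id[cohort$samples$status == "control"]
    compute_scores(matched, gm2, controls)$normalized
  }
  base <- score_of(g0)
  noisy_at <- function(eps) {
    g <- g0; sel <- u < eps
    g[sel] <- redraw[sel]
    g
  }
  rho_at <- function(eps)
    stats::cor(base, score_of(noisy_at(eps)), method = "spearman")

  if (is.null(epsilon)) {
    lo <- 0; hi <- 1
    if (rho_at(1) > target_rho) {
      epsilon <- 1
    } else {
      while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        if (rho_at(mid) > target_rho) lo <- mid else hi <- mid
      }
      epsilon <- (lo + hi) / 2
    }
  }
  g_noisy <- noisy_at(epsilon)
  gm_out <- gm; gm_out$dosages <- g_noisy
  list(genotypes = gm_out, epsilon = epsilon,
       achieved_rho = stats::cor(base, score_of(g_noisy), method = "spearman"))
}

#' Fast score-level liability simulator
#'
#' Draws the standardized true score directly (`z ~ N(0, 1)` in the
#' population) and disease status from
#' `P(case) = expit(alpha0 + gamma z)`, with the intercept solved
#' numerically for the target prevalence — the score-level skeleton of
#' [simulate_cohort()] used for statistical calibration checks (parameter
#' recovery, AUC oracles, decile staircases) where genotypes are
#' irrelevant.
#'
#' `simulate_liability_scores()` samples the population down to a
#' case-control design and standardizes the score against the sampled
#' controls; `simulate_liability_population()` returns the whole
#' population cross-section.
#'
#' @param n_cases,n_controls Case-control sizes to sample.
#' @param gamma True log-OR per population SD.
#' @param prevalence Population disease prevalence.
#' @param seed Integer seed.
#' @return A tibble `sample_id`, `z` (population scale), `standardized`
#'   (control-standardized), `status`.
#' @export
simulate_liability_scores <- function(n_cases, n_controls,
                                      gamma = log(1.43), prevalence = 0.1,
                                      seed) {
  if (missing(seed)) stopf("seed is required")
  withr::with_seed(seed, {
    alpha0 <- liability_intercept(gamma, prevalence)
    need <- ceiling(max(
      (n_cases + 4 * sqrt(n_cases) + 20) / prevalence,
      (n_controls + 4 * sqrt(n_controls) + 20) / (1 - prevalence)))
    z <- stats::rnorm(need)
    y <- as.integer(stats::runif(need) < stats::plogis(alpha0 + gamma * z))
    if (sum(y) < n_cases || sum(!y) < n_controls)
      stopf("population too small for requested case/control counts")
    take <- c(sample(which(y == 1L), n_cases),
              sample(which(y == 0L), n_controls))
    z <- z[take]; y <- y[take]
    ctrl <- y == 0L
    tibble(sample_id = sprintf("L%06d", seq_along(z)), z = z,
           standardized = (z - mean(z[ctrl])) / stats::sd(z[ctrl]),
           status = ifelse(y == 1L, "case", "control"))
  })
}

#' @rdname simulate_liability_scores
#' @param n Population size.
#' @export
simulate_liability_population <- function(n, gamma = log(1.43),
                                          prevalence = 0.1, seed) {
  if (missing(seed)) stopf("seed is required")
  withr::with_seed(seed, {
    alpha0 <- liability_intercept(gamma, prevalence)
    z <- stats::rnorm(n)
    y <- as.integer(stats::runif(n) < stats::plogis(alpha0 + gamma * z))
    ctrl <- y == 0L
    tibble(sample_id = sprintf("P%06d", seq_len(n)), z = z,
           standardized = (z - mean(z[ctrl])) / stats::sd(z[ctrl]),
           status = ifelse(y == 1L, "case", "control"))
  })
}

# intercept giving E_z[expit(a + gamma z)] = prevalence under z ~ N(0,1)
liability_intercept <- function(gamma, prevalence) {
  f <- function(a)
    stats::integrate(function(z) stats::dnorm(z) * stats::plogis(a + gamma * z),
                     -8, 8)$value - prevalence
  stats::uniroot(f, c(-30, 30), tol = 1e-12)$root
}

#' Write a simulated cohort to disk
#'
#' Emits the plain-text artifacts every pipeline stage consumes: a VCF
#' (GT + DS), the scoring TSV, metadata/kinship/ancestry TSVs, a
#' per-sample truth TSV and a truth JSON of scalar generator settings.
#'
#' @param cohort A `prs_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             scoring = file.path(dir, "scoring.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             kinship = file.path(dir, "kinship.tsv"),
             ancestry = file.path(dir, "ancestry.tsv"),
             truth = file.path(dir, "truth.tsv"),
             truth_json = file.path(dir, "truth.json"))
  write_vcf(cohort$genotypes, paths["vcf"])
  write_scoring_file(cohort$scoring, paths["scoring"])
  meta_cols <- c("sample_id", "status", "sex", "age",
                 intersect(CARRIER_GENES, names(cohort$samples)))
  readr::write_tsv(cohort$samples[meta_cols], paths["metadata"])
  readr::write_tsv(cohort$kinship, paths["kinship"])
  readr::write_tsv(cohort$samples[c("sample_id", ANCESTRIES)], paths["ancestry"])
  readr::write_tsv(cohort$truth, paths["truth"])
  cfg <- attr(cohort$truth, "config")
  jsonlite::write_json(list(alpha0 = attr(cohort$truth, "alpha0"),
                            gamma = cfg$gamma, prevalence = cfg$prevalence,
                            seed = cfg$seed, n_variants = cfg$n_variants),
                       paths["truth_json"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
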