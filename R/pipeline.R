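#' Subset a genotype matrix to a set of samples
#'
#' @param gm A `genotype_matrix`.
#' @param ids Sample ids to keep (order preserved from `gm`).
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(gm, ids) {
  keep <- gm$samples %in% ids
  if (!any(keep)) stopf("no requested samples present in genotype matrix")
  genotype_matrix(gm$dosages[keep, , drop = FALSE], gm$samples[keep],
                  gm$variants)
}

pipeline_schema <- list(
  out_dir = NULL, seed = NULL,
  simulate = c("n_cases", "n_controls", "n_variants", "gamma", "prevalence",
               "fst", "n_families", "family_size", "target_rho", "seed"),
  inputs = c("scoring", "vcf", "metadata", "kinship", "ancestry",
             "targets_bed", "scoring_dialect"),
  score = c("max_distance_bp", "maf_min", "exclude_ids", "prefer_dosage",
            "include_ambiguous"),
  qc = c("carrier_genes", "seed"),
  pca = c("maf_min", "k"),
  assoc = c("bins", "boundary_source", "test_fraction", "folds",
            "bonferroni_m", "seed"),
  concord = c("target_rho", "epsilon", "seed"))

validate_pipeline_config <- function(config) {
  unknown <- setdiff(names(config), names(pipeline_schema))
  if (length(unknown) > 0)
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  for (blk in intersect(names(config), names(pipeline_schema))) {
    allowed <- pipeline_schema[[blk]]
    if (is.null(allowed) || !is.list(config[[blk]])) next
    bad <- setdiff(names(config[[blk]]), allowed)
    if (length(bad) > 0)
      stopf("unknown config key(s) in '%s': %s", blk, paste(bad, collapse = ", "))
  }
  if (is.null(config$out_dir)) stopf("config requires 'out_dir'")
  if (is.null(config$simulate) && is.null(config$inputs))
    stopf("config needs either a 'simulate' or an 'inputs' block")
  invisible(config)
}

#' Run the full validation pipeline from one configuration
#'
#' Orchestrates the analysis end to end in the fixed order
#' simulate/ingest -> QC -> scoring -> PCA -> association
#' (-> concordance when a paired score set is requested), so that excluded
#' samples never reach any statistic, and writes all result tables plus a
#' reproducible JSON run manifest. Re-running with an identical
#' configuration reproduces every output bit-identically.
#'
#' @param config A YAML file path or a nested list with blocks `out_dir`,
#'   `seed`, and either `simulate` (arguments to [sim_config()]) or
#'   `inputs` (paths: `scoring`, `vcf`, `metadata`, `kinship`, `ancestry`,
#'   `targets_bed`), plus optional `score`, `qc`, `pca`, `assoc`,
#'   `concord` stage blocks. Unknown keys are rejected by name.
#' @return The run manifest (list), invisibly; side effect: tables and
#'   `manifest.json` under `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  validate_pipeline_config(config)
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character()
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  manifest <- list(seeds = list(run = seed), stages = list(), outputs = list())

  ## -- ingest or simulate ---------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- as.integer(sim_args$seed %||% seed)
    cohort <- simulate_cohort(do.call(sim_config, sim_args))
    scoring <- cohort$scoring
    gm <- cohort$genotypes
    samples <- cohort$samples
    kinship <- cohort$kinship
    targets <- NULL
    note("simulate: %d samples, %d variants, seed %d",
         nrow(samples), nrow(scoring), sim_args$seed)
  } else {
    inp <- config$inputs
    scoring <- read_scoring_file(inp$scoring,
                                 dialect = inp$scoring_dialect %||% "pgs_catalog")
    tabs <- read_cohort_tables(inp$metadata, inp$kinship, inp$ancestry)
    samples <- tabs$samples
    kinship <- tabs$kinship
    gm <- read_genotypes(inp$vcf, scoring,
                         prefer_dosage = isTRUE(config$score$prefer_dosage %||% TRUE))
    targets <- if (!is.null(inp$targets_bed)) read_bed(inp$targets_bed) else NULL
    manifest$inputs <- lapply(
      inp[intersect(names(inp), c("scoring", "vcf", "metadata", "kinship",
                                  "ancestry", "targets_bed"))],
      function(p) unname(tools::md5sum(p)))
    note("ingest: %d samples, %d scoring variants", nrow(samples), nrow(scoring))
  }
  initial_n <- nrow(samples)

  ## -- QC -------------------------------------------------------------------
  qc_seed <- as.integer(config$qc$seed %||% seed)
  pr <- prune_related(samples, kinship, seed = qc_seed)
  samples_qc <- samples[samples$sample_id %in% pr$kept, ]
  ec <- exclude_carriers(samples_qc,
                         genes = config$qc$carrier_genes %||% HIGH_PENETRANCE_GENES)
  samples_qc <- samples_qc[samples_qc$sample_id %in% ec$kept, ]
  ledger <- build_ledger(initial_n, relatedness = pr$removed,
                         carriers = ec$removed,
                         final_cases = sum(samples_qc$status == "case"),
                         final_controls = sum(samples_qc$status == "control"))
  samples_qc <- assign_ancestry_groups(samples_qc)
  note("qc: removed %d related, %d carriers; %d remain (seed %d)",
       length(pr$removed), length(ec$removed), nrow(samples_qc), qc_seed)
  manifest$stages$qc <- list(initial_n = initial_n,
                             removed_relatedness = length(pr$removed),
                             removed_carriers = length(ec$removed),
                             final_n = nrow(samples_qc))

  ## -- scoring --------------------------------------------------------------
  gm_qc <- subset_genotypes(gm, samples_qc$sample_id)
  sc <- config$score %||% list()
  flt <- filter_scoring_variants(
    scoring, targets = targets,
    max_distance_bp = sc$max_distance_bp %||% 200L,
    maf = cohort_maf(gm_qc), maf_min = sc$maf_min %||% 0.001,
    exclusion_ids = sc$exclude_ids %||% character())
  matched <- match_alleles(flt$scoring, gm_qc,
                           include_ambiguous = isTRUE(sc$include_ambiguous))
  controls <- samples_qc$sample_id[samples_qc$status == "control"]
  scores <- compute_scores(matched, gm_qc, controls)
  note("score: %d variants used, %d dropped pre-match",
       scores$n_variants_used[1], nrow(flt$drops))
  manifest$stages$score <- list(
    n_variants_used = scores$n_variants_used[1],
    drops = stats::setNames(as.list(flt$drop_counts$n), flt$drop_counts$reason),
    n_unmatched = sum(!matched$orientation %in%
                        c("effect-is-alt", "effect-is-ref")))

  ## -- PCA ------------------------------------------------------------------
  pc_cfg <- config$pca %||% list()
  K <- as.integer(pc_cfg$k %||% 10L)
  pcs <- zscore_pcs(compute_pcs(gm_qc, maf_min = pc_cfg$maf_min %||% 0.01, K = K))
  note("pca: %d z-scored components", K)

  ## -- association ----------------------------------------------------------
  as_cfg <- config$assoc %||% list()
  assoc_seed <- as.integer(as_cfg$seed %||% seed)
  dat <- samples_qc %>%
    left_join(scores, by = "sample_id") %>%
    left_join(pcs, by = "sample_id")
  res_sd <- or_per_sd(dat)
  binned <- make_bins(dat, kind = as_cfg$bins %||% "decile",
                      boundary_source = as_cfg$boundary_source %||% "controls")
  staircase <- bin_or_table(binned)
  auc_ho <- auc_holdout(dat, test_fraction = as_cfg$test_fraction %||% 0.25,
                        seed = assoc_seed)
  cv <- auc_cv(dat, folds = as_cfg$folds %||% 10L, seed = assoc_seed)

  group_rows <- dat %>%
    filter(!is.na(.data$ancestry_group)) %>%
    dplyr::group_split(.data$ancestry_group) %>%
    purrr::keep(~ min(table(.x$status)) >= 25) %>%
    purrr::map_dfr(function(d)
      mutate(tidy(or_per_sd(d)),
             contrast = paste0("per-SD [", as.character(d$ancestry_group[1]), "]")))
  if (nrow(group_rows) > 0)
    group_rows$p_bonferroni <- bonferroni(group_rows$p_value,
                                          m = as_cfg$bonferroni_m %||%
                                            nrow(group_rows))
  carrier_rows <- purrr::map_dfr(intersect(CARRIER_GENES, names(dat)),
                                 function(g) tidy(two_by_two_or(dat, g)))
  assoc_tbl <- bind_rows(tidy(res_sd), group_rows, carrier_rows)
  note("assoc: OR/SD %.3f, holdout AUC %.3f, CV AUC %.3f (seed %d)",
       res_sd$or, auc_ho, cv$mean_auc, assoc_seed)
  manifest$stages$assoc <- list(or_per_sd = res_sd$or, auc_holdout = auc_ho,
                                auc_cv_mean = cv$mean_auc,
                                n_rows = nrow(assoc_tbl))

  ## -- concordance (optional) ----------------------------------------------
  concord_report <- NULL
  if (!is.null(config$concord) && !is.null(config$simulate)) {
    cc <- config$concord
    noisy <- add_imputation_noise(cohort, epsilon = cc$epsilon,
                                  target_rho = cc$target_rho,
                                  seed = as.integer(cc$seed %||% seed))
    matched_n <- match_alleles(flt$scoring,
                               subset_genotypes(noisy$genotypes,
                                                samples_qc$sample_id))
    scores_n <- compute_scores(matched_n,
                               subset_genotypes(noisy$genotypes,
                                                samples_qc$sample_id),
                               controls)
    concord_report <- compare_scores(scores, scores_n)
    note("concord: rho %.3f at epsilon %.4f", concord_report$spearman_rho,
         noisy$epsilon)
    manifest$stages$concord <- list(epsilon = noisy$epsilon,
                                    spearman_rho = concord_report$spearman_rho)
  }

  ## -- write outputs --------------------------------------------------------
  outs <- list(scores = "scores.tsv", pcs = "pcs.tsv", assoc = "assoc.tsv",
               staircase = "staircase.tsv", ledger = "ledger.json",
               manifest = "manifest.json")
  readr::write_tsv(scores, file.path(out_dir, outs$scores))
  readr::write_tsv(pcs, file.path(out_dir, outs$pcs))
  readr::write_tsv(assoc_tbl, file.path(out_dir, outs$assoc))
  readr::write_tsv(staircase, file.path(out_dir, outs$staircase))
  jsonlite::write_json(list(
    initial_n = attr(ledger, "initial_n"), final_n = attr(ledger, "final_n"),
    analyzed_total = attr(ledger, "analyzed_total"),
    stages = as.list(stats::setNames(ledger$n_removed, ledger$stage))),
    file.path(out_dir, outs$ledger), auto_unbox = TRUE, digits = NA)
  if (!is.null(concord_report))
    jsonlite::write_json(tidy(concord_report),
                         file.path(out_dir, "concordance.json"), digits = NA)
  manifest$outputs <- lapply(outs[names(outs) != "manifest"],
                             function(f) file.path(out_dir, f))
  jsonlite::write_json(manifest, file.path(out_dir, outs$manifest),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, log_path)
  invisible(manifest)
}
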