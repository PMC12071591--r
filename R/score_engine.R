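#' Cohort allele frequencies from a genotype matrix
#'
#' ALT-allele frequency and minor-allele frequency per variant, estimated
#' from non-missing dosages.
#'
#' @param gm A `genotype_matrix`.
#' @return Tibble with `variant_id`, `alt_af`, `maf`.
#' @export
cohort_maf <- function(gm) {
  af <- colMeans(gm$dosages, na.rm = TRUE) / 2
  tibble(variant_id = gm$variants$variant_id,
         alt_af = unname(af), maf = pmin(af, 1 - af))
}

#' Filter scoring variants before scoring
#'
#' Applies the pre-scoring variant filters, in order: zero-weight removal
#' (null betas carry no information), explicit exclusion list (e.g. a known
#' moderate-penetrance pathogenic variant that would conflate monogenic and
#' polygenic risk), distance from the capture target regions (imputation
#' quality decays away from covered exonic sequence), and cohort minor
#' allele frequency. Every drop is recorded with its reason.
#'
#' @param scoring A `prs_scoring` tibble.
#' @param targets Optional target regions: tibble with `chrom`, `start`,
#'   `end` (1-based closed, as returned by [read_bed()]). `NULL` skips the
#'   distance filter.
#' @param max_distance_bp Maximum distance (bp) from the nearest target
#'   interval; 0 means inside/overlapping. Default 200.
#' @param maf Optional per-variant MAF lookup: tibble with `variant_id` and
#'   `maf` (see [cohort_maf()]). `NULL` skips the MAF filter.
#' @param maf_min Minimum cohort MAF. Default 0.001.
#' @param exclusion_ids Variant ids to drop unconditionally.
#' @return A list: `scoring` (filtered `prs_scoring`), `drops` (tibble
#'   `variant_id`, `reason`), `drop_counts` (tibble `reason`, `n`).
#' @export
filter_scoring_variants <- function(scoring, targets = NULL,
                                    max_distance_bp = 200L,
                                    maf = NULL, maf_min = 0.001,
                                    exclusion_ids = character()) {
  stopifnot(max_distance_bp >= 0)
  reason <- rep(NA_character_, nrow(scoring))
  take <- function(cond, why) {
    hit <- is.na(reason) & cond
    reason[hit] <<- why
  }
  take(scoring$beta == 0, "null-beta")
  take(scoring$variant_id %in% exclusion_ids, "exclusion-list")
  if (!is.null(targets)) {
    dist <- distance_to_targets(scoring, targets)
    take(is.na(dist) | dist > max_distance_bp, "off-target")
  }
  if (!is.null(maf)) {
    m <- maf$maf[match(scoring$variant_id, maf$variant_id)]
    take(!is.na(m) & m < maf_min, "maf-filtered")
  }
  keep <- is.na(reason)
  if (!any(keep)) stopf("no scorable variants remain after filtering")
  drops <- tibble(variant_id = scoring$variant_id[!keep],
                  reason = reason[!keep])
  filtered <- new_prs_scoring(as_tibble(scoring)[keep, ],
                              prs_name = attr(scoring, "prs_name") %||% "prs",
                              provenance = attr(scoring, "provenance") %||% "",
                              n_rejected = attr(scoring, "n_rejected") %||% 0L)
  list(scoring = filtered, drops = drops,
       drop_counts = dplyr::count(drops, .data$reason, name = "n"))
}

# bp distance from each scoring variant to the nearest target interval
# (0 when inside); NA when the chromosome has no targets
distance_to_targets <- function(scoring, targets) {
  v <- GenomicRanges::GRanges(scoring$chrom,
                              IRanges::IRanges(scoring$pos, scoring$pos))
  t <- GenomicRanges::GRanges(targets$chrom,
                              IRanges::IRanges(targets$start, targets$end))
  hits <- GenomicRanges::distanceToNearest(v, t)
  out <- rep(NA_real_, nrow(scoring))
  out[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  out
}

#' Match scoring-file alleles against VCF REF/ALT
#'
#' Resolves, per scoring variant, whether the effect allele is the VCF ALT
#' (dosage used as-is) or the REF (dosage flipped as `2 - d`). A/T and C/G
#' pairs are strand-indistinguishable and excluded by default, the
#' conservative convention for transferred scores; variants absent from the
#' genotype matrix or with incompatible alleles are excluded with reasons
#' `not-found` / `allele-mismatch`. Exclusions are data, not errors.
#'
#' @param scoring A `prs_scoring` tibble.
#' @param gm A `genotype_matrix` (its variant table carries REF/ALT).
#' @param include_ambiguous Keep A/T and C/G variants (default `FALSE`).
#' @return Tibble with the scoring columns plus `genotype_column` (index
#'   into `gm` or `NA`) and `orientation`
#'   (`effect-is-alt`, `effect-is-ref`, or an exclusion reason among
#'   `ambiguous-strand`, `allele-mismatch`, `not-found`).
#' @export
match_alleles <- function(scoring, gm, include_ambiguous = FALSE) {
  gv <- gm$variants
  key <- function(chrom, pos, a, b)
    paste(chrom, pos, pmin(a, b), pmax(a, b), sep = ":")
  col <- match(key(scoring$chrom, scoring$pos, scoring$effect_allele,
                   scoring$other_allele),
               key(gv$chrom, gv$pos, gv$ref, gv$alt))
  # allele pair not present: fall back to any column at the position so the
  # mismatch is reported against the observed REF/ALT
  posfall <- match(paste(scoring$chrom, scoring$pos, sep = ":"),
                   paste(gv$chrom, gv$pos, sep = ":"))
  col[is.na(col)] <- posfall[is.na(col)]

  ambiguous <- (scoring$effect_allele == "A" & scoring$other_allele == "T") |
    (scoring$effect_allele == "T" & scoring$other_allele == "A") |
    (scoring$effect_allele == "C" & scoring$other_allele == "G") |
    (scoring$effect_allele == "G" & scoring$other_allele == "C")

  orientation <- dplyr::case_when(
    is.na(col) ~ "not-found",
    ambiguous & !include_ambiguous ~ "ambiguous-strand",
    scoring$effect_allele == gv$alt[col] & scoring$other_allele == gv$ref[col] ~
      "effect-is-alt",
    scoring$effect_allele == gv$ref[col] & scoring$other_allele == gv$alt[col] ~
      "effect-is-ref",
    TRUE ~ "allele-mismatch")

  mutate(as_tibble(scoring),
         genotype_column = ifelse(orientation %in%
                                    c("effect-is-alt", "effect-is-ref"),
                                  col, NA_integer_),
         orientation = orientation)
}

#' Compute raw, normalized and control-standardized polygenic scores
#'
#' For each sample the raw score is the weighted sum of effect-allele
#' dosages, \eqn{S = \sum_i \beta_i d_i}, with \eqn{d_i = 2 - d^{alt}_i}
#' for variants whose effect allele is the VCF REF. Missing dosages are
#' mean-imputed with twice the cohort effect-allele frequency, which keeps
#' the normalization bounds sample-independent. The raw score is then
#' rescaled by its diploid extrema so it ranges from zero to one:
#' \deqn{S_{norm} = \frac{S - 2\sum_{\beta_i<0}\beta_i}
#'                       {2\sum_{\beta_i>0}\beta_i - 2\sum_{\beta_i<0}\beta_i}}
#' and finally standardized relative to the control distribution,
#' \eqn{z = (S_{norm} - \bar S_{ctrl}) / sd_{ctrl}}.
#'
#' @param matched Output of [match_alleles()]; only rows with a resolved
#'   orientation contribute.
#' @param gm The `genotype_matrix` the matching was done against.
#' @param controls Character vector of control sample ids (non-empty).
#' @param eaf Optional tibble `variant_id`, `eaf` giving the effect-allele
#'   frequency used for missing-dosage imputation; estimated from the
#'   cohort when `NULL`.
#' @return A tibble of class `prs_scores`: `sample_id`, `raw`, `normalized`,
#'   `standardized`, `n_variants_used`.
#' @export
compute_scores <- function(matched, gm, controls, eaf = NULL) {
  use <- matched[matched$orientation %in% c("effect-is-alt", "effect-is-ref"), ]
  if (nrow(use) == 0) stopf("no usable matched variants to score")
  controls <- intersect(as.character(controls), gm$samples)
  if (length(controls) == 0) stopf("no control samples available for standardization")

  d_alt <- gm$dosages[, use$genotype_column, drop = FALSE]
  flip <- use$orientation == "effect-is-ref"
  d_eff <- d_alt
  if (any(flip)) d_eff[, flip] <- 2 - d_eff[, flip]

  if (is.null(eaf)) {
    eaf_vec <- colMeans(d_eff, na.rm = TRUE) / 2
  } else {
    eaf_vec <- eaf$eaf[match(use$variant_id, eaf$variant_id)]
    if (anyNA(eaf_vec)) stopf("eaf table does not cover all scored variants")
  }
  miss <- is.na(d_eff)
  if (any(miss)) {
    fill <- matrix(rep(2 * eaf_vec, each = nrow(d_eff)), nrow = nrow(d_eff))
    d_eff[miss] <- fill[miss]
  }
  d_eff <- pmin(pmax(d_eff, 0), 2)

  beta <- use$beta
  raw <- as.vector(d_eff %*% beta)
  lo <- 2 * sum(beta[beta < 0])
  hi <- 2 * sum(beta[beta > 0])
  if (hi - lo <= 0) stopf("degenerate normalization range (all betas zero?)")
  normalized <- (raw - lo) / (hi - lo)

  is_ctrl <- gm$samples %in% controls
  mu <- mean(normalized[is_ctrl])
  sdev <- stats::sd(normalized[is_ctrl])
  if (!is.finite(sdev) || sdev == 0)
    stopf("control score standard deviation is zero; cannot standardize")

  out <- tibble(sample_id = gm$samples, raw = raw, normalized = normalized,
                standardized = (normalized - mu) / sdev,
                n_variants_used = nrow(use))
  class(out) <- c("prs_scores", class(out))
  out
}
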