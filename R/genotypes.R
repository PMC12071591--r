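#' Construct a genotype/dosage matrix object
#'
#' The package's in-memory genotype container: per-sample ALT-allele dosages
#' in `[0, 2]` (hard genotypes give 0/1/2, imputation gives fractions;
#' `NA` marks a missing genotype) together with the variant table carrying
#' the source REF/ALT needed for effect-allele orientation.
#'
#' @param dosages Numeric matrix, samples x variants; `NA` allowed.
#' @param samples Character vector of sample ids (row order).
#' @param variants Tibble with columns `variant_id`, `chrom`, `pos`, `ref`,
#'   `alt` (column order).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, samples, variants) {
  dosages <- as.matrix(dosages)
  if (length(samples) != nrow(dosages))
    stopf("sample count (%d) != dosage rows (%d)", length(samples), nrow(dosages))
  if (nrow(variants) != ncol(dosages))
    stopf("variant count (%d) != dosage cols (%d)", nrow(variants), ncol(dosages))
  rng <- range(dosages, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    stopf("dosages outside [0,2] (range %.3f..%.3f)", rng[1], rng[2])
  need <- c("variant_id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(variants)))
    stopf("variants table needs columns: %s", paste(need, collapse = ", "))
  dimnames(dosages) <- list(samples, variants$variant_id)
  structure(list(samples = as.character(samples),
                 variants = as_tibble(variants)[need],
                 dosages = dosages),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d sample(s) x %d variant(s); %.2f%% missing\n",
              length(x$samples), nrow(x$variants),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Read sample genotypes/dosages for a scoring file from a VCF
#'
#' Loads one dosage column per scoring variant found in the VCF, keyed by
#' (chrom, pos). Multi-allelic records are split into biallelic alternates;
#' a scoring variant matches the alternate whose unordered allele pair equals
#' its own `{effect, other}` pair when one exists, otherwise the record's
#' first alternate (downstream allele matching will then exclude it as a
#' mismatch rather than silently mis-assign). When `prefer_dosage` and a
#' `DS` FORMAT field is present, the imputed dosage is used; otherwise
#' GT is converted to 0/1/2 and `./.` becomes `NA` (missing-genotype policy
#' is applied at scoring time, not at parse time).
#'
#' @param vcf_path Path to a VCF (4.2+) with GT and optionally DS.
#' @param scoring A `prs_scoring` tibble ([read_scoring_file()]); positions
#'   must be on the same genome build as the VCF.
#' @param prefer_dosage Use DS when available (default `TRUE`).
#' @return A `genotype_matrix` whose columns are the scoring variants found
#'   in the VCF, with attribute `not_found`: a tibble of scoring variants
#'   absent from the VCF.
#' @export
read_genotypes <- function(vcf_path, scoring, prefer_dosage = TRUE) {
  if (!file.exists(vcf_path)) stopf("VCF not found: %s", vcf_path)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  n_samp <- ncol(vcf@gt) - 1L
  if (is.na(n_samp) || n_samp < 1L) stopf("VCF %s carries no sample columns", vcf_path)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  fix$CHROM <- sub("^chr", "", fix$CHROM)
  fix$POS <- as.integer(fix$POS)

  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  has_ds <- any(grepl("(^|:)DS(:|$)", vcf@gt[, "FORMAT"]))
  ds_raw <- if (has_ds) vcfR::extract.gt(vcf, element = "DS") else NULL

  # expand multi-allelic records into one row per alternate
  alt_list <- strsplit(fix$ALT, ",", fixed = TRUE)
  rec_idx <- rep(seq_len(nrow(fix)), lengths(alt_list))
  alt_idx <- unlist(lapply(lengths(alt_list), seq_len))
  exp_var <- tibble(
    rec = rec_idx, alt_no = alt_idx,
    chrom = fix$CHROM[rec_idx], pos = fix$POS[rec_idx],
    ref = toupper(fix$REF[rec_idx]), alt = toupper(unlist(alt_list)))

  key_pair <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "/")
  exp_var$poskey <- paste(exp_var$chrom, exp_var$pos, sep = ":")
  exp_var$fullkey <- paste(exp_var$poskey, key_pair(exp_var$ref, exp_var$alt), sep = ":")
  sc_poskey <- paste(scoring$chrom, scoring$pos, sep = ":")
  sc_fullkey <- paste(sc_poskey, key_pair(scoring$effect_allele, scoring$other_allele),
                      sep = ":")

  hit <- match(sc_fullkey, exp_var$fullkey)          # exact allele-pair match
  pos_only <- match(sc_poskey, exp_var$poskey)       # positional fallback
  hit[is.na(hit)] <- pos_only[is.na(hit)]
  found <- !is.na(hit)
  not_found <- as_tibble(scoring)[!found, ]

  if (!any(found)) stopf("no scoring variant found in VCF %s", vcf_path)
  sel <- exp_var[hit[found], ]
  samples <- colnames(vcf@gt)[-1]

  dos <- vapply(seq_len(nrow(sel)), function(i) {
    rec <- sel$rec[i]; k <- sel$alt_no[i]
    ds_i <- if (!is.null(ds_raw) && prefer_dosage) ds_raw[rec, ] else NULL
    if (!is.null(ds_i) && !all(is.na(ds_i))) {
      parts <- strsplit(as.character(ds_i), ",", fixed = TRUE)
      d <- suppressWarnings(as.numeric(vapply(
        parts, function(p) if (length(p) >= k) p[k] else NA_character_, "")))
    } else {
      g <- gt_raw[rec, ]
      d <- alt_count_from_gt(g, k)
    }
    d
  }, numeric(length(samples)))
  dos <- matrix(dos, nrow = length(samples))
  dos[!is.na(dos)] <- pmin(pmax(dos[!is.na(dos)], 0), 2)

  variants <- tibble(
    variant_id = scoring$variant_id[found],
    chrom = sel$chrom, pos = sel$pos, ref = sel$ref, alt = sel$alt)
  gm <- genotype_matrix(dos, samples, variants)
  attr(gm, "not_found") <- not_found
  gm
}

# count of alternate allele k in GT strings like "0/1", "1|2", "./."
alt_count_from_gt <- function(gt, k) {
  vapply(gt, function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_real_)
    sum(alleles == as.character(k))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Write a genotype matrix as a minimal VCF 4.2
#'
#' Emits biallelic records with GT (hard call by rounding the dosage) and,
#' when `write_ds = TRUE`, DS carrying the exact dosage. Used by the
#' synthetic-cohort generator; integer dosages round-trip exactly through
#' GT, fractional dosages through DS.
#'
#' @param gm A `genotype_matrix`.
#' @param path Output path (plain text).
#' @param write_ds Include a DS FORMAT field (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, write_ds = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=admixprs",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (write_ds)
      '##FORMAT=<ID=DS,Number=A,Type=Float,Description="Estimated ALT dose">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")), con)
  fmt <- if (write_ds) "GT:DS" else "GT"
  gt_str <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(gm$variants))) {
    d <- gm$dosages[, j]
    hard <- pmin(pmax(round(d), 0), 2)
    cell <- ifelse(is.na(d), if (write_ds) "./.:." else "./.",
                   if (write_ds) paste0(gt_str[hard + 1], ":", format(d, trim = TRUE, digits = 8))
                   else gt_str[hard + 1])
    v <- gm$variants[j, ]
    writeLines(paste(c(v$chrom, v$pos, v$variant_id, v$ref, v$alt, ".", "PASS",
                       ".", fmt, cell), collapse = "\t"), con)
  }
  invisible(path)
}
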