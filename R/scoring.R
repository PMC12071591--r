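#' Read a PGS-Catalog-style scoring file
#'
#' Parses a tab-separated scoring file into a tibble of scoring variants.
#' Two column dialects are understood out of the box: `"pgs_catalog"`
#' (harmonized PGS Catalog headers `rsID`, `chr_name`, `chr_position`,
#' `effect_allele`, `other_allele`, `effect_weight`) and `"generic"`
#' (`variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `beta`).
#' A named character vector can be supplied instead to map arbitrary headers
#' onto the canonical names.
#'
#' Rows with non-ACGT alleles, identical effect/other alleles, non-finite
#' betas or non-positive positions are rejected with a warning giving the
#' count; a zero beta is *not* a parse error (null-beta filtering is a
#' downstream scoring decision, see [filter_scoring_variants()]).
#'
#' @param path Path to a TSV file with a header line. Lines starting with
#'   `#` are treated as comments/provenance.
#' @param dialect `"pgs_catalog"`, `"generic"`, or a named character vector
#'   mapping canonical names (`variant_id`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `beta`) to the file's column names.
#' @param prs_name Label for the score; defaults to the file name.
#'
#' @return A tibble of class `prs_scoring` with columns `variant_id`, `chrom`
#'   (character), `pos` (integer, 1-based), `effect_allele`, `other_allele`,
#'   `beta` (double), and attributes `prs_name`, `provenance` and
#'   `n_rejected` (count of rejected rows).
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("rsID\tchr_name\tchr_position\teffect_allele\tother_allele\teffect_weight",
#'              "rs1\t1\t1000\tA\tG\t0.12"), f)
#' read_scoring_file(f)
read_scoring_file <- function(path, dialect = "pgs_catalog", prs_name = NULL) {
  if (!file.exists(path)) stopf("scoring file not found: %s", path)
  map <- scoring_dialect(dialect)
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  missing_cols <- setdiff(unname(map), names(raw))
  if (length(missing_cols) > 0)
    stopf("scoring file %s lacks required column(s): %s",
          path, paste(missing_cols, collapse = ", "))
  out <- tibble(
    variant_id    = raw[[map[["variant_id"]]]],
    chrom         = sub("^chr", "", raw[[map[["chrom"]]]]),
    pos           = suppressWarnings(as.integer(raw[[map[["pos"]]]])),
    effect_allele = toupper(raw[[map[["effect_allele"]]]]),
    other_allele  = toupper(raw[[map[["other_allele"]]]]),
    beta          = suppressWarnings(as.numeric(raw[[map[["beta"]]]]))
  )
  ok <- is_acgt(out$effect_allele) & is_acgt(out$other_allele) &
    out$effect_allele != out$other_allele &
    !is.na(out$pos) & out$pos >= 1L & is.finite(out$beta)
  n_rej <- sum(!ok)
  if (n_rej > 0) {
    bad_rows <- which(!ok)
    warn(sprintf("rejected %d scoring row(s) (rows: %s)", n_rej,
                 paste(utils::head(bad_rows, 10), collapse = ", ")))
    out <- out[ok, ]
  }
  dup <- duplicated(out[c("chrom", "pos", "effect_allele", "other_allele")])
  if (any(dup))
    stopf("scoring file %s has %d duplicate variant key(s)", path, sum(dup))
  new_prs_scoring(out,
                  prs_name   = prs_name %||% sub("\\.[^.]*$", "", basename(path)),
                  provenance = path,
                  n_rejected = n_rej)
}

scoring_dialect <- function(dialect) {
  canonical <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele", "beta")
  if (is.character(dialect) && length(dialect) == 1) {
    map <- switch(dialect,
      pgs_catalog = c(variant_id = "rsID", chrom = "chr_name", pos = "chr_position",
                      effect_allele = "effect_allele", other_allele = "other_allele",
                      beta = "effect_weight"),
      generic = stats::setNames(canonical, canonical),
      stopf("unknown scoring dialect '%s'", dialect))
    return(map)
  }
  if (!all(canonical %in% names(dialect)))
    stopf("custom dialect must name all of: %s", paste(canonical, collapse = ", "))
  dialect[canonical]
}

new_prs_scoring <- function(df, prs_name = "prs", provenance = "", n_rejected = 0L) {
  out <- as_tibble(df)
  attr(out, "prs_name") <- prs_name
  attr(out, "provenance") <- provenance
  attr(out, "n_rejected") <- n_rejected
  class(out) <- c("prs_scoring", class(out))
  out
}

#' Write a scoring tibble back to PGS-Catalog harmonized TSV
#'
#' Inverse of [read_scoring_file()] for conformant files: a write/read
#' round trip preserves every field.
#'
#' @param scoring A `prs_scoring` tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_scoring_file <- function(scoring, path) {
  out <- tibble(
    rsID = scoring$variant_id, chr_name = scoring$chrom,
    chr_position = scoring$pos, effect_allele = scoring$effect_allele,
    other_allele = scoring$other_allele, effect_weight = scoring$beta
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @export
print.prs_scoring <- function(x, ...) {
  cat(sprintf("<prs_scoring> %s: %d variant(s), %d row(s) rejected at parse\n",
              attr(x, "prs_name") %||% "prs", nrow(x), attr(x, "n_rejected") %||% 0L))
  NextMethod()
}
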