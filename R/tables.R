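#' Read sample metadata, kinship and ancestry tables
#'
#' `read_cohort_tables()` loads and joins the three tab-separated side tables
#' of a cohort:
#'
#' * **metadata** — columns `sample_id`, `status` (`case`/`control`), `sex`,
#'   optional `age`, plus one logical/0-1 column per tracked carrier gene
#'   (see [CARRIER_GENES]);
#' * **kinship** — columns `sample_a`, `sample_b` and either `degree`
#'   (integer, 1 = first degree) or `coefficient` (kinship coefficient in
#'   (0, 0.5]); self-pairs are rejected, pairs naming unknown samples are
#'   dropped with a warning;
#' * **ancestry** — columns `sample_id`, `EUR`, `AFR`, `EAS`, `AMR`.
#'   Rows summing to 1 within `[0.98, 1.02]` are renormalized (upstream
#'   ancestry estimates are rounded); rows outside that band are treated as
#'   corrupt and rejected with a warning. Samples missing from the ancestry
#'   table keep `NA` proportions.
#'
#' @param metadata_path,kinship_path,ancestry_path TSV paths; `kinship_path`
#'   and `ancestry_path` may be `NULL`.
#' @return A list with `samples` (tibble: metadata joined with ancestry
#'   proportions) and `kinship` (tibble of pairs).
#' @export
read_cohort_tables <- function(metadata_path, kinship_path = NULL,
                               ancestry_path = NULL) {
  samples <- read_sample_metadata(metadata_path)
  if (!is.null(ancestry_path)) {
    anc <- read_ancestry_props(ancestry_path)
    extra <- setdiff(anc$sample_id, samples$sample_id)
    if (length(extra) > 0)
      warn(sprintf("dropping %d ancestry row(s) for unknown sample(s)", length(extra)))
    samples <- left_join(samples, anc, by = "sample_id")
  } else {
    samples[ANCESTRIES] <- NA_real_
  }
  kinship <- if (is.null(kinship_path)) {
    tibble(sample_a = character(), sample_b = character(), degree = integer())
  } else {
    read_kinship_pairs(kinship_path, known_ids = samples$sample_id)
  }
  list(samples = samples, kinship = kinship)
}

#' @rdname read_cohort_tables
#' @param path A TSV path.
#' @export
read_sample_metadata <- function(path) {
  md <- readr::read_tsv(path, show_col_types = FALSE)
  for (col in c("sample_id", "status"))
    if (!col %in% names(md)) stopf("metadata lacks required column '%s'", col)
  if (anyDuplicated(md$sample_id))
    stopf("duplicate sample_id in metadata: %s",
          paste(unique(md$sample_id[duplicated(md$sample_id)]), collapse = ", "))
  bad <- setdiff(unique(md$status), c("case", "control"))
  if (length(bad) > 0)
    stopf("status must be 'case'/'control'; found: %s", paste(bad, collapse = ", "))
  md$sample_id <- as.character(md$sample_id)
  for (g in intersect(CARRIER_GENES, names(md)))
    md[[g]] <- as.logical(md[[g]])
  as_tibble(md)
}

#' @rdname read_cohort_tables
#' @param known_ids Optional id vector; pairs naming other ids are dropped.
#' @export
read_kinship_pairs <- function(path, known_ids = NULL) {
  kp <- readr::read_tsv(path, show_col_types = FALSE)
  for (col in c("sample_a", "sample_b"))
    if (!col %in% names(kp)) stopf("kinship table lacks column '%s'", col)
  if (!any(c("degree", "coefficient") %in% names(kp)))
    stopf("kinship table needs a 'degree' or 'coefficient' column")
  kp$sample_a <- as.character(kp$sample_a)
  kp$sample_b <- as.character(kp$sample_b)
  self <- kp$sample_a == kp$sample_b
  if (any(self)) {
    warn(sprintf("dropping %d self-pair(s) from kinship table", sum(self)))
    kp <- kp[!self, ]
  }
  if ("coefficient" %in% names(kp)) {
    bad <- !is.na(kp$coefficient) & (kp$coefficient <= 0 | kp$coefficient > 0.5)
    if (any(bad)) stopf("%d kinship coefficient(s) outside (0, 0.5]", sum(bad))
  }
  if (!is.null(known_ids)) {
    unknown <- !(kp$sample_a %in% known_ids & kp$sample_b %in% known_ids)
    if (any(unknown)) {
      warn(sprintf("dropping %d kinship pair(s) naming unknown sample(s)", sum(unknown)))
      kp <- kp[!unknown, ]
    }
  }
  as_tibble(kp)
}

#' @rdname read_cohort_tables
#' @export
read_ancestry_props <- function(path) {
  anc <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("sample_id", ANCESTRIES)
  miss <- setdiff(need, names(anc))
  if (length(miss) > 0)
    stopf("ancestry table lacks column(s): %s", paste(miss, collapse = ", "))
  anc$sample_id <- as.character(anc$sample_id)
  if (anyDuplicated(anc$sample_id)) stopf("duplicate sample_id in ancestry table")
  q <- as.matrix(anc[ANCESTRIES])
  rs <- rowSums(q)
  ok <- rs >= 0.98 & rs <= 1.02
  if (any(!ok))
    warn(sprintf("rejected %d ancestry row(s) with proportions summing outside [0.98, 1.02]",
                 sum(!ok)))
  anc <- anc[ok, ]
  anc[ANCESTRIES] <- q[ok, , drop = FALSE] / rs[ok]
  as_tibble(anc[need])
}

#' Read an exome-target BED file
#'
#' BED is 0-based half-open; intervals are converted to 1-based closed
#' coordinates matching VCF/scoring positions.
#'
#' @param path BED path (first three columns chrom, start, end).
#' @return A tibble with `chrom`, `start`, `end` (1-based closed).
#' @export
read_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         show_col_types = FALSE)
  if (ncol(bed) < 3) stopf("BED file %s needs at least 3 columns", path)
  tibble(chrom = sub("^chr", "", as.character(bed[[1]])),
         start = as.integer(bed[[2]]) + 1L,
         end = as.integer(bed[[3]]))
}
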