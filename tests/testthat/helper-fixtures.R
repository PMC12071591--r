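# in-code fixtures shared across test files

# tiny scoring tibble built directly (no file round trip)
tiny_scoring <- function(beta = c(0.2, -0.1, 0.3)) {
  admixprs:::new_prs_scoring(tibble::tibble(
    variant_id = paste0("rs", seq_along(beta)),
    chrom = as.character(seq_along(beta)),
    pos = 1000L * seq_along(beta),
    effect_allele = rep("G", length(beta)),
    other_allele = rep("A", length(beta)),
    beta = beta), prs_name = "tiny")
}

# genotype matrix aligned to tiny_scoring, effect allele == ALT
tiny_gm <- function(dosages, scoring = tiny_scoring()) {
  genotype_matrix(dosages,
                  samples = sprintf("S%02d", seq_len(nrow(dosages))),
                  variants = tibble::tibble(
                    variant_id = scoring$variant_id, chrom = scoring$chrom,
                    pos = scoring$pos, ref = scoring$other_allele,
                    alt = scoring$effect_allele))
}

# write a scoring TSV in PGS-Catalog harmonized layout
write_scoring_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c("rsID\tchr_name\tchr_position\teffect_allele\tother_allele\teffect_weight",
               rows), path)
  path
}

write_tsv_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# random scoring + genotype pair with mixed effect-allele orientation;
# used by oracle-equivalence and invariance checks
random_instance <- function(n, m, seed) {
  withr::with_seed(seed, {
    eff_is_alt <- runif(m) < 0.5
    pairs <- rbind(c("A", "G"), c("C", "T"), c("G", "A"), c("T", "C"))
    pick <- sample(4, m, replace = TRUE)
    ref <- pairs[pick, 1]; alt <- pairs[pick, 2]
    scoring <- admixprs:::new_prs_scoring(tibble::tibble(
      variant_id = sprintf("v%04d", 1:m),
      chrom = as.character(rep_len(1:22, m)), pos = 100L * (1:m),
      effect_allele = ifelse(eff_is_alt, alt, ref),
      other_allele = ifelse(eff_is_alt, ref, alt),
      beta = rnorm(m, 0, 0.2)))
    gm <- genotype_matrix(
      matrix(sample(0:2, n * m, replace = TRUE), nrow = n),
      samples = sprintf("S%05d", 1:n),
      variants = tibble::tibble(variant_id = scoring$variant_id,
                                chrom = scoring$chrom, pos = scoring$pos,
                                ref = ref, alt = alt))
    list(scoring = scoring, gm = gm, eff_is_alt = eff_is_alt)
  })
}

# per-sample / per-variant explicit-loop scoring oracle: raw sum and the
# zero-to-one rescaling computed scalar by scalar, never vectorized
oracle_scores <- function(scoring, gm, eff_is_alt) {
  n <- length(gm$samples); m <- nrow(scoring)
  raw <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(m)) {
      d <- gm$dosages[i, j]
      if (!eff_is_alt[j]) d <- 2 - d
      s <- s + scoring$beta[j] * d
    }
    raw[i] <- s
  }
  lo <- 0; hi <- 0
  for (j in seq_len(m)) {
    if (scoring$beta[j] < 0) lo <- lo + 2 * scoring$beta[j]
    if (scoring$beta[j] > 0) hi <- hi + 2 * scoring$beta[j]
  }
  list(raw = raw, normalized = (raw - lo) / (hi - lo))
}

# binned tibble built straight from 2x2 counts: one score value per stratum
# placed in the target / reference bin
binned_from_counts <- function(a, b, c, d) {
  df <- tibble::tibble(
    standardized = c(rep(2, a + b), rep(0, c + d)),
    status = c(rep("case", a), rep("control", b),
               rep("case", c), rep("control", d)))
  out <- df
  out$bin <- ifelse(df$standardized == 2, 10L, 5L)
  attr(out, "reference_bins") <- c(5L, 6L)
  attr(out, "kind") <- "decile"
  out
}
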