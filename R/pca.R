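#' Genotype principal components for covariate adjustment
#'
#' Computes the top-K principal components of the cohort genotype matrix,
#' the standard population-structure covariates for association models.
#' Variants are filtered to cohort MAF above `maf_min`, duplicated variant
#' keys and monomorphic columns are dropped, missing dosages are
#' mean-imputed, and each column is centered at `2p` and scaled by
#' `sqrt(2p(1-p))` before a truncated SVD. Each PC's sign is fixed so that
#' its largest-magnitude variant loading is positive, making results
#' deterministic across SVD implementations.
#'
#' @param gm A `genotype_matrix`.
#' @param maf_min Minimum cohort MAF for a variant to enter the PCA
#'   (default 0.01).
#' @param K Number of components (default 10).
#' @return A tibble of class `prs_pcs` with `sample_id` and columns
#'   `PC1..PCK`; attributes `explained_variance` (proportion per PC,
#'   non-increasing) and `zscored` (logical).
#' @export
compute_pcs <- function(gm, maf_min = 0.01, K = 10L) {
  X <- gm$dosages
  if (nrow(X) <= K) stopf("need more samples (%d) than components (%d)", nrow(X), K)
  key <- paste(gm$variants$chrom, gm$variants$pos,
               pmin(gm$variants$ref, gm$variants$alt),
               pmax(gm$variants$ref, gm$variants$alt), sep = ":")
  keep <- !duplicated(key)
  p <- colMeans(X, na.rm = TRUE) / 2
  v <- colMeans(X^2, na.rm = TRUE) - colMeans(X, na.rm = TRUE)^2
  keep <- keep & pmin(p, 1 - p) > maf_min & v > 0
  if (sum(keep) < K)
    stopf("only %d non-degenerate variant(s) pass the PCA filters; need >= %d",
          sum(keep), K)
  X <- X[, keep, drop = FALSE]
  p <- p[keep]
  ctr <- sweep(X, 2, 2 * p)
  ctr[is.na(ctr)] <- 0                       # mean imputation after centering
  Z <- sweep(ctr, 2, sqrt(2 * p * (1 - p)), "/")
  sv <- svd(Z, nu = K, nv = K)
  # deterministic sign: largest-|loading| positive per component
  for (k in seq_len(K)) {
    j <- which.max(abs(sv$v[, k]))
    if (sv$v[j, k] < 0) { sv$v[, k] <- -sv$v[, k]; sv$u[, k] <- -sv$u[, k] }
  }
  pcs <- sweep(sv$u[, seq_len(K), drop = FALSE], 2, sv$d[seq_len(K)], "*")
  colnames(pcs) <- paste0("PC", seq_len(K))
  out <- bind_cols(tibble(sample_id = gm$samples), as_tibble(pcs))
  attr(out, "explained_variance") <- sv$d[seq_len(K)]^2 / sum(sv$d^2)
  attr(out, "zscored") <- FALSE
  class(out) <- c("prs_pcs", class(out))
  out
}

#' Z-score principal components
#'
#' Standardizes each PC column to mean 0, SD 1, as used for covariate
#' adjustment. Idempotent.
#'
#' @param pcs A `prs_pcs` tibble from [compute_pcs()].
#' @return The same tibble with standardized PC columns and
#'   `zscored = TRUE`.
#' @export
zscore_pcs <- function(pcs) {
  cols <- grep("^PC[0-9]+$", names(pcs), value = TRUE)
  for (cl in cols) {
    s <- stats::sd(pcs[[cl]])
    if (!is.finite(s) || s == 0) stopf("PC column %s has zero variance", cl)
    pcs[[cl]] <- (pcs[[cl]] - mean(pcs[[cl]])) / s
  }
  attr(pcs, "zscored") <- TRUE
  pcs
}
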