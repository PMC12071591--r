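#' Concordance between two score sets for the same samples
#'
#' Quantifies how well two scorings of the same cohort (e.g. scores from
#' imputed exomes versus directly sequenced genomes) agree: Spearman rank
#' correlation (average-rank ties) with a two-tailed p-value, a 10x10
#' decile cross-classification matrix in which each set is binned by its
#' *own* decile boundaries, the percentage of set-A top/bottom-decile
#' samples assigned to the same decile in set B (jointly over the union,
#' and separately per extreme), and the percentage of all samples landing
#' in the same or an adjacent decile.
#'
#' @param scores_a,scores_b Data frames with an id column and a score
#'   column (e.g. two [compute_scores()] outputs); joined on `id`, which
#'   must yield identical sample sets.
#' @param score,id Column names (defaults `"normalized"`, `"sample_id"`).
#' @return An object of class `prs_concordance`: `spearman_rho`,
#'   `spearman_p`, `decile_agreement` (10x10 count matrix, rows = set A),
#'   `extreme_overlap_pct`, `top_overlap_pct`, `bottom_overlap_pct`,
#'   `adjacent_pct`, `n`.
#' @export
compare_scores <- function(scores_a, scores_b, score = "normalized",
                           id = "sample_id") {
  a <- tibble(id = as.character(scores_a[[id]]), a = scores_a[[score]])
  b <- tibble(id = as.character(scores_b[[id]]), b = scores_b[[score]])
  if (!setequal(a$id, b$id))
    stopf("the two score sets must cover identical samples")
  m <- left_join(a, b, by = "id")
  if (nrow(m) < 3) stopf("need at least 3 paired samples")

  ct <- suppressWarnings(stats::cor.test(m$a, m$b, method = "spearman",
                                         exact = FALSE))
  dec_a <- own_deciles(m$a)
  dec_b <- own_deciles(m$b)
  agreement <- table(factor(dec_a, levels = 1:10), factor(dec_b, levels = 1:10))
  agreement <- unclass(agreement)
  dimnames(agreement) <- list(set_a = 1:10, set_b = 1:10)

  ext <- dec_a %in% c(1L, 10L)
  same <- dec_a == dec_b
  top <- dec_a == 10L
  bot <- dec_a == 1L
  structure(list(
    spearman_rho = unname(ct$estimate), spearman_p = ct$p.value,
    decile_agreement = agreement,
    extreme_overlap_pct = 100 * sum(same & ext) / sum(ext),
    top_overlap_pct = 100 * sum(same & top) / max(sum(top), 1L),
    bottom_overlap_pct = 100 * sum(same & bot) / max(sum(bot), 1L),
    adjacent_pct = 100 * mean(abs(dec_a - dec_b) <= 1),
    n = nrow(m)), class = "prs_concordance")
}

own_deciles <- function(x) {
  bounds <- stats::quantile(x, seq(0.1, 0.9, 0.1), type = 7)
  as.integer(cut(x, breaks = c(-Inf, bounds, Inf), right = TRUE))
}

#' @export
print.prs_concordance <- function(x, ...) {
  cat(sprintf(paste0(
    "<prs_concordance> n = %d\n",
    "  Spearman rho = %.3f (p = %.3g)\n",
    "  extreme-decile overlap = %.1f%% (top %.1f%%, bottom %.1f%%)\n",
    "  same-or-adjacent decile = %.1f%%\n"),
    x$n, x$spearman_rho, x$spearman_p, x$extreme_overlap_pct,
    x$top_overlap_pct, x$bottom_overlap_pct, x$adjacent_pct))
  invisible(x)
}
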