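#' Prune first-degree relatives from a cohort
#'
#' Implements the relatedness exclusion rule: build a graph whose edges are
#' first-degree relationships; for an isolated pair one member is removed,
#' chosen by a seeded random draw; in any connected component where some
#' individual has two or more first-degree relationships, *all* members of
#' that component are removed.
#'
#' When the kinship table carries a `coefficient` instead of a `degree`,
#' first-degree pairs are taken as kinship coefficient in `[0.177, 0.354]`
#' (the standard KING-style band around 0.25).
#'
#' @param samples Tibble with a `sample_id` column (e.g. from
#'   [read_cohort_tables()]).
#' @param kinship Tibble of pairs with `sample_a`, `sample_b` and `degree`
#'   or `coefficient`.
#' @param seed Integer seed for the random pair-member choice (recorded so
#'   the pruning is reproducible).
#' @return A list: `kept` and `removed` (character id vectors), `n_pairs`
#'   (isolated first-degree pairs), `n_components_removed` (components
#'   removed wholesale).
#' @export
prune_related <- function(samples, kinship, seed = 1L) {
  ids <- samples$sample_id
  fd <- first_degree_pairs(kinship)
  fd <- fd[fd$sample_a %in% ids & fd$sample_b %in% ids, ]
  if (nrow(fd) == 0)
    return(list(kept = ids, removed = character(), n_pairs = 0L,
                n_components_removed = 0L))
  g <- igraph::graph_from_data_frame(fd[c("sample_a", "sample_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  deg <- igraph::degree(g)
  membership <- comp$membership
  removed <- character()
  n_pairs <- 0L; n_comp_rm <- 0L
  withr::with_seed(seed, {
    for (k in seq_len(comp$no)) {
      members <- names(membership)[membership == k]
      if (any(deg[members] >= 2)) {           # >=2 first-degree links somewhere
        removed <- c(removed, members)
        n_comp_rm <- n_comp_rm + 1L
      } else {                                # isolated pair: drop one at random
        removed <- c(removed, sample(members, 1L))
        n_pairs <- n_pairs + 1L
      }
    }
  })
  list(kept = setdiff(ids, removed), removed = removed,
       n_pairs = n_pairs, n_components_removed = n_comp_rm)
}

first_degree_pairs <- function(kinship) {
  if ("degree" %in% names(kinship)) {
    kinship[!is.na(kinship$degree) & kinship$degree == 1L, ]
  } else if ("coefficient" %in% names(kinship)) {
    kinship[!is.na(kinship$coefficient) &
              kinship$coefficient >= 0.177 & kinship$coefficient <= 0.354, ]
  } else {
    stopf("kinship table needs a 'degree' or 'coefficient' column")
  }
}

#' Exclude carriers of pathogenic variants in high-penetrance genes
#'
#' Removes samples flagged as pathogenic/likely-pathogenic carriers in any
#' gene of the high-penetrance set (OR > 5): BRCA1, BRCA2, TP53, PALB2,
#' PTEN by default. Moderate-risk genes (ATM, CHEK2) are deliberately not
#' excluded; their carriers remain for 2x2 contrasts.
#'
#' @param samples Tibble with `sample_id` and one logical column per gene.
#' @param genes Genes whose carriers are excluded.
#' @return A list with `kept` and `removed` id vectors.
#' @export
exclude_carriers <- function(samples, genes = HIGH_PENETRANCE_GENES) {
  present <- intersect(genes, names(samples))
  if (length(present) == 0)
    return(list(kept = samples$sample_id, removed = character()))
  flags <- as.matrix(samples[present])
  flags[is.na(flags)] <- FALSE
  hit <- rowSums(flags) > 0
  list(kept = samples$sample_id[!hit], removed = samples$sample_id[hit])
}

#' Assign continental-ancestry groups
#'
#' Groups samples by admixture proportions: `EAS-majority` when the East
#' Asian proportion exceeds 0.5; otherwise `NonEUR-majority` when the
#' European proportion is at most 0.5 (right-closed at 50%); otherwise
#' `EUR-majority`. Samples without ancestry proportions are left
#' unassigned (`NA`) and counted.
#'
#' @param samples Tibble with `sample_id` and columns `EUR`, `AFR`, `EAS`,
#'   `AMR`.
#' @return The input tibble with an added `ancestry_group` factor column
#'   (levels `EAS-majority`, `NonEUR-majority`, `EUR-majority`); attribute
#'   `n_unassigned` counts samples lacking proportions.
#' @export
assign_ancestry_groups <- function(samples) {
  has <- !is.na(samples$EUR) & !is.na(samples$EAS)
  grp <- rep(NA_character_, nrow(samples))
  grp[has & samples$EAS > 0.5] <- "EAS-majority"
  grp[has & samples$EAS <= 0.5 & samples$EUR <= 0.5] <- "NonEUR-majority"
  grp[has & samples$EAS <= 0.5 & samples$EUR > 0.5] <- "EUR-majority"
  out <- mutate(samples, ancestry_group = factor(
    grp, levels = c("EAS-majority", "NonEUR-majority", "EUR-majority")))
  attr(out, "n_unassigned") <- sum(!has)
  out
}

#' Build the cohort exclusion ledger
#'
#' Cross-checked bookkeeping of every exclusion stage. Removal id sets must
#' be pairwise disjoint and the final count must equal the initial count
#' minus all removals; violations are errors, never silently reconciled.
#' Counts may be supplied instead of id vectors when only published totals
#' are available.
#'
#' @param initial_n Number of samples before any exclusion.
#' @param relatedness,missing_inputs,low_quality,carriers Either an id
#'   character vector or a single count for each removal stage.
#' @param final_cases,final_controls Optional case/control counts after all
#'   exclusions; when given, `analyzed_total` is their sum.
#' @return A tibble of class `prs_ledger` with one row per stage
#'   (`stage`, `n_removed`, `n_remaining`) and attributes `final_n`,
#'   `analyzed_total`, `removed_ids`.
#' @export
build_ledger <- function(initial_n, relatedness = character(),
                         missing_inputs = character(),
                         low_quality = character(), carriers = character(),
                         final_cases = NULL, final_controls = NULL) {
  stages <- list(relatedness = relatedness, missing_inputs = missing_inputs,
                 low_quality = low_quality, carriers = carriers)
  counts <- vapply(stages, function(s) if (is.numeric(s)) as.integer(s) else length(s),
                   integer(1))
  ids <- lapply(stages, function(s) if (is.character(s)) s else character())
  all_ids <- unlist(ids)
  if (anyDuplicated(all_ids))
    stopf("removal id sets overlap: %s",
          paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  remaining <- initial_n - cumsum(counts)
  if (any(remaining < 0)) stopf("removals exceed the initial cohort size")
  out <- tibble(stage = names(stages), n_removed = unname(counts),
                n_remaining = unname(remaining))
  attr(out, "initial_n") <- as.integer(initial_n)
  attr(out, "final_n") <- as.integer(remaining[length(remaining)])
  attr(out, "analyzed_total") <-
    if (!is.null(final_cases) && !is.null(final_controls))
      as.integer(final_cases + final_controls) else NA_integer_
  attr(out, "removed_ids") <- ids
  class(out) <- c("prs_ledger", class(out))
  out
}

#' @export
print.prs_ledger <- function(x, ...) {
  cat(sprintf("<prs_ledger> initial %d -> final %d\n",
              attr(x, "initial_n"), attr(x, "final_n")))
  if (!is.na(attr(x, "analyzed_total")))
    cat(sprintf("  analyzed total (cases + controls): %d\n",
                attr(x, "analyzed_total")))
  NextMethod()
}
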