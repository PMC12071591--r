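#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an association result
#'
#' One row per contrast: `contrast`, `or`, `ci_low`, `ci_high`, `p_value`,
#' `n_case`, `n_control`, `flag`.
#'
#' @param x A `prs_assoc` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method tidy prs_assoc
#' @export
tidy.prs_assoc <- function(x, ...) {
  tibble(contrast = x$contrast, or = x$or, ci_low = x$ci_low,
         ci_high = x$ci_high, p_value = x$p_value,
         n_case = x$n_case, n_control = x$n_control, flag = x$flag)
}

#' Model-level summary of an association result
#'
#' @param x A `prs_assoc` object.
#' @param ... Unused.
#' @return A one-row tibble with `n`, `n_covariates`, `pseudo_r2_nagelkerke`,
#'   `pseudo_r2_mcfadden`.
#' @method glance prs_assoc
#' @export
glance.prs_assoc <- function(x, ...) {
  tibble(n = x$n_case + x$n_control, n_covariates = length(x$covariates),
         pseudo_r2_nagelkerke = unname(x$pseudo_r2["nagelkerke"]),
         pseudo_r2_mcfadden = unname(x$pseudo_r2["mcfadden"]))
}

#' Tidy a concordance report
#'
#' @param x A `prs_concordance` object.
#' @param ... Unused.
#' @return A one-row tibble of the headline agreement metrics.
#' @method tidy prs_concordance
#' @export
tidy.prs_concordance <- function(x, ...) {
  tibble(spearman_rho = x$spearman_rho, spearman_p = x$spearman_p,
         extreme_overlap_pct = x$extreme_overlap_pct,
         top_overlap_pct = x$top_overlap_pct,
         bottom_overlap_pct = x$bottom_overlap_pct,
         adjacent_pct = x$adjacent_pct, n = x$n)
}

#' Tidy an exclusion ledger
#'
#' @param x A `prs_ledger` object.
#' @param ... Unused.
#' @return The per-stage tibble plus an initial row, with running totals.
#' @method tidy prs_ledger
#' @export
tidy.prs_ledger <- function(x, ...) {
  bind_rows(tibble(stage = "initial", n_removed = 0L,
                   n_remaining = attr(x, "initial_n")),
            as_tibble(x))
}
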