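#' @importFrom ggplot2 ggplot aes geom_point geom_errorbar geom_hline
#'   geom_tile geom_col scale_fill_gradient labs theme_minimal autoplot
NULL

#' @export
ggplot2::autoplot

#' Decile/percentile staircase plot
#'
#' Plots per-bin odds ratios with 95% CIs against the reference interval —
#' the characteristic "staircase" of a well-calibrated risk score.
#'
#' @param object A tibble from [bin_or_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_staircase <- function(object, ...) {
  ggplot(object, aes(x = factor(.data$bin), y = .data$or)) +
    geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    geom_errorbar(aes(ymin = .data$ci_low, ymax = .data$ci_high), width = 0.25) +
    geom_point(aes(colour = .data$is_reference), size = 2, show.legend = FALSE) +
    labs(x = "score bin", y = "odds ratio vs reference interval") +
    theme_minimal()
}

#' Decile agreement heatmap for a concordance report
#'
#' @param object A `prs_concordance` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot prs_concordance
#' @export
autoplot.prs_concordance <- function(object, ...) {
  df <- as.data.frame(as.table(object$decile_agreement))
  names(df) <- c("set_a", "set_b", "n")
  ggplot(df, aes(x = .data$set_a, y = .data$set_b, fill = .data$n)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "steelblue") +
    labs(x = "decile (set A)", y = "decile (set B)", fill = "samples") +
    theme_minimal()
}

#' Stacked ancestry-proportion bar plot
#'
#' Per-sample admixture proportions ordered by European fraction, the
#' standard way to display a cohort's ancestry composition.
#'
#' @param samples Tibble with `sample_id` and `EUR`, `AFR`, `EAS`, `AMR`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_ancestry <- function(samples, ...) {
  df <- samples %>%
    filter(!is.na(.data$EUR)) %>%
    arrange(dplyr::desc(.data$EUR)) %>%
    mutate(rank = dplyr::row_number()) %>%
    tidyr::pivot_longer(all_of(ANCESTRIES), names_to = "ancestry",
                        values_to = "proportion")
  ggplot(df, aes(x = .data$rank, y = .data$proportion, fill = .data$ancestry)) +
    geom_col(width = 1) +
    labs(x = "sample (sorted by EUR fraction)", y = "ancestry proportion") +
    theme_minimal()
}
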