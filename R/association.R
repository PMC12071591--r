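#' @keywords internal
as_status01 <- function(status) {
  if (is.numeric(status)) {
    if (!all(status %in% c(0, 1))) stopf("numeric status must be 0/1")
    return(as.integer(status))
  }
  s <- as.character(status)
  bad <- setdiff(unique(s), c("case", "control"))
  if (length(bad) > 0)
    stopf("status must be case/control or 0/1; found: %s", paste(bad, collapse = ", "))
  as.integer(s == "case")
}

new_prs_assoc <- function(contrast, or, ci_low, ci_high, p_value,
                          n_case, n_control, covariates = character(),
                          pseudo_r2 = c(nagelkerke = NA_real_, mcfadden = NA_real_),
                          flag = NA_character_, fit = NULL) {
  structure(list(contrast = contrast, or = or, ci_low = ci_low,
                 ci_high = ci_high, p_value = p_value, n_case = n_case,
                 n_control = n_control, covariates = covariates,
                 pseudo_r2 = pseudo_r2, flag = flag, fit = fit),
            class = "prs_assoc")
}

#' @export
print.prs_assoc <- function(x, ...) {
  cat(sprintf("<prs_assoc> %s: OR %.3f (95%% CI %.3f-%.3f), p = %.3g [%d cases / %d controls]\n",
              x$contrast, x$or, x$ci_low, x$ci_high, x$p_value,
              x$n_case, x$n_control))
  if (!is.na(x$flag)) cat(sprintf("  flag: %s\n", x$flag))
  invisible(x)
}

# logistic fit with Wald inference on `term`; aborts on separation
fit_logit_or <- function(df, term, contrast, covariates = character()) {
  fml <- stats::reformulate(c(term, covariates), response = ".y")
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-12, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  if (sep || !fit$converged || !(term %in% rownames(co)) ||
      abs(co[term, "Estimate"]) > 15)
    stopf("logistic model for '%s' shows separation or failed to converge", contrast)
  est <- co[term, "Estimate"]; se <- co[term, "Std. Error"]
  z <- stats::qnorm(0.975)
  ll <- as.numeric(stats::logLik(fit))
  ll0 <- as.numeric(stats::logLik(
    stats::glm(.y ~ 1, data = df, family = stats::binomial())))
  n <- nrow(df)
  r2_cs <- 1 - exp(-2 * (ll - ll0) / n)
  r2_nag <- r2_cs / (1 - exp(2 * ll0 / n))
  r2_mcf <- 1 - ll / ll0
  new_prs_assoc(contrast, exp(est), exp(est - z * se), exp(est + z * se),
                2 * stats::pnorm(-abs(est / se)),
                n_case = sum(df$.y == 1), n_control = sum(df$.y == 0),
                covariates = covariates,
                pseudo_r2 = c(nagelkerke = r2_nag, mcfadden = r2_mcf),
                fit = fit)
}

#' Odds ratio per standard deviation of the PRS
#'
#' Maximum-likelihood logistic regression of case/control status on the
#' control-standardized score, adjusting for z-scored genotype PCs. The OR
#' is the exponentiated score coefficient with a Wald 95% CI and two-tailed
#' Wald p-value; Nagelkerke and McFadden pseudo-R-squared are reported
#' against the intercept-only model.
#'
#' @param data Data frame with score, status and (optionally) PC columns.
#' @param score Name of the standardized-score column.
#' @param status Name of the status column (`case`/`control` or 0/1).
#' @param pc_cols Names of covariate columns; by default every `PC<k>`
#'   column present in `data`. Use `character()` for an unadjusted fit.
#' @return A `prs_assoc` object; see [tidy.prs_assoc()].
#' @export
or_per_sd <- function(data, score = "standardized", status = "status",
                      pc_cols = grep("^PC[0-9]+$", names(data), value = TRUE)) {
  df <- data.frame(.y = as_status01(data[[status]]),
                   .score = data[[score]], check.names = FALSE)
  if (min(table(df$.y)) < 2) stopf("need at least 2 samples of each status")
  for (cl in pc_cols) df[[cl]] <- data[[cl]]
  fit_logit_or(df, ".score", contrast = "per-SD", covariates = pc_cols)
}

#' Partition samples into score deciles or reporting percentiles
#'
#' Cutpoints are quantiles of the boundary source (`"controls"` by default,
#' matching control-standardization; `"all"` uses the whole cohort).
#' Intervals are left-open, right-closed: a score exactly equal to a
#' cutpoint falls in the lower bin. The decile partition uses quantiles
#' 10-90% and takes the 40-60% interval (bins 5 and 6) as reference; the
#' percentile scheme uses edges 0,1,5,10,20,40,60,80,90,95,99,100 with the
#' single (40,60] bin as reference.
#'
#' @param data Data frame with score (and, for control boundaries, status).
#' @param score,status Column names.
#' @param kind `"decile"` or `"percentile"`.
#' @param boundary_source `"controls"` or `"all"`.
#' @return `data` with an integer `bin` column; attributes `boundaries`
#'   (ascending cutpoints), `reference_bins`, `kind`, `boundary_source`.
#' @export
make_bins <- function(data, score = "standardized", status = "status",
                      kind = c("decile", "percentile"),
                      boundary_source = c("controls", "all")) {
  kind <- match.arg(kind)
  boundary_source <- match.arg(boundary_source)
  x <- data[[score]]
  src <- if (boundary_source == "controls") {
    x[as_status01(data[[status]]) == 0]
  } else x
  if (length(src) < 2) stopf("not enough samples to place bin boundaries")
  probs <- switch(kind,
    decile = seq(0.1, 0.9, by = 0.1),
    percentile = c(1, 5, 10, 20, 40, 60, 80, 90, 95, 99) / 100)
  bounds <- unname(stats::quantile(src, probs, type = 7))
  # strict-greater counting keeps intervals (lo, hi] and tolerates tied
  # boundaries (heavy ties give unequal, possibly empty, bins)
  bin <- 1L + as.integer(rowSums(outer(x, bounds, ">")))
  out <- mutate(as_tibble(data), bin = bin)
  attr(out, "boundaries") <- bounds
  attr(out, "reference_bins") <- if (kind == "decile") c(5L, 6L) else 6L
  attr(out, "kind") <- kind
  attr(out, "boundary_source") <- boundary_source
  out
}

#' Odds ratio of a score bin versus the median interval
#'
#' Subsets the cohort to the target bin plus the reference (40-60%)
#' interval, binarizes membership (target = 1, reference = 0) and fits a
#' PC-adjusted logistic regression of status on membership. Without
#' covariates this is algebraically the 2x2 contingency OR. Comparing the
#' reference interval against itself returns OR 1 exactly (flagged).
#'
#' @param binned Output of [make_bins()].
#' @param bin Target bin index (may be a vector of indices).
#' @param status Status column name.
#' @param pc_cols Covariate columns (default: every `PC<k>` present).
#' @return A `prs_assoc` object.
#' @export
bin_or <- function(binned, bin, status = "status",
                   pc_cols = grep("^PC[0-9]+$", names(binned), value = TRUE)) {
  ref <- attr(binned, "reference_bins")
  if (is.null(ref)) stopf("input lacks bin attributes; call make_bins() first")
  label <- sprintf("bin %s vs reference (%s)",
                   paste(bin, collapse = "+"), paste(ref, collapse = "+"))
  if (setequal(bin, ref)) {
    y <- as_status01(binned[[status]][binned$bin %in% ref])
    return(new_prs_assoc(label, 1, 1, 1, 1, sum(y == 1), sum(y == 0),
                         flag = "self-comparison"))
  }
  keep <- binned$bin %in% c(bin, ref)
  df <- data.frame(.y = as_status01(binned[[status]][keep]),
                   .member = as.integer(binned$bin[keep] %in% bin))
  for (cl in pc_cols) df[[cl]] <- binned[[cl]][keep]
  if (length(unique(df$.member)) < 2)
    stopf("target bin %s is empty (or reference is empty)", paste(bin, collapse = "+"))
  fit_logit_or(df, ".member", contrast = label, covariates = pc_cols)
}

#' Per-bin odds ratios for every non-reference bin
#'
#' Convenience wrapper running [bin_or()] across all bins of a partition,
#' returning the tidy staircase table used for decile plots.
#'
#' @inheritParams bin_or
#' @return A tibble with one row per bin (`bin`, `or`, `ci_low`, `ci_high`,
#'   `p_value`, `n_case`, `n_control`, `is_reference`).
#' @export
bin_or_table <- function(binned, status = "status",
                         pc_cols = grep("^PC[0-9]+$", names(binned), value = TRUE)) {
  ref <- attr(binned, "reference_bins")
  bins <- sort(unique(binned$bin))
  purrr::map_dfr(bins, function(b) {
    res <- if (b %in% ref) {
      y <- as_status01(binned[[status]][binned$bin == b])
      new_prs_assoc("reference", 1, 1, 1, 1, sum(y == 1), sum(y == 0),
                    flag = "self-comparison")
    } else bin_or(binned, b, status = status, pc_cols = pc_cols)
    tibble(bin = b, or = res$or, ci_low = res$ci_low, ci_high = res$ci_high,
           p_value = res$p_value, n_case = res$n_case,
           n_control = res$n_control, is_reference = b %in% ref)
  })
}

#' Closed-form 2x2 odds ratio with Wald confidence interval
#'
#' `OR = (a d) / (b c)` from the exposure-by-status table, with
#' `CI = exp(ln OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))` and a two-tailed
#' Wald p-value. A zero cell triggers the Haldane-Anscombe correction
#' (+0.5 to every cell) and is flagged rather than failing: tiny exposed
#' strata are routine for rare carriers and extreme percentile bins.
#'
#' @param a,b,c,d Exposed cases, exposed controls, unexposed cases,
#'   unexposed controls.
#' @param contrast Label for the result.
#' @return A `prs_assoc` object (flag `"haldane-anscombe"` if corrected).
#' @export
or_from_table <- function(a, b, c, d, contrast = "2x2") {
  flag <- NA_character_
  if (min(a, b, c, d) < 0) stopf("cell counts must be non-negative")
  if (min(a, b, c, d) == 0) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
    flag <- "haldane-anscombe"
  }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(0.975)
  new_prs_assoc(contrast, or, exp(log(or) - z * se), exp(log(or) + z * se),
                2 * stats::pnorm(-abs(log(or) / se)),
                n_case = round(a + c), n_control = round(b + d), flag = flag)
}

#' 2x2 odds ratio for an exposure (e.g. carrier status)
#'
#' Builds the exposure-by-status table from the cohort and calls
#' [or_from_table()]; used for per-gene carrier odds ratios.
#'
#' @param data Data frame with status and the exposure column.
#' @param exposure Name of a logical/0-1 exposure column (e.g. a carrier
#'   gene flag).
#' @param status Status column name.
#' @return A `prs_assoc` object.
#' @export
two_by_two_or <- function(data, exposure, status = "status") {
  y <- as_status01(data[[status]])
  e <- as.logical(data[[exposure]])
  e[is.na(e)] <- FALSE
  or_from_table(a = sum(e & y == 1), b = sum(e & y == 0),
                c = sum(!e & y == 1), d = sum(!e & y == 0),
                contrast = exposure)
}

#' AUC of the score on a stratified holdout split
#'
#' Splits the cohort into train/test preserving the case:control ratio,
#' then computes the ROC AUC of the score on the held-out fraction (the
#' score needs no training, so the split isolates an evaluation set of the
#' size a train/test protocol would use).
#'
#' @param data Data frame with score and status columns.
#' @param score,status Column names.
#' @param test_fraction Held-out fraction (default 0.25).
#' @param seed Integer seed for the stratified split.
#' @return The holdout AUC (double).
#' @export
auc_holdout <- function(data, score = "standardized", status = "status",
                        test_fraction = 0.25, seed = 1L) {
  y <- as_status01(data[[status]])
  x <- data[[score]]
  test <- withr::with_seed(seed, {
    idx <- logical(length(y))
    for (cls in c(0L, 1L)) {
      members <- which(y == cls)
      idx[sample(members, max(1L, round(test_fraction * length(members))))] <- TRUE
    }
    idx
  })
  roc_auc(y[test], x[test])
}

#' AUC by stratified k-fold cross-validation
#'
#' Assigns samples to `folds` folds preserving the case:control ratio and
#' computes the score's AUC within each held-out fold.
#'
#' @inheritParams auc_holdout
#' @param folds Number of folds (default 10).
#' @return A list: `mean_auc` and `folds` (tibble `fold`, `auc`, `n`).
#' @export
auc_cv <- function(data, score = "standardized", status = "status",
                   folds = 10L, seed = 1L) {
  y <- as_status01(data[[status]])
  x <- data[[score]]
  fold_of <- withr::with_seed(seed, {
    f <- integer(length(y))
    for (cls in c(0L, 1L)) {
      members <- sample(which(y == cls))
      f[members] <- rep_len(seq_len(folds), length(members))
    }
    f
  })
  per_fold <- purrr::map_dfr(seq_len(folds), function(k) {
    sel <- fold_of == k
    tibble(fold = k, auc = roc_auc(y[sel], x[sel]), n = sum(sel))
  })
  list(mean_auc = mean(per_fold$auc), folds = per_fold)
}

# rank-based ROC AUC (P(score_case > score_control), ties = 1/2) via pROC
roc_auc <- function(y01, x) {
  if (length(unique(y01)) < 2) stopf("AUC needs both classes present")
  as.numeric(pROC::auc(pROC::roc(response = y01, predictor = x,
                                 levels = c(0, 1), direction = "<",
                                 quiet = TRUE)))
}

#' Bonferroni correction
#'
#' `min(1, m p)` for a family of `m` tests (e.g. the 3 scores x 3 ancestry
#' groups layout gives m = 9).
#'
#' @param p Vector of p-values.
#' @param m Family size; defaults to `length(p)`.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (m < length(p)) stopf("family size m (%d) smaller than number of p-values (%d)",
                           m, length(p))
  stats::p.adjust(p, method = "bonferroni", n = m)
}
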