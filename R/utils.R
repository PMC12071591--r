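#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>% mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows bind_cols distinct rename n across all_of
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

# Valid SNV alleles; scoring rows outside this set are rejected, not coerced.
.ACGT <- c("A", "C", "G", "T")

is_acgt <- function(x) !is.na(x) & x %in% .ACGT

#' @keywords internal
stopf <- function(fmt, ...) abort(sprintf(fmt, ...))

#' Ancestry component labels used throughout the package
#'
#' Continental ancestry components, in the fixed order used by ancestry
#' tables, the simulator and group assignment.
#' @export
ANCESTRIES <- c("EUR", "AFR", "EAS", "AMR")

#' Monogenic breast-cancer genes tracked as carrier flags
#'
#' `HIGH_PENETRANCE_GENES` is the OR > 5 set whose pathogenic/likely-pathogenic
#' carriers are excluded before PRS analysis; `CARRIER_GENES` is the full set
#' of flags carried in sample metadata (moderate-risk genes and the TP53 R337H
#' founder variant are kept for 2x2 contrasts, not excluded).
#' @export
HIGH_PENETRANCE_GENES <- c("BRCA1", "BRCA2", "TP53", "PALB2", "PTEN")

#' @rdname HIGH_PENETRANCE_GENES
#' @export
CARRIER_GENES <- c(HIGH_PENETRANCE_GENES, "ATM", "CHEK2", "TP53_R337H")
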