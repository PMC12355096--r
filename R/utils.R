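#' @keywords internal
#' @import stats
#' @importFrom utils read.delim write.table head packageVersion
#' @importFrom survival coxph Surv coxph.control
#' @importFrom methods new
#' @importFrom tools md5sum
"_PACKAGE"

# The 11-gene CHIP panel used throughout the package.
#' Genes of the CHIP panel
#'
#' The 11 recurrently mutated genes considered when calling clonal
#' hematopoiesis of indeterminate potential (CHIP) from blood-derived
#' sequencing data.
#'
#' @return Character vector of 11 gene symbols.
#' @export
chip_panel_genes <- function() {
  c("ASXL1", "CBL", "DNMT3A", "GNAS", "GNB1", "JAK2",
    "PPM1D", "SF3B1", "SRSF2", "TET2", "TP53")
}

#' Round half away from zero
#'
#' Display rounding for tables: halves round up in magnitude (so 25.75
#' prints as 25.8), unlike [base::round()]'s round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Percentage with table rounding
#'
#' @param num Numerator count(s).
#' @param den Denominator count(s).
#' @param digits Decimal places (default 1, the display convention).
#' @return Numeric percentage, `100 * num / den` rounded half-up.
#' @export
percent_of <- function(num, den, digits = 1) {
  stopifnot(all(den > 0))
  round_half_up(100 * num / den, digits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shared validation helpers ------------------------------------------------

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

assert_proportion <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("'%s' must be a proportion in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

wald_ci <- function(est, se, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  cbind(low = est - z * se, high = est + z * se)
}
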