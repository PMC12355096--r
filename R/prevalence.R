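# Logistic prevalence models: who carries CHIP / mCA, co-occurrence, and
# gene-level enrichment comparisons.

#' Fit a logistic prevalence model
#'
#' Maximum-likelihood logistic regression of a binary carrier outcome on
#' one or more predictors, with Wald confidence intervals on the
#' odds-ratio scale. Analyses of the sex-chromosome mosaic events are
#' sex-restricted: when the outcome or a predictor is `loy` the model is
#' fitted in men only, when `lox` in women only, and `sex` is dropped
#' from the adjustment set (it would be constant). Rows with unknown
#' smoking are dropped when smoking enters the model (complete-case).
#'
#' @param table Analysis table from [build_analysis_table()] (or any data
#'   frame with the needed columns).
#' @param outcome Name of a logical/0-1 column (e.g. `"chip"`,
#'   `"any_mca"`, `"loy"`).
#' @param predictors Character vector of predictor columns.
#' @param adjust Character vector of adjustment covariates
#'   (default `c("age_baseline", "sex")`).
#' @param min_n Minimum complete-case rows (default 50).
#' @return Data frame of class `or_results`, one row per non-reference
#'   model term: `term`, `or`, `ci_low`, `ci_high`, `p`, `n_used`,
#'   `separation` flag; the fitted `glm` is kept in attribute `fit`.
#' @export
fit_prevalence_model <- function(table, outcome, predictors,
                                 adjust = c("age_baseline", "sex"),
                                 min_n = 50) {
  sex_restricted <- intersect(c("loy", "lox"), c(outcome, predictors))
  if (length(sex_restricted)) {
    table <- table[table$sex == if ("loy" %in% sex_restricted) "M" else "F", ,
                   drop = FALSE]
    adjust <- setdiff(adjust, "sex")
  }
  vars <- unique(c(outcome, predictors, setdiff(adjust, predictors)))
  dat <- table[, vars, drop = FALSE]
  if ("smoking" %in% vars) {
    dat <- dat[dat$smoking != "unknown", , drop = FALSE]
    dat$smoking <- factor(dat$smoking,
                          levels = c("current", "never", "previous"))
  }
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < min_n) {
    stop(sprintf("only %d complete-case rows (< %d)", nrow(dat), min_n),
         call. = FALSE)
  }
  dat[[outcome]] <- as.integer(dat[[outcome]])
  if (length(unique(dat[[outcome]])) < 2) {
    stop("outcome has an empty cell: all rows share one outcome value",
         call. = FALSE)
  }
  rhs <- unique(c(predictors, setdiff(adjust, outcome)))
  form <- stats::reformulate(rhs, response = outcome)
  fit <- stats::glm(form, data = dat, family = stats::binomial())
  co <- summary(fit)$coefficients
  co <- co[rownames(co) != "(Intercept)", , drop = FALSE]
  separation <- !fit$converged | any(abs(co[, 1]) > 15)
  ci <- wald_ci(co[, 1], co[, 2])
  out <- data.frame(term = rownames(co),
                    or = exp(co[, 1]),
                    ci_low = exp(ci[, "low"]),
                    ci_high = exp(ci[, "high"]),
                    p = co[, 4],
                    n_used = nrow(dat),
                    separation = separation,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("or_results", "data.frame")
  attr(out, "fit") <- fit
  out
}

#' Compare the proportion of carriers mutated in a gene between strata
#'
#' Among CHIP carriers, compares the proportion whose surviving call set
#' includes `gene` between the two levels of a binary stratifier (for
#' example chemotherapy-exposed versus not). Uses a Pearson chi-squared
#' test with continuity correction, falling back to Fisher's exact test
#' when any expected cell count is below 5 or a stratum has no carriers.
#'
#' @param calls Surviving variant calls (`call_chip()` `$calls`).
#' @param stratifier Named logical/0-1 vector: names are participant ids
#'   of CHIP carriers, values the stratum.
#' @param gene Gene symbol to compare.
#' @return List: `prop1` (stratum TRUE), `prop0`, `p`, `method`, `table`.
#' @export
compare_gene_proportions <- function(calls, stratifier, gene) {
  stopifnot(gene %in% chip_panel_genes(), !is.null(names(stratifier)))
  carriers <- names(stratifier)
  has_gene <- vapply(carriers, function(id)
    any(calls$participant_id == id & calls$gene == gene), logical(1))
  strat <- as.logical(stratifier)
  tab <- table(factor(strat, levels = c(FALSE, TRUE)),
               factor(has_gene, levels = c(FALSE, TRUE)))
  use_fisher <- any(rowSums(tab) == 0) ||
    any(suppressWarnings(stats::chisq.test(tab, correct = TRUE))$expected < 5)
  if (any(rowSums(tab) == 0)) {
    p <- stats::fisher.test(tab)$p.value
    method <- "fisher"
  } else if (use_fisher) {
    p <- stats::fisher.test(tab)$p.value
    method <- "fisher"
  } else {
    p <- stats::chisq.test(tab, correct = TRUE)$p.value
    method <- "chisq"
  }
  n1 <- sum(strat); n0 <- sum(!strat)
  list(prop1 = if (n1) mean(has_gene[strat]) else NA_real_,
       prop0 = if (n0) mean(has_gene[!strat]) else NA_real_,
       p = p, method = method, table = tab)
}
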