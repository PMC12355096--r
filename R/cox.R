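# Cox proportional-hazards fitting for the study endpoints. The fit
# itself is a standard partial-likelihood fit (survival::coxph, Breslow
# tie handling); this wrapper standardises exposure coding, covariate
# handling, and the result container consumed by the interaction metrics.

#' Default adjustment covariates for the survival models
#'
#' Age at baseline, sex, smoking status, chemotherapy, radiotherapy,
#' prevalent cardiovascular disease, the recruitment-to-diagnosis delay
#' (days), and the first ten genetic principal components.
#'
#' @return Character vector of column names.
#' @export
default_covariates <- function() {
  c("age_baseline", "sex", "smoking", "chemo", "radio", "prevalent_cvd",
    "delay_days", paste0("pc", 1:10))
}

#' Fit a Cox proportional-hazards model for one endpoint
#'
#' Builds `Surv(time_<endpoint>, event_<endpoint>) ~ exposure + covariates`
#' and fits it by partial likelihood with Breslow tie handling. Exposure
#' specifications:
#' \describe{
#'   \item{`"chip"`}{binary CHIP carriage (any versus none);}
#'   \item{`"ch4"`}{four-category CH exposure `exposure4`
#'     (`no_ch` reference, `chip_only`, `mca_only`, `both`);}
#'   \item{`"chip_x_mca"`}{product-term parameterisation
#'     `chip + any_mca + chip:any_mca` of the same model;}
#'   \item{`"mutation_count"`}{dose-response classes 1 / 2 / 3+ CHIP
#'     mutations versus 0;}
#'   \item{`"chip_expanded"`}{binary expanded-clone CHIP (VAF >= 10%);}
#'   \item{any other string}{used verbatim as model terms.}
#' }
#' Rows with unknown smoking are dropped when smoking is among the
#' covariates (complete-case).
#'
#' @param table Analysis table from [build_analysis_table()].
#' @param endpoint One of [endpoint_names()].
#' @param exposure Exposure specification (see Details).
#' @param covariates Adjustment covariates (default
#'   [default_covariates()]); covariates absent from `table` are an
#'   error.
#' @param subset_sex Optional `"F"`/`"M"` restriction.
#' @param min_events Minimum required events (default 10).
#' @return Object of class `chcv_cox`: list with `terms`, `beta`, `se`,
#'   `vcov`, `hr` (data frame with Wald CIs and p-values), `n`,
#'   `n_events`, `endpoint`, the fitted `coxph` object (`fit`), and the
#'   model `data` (for bootstrap resampling).
#' @export
fit_cox <- function(table, endpoint, exposure = "ch4",
                    covariates = default_covariates(),
                    subset_sex = NULL, min_events = 10) {
  stopifnot(endpoint %in% endpoint_names())
  if (!is.null(subset_sex)) {
    table <- table[table$sex == subset_sex, , drop = FALSE]
    covariates <- setdiff(covariates, "sex")
  }
  terms <- switch(exposure,
    chip = "chip",
    ch4 = "exposure4",
    chip_x_mca = c("chip", "any_mca", "chip:any_mca"),
    mutation_count = "mutation_count_class",
    chip_expanded = "chip_expanded",
    exposure)
  tvar <- paste0("time_", endpoint)
  evar <- paste0("event_", endpoint)
  assert_columns(table, c(tvar, evar), "analysis table")
  base_vars <- unique(c(all.vars(stats::reformulate(c(terms, covariates)))))
  miss <- setdiff(base_vars, names(table))
  if (length(miss)) {
    stop("analysis table lacks model column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  dat <- table[, c(tvar, evar, base_vars), drop = FALSE]
  if ("smoking" %in% base_vars) {
    dat <- dat[dat$smoking != "unknown", , drop = FALSE]
    dat$smoking <- factor(dat$smoking,
                          levels = c("current", "never", "previous"))
  }
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  dat$.time <- dat[[tvar]]
  dat$.event <- as.integer(dat[[evar]])
  if (sum(dat$.event) < min_events) {
    stop(sprintf("only %d events for endpoint '%s' (< %d required)",
                 sum(dat$.event), endpoint, min_events), call. = FALSE)
  }
  empty_check_exposure(dat, terms)
  form <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                  paste(c(terms, covariates), collapse = " + ")))
  fit <- survival::coxph(form, data = dat, ties = "breslow",
                         control = survival::coxph.control(
                           eps = 1e-11, toler.chol = 1e-13, iter.max = 50))
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  ci <- wald_ci(beta, se)
  hr <- data.frame(term = names(beta), hr = exp(beta),
                   ci_low = exp(ci[, "low"]), ci_high = exp(ci[, "high"]),
                   p = 2 * stats::pnorm(-abs(beta / se)),
                   row.names = NULL, stringsAsFactors = FALSE)
  structure(list(terms = names(beta), beta = beta, se = se,
                 vcov = stats::vcov(fit), hr = hr,
                 n = nrow(dat), n_events = sum(dat$.event),
                 endpoint = endpoint, exposure = exposure,
                 formula = form, fit = fit, data = dat),
            class = "chcv_cox")
}

# A factor exposure category with zero events produces a monotone
# partial likelihood; name the category instead of letting coxph drift.
empty_check_exposure <- function(dat, terms) {
  for (tm in setdiff(terms, grep(":", terms, value = TRUE))) {
    x <- dat[[tm]]
    if (is.factor(x) || is.logical(x)) {
      ev <- tapply(dat$.event, x, sum)
      bad <- names(ev)[is.na(ev) | ev == 0]
      if (length(bad)) {
        stop(sprintf("no events in exposure category '%s' of '%s'",
                     paste(bad, collapse = ","), tm), call. = FALSE)
      }
    }
  }
  invisible(NULL)
}

#' @export
print.chcv_cox <- function(x, digits = 3, ...) {
  cat(sprintf("Cox model [%s], n = %d, events = %d\n",
              x$endpoint, x$n, x$n_events))
  hr <- x$hr
  hr[, c("hr", "ci_low", "ci_high")] <-
    lapply(hr[, c("hr", "ci_low", "ci_high")], round_half_up, digits)
  print(hr, row.names = FALSE)
  invisible(x)
}
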