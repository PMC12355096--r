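# Additive and multiplicative interaction between CHIP and mCA on the
# hazard-ratio scale. Conventions, with hazard ratios relative to the
# no-CH reference: h11 = both exposures, h10 = CHIP only, h01 = mCA only.
#
#   RERI          = h11 - h10 - h01 + 1      (excess risk beyond additivity)
#   AP            = RERI / h11               (share of joint risk from interaction)
#   mult. ratio   = h11 / (h10 * h01)        (the quantity reported as "SI"
#                                             in CH-cardiovascular tables;
#                                             equals exp of the product-term
#                                             Cox interaction coefficient)
#   classical SI  = (h11 - 1) / ((h10 - 1) + (h01 - 1))
#                                             (Rothman's synergy index,
#                                             provided separately because the
#                                             label "SI" conventionally means
#                                             this quantity)

check_hrs <- function(...) {
  h <- c(...)
  if (any(!is.finite(h)) || any(h <= 0)) {
    stop("hazard ratios must be finite and > 0", call. = FALSE)
  }
  invisible(h)
}

#' Relative excess risk due to interaction
#'
#' @param h11 Adjusted hazard ratio for carrying both exposures versus
#'   neither.
#' @param h10 Hazard ratio for the first exposure only.
#' @param h01 Hazard ratio for the second exposure only.
#' @return `h11 - h10 - h01 + 1`.
#' @export
compute_reri <- function(h11, h10, h01) {
  check_hrs(h11, h10, h01)
  h11 - h10 - h01 + 1
}

#' Attributable proportion of joint-exposure risk due to interaction
#'
#' @param reri Relative excess risk due to interaction
#'   ([compute_reri()]).
#' @param h11 Hazard ratio for both exposures versus neither.
#' @return `reri / h11`.
#' @export
compute_ap <- function(reri, h11) {
  check_hrs(h11)
  stopifnot(is.finite(reri))
  reri / h11
}

#' Multiplicative interaction ratio
#'
#' The departure of the joint hazard ratio from the product of the
#' individual hazard ratios, `h11 / (h10 * h01)`. It is identical to the
#' exponentiated interaction coefficient of the product-term Cox
#' parameterisation, and is the quantity labelled "SI" in some clonal
#' hematopoiesis reports (distinct from the classical synergy index,
#' [compute_classical_si()]).
#'
#' @inheritParams compute_reri
#' @return `h11 / (h10 * h01)`.
#' @export
compute_mult_ratio <- function(h11, h10, h01) {
  check_hrs(h11, h10, h01)
  h11 / (h10 * h01)
}

#' Classical (Rothman) synergy index
#'
#' Ratio of the joint excess risk to the sum of the individual excess
#' risks, `(h11 - 1) / ((h10 - 1) + (h01 - 1))`. Undefined (returned as
#' `NA` with a warning) when the denominator is zero.
#'
#' @inheritParams compute_reri
#' @return The synergy index, or `NA` when undefined.
#' @export
compute_classical_si <- function(h11, h10, h01) {
  check_hrs(h11, h10, h01)
  den <- (h10 - 1) + (h01 - 1)
  if (den == 0) {
    warning("classical synergy index undefined: zero excess-risk denominator")
    return(NA_real_)
  }
  (h11 - 1) / den
}

# Locate the three exposure coefficients in a four-category CH fit.
ch4_beta_index <- function(cox) {
  need <- c(both = "exposure4both", chip_only = "exposure4chip_only",
            mca_only = "exposure4mca_only")
  idx <- match(need, cox$terms)
  if (anyNA(idx)) {
    stop("Cox fit does not carry the four-category CH exposure terms",
         call. = FALSE)
  }
  stats::setNames(idx, names(need))
}

metric_value <- function(b11, b10, b01, metric) {
  h11 <- exp(b11); h10 <- exp(b10); h01 <- exp(b01)
  switch(metric,
    reri = compute_reri(h11, h10, h01),
    ap = compute_ap(compute_reri(h11, h10, h01), h11),
    mult_ratio = compute_mult_ratio(h11, h10, h01),
    classical_si = suppressWarnings(compute_classical_si(h11, h10, h01)),
    stop("unknown metric: ", metric, call. = FALSE))
}

#' Confidence interval for an interaction metric
#'
#' Propagates the Cox coefficient covariance through the metric. The
#' delta method uses the analytic gradient of the metric with respect to
#' the three exposure log-hazard-ratios (natural scale for RERI, AP and
#' the classical synergy index; log scale for the multiplicative ratio,
#' whose log is linear in the coefficients). The bootstrap resamples
#' participants with replacement, refits the Cox model and takes
#' percentile limits.
#'
#' @param cox A `chcv_cox` fit with the four-category CH exposure.
#' @param metric One of `"reri"`, `"ap"`, `"mult_ratio"`,
#'   `"classical_si"`.
#' @param method `"delta"` (default) or `"bootstrap"`.
#' @param level Confidence level (default 0.95).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Seed for bootstrap resampling.
#' @return List: `estimate`, `low`, `high`, `method`.
#' @export
interaction_ci <- function(cox, metric = c("reri", "ap", "mult_ratio",
                                           "classical_si"),
                           method = c("delta", "bootstrap"),
                           level = 0.95, n_boot = 1000, seed = 1L) {
  metric <- match.arg(metric)
  method <- match.arg(method)
  stopifnot(inherits(cox, "chcv_cox"))
  idx <- ch4_beta_index(cox)
  b <- stats::setNames(cox$beta[idx], names(idx))
  est <- metric_value(b["both"], b["chip_only"], b["mca_only"], metric)
  V <- cox$vcov[idx, idx]
  if (method == "delta" && (kappa(V) > 1e12 || any(!is.finite(V)))) {
    warning("singular coefficient covariance; falling back to bootstrap")
    method <- "bootstrap"
  }
  if (method == "delta") {
    h11 <- exp(b["both"]); h10 <- exp(b["chip_only"]); h01 <- exp(b["mca_only"])
    z <- stats::qnorm(1 - (1 - level) / 2)
    if (metric == "mult_ratio") {
      g <- c(1, -1, -1)
      se <- sqrt(drop(t(g) %*% V %*% g))
      lm <- log(h11 / (h10 * h01))
      ci <- c(exp(lm - z * se), exp(lm + z * se))
    } else {
      grad <- switch(metric,
        reri = c(h11, -h10, -h01),
        ap = c((h10 + h01 - 1) / h11, -h10 / h11, -h01 / h11),
        classical_si = {
          D <- (h10 - 1) + (h01 - 1)
          c(h11 / D, -h10 * (h11 - 1) / D^2, -h01 * (h11 - 1) / D^2)
        })
      se <- sqrt(drop(t(grad) %*% V %*% grad))
      ci <- c(est - z * se, est + z * se)
    }
  } else {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    vals <- vapply(seq_len(n_boot), function(r) {
      rows <- sample.int(nrow(cox$data), replace = TRUE)
      refit <- tryCatch(
        survival::coxph(cox$formula, data = cox$data[rows, , drop = FALSE],
                        ties = "breslow"),
        error = function(e) NULL)
      if (is.null(refit)) return(NA_real_)
      bb <- stats::coef(refit)[cox$terms[idx]]
      metric_value(bb[1], bb[2], bb[3], metric)
    }, numeric(1))
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    ci <- stats::quantile(vals, c((1 - level) / 2, 1 - (1 - level) / 2),
                          na.rm = TRUE, names = FALSE)
  }
  list(estimate = unname(est), low = unname(ci[1]), high = unname(ci[2]),
       method = method)
}

ch_pair_columns <- function(pair) {
  switch(pair,
    chip_mca = list(chip = "chip", mca = "any_mca", sex = NULL),
    chip_loy = list(chip = "chip", mca = "loy", sex = "M"),
    chip_lox = list(chip = "chip", mca = "lox", sex = "F"),
    expanded_chip_mca = list(chip = "chip_expanded", mca = "any_mca",
                             sex = NULL),
    chip_expanded_mca = list(chip = "chip", mca = "mca_expanded", sex = NULL),
    stop("unknown CH pair: ", pair, call. = FALSE))
}

#' Run the CHIP-by-mCA interaction analysis
#'
#' For each endpoint: fits the four-category CH exposure Cox model and
#' the product-term parameterisation, and computes RERI, AP, the
#' multiplicative interaction ratio and the classical synergy index with
#' confidence intervals. Sex-chromosome pairs restrict the cohort (LOY:
#' men, LOX: women) and drop sex from the covariates. When a fit fails —
#' typically because an exposure cell has no events — the endpoint's
#' metrics are marked not reportable rather than raising an error.
#'
#' @param table Analysis table from [build_analysis_table()].
#' @param endpoints Endpoints to analyse (default all five).
#' @param pair One of `"chip_mca"`, `"chip_loy"`, `"chip_lox"`,
#'   `"expanded_chip_mca"`, `"chip_expanded_mca"`.
#' @param covariates Adjustment covariates.
#' @param ci_method `"delta"` or `"bootstrap"`.
#' @param level Confidence level.
#' @param n_boot,seed Bootstrap controls.
#' @return Object of class `chcv_interaction_report`: a list with one
#'   entry per endpoint holding `cox` (four-category fit or `NULL`),
#'   `hr` (category hazard-ratio table), `metrics` (data frame with
#'   estimate, CI, method, `reportable`), and `note` for non-reportable
#'   endpoints.
#' @export
run_interaction_analysis <- function(table, endpoints = endpoint_names(),
                                     pair = "chip_mca",
                                     covariates = default_covariates(),
                                     ci_method = "delta", level = 0.95,
                                     n_boot = 1000, seed = 1L) {
  spec <- ch_pair_columns(pair)
  if (!is.null(spec$sex)) {
    table <- table[table$sex == spec$sex, , drop = FALSE]
    covariates <- setdiff(covariates, "sex")
  }
  table$exposure4 <- ch4_factor(as.logical(table[[spec$chip]]),
                                as.logical(table[[spec$mca]]))
  metrics_names <- c("reri", "ap", "mult_ratio", "classical_si")
  report <- lapply(endpoints, function(ep) {
    fit <- tryCatch(fit_cox(table, ep, exposure = "ch4",
                            covariates = covariates),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      return(list(endpoint = ep, cox = NULL, hr = NULL,
                  metrics = data.frame(metric = metrics_names,
                                       estimate = NA_real_, low = NA_real_,
                                       high = NA_real_, method = ci_method,
                                       reportable = FALSE),
                  note = conditionMessage(fit)))
    }
    mets <- do.call(rbind, lapply(metrics_names, function(m) {
      ci <- interaction_ci(fit, m, method = ci_method, level = level,
                           n_boot = n_boot, seed = seed)
      data.frame(metric = m, estimate = ci$estimate, low = ci$low,
                 high = ci$high, method = ci$method,
                 reportable = is.finite(ci$estimate))
    }))
    list(endpoint = ep, cox = fit,
         hr = fit$hr[grep("^exposure4", fit$hr$term), , drop = FALSE],
         metrics = mets, note = NA_character_)
  })
  names(report) <- endpoints
  structure(list(pair = pair, endpoints = report, level = level),
            class = "chcv_interaction_report")
}

#' @export
print.chcv_interaction_report <- function(x, digits = 3, ...) {
  cat("CH interaction analysis [", x$pair, "]\n", sep = "")
  for (ep in x$endpoints) {
    cat("\n== ", ep$endpoint, " ==\n", sep = "")
    if (is.null(ep$cox)) {
      cat("  not reportable: ", ep$note, "\n", sep = "")
      next
    }
    hr <- ep$hr
    hr[, -1] <- lapply(hr[, -1], round_half_up, digits)
    print(hr, row.names = FALSE)
    m <- ep$metrics
    for (i in seq_len(nrow(m))) {
      if (!m$reportable[i]) {
        cat(sprintf("  %-12s nr\n", m$metric[i]))
      } else {
        cat(sprintf("  %-12s %+.3f (%.3f to %.3f) [%s]\n", m$metric[i],
                    m$estimate[i], m$low[i], m$high[i], m$method[i]))
      }
    }
  }
  invisible(x)
}
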