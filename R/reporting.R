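# Summary tables, the published interaction reference values, and
# end-to-end pipeline orchestration.

#' Descriptive characteristics by CHIP status
#'
#' Counts and percentages for each cohort characteristic, overall and
#' stratified by CHIP carriage, plus age summaries (mean/SD, median/IQR,
#' range). Percentages use the display convention of cohort tables:
#' 100 * numerator / denominator rounded half-up to one decimal.
#'
#' @param table Analysis table from [build_analysis_table()].
#' @return Data frame of class `chcv_descriptives` with numeric columns
#'   `overall_n`, `overall_pct`, `no_chip_n`, `no_chip_pct`, `chip_n`,
#'   `chip_pct`, one row per characteristic. The formatted age summaries
#'   (mean/SD, median/IQR, range, per stratum) are in the `age_stats`
#'   attribute.
#' @export
summarize_descriptives <- function(table) {
  if (nrow(table) == 0) stop("empty analysis table", call. = FALSE)
  groups <- list(overall = rep(TRUE, nrow(table)),
                 no_chip = !table$chip,
                 chip = table$chip)
  dens <- vapply(groups, sum, numeric(1))

  count_row <- function(label, flag) {
    cells <- lapply(names(groups), function(g) {
      num <- sum(flag & groups[[g]])
      c(n = num, pct = unname(percent_of(num, dens[g])))
    })
    data.frame(label = label,
               overall_n = cells[[1]][["n"]],
               overall_pct = cells[[1]][["pct"]],
               no_chip_n = cells[[2]][["n"]],
               no_chip_pct = cells[[2]][["pct"]],
               chip_n = cells[[3]][["n"]], chip_pct = cells[[3]][["pct"]],
               row.names = NULL)
  }
  age_stats <- do.call(rbind, lapply(names(groups), function(g) {
    x <- table$age_baseline[groups[[g]]]
    data.frame(stratum = g,
               mean_sd = sprintf("%.1f (%.1f)", mean(x), stats::sd(x)),
               median_iqr = sprintf("%.0f (%.0f-%.0f)", stats::median(x),
                                    stats::quantile(x, 0.25),
                                    stats::quantile(x, 0.75)),
               range = sprintf("%.0f-%.0f", min(x), max(x)),
               row.names = NULL)
  }))

  rows <- list(
    count_row("sex_female", table$sex == "F"),
    count_row("sex_male", table$sex == "M"),
    count_row("smoking_current", table$smoking == "current"),
    count_row("smoking_never", table$smoking == "never"),
    count_row("smoking_previous", table$smoking == "previous"),
    count_row("smoking_unknown", table$smoking == "unknown"),
    count_row("prevalent_cvd", table$prevalent_cvd == 1),
    count_row("chemotherapy", table$chemo == 1),
    count_row("radiotherapy", table$radio == 1),
    count_row("any_mca", table$any_mca),
    count_row("loy", table$loy),
    count_row("lox", table$lox),
    count_row("expanded_mca", table$mca_expanded),
    count_row("expanded_chip", table$chip_expanded),
    count_row("chip", table$chip))
  out <- do.call(rbind, rows)
  attr(out, "age_stats") <- age_stats
  class(out) <- c("chcv_descriptives", "data.frame")
  out
}

#' Published interaction reference values
#'
#' The adjusted hazard ratios (both / CHIP only / mCA only, each versus
#' no clonal hematopoiesis) and the printed RERI / AP / SI values for
#' the five endpoints of the published CHIP-by-mCA, CHIP-by-LOY (men)
#' and CHIP-by-LOX (women) analyses, shipped as package data. Cells the
#' source marked not reportable (too few events) are `NA`.
#'
#' @return Data frame with columns `analysis`, `endpoint`, `hr_both`,
#'   `hr_chip_only`, `hr_mca_only`, `reri`, `ap`, `si`.
#' @export
published_interaction_hr <- function() {
  utils::read.delim(system.file("extdata", "published_interaction_hr.tsv",
                                package = "chcv", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' Recompute interaction metrics from published hazard ratios
#'
#' Applies [compute_reri()], [compute_ap()] and [compute_mult_ratio()]
#' to the published per-category hazard ratios and returns them next to
#' the printed values. Rows with a non-positive joint hazard ratio are
#' skipped (the metrics are undefined there, as the source also marks).
#'
#' @param published Reference table (default
#'   [published_interaction_hr()]).
#' @return The table with added columns `reri_computed`, `ap_computed`,
#'   `si_computed`.
#' @export
recompute_published_metrics <- function(published = published_interaction_hr()) {
  published$reri_computed <- NA_real_
  published$ap_computed <- NA_real_
  published$si_computed <- NA_real_
  ok <- published$hr_both > 0 & published$hr_chip_only > 0 &
    published$hr_mca_only > 0
  for (i in which(ok)) {
    r <- compute_reri(published$hr_both[i], published$hr_chip_only[i],
                      published$hr_mca_only[i])
    published$reri_computed[i] <- r
    published$ap_computed[i] <- compute_ap(r, published$hr_both[i])
    published$si_computed[i] <- compute_mult_ratio(
      published$hr_both[i], published$hr_chip_only[i],
      published$hr_mca_only[i])
  }
  published
}

pipeline_log <- function(con, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, msg)
  writeLines(line, con)
  message(line)
}

#' Run the full pipeline on a simulated cohort
#'
#' Executes simulate -> write bundle -> read back -> call CHIP ->
#' classify mCA -> build cohort (with exclusions) -> prevalence models
#' -> survival interaction analysis, writing every intermediate table,
#' a per-stage log with in/out counts, and a manifest with the seed and
#' MD5 hash of every output file. Any stage failure aborts with the
#' stage name in the error.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory.
#' @param seed Optional override of `config$seed`.
#' @return Invisibly, a list with the analysis table, the prevalence and
#'   interaction results, and the manifest path.
#' @export
run_pipeline <- function(config = simulation_config(), out_dir,
                         seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  con <- file(log_path, open = "wt")
  on.exit(close(con), add = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      pipeline_log(con, name, paste("FAILED:", conditionMessage(e)))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  bundle <- stage("simulate", {
    b <- generate_cohort(config)
    pipeline_log(con, "simulate",
                 sprintf("n=%d participants, %d evidence records, seed=%d",
                         nrow(b$participants), nrow(b$variant_evidence),
                         config$seed))
    b
  })
  stage("write_bundle", {
    write_bundle(bundle, out_dir)
    pipeline_log(con, "write_bundle", paste("written to", out_dir))
  })
  inputs <- stage("read_bundle", read_bundle(out_dir))

  chip <- stage("call_chip", {
    cc <- call_chip(inputs$variant_evidence, load_whitelist(),
                    inputs$participants)
    pipeline_log(con, "call_chip",
                 sprintf("%d candidates in -> %d calls kept (%d removed), %d carriers",
                         nrow(cc$audit), nrow(cc$calls),
                         sum(!cc$audit$kept), sum(cc$status$carrier)))
    utils::write.table(cc$status, file.path(out_dir, "chip_status.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cc$audit, file.path(out_dir, "chip_audit.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cc
  })
  mca <- stage("classify_mca", {
    ms <- mca_status_table(inputs$mca_calls, inputs$participants)
    pipeline_log(con, "classify_mca",
                 sprintf("%d calls in -> %d mCA carriers (%d LOY, %d LOX)",
                         nrow(inputs$mca_calls), sum(ms$any_mca),
                         sum(ms$loy), sum(ms$lox)))
    utils::write.table(ms, file.path(out_dir, "mca_status.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ms
  })
  tab <- stage("build_cohort", {
    roster <- apply_exclusions(inputs$participants, seed = config$seed)
    excl <- attr(roster, "exclusions")
    utils::write.table(excl, file.path(out_dir, "exclusions.log"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    t <- build_analysis_table(roster, chip$status, mca, censor_date = NULL)
    pipeline_log(con, "build_cohort",
                 sprintf("%d in -> %d excluded -> %d analysis rows",
                         nrow(inputs$participants), nrow(excl), nrow(t)))
    t_out <- t
    for (cl in names(t_out)[vapply(t_out, inherits, logical(1), "Date")]) {
      t_out[[cl]] <- as.character(t_out[[cl]])
    }
    utils::write.table(t_out, file.path(out_dir, "analysis_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    t
  })
  prev <- stage("prevalence", {
    p <- fit_prevalence_model(tab, "chip",
                              c("age_baseline", "sex", "smoking", "chemo",
                                "radio"), adjust = character(0))
    jsonlite::write_json(p, file.path(out_dir, "prevalence.json"),
                         dataframe = "rows", digits = NA)
    pipeline_log(con, "prevalence",
                 sprintf("CHIP model on %d rows", p$n_used[1]))
    p
  })
  surv <- stage("survival", {
    s <- run_interaction_analysis(tab, pair = "chip_mca")
    res <- do.call(rbind, lapply(s$endpoints, function(ep)
      cbind(endpoint = ep$endpoint, ep$metrics)))
    jsonlite::write_json(res, file.path(out_dir, "interaction_metrics.json"),
                         dataframe = "rows", digits = NA)
    pipeline_log(con, "survival",
                 sprintf("interaction metrics for %d endpoints",
                         length(s$endpoints)))
    s
  })

  descr <- summarize_descriptives(tab)
  utils::write.table(descr, file.path(out_dir, "descriptives.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  files <- setdiff(list.files(out_dir, full.names = TRUE),
                   file.path(out_dir, c("manifest.json", "pipeline.log")))
  manifest <- list(package_version = as.character(utils::packageVersion("chcv")),
                   seed = config$seed,
                   n_participants = config$n_participants,
                   files = data.frame(file = basename(files),
                                      md5 = unname(tools::md5sum(files)),
                                      stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  pipeline_log(con, "done", "manifest.json written")
  invisible(list(table = tab, chip = chip, mca = mca, prevalence = prev,
                 interaction = surv,
                 manifest = file.path(out_dir, "manifest.json")))
}
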