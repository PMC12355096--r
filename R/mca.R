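# Classification of mosaic chromosomal alteration (mCA) call tables into
# the exposure categories used downstream: any mCA, LOY, LOX, autosomal,
# expanded. Detection of mCAs from array intensities is upstream of this
# package; calls arrive as (participant, chromosome, event type, cell
# fraction) records.

#' Classify one participant's mCA calls
#'
#' @param calls Data frame with columns `chrom` (`"1"`..`"22"`, `"X"`,
#'   `"Y"`), `event_type` (`"loss"`, `"gain"`, `"cnloh"`) and
#'   `cell_fraction` (in (0, 1]); zero rows for participants without mCAs.
#' @param sex `"F"` or `"M"`. LOY is only defined in men, LOX only in
#'   women; a chrY call in a female is a sex-consistency error.
#' @param expanded_cf Cell-fraction threshold for the expanded flag
#'   (default 0.10, inclusive).
#' @param strict_expanded If `TRUE`, use strict inequality (> threshold)
#'   as some summary tables do; default `FALSE` (>=).
#' @return One-row data frame: `any_mca`, `loy`, `lox`, `autosomal`,
#'   `expanded`, `max_cell_fraction` (0 when there are no calls).
#' @export
classify_mca <- function(calls, sex, expanded_cf = 0.10,
                         strict_expanded = FALSE) {
  stopifnot(sex %in% c("F", "M"))
  assert_columns(calls, c("chrom", "event_type", "cell_fraction"), "mCA calls")
  if (nrow(calls)) {
    stopifnot(all(calls$event_type %in% c("loss", "gain", "cnloh")))
    cf <- calls$cell_fraction
    if (any(cf <= 0 | cf > 1)) {
      stop("cell_fraction must lie in (0, 1]", call. = FALSE)
    }
    if (sex == "F" && any(calls$chrom == "Y")) {
      stop("chrY mCA call in a female participant: sex-inconsistent input",
           call. = FALSE)
    }
  }
  max_cf <- if (nrow(calls)) max(calls$cell_fraction) else 0
  data.frame(
    any_mca = nrow(calls) > 0,
    loy = sex == "M" && any(calls$chrom == "Y" & calls$event_type == "loss"),
    lox = sex == "F" && any(calls$chrom == "X" & calls$event_type == "loss"),
    autosomal = any(calls$chrom %in% as.character(1:22)),
    expanded = if (strict_expanded) max_cf > expanded_cf else
      max_cf >= expanded_cf,
    max_cell_fraction = max_cf
  )
}

#' Classify mCA calls for a whole cohort
#'
#' Applies [classify_mca()] to every participant in the phenotype table,
#' producing one status row per participant (all flags `FALSE` for
#' participants without calls).
#'
#' @param calls Data frame with columns `participant_id`, `chrom`,
#'   `event_type`, `cell_fraction`.
#' @param phenotypes Data frame with `participant_id` and `sex`.
#' @inheritParams classify_mca
#' @return Data frame with one row per phenotype participant.
#' @export
mca_status_table <- function(calls, phenotypes, expanded_cf = 0.10,
                             strict_expanded = FALSE) {
  assert_columns(calls, c("participant_id", "chrom", "event_type",
                          "cell_fraction"), "mCA calls")
  assert_columns(phenotypes, c("participant_id", "sex"), "phenotypes")
  orphan <- setdiff(calls$participant_id, phenotypes$participant_id)
  if (length(orphan)) {
    stop("mCA calls for participants absent from phenotypes: ",
         paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
  }
  sp <- split(calls, factor(calls$participant_id,
                            levels = phenotypes$participant_id))
  out <- do.call(rbind, lapply(seq_along(sp), function(i) {
    classify_mca(sp[[i]], phenotypes$sex[i], expanded_cf, strict_expanded)
  }))
  cbind(participant_id = phenotypes$participant_id, out,
        stringsAsFactors = FALSE)
}
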