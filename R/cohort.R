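# Cohort eligibility rules and per-endpoint time-to-event construction.

#' Endpoint names used throughout the package
#'
#' @return Character vector of the five study endpoints.
#' @export
endpoint_names <- function() {
  c("incident_cvd", "incident_cad", "cv_death", "cad_death", "any_death")
}

endpoint_date_col <- function(endpoint) {
  ifelse(endpoint == "any_death", "death_date", paste0(endpoint, "_date"))
}

#' Apply cohort eligibility exclusions
#'
#' Three rules, mirroring standard biobank practice for clonal
#' hematopoiesis studies:
#' \enumerate{
#'   \item participants with a hematologic cancer diagnosed within +/- 6
#'     months (182 days on either side) of study entry are excluded;
#'   \item participants without genotypic-phenotypic sex concordance are
#'     excluded;
#'   \item one member of each pair (or connected group) of first/second
#'     degree relatives is removed at random, using a seeded RNG over a
#'     canonically sorted group list so the retained set is reproducible
#'     and independent of the order in which rules are applied.
#' }
#' The three exclusion sets are computed independently on the full roster
#' and unioned, which makes the result order-independent by construction.
#'
#' @param roster Phenotype data frame with `participant_id`,
#'   `recruit_date`, and the annotation columns `hem_cancer_dx_date`
#'   (`NA` if none), `genotypic_sex_concordant` (logical) and
#'   `relative_pair_id` (`NA` for unrelated participants).
#' @param seed Integer seed for the relative-pruning choice.
#' @return The retained roster, with an `exclusions` attribute: a data
#'   frame (`participant_id`, `reason`) logging every removal.
#' @export
apply_exclusions <- function(roster, seed = 1L) {
  assert_columns(roster, c("participant_id", "recruit_date",
                           "hem_cancer_dx_date", "genotypic_sex_concordant",
                           "relative_pair_id"), "roster")
  hem <- !is.na(roster$hem_cancer_dx_date) &
    abs(as.numeric(as.Date(roster$hem_cancer_dx_date) -
                   as.Date(roster$recruit_date))) <= 182
  disc <- !roster$genotypic_sex_concordant

  rel_excl <- character(0)
  grp <- roster$relative_pair_id
  groups <- sort(unique(grp[!is.na(grp)]))
  if (length(groups)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    for (g in groups) {
      members <- sort(roster$participant_id[!is.na(grp) & grp == g])
      if (length(members) < 2) next
      keep <- sample(members, 1L)
      rel_excl <- c(rel_excl, setdiff(members, keep))
    }
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }

  mk <- function(ids, reason) {
    data.frame(participant_id = ids, reason = rep(reason, length(ids)),
               stringsAsFactors = FALSE)
  }
  log <- rbind(mk(roster$participant_id[hem], "hematologic_cancer_within_6mo"),
               mk(roster$participant_id[disc], "sex_discordance"),
               mk(rel_excl, "relative_pruning"))
  drop <- roster$participant_id %in% log$participant_id
  out <- roster[!drop, , drop = FALSE]
  attr(out, "exclusions") <- log
  out
}

#' Derive a time-to-event record
#'
#' The time origin is the assessment (recruitment) visit for participants
#' whose cancer was diagnosed on or before baseline (prevalent cancer),
#' and the cancer diagnosis date for cancers diagnosed after baseline.
#' Time in years is days / 365.25 from the origin to the earlier of the
#' event and the administrative censoring date (the last registered death
#' date in the dataset). Events after the censoring date are censored.
#' Rows whose event precedes the origin are flagged in `dropped` for the
#' caller to remove and log.
#'
#' @param recruit_date,cancer_dx_date,event_date Date vectors
#'   (`event_date` is `NA` for participants without the event).
#' @param censor_date Single administrative censoring date.
#' @return Data frame: `origin_date`, `time_years`, `event`, `dropped`.
#' @export
derive_time_to_event <- function(recruit_date, cancer_dx_date, event_date,
                                 censor_date) {
  recruit_date <- as.Date(recruit_date)
  cancer_dx_date <- as.Date(cancer_dx_date)
  event_date <- as.Date(event_date)
  censor_date <- as.Date(censor_date)
  stopifnot(length(censor_date) == 1, !is.na(censor_date))
  origin <- recruit_date
  incident <- !is.na(cancer_dx_date) & cancer_dx_date > recruit_date
  origin[incident] <- cancer_dx_date[incident]
  event <- !is.na(event_date) & event_date <= censor_date
  end <- rep(censor_date, length(origin))
  end[event] <- pmin(event_date[event], censor_date)
  time_years <- as.numeric(end - origin) / 365.25
  dropped <- !is.na(event_date) & event_date < origin
  data.frame(origin_date = origin, time_years = time_years,
             event = event & !dropped, dropped = dropped)
}

#' Build the per-participant analysis table
#'
#' Joins the (post-exclusion) phenotype roster with CHIP and mCA status,
#' derives the four-category clonal-hematopoiesis exposure, the
#' prevalent-cancer delay covariate, and one (time, event) pair per
#' endpoint. The administrative censoring date is the last registered
#' death date in the roster (or `censor_date` if supplied). Rows with an
#' event recorded before the time origin for some endpoint are dropped
#' and logged in the `dropped` attribute.
#'
#' @param roster Phenotype data frame (post-exclusions), with the
#'   per-endpoint event date columns `incident_cvd_date`,
#'   `incident_cad_date`, `cv_death_date`, `cad_death_date`,
#'   `death_date`.
#' @param chip_status CHIP status table ([call_chip()] `$status`, or any
#'   data frame with `participant_id`, `carrier`, `n_mutations`,
#'   `max_vaf`, `expanded`, `mutation_count_class`).
#' @param mca_status mCA status table ([mca_status_table()]).
#' @param censor_date Optional explicit censoring date.
#' @return Data frame with one row per retained participant: roster
#'   covariates, `chip`, `chip_expanded`, `mutation_count_class`,
#'   `any_mca`, `loy`, `lox`, `mca_expanded`, `exposure4`
#'   (factor `no_ch` / `chip_only` / `mca_only` / `both`), `delay_days`,
#'   and `time_<endpoint>` / `event_<endpoint>` per endpoint. Attributes:
#'   `censor_date`, `dropped`.
#' @export
build_analysis_table <- function(roster, chip_status, mca_status,
                                 censor_date = NULL) {
  assert_columns(roster, c("participant_id", "recruit_date",
                           "cancer_dx_date", endpoint_date_col(endpoint_names())),
                 "roster")
  for (tab in list(chip_status, mca_status)) {
    miss <- setdiff(roster$participant_id, tab$participant_id)
    if (length(miss)) {
      stop("missing CHIP/mCA status for retained participant(s): ",
           paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
    }
  }
  ci <- match(roster$participant_id, chip_status$participant_id)
  mi <- match(roster$participant_id, mca_status$participant_id)
  tab <- roster
  tab$chip <- chip_status$carrier[ci]
  tab$chip_expanded <- chip_status$expanded[ci] & chip_status$carrier[ci]
  tab$n_mutations <- chip_status$n_mutations[ci]
  tab$mutation_count_class <- chip_status$mutation_count_class[ci]
  tab$max_vaf <- chip_status$max_vaf[ci]
  tab$any_mca <- mca_status$any_mca[mi]
  tab$loy <- mca_status$loy[mi]
  tab$lox <- mca_status$lox[mi]
  tab$mca_expanded <- mca_status$expanded[mi]
  tab$exposure4 <- ch4_factor(tab$chip, tab$any_mca)
  tab$delay_days <- pmax(0, as.numeric(as.Date(tab$recruit_date) -
                                         as.Date(tab$cancer_dx_date)))
  tab$delay_days[is.na(tab$delay_days)] <- 0

  if (is.null(censor_date)) {
    dd <- as.Date(roster$death_date)
    if (all(is.na(dd))) {
      stop("no registered deaths: supply censor_date explicitly", call. = FALSE)
    }
    censor_date <- max(dd, na.rm = TRUE)
  }
  dropped <- rep(FALSE, nrow(tab))
  for (ep in endpoint_names()) {
    rec <- derive_time_to_event(tab$recruit_date, tab$cancer_dx_date,
                                tab[[endpoint_date_col(ep)]], censor_date)
    tab[[paste0("time_", ep)]] <- rec$time_years
    tab[[paste0("event_", ep)]] <- rec$event
    dropped <- dropped | rec$dropped
  }
  out <- tab[!dropped, , drop = FALSE]
  attr(out, "censor_date") <- as.Date(censor_date)
  attr(out, "dropped") <- tab$participant_id[dropped]
  out
}

#' Four-category clonal-hematopoiesis exposure
#'
#' @param chip,mca Logical vectors: CHIP carriage and mCA carriage.
#' @return Factor with levels `no_ch`, `chip_only`, `mca_only`, `both`
#'   (reference first).
#' @export
ch4_factor <- function(chip, mca) {
  factor(ifelse(chip & mca, "both",
         ifelse(chip, "chip_only",
         ifelse(mca, "mca_only", "no_ch"))),
         levels = c("no_ch", "chip_only", "mca_only", "both"))
}
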