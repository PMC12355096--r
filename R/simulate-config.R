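# Simulation configuration: the study conditions the synthetic cohort
# emulates. Defaults target the marginal structure of a UK-biobank-style
# cancer cohort aged 40-71: ~5.5% CHIP, ~20.7% any mCA, smoking and
# chemotherapy enrichment of CHIP, LOY negatively and LOX positively
# associated with CHIP, a 2% VAF detection floor with ~63% of carriers at
# VAF >= 10%, and exponential proportional-hazards event times for five
# endpoints.

#' Hazard configuration for the event-time generator
#'
#' Per-endpoint baseline exponential hazard rates (events per
#' person-year), log hazard ratios for the three clonal-hematopoiesis
#' exposure categories versus no CH, and shared covariate log hazard
#' ratios. Default exposure log-HRs sit near values reported for cancer
#' cohorts (e.g. CHIP-only HR ~1.08 for incident CVD, ~1.31 for overall
#' death).
#'
#' @param baseline Named numeric: baseline rate per endpoint.
#' @param exposure_log_hr Named list: per endpoint, numeric
#'   `c(chip_only=, mca_only=, both=)`.
#' @param covariate_log_hr Named numeric log-HRs applied to all
#'   endpoints: `age` (per year), `sex_male`, `smoking_current`,
#'   `smoking_previous` (versus never), `chemo`, `prevalent_cvd`.
#' @param horizon_years Administrative follow-up horizon after the last
#'   recruitment date.
#' @return List of class `hazard_config`.
#' @export
hazard_config <- function(
    baseline = c(incident_cvd = 0.055, incident_cad = 0.010,
                 cv_death = 0.0011, cad_death = 0.00045,
                 any_death = 0.016),
    exposure_log_hr = list(
      incident_cvd = log(c(chip_only = 1.082, mca_only = 0.995, both = 1.048)),
      incident_cad = log(c(chip_only = 1.110, mca_only = 1.031, both = 1.069)),
      cv_death     = log(c(chip_only = 1.073, mca_only = 1.148, both = 1.090)),
      cad_death    = log(c(chip_only = 0.798, mca_only = 1.363, both = 1.210)),
      any_death    = log(c(chip_only = 1.305, mca_only = 1.068, both = 1.406))),
    covariate_log_hr = c(age = 0.04, sex_male = 0.25, smoking_current = 0.35,
                         smoking_previous = 0.10, chemo = 0.20,
                         prevalent_cvd = 0.30),
    horizon_years = 15) {
  stopifnot(all(baseline > 0), horizon_years > 0,
            setequal(names(baseline), endpoint_names()),
            setequal(names(exposure_log_hr), endpoint_names()))
  structure(list(baseline = baseline, exposure_log_hr = exposure_log_hr,
                 covariate_log_hr = covariate_log_hr,
                 horizon_years = horizon_years),
            class = "hazard_config")
}

#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic cohort
#' generator. Prevalence parameters are interpreted as target marginal
#' prevalences: the generator solves the logistic intercept numerically
#' so the expected cohort-wide carrier fraction equals the target given
#' the realised covariates.
#'
#' @param n_participants Cohort size.
#' @param seed Integer RNG seed.
#' @param age_range Recruitment age window in years, `c(min, max)`.
#' @param age_mean,age_sd Mean/SD of the (truncated normal) age
#'   distribution.
#' @param sex_male_prop Proportion of men.
#' @param smoking_props Named proportions for
#'   `current`/`never`/`previous`/`unknown` smoking (sum to 1).
#' @param chemo_prop,radio_prop,prevalent_cvd_prop Covariate
#'   proportions.
#' @param prevalent_cancer_prop Proportion whose cancer was diagnosed
#'   before baseline.
#' @param cancer_type_frequencies Named proportions over cancer types.
#' @param chip_prevalence Target marginal CHIP prevalence.
#' @param chip_log_or_per_year_age Age log-OR for CHIP carriage.
#' @param chip_log_or_never,chip_log_or_previous Smoking log-ORs versus
#'   current smokers.
#' @param chip_log_or_chemo Chemotherapy log-OR.
#' @param mca_loy_prevalence LOY target prevalence among men.
#' @param mca_lox_prevalence LOX target prevalence among women.
#' @param mca_autosomal_prevalence Autosomal-mCA target prevalence.
#' @param mca_log_or_per_year_age Age log-OR shared by mCA components.
#' @param loy_chip_log_or LOY-on-CHIP log-OR (negative: LOY is depleted
#'   in CHIP carriers).
#' @param lox_chip_log_or LOX-on-CHIP log-OR (positive).
#' @param vaf_distribution List `floor`, `shape1`, `shape2`: clone VAFs
#'   are Beta(shape1, shape2) left-truncated at `floor`.
#' @param cell_fraction_distribution List `floor`, `shape1`, `shape2`
#'   for mCA cell fractions.
#' @param mutation_count_probs Probabilities of 1 / 2 / 3+ mutations per
#'   carrier.
#' @param gene_frequencies Named sampling weights over panel genes.
#' @param tert_maf Allele frequency of the TERT rs7705526 risk allele.
#' @param decoy_fraction Fraction of participants receiving one
#'   deterministic-failure decoy variant.
#' @param recurrent_decoy_n Carriers of the age/TERT-independent
#'   recurrent decoy variant (0 disables; capped at n/5).
#' @param hem_cancer_prop,sex_discordant_prop,relative_pair_prop
#'   Fractions exercising the three eligibility exclusions.
#' @param hazard A [hazard_config()].
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(
    n_participants = 10000,
    seed = 1L,
    age_range = c(40, 71),
    age_mean = 60, age_sd = 7,
    sex_male_prop = 0.458,
    smoking_props = c(current = 0.112, never = 0.488, previous = 0.394,
                      unknown = 0.006),
    chemo_prop = 0.233,
    radio_prop = 0.063,
    prevalent_cvd_prop = 0.226,
    prevalent_cancer_prop = 0.5,
    cancer_type_frequencies = c(breast = 0.28, prostate = 0.20,
                                colorectal = 0.12, melanoma = 0.10,
                                lung = 0.07, uterus = 0.06, kidney = 0.05,
                                bladder = 0.05, other = 0.07),
    chip_prevalence = 0.055,
    chip_log_or_per_year_age = 0.077,
    chip_log_or_never = log(0.684),
    chip_log_or_previous = log(0.764),
    chip_log_or_chemo = log(1.258),
    mca_loy_prevalence = 0.29,
    mca_lox_prevalence = 0.062,
    mca_autosomal_prevalence = 0.049,
    mca_log_or_per_year_age = log(1.10),
    loy_chip_log_or = log(0.652),
    lox_chip_log_or = log(1.242),
    vaf_distribution = list(floor = 0.02, shape1 = 1.5, shape2 = 8.6),
    cell_fraction_distribution = list(floor = 0.005, shape1 = 1,
                                      shape2 = 16),
    mutation_count_probs = c(0.844, 0.086, 0.070),
    gene_frequencies = c(DNMT3A = 0.52, TET2 = 0.22, ASXL1 = 0.14,
                         PPM1D = 0.040, TP53 = 0.030, JAK2 = 0.020,
                         SF3B1 = 0.015, CBL = 0.013, SRSF2 = 0.012,
                         GNAS = 0.010, GNB1 = 0.008),
    tert_maf = 0.3,
    decoy_fraction = 0.02,
    recurrent_decoy_n = 60,
    hem_cancer_prop = 0.004,
    sex_discordant_prop = 0.002,
    relative_pair_prop = 0.01,
    hazard = hazard_config()) {
  if (!is.numeric(n_participants) || length(n_participants) != 1 ||
      n_participants < 1 || n_participants != round(n_participants)) {
    stop("n_participants must be a positive integer", call. = FALSE)
  }
  stopifnot(length(age_range) == 2, age_range[1] < age_range[2])
  assert_proportion(chip_prevalence, "chip_prevalence")
  assert_proportion(c(mca_loy_prevalence, mca_lox_prevalence,
                      mca_autosomal_prevalence), "mca prevalences")
  assert_proportion(smoking_props, "smoking_props")
  assert_proportion(c(chemo_prop, radio_prop, prevalent_cvd_prop,
                      prevalent_cancer_prop, decoy_fraction, tert_maf,
                      hem_cancer_prop, sex_discordant_prop,
                      relative_pair_prop, sex_male_prop), "proportions")
  if (abs(sum(smoking_props) - 1) > 1e-8) {
    stop("smoking_props must sum to 1", call. = FALSE)
  }
  if (vaf_distribution$floor < 0.02) {
    stop("VAF floor must be >= 0.02 (the CHIP detection threshold)",
         call. = FALSE)
  }
  stopifnot(inherits(hazard, "hazard_config"))
  structure(as.list(environment()), class = "simulation_config")
}

#' Read a simulation configuration from YAML
#'
#' Top-level keys are the arguments of [simulation_config()]; a
#' `hazard:` block holds [hazard_config()] arguments. Keys left out take
#' the defaults. `seed` (if supplied) overrides the config file's seed.
#'
#' @param path YAML file path.
#' @param seed Optional seed override.
#' @return A `simulation_config`.
#' @export
read_simulation_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$hazard)) {
    hz <- y$hazard
    if (!is.null(hz$baseline)) hz$baseline <- unlist(hz$baseline)
    if (!is.null(hz$exposure_log_hr)) {
      hz$exposure_log_hr <- lapply(hz$exposure_log_hr, unlist)
    }
    if (!is.null(hz$covariate_log_hr)) {
      hz$covariate_log_hr <- unlist(hz$covariate_log_hr)
    }
    y$hazard <- do.call(hazard_config, hz)
  }
  for (k in c("smoking_props", "cancer_type_frequencies",
              "gene_frequencies")) {
    if (!is.null(y[[k]])) y[[k]] <- unlist(y[[k]])
  }
  for (k in c("age_range", "mutation_count_probs")) {
    if (!is.null(y[[k]])) y[[k]] <- as.numeric(unlist(y[[k]]))
  }
  if (!is.null(seed)) y$seed <- as.integer(seed)
  do.call(simulation_config, y)
}
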