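# Synthetic cohort generator. Latent CHIP and mCA carriage are drawn
# from logistic models in age, smoking and chemotherapy (CHIP) and age
# plus CHIP (sex-chromosome mCA components, giving the LOY/LOX
# correlations); carriers receive whitelist variants with read-level
# evidence engineered to pass the filter cascade; labelled decoy
# variants violate identifiable rules; event times are exponential
# proportional hazards with administrative censoring. Everything latent
# is recorded in a truth block for parameter-recovery tests.

# Truncated-normal and left-truncated-Beta draws via inverse CDF so the
# RNG stream length is deterministic.
rtnorm <- function(n, mean, sd, lo, hi) {
  a <- stats::pnorm((lo - mean) / sd)
  b <- stats::pnorm((hi - mean) / sd)
  mean + sd * stats::qnorm(a + stats::runif(n) * (b - a))
}

rbeta_trunc <- function(n, shape1, shape2, floor) {
  a <- stats::pbeta(floor, shape1, shape2)
  stats::qbeta(a + stats::runif(n) * (1 - a), shape1, shape2)
}

# Solve the logistic intercept so the mean carrier probability over the
# realised covariate offsets equals the target marginal prevalence.
calibrate_intercept <- function(offset, target) {
  if (target == 0) return(-Inf)
  if (target == 1) return(Inf)
  stats::uniroot(function(b0) mean(stats::plogis(b0 + offset)) - target,
                 c(-40, 40), tol = 1e-10)$root
}

# Pseudo-genomic coordinates for generated variants: gene anchor plus
# three bases per residue parsed from the protein change.
gene_anchor <- function() {
  data.frame(
    gene = c("ASXL1", "CBL", "DNMT3A", "GNAS", "GNB1", "JAK2",
             "PPM1D", "SF3B1", "SRSF2", "TET2", "TP53"),
    chrom = c("20", "11", "2", "20", "1", "9", "17", "2", "17", "4", "17"),
    base = c(32358000L, 119206000L, 25234000L, 58839000L, 1785000L,
             5021000L, 60663000L, 197389000L, 76734000L, 105233000L,
             7571000L),
    stringsAsFactors = FALSE)
}

hgvs_residue <- function(hgvs_p) {
  as.integer(sub("^p\\.[A-Za-z]+([0-9]+).*$", "\\1", hgvs_p))
}

variant_coords <- function(gene, hgvs_p, consequence) {
  an <- gene_anchor()
  i <- match(gene, an$gene)
  pos <- an$base[i] + 3L * hgvs_residue(hgvs_p)
  snv <- consequence %in% c("missense", "nonsense", "splice")
  # distinct protein changes at one residue get distinct alt alleles
  hash <- vapply(hgvs_p, function(h) sum(utf8ToInt(h)) %% 3L, integer(1),
                 USE.NAMES = FALSE)
  data.frame(chrom = an$chrom[i], pos = pos,
             ref = ifelse(snv, "C", "CA"),
             alt = ifelse(snv,
                          ifelse(consequence == "missense",
                                 c("T", "G", "A")[hash + 1L], "A"),
                          "C"),
             stringsAsFactors = FALSE)
}

# Sites reserved for decoy variants: kept out of the true-clone site
# pool so a locus has one consistent evidence profile and removing a
# decoy locus can never remove a genuine clone.
RECURRENT_DECOY_SITE <- c(gene = "TET2", hgvs_p = "p.C1135Y")
DECOY_SITES <- data.frame(
  gene = c("TET2", "DNMT3A", "DNMT3A", "JAK2", "SF3B1", "GNB1"),
  hgvs_p = c("p.C1135Y", "p.R736H", "p.R729W", "p.R683G", "p.G742D",
             "p.I80T"),
  stringsAsFactors = FALSE)

# Hotspot sites the generator assigns to true clones: packaged whitelist
# site entries minus named artifacts and the reserved decoy sites, plus
# truncating hotspots matched by the gene-level rules.
true_site_table <- function(wl) {
  sites <- wl$sites
  art <- c(paste(wl$artifacts$gene, wl$artifacts$hgvs_p),
           paste(DECOY_SITES$gene, DECOY_SITES$hgvs_p))
  sites <- sites[!paste(sites$gene, sites$hgvs_p) %in% art, ]
  trunc <- data.frame(
    gene = c("ASXL1", "ASXL1", "PPM1D", "TET2", "DNMT3A", "TP53"),
    hgvs_p = c("p.E635Rfs*15", "p.R693*", "p.R552*", "p.Q916*",
               "p.W795*", "p.R196*"),
    consequence = c("frameshift", "nonsense", "nonsense", "nonsense",
                    "nonsense", "nonsense"),
    stringsAsFactors = FALSE)
  rbind(sites, trunc)
}

NO_RUN_CONTEXT <- "ACGTACGTACG"
RUN_CONTEXT <- "GCAAAAAGTCA"   # centre base inside a 5-base A run

binom_half_p <- function(ad, dp) stats::binom.test(ad, dp, p = 0.5)$p.value

# Evidence for one true clone: depth/strand compliant, VAF floor
# respected, and (for missense in the binomial-tested genes) allele
# counts consistent with a somatic clone at the 0.01 level.
draw_clone_evidence <- function(vaf_target, gene, hgvs_p, consequence, wl) {
  dp <- 30L + stats::rpois(1, 40)
  ad <- stats::rbinom(1, dp, vaf_target)
  ad <- max(5L, min(ad, dp - 1L))
  needs_binom <- consequence == "missense" &&
    gene %in% c("CBL", "TET2", "DNMT3A", "TP53") &&
    !is_binomial_exempt(gene, hgvs_p, wl)
  if (needs_binom) {
    while (ad > 5L && binom_half_p(ad, dp) >= 0.01) ad <- ad - 1L
  }
  f1r2 <- stats::rbinom(1, ad, 0.5)
  f1r2 <- max(1L, min(f1r2, ad - 1L))
  c(dp = dp, ad = ad, f1r2 = f1r2, f2r1 = ad - f1r2)
}

evidence_row <- function(participant_id, gene, hgvs_p, consequence,
                         dp, ad, f1r2, f2r1, context) {
  co <- variant_coords(gene, hgvs_p, consequence)
  data.frame(participant_id = participant_id, gene = gene, hgvs_p = hgvs_p,
             chrom = co$chrom, pos = co$pos, ref = co$ref, alt = co$alt,
             dp = as.integer(dp), ad = as.integer(ad),
             f1r2 = as.integer(f1r2), f2r1 = as.integer(f2r1),
             vaf = ad / dp, context = context, consequence = consequence,
             stringsAsFactors = FALSE)
}

# Deterministic-failure decoy classes: each violates at least one
# per-variant rule so the cascade must remove it regardless of seed.
DECOY_CLASSES <- c("low_dp", "low_ad", "strand", "homopolymer",
                   "artifact_p72r", "artifact_g646", "germline_vaf",
                   "non_whitelist")

decoy_evidence <- function(participant_id, class) {
  switch(class,
    low_dp = evidence_row(participant_id, "DNMT3A", "p.R729W", "missense",
                          15, 6, 3, 3, NO_RUN_CONTEXT),
    low_ad = evidence_row(participant_id, "JAK2", "p.R683G", "missense",
                          40, 3, 1, 2, NO_RUN_CONTEXT),
    strand = evidence_row(participant_id, "SF3B1", "p.G742D", "missense",
                          50, 10, 10, 0, NO_RUN_CONTEXT),
    homopolymer = evidence_row(participant_id, "GNB1", "p.I80T", "missense",
                               45, 8, 4, 4, RUN_CONTEXT),
    artifact_p72r = evidence_row(participant_id, "TP53", "p.P72R", "missense",
                                 60, 21, 10, 11, NO_RUN_CONTEXT),
    artifact_g646 = evidence_row(participant_id, "ASXL1", "p.G646Wfs*12",
                                 "frameshift", 60, 5, 2, 3, NO_RUN_CONTEXT),
    germline_vaf = evidence_row(participant_id, "DNMT3A", "p.R736H",
                                "missense", 80, 40, 20, 20, NO_RUN_CONTEXT),
    non_whitelist = evidence_row(participant_id, "GNAS", "p.A123V",
                                 "missense", 50, 12, 6, 6, NO_RUN_CONTEXT),
    stop("unknown decoy class: ", class, call. = FALSE))
}

#' Generate a synthetic cohort
#'
#' Draws a full cohort — phenotypes, latent CHIP/mCA carriage,
#' variant-level read evidence (true clones plus labelled decoys), mCA
#' call table, and per-endpoint event dates — from the configured study
#' conditions. Deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param wl CHIP whitelist used to choose clone variants (default:
#'   packaged list).
#' @return Object of class `cohort_bundle`: list with `participants`
#'   (phenotype data frame), `variant_evidence`, `mca_calls`, and
#'   `truth` (latent carrier assignments, decoy labels, and the hazard
#'   configuration used).
#' @export
generate_cohort <- function(config, wl = load_whitelist()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- as.integer(config$n_participants)
  ids <- sprintf("P%06d", seq_len(n))

  age <- rtnorm(n, config$age_mean, config$age_sd,
                config$age_range[1], config$age_range[2])
  sex <- ifelse(stats::runif(n) < config$sex_male_prop, "M", "F")
  smoking <- sample(names(config$smoking_props), n, replace = TRUE,
                    prob = config$smoking_props)
  chemo <- stats::rbinom(n, 1, config$chemo_prop)
  radio <- stats::rbinom(n, 1, config$radio_prop)
  prevalent_cvd <- stats::rbinom(n, 1, config$prevalent_cvd_prop)
  cancer_type <- sample(names(config$cancer_type_frequencies), n,
                        replace = TRUE,
                        prob = config$cancer_type_frequencies)
  tert <- stats::rbinom(n, 2, config$tert_maf)
  pcs <- matrix(stats::rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("pc", 1:10)))

  recruit <- as.Date("2006-01-01") + sample(0:1825, n, replace = TRUE)
  prevalent_cancer <- stats::runif(n) < config$prevalent_cancer_prop
  dx_offset <- ifelse(prevalent_cancer,
                      -sample(30:3650, n, replace = TRUE),
                      sample(1:1825, n, replace = TRUE))
  cancer_dx <- recruit + dx_offset

  # latent CHIP carriage
  chip_off <- config$chip_log_or_per_year_age * (age - config$age_mean) +
    config$chip_log_or_never * (smoking == "never") +
    config$chip_log_or_previous * (smoking == "previous") +
    config$chip_log_or_chemo * chemo
  b0 <- calibrate_intercept(chip_off, config$chip_prevalence)
  chip <- stats::runif(n) < stats::plogis(b0 + chip_off)

  # latent mCA components: age-dependent, LOY depleted / LOX enriched in
  # CHIP carriers; autosomal events independent of CHIP
  age_off <- config$mca_log_or_per_year_age * (age - config$age_mean)
  men <- sex == "M"; women <- !men
  loy <- lox <- rep(FALSE, n)
  if (any(men)) {
    off <- age_off[men] + config$loy_chip_log_or * chip[men]
    loy[men] <- stats::runif(sum(men)) <
      stats::plogis(calibrate_intercept(off, config$mca_loy_prevalence) + off)
  }
  if (any(women)) {
    off <- age_off[women] + config$lox_chip_log_or * chip[women]
    lox[women] <- stats::runif(sum(women)) <
      stats::plogis(calibrate_intercept(off, config$mca_lox_prevalence) + off)
  }
  auto_off <- age_off
  auto <- stats::runif(n) <
    stats::plogis(calibrate_intercept(auto_off,
                                      config$mca_autosomal_prevalence) +
                  auto_off)
  any_mca <- loy | lox | auto
  exposure4 <- ch4_factor(chip, any_mca)

  # mCA call table
  cfd <- config$cell_fraction_distribution
  mca_calls <- list()
  if (any(loy)) {
    mca_calls$loy <- data.frame(
      participant_id = ids[loy], chrom = "Y", event_type = "loss",
      cell_fraction = rbeta_trunc(sum(loy), cfd$shape1, cfd$shape2,
                                  cfd$floor), stringsAsFactors = FALSE)
  }
  if (any(lox)) {
    mca_calls$lox <- data.frame(
      participant_id = ids[lox], chrom = "X", event_type = "loss",
      cell_fraction = rbeta_trunc(sum(lox), cfd$shape1, cfd$shape2,
                                  cfd$floor), stringsAsFactors = FALSE)
  }
  if (any(auto)) {
    mca_calls$auto <- data.frame(
      participant_id = ids[auto],
      chrom = as.character(sample(1:22, sum(auto), replace = TRUE)),
      event_type = sample(c("loss", "gain", "cnloh"), sum(auto),
                          replace = TRUE),
      cell_fraction = rbeta_trunc(sum(auto), cfd$shape1, cfd$shape2,
                                  cfd$floor), stringsAsFactors = FALSE)
  }
  mca_calls <- if (length(mca_calls)) do.call(rbind, mca_calls) else
    data.frame(participant_id = character(0), chrom = character(0),
               event_type = character(0), cell_fraction = numeric(0),
               stringsAsFactors = FALSE)
  rownames(mca_calls) <- NULL

  # variant evidence for true clones
  sites <- true_site_table(wl)
  vd <- config$vaf_distribution
  ev <- list()
  for (i in which(chip)) {
    k <- sample(3L, 1, prob = config$mutation_count_probs)
    genes <- sample(names(config$gene_frequencies), k, replace = FALSE,
                    prob = config$gene_frequencies)
    for (g in genes) {
      cand <- sites[sites$gene == g, ]
      pick <- cand[sample(nrow(cand), 1), ]
      vaf <- rbeta_trunc(1, vd$shape1, vd$shape2, vd$floor)
      e <- draw_clone_evidence(vaf, g, pick$hgvs_p, pick$consequence, wl)
      ev[[length(ev) + 1L]] <- evidence_row(ids[i], g, pick$hgvs_p,
                                            pick$consequence, e["dp"],
                                            e["ad"], e["f1r2"], e["f2r1"],
                                            NO_RUN_CONTEXT)
    }
  }
  true_evidence <- if (length(ev)) do.call(rbind, ev) else NULL

  # labelled decoys: deterministic-failure classes
  n_decoy <- round(config$decoy_fraction * n)
  decoy_tab <- NULL
  decoy_evid <- NULL
  if (n_decoy > 0) {
    who <- sample(ids, n_decoy)
    cls <- rep_len(DECOY_CLASSES, n_decoy)
    decoy_evid <- do.call(rbind, Map(decoy_evidence, who, cls))
    decoy_tab <- data.frame(participant_id = who, decoy_class = cls,
                            stringsAsFactors = FALSE)
  }
  # recurrent decoy: >20 carriers, independent of age and TERT
  n_rec <- min(config$recurrent_decoy_n, floor(n / 5))
  if (n_rec > 0) {
    who <- sample(ids, n_rec)
    rec_evid <- do.call(rbind, lapply(who, function(id)
      evidence_row(id, RECURRENT_DECOY_SITE["gene"],
                   RECURRENT_DECOY_SITE["hgvs_p"], "missense", 60, 12, 6, 6,
                   NO_RUN_CONTEXT)))
    decoy_evid <- rbind(decoy_evid, rec_evid)
    decoy_tab <- rbind(decoy_tab,
                       data.frame(participant_id = who,
                                  decoy_class = "recurrent",
                                  stringsAsFactors = FALSE))
  }
  evidence <- rbind(true_evidence, decoy_evid)
  if (is.null(evidence)) {
    evidence <- evidence_row(character(0), character(0), character(0),
                             character(0), integer(0), integer(0),
                             integer(0), integer(0), character(0))
  }
  # a decoy may collide with a participant's true variant at the same
  # site; drop the duplicate decoy record
  key <- paste(evidence$participant_id, evidence$chrom, evidence$pos,
               evidence$ref, evidence$alt)
  evidence <- evidence[!duplicated(key), , drop = FALSE]
  rownames(evidence) <- NULL

  # event times: exponential proportional hazards, administrative
  # censoring at a fixed end-of-follow-up date
  hz <- config$hazard
  chr <- hz$covariate_log_hr
  lp_cov <- chr["age"] * (age - config$age_mean) +
    chr["sex_male"] * (sex == "M") +
    chr["smoking_current"] * (smoking == "current") +
    chr["smoking_previous"] * (smoking == "previous") +
    chr["chemo"] * chemo + chr["prevalent_cvd"] * prevalent_cvd
  origin <- as.Date(ifelse(cancer_dx > recruit, cancer_dx, recruit),
                    origin = "1970-01-01")
  end_date <- max(recruit) + round(hz$horizon_years * 365.25)
  event_dates <- list()
  latent_times <- list()
  for (ep in endpoint_names()) {
    bexp <- hz$exposure_log_hr[[ep]]
    lp <- lp_cov +
      bexp["chip_only"] * (exposure4 == "chip_only") +
      bexp["mca_only"] * (exposure4 == "mca_only") +
      bexp["both"] * (exposure4 == "both")
    tt <- stats::rexp(n, rate = hz$baseline[ep] * exp(lp))
    dates <- origin + round(tt * 365.25)
    dates[dates > end_date] <- NA
    event_dates[[ep]] <- dates
    latent_times[[ep]] <- tt
  }

  # eligibility-exclusion annotations
  hem_dx <- as.Date(rep(NA, n))
  hem <- stats::runif(n) < config$hem_cancer_prop
  if (any(hem)) {
    hem_dx[hem] <- recruit[hem] + sample(-300:300, sum(hem), replace = TRUE)
  }
  concordant <- stats::runif(n) >= config$sex_discordant_prop
  rel <- rep(NA_character_, n)
  n_pairs <- floor(config$relative_pair_prop * n / 2)
  if (n_pairs > 0) {
    members <- sample(ids, 2 * n_pairs)
    rel[match(members, ids)] <- rep(sprintf("R%04d", seq_len(n_pairs)),
                                    each = 2)
  }

  participants <- data.frame(
    participant_id = ids, sex = sex, age_baseline = age, smoking = smoking,
    chemo = chemo, radio = radio, prevalent_cvd = prevalent_cvd,
    cancer_type = cancer_type, cancer_dx_date = cancer_dx,
    recruit_date = recruit, tert_dosage = tert, pcs,
    incident_cvd_date = event_dates$incident_cvd,
    incident_cad_date = event_dates$incident_cad,
    cv_death_date = event_dates$cv_death,
    cad_death_date = event_dates$cad_death,
    death_date = event_dates$any_death,
    hem_cancer_dx_date = hem_dx,
    genotypic_sex_concordant = concordant,
    relative_pair_id = rel,
    stringsAsFactors = FALSE)

  truth <- list(
    chip = stats::setNames(chip, ids),
    loy = stats::setNames(loy, ids),
    lox = stats::setNames(lox, ids),
    autosomal = stats::setNames(auto, ids),
    any_mca = stats::setNames(any_mca, ids),
    exposure4 = stats::setNames(as.character(exposure4), ids),
    decoys = decoy_tab,
    end_date = end_date,
    hazard = hz,
    latent_times = latent_times)

  structure(list(participants = participants, variant_evidence = evidence,
                 mca_calls = mca_calls, truth = truth, config = config),
            class = "cohort_bundle")
}

#' Status tables from the latent truth of a synthetic cohort
#'
#' Builds CHIP- and mCA-status tables directly from the generator's
#' latent carrier assignments, bypassing variant calling. Used in
#' parameter-recovery studies, where model error should not be
#' confounded with calling error.
#'
#' @param bundle A `cohort_bundle`.
#' @return List with `chip` and `mca` status data frames in the formats
#'   of [call_chip()] `$status` and [mca_status_table()].
#' @export
truth_status <- function(bundle) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  ids <- bundle$participants$participant_id
  tr <- bundle$truth
  chip <- data.frame(
    participant_id = ids, carrier = unname(tr$chip[ids]),
    n_mutations = as.integer(tr$chip[ids]), genes = "",
    max_vaf = 0, expanded = FALSE,
    mutation_count_class = factor(ifelse(tr$chip[ids], "1", "0"),
                                  levels = c("0", "1", "2", "3+")),
    stringsAsFactors = FALSE)
  mca <- data.frame(
    participant_id = ids, any_mca = unname(tr$any_mca[ids]),
    loy = unname(tr$loy[ids]), lox = unname(tr$lox[ids]),
    autosomal = unname(tr$autosomal[ids]), expanded = FALSE,
    max_cell_fraction = 0, stringsAsFactors = FALSE)
  list(chip = chip, mca = mca)
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$participants), "participants,",
      sum(x$truth$chip), "true CHIP carriers,",
      sum(x$truth$any_mca), "mCA carriers,",
      nrow(x$variant_evidence), "variant-evidence records\n")
  invisible(x)
}
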