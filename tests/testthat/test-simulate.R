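test_that("configuration validation rejects impossible study conditions", {
  expect_error(simulation_config(n_participants = 0), "positive integer")
  expect_error(simulation_config(chip_prevalence = 1.2), "proportion")
  expect_error(simulation_config(age_range = c(71, 40)))
  expect_error(simulation_config(
    vaf_distribution = list(floor = 0.01, shape1 = 1.5, shape2 = 8.6)),
    "0.02")
})

test_that("generation is deterministic given the seed", {
  cfg <- simulation_config(n_participants = 500, seed = 77)
  b1 <- generate_cohort(cfg)
  b2 <- generate_cohort(cfg)
  expect_identical(b1$participants, b2$participants)
  expect_identical(b1$variant_evidence, b2$variant_evidence)
  expect_identical(b1$mca_calls, b2$mca_calls)
  b3 <- generate_cohort(simulation_config(n_participants = 500, seed = 78))
  expect_false(identical(b1$participants, b3$participants))
})

test_that("zero CHIP prevalence yields no true clone evidence", {
  cfg <- simulation_config(n_participants = 400, seed = 5,
                           chip_prevalence = 0, decoy_fraction = 0,
                           recurrent_decoy_n = 0)
  b <- generate_cohort(cfg)
  expect_false(any(b$truth$chip))
  expect_equal(nrow(b$variant_evidence), 0)
})

test_that("realised prevalences track their targets", {
  cfg <- simulation_config(n_participants = 20000, seed = 13)
  b <- generate_cohort(cfg)
  se <- function(p) sqrt(p * (1 - p) / 20000)
  expect_lt(abs(mean(b$truth$chip) - 0.055), 3 * se(0.055))
  expect_lt(abs(mean(b$truth$any_mca) - 0.207), 4 * se(0.207))
  # clone-size skew: ~63% of carriers at VAF >= 0.10, VAF floor respected
  ev <- b$variant_evidence
  true_ids <- names(b$truth$chip)[b$truth$chip]
  tv <- ev[ev$participant_id %in%
             setdiff(true_ids, b$truth$decoys$participant_id), ]
  expect_true(all(tv$vaf >= 0.02 | tv$ad == 5))
  carrier_max <- tapply(tv$vaf, tv$participant_id, max)
  expect_equal(mean(carrier_max >= 0.10), 0.634, tolerance = 0.1)
})

test_that("CHIP prevalence increases across age deciles", {
  cfg <- simulation_config(n_participants = 30000, seed = 21)
  b <- generate_cohort(cfg)
  dec <- cut(b$participants$age_baseline,
             quantile(b$participants$age_baseline, 0:10 / 10),
             include.lowest = TRUE)
  prev <- tapply(b$truth$chip, dec, mean)
  expect_gt(prev[10], prev[1])
  expect_gt(cor(seq_along(prev), prev, method = "spearman"), 0.8)
})

test_that("LOY is depleted and LOX enriched among CHIP carriers", {
  cfg <- simulation_config(n_participants = 40000, seed = 29)
  b <- generate_cohort(cfg)
  tr <- b$truth
  men <- b$participants$sex == "M"
  or_loy <- (mean(tr$loy[men & tr$chip]) / (1 - mean(tr$loy[men & tr$chip]))) /
    (mean(tr$loy[men & !tr$chip]) / (1 - mean(tr$loy[men & !tr$chip])))
  expect_lt(or_loy, 0.85)
  women <- !men
  or_lox <- (mean(tr$lox[women & tr$chip]) /
               (1 - mean(tr$lox[women & tr$chip]))) /
    (mean(tr$lox[women & !tr$chip]) / (1 - mean(tr$lox[women & !tr$chip])))
  expect_gt(or_lox, 1)
})

test_that("null exposure hazards give exchangeable survival (log-rank)", {
  hz <- hazard_config(exposure_log_hr = lapply(
    setNames(endpoint_names(), endpoint_names()),
    function(e) c(chip_only = 0, mca_only = 0, both = 0)))
  pvals <- sapply(1:8, function(s) {
    b <- generate_cohort(simulation_config(n_participants = 3000, seed = s,
                                           decoy_fraction = 0,
                                           recurrent_decoy_n = 0,
                                           hazard = hz))
    tab <- truth_table(b)
    sd <- survival::survdiff(
      survival::Surv(time_any_death, event_any_death) ~ chip, data = tab)
    1 - pchisq(sd$chisq, 1)
  })
  # under the null, carrier/non-carrier curves differ only by noise:
  # p-values should not pile up near 0
  expect_gt(min(pvals), 0.001)
  expect_gt(mean(pvals > 0.05), 0.5)
})

test_that("bundles round-trip losslessly through VCF/TSV/JSON", {
  cfg <- simulation_config(n_participants = 600, seed = 61)
  b <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  back <- read_bundle(dir)
  ev1 <- b$variant_evidence
  ev1 <- ev1[order(ev1$participant_id, ev1$chrom, ev1$pos, ev1$ref,
                   ev1$alt), ]
  rownames(ev1) <- NULL
  expect_identical(ev1, back$variant_evidence)
  expect_equal(b$participants, back$participants, ignore_attr = TRUE)
  expect_equal(b$mca_calls, back$mca_calls, ignore_attr = TRUE)
  expect_equal(sum(unlist(back$truth$chip)), sum(b$truth$chip))
})

test_that("single-variant bundle encodes sample fields as DP:AD ref,alt", {
  cfg <- simulation_config(n_participants = 5, seed = 1,
                           chip_prevalence = 0, decoy_fraction = 0,
                           recurrent_decoy_n = 0)
  b <- generate_cohort(cfg)
  b$variant_evidence <- make_evidence("P000001", dp = 40, ad = 8,
                                      f1r2 = 4, f2r1 = 4)
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  lines <- readLines(gzfile(file.path(dir, "variant_evidence.vcf.gz")))
  body <- lines[!startsWith(lines, "##")]
  expect_match(body[1], "FORMAT\tP000001")
  expect_match(body[2], "GT:DP:AD:F1R2:F2R1")
  expect_match(body[2], "0/1:40:32,8:4:4")
})

test_that("empty bundles produce valid headed files", {
  cfg <- simulation_config(n_participants = 3, seed = 2,
                           chip_prevalence = 0, mca_loy_prevalence = 0,
                           mca_lox_prevalence = 0,
                           mca_autosomal_prevalence = 0,
                           decoy_fraction = 0, recurrent_decoy_n = 0)
  b <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  back <- read_bundle(dir)
  expect_equal(nrow(back$variant_evidence), 0)
  expect_equal(nrow(back$mca_calls), 0)
  expect_equal(nrow(back$participants), 3)
})

test_that("YAML configuration round-trips and honours the seed override", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_participants: 123", "seed: 9", "chip_prevalence: 0.08",
               "hazard:", "  horizon_years: 12"), path)
  cfg <- read_simulation_config(path)
  expect_equal(cfg$n_participants, 123)
  expect_equal(cfg$seed, 9L)
  expect_equal(cfg$chip_prevalence, 0.08)
  expect_equal(cfg$hazard$horizon_years, 12)
  cfg2 <- read_simulation_config(path, seed = 4)
  expect_equal(cfg2$seed, 4L)
})
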