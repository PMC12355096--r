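base_roster <- function(n = 6) {
  data.frame(participant_id = sprintf("P%02d", seq_len(n)),
             recruit_date = as.Date("2008-06-01"),
             hem_cancer_dx_date = as.Date(NA),
             genotypic_sex_concordant = TRUE,
             relative_pair_id = NA_character_,
             stringsAsFactors = FALSE)
}

test_that("hematologic cancers near study entry are excluded, remote ones kept", {
  r <- base_roster(3)
  r$hem_cancer_dx_date[1] <- r$recruit_date[1] + 90    # 3 months after
  r$hem_cancer_dx_date[2] <- r$recruit_date[2] - 365   # 12 months before
  out <- apply_exclusions(r)
  expect_false("P01" %in% out$participant_id)
  expect_true("P02" %in% out$participant_id)
  log <- attr(out, "exclusions")
  expect_equal(log$reason[log$participant_id == "P01"],
               "hematologic_cancer_within_6mo")
})

test_that("sex-discordant participants are excluded", {
  r <- base_roster(2)
  r$genotypic_sex_concordant[2] <- FALSE
  out <- apply_exclusions(r)
  expect_equal(out$participant_id, "P01")
})

test_that("relative pruning keeps exactly one per pair, deterministically", {
  r <- base_roster(6)
  r$relative_pair_id[c(1, 4)] <- "R1"
  r$relative_pair_id[c(2, 5)] <- "R2"
  out1 <- apply_exclusions(r, seed = 7)
  out2 <- apply_exclusions(r, seed = 7)
  expect_identical(out1$participant_id, out2$participant_id)
  expect_equal(sum(c("P01", "P04") %in% out1$participant_id), 1)
  expect_equal(sum(c("P02", "P05") %in% out1$participant_id), 1)
  # a different seed may keep the other member but still exactly one
  out3 <- apply_exclusions(r, seed = 99)
  expect_equal(sum(c("P01", "P04") %in% out3$participant_id), 1)
})

test_that("exclusion rules are order-independent (computed on the full roster)", {
  r <- base_roster(6)
  r$hem_cancer_dx_date[1] <- r$recruit_date[1]
  r$genotypic_sex_concordant[4] <- FALSE
  r$relative_pair_id[c(1, 3)] <- "R1"  # P01 also hits the hematologic rule
  out <- apply_exclusions(r, seed = 3)
  log <- attr(out, "exclusions")
  # P01 must be logged for the hematologic rule regardless of pruning,
  # and exactly one of the pair must be pruned
  expect_true("hematologic_cancer_within_6mo" %in%
                log$reason[log$participant_id == "P01"])
  expect_equal(sum(c("P01", "P03") %in%
                     log$participant_id[log$reason == "relative_pruning"]), 1)
})

test_that("time origin switches between recruitment and cancer diagnosis", {
  censor <- as.Date("2020-06-01")
  recruit <- as.Date("2010-06-01")
  # prevalent cancer: origin is the assessment visit (4 y = 1461 days)
  r1 <- derive_time_to_event(recruit, recruit - 730, recruit + 1461, censor)
  expect_equal(r1$origin_date, recruit)
  expect_equal(r1$time_years, 4, tolerance = 1e-9)
  expect_true(r1$event)
  # incident cancer: origin is the diagnosis date; censored at 8 years
  dx <- recruit + 365
  r2 <- derive_time_to_event(recruit, dx, as.Date(NA), dx + 2922)
  expect_equal(r2$origin_date, dx)
  expect_equal(r2$time_years, 8, tolerance = 1e-9)
  expect_false(r2$event)
  # event after the censoring date counts as censored
  r3 <- derive_time_to_event(recruit, recruit - 10, censor + 50, censor)
  expect_false(r3$event)
  expect_equal(r3$time_years,
               as.numeric(censor - recruit) / 365.25)
})

test_that("events before the time origin are flagged for dropping", {
  recruit <- as.Date("2010-06-01")
  dx <- recruit + 200
  r <- derive_time_to_event(recruit, dx, dx - 50, as.Date("2020-01-01"))
  expect_true(r$dropped)
  expect_false(r$event)
})

test_that("analysis table joins statuses, codes exposure and delay", {
  cfg <- simulation_config(n_participants = 1000, seed = 12)
  b <- generate_cohort(cfg)
  st <- truth_status(b)
  tab <- build_analysis_table(b$participants, st$chip, st$mca)
  # partition of the four-category exposure
  expect_equal(sum(table(tab$exposure4)), nrow(tab))
  expect_true(all(tab$exposure4[tab$chip & !tab$any_mca] == "chip_only"))
  expect_true(all(tab$exposure4[tab$chip & tab$loy] == "both"))
  # delay covariate: positive only for prevalent cancers
  prev <- tab$cancer_dx_date <= tab$recruit_date
  expect_true(all(tab$delay_days[!prev] == 0))
  expect_true(all(tab$delay_days[prev] ==
                    as.numeric(tab$recruit_date[prev] -
                                 tab$cancer_dx_date[prev])))
  # no negative times; censoring date shared
  tcols <- paste0("time_", endpoint_names())
  expect_true(all(sapply(tcols, function(cl) all(tab[[cl]] >= 0))))
  expect_s3_class(attr(tab, "censor_date"), "Date")
})

test_that("missing status rows for retained participants are a join error", {
  cfg <- simulation_config(n_participants = 200, seed = 2)
  b <- generate_cohort(cfg)
  st <- truth_status(b)
  expect_error(build_analysis_table(b$participants, st$chip[-1, ], st$mca),
               "missing CHIP/mCA status")
})
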