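test_that("interaction metrics satisfy their defining arithmetic", {
  # worked example from a published CV-death analysis:
  # HR(both) 1.090, HR(CHIP only) 1.073, HR(mCA only) 1.148
  expect_equal(round(compute_reri(1.090, 1.073, 1.148), 3), -0.131)
  expect_equal(round(compute_ap(compute_reri(1.090, 1.073, 1.148), 1.090), 3),
               -0.120)
  expect_equal(round(compute_mult_ratio(1.090, 1.073, 1.148), 3), 0.885)
  # nulls and exact arithmetic
  expect_equal(compute_reri(1, 1, 1), 0)
  expect_equal(compute_reri(2.0, 1.5, 1.3), 0.2)
  expect_equal(compute_ap(0, 1.7), 0)
  expect_equal(compute_ap(0.2, 2.0), 0.1)
  expect_equal(compute_mult_ratio(1, 1, 1), 1)
  expect_equal(compute_classical_si(3, 2, 2), 1.0)
  expect_equal(compute_classical_si(2.0, 1.5, 1.3), 1.25)
})

test_that("degenerate metric inputs are rejected or flagged", {
  expect_error(compute_reri(0, 1, 1), "hazard ratios")
  expect_error(compute_mult_ratio(1.1, -1, 1), "hazard ratios")
  expect_error(compute_ap(0.1, 0), "hazard ratios")
  expect_warning(si <- compute_classical_si(1, 1, 1), "undefined")
  expect_true(is.na(si))
})

test_that("Cox fit matches a brute-force partial-likelihood oracle", {
  # tiny printed fixture, no ties
  fx <- data.frame(
    participant_id = sprintf("F%d", 1:8),
    time_any_death = c(1.3, 2.1, 3.4, 4.0, 5.2, 6.7, 7.1, 8.5),
    event_any_death = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE),
    x = c(1, 0, 1, 1, 0, 0, 1, 0))
  fit <- fit_cox(fx, "any_death", exposure = "x", covariates = character(0),
                 min_events = 1)
  oracle <- optimize(cox_negloglik_oracle, c(-5, 5),
                     time = fx$time_any_death,
                     status = as.integer(fx$event_any_death), x = fx$x,
                     tol = 1e-12)$minimum
  expect_equal(unname(fit$beta["x"]), oracle, tolerance = 1e-6)
})

test_that("multiplicative ratio equals the exponentiated interaction term", {
  cfg <- simulation_config(n_participants = 3000, seed = 19)
  b <- generate_cohort(cfg)
  tab <- truth_table(b)
  f4 <- fit_cox(tab, "any_death", exposure = "ch4")
  fx <- fit_cox(tab, "any_death", exposure = "chip_x_mca")
  h <- exp(f4$beta[c("exposure4both", "exposure4chip_only",
                     "exposure4mca_only")])
  bint <- fx$beta[grep(":", names(fx$beta))]
  expect_equal(unname(compute_mult_ratio(h[1], h[2], h[3])),
               unname(exp(bint)), tolerance = 1e-10)
})

test_that("too few events and empty exposure categories raise named errors", {
  fx <- data.frame(time_cv_death = 1:20 / 2,
                   event_cv_death = rep(c(TRUE, rep(FALSE, 4)), 4),
                   x = rep(0:1, 10))
  expect_error(fit_cox(fx, "cv_death", exposure = "x",
                       covariates = character(0), min_events = 10),
               "only 4 events")
  tab <- data.frame(time_any_death = runif(60, 1, 5),
                    event_any_death = rep(c(TRUE, FALSE), 30),
                    exposure4 = factor(rep(c("no_ch", "chip_only"), 30),
                                       levels = c("no_ch", "chip_only",
                                                  "mca_only", "both")))
  tab$event_any_death[tab$exposure4 == "chip_only"] <- FALSE
  expect_error(fit_cox(tab, "any_death", exposure = "ch4",
                       covariates = character(0), min_events = 1),
               "chip_only")
})

test_that("delta and bootstrap intervals agree on a well-powered cohort", {
  cfg <- simulation_config(n_participants = 4000, seed = 25)
  b <- generate_cohort(cfg)
  tab <- truth_table(b)
  fit <- fit_cox(tab, "incident_cvd", exposure = "ch4",
                 covariates = c("age_baseline", "sex"))
  d <- interaction_ci(fit, "reri", method = "delta")
  bs <- interaction_ci(fit, "reri", method = "bootstrap", n_boot = 400,
                       seed = 4)
  expect_equal(d$estimate, bs$estimate)
  w_d <- d$high - d$low
  w_b <- bs$high - bs$low
  expect_lt(abs(w_d - w_b) / w_d, 0.15)
})

test_that("interaction report flags endpoints with empty cells as nr", {
  cfg <- simulation_config(n_participants = 1500, seed = 33)
  b <- generate_cohort(cfg)
  tab <- truth_table(b)
  # force zero events in the 'both' cell for CV death
  tab$event_cv_death[tab$exposure4 == "both"] <- FALSE
  rep <- run_interaction_analysis(tab, endpoints = c("cv_death", "any_death"),
                                  pair = "chip_mca")
  expect_false(any(rep$endpoints$cv_death$metrics$reportable))
  expect_match(rep$endpoints$cv_death$note, "both")
  expect_true(all(rep$endpoints$any_death$metrics$reportable[1:3]))
})

test_that("sex-chromosome pairs restrict the cohort by sex", {
  cfg <- simulation_config(n_participants = 4000, seed = 3)
  b <- generate_cohort(cfg)
  tab <- truth_table(b)
  rep <- run_interaction_analysis(tab, endpoints = "any_death",
                                  pair = "chip_lox")
  fit <- rep$endpoints$any_death$cox
  expect_equal(fit$n, sum(tab$sex == "F" & tab$smoking != "unknown"))
  expect_false(any(grepl("sex", fit$terms)))
})
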