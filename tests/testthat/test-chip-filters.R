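wl <- load_whitelist()

test_that("depth filter enforces DP/AD and both read-pair orientations", {
  ev <- rbind(
    make_evidence(dp = 20, ad = 5, f1r2 = 2, f2r1 = 3),   # at boundary
    make_evidence(dp = 19, ad = 10, f1r2 = 5, f2r1 = 5),  # DP one short
    make_evidence(dp = 100, ad = 6, f1r2 = 6, f2r1 = 0),  # one-sided strand
    make_evidence(dp = 40, ad = 4, f1r2 = 2, f2r1 = 2))   # AD one short
  v <- depth_filter(ev)
  expect_equal(v$kept, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(v$failed_rules[2], "depth_dp")
  expect_equal(v$failed_rules[3], "depth_f2r1")
  expect_equal(v$failed_rules[4], "depth_ad")
})

test_that("ill-formed evidence is rejected", {
  ev <- make_evidence(dp = 10, ad = 12)
  ev$vaf <- 1
  expect_error(depth_filter(ev), "ad")
  ev2 <- make_evidence()
  ev2$vaf <- 0.9  # breaks vaf == ad/dp
  expect_error(depth_filter(ev2), "vaf")
  ev3 <- make_evidence(context = "ACGT")
  expect_error(depth_filter(ev3), "context")
})

test_that("homopolymer rule removes weakly supported sites in 5-base runs", {
  run_ctx <- "GCAAAAAGTCA"  # centre base inside an A5 run
  ev <- rbind(
    make_evidence(dp = 40, ad = 8, f1r2 = 4, f2r1 = 4, context = run_ctx),
    make_evidence(dp = 80, ad = 12, f1r2 = 6, f2r1 = 6, context = run_ctx),
    make_evidence(dp = 100, ad = 5, f1r2 = 2, f2r1 = 3))
  v <- homopolymer_filter(ev)
  # ad 8 < 10 -> removed despite vaf 0.20
  expect_false(v$kept[1])
  # ad 12 >= 10 and vaf 0.15 >= 0.08 -> kept
  expect_true(v$kept[2])
  # no run in context: rule not applicable even at vaf 0.05
  expect_true(v$kept[3])
})

test_that("homopolymer detection sees runs adjacent to the variant", {
  # run of 5 ends immediately left of the centre base
  adj <- "AAAAACGTCGT"
  far <- "AAAAGCGTCGT"  # run of only 4
  v <- homopolymer_filter(rbind(
    make_evidence(dp = 40, ad = 8, f1r2 = 4, f2r1 = 4, context = adj),
    make_evidence(dp = 40, ad = 8, f1r2 = 4, f2r1 = 4, context = far)))
  expect_false(v$kept[1])
  expect_true(v$kept[2])
})

test_that("named artifacts are removed per their VAF scope", {
  p72r_hi <- make_evidence(gene = "TP53", hgvs_p = "p.P72R", chrom = "17",
                           pos = 7571216L, dp = 60, ad = 27, f1r2 = 13,
                           f2r1 = 14)
  g646_lo <- make_evidence(gene = "ASXL1", hgvs_p = "p.G646Wfs*12",
                           chrom = "20", pos = 32359938L, ref = "CA",
                           alt = "C", dp = 60, ad = 3, f1r2 = 1, f2r1 = 2,
                           consequence = "frameshift")
  g646_hi <- make_evidence(gene = "ASXL1", hgvs_p = "p.G646Wfs*12",
                           chrom = "20", pos = 32359938L, ref = "CA",
                           alt = "C", dp = 60, ad = 12, f1r2 = 6, f2r1 = 6,
                           consequence = "frameshift")
  ev <- rbind(p72r_hi, g646_lo, g646_hi)
  v <- named_artifact_filter(ev, wl)
  expect_equal(v$kept, c(FALSE, FALSE, TRUE))
  # "all" scope: the VAF < 0.1 condition applies to every named artifact,
  # so high-VAF P72R survives this rule
  v_all <- named_artifact_filter(ev, wl, scope = "all")
  expect_equal(v_all$kept, c(TRUE, FALSE, TRUE))
})

test_that("binomial somatic test removes germline-like missense calls", {
  ev <- rbind(
    make_evidence(ad = 5, dp = 20, f1r2 = 2, f2r1 = 3),       # p ~ 0.041
    make_evidence(gene = "TET2", hgvs_p = "p.C1193W", chrom = "4",
                  pos = 105236579L, ad = 30, dp = 60, f1r2 = 15,
                  f2r1 = 15),                                  # p = 1
    make_evidence(gene = "TET2", hgvs_p = "p.H1904R", chrom = "4",
                  pos = 105238712L, ad = 30, dp = 60, f1r2 = 15,
                  f2r1 = 15),                                  # exempt
    make_evidence(gene = "JAK2", hgvs_p = "p.V617F", chrom = "9",
                  pos = 5022851L, ad = 30, dp = 60, f1r2 = 15,
                  f2r1 = 15))                                  # not tested
  v <- binomial_somatic_test(ev, wl)
  expect_false(v$kept[1])
  expect_equal(v$detail[1], 0.0414, tolerance = 1e-3)
  expect_false(v$kept[2])
  expect_equal(v$detail[2], 1)
  expect_true(v$kept[3])   # TET2 p.H1904R exempt
  expect_true(is.na(v$detail[3]))
  expect_true(v$kept[4])   # gene outside CBL/TET2/DNMT3A/TP53
})

test_that("binomial p-values equal the combinatorial summation oracle", {
  cases <- expand.grid(dp = c(20, 37, 100, 250, 500),
                       frac = c(0.1, 0.25, 0.4, 0.5))
  for (i in seq_len(nrow(cases))) {
    dp <- cases$dp[i]
    ad <- max(5, round(cases$frac[i] * dp))
    ev <- make_evidence(dp = dp, ad = ad, f1r2 = 2, f2r1 = 2)
    p <- binomial_somatic_test(ev, wl)$detail
    expect_equal(p, binom_two_sided_oracle(ad, dp), tolerance = 1e-12)
  }
})

test_that("recurrence filter skips rare variants and keeps age-selected ones", {
  ph <- make_phenotypes(4000, seed = 9)
  # 15 carriers: below the >20 threshold, kept untested
  few <- sample(ph$participant_id, 15)
  r1 <- recurrence_filter(rep("v1", 15), few, ph)
  expect_true(r1$kept)
  expect_false(r1$tested)
  # 200 carriers enriched in older participants: age association detected
  set.seed(2)
  w <- plogis(0.1 * (ph$age_baseline - 60))
  old <- sample(ph$participant_id, 200, prob = w)
  r2 <- recurrence_filter(rep("v2", 200), old, ph)
  expect_true(r2$tested)
  expect_true(r2$kept)
  expect_lte(r2$p_age, 0.1)
})

test_that("either/both combination rules differ as configured", {
  ph <- make_phenotypes(3000, seed = 4)
  set.seed(8)
  # age-selected but TERT-independent carriers
  w <- plogis(0.15 * (ph$age_baseline - 60))
  carriers <- sample(ph$participant_id, 300, prob = w)
  r_either <- recurrence_filter(rep("v", 300), carriers, ph,
                                combine = "either")
  expect_true(r_either$kept)
  if (r_either$p_tert > 0.1) {
    r_both <- recurrence_filter(rep("v", 300), carriers, ph,
                                combine = "both")
    expect_false(r_both$kept)
  }
})
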