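wl <- load_whitelist()

test_that("call_chip aggregates surviving variants into carrier status", {
  ph <- make_phenotypes(5)
  ev <- rbind(
    make_evidence("P0001", dp = 50, ad = 6, f1r2 = 3, f2r1 = 3),   # vaf 0.12
    make_evidence("P0002", gene = "TET2", hgvs_p = "p.C1193W", chrom = "4",
                  pos = 105236579L, dp = 60, ad = 6, f1r2 = 3, f2r1 = 3),
    make_evidence("P0002", gene = "ASXL1", hgvs_p = "p.R693*", chrom = "20",
                  pos = 32360079L, alt = "A", dp = 40, ad = 6, f1r2 = 3,
                  f2r1 = 3, consequence = "nonsense"))
  cc <- call_chip(ev, wl, ph)
  st <- cc$status
  expect_equal(nrow(st), 5)
  # P0001: one surviving DNMT3A variant at vaf 0.12 -> expanded carrier
  p1 <- st[st$participant_id == "P0001", ]
  expect_true(p1$carrier)
  expect_equal(p1$n_mutations, 1L)
  expect_true(p1$expanded)
  expect_equal(as.character(p1$mutation_count_class), "1")
  # P0002: two genes, max vaf 0.15
  p2 <- st[st$participant_id == "P0002", ]
  expect_equal(p2$n_mutations, 2L)
  expect_equal(p2$genes, "ASXL1,TET2")
  # participants with no candidates: clean non-carriers
  p3 <- st[st$participant_id == "P0003", ]
  expect_false(p3$carrier)
  expect_equal(p3$n_mutations, 0L)
  expect_false(p3$expanded)
})

test_that("the audit trail lists every failed rule, not just the first", {
  ph <- make_phenotypes(3)
  # fails depth (dp 15), homopolymer (in run, ad < 10) and the binomial
  # test (vaf near 0.5) at once
  bad <- make_evidence("P0001", dp = 15, ad = 7, f1r2 = 3, f2r1 = 4,
                       context = "GCAAAAAGTCA")
  cc <- call_chip(bad, wl, ph)
  rules <- strsplit(cc$audit$failed_rules, ";")[[1]]
  expect_true(all(c("depth_dp", "homopolymer", "binomial_germline") %in%
                    rules))
  expect_false(cc$audit$kept)
})

test_that("duplicate (participant, variant) records are an input error", {
  ph <- make_phenotypes(2)
  ev <- rbind(make_evidence("P0001"), make_evidence("P0001"))
  expect_error(call_chip(ev, wl, ph), "duplicate")
})

test_that("call_chip is idempotent on its own surviving call set", {
  cfg <- simulation_config(n_participants = 1500, seed = 31)
  b <- generate_cohort(cfg)
  cc1 <- call_chip(b$variant_evidence, wl, b$participants)
  cc2 <- call_chip(cc1$calls, wl, b$participants)
  expect_equal(cc2$calls, cc1$calls, ignore_attr = TRUE)
  expect_equal(cc2$status, cc1$status)
})

test_that("per-variant verdicts commute: rule order cannot matter", {
  # each per-variant filter depends only on the variant record, so
  # applying them in any order to a shuffled table gives the same kept set
  cfg <- simulation_config(n_participants = 800, seed = 17)
  b <- generate_cohort(cfg)
  ev <- b$variant_evidence
  perm <- sample(nrow(ev))
  key <- function(e) paste(e$participant_id, e$chrom, e$pos, e$alt)
  kept_fwd <- key(ev)[depth_filter(ev)$kept &
                        homopolymer_filter(ev)$kept &
                        named_artifact_filter(ev, wl)$kept &
                        binomial_somatic_test(ev, wl)$kept]
  evp <- ev[perm, ]
  kept_rev <- key(evp)[binomial_somatic_test(evp, wl)$kept &
                         named_artifact_filter(evp, wl)$kept &
                         homopolymer_filter(evp)$kept &
                         depth_filter(evp)$kept]
  expect_setequal(kept_fwd, kept_rev)
})

test_that("empty evidence yields all-non-carrier status", {
  ph <- make_phenotypes(4)
  cc <- call_chip(make_evidence()[0, ], wl, ph)
  expect_equal(nrow(cc$status), 4)
  expect_false(any(cc$status$carrier))
  expect_equal(nrow(cc$audit), 0)
})
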