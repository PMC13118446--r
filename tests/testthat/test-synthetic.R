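test_that("invalid configurations are rejected with the offending field named", {
  expect_error(synthetic_config(n_cases = 0), "n_cases")
  expect_error(synthetic_config(sex_probs = c(F = 0.5, M = 0.4)), "sex_probs")
  expect_error(synthetic_config(dup_prob = 1.5), "dup_prob")
  expect_error(synthetic_config(pts_per_report_mean = 0.5),
               "pts_per_report_mean")
  expect_error(
    synthetic_config(planted_rr = tibble::tibble(drug = "nosuch",
                                                 pt = "Nausea", rr = 2)),
    "planted_rr")
  expect_error(
    synthetic_config(planted_rr = tibble::tibble(drug = "amlodipine",
                                                 pt = "Nausea", rr = -1)),
    "planted_rr")
})

test_that("identical seeds reproduce identical bundles, different seeds differ", {
  cfg <- synthetic_config(n_cases = 1000, dup_prob = 0, seed = 7)
  b1 <- suppressMessages(generate_reports(cfg))
  b2 <- suppressMessages(generate_reports(cfg))
  expect_identical(b1$demo, b2$demo)
  expect_identical(b1$drug, b2$drug)
  expect_identical(b1$reac, b2$reac)
  b3 <- suppressMessages(generate_reports(
    synthetic_config(n_cases = 1000, dup_prob = 0, seed = 8)))
  expect_false(identical(b1$demo$primaryid, b3$demo$primaryid))
})

test_that("row counts reconcile: DEMO = cases + follow-ups; ids resolve", {
  cfg <- synthetic_config(n_cases = 2000, dup_prob = 0.3, seed = 21)
  b <- suppressMessages(generate_reports(cfg))
  n_cases <- length(unique(b$demo$caseid))
  expect_equal(n_cases, 2000)
  n_followups <- nrow(b$demo) - n_cases
  expect_gt(n_followups, 0)
  expect_true(all(b$drug$primaryid %in% b$demo$primaryid))
  expect_true(all(b$reac$primaryid %in% b$demo$primaryid))
  expect_true(all(b$outc$primaryid %in% b$demo$primaryid))
  expect_true(all(b$indi$primaryid %in% b$demo$primaryid))
  # every case version carries at least one reaction and one PS drug
  ps <- b$drug[b$drug$role_cod == "PS", ]
  expect_true(all(b$demo$primaryid %in% ps$primaryid))
  expect_true(all(b$demo$primaryid %in% b$reac$primaryid))
})

test_that("follow-ups share caseid with a later fda_dt and larger primaryid", {
  cfg <- synthetic_config(n_cases = 1500, dup_prob = 0.4, seed = 9)
  b <- suppressMessages(generate_reports(cfg))
  versions <- dplyr::add_count(b$demo, caseid)
  dups <- versions[versions$n == 2, ]
  by_case <- split(dups, dups$caseid)
  expect_gt(length(by_case), 0)
  for (v in by_case[1:min(200, length(by_case))]) {
    ord <- order(as.numeric(v$primaryid))
    expect_lt(v$fda_dt[ord[1]], v$fda_dt[ord[2]])
  }
})

test_that("null model expectations: unit ROR everywhere, product-rule cells", {
  cfg <- synthetic_config(n_cases = 10000, seed = 1)
  gt <- expected_cells(cfg, pairs = tibble::tibble(
    drug = c("amlodipine", "felodipine"), pt = c("Nausea", "Tinnitus")))
  expect_true(all(abs(gt$ror - 1) < 1e-9))
  expect_true(all(abs(gt$prr - 1) < 1e-9))
  # single-drug, single-PT product rule
  cat1 <- tibble::tibble(ingredient = "amlodipine", synonyms = list("NORVASC"),
                         class = "target", exposure_prob = 0.5)
  pt1 <- tibble::tibble(pt = c("Headache", "Other"), prob = c(0.1, 0.9))
  cfg1 <- synthetic_config(n_cases = 1000, drug_catalog = cat1,
                           pt_catalog = pt1, pts_per_report_mean = 1,
                           seed = 1)
  gt1 <- expected_cells(cfg1, pairs = tibble::tibble(drug = "amlodipine",
                                                     pt = "Headache"))
  full <- gt1[gt1$background == "full", ]
  retention <- 0.40 + 0.12 + 0.18
  # exposure 0.5 plus forced assignment of unexposed cases: all cases
  # carry the only drug, so expected a = n_pairs * p(PT)
  expect_equal(full$a, 1000 * retention * 1 * 0.1, tolerance = 1e-9)
})

test_that("planted multiplier appears in the expected PRR in the rare-PT limit", {
  cfg <- recovery_config(seed = 1)
  gt <- expected_cells(cfg)
  full <- gt[gt$background == "full", ]
  # renormalisation shrinks the realised ratio to r / (1 + p (r - 1))
  expect_equal(full$prr, 8 / (1 + 0.002 * 7), tolerance = 1e-6)
  expect_gt(full$prr, 0.98 * 8 / (1 + 0.002 * 7))
})

test_that("generated counts track the analytic expectation for a planted pair", {
  cfg <- recovery_config(seed = 31)
  res <- run_recovery_pipeline(cfg)
  gt <- expected_cells(cfg)
  full <- gt[gt$background == "full", ]
  # empirical rate ratio within 15% of the planted multiplier
  emp_rr <- (res$a / (res$a + res$b)) / (res$c / (res$c + res$d))
  expect_lt(abs(emp_rr - 8) / 8, 0.15)
  # cells within sampling error of the analytic ground truth
  expect_lt(abs(res$a - full$a) / full$a, 0.2)
})
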