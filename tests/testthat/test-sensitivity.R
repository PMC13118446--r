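test_that("excluding co-medicated reports removes a confounded signal", {
  co <- confounded_cohort()
  tabs <- contingency_tables(co, drugs = "amlodipine",
                             pts = "Completed suicide")
  primary <- suppressWarnings(evaluate_signals(tabs))
  expect_true(primary$consensus)  # the spurious signal is there

  co2 <- exclude_comedication(co, c("sertraline"))
  tabs2 <- suppressMessages(contingency_tables(co2, drugs = "amlodipine",
                                               pts = "Completed suicide"))
  sens <- suppressWarnings(evaluate_signals(tabs2))
  expect_false(sens$consensus)

  rep <- compare_runs(primary, sens)
  expect_false(rep$persisted)
  expect_equal(attr(rep, "summary")$n_lost, 1L)
})

test_that("co-medication exclusion validates input and is idempotent", {
  co <- confounded_cohort(n = 500, seed = 3)
  expect_error(exclude_comedication(co, character(0)), "nonempty")
  once <- exclude_comedication(co, c("sertraline"))
  twice <- exclude_comedication(once, c("sertraline"))
  expect_equal(once$reports, twice$reports)
  expect_lte(nrow(once$reports), nrow(co$reports))
})

test_that("pregnancy filter keeps PS target reports and drops flagged indications", {
  demo <- tibble::tibble(
    primaryid = paste0(1:4, "1"), caseid = as.character(1:4),
    fda_dt = 20200101L, sex = "F", age = 30, age_cod = "YR",
    occp_cod = "MD", reporter_country = "US")
  drug <- tibble::tibble(
    primaryid = paste0(1:4, "1"), drug_seq = 1L,
    role_cod = c("PS", "SS", "PS", "PS"),
    drugname = c("D", "D", "D", "E"), prod_ai = c("D", "D", "D", "E"))
  reac <- tibble::tibble(primaryid = paste0(1:4, "1"), pt = "X")
  indi <- tibble::tibble(primaryid = c("31"), indi_pt = "Pre-eclampsia")
  co <- suppressMessages(build_cohort(
    make_bundle(demo, drug, reac, indi = indi),
    dictionary = toy_dictionary()))
  out <- exclude_pregnancy_indications(co)
  # report 2: target carried as SS only -> removed
  # report 3: pregnancy indication -> removed
  expect_setequal(out$reports$primaryid, c("11", "41"))
})

test_that("physician stratification keeps exactly the MD reports", {
  cfg <- synthetic_config(n_cases = 1000, seed = 5)
  b <- suppressMessages(generate_reports(cfg))
  co <- suppressMessages(build_cohort(b, dictionary = attr(b, "dictionary")))
  md <- stratify_physician(co)
  expect_true(all(md$reports$occupation == "MD"))
  expect_equal(nrow(md$reports), sum(co$reports$occupation == "MD"))
  expect_equal(stratify_physician(md)$reports, md$reports)
})

test_that("exclusion operators are monotone, idempotent and commute", {
  for (s in 1:10) {
    cfg <- synthetic_config(n_cases = 400, seed = 100 + s)
    b <- suppressMessages(generate_reports(cfg))
    co <- suppressMessages(build_cohort(b, dictionary = attr(b, "dictionary")))
    f1 <- function(x) exclude_comedication(x, default_psychotropics())
    f2 <- exclude_pregnancy_indications
    f3 <- stratify_physician
    a <- f3(f2(f1(co)))
    bb <- f1(f3(f2(co)))
    cc <- f2(f1(f3(co)))
    expect_setequal(a$reports$primaryid, bb$reports$primaryid)
    expect_setequal(a$reports$primaryid, cc$reports$primaryid)
    expect_true(all(a$reports$primaryid %in% co$reports$primaryid))
    again <- f3(f2(f1(a)))
    expect_setequal(again$reports$primaryid, a$reports$primaryid)
  }
})

test_that("run comparison on identical inputs shows zero deltas", {
  co <- toy_cohort()
  tabs <- contingency_tables(co, drugs = "D")
  res <- suppressWarnings(evaluate_signals(tabs))
  rep <- compare_runs(res, res)
  expect_true(all(rep$delta_ror == 0))
  expect_true(all(rep$persisted == rep$consensus_before))
  expect_equal(attr(rep, "summary")$n_lost, 0L)
})

test_that("a pair falling below the minimum count is lost with reason min_count", {
  primary <- suppressWarnings(evaluate_signals(
    tibble::tibble(drug = "D", pt = "X", background = "full",
                   a = 10, b = 90, c = 100, d = 9900)))
  sens <- suppressWarnings(evaluate_signals(
    tibble::tibble(drug = "D", pt = "X", background = "full",
                   a = 2, b = 90, c = 100, d = 9900)))
  rep <- compare_runs(primary, sens)
  expect_false(rep$persisted)
  expect_equal(rep$lost_reason, "min_count")
  expect_error(compare_runs(primary, sens[0, ]), "same")
})
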