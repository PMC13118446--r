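# small helper: simulate a case-noncase design directly from a logistic
# model, used to check estimation independently of the FAERS pipeline
simulate_design <- function(n, beta_drug = log(2), intercept = qlogis(0.05),
                            seed = 1) {
  withr::with_seed(seed, {
    drug <- factor(sample(c("amlodipine", "felodipine"), n, replace = TRUE,
                          prob = c(0.7, 0.3)), levels = c("amlodipine",
                                                          "felodipine"))
    sex <- factor(sample(c("M", "F"), n, replace = TRUE), levels = c("M", "F"))
    age_group <- factor(sample(c("18-44", "45-64", ">75"), n, replace = TRUE),
                        levels = c("18-44", "45-64", ">75"))
    eta <- intercept + beta_drug * (drug == "felodipine") +
      0.2 * (sex == "F") + 0.3 * (age_group == "45-64") +
      0.5 * (age_group == ">75")
    y <- rbinom(n, 1, plogis(eta))
    tibble::tibble(y = y, drug = drug, sex = sex, age_group = age_group)
  })
}

test_that("a single-predictor fit equals the 2x2 odds ratio exactly", {
  df <- tibble::tibble(
    y = rep(c(1, 0, 1, 0), c(30, 270, 20, 680)),
    drug = factor(rep(c("felodipine", "felodipine", "amlodipine",
                        "amlodipine"), c(30, 270, 20, 680)),
                  levels = c("amlodipine", "felodipine")))
  fit <- fit_case_noncase(df, predictors = "drug")
  or_tab <- (30 * 680) / (270 * 20)
  est <- tidy(fit)
  expect_equal(est$aor[est$term == "drugfelodipine"], or_tab,
               tolerance = 1e-8)
  # and it agrees with the disproportionality ROR point
  expect_equal(est$aor[est$term == "drugfelodipine"],
               compute_ror(30, 270, 20, 680)$ror, tolerance = 1e-8)
})

test_that("the design encodes outcomes, factors and reference levels", {
  cfg <- synthetic_config(
    n_cases = 3000,
    planted_rr = tibble::tibble(drug = "amlodipine",
                                pt = "Completed suicide", rr = 6),
    seed = 11)
  b <- suppressMessages(generate_reports(cfg))
  co <- suppressMessages(build_cohort(b, dictionary = attr(b, "dictionary")))
  des <- suppressMessages(build_design(co, "Completed suicide"))
  expect_setequal(unique(des$y), c(0L, 1L))
  expect_equal(levels(des$drug)[1], "amlodipine")
  expect_equal(levels(des$sex)[1], "M")
  expect_equal(levels(des$age_group)[1], "18-44")
  expect_equal(levels(des$occupation)[1], "MD")
  # outcome marks exactly the reports whose PT set holds the outcome PT
  case_ids <- co$pts$primaryid[co$pts$pt == "Completed suicide"]
  expect_setequal(des$primaryid[des$y == 1],
                  intersect(des$primaryid, case_ids))
})

test_that("reports with several target drugs are excluded from the design", {
  cfg <- synthetic_config(n_cases = 4000, seed = 23)
  b <- suppressMessages(generate_reports(cfg))
  co <- suppressMessages(build_cohort(b, dictionary = attr(b, "dictionary")))
  des <- suppressMessages(build_design(co, "Nausea"))
  targets <- target_drugs(co$dictionary)
  n_multi <- co$drugs |>
    dplyr::filter(ingredient %in% targets) |>
    dplyr::distinct(primaryid, ingredient) |>
    dplyr::count(primaryid) |>
    dplyr::filter(n > 1) |>
    nrow()
  expect_equal(attr(des, "n_excluded_multi"), n_multi)
  expect_false(any(des$primaryid %in% (
    co$drugs |>
      dplyr::filter(ingredient %in% targets) |>
      dplyr::distinct(primaryid, ingredient) |>
      dplyr::count(primaryid) |>
      dplyr::filter(n > 1) |>
      dplyr::pull(primaryid))))
})

test_that("estimates are invariant to row order", {
  df <- simulate_design(5000, seed = 42)
  fit1 <- fit_case_noncase(df, predictors = c("drug", "sex", "age_group"))
  df2 <- df[rev(seq_len(nrow(df))), ]
  fit2 <- fit_case_noncase(df2, predictors = c("drug", "sex", "age_group"))
  expect_equal(tidy(fit1)$estimate, tidy(fit2)$estimate, tolerance = 1e-10)
})

test_that("degenerate outcomes and missing events are refused", {
  df <- simulate_design(200, seed = 2)
  df$y <- 0L
  expect_error(fit_case_noncase(df), "at least one event")
})

test_that("a planted twofold drug effect is recovered with a sane interval", {
  df <- simulate_design(50000, beta_drug = log(2), seed = 7)
  fit <- fit_case_noncase(df, predictors = c("drug", "sex", "age_group"))
  est <- tidy(fit)
  row <- est[est$term == "drugfelodipine", ]
  expect_lt(row$aor_low, 2)
  expect_gt(row$aor_high, 2)
  expect_lt(abs(row$aor - 2), 0.3)
  g <- glance(fit)
  expect_true(g$converged)
  expect_equal(g$n, 50000)
})
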