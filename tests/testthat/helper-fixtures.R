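# Hand-built fixtures used across test files. Everything is constructed
# in code; no data files.

make_bundle <- function(demo, drug, reac,
                        outc = tibble::tibble(primaryid = character(0),
                                              outc_cod = character(0)),
                        indi = tibble::tibble(primaryid = character(0),
                                              indi_pt = character(0))) {
  structure(list(demo = demo, drug = drug, reac = reac,
                 outc = outc, indi = indi),
            class = "faers_bundle")
}

# dictionary with two toy target drugs D and E
toy_dictionary <- function() {
  tibble::tibble(ingredient = c("D", "E"), synonym = c("D", "E"),
                 class = "target")
}

# three reports: R1 carries D with PTs {X, Y}; R2 carries D with {X};
# R3 carries E with {X, Z}
toy_bundle <- function() {
  make_bundle(
    demo = tibble::tibble(
      primaryid = c("11", "21", "31"), caseid = c("1", "2", "3"),
      fda_dt = c(20200101L, 20200102L, 20200103L),
      sex = c("F", "M", "F"), age = c(50, 60, 70),
      age_cod = "YR", occp_cod = c("MD", "PH", "HP"),
      reporter_country = c("US", "US", "FR")),
    drug = tibble::tibble(
      primaryid = c("11", "21", "31"), drug_seq = 1L, role_cod = "PS",
      drugname = c("D", "D", "E"), prod_ai = c("D", "D", "E")),
    reac = tibble::tibble(
      primaryid = c("11", "11", "21", "31", "31"),
      pt = c("X", "Y", "X", "X", "Z"))
  )
}

toy_cohort <- function() {
  suppressMessages(build_cohort(toy_bundle(), dictionary = toy_dictionary()))
}

# random valid 2x2 tables with a >= a_min, for property checks
random_tables <- function(n, a_min = 3, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      a = a_min + rpois(n, 40),
      b = 1 + rpois(n, 400),
      c = 1 + rpois(n, 150),
      d = 1000 + rpois(n, 50000)
    )
  })
}

# the benchmark parameter-recovery configuration: one target drug at
# exposure 0.05 with an eight-fold planted multiplier on a PT whose
# baseline probability is 0.002
recovery_config <- function(seed, n_cases = 200000) {
  cat_tbl <- tibble::tibble(
    ingredient = c("felodipine", "amlodipine", "lisinopril", "metformin"),
    synonyms = list("PLENDIL", "NORVASC", character(0), character(0)),
    class = c("target", "target", "other", "other"),
    exposure_prob = c(0.05, 0.10, 0.15, 0.12))
  pt_tbl <- tibble::tibble(
    pt = c(sprintf("Common PT %02d", 1:10), "Rare event"),
    prob = c(rep(0.0998, 10), 0.002))
  synthetic_config(
    n_cases = n_cases, drug_catalog = cat_tbl, pt_catalog = pt_tbl,
    planted_rr = tibble::tibble(drug = "felodipine", pt = "Rare event",
                                rr = 8),
    seed = seed)
}

# a cohort where a suicide-type PT rides along only with a listed
# co-medication: the target drug shows a spurious signal that must
# vanish once co-medicated reports are excluded
confounded_cohort <- function(n = 4000, seed = 1) {
  withr::with_seed(seed, {
    primaryid <- as.character(seq_len(n) * 10 + 1)
    caseid <- as.character(seq_len(n))
    target <- runif(n) < 0.15
    comed <- ifelse(target, runif(n) < 0.6, runif(n) < 0.1)
    event <- comed & runif(n) < 0.25   # event only via the co-medication
    filler_pt <- sample(c("Nausea", "Headache", "Dizziness", "Rash"), n,
                        replace = TRUE)
    demo <- tibble::tibble(
      primaryid = primaryid, caseid = caseid, fda_dt = 20200101L,
      sex = "F", age = 50, age_cod = "YR", occp_cod = "MD",
      reporter_country = "US")
    drug <- dplyr::bind_rows(
      tibble::tibble(primaryid = primaryid, drug_seq = 1L, role_cod = "PS",
                     drugname = ifelse(target, "AMLODIPINE", "LISINOPRIL"),
                     prod_ai = ifelse(target, "AMLODIPINE", "LISINOPRIL")),
      tibble::tibble(primaryid = primaryid[comed], drug_seq = 2L,
                     role_cod = "SS", drugname = "SERTRALINE",
                     prod_ai = "SERTRALINE"))
    reac <- dplyr::bind_rows(
      tibble::tibble(primaryid = primaryid, pt = filler_pt),
      tibble::tibble(primaryid = primaryid[event], pt = "Completed suicide"))
    dict <- tibble::tibble(ingredient = "amlodipine",
                           synonym = "AMLODIPINE", class = "target")
    suppressMessages(build_cohort(make_bundle(demo, drug, reac),
                                  dictionary = dict))
  })
}

run_recovery_pipeline <- function(cfg) {
  b <- suppressMessages(generate_reports(cfg))
  co <- suppressMessages(build_cohort(b, dictionary = attr(b, "dictionary")))
  ct <- contingency_tables(co, drugs = "felodipine", pts = "Rare event")
  suppressWarnings(evaluate_signals(ct))
}
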