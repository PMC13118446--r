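#' Default synthetic drug catalog
#'
#' Drugs emulating the study setting: the four target dihydropyridines,
#' one further class member (so the class background is a strict
#' superset of the targets), common co-medications including an
#' antidepressant and an antipsychotic (used by the sensitivity
#' filters), and unrelated background drugs.
#'
#' @return Tibble with columns `ingredient`, `synonyms` (list column),
#'   `class` (`"target"`, `"class_background"` or `"other"`) and
#'   `exposure_prob`.
#' @export
default_drug_catalog <- function() {
  tibble(
    ingredient = c("amlodipine", "felodipine", "nicardipine", "nifedipine",
                   "nimodipine", "lisinopril", "metformin", "sertraline",
                   "quetiapine"),
    synonyms = list("NORVASC", "PLENDIL", "CARDENE", "ADALAT",
                    "NIMOTOP", character(0), character(0), "ZOLOFT",
                    "SEROQUEL"),
    class = c(rep("target", 4), "class_background", rep("other", 4)),
    exposure_prob = c(0.12, 0.02, 0.01, 0.04, 0.01, 0.20, 0.18, 0.08, 0.04)
  )
}

#' Default synthetic PT catalog
#'
#' Baseline multinomial over preferred terms: a mix of common
#' non-specific terms and the rare, clinically specific terms the study
#' drugs are screened for. Probabilities sum to one.
#'
#' @return Tibble with columns `pt`, `prob`.
#' @export
default_pt_catalog <- function() {
  pts <- tibble(
    pt = c("Nausea", "Headache", "Dizziness", "Fatigue", "Vomiting",
           "Diarrhoea", "Rash", "Pruritus", "Dyspnoea", "Oedema peripheral",
           "Hypotension", "Fall", "Malaise", "Pyrexia", "Pain",
           "Drug ineffective", "Off label use", "Drug interaction",
           "Palpitations", "Tinnitus", "Bradycardia", "Hyperkalaemia",
           "Hyponatraemia", "Completed suicide", "Suicide attempt",
           "Premature delivery", "Premature baby",
           "Cerebral vasoconstriction", "Angioedema", "Migraine"),
    prob = c(0.10, 0.09, 0.08, 0.07, 0.06,
             0.05, 0.05, 0.04, 0.05, 0.04,
             0.05, 0.04, 0.04, 0.04, 0.04,
             0.05, 0.03, 0.02,
             0.015, 0.010, 0.010, 0.008,
             0.007, 0.004, 0.004,
             0.003, 0.002,
             0.001, 0.004, 0.003)
  )
  pts$prob <- pts$prob / sum(pts$prob)
  pts
}

check_prob_vector <- function(p, field, sum_to_one = TRUE) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort(paste0("configuration error in '", field,
                 "': probabilities must lie in [0, 1]"))
  }
  if (sum_to_one && abs(sum(p) - 1) > 1e-9) {
    abort(paste0("configuration error in '", field,
                 "': probabilities must sum to 1"))
  }
  invisible(p)
}

#' Configuration of the synthetic report generator
#'
#' Fully specifies the generative model: case count, drug catalog with
#' per-drug exposure probabilities, baseline PT multinomial, planted
#' per-(drug, PT) reporting-rate multipliers, the per-report PT count
#' distribution (1 + Poisson(`pts_per_report_mean` - 1), truncated at
#' the catalog size), the follow-up duplicate process, reporter and
#' demographic categoricals, field-level missingness, and the RNG seed.
#'
#' @param n_cases Number of distinct cases (>= 1).
#' @param drug_catalog Tibble as [default_drug_catalog()].
#' @param pt_catalog Tibble as [default_pt_catalog()].
#' @param planted_rr Tibble with columns `drug`, `pt`, `rr` (rate
#'   multipliers >= 0); unlisted pairs default to 1.
#' @param pts_per_report_mean Mean PT count per report (>= 1).
#' @param dup_prob Probability a case emits one follow-up version.
#' @param occupation_probs,sex_probs,age_group_probs,country_probs
#'   Named categorical probability vectors (must sum to 1).
#' @param outcome_probs Named categorical over outcome codes plus
#'   `"none"`.
#' @param indication_probs Named categorical over indication PTs plus
#'   `"none"`; the indication attaches to the primary-suspect drug.
#' @param missingness_probs Named vector: per-field blanking
#'   probability for `sex`, `age`, `country`.
#' @param seed Integer RNG seed.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_cases = 20000,
    drug_catalog = default_drug_catalog(),
    pt_catalog = default_pt_catalog(),
    planted_rr = NULL,
    pts_per_report_mean = 2,
    dup_prob = 0.2,
    occupation_probs = c(MD = 0.40, PH = 0.12, HP = 0.18, CN = 0.25,
                         LW = 0.01, unknown = 0.04),
    sex_probs = c(F = 0.55, M = 0.43, unknown = 0.02),
    age_group_probs = c("<18" = 0.04, "18-44" = 0.20, "45-64" = 0.33,
                        "65-75" = 0.24, ">75" = 0.15, unknown = 0.04),
    country_probs = c(US = 0.45, GB = 0.12, CA = 0.10, FR = 0.10,
                      JP = 0.08, DE = 0.05, other = 0.10),
    outcome_probs = c(none = 0.35, OT = 0.25, HO = 0.20, DE = 0.07,
                      LT = 0.05, DS = 0.03, CA = 0.02, RI = 0.03),
    indication_probs = c(none = 0.55, "Hypertension" = 0.30,
                         "Angina pectoris" = 0.05,
                         "Raynaud's phenomenon" = 0.02,
                         "Gestational hypertension" = 0.03,
                         "Pre-eclampsia" = 0.02,
                         "Premature labour" = 0.03),
    missingness_probs = c(sex = 0.01, age = 0.08, country = 0.02),
    seed = 1L) {
  if (!is.numeric(n_cases) || length(n_cases) != 1 || n_cases < 1) {
    abort("configuration error in 'n_cases': need a positive integer")
  }
  stopifnot(is.data.frame(drug_catalog),
            all(c("ingredient", "class", "exposure_prob") %in%
                  names(drug_catalog)),
            is.data.frame(pt_catalog),
            all(c("pt", "prob") %in% names(pt_catalog)))
  check_prob_vector(drug_catalog$exposure_prob, "drug_catalog$exposure_prob",
                    sum_to_one = FALSE)
  check_prob_vector(pt_catalog$prob, "pt_catalog$prob")
  check_prob_vector(occupation_probs, "occupation_probs")
  check_prob_vector(sex_probs, "sex_probs")
  check_prob_vector(age_group_probs, "age_group_probs")
  check_prob_vector(country_probs, "country_probs")
  check_prob_vector(outcome_probs, "outcome_probs")
  check_prob_vector(indication_probs, "indication_probs")
  check_prob_vector(missingness_probs, "missingness_probs",
                    sum_to_one = FALSE)
  check_prob_vector(dup_prob, "dup_prob", sum_to_one = FALSE)
  if (pts_per_report_mean < 1) {
    abort("configuration error in 'pts_per_report_mean': must be >= 1")
  }
  if (is.null(planted_rr)) {
    planted_rr <- tibble(drug = character(0), pt = character(0),
                         rr = numeric(0))
  }
  stopifnot(all(c("drug", "pt", "rr") %in% names(planted_rr)))
  if (any(planted_rr$rr < 0)) {
    abort("configuration error in 'planted_rr': multipliers must be >= 0")
  }
  if (!all(planted_rr$drug %in% drug_catalog$ingredient)) {
    abort("configuration error in 'planted_rr': unknown drug")
  }
  if (!all(planted_rr$pt %in% pt_catalog$pt)) {
    abort("configuration error in 'planted_rr': unknown pt")
  }
  structure(list(
    n_cases = as.integer(n_cases), drug_catalog = drug_catalog,
    pt_catalog = pt_catalog, planted_rr = as_tibble(planted_rr),
    pts_per_report_mean = pts_per_report_mean, dup_prob = dup_prob,
    occupation_probs = occupation_probs, sex_probs = sex_probs,
    age_group_probs = age_group_probs, country_probs = country_probs,
    outcome_probs = outcome_probs, indication_probs = indication_probs,
    missingness_probs = missingness_probs, seed = as.integer(seed)),
    class = "synthetic_config")
}

#' Dictionary matching a synthetic configuration
#'
#' Builds the drug dictionary implied by a config's catalog: targets and
#' class members with their synonyms, so [build_cohort()] resolves the
#' generator's own drug mentions.
#'
#' @param config A [synthetic_config()].
#' @return Dictionary tibble (`ingredient`, `synonym`, `class`).
#' @export
config_dictionary <- function(config) {
  cat_tbl <- config$drug_catalog
  cls <- dplyr::recode(cat_tbl$class, target = "target",
                       class_background = "class", other = "other")
  keep <- cls %in% c("target", "class")
  purrr::pmap(list(cat_tbl$ingredient[keep],
                   cat_tbl$synonyms[keep] %||% list(),
                   cls[keep]),
              function(ing, syn, cl) {
                tibble(ingredient = ing,
                       synonym = toupper(c(ing, unlist(syn))), class = cl)
              }) |>
    bind_rows() |>
    distinct()
}

sample_cat <- function(n, probs) {
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

#' Generate a synthetic FAERS-dialect report bundle
#'
#' Draws `n_cases` spontaneous reports from the generative model in
#' `config`: independent per-drug exposure (every case is guaranteed at
#' least one drug, which becomes the primary suspect), per-report PT
#' sets drawn from the baseline multinomial re-weighted by the planted
#' multipliers of the drugs on the report, demographics, outcomes and
#' indications from their categoricals, and a follow-up duplicate
#' process in which a case emits a second version with a strictly later
#' `fda_dt`, a larger `primaryid` and possibly one mutated field.
#' Identical seeds give identical bundles.
#'
#' @param config A [synthetic_config()].
#' @return A `faers_bundle` (tibbles `demo`, `drug`, `reac`, `outc`,
#'   `indi`) with attributes `ground_truth` (see [expected_cells()])
#'   and `dictionary`.
#' @export
generate_reports <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_cases
  cat_tbl <- config$drug_catalog
  drugs <- cat_tbl$ingredient
  nd <- length(drugs)
  pt_tbl <- config$pt_catalog
  npt <- nrow(pt_tbl)

  ## --- exposure matrix (cases x drugs) ---
  expo <- matrix(rbinom(n * nd, 1, rep(cat_tbl$exposure_prob, each = n)) == 1,
                 nrow = n)
  none <- !matrixStats_rowAnys(expo)
  if (any(none)) {
    forced <- sample.int(nd, sum(none), replace = TRUE,
                         prob = cat_tbl$exposure_prob)
    expo[cbind(which(none), forced)] <- TRUE
  }

  ## --- primary-suspect drug: one random exposed drug per case ---
  rmat <- matrix(runif(n * nd), nrow = n)
  rmat[!expo] <- -Inf
  ps_idx <- max.col(rmat)

  ## --- PT sets: group cases by their planted-multiplier signature ---
  rr_tbl <- config$planted_rr
  rr_drugs <- unique(rr_tbl$drug)
  rr_idx <- match(rr_drugs, drugs)
  sig <- if (length(rr_idx) == 0) rep(0, n) else
    as.vector(matrix(expo[, rr_idx], nrow = n) %*% 2^(seq_along(rr_idx) - 1))
  k <- 1L + rpois(n, config$pts_per_report_mean - 1)
  k <- pmin(k, npt)
  case_pts <- vector("list", length(unique(sig)))
  groups <- split(seq_len(n), sig)
  gi <- 0
  for (g in groups) {
    gi <- gi + 1
    mult <- rep(1, npt)
    if (length(rr_idx) > 0) {
      active <- rr_drugs[expo[g[1], rr_idx]]
      if (length(active) > 0) {
        sub <- rr_tbl[rr_tbl$drug %in% active, ]
        agg <- tapply(sub$rr, sub$pt, prod)
        mult[match(names(agg), pt_tbl$pt)] <- as.numeric(agg)
      }
    }
    q <- pt_tbl$prob * mult
    q <- q / sum(q)
    tot <- sum(k[g])
    draws <- sample.int(npt, tot, replace = TRUE, prob = q)
    case_pts[[gi]] <- tibble(case = rep(g, k[g]), pt_i = draws)
  }
  pair_tbl <- bind_rows(case_pts) |> distinct()

  ## --- identifiers and dates ---
  # id block depends on the seed so distinct seeds yield distinct
  # primaryid sequences; stays well inside exact-double range
  caseid_num <- (abs(as.numeric(config$seed)) %% 1009 + 1) * 1e7 + seq_len(n)
  caseid <- as.character(caseid_num)
  primaryid <- as.character(caseid_num * 10 + 1)
  pid2 <- as.character(caseid_num * 10 + 2)
  date_pool <- seq(as.Date("2014-07-01"), as.Date("2024-12-31"), by = "day")
  date_int_pool <- as.integer(format(date_pool, "%Y%m%d"))
  # originals leave 90 days of head-room so a follow-up is always
  # strictly later yet still inside the study window
  date_idx <- sample.int(length(date_pool) - 90L, n, replace = TRUE)

  ## --- demographics ---
  sex <- sample_cat(n, config$sex_probs)
  agegrp <- sample_cat(n, config$age_group_probs)
  bin_lo <- c("<18" = 1, "18-44" = 18, "45-64" = 44.5, "65-75" = 64.5,
              ">75" = 75.5, unknown = NA)
  bin_hi <- c("<18" = 17.5, "18-44" = 44, "45-64" = 64, "65-75" = 75,
              ">75" = 95, unknown = NA)
  u <- runif(n)
  age_years <- unname(bin_lo[agegrp] + u * (bin_hi[agegrp] - bin_lo[agegrp]))
  unit <- sample_cat(n, c(YR = 0.90, MON = 0.04, DEC = 0.04, DY = 0.02))
  unit_mult <- c(YR = 1, MON = 12, DEC = 0.1, DY = 365.25)
  age_val <- round(unname(age_years * unit_mult[unit]), 2)
  occp <- sample_cat(n, config$occupation_probs)
  country <- sample_cat(n, config$country_probs)

  miss <- config$missingness_probs
  blank <- function(x, p) {
    if (is.na(p) || p <= 0) return(x)
    x[runif(length(x)) < p] <- NA
    x
  }
  sex[sex == "unknown"] <- NA
  occp[occp == "unknown"] <- NA
  sex <- blank(sex, miss["sex"])
  age_val <- blank(age_val, miss["age"])
  unit[is.na(age_val)] <- NA
  country <- blank(country, miss["country"])

  demo <- tibble(
    primaryid = primaryid, caseid = caseid,
    fda_dt = date_int_pool[date_idx],
    sex = sex, age = age_val, age_cod = unit, occp_cod = occp,
    reporter_country = country
  )

  ## --- follow-up duplicates ---
  dup <- runif(n) < config$dup_prob
  if (any(dup)) {
    fu <- demo[dup, ]
    fu$primaryid <- pid2[dup]
    fu_idx <- date_idx[dup] + sample.int(90, sum(dup), replace = TRUE)
    fu$fda_dt <- date_int_pool[fu_idx]
    # one field may mutate between versions
    flip <- runif(sum(dup)) < 0.5
    new_sex <- fu$sex[flip]
    new_sex[is.na(new_sex) | new_sex != "F"] <- "F"
    new_sex[!is.na(fu$sex[flip]) & fu$sex[flip] == "F"] <- "M"
    fu$sex[flip] <- new_sex
    demo <- bind_rows(demo, fu)
  }

  ## --- DRUG rows: every exposed drug on each version ---
  which_expo <- which(expo, arr.ind = TRUE)
  ord <- order(which_expo[, 1], which_expo[, 2])
  which_expo <- which_expo[ord, , drop = FALSE]
  ncase <- which_expo[, 1]
  ndrug <- which_expo[, 2]
  is_ps <- ps_idx[ncase] == ndrug
  other_roles <- sample(c("SS", "I"), length(ncase), replace = TRUE,
                        prob = c(0.8, 0.2))
  role <- other_roles
  role[is_ps] <- "PS"
  # prod_ai carries an occasional salt suffix; drugname an occasional brand
  drugs_up <- toupper(drugs)
  ing_up <- drugs_up[ndrug]
  salted <- runif(length(ncase)) < 0.25 & drugs[ndrug] == "amlodipine"
  prod_ai <- ing_up
  prod_ai[salted] <- paste(ing_up[salted], "BESYLATE")
  syns <- cat_tbl$synonyms
  has_brand <- lengths(syns)[ndrug] > 0
  use_brand <- runif(length(ncase)) < 0.3 & has_brand
  brand1 <- vapply(syns, function(s) if (length(s)) toupper(s[[1]]) else "",
                   character(1))
  drugname <- ing_up
  drugname[use_brand] <- brand1[ndrug][use_brand]
  drug_seq <- sequence(rle(ncase)$lengths)  # ncase is sorted
  drug_one <- tibble(
    case = ncase, drug_seq = drug_seq, role_cod = role,
    drugname = drugname, prod_ai = prod_ai
  )
  drug_rows <- bind_rows(
    drug_one |> mutate(primaryid = primaryid[.data$case]),
    drug_one[dup[drug_one$case], ] |>
      mutate(primaryid = pid2[.data$case])
  ) |>
    select("primaryid", "drug_seq", "role_cod", "drugname", "prod_ai")

  ## --- REAC rows ---
  reac_one <- pair_tbl |> mutate(pt = pt_tbl$pt[.data$pt_i])
  reac_rows <- bind_rows(
    reac_one |> mutate(primaryid = primaryid[.data$case]),
    reac_one[dup[reac_one$case], ] |>
      mutate(primaryid = pid2[.data$case])
  ) |>
    select("primaryid", "pt")

  ## --- OUTC rows ---
  outc_draw <- sample_cat(n, config$outcome_probs)
  has_outc <- outc_draw != "none"
  outc_one <- tibble(case = which(has_outc), outc_cod = outc_draw[has_outc])
  outc_rows <- bind_rows(
    outc_one |> mutate(primaryid = primaryid[.data$case]),
    outc_one[dup[outc_one$case], ] |>
      mutate(primaryid = pid2[.data$case])
  ) |>
    select("primaryid", "outc_cod")

  ## --- INDI rows (attached to the PS drug's drug_seq) ---
  indi_draw <- sample_cat(n, config$indication_probs)
  has_indi <- indi_draw != "none"
  ps_seq <- drug_one |>
    filter(.data$role_cod == "PS") |>
    distinct(.data$case, .keep_all = TRUE)
  indi_one <- tibble(case = which(has_indi), indi_pt = indi_draw[has_indi]) |>
    left_join(ps_seq |> select("case", "drug_seq"), by = "case")
  indi_rows <- bind_rows(
    indi_one |> mutate(primaryid = primaryid[.data$case]),
    indi_one[dup[indi_one$case], ] |>
      mutate(primaryid = pid2[.data$case])
  ) |>
    select("primaryid", indi_drug_seq = "drug_seq", "indi_pt")

  bundle <- structure(
    list(demo = demo, drug = drug_rows, reac = reac_rows,
         outc = outc_rows, indi = indi_rows),
    class = "faers_bundle")
  attr(bundle, "ground_truth") <- expected_cells(config)
  attr(bundle, "dictionary") <- config_dictionary(config)
  bundle
}

# base-R stand-in for matrixStats::rowAnys on a logical matrix
matrixStats_rowAnys <- function(m) rowSums(m) > 0

#' Analytic expected 2x2 cells under the generative model
#'
#' Closed-form first-order expectations of the (report, PT)-pair cells
#' for every planted (drug, PT) pair (plus any extra pairs requested),
#' under both backgrounds. Exposures are independent across drugs, so
#' for a drug with exposure probability p_D the expected pair universe
#' is N x retention x E\[k\], of which a fraction p_D lies on exposed
#' reports; within exposed reports the PT multinomial is the baseline
#' re-weighted by the drug's planted multipliers and renormalised. The
#' expectations ignore the within-report deduplication of repeated PT
#' draws and rare forced exposures, so they are exact in the rare-PT
#' limit and first-order accurate otherwise.
#'
#' @param config A [synthetic_config()].
#' @param pairs Optional tibble (`drug`, `pt`) of extra pairs; defaults
#'   to the planted pairs.
#' @return Tibble: `drug`, `pt`, `background`, `rr` (planted
#'   multiplier), `a`, `b`, `c`, `d`, `n` (real-valued expectations),
#'   plus `ror` and `prr` implied by the expectations.
#' @export
expected_cells <- function(config, pairs = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  cat_tbl <- config$drug_catalog
  pt_tbl <- config$pt_catalog
  rr_tbl <- config$planted_rr
  if (is.null(pairs)) {
    pairs <- rr_tbl |> select("drug", "pt")
    if (nrow(pairs) == 0) {
      pairs <- tidyr::expand_grid(
        drug = cat_tbl$ingredient[cat_tbl$class == "target"],
        pt = pt_tbl$pt[1]
      )
    }
  }
  retention <- sum(config$occupation_probs[c("MD", "PH", "HP")], na.rm = TRUE)
  ek <- 1 + (config$pts_per_report_mean - 1)  # Poisson mean, untruncated
  n_reports <- config$n_cases * retention
  n_pairs_total <- n_reports * ek

  # effective exposure: independent draw plus the forced single drug
  # assigned (proportionally) to cases that drew no drug at all
  p_raw <- setNames(cat_tbl$exposure_prob, cat_tbl$ingredient)
  p_none <- prod(1 - p_raw)
  p_eff <- p_raw + p_none * p_raw / sum(p_raw)

  q_given <- function(drug) {
    # PT multinomial conditional on exposure to `drug`; other planted
    # drugs enter at their exposure-weighted average multiplier
    mult <- rep(1, nrow(pt_tbl))
    own <- rr_tbl[rr_tbl$drug == drug, ]
    mult[match(own$pt, pt_tbl$pt)] <- own$rr
    others <- rr_tbl[rr_tbl$drug != drug, ]
    if (nrow(others) > 0) {
      p_exp <- p_eff
      for (i in seq_len(nrow(others))) {
        j <- match(others$pt[i], pt_tbl$pt)
        mult[j] <- mult[j] * (1 + p_exp[others$drug[i]] * (others$rr[i] - 1))
      }
    }
    q <- pt_tbl$prob * mult
    q / sum(q)
  }
  q_without <- function(drug) {
    mult <- rep(1, nrow(pt_tbl))
    others <- rr_tbl[rr_tbl$drug != drug, ]
    if (nrow(others) > 0) {
      p_exp <- p_eff
      for (i in seq_len(nrow(others))) {
        j <- match(others$pt[i], pt_tbl$pt)
        mult[j] <- mult[j] * (1 + p_exp[others$drug[i]] * (others$rr[i] - 1))
      }
    }
    q <- pt_tbl$prob * mult
    q / sum(q)
  }

  p_exp <- p_eff
  is_class <- cat_tbl$class %in% c("target", "class_background")
  p_class <- 1 - prod(1 - cat_tbl$exposure_prob[is_class])

  one_bg <- function(drug, pt, background) {
    p_d <- p_exp[[drug]]
    p_universe <- if (background == "full") 1 else p_class
    p_not_d <- p_universe - p_d
    qg <- q_given(drug)
    qw <- q_without(drug)
    j <- match(pt, pt_tbl$pt)
    a <- n_pairs_total * p_d * qg[j]
    b <- n_pairs_total * p_d * (1 - qg[j])
    c <- n_pairs_total * p_not_d * qw[j]
    d <- n_pairs_total * p_not_d * (1 - qw[j])
    rr <- rr_tbl$rr[rr_tbl$drug == drug & rr_tbl$pt == pt]
    tibble(drug = drug, pt = pt, background = background,
           rr = if (length(rr)) rr else 1,
           a = a, b = b, c = c, d = d, n = a + b + c + d,
           ror = (a * d) / (b * c),
           prr = (a / (a + b)) / (c / (c + d)))
  }
  purrr::pmap(tidyr::expand_grid(pairs, background = c("full", "class")),
              function(drug, pt, background) one_bg(drug, pt, background)) |>
    bind_rows()
}
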