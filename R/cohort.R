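#' Deduplicate FAERS case versions
#'
#' FAERS stores follow-up submissions as new report versions
#' (`primaryid`) of the same case (`caseid`). Per the FDA-recommended
#' rule, only the version with the most recent `fda_dt` is kept; when
#' several versions share that date the one with the largest
#' `primaryid` wins. Rows missing `caseid`, `primaryid` or `fda_dt` are
#' dropped before selection. The result does not depend on input order.
#'
#' @param demo Tibble with columns `primaryid`, `caseid`, `fda_dt`.
#' @return Tibble of the kept rows, one per `caseid`.
#' @export
deduplicate_cases <- function(demo) {
  stopifnot(all(c("primaryid", "caseid", "fda_dt") %in% names(demo)))
  demo |>
    filter(!is.na(.data$caseid), !is.na(.data$primaryid), !is.na(.data$fda_dt)) |>
    mutate(.pid_num = suppressWarnings(as.numeric(.data$primaryid))) |>
    arrange(.data$caseid, dplyr::desc(.data$fda_dt), dplyr::desc(.data$.pid_num)) |>
    distinct(.data$caseid, .keep_all = TRUE) |>
    select(-".pid_num")
}

#' Age bins used for demographic summaries and regression
#'
#' Half-open bins: `<18` is \[0, 18), `18-44` is \[18, 44\], `45-64` is
#' (44, 64\], `65-75` is (64, 75\], `>75` is (75, Inf); missing age maps
#' to `"unknown"`.
#'
#' @param age_years Numeric age in years.
#' @return Character vector of bin labels.
#' @export
age_group <- function(age_years) {
  dplyr::case_when(
    is.na(age_years) ~ "unknown",
    age_years < 18 ~ "<18",
    age_years <= 44 ~ "18-44",
    age_years <= 64 ~ "45-64",
    age_years <= 75 ~ "65-75",
    TRUE ~ ">75"
  )
}

#' Build the cleaned analysis cohort from a raw bundle
#'
#' Applies the full cleaning chain: records missing `caseid`,
#' `primaryid` or `fda_dt` are excluded; case versions are deduplicated
#' with [deduplicate_cases()]; reports are restricted to the retained
#' reporter occupations (physician `MD`, pharmacist `PH`, other health
#' professional `HP`); drug mentions are restricted to suspect or
#' interacting roles (`PS`, `SS`, `I`) and resolved against the
#' dictionary; reports with no remaining dictionary-resolved PT or drug
#' context are kept only if they still have at least one reaction PT.
#'
#' @param bundle A `faers_bundle` (tibbles `demo`, `drug`, `reac`, and
#'   optionally `outc`, `indi`).
#' @param dictionary Drug dictionary tibble; defaults to
#'   [dhp_dictionary()].
#' @param occupations Reporter occupation codes retained.
#' @param roles Drug role codes that qualify a mention.
#' @return A `faers_cohort`: list of tibbles `reports` (one row per
#'   case: `caseid`, `primaryid`, `fda_dt`, `sex`, `age_years`,
#'   `age_group`, `occupation`, `country`), `drugs` (per report x
#'   matched ingredient with best `role`), `drug_mentions` (all
#'   qualifying raw mentions), `pts`, `indications`, `outcomes`.
#' @export
build_cohort <- function(bundle, dictionary = dhp_dictionary(),
                         occupations = c("MD", "PH", "HP"),
                         roles = c("PS", "SS", "I")) {
  demo <- as_tibble(bundle$demo)
  kept <- deduplicate_cases(demo)
  kept <- kept |> filter(.data$occp_cod %in% occupations)

  mentions <- as_tibble(bundle$drug) |>
    semi_join(kept, by = "primaryid") |>
    filter(.data$role_cod %in% roles)

  # a report with no qualifying (suspect/interacting) drug mention is dropped
  kept <- kept |> semi_join(mentions, by = "primaryid")

  reac <- as_tibble(bundle$reac) |>
    filter(!is.na(.data$pt)) |>
    semi_join(kept, by = "primaryid") |>
    distinct(.data$primaryid, .data$pt)

  # a FAERS report must carry at least one reaction
  kept <- kept |> semi_join(reac, by = "primaryid")
  mentions <- mentions |> semi_join(kept, by = "primaryid")

  matched <- match_drug_table(mentions, dictionary)
  role_rank <- c(PS = 1, SS = 2, I = 3)
  drugs <- matched |>
    mutate(.rank = role_rank[.data$role_cod]) |>
    arrange(.data$primaryid, .data$ingredient, .data$.rank) |>
    distinct(.data$primaryid, .data$ingredient, .keep_all = TRUE) |>
    mutate(role = .data$role_cod) |>
    select("primaryid", "ingredient", "role")

  age_yr <- if (all(c("age", "age_cod") %in% names(kept))) {
    suppressWarnings(age_in_years(as.numeric(kept$age), kept$age_cod))
  } else {
    rep(NA_real_, nrow(kept))
  }
  reports <- kept |>
    mutate(
      sex = dplyr::coalesce(.data$sex, "unknown"),
      age_years = age_yr,
      age_group = age_group(age_yr),
      occupation = .data$occp_cod,
      country = if ("reporter_country" %in% names(kept))
        dplyr::coalesce(.data$reporter_country, "unknown") else "unknown"
    ) |>
    select("caseid", "primaryid", "fda_dt", "sex", "age_years",
           "age_group", "occupation", "country")

  outc <- if (!is.null(bundle$outc)) {
    as_tibble(bundle$outc) |> semi_join(kept, by = "primaryid") |>
      distinct(.data$primaryid, .data$outc_cod)
  } else {
    tibble(primaryid = character(0), outc_cod = character(0))
  }
  indi <- if (!is.null(bundle$indi)) {
    as_tibble(bundle$indi) |> semi_join(kept, by = "primaryid") |>
      filter(!is.na(.data$indi_pt)) |>
      distinct(.data$primaryid, .data$indi_pt)
  } else {
    tibble(primaryid = character(0), indi_pt = character(0))
  }

  cohort <- structure(
    list(reports = reports, drugs = drugs, drug_mentions = mentions,
         pts = reac, indications = indi, outcomes = outc,
         dictionary = dictionary),
    class = "faers_cohort")
  if (nrow(reports) == 0) {
    warn("empty cohort: no reports survived cleaning")
  }
  cohort
}

#' @export
print.faers_cohort <- function(x, ...) {
  cat(sprintf("<faers_cohort> %d reports, %d (report, PT) pairs, %d drug flags\n",
              nrow(x$reports), nrow(x$pts), nrow(x$drugs)))
  invisible(x)
}

# Restrict a cohort to a subset of primaryids, keeping all component
# tables consistent. Internal workhorse for the sensitivity filters.
subset_cohort <- function(cohort, keep_primaryid) {
  keep <- tibble(primaryid = keep_primaryid)
  out <- cohort
  out$reports <- semi_join(cohort$reports, keep, by = "primaryid")
  out$drugs <- semi_join(cohort$drugs, keep, by = "primaryid")
  out$drug_mentions <- semi_join(cohort$drug_mentions, keep, by = "primaryid")
  out$pts <- semi_join(cohort$pts, keep, by = "primaryid")
  out$indications <- semi_join(cohort$indications, keep, by = "primaryid")
  out$outcomes <- semi_join(cohort$outcomes, keep, by = "primaryid")
  out
}
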