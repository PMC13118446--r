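#' Default psychotropic co-medication list
#'
#' Common antidepressant (ATC N06A) and antipsychotic (N05A) active
#' ingredients, used by [exclude_comedication()] to probe confounding
#' of suicide-related signals. Editable: pass any character vector.
#'
#' @return Uppercase character vector of ingredient names.
#' @export
default_psychotropics <- function() {
  toupper(c(
    "sertraline", "fluoxetine", "paroxetine", "citalopram", "escitalopram",
    "venlafaxine", "desvenlafaxine", "duloxetine", "mirtazapine",
    "bupropion", "trazodone", "amitriptyline", "nortriptyline",
    "clomipramine", "vortioxetine",
    "quetiapine", "olanzapine", "risperidone", "paliperidone",
    "aripiprazole", "haloperidol", "clozapine", "ziprasidone",
    "lurasidone", "chlorpromazine", "lithium"
  ))
}

#' Default pregnancy-related indication PT list
#'
#' Indications naming pregnancy-related conditions or tocolysis, used
#' by [exclude_pregnancy_indications()].
#'
#' @return Character vector of indication PT labels.
#' @export
default_pregnancy_indications <- function() {
  c("Gestational hypertension", "Pre-eclampsia", "Preeclampsia",
    "Eclampsia", "Premature labour", "Tocolysis",
    "Pregnancy maintenance", "HELLP syndrome")
}

# match any qualifying raw drug mention of a report against a name list
reports_mentioning <- function(cohort, ingredient_list) {
  suffixes <- getOption("faersignal.salt_suffixes", default_salt_suffixes())
  lst <- toupper(trimws(ingredient_list))
  m <- cohort$drug_mentions
  strings <- unique(c(m$prod_ai, m$drugname))
  strings <- strings[!is.na(strings)]
  hit_string <- vapply(strings, function(s) {
    comps <- split_components(normalize_drug_string(s))
    comps <- vapply(comps, strip_salt, character(1), suffixes = suffixes)
    any(comps %in% lst)
  }, logical(1))
  hits <- strings[hit_string]
  m |>
    filter(.data$prod_ai %in% hits | .data$drugname %in% hits) |>
    distinct(.data$primaryid)
}

#' Exclude reports co-mentioning listed drugs
#'
#' Removes every report with any drug mention (any role) whose active
#' ingredient or verbatim name matches the list, after the same
#' normalisation as dictionary matching. Monotone and idempotent.
#'
#' @param cohort A `faers_cohort`.
#' @param ingredient_list Nonempty character vector of ingredient
#'   names; defaults to [default_psychotropics()].
#' @return The filtered `faers_cohort`.
#' @export
exclude_comedication <- function(cohort,
                                 ingredient_list = default_psychotropics()) {
  stopifnot(inherits(cohort, "faers_cohort"))
  if (length(ingredient_list) == 0) {
    abort("ingredient_list must be nonempty")
  }
  drop <- reports_mentioning(cohort, ingredient_list)
  keep <- setdiff(cohort$reports$primaryid, drop$primaryid)
  subset_cohort(cohort, keep)
}

#' Restrict to primary-suspect use and exclude pregnancy indications
#'
#' For pregnancy-signal robustness: keeps only reports where at least
#' one target drug has role `PS`, then removes reports whose indication
#' set intersects the pregnancy-related list. Monotone and idempotent.
#'
#' @param cohort A `faers_cohort`.
#' @param pregnancy_pt_list Indication PT labels to exclude; defaults
#'   to [default_pregnancy_indications()].
#' @return The filtered `faers_cohort`.
#' @export
exclude_pregnancy_indications <- function(
    cohort, pregnancy_pt_list = default_pregnancy_indications()) {
  stopifnot(inherits(cohort, "faers_cohort"))
  if (length(pregnancy_pt_list) == 0) {
    abort("pregnancy_pt_list must be nonempty")
  }
  targets <- target_drugs(cohort$dictionary)
  # a report that carries a target drug must carry it as PS; reports
  # without any target drug stay in the background universe untouched
  target_status <- cohort$drugs |>
    filter(.data$ingredient %in% targets) |>
    group_by(.data$primaryid) |>
    summarise(has_ps = any(.data$role == "PS"), .groups = "drop")
  non_ps <- target_status |> filter(!.data$has_ps)
  preg <- cohort$indications |>
    filter(tolower(.data$indi_pt) %in% tolower(pregnancy_pt_list)) |>
    distinct(.data$primaryid)
  keep <- setdiff(cohort$reports$primaryid,
                  union(non_ps$primaryid, preg$primaryid))
  subset_cohort(cohort, keep)
}

#' Restrict to physician-submitted reports
#'
#' @param cohort A `faers_cohort`.
#' @return The cohort restricted to occupation code `MD`.
#' @export
stratify_physician <- function(cohort) {
  stopifnot(inherits(cohort, "faers_cohort"))
  keep <- cohort$reports$primaryid[cohort$reports$occupation == "MD"]
  subset_cohort(cohort, keep)
}

#' Compare primary and sensitivity signal runs
#'
#' Joins two [evaluate_signals()] outputs on (`drug`, `pt`,
#' `background`) and reports, per pair, whether the consensus signal
#' persisted, the reason it was lost (`"min_count"` when the count
#' dropped below the threshold, otherwise the first failing method),
#' and the deltas of the main statistics.
#'
#' @param primary,sensitivity `dispro_tbl` results over the same pair
#'   key set.
#' @param thresholds The [signal_thresholds()] used.
#' @return Tibble keyed by (`drug`, `pt`, `background`) with
#'   `consensus_before`, `consensus_after`, `persisted`, `lost_reason`,
#'   and `delta_*` columns; attribute `summary` holds retained/lost
#'   counts.
#' @export
compare_runs <- function(primary, sensitivity,
                         thresholds = signal_thresholds()) {
  key <- c("drug", "pt", "background")
  stopifnot(all(key %in% names(primary)), all(key %in% names(sensitivity)))
  if (nrow(anti_join(primary, sensitivity, by = key)) > 0 ||
      nrow(anti_join(sensitivity, primary, by = key)) > 0) {
    abort("primary and sensitivity runs must cover the same (drug, pt, background) pairs")
  }
  sens <- sensitivity |>
    select(dplyr::all_of(key), a_after = "a", ror_after = "ror",
           prr_after = "prr", ic025_after = "ic025", chi2_after = "chi2",
           consensus_after = "consensus",
           ror_signal_after = "ror_signal", prr_signal_after = "prr_signal",
           mhra_signal_after = "mhra_signal", ic_signal_after = "ic_signal")
  out <- primary |>
    select(dplyr::all_of(key), a_before = "a", ror_before = "ror",
           prr_before = "prr", ic025_before = "ic025", chi2_before = "chi2",
           consensus_before = "consensus") |>
    inner_join(sens, by = key) |>
    mutate(
      persisted = .data$consensus_before & .data$consensus_after,
      lost_reason = dplyr::case_when(
        !.data$consensus_before ~ NA_character_,
        .data$consensus_after ~ NA_character_,
        .data$a_after < thresholds$min_count ~ "min_count",
        !.data$ror_signal_after ~ "ror",
        !.data$prr_signal_after ~ "prr",
        !.data$mhra_signal_after ~ "mhra",
        TRUE ~ "ic"
      ),
      delta_ror = .data$ror_after - .data$ror_before,
      delta_prr = .data$prr_after - .data$prr_before,
      delta_ic025 = .data$ic025_after - .data$ic025_before,
      delta_chi2 = .data$chi2_after - .data$chi2_before,
      delta_a = .data$a_after - .data$a_before
    )
  attr(out, "summary") <- tibble(
    n_signals_before = sum(out$consensus_before),
    n_retained = sum(out$persisted),
    n_lost = sum(out$consensus_before & !out$consensus_after),
    n_gained = sum(!out$consensus_before & out$consensus_after)
  )
  out
}
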