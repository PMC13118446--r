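#' Build 2x2 contingency tables at the (report, PT) pair level
#'
#' The analysis unit is one distinct (report, preferred term) pair;
#' drug exposure is defined at report level. For a (drug, PT) pair:
#' `a` counts pairs whose report carries the drug and whose PT is the
#' event, `b` the drug's other pairs, `c` the event's pairs on
#' non-carrying reports and `d` the rest. Under the `"class"`
#' background the pair universe is restricted to reports carrying any
#' class-member ingredient, and "without the drug" means class reports
#' not carrying the target.
#'
#' @param cohort A `faers_cohort`.
#' @param drugs Character vector of target ingredients (default: the
#'   dictionary's targets).
#' @param pts Character vector of PTs; default all PTs present. A PT
#'   absent from the data yields a valid table with `a = 0`.
#' @param background `"full"` or `"class"`.
#' @return Tibble: `drug`, `pt`, `background`, `a`, `b`, `c`, `d`, `n`.
#' @examples
#' # see the package vignette for an end-to-end example
#' @export
contingency_tables <- function(cohort,
                               drugs = target_drugs(cohort$dictionary),
                               pts = NULL,
                               background = c("full", "class")) {
  background <- match.arg(background)
  stopifnot(inherits(cohort, "faers_cohort"))
  if (nrow(cohort$reports) == 0) abort("empty cohort")

  pairs <- cohort$pts  # primaryid, pt: already distinct
  if (background == "class") {
    cls <- class_drugs(cohort$dictionary)
    class_reports <- cohort$drugs |>
      filter(.data$ingredient %in% cls) |>
      distinct(.data$primaryid)
    pairs <- semi_join(pairs, class_reports, by = "primaryid")
  }
  n_total <- nrow(pairs)
  if (pts_null <- is.null(pts)) pts <- sort(unique(pairs$pt))

  out <- purrr::map(drugs, function(dg) {
    exposed <- cohort$drugs |>
      filter(.data$ingredient == dg) |>
      distinct(.data$primaryid)
    pairs_d <- semi_join(pairs, exposed, by = "primaryid")
    margin_a_b <- nrow(pairs_d)
    counts_exposed <- pairs_d |> count(.data$pt, name = "a")
    counts_all <- pairs |> count(.data$pt, name = "tot")
    tibble(pt = pts) |>
      left_join(counts_exposed, by = "pt") |>
      left_join(counts_all, by = "pt") |>
      mutate(
        drug = dg,
        a = dplyr::coalesce(.data$a, 0L),
        tot = dplyr::coalesce(.data$tot, 0L),
        b = margin_a_b - .data$a,
        c = .data$tot - .data$a,
        d = n_total - margin_a_b - .data$c
      )
  }) |>
    bind_rows() |>
    mutate(background = background, n = .data$a + .data$b + .data$c + .data$d) |>
    select("drug", "pt", "background", "a", "b", "c", "d", "n")
  if (!pts_null) {
    absent <- setdiff(pts, unique(pairs$pt))
    if (length(absent) > 0) {
      inform(sprintf("%d requested PT(s) absent from dataset (a = 0)",
                     length(absent)))
    }
  }
  out
}

#' Top-k preferred terms for a drug, with exclusions
#'
#' Ranks PTs by their (report, PT) pair count with the drug, descending,
#' ties broken alphabetically. PTs on the exclusion list (matched
#' case-insensitively) are removed before the top k are taken, so an
#' excluded high-frequency term does not consume a slot.
#'
#' @param cohort A `faers_cohort`.
#' @param drug One target ingredient.
#' @param k Number of PTs to return.
#' @param exclusion_list PT labels to drop; defaults to the
#'   drug-unrelated administrative terms.
#' @return Character vector of up to `k` PT labels, most frequent first.
#' @export
top_pts <- function(cohort, drug, k = 20,
                    exclusion_list = default_pt_exclusions()) {
  stopifnot(k >= 1, length(drug) == 1)
  exposed <- cohort$drugs |>
    filter(.data$ingredient == drug) |>
    distinct(.data$primaryid)
  counts <- cohort$pts |>
    semi_join(exposed, by = "primaryid") |>
    count(.data$pt, name = "a_count") |>
    filter(!tolower(.data$pt) %in% tolower(exclusion_list)) |>
    arrange(dplyr::desc(.data$a_count), .data$pt)
  if (nrow(counts) < k) {
    inform(sprintf("only %d PT(s) available for %s (k = %d)",
                   nrow(counts), drug, k))
  }
  utils::head(counts$pt, k)
}

#' Default drug-unrelated PT exclusion list
#'
#' Administrative terms that describe how a drug was used rather than an
#' adverse reaction, removed before the top-k screen.
#'
#' @return Character vector of PT labels.
#' @export
default_pt_exclusions <- function() {
  c("Drug interaction", "Off label use",
    "Product use in unapproved indication", "Intentional product misuse")
}
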