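#' Demographic and outcome summary per target drug
#'
#' Report-level counts by sex, age group, reporter occupation, top
#' countries and outcome codes, per target drug and in total, in the
#' style of a study "Table 1". A report carrying several target drugs
#' contributes to each drug's column. Outcome entries may exceed report
#' counts because one report can carry several outcome codes.
#'
#' @param cohort A `faers_cohort`.
#' @param drugs Target ingredients to tabulate.
#' @param top_countries How many countries to keep (most frequent
#'   overall).
#' @return Long tibble: `characteristic`, `level`, `drug`, `count`.
#' @export
summarize_demographics <- function(cohort,
                                   drugs = target_drugs(cohort$dictionary),
                                   top_countries = 5) {
  stopifnot(inherits(cohort, "faers_cohort"))
  flags <- cohort$drugs |>
    filter(.data$ingredient %in% drugs) |>
    distinct(.data$primaryid, .data$ingredient)
  base <- cohort$reports |>
    inner_join(flags, by = "primaryid", relationship = "many-to-many")
  if (nrow(base) == 0) {
    return(tibble(characteristic = character(0), level = character(0),
                  drug = character(0), count = integer(0)))
  }
  count_by <- function(df, col, characteristic) {
    df |>
      count(level = .data[[col]], drug = .data$ingredient, name = "count") |>
      mutate(characteristic = characteristic) |>
      select("characteristic", "level", "drug", "count")
  }
  sex_tab <- count_by(base, "sex", "sex")
  age_tab <- count_by(base, "age_group", "age_group")
  occ_tab <- count_by(base, "occupation", "occupation")
  keep_countries <- base |>
    count(.data$country, sort = TRUE) |>
    dplyr::slice_head(n = top_countries) |>
    pull(.data$country)
  cty_tab <- base |>
    filter(.data$country %in% keep_countries) |>
    count_by("country", "country")
  outc_tab <- cohort$outcomes |>
    inner_join(flags, by = "primaryid", relationship = "many-to-many") |>
    count(level = .data$outc_cod, drug = .data$ingredient, name = "count") |>
    mutate(characteristic = "outcome") |>
    select("characteristic", "level", "drug", "count")
  total_tab <- base |>
    count(drug = .data$ingredient, name = "count") |>
    mutate(characteristic = "total", level = "reports") |>
    select("characteristic", "level", "drug", "count")
  bind_rows(total_tab, sex_tab, age_tab, cty_tab, occ_tab, outc_tab) |>
    arrange(.data$characteristic, .data$level, .data$drug)
}

#' ROR heatmap matrix of signal strengths
#'
#' PTs x drugs matrix holding the ROR point estimate wherever the ROR
#' lower 95% limit exceeds 1, `NA` elsewhere: the testable artifact
#' behind the signal-strength heatmap figure. Rows and columns are
#' sorted deterministically (PTs alphabetically, drugs alphabetically).
#'
#' @param results A `dispro_tbl` from [evaluate_signals()], one
#'   background.
#' @return Wide tibble: column `pt`, one numeric column per drug.
#' @export
heatmap_matrix <- function(results) {
  stopifnot(all(c("drug", "pt", "ror", "ror_low") %in% names(results)))
  if ("background" %in% names(results) &&
      length(unique(results$background)) > 1) {
    abort("supply results for a single background")
  }
  results |>
    mutate(cell = if_else(.data$ror_low > 1, .data$ror, NA_real_)) |>
    select("pt", "drug", "cell") |>
    arrange(.data$pt, .data$drug) |>
    tidyr::pivot_wider(names_from = "drug", values_from = "cell",
                       names_sort = TRUE)
}

#' Write a heatmap matrix as TSV
#'
#' @param matrix_tbl Output of [heatmap_matrix()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_heatmap_tsv <- function(matrix_tbl, path) {
  readr::write_tsv(matrix_tbl, path)
  invisible(path)
}

#' Plot a signal-strength heatmap
#'
#' Tile plot of the [heatmap_matrix()] cells: colour depth proportional
#' to log10(ROR), clipped to \[0, 3.5\]; pairs whose ROR lower limit
#' does not exceed 1 are blank.
#'
#' @param object A `dispro_tbl`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dispro_tbl <- function(object, ...) {
  df <- object |>
    mutate(cell = if_else(.data$ror_low > 1,
                          pmin(pmax(log10(.data$ror), 0), 3.5), NA_real_))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$drug, y = .data$pt,
                                   fill = .data$cell)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_gradient(low = "#fff5f0", high = "#67000d",
                                 limits = c(0, 3.5), na.value = "white",
                                 name = "log10(ROR)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Write disproportionality results as CSV
#'
#' Long-format export of the per-(drug, pt, background) statistics,
#' flags and consensus verdicts.
#'
#' @param results A `dispro_tbl`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_signals_csv <- function(results, path) {
  readr::write_csv(as_tibble(results), path)
  invisible(path)
}
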