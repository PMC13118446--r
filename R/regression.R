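#' Build the case-noncase design for one outcome PT
#'
#' One row per cleaned report carrying exactly one target drug; reports
#' with two or more target drugs are excluded (and counted), as are
#' reports with unknown sex or age. The outcome is 1 when the report's
#' PT set contains `outcome_pt`. Factors are released with the stated
#' reference levels: drug reference `amlodipine`, sex reference `M`,
#' age-group reference `18-44`, occupation reference `MD` (physician).
#'
#' @param cohort A `faers_cohort`.
#' @param outcome_pt Preferred-term label defining the cases.
#' @param drug_ref,sex_ref,age_ref,occ_ref Reference levels.
#' @return Tibble with columns `primaryid`, `y`, and factors `drug`,
#'   `sex`, `age_group`, `occupation`; attributes `n_excluded_multi`
#'   and `n_excluded_missing` record the dropped rows.
#' @export
build_design <- function(cohort, outcome_pt,
                         drug_ref = "amlodipine", sex_ref = "M",
                         age_ref = "18-44", occ_ref = "MD") {
  stopifnot(inherits(cohort, "faers_cohort"))
  targets <- target_drugs(cohort$dictionary)
  tflags <- cohort$drugs |>
    filter(.data$ingredient %in% targets) |>
    distinct(.data$primaryid, .data$ingredient)
  per_report <- tflags |> count(.data$primaryid, name = "n_targets")
  multi <- per_report |> filter(.data$n_targets > 1)
  if (nrow(multi) > 0) {
    inform(sprintf("%d report(s) with multiple target drugs excluded",
                   nrow(multi)))
  }
  single <- tflags |>
    anti_join(multi, by = "primaryid") |>
    semi_join(per_report, by = "primaryid")

  cases <- cohort$pts |>
    filter(.data$pt == outcome_pt) |>
    distinct(.data$primaryid) |>
    mutate(y = 1L)

  df <- cohort$reports |>
    inner_join(single, by = "primaryid") |>
    left_join(cases, by = "primaryid") |>
    mutate(y = dplyr::coalesce(.data$y, 0L))
  n_before <- nrow(df)
  df <- df |>
    filter(.data$sex %in% c("M", "F"), .data$age_group != "unknown",
           !is.na(.data$occupation))
  n_missing <- n_before - nrow(df)
  if (n_missing > 0) {
    inform(sprintf("%d report(s) with unknown sex/age/occupation excluded",
                   n_missing))
  }

  relevel_present <- function(x, ref, ordered_levels) {
    lv <- intersect(ordered_levels, unique(x))
    dropped <- setdiff(ordered_levels, lv)
    if (length(dropped) > 0 && any(dropped %in% x)) {
      # cannot happen: lv built from data
    }
    factor(x, levels = union(intersect(ref, lv), lv))
  }
  out <- df |>
    mutate(
      drug = relevel_present(.data$ingredient, drug_ref, targets),
      sex = relevel_present(.data$sex, sex_ref, c("M", "F")),
      age_group = relevel_present(.data$age_group, age_ref,
                                  c("<18", "18-44", "45-64", "65-75", ">75")),
      occupation = relevel_present(.data$occupation, occ_ref,
                                   c("MD", "PH", "HP"))
    ) |>
    select("primaryid", "y", "drug", "sex", "age_group", "occupation")
  for (col in c("drug", "sex", "age_group", "occupation")) {
    lv <- levels(out[[col]])
    used <- lv[lv %in% unique(as.character(out[[col]]))]
    if (length(used) < length(lv)) {
      warn(sprintf("level(s) %s of '%s' have zero rows and are dropped",
                   paste(setdiff(lv, used), collapse = ", "), col))
      out[[col]] <- factor(as.character(out[[col]]), levels = used)
    }
  }
  attr(out, "n_excluded_multi") <- nrow(multi)
  attr(out, "n_excluded_missing") <- n_missing
  attr(out, "outcome_pt") <- outcome_pt
  out
}

#' Fit the case-noncase logistic regression
#'
#' Maximum-likelihood logistic regression of the outcome on the
#' categorical predictors present in the design (any of `drug`, `sex`,
#' `age_group`, `occupation` with 2+ levels), via iteratively
#' reweighted least squares. Adjusted odds ratios are exp(coefficient)
#' with Wald 95% intervals exp(coef +/- 1.96 SE) and Wald p-values.
#'
#' @param design A design tibble from [build_design()] (or any data
#'   frame with a 0/1 column `y` and factor predictors).
#' @param predictors Character vector of predictor columns; defaults to
#'   the usual four, restricted to those present with >= 2 levels.
#' @return An object of class `case_noncase_fit` wrapping the `glm`
#'   fit; see [tidy.case_noncase_fit()] and
#'   [glance.case_noncase_fit()].
#' @export
fit_case_noncase <- function(design,
                             predictors = c("drug", "sex", "age_group",
                                            "occupation")) {
  stopifnot("y" %in% names(design))
  if (sum(design$y == 1) < 1 || sum(design$y == 0) < 1) {
    abort("need at least one event and one non-event to fit")
  }
  predictors <- predictors[predictors %in% names(design)]
  predictors <- predictors[vapply(predictors, function(p) {
    length(unique(design[[p]][!is.na(design[[p]])])) >= 2
  }, logical(1))]
  if (length(predictors) == 0) abort("no usable predictors")
  fml <- stats::as.formula(paste("y ~", paste(predictors, collapse = " + ")))
  fit <- glm(fml, family = binomial(), data = design,
             control = list(epsilon = 1e-10, maxit = 100))
  if (!fit$converged) {
    abort("logistic fit did not converge (possible complete separation)")
  }
  mm_rank <- fit$rank
  mm_cols <- length(coef(fit))
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    abort(paste0("rank-deficient design; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
  structure(list(fit = fit, predictors = predictors,
                 outcome_pt = attr(design, "outcome_pt"),
                 n = nrow(design), n_events = sum(design$y == 1),
                 rank = mm_rank, n_coef = mm_cols),
            class = "case_noncase_fit")
}

#' @export
print.case_noncase_fit <- function(x, ...) {
  cat(sprintf("<case_noncase_fit> outcome %s: %d rows, %d events\n",
              x$outcome_pt %||% "?", x$n, x$n_events))
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy a case-noncase fit into adjusted odds ratios
#'
#' @param x A `case_noncase_fit`.
#' @param z Normal quantile for the Wald interval.
#' @param ... Unused.
#' @return Tibble: `term`, `estimate` (log-odds), `std_error`, `aor`,
#'   `aor_low`, `aor_high`, `p_value`.
#' @export
tidy.case_noncase_fit <- function(x, z = 1.96, ...) {
  co <- coef(x$fit)
  se <- sqrt(diag(vcov(x$fit)))
  tibble(
    term = names(co),
    estimate = unname(co),
    std_error = unname(se),
    aor = exp(unname(co)),
    aor_low = exp(unname(co) - z * se),
    aor_high = exp(unname(co) + z * se),
    p_value = 2 * pnorm(-abs(unname(co) / se))
  )
}

#' One-line summary of a case-noncase fit
#'
#' @param x A `case_noncase_fit`.
#' @param ... Unused.
#' @return Tibble: `n`, `n_events`, `log_lik`, `aic`, `iterations`,
#'   `converged`.
#' @export
glance.case_noncase_fit <- function(x, ...) {
  tibble(
    n = x$n, n_events = x$n_events,
    log_lik = as.numeric(stats::logLik(x$fit)),
    aic = stats::AIC(x$fit),
    iterations = x$fit$iter,
    converged = x$fit$converged
  )
}
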