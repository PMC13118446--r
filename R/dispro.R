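#' Signal-detection thresholds
#'
#' The per-method decision rules used throughout: a pair is flagged by
#' ROR or PRR when the raw report count is at least `min_count` and the
#' lower 95% confidence limit exceeds `ci_floor`; by the MHRA rule when
#' the count, the PRR point and the Yates-corrected chi-square clear
#' `min_count`, `mhra_prr` and `mhra_chi2`; and by the BCPNN rule when
#' IC025 exceeds `ic025_floor`. The consensus verdict is the conjunction
#' of all four.
#'
#' @param min_count Minimum raw `a` cell for any method to fire.
#' @param ci_floor Floor that the ROR/PRR lower 95% limit must exceed.
#' @param mhra_prr Minimum PRR point estimate for the MHRA rule.
#' @param mhra_chi2 Minimum Yates-corrected chi-square for the MHRA rule.
#' @param ic025_floor Floor that IC025 must exceed.
#' @param z Normal quantile used for all Wald-type intervals.
#' @return A list of class `signal_thresholds`.
#' @export
signal_thresholds <- function(min_count = 3, ci_floor = 1, mhra_prr = 2,
                              mhra_chi2 = 4, ic025_floor = 0, z = 1.96) {
  vals <- c(min_count, ci_floor, mhra_prr, mhra_chi2, ic025_floor, z)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort("all thresholds must be finite and non-negative")
  }
  structure(list(min_count = min_count, ci_floor = ci_floor,
                 mhra_prr = mhra_prr, mhra_chi2 = mhra_chi2,
                 ic025_floor = ic025_floor, z = z),
            class = "signal_thresholds")
}

check_cells <- function(a, b, c, d) {
  if (any(!is.finite(c(a, b, c, d))) || any(c(a, b, c, d) < 0)) {
    abort("2x2 cells must be finite and non-negative")
  }
  if (all(c(a, b, c, d) == 0)) {
    abort("all-zero 2x2 table: statistics undefined")
  }
  invisible(NULL)
}

# Haldane-Anscombe continuity correction: applied to ROR/PRR/chi-square
# whenever any cell is zero; the IC shrinkage form needs no correction.
correct_cells <- function(a, b, c, d) {
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  k <- ifelse(zero, 0.5, 0)
  list(a = a + k, b = b + k, c = c + k, d = d + k)
}

#' Reporting odds ratio with Woolf confidence limits
#'
#' ROR = (a d)/(b c); limits are exp(log ROR -/+ z * sqrt(1/a + 1/b +
#' 1/c + 1/d)). Tables with a zero cell receive the Haldane-Anscombe
#' 0.5 correction in every cell before computation.
#'
#' @param a,b,c,d Cells of the 2x2 table: `a` drug-and-event pairs, `b`
#'   drug without the event, `c` event without the drug, `d` neither.
#' @param z Normal quantile for the interval (default 1.96).
#' @return A tibble with columns `ror`, `ror_low`, `ror_high`.
#' @examples
#' compute_ror(10, 90, 100, 9900)
#' @export
compute_ror <- function(a, b, c, d, z = 1.96) {
  check_cells(a, b, c, d)
  cc <- correct_cells(a, b, c, d)
  ror <- (cc$a * cc$d) / (cc$b * cc$c)
  se <- sqrt(1 / cc$a + 1 / cc$b + 1 / cc$c + 1 / cc$d)
  tibble(ror = ror, ror_low = ror * exp(-z * se), ror_high = ror * exp(z * se))
}

#' Proportional reporting ratio with confidence limits
#'
#' PRR = \[a/(a+b)\] / \[c/(c+d)\]; limits are exp(log PRR -/+ z *
#' sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))). Zero cells are corrected as in
#' [compute_ror()].
#'
#' @inheritParams compute_ror
#' @return A tibble with columns `prr`, `prr_low`, `prr_high`.
#' @export
compute_prr <- function(a, b, c, d, z = 1.96) {
  check_cells(a, b, c, d)
  cc <- correct_cells(a, b, c, d)
  u <- cc$a + cc$b
  v <- cc$c + cc$d
  prr <- (cc$a / u) / (cc$c / v)
  se <- sqrt(1 / cc$a - 1 / u + 1 / cc$c - 1 / v)
  tibble(prr = prr, prr_low = prr * exp(-z * se), prr_high = prr * exp(z * se))
}

#' Yates-corrected chi-square of a 2x2 table
#'
#' N(|ad - bc| - N/2)^2 / ((a+b)(c+d)(a+c)(b+d)), truncated to zero when
#' |ad - bc| <= N/2 (so near-independent tables score 0 rather than a
#' spurious positive value).
#'
#' @inheritParams compute_ror
#' @return Numeric chi-square value (vectorised).
#' @export
compute_chi2 <- function(a, b, c, d) {
  check_cells(a, b, c, d)
  cc <- correct_cells(a, b, c, d)
  a <- cc$a; b <- cc$b; c <- cc$c; d <- cc$d
  N <- a + b + c + d
  if (any((a + b) == 0 | (c + d) == 0 | (a + c) == 0 | (b + d) == 0)) {
    abort("degenerate margin: chi-square undefined")
  }
  dev <- abs(a * d - b * c)
  excess <- pmax(dev - N / 2, 0)
  N * excess^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

#' BCPNN information component with shrinkage
#'
#' The expected count is E = (a+b)(a+c)/N; the information component is
#' IC = log2((a + 0.5)/(E + 0.5)) and its lower 95% credibility bound is
#' approximated as IC025 = IC - 3.3 (a + 0.5)^(-1/2) - 2 (a + 0.5)^(-3/2).
#'
#' @inheritParams compute_ror
#' @return A tibble with columns `ic`, `ic025`, `e_count`.
#' @export
compute_ic <- function(a, b, c, d) {
  check_cells(a, b, c, d)
  N <- a + b + c + d
  e_count <- (a + b) * (a + c) / N
  ic <- log2((a + 0.5) / (e_count + 0.5))
  ic025 <- ic - 3.3 * (a + 0.5)^(-0.5) - 2 * (a + 0.5)^(-1.5)
  tibble(ic = ic, ic025 = ic025, e_count = e_count)
}

#' All four disproportionality statistics with signal flags
#'
#' Takes a data frame of 2x2 tables (columns `a`, `b`, `c`, `d`; any
#' identifier columns such as `drug`, `pt`, `background` are carried
#' through) and appends the four statistics, their intervals, per-method
#' flags and the all-method consensus verdict. Flags always require the
#' raw (uncorrected) `a` count to reach the `min_count` threshold.
#'
#' @param tables Data frame with integer columns `a`, `b`, `c`, `d`.
#' @param thresholds A [signal_thresholds()] object.
#' @return The input tibble with columns `ror`, `ror_low`, `ror_high`,
#'   `prr`, `prr_low`, `prr_high`, `chi2`, `ic`, `ic025`, `e_count`,
#'   `ror_signal`, `prr_signal`, `mhra_signal`, `ic_signal`, `consensus`
#'   appended; class `dispro_tbl`.
#' @examples
#' evaluate_signals(tibble::tibble(a = 10, b = 90, c = 100, d = 9900))
#' @export
evaluate_signals <- function(tables, thresholds = signal_thresholds()) {
  stopifnot(is.data.frame(tables), all(c("a", "b", "c", "d") %in% names(tables)))
  if (nrow(tables) == 0) {
    abort("no 2x2 tables supplied")
  }
  th <- thresholds
  out <- as_tibble(tables)
  ok <- with(out, a + b + c + d > 0)
  if (any(!ok)) {
    warn(sprintf("%d all-zero 2x2 table(s): statistics set NA, flagged non-signal",
                 sum(!ok)))
  }
  res <- tibble(ror = NA_real_, ror_low = NA_real_, ror_high = NA_real_,
                prr = NA_real_, prr_low = NA_real_, prr_high = NA_real_,
                chi2 = NA_real_, ic = NA_real_, ic025 = NA_real_,
                e_count = NA_real_)[rep(1, nrow(out)), ]
  if (any(ok)) {
    res[ok, ] <- dplyr::bind_cols(
      compute_ror(out$a[ok], out$b[ok], out$c[ok], out$d[ok], z = th$z),
      compute_prr(out$a[ok], out$b[ok], out$c[ok], out$d[ok], z = th$z),
      tibble(chi2 = compute_chi2(out$a[ok], out$b[ok], out$c[ok], out$d[ok])),
      compute_ic(out$a[ok], out$b[ok], out$c[ok], out$d[ok])
    )
  }
  out <- dplyr::bind_cols(out, res)
  out <- out |>
    mutate(
      ror_signal  = dplyr::coalesce(
        .data$a >= th$min_count & .data$ror_low > th$ci_floor, FALSE),
      prr_signal  = dplyr::coalesce(
        .data$a >= th$min_count & .data$prr_low > th$ci_floor, FALSE),
      mhra_signal = dplyr::coalesce(
        .data$a >= th$min_count & .data$prr >= th$mhra_prr &
          .data$chi2 >= th$mhra_chi2, FALSE),
      ic_signal   = dplyr::coalesce(
        .data$a >= th$min_count & .data$ic025 > th$ic025_floor, FALSE),
      consensus   = .data$ror_signal & .data$prr_signal &
        .data$mhra_signal & .data$ic_signal
    )
  class(out) <- c("dispro_tbl", class(out))
  out
}

#' Reconstruct a 2x2 table from published summary statistics
#'
#' Closed-form inversion of the ROR/PRR interval formulas: given the
#' event count `a`, the ROR point `ror`, the PRR point `prr` and the PRR
#' lower 95% limit `prr_low` as printed in a disproportionality table,
#' recovers the real-valued cells (b, c, d) of the underlying 2x2 table.
#' With w = c/(c+d) the background event rate and u = a+b the drug's
#' pair total, the identities w = (R - P) / (P (R - 1)), u = a/(P w),
#' V = (log(P / L) / z)^2 and c = (1 - w)/(V - 1/a + 1/u), d = c (1-w)/w
#' follow from the definitions of ROR, PRR and the Woolf-type PRR
#' variance. Recomputing the forward statistics from the reconstructed
#' table reproduces the inputs, so published rows can be validated
#' without access to the source database.
#'
#' @param a Reported drug-and-event count (>= 1).
#' @param ror ROR point estimate (> 1).
#' @param prr PRR point estimate (0 < prr < ror).
#' @param prr_low PRR lower 95% confidence limit (0 < prr_low < prr).
#' @param z Normal quantile used for the printed interval.
#' @return A tibble with columns `a`, `b`, `c`, `d` (reals), `n`, `w`,
#'   `u`, `v_var`.
#' @examples
#' invert_stats(10, 11, 10, 5.3817)
#' @export
invert_stats <- function(a, ror, prr, prr_low, z = 1.96) {
  if (any(a < 1)) abort("inversion requires a >= 1")
  if (any(!(ror > prr & prr > prr_low & prr_low > 0 & ror > 1))) {
    abort("inversion infeasible: need ror > prr > prr_low > 0 and ror > 1")
  }
  w <- (ror - prr) / (prr * (ror - 1))
  u <- a / (prr * w)
  v_var <- (log(prr / prr_low) / z)^2
  c_cell <- (1 - w) / (v_var - 1 / a + 1 / u)
  d_cell <- c_cell * (1 - w) / w
  b_cell <- u - a
  bad <- !(w > 0 & w < 1) | u <= a | c_cell <= 0 | d_cell <= 0
  if (any(bad)) {
    abort("inversion infeasible: printed statistics are mutually inconsistent")
  }
  tibble(a = a, b = b_cell, c = c_cell, d = d_cell,
         n = a + b_cell + c_cell + d_cell, w = w, u = u, v_var = v_var)
}
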