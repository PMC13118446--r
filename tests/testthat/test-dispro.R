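test_that("ROR point and Woolf limits match hand arithmetic", {
  r <- compute_ror(10, 90, 100, 9900)
  expect_equal(r$ror, 11.0)
  # ln ROR = ln 11, SE = sqrt(1/10 + 1/90 + 1/100 + 1/9900) = 0.348155
  expect_equal(r$ror_low, 5.560, tolerance = 1e-3)
  expect_equal(r$ror_high, 21.765, tolerance = 1e-3)
  # symmetric table
  expect_equal(compute_ror(5, 5, 5, 5)$ror, 1.0)
})

test_that("PRR matches hand arithmetic and sits below ROR for enriched tables", {
  p <- compute_prr(10, 90, 100, 9900)
  expect_equal(p$prr, 10.0)
  expect_equal(p$prr_low, 5.382, tolerance = 1e-3)
  expect_equal(compute_prr(5, 5, 5, 5)$prr, 1.0)
  tabs <- random_tables(200, seed = 11)
  enriched <- with(tabs, a / (a + b) > c / (c + d))
  expect_true(all(compute_prr(tabs$a, tabs$b, tabs$c, tabs$d)$prr[enriched] <=
                    compute_ror(tabs$a, tabs$b, tabs$c, tabs$d)$ror[enriched]))
})

test_that("Yates chi-square matches hand arithmetic and truncates at independence", {
  expect_equal(compute_chi2(10, 90, 100, 9900), 66.33, tolerance = 1e-3)
  # ad = bc: continuity excess is zero
  expect_equal(compute_chi2(10, 20, 30, 60), 0)
})

test_that("information component and IC025 match the shrinkage formulas", {
  ic <- compute_ic(10, 90, 100, 9900)
  expect_equal(ic$e_count, 1.08911, tolerance = 1e-5)
  expect_equal(ic$ic, 2.724099, tolerance = 1e-5)
  expect_equal(ic$ic025, 1.646915, tolerance = 1e-5)
  # observed equals expected at scale: IC near zero
  big <- compute_ic(1000, 9000, 10000, 90000)
  expect_lt(abs(big$ic), 0.01)
})

test_that("zero cells get the Haldane-Anscombe correction, all-zero errors", {
  r <- compute_ror(3, 0, 5, 100)
  expect_true(is.finite(r$ror) && is.finite(r$ror_high))
  expect_equal(r$ror, (3.5 * 100.5) / (0.5 * 5.5))
  expect_error(compute_ror(0, 0, 0, 0), "all-zero")
  expect_error(compute_prr(0, 0, 0, 0), "all-zero")
})

test_that("signal flags follow the four per-method rules and their conjunction", {
  res <- evaluate_signals(tibble::tibble(a = 10, b = 90, c = 100, d = 9900))
  expect_true(all(res$ror_signal, res$prr_signal, res$mhra_signal,
                  res$ic_signal, res$consensus))
  # below the minimum count nothing fires, however large the ROR
  res2 <- evaluate_signals(tibble::tibble(a = 2, b = 1, c = 1, d = 10000))
  expect_false(any(res2$ror_signal, res2$consensus))
  # MHRA's PRR >= 2 rule can veto consensus on its own
  res3 <- evaluate_signals(tibble::tibble(a = 50, b = 2000, c = 130, d = 9900))
  expect_true(res3$prr > 1 && res3$prr < 2)
  expect_false(res3$mhra_signal)
  expect_false(res3$consensus)
})

test_that("consensus is a subset of every single-method signal set", {
  tabs <- random_tables(500, seed = 7)
  res <- evaluate_signals(tabs)
  expect_true(all(res$consensus <= res$ror_signal))
  expect_true(all(res$consensus <= res$prr_signal))
  expect_true(all(res$consensus <= res$mhra_signal))
  expect_true(all(res$consensus <= res$ic_signal))
})

test_that("statistics increase with a when the other cells are fixed", {
  a <- 5:50
  r <- compute_ror(a, 500, 200, 50000)
  p <- compute_prr(a, 500, 200, 50000)
  ic <- compute_ic(a, 500, 200, 50000)
  expect_true(all(diff(r$ror) > 0))
  expect_true(all(diff(p$prr) > 0))
  expect_true(all(diff(ic$ic) > 0))
})

test_that("inversion reconstructs the worked 2x2 table exactly", {
  p <- compute_prr(10, 90, 100, 9900)
  sol <- invert_stats(10, 11.0, 10.0, p$prr_low)
  expect_equal(sol$b, 90, tolerance = 1e-6)
  expect_equal(sol$c, 100, tolerance = 1e-6)
  expect_equal(sol$d, 9900, tolerance = 1e-4)
})

test_that("inversion rejects inconsistent printed inputs", {
  expect_error(invert_stats(10, 5, 5, 4), "infeasible")     # R = P
  expect_error(invert_stats(10, 0.9, 0.8, 0.5), "infeasible") # R <= 1
  expect_error(invert_stats(0.5, 11, 10, 5), "a >= 1")
})

test_that("forward-invert-forward is the identity on random tables", {
  tabs <- random_tables(300, seed = 23)
  r <- compute_ror(tabs$a, tabs$b, tabs$c, tabs$d)
  p <- compute_prr(tabs$a, tabs$b, tabs$c, tabs$d)
  ok <- r$ror > p$prr & p$prr > 1
  tabs <- tabs[ok, ]; r <- r[ok, ]; p <- p[ok, ]
  sol <- invert_stats(tabs$a, r$ror, p$prr, p$prr_low)
  expect_equal(sol$b, tabs$b, tolerance = 1e-6)
  expect_equal(sol$c, tabs$c, tolerance = 1e-6)
  expect_equal(sol$d, tabs$d, tolerance = 1e-6)
})

test_that("degenerate rows inside a batch become flagged non-signals", {
  tabs <- tibble::tibble(a = c(10, 0), b = c(90, 0), c = c(100, 0),
                         d = c(9900, 0))
  expect_warning(res <- evaluate_signals(tabs), "all-zero")
  expect_true(res$consensus[1])
  expect_false(res$consensus[2])
  expect_true(is.na(res$ror[2]))
})
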