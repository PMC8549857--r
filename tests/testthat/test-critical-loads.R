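# Decline-curve inversion: critical loads, risk classes, anchor tables and
# bootstrap confidence intervals.

test_that("decline fractions are relative to the reference value", {
  expect_equal(decline_fraction(c(10, -1), 0, 0), 0)
  expect_equal(decline_fraction(c(10, -1), 2, 0), 0.2)
  expect_error(decline_fraction(c(0, -1), 2, 0), "positive")
  # clipping: declines cannot exceed 100% or fall below 0
  expect_equal(decline_fraction(c(10, -1), 25, 0), 1)
  expect_equal(decline_fraction(c(10, 1), 3, 0), 0)
})

test_that("the anchor quadratic reproduces its tabulated declines", {
  co <- anchor_quadratic(c(0.1, 0.7, 3.5), c(0, 0.10, 0.50))
  expect_equal(decline_fraction(co, 0.7, 0.1), 0.10, tolerance = 1e-10)
  expect_equal(decline_fraction(co, 3.5, 0.1), 0.50, tolerance = 1e-10)
  expect_equal(decline_fraction(co, 0.1, 0.1), 0)
})

test_that("deposition_at_decline inverts linear and quadratic curves", {
  expect_equal(deposition_at_decline(c(10, -1), 0, 0.2, 20), 2,
               tolerance = 1e-6)
  expect_equal(deposition_at_decline(c(10, -1), 0, 0, 20), 0)
  expect_true(is.na(deposition_at_decline(c(10, -0.1), 0, 0.9, 20)))
  expect_error(deposition_at_decline(c(NA, 1), 0, 0.2, 20), "finite")
  expect_error(deposition_at_decline(c(10, -1), 0, 1.2, 20), "target")
})

test_that("numeric inversion matches the closed-form oracle on random quadratics", {
  set.seed(88)
  for (i in 1:100) {
    curve <- decline_curve(runif(1, 5, 50), runif(1, 5, 30))
    x_min <- runif(1, 0.1, 1)
    decl <- runif(1, 0.01, 0.85)
    num <- deposition_at_decline(curve, x_min, decl, window = 40)
    cf <- true_deposition_at_decline(curve, x_min, decl)
    expect_lt(abs(num - cf), 1e-5)
  }
})

test_that("inversion is monotone in the target and round-trips", {
  curve <- decline_curve(30, 15)
  x_min <- 0.2
  targets <- c(0.05, 0.1, 0.2, 0.5, 0.8)
  deps <- vapply(targets, function(t)
    deposition_at_decline(curve, x_min, t, 20), numeric(1))
  expect_true(all(diff(deps) > 0))
  for (k in seq_along(targets)) {
    expect_equal(decline_fraction(curve, deps[k], x_min), targets[k],
                 tolerance = 1e-6)
  }
})

test_that("risk classes use half-open intervals with boundaries upward", {
  expect_identical(classify_risk(0.19), "low")
  expect_identical(classify_risk(0.20), "moderate")
  expect_identical(classify_risk(0.35), "moderate")
  expect_identical(classify_risk(0.50), "high")
  expect_identical(classify_risk(0.80), "very_high")
  expect_identical(classify_risk(c(0, 1)), c("low", "very_high"))
  expect_error(classify_risk(1.2))
})

test_that("the risk table carries anchors, rounded counts and a grid", {
  # reference value 30: the 80% anchor count is 30 * 0.2 = 6
  curve <- decline_curve(30, 12)
  rt <- build_risk_table(curve, x_min = 0.1, window = 20,
                         metric = "forage_abundance", pollutant = "N")
  expect_equal(rt$anchors$value,
               round_half_away(poly_eval(curve, 0.1) *
                                 (1 - c(0, .1, .2, .5, .8))))
  expect_equal(rt$anchors$value[5],
               round_half_away(poly_eval(curve, 0.1) * 0.2))
  expect_true(all(diff(rt$anchors$deposition) > 0))
  expect_true(all(diff(rt$anchors$value) <= 0))
  expect_equal(rt$cl, rt$anchors$deposition[rt$anchors$decline == 0.2])
  # grid entries beyond the window are unavailable
  rt2 <- build_risk_table(curve, 0.1, window = 10, metric = "m")
  expect_true(all(is.na(rt2$decline_grid$percent_decline[
    rt2$decline_grid$deposition > 10])))
  # decline at the reference deposition is zero
  expect_equal(decline_fraction(curve, 0.1, 0.1), 0)
})

test_that("a curve still rising at the reference triggers a warning", {
  expect_warning(build_risk_table(c(10, 1, -0.2), x_min = 0.5,
                                  window = 10, metric = "m"),
                 "increasing")
})

test_that("bootstrap CLs give ordered, degenerate-aware intervals", {
  boot <- structure(list(coefficients = matrix(rep(c(30, -3, 0.05), 10),
                                               10, 3, byrow = TRUE)),
                    class = "qr_bootstrap")
  ci <- cl_confidence_interval(boot, x_min = 0.2, window = 12)
  expect_equal(ci$lower, ci$upper, tolerance = 1e-6)
  expect_equal(ci$lower,
               true_deposition_at_decline(c(30, -3, 0.05), 0.2, 0.2),
               tolerance = 1e-4)
  # flat replicates never reach the decline: counted, then error at >50%
  flat <- structure(list(coefficients = matrix(rep(c(30, 0, 0), 10),
                                               10, 3, byrow = TRUE)),
                    class = "qr_bootstrap")
  expect_error(cl_confidence_interval(flat, 0.2, 12), "half")
  mixed <- structure(list(coefficients = rbind(
    matrix(rep(c(30, -3, 0.05), 7), 7, 3, byrow = TRUE),
    matrix(rep(c(30, 0, 0), 3), 3, 3, byrow = TRUE))),
    class = "qr_bootstrap")
  ci2 <- cl_confidence_interval(mixed, 0.2, 12)
  expect_equal(ci2$n_unusable, 3)
  expect_lte(ci2$lower, ci2$upper)
})
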