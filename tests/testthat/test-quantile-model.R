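# The interior-point pinball solver, its fit statistics, model selection
# and the pairs bootstrap.

test_that("degenerate and hand-computable fits are exact", {
  # constant response, intercept only
  f <- fit_quantile_regression(matrix(1, 5, 1), rep(3, 5), tau = 0.9)
  expect_equal(unname(coef(f)), 3)
  expect_equal(f$objective, 0)

  # two points, intercept + slope: exact interpolation
  f2 <- fit_quantile_regression(cbind(1, c(0, 1)), c(0, 10), tau = 0.9,
                                check_rank = FALSE)
  expect_equal(f2$objective, 0)
  expect_equal(unname(coef(f2)), c(0, 10))

  # same data, intercept only: the pinball objective 0.1 c + 0.9 (10 - c)
  # is minimized at c = 10 with value 1
  f3 <- fit_quantile_regression(matrix(1, 2, 1), c(0, 10), tau = 0.9)
  expect_equal(unname(coef(f3)), 10, tolerance = 1e-8)
  expect_equal(f3$objective, 1, tolerance = 1e-8)
  expect_equal(r1_statistic(f2, f3), 1)
})

test_that("LP objective matches the interpolating-subset oracle", {
  set.seed(401)
  for (i in 1:12) {
    n <- sample(6:15, 1)
    p <- sample(2:3, 1)
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
    y <- rnorm(n, sd = 3)
    tau <- sample(c(0.5, 0.75, 0.9), 1)
    fit <- fit_quantile_regression(X, y, tau)
    expect_equal(fit$objective, brute_force_pinball(X, y, tau),
                 tolerance = 1e-8)
    expect_true(residual_sign_condition(fit))
  }
})

test_that("residual-sign counts bracket tau on larger noisy fits", {
  set.seed(402)
  for (i in 1:5) {
    n <- 500
    x <- runif(n, 0.2, 12)
    y <- pmax(0, round((30 - 3 * x + 0.05 * x^2) * runif(n, 0, 1 / 0.9)))
    fit <- fit_quantile_regression(deposition_design(x, 2), y, 0.9)
    expect_true(residual_sign_condition(fit))
    expect_true(fit$converged)
  }
})

test_that("scaling the response scales coefficients and objective, not R1", {
  set.seed(403)
  n <- 200
  x <- runif(n, 0, 10)
  X <- deposition_design(x, 2)
  y <- pmax(0, (25 - 2 * x) * runif(n, 0, 1 / 0.9))
  f1 <- fit_quantile_regression(X, y, 0.9)
  f2 <- fit_quantile_regression(X, 7 * y, 0.9)
  expect_equal(coef(f2), 7 * coef(f1), tolerance = 1e-6)
  expect_equal(f2$objective, 7 * f1$objective, tolerance = 1e-6)
  n1 <- fit_quantile_regression(X[, 1, drop = FALSE], y, 0.9)
  n2 <- fit_quantile_regression(X[, 1, drop = FALSE], 7 * y, 0.9)
  expect_equal(r1_statistic(f2, n2), r1_statistic(f1, n1),
               tolerance = 1e-6)
})

test_that("rank-deficient designs are rejected naming the columns", {
  X <- cbind(intercept = 1, a = 1:10, b = 2 * (1:10))
  expect_error(fit_quantile_regression(X, rnorm(10), 0.9), "b")
})

test_that("R1 is 0 for the null model, 1 for interpolation, NA when V0 = 0", {
  set.seed(404)
  y <- rnorm(30)
  X0 <- matrix(1, 30, 1)
  f0 <- fit_quantile_regression(X0, y, 0.9)
  expect_equal(r1_statistic(f0, f0), 0)
  fc <- fit_quantile_regression(X0, rep(2, 30), 0.9)
  expect_warning(r1 <- r1_statistic(fc, fc), "undefined")
  expect_true(is.na(r1))
})

test_that("delta-AIC depends only on n, the p's, and the objective ratio", {
  set.seed(405)
  n <- 150
  x <- runif(n, 0, 10)
  y <- pmax(0, (20 - x) * runif(n, 0, 1 / 0.9))
  f1 <- fit_quantile_regression(deposition_design(x, 1), y, 0.9)
  f2 <- fit_quantile_regression(deposition_design(x, 3), y, 0.9)
  expect_equal(qr_aic(f1) - qr_aic(f2),
               2 * n * log(f1$objective / f2$objective) +
                 2 * (f1$p - f2$p))
  # interpolating fit gets the -Inf sentinel
  fi <- fit_quantile_regression(cbind(1, c(0, 1, 2), c(0, 1, 2)^2),
                                c(0, 10, 3), tau = 0.9,
                                check_rank = FALSE)
  expect_identical(unclass(qr_aic(fi))[1], -Inf)
})

test_that("a richer model needs a large AIC drop to be selected", {
  # equal objectives, three extra parameters: delta-AIC = 6 favors the
  # smaller model, far under the threshold of 25
  f_small <- structure(list(objective = 100, n = 500, p = 2, tau = 0.9),
                       class = "quantile_fit")
  f_big <- structure(list(objective = 100, n = 500, p = 5, tau = 0.9),
                     class = "quantile_fit")
  sel <- compare_models(list(small = f_small, big = f_big))
  expect_identical(sel$selected, "small")
  expect_equal(unname(sel$delta_aic[2]), -6)
})

test_that("a real deposition effect is selected over climate alone", {
  set.seed(406)
  n <- 2000
  x <- exp(runif(n, log(0.2), log(12)))
  clim <- cbind(precip = 800 + 300 * scale(log(x))[, 1] + rnorm(n, 0, 300),
                tmax = rnorm(n, 24, 4))
  y <- pmax(0, round((30 - 3 * x + 0.05 * x^2) * runif(n, 0, 1 / 0.9)))
  f_clim <- fit_quantile_regression(cbind(1, clim), y, 0.9)
  f_full <- fit_quantile_regression(cbind(deposition_design(x, 2), clim),
                                    y, 0.9)
  sel <- compare_models(list(clim = f_clim, dep_clim = f_full))
  expect_identical(sel$selected, "dep_clim")
  expect_gt(unname(sel$delta_aic[2]), 25)
})

test_that("pure-noise responses retain the simpler nested model", {
  kept_simple <- 0
  for (s in 1:10) {
    set.seed(500 + s)
    n <- 400
    x <- runif(n, 0.2, 12)
    y <- runif(n, 0, 30)  # no deposition effect
    f1 <- fit_quantile_regression(deposition_design(x, 1), y, 0.9)
    f2 <- fit_quantile_regression(deposition_design(x, 3), y, 0.9)
    if (compare_models(list(a = f1, b = f2))$selected == "a") {
      kept_simple <- kept_simple + 1
    }
  }
  expect_gte(kept_simple, 9)
})

test_that("the pairs bootstrap is seed-reproducible with ordered bands", {
  set.seed(407)
  n <- 120
  x <- runif(n, 0.2, 12)
  X <- deposition_design(x, 2)
  y <- pmax(0, round((30 - 3 * x + 0.05 * x^2) * runif(n, 0, 1 / 0.9)))
  b1 <- bootstrap_fits(X, y, 0.9, n_reps = 2, seed = 99)
  b2 <- bootstrap_fits(X, y, 0.9, n_reps = 2, seed = 99)
  expect_identical(b1$coefficients, b2$coefficients)

  b3 <- bootstrap_fits(X, y, 0.9, n_reps = 50, seed = 7)
  grid <- deposition_design(seq(0.5, 11, length.out = 40), 2)
  band <- bootstrap_band(b3, grid)
  expect_true(all(band$lower <= band$upper))
})
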