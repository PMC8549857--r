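# The synthetic survey generator: determinism, exact conditional-quantile
# structure, and the closed-form decline oracle.

test_that("identical seeds reproduce the dataset exactly", {
  cfg <- synthetic_config(n_sites = 300, seed = 42)
  d1 <- generate_dataset(cfg, mode = "metric")
  d2 <- generate_dataset(cfg, mode = "metric")
  expect_identical(d1$sites, d2$sites)
  expect_identical(d1$metrics, d2$metrics)
  s1 <- generate_dataset(cfg, mode = "species")
  s2 <- generate_dataset(cfg, mode = "species")
  expect_identical(s1$detections, s2$detections)
  expect_identical(s1$species, s2$species)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_sites = 0), "positive")
  expect_error(synthetic_config(deposition_law = list(
    west = c(min = -1, max = 5), east = c(min = 2, max = 20))),
    "positive")
  expect_error(synthetic_config(
    true_curve = list(total_richness = c(-5, 0, 0))), "negative")
})

test_that("an empty functional group yields a zero abundance index", {
  cfg <- synthetic_config(n_sites = 200, seed = 5,
                          n_species = c(cyano_large = 0,
                                        cyano_small_med = 0,
                                        forage_pendant = 8,
                                        forage_shrubby = 8,
                                        matrix_med_large = 20,
                                        matrix_small = 15))
  d <- generate_dataset(cfg, mode = "species")
  m <- compute_site_metrics(d$detections, d$species, d$sites)
  expect_true(all(m$cyano_abundance == 0))
})

test_that("every detection carries a valid code and site fields are complete", {
  d <- generate_dataset(synthetic_config(n_sites = 250, seed = 9),
                        mode = "species")
  expect_true(all(d$detections$abundance_code %in% 1:4))
  expect_false(anyNA(d$sites[c("n_dep", "s_dep", "precip_mm",
                               "tmax_aug_c", "tmin_dec_c",
                               "continentality_c", "cmd_mm")]))
  expect_true(all(d$sites$n_dep > 0 & d$sites$s_dep > 0))
  expect_false(any(duplicated(d$detections[c("site_id", "species_id")])))
})

test_that("sample_metric_values honors its noise law and rounding", {
  x <- runif(100, 1, 10)
  expect_true(all(sample_metric_values(x, c(0, 0, 0)) == 0))
  # noise-free limit: exact rounded curve values
  y <- sample_metric_values(x, c(30, -3, 0.05), noise_law = "degenerate")
  expect_equal(y, round_half_away(30 - 3 * x + 0.05 * x^2))
  expect_error(sample_metric_values(seq(0, 40, 1), c(30, -3, 0.05)),
               "negative")
})

test_that("the empirical 90th percentile at fixed deposition hits the curve", {
  set.seed(21)
  y <- sample_metric_values(rep(5, 50000), c(20, 0, 0))  # f = 20
  q <- unname(quantile(y, 0.9))
  expect_gte(q, 19)
  expect_lte(q, 21)
})

test_that("binned empirical 90th percentiles track the generating quadratic", {
  cfg <- synthetic_config(
    n_sites = 2000, seed = 31,
    deposition_law = list(west = c(min = 0.2, max = 12),
                          east = c(min = 2.2, max = 12)),
    true_curve = list(total_richness = c(30, -3, 0.05)))
  d <- generate_dataset(cfg, mode = "metric")
  x <- d$sites$n_dep
  y <- d$metrics$total_richness
  for (center in c(1, 2, 3, 5, 7)) {
    in_bin <- abs(x - center) < 0.5
    expect_gt(sum(in_bin), 50)
    q <- unname(quantile(y[in_bin], 0.9))
    expect_lt(abs(q - (30 - 3 * center + 0.05 * center^2)), 2)
  }
})

test_that("closed-form decline depositions handle linear and edge cases", {
  expect_equal(true_deposition_at_decline(c(10, -1, 0), 0, 0.2), 2)
  expect_equal(true_deposition_at_decline(c(30, -3, 0.05), 0.7, 0), 0.7)
  expect_error(true_deposition_at_decline(c(10, -1, 0), 0, 1), "decline")
  expect_error(true_deposition_at_decline(c(10, -1, 0), 0, -0.1),
               "decline")
  # a curve that never reaches the target has no real root
  expect_true(is.na(true_deposition_at_decline(c(10, 0, 0.001), 0, 0.5)))
})

test_that("quadratic-formula depositions agree with bisection to 1e-6", {
  set.seed(77)
  for (i in 1:100) {
    curve <- decline_curve(runif(1, 5, 50), runif(1, 5, 30))
    x_min <- runif(1, 0.1, 1)
    decl <- runif(1, 0.01, 0.9)
    a <- true_deposition_at_decline(curve, x_min, decl)
    b <- bisect_decline(curve, x_min, decl, upper = 40)
    expect_lt(abs(a - b), 1e-6)
  }
})
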