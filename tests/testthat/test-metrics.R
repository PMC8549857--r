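# Functional-group assignment, per-site metric construction, sensitivity
# ratings and rarity classes.

test_that("genus lookup assigns functional groups, with form disambiguation", {
  expect_identical(
    assign_functional_group("Lobaria", "foliose-large", "cyano"),
    "cyano_large")
  expect_identical(assign_functional_group("Usnea", "pendant", "green"),
                   "forage_pendant")
  expect_identical(assign_functional_group("Usnea", "shrubby", "green"),
                   "forage_shrubby")
  expect_identical(assign_functional_group("Ramalina", "pendant"),
                   "forage_pendant")
  expect_identical(assign_functional_group("Cladonia", "foliose-small"),
                   "matrix_small")
  # unknown genus: photobiont/growth-form fallback, else unassigned
  expect_identical(
    assign_functional_group("Ignotus", "foliose-large", "cyano"),
    "cyano_large")
  expect_identical(assign_functional_group("Ignotus", "pendant", "green"),
                   "forage_pendant")
  expect_true(is.na(assign_functional_group("Ignotus", "other", "green")))
  expect_error(assign_functional_group(""), "nonempty")
})

test_that("abundance index is the sum of codes above the floor", {
  det <- data.frame(site_id = "A", species_id = paste0("SP", 1:7),
                    abundance_code = c(3, 3, 3, 4, 4, 1, 2))
  spp <- make_species(paste0("SP", 1:7),
                      fg = c(rep("cyano_large", 5), "cyano_small_med",
                             "cyano_large"))
  m <- compute_site_metrics(det, spp, make_sites("A"))
  # codes 1 and 2 are excluded; 3 + 3 + 3 + 4 + 4
  expect_equal(m$cyano_abundance, 17)
  expect_equal(m$total_richness, 7)
  expect_equal(m$forage_abundance, 0)

  # all codes at or below 2: every abundance index is zero
  det2 <- transform(det, abundance_code = pmin(abundance_code, 2))
  m2 <- compute_site_metrics(det2, spp, make_sites("A"))
  expect_true(all(m2[c("cyano_abundance", "forage_abundance",
                       "matrix_abundance")] == 0))
})

test_that("sensitive richness uses strict region-matched cut-offs", {
  spp <- make_species(c("S1", "S2", "S3"),
                      n_west = c(3.0, 4.2, NA),
                      n_east = c(NA, NA, 1.0),
                      s_west = c(2.69, 2.7, NA))
  det <- data.frame(site_id = "A", species_id = c("S1", "S2", "S3"),
                    abundance_code = 3)
  m <- compute_site_metrics(det, spp, make_sites("A", "West"))
  # 3.0 < 4.2 counts; exactly 4.2 does not; an East-only rating does not
  # count in the West
  expect_equal(m$oligotroph_richness, 1)
  expect_equal(m$s_sensitive_richness, 1)  # 2.69 < 2.7, not 2.7 itself
  m_e <- compute_site_metrics(det, spp, make_sites("A", "East"))
  expect_equal(m_e$oligotroph_richness, 1)  # S3 rated 1.0 in the East
})

test_that("metrics are invariant to row order and monotone in detections", {
  set.seed(61)
  d <- generate_dataset(synthetic_config(n_sites = 120, seed = 8),
                        mode = "species")
  m1 <- compute_site_metrics(d$detections, d$species, d$sites)
  shuffled <- d$detections[sample(nrow(d$detections)), ]
  m2 <- compute_site_metrics(shuffled, d$species, d$sites)
  expect_equal(m1, m2)

  # adding a code-2 detection of a new species: abundance unchanged,
  # richness up by one on that site
  site <- d$sites$site_id[1]
  extra <- data.frame(site_id = site, species_id = "SPX",
                      abundance_code = 2)
  spp2 <- rbind(d$species[0, ], NA)[0, ]
  spp_x <- d$species
  spp_x[nrow(spp_x) + 1, "species_id"] <- "SPX"
  spp_x$functional_group[nrow(spp_x)] <- "cyano_large"
  m3 <- compute_site_metrics(rbind(d$detections, extra), spp_x, d$sites)
  i <- match(site, m1$site_id)
  expect_equal(m3$cyano_abundance[i], m1$cyano_abundance[i])
  expect_equal(m3$total_richness[i], m1$total_richness[i] + 1)
  expect_true(all(m3$total_richness >= m1$total_richness))
})

test_that("invalid codes and orphan species are rejected", {
  spp <- make_species("S1")
  expect_error(compute_site_metrics(
    data.frame(site_id = "A", species_id = "S1", abundance_code = 5),
    spp, make_sites("A")), "abundance codes")
  expect_error(compute_site_metrics(
    data.frame(site_id = "A", species_id = "S9", abundance_code = 3),
    spp, make_sites("A")), "absent")
})

test_that("sites below the richness floor are flagged, not dropped", {
  spp <- make_species(paste0("S", 1:6))
  det <- rbind(
    data.frame(site_id = "A", species_id = paste0("S", 1:6),
               abundance_code = 3),
    data.frame(site_id = "B", species_id = paste0("S", 1:3),
               abundance_code = 3))
  m <- compute_site_metrics(det, spp, make_sites(c("A", "B")))
  expect_identical(m$excluded, c(FALSE, TRUE))
  expect_equal(nrow(m), 2)
})

test_that("recomputed metrics match an independent tally on species mode", {
  d <- generate_dataset(synthetic_config(n_sites = 150, seed = 13),
                        mode = "species")
  m <- compute_site_metrics(d$detections, d$species, d$sites)
  # independent bookkeeping: plain merge + aggregate
  det <- merge(d$detections, d$species[c("species_id",
                                         "functional_group")])
  for (s in sample(d$sites$site_id, 10)) {
    rows <- det[det$site_id == s, ]
    i <- match(s, m$site_id)
    expect_equal(m$total_richness[i], length(unique(rows$species_id)))
    expect_equal(m$cyano_abundance[i],
                 sum(rows$abundance_code[rows$abundance_code >= 3 &
                       grepl("^cyano", rows$functional_group)]))
  }
})

test_that("sensitivity rating recovers a known detection peak", {
  set.seed(71)
  n <- 3000
  x <- exp(runif(n, log(0.2), log(12)))
  pr <- 0.8 * exp(-(log(x) - log(2))^2 / (2 * 0.6^2))
  detected <- runif(n) < pr
  r <- rate_sensitivity(detected, x)
  expect_true(r$rated)
  expect_identical(r$shape, "hump")
  expect_gte(r$rating, 1.6)
  expect_lte(r$rating, 2.4)
  # rating is insensitive to the grid resolution on well-sampled species
  r2 <- rate_sensitivity(detected, x, grid_size = 400)
  expect_lt(abs(r2$rating - r$rating) / r$rating, 0.1)
})

test_that("sparse or degenerate species are unrated", {
  x <- exp(runif(500, log(0.2), log(12)))
  det7 <- c(rep(TRUE, 7), rep(FALSE, 493))
  expect_false(rate_sensitivity(det7, x)$rated)
  # all sites at one deposition value: undefined curve
  expect_false(rate_sensitivity(rep(c(TRUE, FALSE), 50),
                                rep(3, 100))$rated)
})

test_that("monotone-decreasing species rate at the gradient minimum", {
  set.seed(72)
  n <- 2000
  x <- exp(runif(n, log(0.2), log(12)))
  detected <- runif(n) < 0.9 * exp(-1.2 * log(x / 0.2))
  r <- rate_sensitivity(detected, x)
  expect_identical(r$shape, "decreasing")
  expect_lt(r$rating, quantile(x, 0.05))
})

test_that("rarity classes split at 1% and 10% of regional sites", {
  expect_identical(classify_rarity(5, 1000), "rare")
  expect_identical(classify_rarity(150, 1000), "common")
  expect_identical(classify_rarity(50, 1000), "intermediate")
  expect_identical(classify_rarity(21, 2156), "rare")
  expect_identical(classify_rarity(22, 2156), "intermediate")
  expect_error(classify_rarity(5, 0), "positive")
})
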