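# Synthetic FIA-style lichen survey data with known ground truth.
#
# Two generation modes:
#   * metric mode — per-site metric values are drawn so that the conditional
#     90th quantile of each metric equals a configured quadratic in
#     deposition exactly (before integer rounding). This is the mode with
#     exact quantile guarantees, used to test the model-fitting and
#     critical-load stages against closed-form truth.
#   * species mode — individual species are given detection-probability
#     bumps along the log-deposition gradient and ocular abundance codes
#     from an ordinal cut of a latent abundance that decays past each
#     species' optimum. This exercises the detections -> metrics bookkeeping
#     and the sensitivity-rating stage.

#' Round half away from zero
#'
#' Counts and abundance values are rounded with ties going away from zero
#' (base `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Evaluate a polynomial with coefficients in increasing order of power
#'
#' @param coefs numeric vector `c(c0, c1, c2, ...)`.
#' @param x evaluation points.
#' @export
poly_eval <- function(coefs, x) {
  out <- rep(0, length(x))
  for (k in rev(seq_along(coefs))) out <- out * x + coefs[k]
  out
}

#' Quadratic decline curve touching zero at a given deposition
#'
#' `f(x) = peak * (1 - x / x0)^2`: monotone decline from `peak` to zero at
#' `x0`, nonnegative everywhere, so it is a valid conditional-quantile
#' curve over any deposition range.
#'
#' @param peak curve value at zero deposition.
#' @param x0 deposition at which the curve reaches zero.
#' @return quadratic coefficients `c(c0, c1, c2)`.
#' @export
decline_curve <- function(peak, x0) {
  c(peak, -2 * peak / x0, peak / x0^2)
}

.default_true_curves <- function() {
  # nonnegative quadratic 90th-quantile curves per metric, steepness
  # ordered like the field pattern: cyanolichens most sensitive, then
  # forage, sensitive richness, total richness; matrix flat
  list(
    total_richness       = decline_curve(33, 22),
    oligotroph_richness  = decline_curve(18, 16),
    s_sensitive_richness = decline_curve(17, 15),
    forage_abundance     = decline_curve(30, 12),
    cyano_abundance      = decline_curve(13, 10),
    matrix_abundance     = c(40, 0, 0)
  )
}

.default_climate_law <- function() {
  # climate normals: mean, sd, and correlation with log-deposition
  list(
    precip_mm        = c(mean = 1100, sd = 500, rho = -0.3),
    tmax_aug_c       = c(mean = 24,   sd = 4,   rho = 0.3),
    tmin_dec_c       = c(mean = -4,   sd = 6,   rho = 0.2),
    continentality_c = c(mean = 28,   sd = 6,   rho = 0.1),
    cmd_mm           = c(mean = 300,  sd = 180, rho = 0.3)
  )
}

#' Configuration for the synthetic survey generator
#'
#' Defaults describe a national-scale FIA-style survey: ~0.38 ha plots, a
#' West-dominated site mix, log-uniform total deposition per region with the
#' West concentrated at low deposition and the East starting higher, five
#' climate normals correlated with deposition, and per-metric quadratic
#' conditional-90th-quantile curves.
#'
#' @param n_sites number of survey sites.
#' @param region_mix fraction of sites in the West.
#' @param deposition_law per-region log-uniform ranges (kg ha-1 yr-1) for N
#'   and S deposition.
#' @param climate_law per-variable mean, sd and correlation with
#'   log-deposition.
#' @param n_species named count of species per functional group (species
#'   mode).
#' @param true_curve named list of quadratic coefficients `c(c0, c1, c2)`
#'   of the conditional 90th quantile of each metric (metric mode).
#' @param noise_law sub-maximal response multiplier law; `"uniform"` is
#'   Uniform(0, 1/0.9), whose 90th percentile is exactly 1; `"degenerate"`
#'   is the noise-free limit (multiplier identically 1).
#' @param pollutant which deposition drives the metric curves, "N" or "S".
#' @param seed integer seed; identical seeds give identical datasets.
#' @return a validated list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_sites = 2000,
                             region_mix = 0.75,
                             deposition_law = list(
                               west = c(min = 0.2, max = 12),
                               east = c(min = 2.2, max = 20)),
                             climate_law = .default_climate_law(),
                             n_species = c(cyano_large = 8,
                                           cyano_small_med = 12,
                                           forage_pendant = 10,
                                           forage_shrubby = 10,
                                           matrix_med_large = 28,
                                           matrix_small = 20),
                             true_curve = .default_true_curves(),
                             noise_law = "uniform",
                             pollutant = c("N", "S"),
                             seed = 1) {
  pollutant <- match.arg(pollutant)
  if (!is.numeric(n_sites) || n_sites < 1) {
    stop("n_sites must be a positive count")
  }
  if (any(unlist(n_species) < 0)) stop("n_species must be non-negative")
  if (region_mix < 0 || region_mix > 1) stop("region_mix must be in [0, 1]")
  for (rg in deposition_law) {
    if (any(rg <= 0)) stop("deposition range must be strictly positive")
    if (rg["min"] >= rg["max"]) stop("deposition min must be below max")
  }
  x_lo <- min(vapply(deposition_law, function(r) r[["min"]], numeric(1)))
  for (nm in names(true_curve)) {
    if (poly_eval(true_curve[[nm]], x_lo) < 0) {
      stop("true curve for ", nm, " is negative at minimum deposition")
    }
  }
  cfg <- list(n_sites = as.integer(n_sites), region_mix = region_mix,
              deposition_law = deposition_law, climate_law = climate_law,
              n_species = n_species, true_curve = true_curve,
              noise_law = noise_law, pollutant = pollutant,
              seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  cfg
}

.rlogunif <- function(n, lo, hi) {
  exp(stats::runif(n, log(lo), log(hi)))
}

.noise_multiplier <- function(n, noise_law) {
  if (is.function(noise_law)) return(noise_law(n))
  switch(noise_law,
    uniform = stats::runif(n, 0, 1 / 0.9),
    degenerate = rep(1, n),
    stop("unknown noise law: ", noise_law)
  )
}

#' Draw metric values whose conditional 90th quantile follows a curve
#'
#' Values are `round_half_away(f(x) * U)` with `U` a multiplier whose 90th
#' percentile is exactly 1 (default Uniform(0, 1/0.9)), so the conditional
#' 90th quantile of the *unrounded* values equals `f(x)` exactly; integer
#' rounding distorts this by at most 0.5.
#'
#' @param x deposition vector.
#' @param curve quadratic coefficients `c(c0, c1, c2)`.
#' @param noise_law `"uniform"`, `"degenerate"`, or a function `n ->
#'   multipliers` (must be renormalized so its 90th percentile is 1).
#' @param seed optional integer seed.
#' @return non-negative integer-valued metric vector.
#' @export
sample_metric_values <- function(x, curve, noise_law = "uniform",
                                 seed = NULL) {
  fx <- poly_eval(curve, x)
  if (any(fx < 0)) {
    stop("curve is negative over the deposition range")
  }
  if (!is.null(seed)) set.seed(seed)
  u <- .noise_multiplier(length(x), noise_law)
  round_half_away(fx * u)
}

#' Closed-form deposition at a fractional decline of a quadratic curve
#'
#' The analytic inverse of the decline curve: the smallest `x >= x_min`
#' with `f(x) = (1 - decline) * f(x_min)`, solved by the quadratic formula.
#' This is the ground-truth oracle the numeric root-finder in the
#' critical-load stage is tested against.
#'
#' @param curve quadratic coefficients `c(c0, c1, c2)`.
#' @param x_min reference deposition (the fitted maximum of the response).
#' @param decline target fractional decline in `[0, 1)`.
#' @return deposition, or `NA` if the curve never reaches the target.
#' @export
true_deposition_at_decline <- function(curve, x_min, decline) {
  if (decline < 0 || decline >= 1) stop("decline must be in [0, 1)")
  target <- (1 - decline) * poly_eval(curve, x_min)
  c2 <- if (length(curve) >= 3) curve[3] else 0
  c1 <- curve[2]
  c0 <- curve[1] - target
  eps <- 1e-9 * (1 + abs(x_min))
  if (abs(c2) < .Machine$double.eps) {
    if (abs(c1) < .Machine$double.eps) {
      return(if (abs(c0) < 1e-12) x_min else NA_real_)
    }
    root <- -c0 / c1
    return(if (root >= x_min - eps) max(root, x_min) else NA_real_)
  }
  disc <- c1^2 - 4 * c2 * c0
  if (disc < 0) return(NA_real_)
  roots <- sort((-c1 + c(-1, 1) * sqrt(disc)) / (2 * c2))
  roots <- roots[roots >= x_min - eps]
  if (!length(roots)) return(NA_real_)
  max(roots[1], x_min)
}

.draw_sites <- function(cfg) {
  n <- cfg$n_sites
  region <- ifelse(stats::runif(n) < cfg$region_mix, "West", "East")
  n_dep <- s_dep <- numeric(n)
  for (rg in c("West", "East")) {
    law <- cfg$deposition_law[[tolower(rg)]]
    idx <- region == rg
    n_dep[idx] <- .rlogunif(sum(idx), law["min"], law["max"])
    s_dep[idx] <- .rlogunif(sum(idx), law["min"], law["max"])
  }
  ldep <- log(if (cfg$pollutant == "N") n_dep else s_dep)
  z <- (ldep - mean(ldep)) / stats::sd(ldep)
  clim <- lapply(cfg$climate_law, function(v) {
    v[["mean"]] + v[["sd"]] *
      (v[["rho"]] * z + sqrt(1 - v[["rho"]]^2) * stats::rnorm(n))
  })
  data.frame(site_id = sprintf("S%05d", seq_len(n)), region = region,
             n_dep = n_dep, s_dep = s_dep, as.data.frame(clim),
             stringsAsFactors = FALSE)
}

# genus pools per functional group, so species-mode datasets round-trip
# through the genus-based functional-group assignment
.genus_pool <- list(
  cyano_large = c("Lobaria", "Nephroma", "Peltigera", "Sticta"),
  cyano_small_med = c("Collema", "Leptogium", "Pannaria", "Scytinium"),
  forage_pendant = c("Alectoria", "Bryoria", "Usnea", "Ramalina"),
  forage_shrubby = c("Evernia", "Letharia", "Sphaerophorus", "Usnea"),
  matrix_med_large = c("Hypogymnia", "Parmelia", "Platismatia", "Physcia"),
  matrix_small = c("Cladonia", "Phaeophyscia", "Xanthomendoza", "Parmeliopsis")
)

.draw_species <- function(cfg) {
  groups <- names(cfg$n_species)
  rows <- list()
  dep_lo <- min(vapply(cfg$deposition_law, function(r) r[["min"]],
                       numeric(1)))
  dep_hi <- max(vapply(cfg$deposition_law, function(r) r[["max"]],
                       numeric(1)))
  # sensitive groups get optima concentrated low on the gradient
  mu_hi <- c(cyano_large = 0.25, cyano_small_med = 0.4,
             forage_pendant = 0.3, forage_shrubby = 0.45,
             matrix_med_large = 1, matrix_small = 0.9)
  k <- 0L
  for (g in groups) {
    ns <- cfg$n_species[[g]]
    if (ns == 0) next
    pool <- .genus_pool[[g]]
    hi <- dep_lo * (dep_hi / dep_lo)^mu_hi[[g]]
    for (j in seq_len(ns)) {
      k <- k + 1L
      genus <- pool[(j - 1L) %% length(pool) + 1L]
      mu_n <- .rlogunif(1, dep_lo * 1.2, hi)
      mu_s <- .rlogunif(1, dep_lo * 1.2, hi)
      rows[[k]] <- data.frame(
        species_id = sprintf("SP%03d", k),
        genus = genus,
        growth_form = switch(g,
          forage_pendant = "pendant",
          forage_shrubby = "shrubby",
          cyano_large = "foliose-large",
          matrix_med_large = "foliose-large",
          "foliose-small"),
        photobiont = if (g %in% c("cyano_large", "cyano_small_med"))
          "cyano" else "green",
        functional_group = g,
        true_mu_n = mu_n,
        true_mu_s = mu_s,
        # log-uniform peak frequencies: most species are infrequent, a
        # few are common, mirroring real survey rarity spectra
        peak_freq = .rlogunif(1, 0.01, 0.9),
        width = stats::runif(1, 0.5, 1.1),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) stop("no species configured")
  do.call(rbind, rows)
}

.draw_detections <- function(sites, species) {
  ldn <- log(sites$n_dep)
  rows <- vector("list", nrow(species))
  for (i in seq_len(nrow(species))) {
    sp <- species[i, ]
    pr <- sp$peak_freq *
      exp(-(ldn - log(sp$true_mu_n))^2 / (2 * sp$width^2))
    hit <- stats::runif(nrow(sites)) < pr
    if (!any(hit)) next
    # latent abundance decays past the optimum; ordinal cut -> codes 1..4
    excess <- pmax(0, ldn[hit] - log(sp$true_mu_n))
    latent <- exp(-excess / sp$width) * stats::runif(sum(hit), 0.3, 1.5)
    code <- cut(latent, c(-Inf, 0.35, 0.7, 1.05, Inf), labels = FALSE)
    rows[[i]] <- data.frame(site_id = sites$site_id[hit],
                            species_id = sp$species_id,
                            abundance_code = as.integer(code),
                            stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(site_id = character(), species_id = character(),
                      abundance_code = integer(), stringsAsFactors = FALSE))
  }
  det <- do.call(rbind, rows)
  det[order(det$site_id, det$species_id), , drop = FALSE]
}

#' Generate a synthetic FIA-style survey dataset
#'
#' @param config a [synthetic_config()].
#' @param mode `"metric"` draws per-site metric values directly from the
#'   configured conditional-90th-quantile curves (exact quantile
#'   guarantees); `"species"` simulates individual species detections and
#'   abundance codes (exercises the metric bookkeeping).
#' @return list of class `"synthetic_dataset"` with elements `sites`,
#'   `species`, `detections`, `metrics` (metric mode only), and
#'   `true_model` (the generating curves / species optima).
#' @export
generate_dataset <- function(config, mode = c("metric", "species")) {
  stopifnot(inherits(config, "synthetic_config"))
  mode <- match.arg(mode)
  set.seed(config$seed)
  sites <- .draw_sites(config)
  species <- .draw_species(config)
  dep <- if (config$pollutant == "N") sites$n_dep else sites$s_dep

  if (mode == "metric") {
    metrics <- data.frame(site_id = sites$site_id,
                          stringsAsFactors = FALSE)
    for (nm in names(config$true_curve)) {
      metrics[[nm]] <- sample_metric_values(dep, config$true_curve[[nm]],
                                            config$noise_law)
    }
    detections <- data.frame(site_id = character(),
                             species_id = character(),
                             abundance_code = integer(),
                             stringsAsFactors = FALSE)
  } else {
    detections <- .draw_detections(sites, species)
    metrics <- NULL
  }

  # rated sensitivity = the true optimum; per-region detection counts
  for (rg in c("East", "West")) {
    cnt <- integer(nrow(species))
    if (nrow(detections)) {
      det_rg <- detections[detections$site_id %in%
                             sites$site_id[sites$region == rg], ]
      tb <- table(det_rg$species_id)
      cnt <- as.integer(tb[species$species_id])
      cnt[is.na(cnt)] <- 0L
    }
    species[[paste0("n_detections_", tolower(rg))]] <- cnt
    species[[paste0("n_rating_", tolower(rg))]] <- species$true_mu_n
    species[[paste0("s_rating_", tolower(rg))]] <- species$true_mu_s
  }

  true_model <- list(
    mode = mode,
    pollutant = config$pollutant,
    curves = config$true_curve,
    x_min = min(dep),
    species_optima = stats::setNames(species$true_mu_n,
                                     species$species_id),
    seed = config$seed
  )
  out <- list(sites = sites, species = species, detections = detections,
              metrics = metrics, true_model = true_model, config = config)
  class(out) <- "synthetic_dataset"
  out
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic lichen survey: %d sites, %d species, %d detections (%s mode)\n",
              nrow(x$sites), nrow(x$species), nrow(x$detections),
              x$true_model$mode))
  invisible(x)
}
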