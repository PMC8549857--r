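# Per-site indicator metrics and per-species sensitivity ratings from
# survey detections with ocular abundance codes.

#' Metric-construction configuration
#'
#' Houses the fixed thresholds of the indicator construction: species are
#' nitrogen-sensitive ("oligotrophs") below 4.2 kg N ha-1 yr-1 and
#' sulfur-sensitive below 2.7 kg S ha-1 yr-1 (strict inequalities);
#' functional-group abundance indices sum ocular codes of 3 and 4 only;
#' sites with fewer than 5 species are flagged for exclusion; a species
#' needs at least 8 detections in a region to be rated; species detected at
#' under 1% of a region's sites are "rare" and at over 10% "common".
#'
#' @param n_sensitive_cutoff kg N ha-1 yr-1.
#' @param s_sensitive_cutoff kg S ha-1 yr-1.
#' @param abundance_code_floor lowest code counted in abundance indices.
#' @param min_site_richness minimum species per site for inclusion.
#' @param min_detections_for_rating minimum detections for a rating.
#' @param rare_fraction,common_fraction rarity-class boundaries.
#' @export
metric_config <- function(n_sensitive_cutoff = 4.2,
                          s_sensitive_cutoff = 2.7,
                          abundance_code_floor = 3L,
                          min_site_richness = 5L,
                          min_detections_for_rating = 8L,
                          rare_fraction = 0.01,
                          common_fraction = 0.10) {
  stopifnot(n_sensitive_cutoff > 0, s_sensitive_cutoff > 0,
            abundance_code_floor == as.integer(abundance_code_floor),
            min_site_richness == as.integer(min_site_richness))
  structure(list(n_sensitive_cutoff = n_sensitive_cutoff,
                 s_sensitive_cutoff = s_sensitive_cutoff,
                 abundance_code_floor = as.integer(abundance_code_floor),
                 min_site_richness = as.integer(min_site_richness),
                 min_detections_for_rating =
                   as.integer(min_detections_for_rating),
                 rare_fraction = rare_fraction,
                 common_fraction = common_fraction),
            class = "metric_config")
}

.fg_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "functional_groups.csv",
                          package = "lichenrisk")
      if (path == "") path <- file.path("inst", "extdata",
                                        "functional_groups.csv")
      cache <<- utils::read.csv(path, stringsAsFactors = FALSE)
    }
    cache
  }
})

#' Genus-to-functional-group lookup table
#'
#' The packaged assignment of genera to the six functional groups (large
#' and small-to-medium cyanolichens, pendant and shrubby forage lichens,
#' medium-to-large and small matrix lichens).
#'
#' @return data.frame with columns `genus`, `functional_group`,
#'   `form_dependent`.
#' @export
functional_group_table <- function() {
  .fg_table()
}

#' Assign species to functional groups
#'
#' Deterministic lookup by genus. *Ramalina* and *Usnea* span the pendant
#' and shrubby forage groups and are disambiguated by growth form. Genera
#' absent from the lookup fall back on photobiont and growth form (a
#' cyanobacterial photobiont implies a cyanolichen group, a pendant or
#' shrubby form a forage group, a foliose form a matrix group); with no
#' usable fallback the species is returned as `NA` (unassigned).
#'
#' @param genus character vector.
#' @param growth_form one of `"pendant"`, `"shrubby"`, `"foliose-large"`,
#'   `"foliose-small"`, `"other"` (recycled).
#' @param photobiont `"green"` or `"cyano"` (recycled).
#' @return character vector of functional groups (`NA` = unassigned).
#' @export
assign_functional_group <- function(genus, growth_form = "other",
                                    photobiont = "green") {
  if (any(!nzchar(genus))) stop("genus must be nonempty")
  n <- length(genus)
  growth_form <- rep_len(growth_form, n)
  photobiont <- rep_len(photobiont, n)
  tab <- .fg_table()
  i <- match(genus, tab$genus)
  out <- tab$functional_group[i]
  dual <- !is.na(i) & tab$form_dependent[i]
  out[dual] <- ifelse(growth_form[dual] == "pendant",
                      "forage_pendant", "forage_shrubby")
  miss <- is.na(i)
  if (any(miss)) {
    fb <- rep(NA_character_, sum(miss))
    gf <- growth_form[miss]
    pb <- photobiont[miss]
    fb[pb == "cyano" & gf == "foliose-large"] <- "cyano_large"
    fb[pb == "cyano" & gf != "foliose-large"] <- "cyano_small_med"
    fb[pb != "cyano" & gf == "pendant"] <- "forage_pendant"
    fb[pb != "cyano" & gf == "shrubby"] <- "forage_shrubby"
    fb[pb != "cyano" & gf == "foliose-large"] <- "matrix_med_large"
    fb[pb != "cyano" & gf == "foliose-small"] <- "matrix_small"
    out[miss] <- fb
  }
  out
}

.validate_detections <- function(detections, species) {
  bad_code <- !detections$abundance_code %in% 1:4
  if (any(bad_code)) {
    stop("abundance codes outside {1, 2, 3, 4} at detection row(s): ",
         paste(utils::head(which(bad_code), 10), collapse = ", "))
  }
  orphan <- !detections$species_id %in% species$species_id
  if (any(orphan)) {
    stop("detections reference species absent from the species table, ",
         "row(s): ", paste(utils::head(which(orphan), 10), collapse = ", "))
  }
}

#' Compute the six per-site indicator metrics
#'
#' Total species richness (distinct species), oligotroph (N-sensitive) and
#' S-sensitive richness (species whose region-matched rating is strictly
#' below the cut-off), and forage, cyanolichen and matrix abundance indices
#' (sum of ocular abundance codes of 3 and 4 over the group's species).
#' Sites below the richness floor are retained with `excluded = TRUE`
#' rather than dropped. A species rated only in the other region does not
#' count toward sensitive richness.
#'
#' @param detections data.frame with `site_id`, `species_id`,
#'   `abundance_code`.
#' @param species species-attribute data.frame with `species_id`,
#'   `functional_group`, and regional rating columns `n_rating_east`,
#'   `n_rating_west`, `s_rating_east`, `s_rating_west` (NA = unrated).
#' @param sites data.frame with `site_id` and `region` ("East"/"West"),
#'   used to match ratings to the site's region.
#' @param config a [metric_config()].
#' @return data.frame with one row per site in `sites`.
#' @export
compute_site_metrics <- function(detections, species, sites,
                                 config = metric_config()) {
  .validate_detections(detections, species)
  i <- match(detections$species_id, species$species_id)
  region <- sites$region[match(detections$site_id, sites$site_id)]
  if (anyNA(region) && nrow(detections)) {
    stop("detections reference sites absent from the site table")
  }
  fg <- species$functional_group[i]

  n_rating <- ifelse(region == "East",
                     species$n_rating_east[i], species$n_rating_west[i])
  s_rating <- ifelse(region == "East",
                     species$s_rating_east[i], species$s_rating_west[i])
  oligo <- !is.na(n_rating) & n_rating < config$n_sensitive_cutoff
  s_sens <- !is.na(s_rating) & s_rating < config$s_sensitive_cutoff
  abundant <- detections$abundance_code >= config$abundance_code_floor
  code_ab <- ifelse(abundant, detections$abundance_code, 0L)

  agg <- function(v, f = sum) {
    out <- tapply(v, factor(detections$site_id, levels = sites$site_id), f)
    out[is.na(out)] <- 0
    as.numeric(out)
  }
  res <- data.frame(
    site_id = sites$site_id,
    total_richness = agg(rep(1L, nrow(detections))),
    oligotroph_richness = agg(as.integer(oligo)),
    s_sensitive_richness = agg(as.integer(s_sens)),
    forage_abundance = agg(code_ab *
      (fg %in% c("forage_pendant", "forage_shrubby"))),
    cyano_abundance = agg(code_ab *
      (fg %in% c("cyano_large", "cyano_small_med"))),
    matrix_abundance = agg(code_ab *
      (fg %in% c("matrix_med_large", "matrix_small"))),
    stringsAsFactors = FALSE
  )
  res$excluded <- res$total_richness < config$min_site_richness
  res
}

#' Rate a species' pollution sensitivity from its detection frequency
#'
#' Detection frequency along the deposition gradient is estimated by a
#' Gaussian-kernel-smoothed binomial frequency on log-deposition
#' (Silverman's-rule bandwidth, 200-point grid spanning the observed
#' range). The rating is the deposition at the curve's maximum; the
#' response shape is "increasing" when the maximum falls in the top 10% of
#' the grid, "decreasing" in the bottom 10%, and "hump" otherwise. Species
#' with fewer than the configured minimum detections are unrated.
#'
#' @param detected logical vector: was the species detected at each site?
#' @param deposition per-site deposition (same order), kg ha-1 yr-1.
#' @param config a [metric_config()].
#' @param grid_size number of grid points.
#' @return list with `rated`, `rating`, `shape`, `n_detections`, and the
#'   frequency `curve` (data.frame `deposition`, `frequency`).
#' @export
rate_sensitivity <- function(detected, deposition,
                             config = metric_config(), grid_size = 200) {
  stopifnot(length(detected) == length(deposition))
  n_det <- sum(detected)
  unrated <- list(rated = FALSE, rating = NA_real_, shape = NA_character_,
                  n_detections = n_det, curve = NULL)
  if (n_det < config$min_detections_for_rating) return(unrated)
  l <- log(deposition)
  sdl <- stats::sd(l)
  if (!is.finite(sdl) || sdl == 0) return(unrated)  # one deposition value
  n <- length(l)
  bw <- 0.9 * min(sdl, stats::IQR(l) / 1.34) * n^(-1 / 5)
  if (bw <= 0) bw <- sdl * n^(-1 / 5)
  grid <- seq(min(l), max(l), length.out = grid_size)
  freq <- vapply(grid, function(g) {
    w <- stats::dnorm((g - l) / bw)
    sum(w * detected) / sum(w)
  }, numeric(1))
  i_max <- which.max(freq)
  shape <- if (i_max > 0.9 * grid_size) "increasing"
           else if (i_max <= 0.1 * grid_size) "decreasing"
           else "hump"
  list(rated = TRUE, rating = exp(grid[i_max]), shape = shape,
       n_detections = n_det,
       curve = data.frame(deposition = exp(grid), frequency = freq))
}

#' Classify species rarity from regional detection counts
#'
#' Rare: detected at under `rare_fraction` (1%) of the region's sites;
#' common: at over `common_fraction` (10%); otherwise intermediate.
#'
#' @param n_detections detections of each species in the region.
#' @param n_sites_region number of surveyed sites in the region.
#' @param config a [metric_config()].
#' @return character vector: "rare", "intermediate" or "common".
#' @export
classify_rarity <- function(n_detections, n_sites_region,
                            config = metric_config()) {
  if (n_sites_region <= 0) stop("n_sites_region must be positive")
  frac <- n_detections / n_sites_region
  ifelse(frac < config$rare_fraction, "rare",
         ifelse(frac > config$common_fraction, "common", "intermediate"))
}
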