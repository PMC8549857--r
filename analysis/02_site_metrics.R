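#!/usr/bin/env Rscript
# Step 2 — build the six per-site indicator metrics from the species-mode
# detections, rate each species' nitrogen sensitivity from its detection
# frequency, and classify rarity. Writes results/site_metrics.csv and
# results/species_ratings.csv.

suppressPackageStartupMessages(library(lichenrisk))

ds <- read_dataset(list(
  detections = "results/data/species_mode/detections.csv",
  sites = "results/data/species_mode/sites.csv",
  species = "results/data/species_mode/species.csv"))

cfg <- metric_config()
metrics <- compute_site_metrics(ds$detections, ds$species, ds$sites, cfg)
utils::write.csv(metrics, "results/site_metrics.csv", row.names = FALSE)

cat(sprintf("%d sites; %d below the %d-species floor (flagged excluded)\n",
            nrow(metrics), sum(metrics$excluded), cfg$min_site_richness))
cat(sprintf("median richness %.0f; cyanolichen abundance index range %d-%d\n",
            median(metrics$total_richness), min(metrics$cyano_abundance),
            max(metrics$cyano_abundance)))

# empirical sensitivity ratings (deposition at peak detection frequency),
# recovered from the smoothed detection-frequency curves, West region
west <- ds$sites$region == "West"
ratings <- do.call(rbind, lapply(seq_len(nrow(ds$species)), function(i) {
  sp <- ds$species[i, ]
  det_sites <- ds$detections$site_id[ds$detections$species_id ==
                                       sp$species_id]
  detected <- ds$sites$site_id[west] %in% det_sites
  r <- rate_sensitivity(detected, ds$sites$n_dep[west], cfg)
  data.frame(species_id = sp$species_id,
             functional_group = sp$functional_group,
             true_optimum = sp$true_mu_n,
             n_detections = r$n_detections, rated = r$rated,
             rating = r$rating, shape = r$shape,
             rarity = classify_rarity(r$n_detections, sum(west), cfg))
}))
utils::write.csv(ratings, "results/species_ratings.csv", row.names = FALSE)

rated <- ratings[ratings$rated & ratings$shape == "hump", ]
err <- abs(log(rated$rating / rated$true_optimum))
cat(sprintf("%d of %d species rated (>= %d detections); %d hump-shaped\n",
            sum(ratings$rated), nrow(ratings),
            cfg$min_detections_for_rating, nrow(rated)))
cat(sprintf(
  "hump-shaped ratings within 25%% of the true optimum: %d of %d (median |log error| %.2f)\n",
  sum(err < log(1.25)), nrow(rated), median(err)))
cat(sprintf("rarity classes: %s\n",
            paste(names(table(ratings$rarity)), table(ratings$rarity),
                  collapse = ", ", sep = "=")))
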