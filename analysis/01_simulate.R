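#!/usr/bin/env Rscript
# Step 1 — simulate the survey data the rest of the workflow analyzes.
#
# Two seeded datasets are written under results/data/:
#   * a species-mode survey (individual detections with ocular abundance
#     codes), which feeds the metric construction, sensitivity-rating and
#     group-comparison steps; and
#   * a metric-mode survey whose per-site metrics have a *known* quadratic
#     conditional 90th quantile, which feeds the model-fitting and
#     critical-load steps and lets us compare estimates to closed-form
#     truth.

suppressPackageStartupMessages(library(lichenrisk))

out_dir <- file.path("results", "data")

species_cfg <- synthetic_config(n_sites = 3000, seed = 101)
species_data <- generate_dataset(species_cfg, mode = "species")
write_dataset(species_data, file.path(out_dir, "species_mode"))

metric_cfg <- synthetic_config(
  n_sites = 3000, seed = 202,
  deposition_law = list(west = c(min = 0.2, max = 12),
                        east = c(min = 2.2, max = 12)),
  true_curve = list(total_richness = c(30, -3, 0.05),
                    oligotroph_richness = decline_curve(18, 16),
                    s_sensitive_richness = decline_curve(17, 15),
                    forage_abundance = decline_curve(30, 12),
                    cyano_abundance = decline_curve(13, 10),
                    matrix_abundance = c(40, 0, 0)))
metric_data <- generate_dataset(metric_cfg, mode = "metric")
write_dataset(metric_data, file.path(out_dir, "metric_mode"))
utils::write.csv(metric_data$metrics,
                 file.path(out_dir, "metric_mode", "site_metrics.csv"),
                 row.names = FALSE)

cat(sprintf(
  "species mode: %d sites, %d species, %d detections\n",
  nrow(species_data$sites), nrow(species_data$species),
  nrow(species_data$detections)))
cat(sprintf("metric mode: %d sites, %d metrics with known quantile curves\n",
            nrow(metric_data$sites),
            length(metric_cfg$true_curve)))
cat("true N critical loads implied by the generating curves:\n")
for (nm in names(metric_cfg$true_curve)) {
  cl <- true_deposition_at_decline(metric_cfg$true_curve[[nm]], 0.2, 0.2)
  cat(sprintf("  %-22s %s kg\n", nm,
              if (is.na(cl)) "-" else sprintf("%.2f", cl)))
}
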