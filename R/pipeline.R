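# End-to-end orchestration: simulate (or read) -> metrics -> 90% quantile
# fits -> critical loads -> species risk -> group comparisons.

#' Pipeline run configuration
#'
#' Either `input_paths` (CSV files for an observed dataset) or
#' `synthetic` (a [synthetic_config()]) must be supplied, not both. Every
#' analysis constant is surfaced here with the workflow's default: tau =
#' 0.9, polynomial degree 2, modeling windows of 12 kg N and 20 kg S,
#' delta-AIC threshold 25, and the bootstrap replicate count.
#'
#' @param input_paths named list of CSVs for [read_dataset()], or `NULL`.
#' @param synthetic a [synthetic_config()], or `NULL`.
#' @param pollutant "N" or "S".
#' @param tau quantile level.
#' @param degree polynomial degree for the deposition-only model.
#' @param fit_window modeling-window upper end (kg ha-1 yr-1); defaults to
#'   12 for N and 20 for S.
#' @param n_boot bootstrap replicates for the critical-load CIs.
#' @param aic_threshold delta-AIC needed to adopt a richer nested model.
#' @param seed integer seed for the bootstrap.
#' @param out_dir where results are written.
#' @export
run_config <- function(input_paths = NULL, synthetic = NULL,
                       pollutant = c("N", "S"), tau = 0.9, degree = 2,
                       fit_window = NULL, n_boot = 1000,
                       aic_threshold = 25, seed = 1,
                       out_dir = "results") {
  pollutant <- match.arg(pollutant)
  if (is.null(input_paths) == is.null(synthetic)) {
    stop("exactly one of input_paths or synthetic must be given")
  }
  if (is.null(fit_window)) fit_window <- if (pollutant == "N") 12 else 20
  structure(list(input_paths = input_paths, synthetic = synthetic,
                 pollutant = pollutant, tau = tau, degree = degree,
                 fit_window = fit_window, n_boot = n_boot,
                 aic_threshold = aic_threshold, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments;
#'   a `synthetic:` block is passed to [synthetic_config()].
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read YAML configurations")
  }
  raw <- yaml::read_yaml(path)
  # YAML 1.1 reads a bare `N` as boolean false; map it back
  if (is.logical(raw$pollutant)) {
    raw$pollutant <- if (isFALSE(raw$pollutant)) "N" else
      stop("pollutant must be \"N\" or \"S\"")
  }
  if (!is.null(raw$synthetic)) {
    raw$synthetic <- do.call(synthetic_config, raw$synthetic)
  }
  do.call(run_config, raw)
}

.log_line <- function(...) {
  message(sprintf("[lichenrisk] %s", sprintf(...)))
}

#' Run the full risk-analysis pipeline
#'
#' Builds (or loads) the dataset, computes per-site metrics, fits the
#' intercept-only, climate-only, deposition-only and deposition+climate
#' 90% quantile models for each metric inside the modeling window, selects
#' among them by the delta-AIC rule, inverts the deposition-only curve
#' into a critical load with a bootstrap confidence interval, and writes
#' every table through [write_results()]. All thresholds in use are
#' echoed to the log.
#'
#' @param config a [run_config()].
#' @param metrics which metrics to model; defaults to the richness metrics
#'   and the forage/cyanolichen abundance indices (matrix abundance is
#'   deliberately retained in the output tables but known to be flat).
#' @return the result manifest, invisibly.
#' @export
run_pipeline <- function(config,
                         metrics = c("total_richness",
                                     "oligotroph_richness",
                                     "s_sensitive_richness",
                                     "forage_abundance",
                                     "cyano_abundance")) {
  stopifnot(inherits(config, "run_config"))
  .log_line("tau = %g, degree = %d, window = %g kg, dAIC > %g, %d boot reps, seed %d",
            config$tau, config$degree, config$fit_window,
            config$aic_threshold, config$n_boot, config$seed)

  if (!is.null(config$synthetic)) {
    dataset <- generate_dataset(config$synthetic,
                                mode = config$synthetic$mode %||% "metric")
    .log_line("synthetic dataset: %d sites (seed %d)",
              nrow(dataset$sites), config$synthetic$seed)
  } else {
    dataset <- read_dataset(config$input_paths)
    .log_line("read dataset: %d sites, %d detections",
              nrow(dataset$sites), nrow(dataset$detections))
  }

  mcfg <- metric_config()
  if (!is.null(dataset$metrics)) {
    site_metrics <- dataset$metrics
    site_metrics$excluded <- FALSE
  } else {
    site_metrics <- compute_site_metrics(dataset$detections,
                                         dataset$species, dataset$sites,
                                         mcfg)
  }
  .log_line("sensitivity cutoffs: %.1f kg N / %.1f kg S; abundance codes >= %d; site richness floor %d",
            mcfg$n_sensitive_cutoff, mcfg$s_sensitive_cutoff,
            mcfg$abundance_code_floor, mcfg$min_site_richness)

  dep <- if (config$pollutant == "N") dataset$sites$n_dep else
    dataset$sites$s_dep
  clim <- as.matrix(dataset$sites[, c("precip_mm", "tmax_aug_c",
                                      "tmin_dec_c", "continentality_c",
                                      "cmd_mm")])
  keep <- dep <= config$fit_window & !site_metrics$excluded
  x <- dep[keep]
  x_min <- min(x)
  rcfg <- risk_config()

  fits <- list()
  cl_rows <- list()
  decline_tabs <- list()
  for (m in intersect(metrics, names(site_metrics))) {
    y <- site_metrics[[m]][keep]
    X_dep <- deposition_design(x, config$degree)
    X_clim <- cbind(intercept = 1, clim[keep, ])
    X_full <- cbind(X_dep, clim[keep, ])
    f_null <- fit_quantile_regression(X_dep[, 1, drop = FALSE], y,
                                      config$tau)
    f_dep <- fit_quantile_regression(X_dep, y, config$tau)
    f_clim <- fit_quantile_regression(X_clim, y, config$tau)
    f_full <- fit_quantile_regression(X_full, y, config$tau)
    sel <- compare_models(list(clim = f_clim, dep_clim = f_full),
                          config$aic_threshold)
    r1_dep <- r1_statistic(f_dep, f_null)
    .log_line("%s: R1(dep) = %.3f, dAIC(dep+clim vs clim) = %.0f -> %s",
              m, r1_dep, sel$delta_aic[2], sel$selected)
    fits[[m]] <- list(
      coefficients = as.list(f_dep$coefficients),
      r1 = r1_dep, aic = qr_aic(f_dep), n = f_dep$n,
      r1_climate = r1_statistic(f_clim, f_null),
      r1_full = r1_statistic(f_full, f_null),
      delta_aic_dep_clim_vs_clim = unname(sel$delta_aic[2]),
      selected = sel$selected
    )

    if (poly_eval(unname(f_dep$coefficients), x_min) <= 0) {
      .log_line("%s: non-positive fitted reference; critical load skipped", m)
      next
    }
    risk <- build_risk_table(f_dep, x_min, config$fit_window, metric = m,
                             pollutant = config$pollutant, config = rcfg)
    boot <- bootstrap_fits(X_dep, y, config$tau, config$n_boot,
                           seed = config$seed)
    ci <- tryCatch(cl_confidence_interval(boot, x_min, config$fit_window,
                                          rcfg),
                   error = function(e) list(lower = NA, upper = NA,
                                            n_unusable = NA))
    cl_rows[[m]] <- data.frame(
      metric = m, pollutant = config$pollutant,
      cl = risk$cl, cl_lower = ci$lower, cl_upper = ci$upper,
      x_min = x_min, reference_value = unname(risk$reference["value"]),
      stringsAsFactors = FALSE)
    anch <- risk$anchors
    anch$metric <- m
    decline_tabs[[m]] <- anch
  }

  results <- list(
    site_metrics = site_metrics,
    model_fits = fits,
    critical_loads = if (length(cl_rows)) do.call(rbind, cl_rows) else NULL,
    decline_anchors = if (length(decline_tabs))
      do.call(rbind, decline_tabs) else NULL
  )

  # functional-group sensitivity comparisons (species with a rating)
  sp <- dataset$species
  rat_col <- paste0(tolower(config$pollutant), "_rating_west")
  if (rat_col %in% names(sp) && sum(!is.na(sp[[rat_col]])) >= 4) {
    cmp <- tryCatch(anom_ranks(sp[[rat_col]], sp$functional_group),
                    error = function(e) NULL)
    if (!is.null(cmp)) results$group_comparison <- cmp$groups
  }

  manifest <- write_results(results, config$out_dir)
  .log_line("results written to %s", config$out_dir)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
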