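# Inversion of fitted 90th-quantile dose-response curves into critical
# loads and ecological-risk classes.
#
# The reference ("maximum") response is the fitted value at the minimum
# observed deposition. A 20% decline from that reference defines the
# critical load; 20-50%, 50-80% and >80% declines mark moderate, high and
# very high risk.

#' Risk / critical-load configuration
#'
#' @param decline_anchors fractional declines tabulated for each metric.
#' @param cl_decline the decline that defines the critical load.
#' @param class_bounds lower edges of the moderate, high and very-high
#'   classes (fractions).
#' @param root_tol root-finding tolerance, kg ha-1 yr-1.
#' @export
risk_config <- function(decline_anchors = c(0, 0.10, 0.20, 0.50, 0.80),
                        cl_decline = 0.20,
                        class_bounds = c(moderate = 0.20, high = 0.50,
                                         very_high = 0.80),
                        root_tol = 1e-6) {
  stopifnot(all(diff(decline_anchors) > 0),
            all(decline_anchors >= 0), all(decline_anchors < 1),
            cl_decline %in% decline_anchors || (cl_decline > 0 &&
                                                  cl_decline < 1))
  structure(list(decline_anchors = decline_anchors,
                 cl_decline = cl_decline, class_bounds = class_bounds,
                 root_tol = root_tol),
            class = "risk_config")
}

.curve_coefs <- function(curve) {
  if (inherits(curve, "quantile_fit")) {
    co <- curve$coefficients
    if (!all(grepl("^(intercept|dep[0-9]*)$", names(co)))) {
      stop("fit must be a deposition-only polynomial model")
    }
    unname(co)
  } else {
    as.numeric(curve)
  }
}

#' Fractional decline of a fitted curve relative to its reference value
#'
#' `1 - f(x) / f(x_min)`, clipped to \[0, 1\]: counts cannot increase risk
#' below the reference and cannot decline by more than 100%.
#'
#' @param curve polynomial coefficients `c(c0, c1, ...)` or a
#'   deposition-only `"quantile_fit"`.
#' @param x deposition at which to evaluate the decline.
#' @param x_min reference deposition (minimum observed).
#' @return fraction(s) in \[0, 1\].
#' @export
decline_fraction <- function(curve, x, x_min) {
  co <- .curve_coefs(curve)
  f0 <- poly_eval(co, x_min)
  if (!is.finite(f0) || f0 <= 0) {
    stop("fitted reference value f(x_min) must be positive")
  }
  pmin(pmax(1 - poly_eval(co, x) / f0, 0), 1)
}

#' Deposition at which a fitted curve reaches a target decline
#'
#' The smallest deposition in `[x_min, window]` at which the decline
#' relative to `f(x_min)` reaches `target`, located by a bracketing
#' root-finder on a fine grid (so the *first* crossing is returned even for
#' non-monotone polynomials). `NA` when the curve never reaches the target
#' within the modeling window.
#'
#' @inheritParams decline_fraction
#' @param target fractional decline in `[0, 1)`.
#' @param window upper end of the modeling window (kg ha-1 yr-1).
#' @param config a [risk_config()] (for the root tolerance).
#' @return deposition in kg ha-1 yr-1, or `NA`.
#' @export
deposition_at_decline <- function(curve, x_min, target, window,
                                  config = risk_config()) {
  if (target < 0 || target >= 1) stop("target must be in [0, 1)")
  co <- .curve_coefs(curve)
  if (!all(is.finite(co))) stop("non-finite curve coefficients")
  if (target == 0) return(x_min)
  g <- function(x) decline_fraction(co, x, x_min) - target
  grid <- seq(x_min, window, length.out = 2048L)
  gv <- g(grid)
  if (gv[1] >= 0) return(x_min)
  hit <- which(gv >= 0)
  if (!length(hit)) return(NA_real_)
  i <- hit[1]
  root <- stats::uniroot(g, lower = grid[i - 1], upper = grid[i],
                         tol = config$root_tol / 10)$root
  root
}

#' Quadratic decline curve through tabulated anchor points
#'
#' Reconstructs the unique relative quadratic `g(x)` (with `g = 1 -
#' decline` at each anchor) through three (deposition, decline) pairs, as
#' used to recover a published decline curve from its tabulated anchors.
#'
#' @param depositions three anchor depositions (kg ha-1 yr-1).
#' @param declines the fractional declines at those depositions.
#' @return coefficients `c(c0, c1, c2)` of the relative curve; the first
#'   anchor serves as `x_min` (where the relative value is `1 -
#'   declines[1]`).
#' @export
anchor_quadratic <- function(depositions, declines) {
  stopifnot(length(depositions) == 3, length(declines) == 3)
  V <- cbind(1, depositions, depositions^2)
  drop(solve(V, 1 - declines))
}

#' Classify ecological risk from a fractional decline
#'
#' Low below 20%, moderate from 20%, high from 50%, very high from 80%;
#' boundaries belong to the upper class.
#'
#' @param fraction fractional decline(s) in \[0, 1\].
#' @param config a [risk_config()].
#' @return character vector of risk classes.
#' @export
classify_risk <- function(fraction, config = risk_config()) {
  stopifnot(all(fraction >= 0 & fraction <= 1))
  b <- config$class_bounds
  ifelse(fraction >= b[["very_high"]], "very_high",
         ifelse(fraction >= b[["high"]], "high",
                ifelse(fraction >= b[["moderate"]], "moderate", "low")))
}

#' Build a critical-load / risk table for one fitted metric
#'
#' Tabulates, for each decline anchor, the deposition at which the fitted
#' 90th-quantile curve reaches that decline and the metric value there
#' (`f(x_min) * (1 - decline)`, rounded half away from zero), plus percent
#' declines on a 1-20 kg deposition grid. Anchors beyond the modeling
#' window are `NA` (printed as "-" in the published layout). If the fitted
#' curve is still rising at `x_min` a warning is raised and the reference
#' stays at `x_min`.
#'
#' @inheritParams decline_fraction
#' @param window upper end of the modeling window.
#' @param metric metric name carried into the output.
#' @param pollutant "N" or "S".
#' @param config a [risk_config()].
#' @param grid depositions for the percent-decline table.
#' @return list of class `"critical_load_result"` with `anchors`
#'   (data.frame), `cl` (the critical load), `reference` (`x_min`,
#'   `f(x_min)`), and `decline_grid`.
#' @export
build_risk_table <- function(curve, x_min, window, metric = "metric",
                             pollutant = c("N", "S"),
                             config = risk_config(),
                             grid = c(1, 1.5, 2, 2.5, 3, 5, 7.5, 10, 12.5,
                                      15, 17.5, 20)) {
  pollutant <- match.arg(pollutant)
  co <- .curve_coefs(curve)
  f0 <- poly_eval(co, x_min)
  if (f0 <= 0) stop("fitted reference value f(x_min) must be positive")
  dfdx <- if (length(co) >= 3) co[2] + 2 * co[3] * x_min else co[2]
  if (is.finite(dfdx) && dfdx > 0) {
    warning("fitted curve is increasing at x_min; reference kept at x_min")
  }
  anchors <- data.frame(
    decline = config$decline_anchors,
    deposition = vapply(config$decline_anchors, function(d) {
      deposition_at_decline(co, x_min, d, window, config)
    }, numeric(1)),
    value = round_half_away(f0 * (1 - config$decline_anchors))
  )
  grid_in <- grid[grid <= window]
  decline_grid <- data.frame(
    deposition = grid,
    percent_decline = ifelse(grid <= window,
      round_half_away(100 * decline_fraction(co, pmax(grid, x_min), x_min)),
      NA_real_)
  )
  cl <- anchors$deposition[anchors$decline == config$cl_decline]
  out <- list(metric = metric, pollutant = pollutant,
              reference = c(x_min = x_min, value = f0),
              anchors = anchors,
              cl = if (length(cl)) cl else NA_real_,
              decline_grid = decline_grid, window = window)
  class(out) <- "critical_load_result"
  out
}

#' @export
print.critical_load_result <- function(x, ...) {
  cat(sprintf("Critical load (%s, %s): %.1f kg ha-1 yr-1\n", x$metric,
              x$pollutant, x$cl))
  print(x$anchors, row.names = FALSE)
  invisible(x)
}

#' Bootstrap confidence interval for a critical load
#'
#' Applies [deposition_at_decline()] to every bootstrap replicate's fitted
#' curve and returns the 2.5/97.5 percentiles of the replicate critical
#' loads. Replicates whose curve never reaches the target decline within
#' the window are counted and excluded; more than 50% unusable is an
#' error.
#'
#' @param boot a `"qr_bootstrap"` from [bootstrap_fits()] of a
#'   deposition-only polynomial model.
#' @param x_min reference deposition.
#' @param window modeling-window upper end.
#' @param config a [risk_config()].
#' @param level confidence level.
#' @return list with `lower`, `upper`, `n_unusable`, `n_used`.
#' @export
cl_confidence_interval <- function(boot, x_min, window,
                                   config = risk_config(), level = 0.95) {
  B <- nrow(boot$coefficients)
  if (B < 2) stop("need at least 2 usable bootstrap replicates")
  cls <- vapply(seq_len(B), function(b) {
    co <- boot$coefficients[b, ]
    if (poly_eval(co, x_min) <= 0) return(NA_real_)
    deposition_at_decline(co, x_min, config$cl_decline, window, config)
  }, numeric(1))
  usable <- is.finite(cls)
  if (mean(!usable) > 0.5) {
    stop("more than half the bootstrap replicates never reach the target ",
         "decline within the window")
  }
  alpha <- (1 - level) / 2
  qs <- stats::quantile(cls[usable], c(alpha, 1 - alpha), names = FALSE)
  list(lower = qs[1], upper = qs[2], n_unusable = sum(!usable),
       n_used = sum(usable))
}

#' Scatter plot of per-site metric values along the deposition gradient
#'
#' The figure analog of the national metric maps, without geographic
#' projection: sites are plotted against deposition and colored by metric
#' value, with the fitted 90th-quantile curve and (optionally) its
#' bootstrap band overlaid.
#'
#' @param deposition per-site deposition.
#' @param metric per-site metric values.
#' @param curve optional polynomial coefficients or `"quantile_fit"`.
#' @param band optional data.frame `lower`/`upper` on `grid`.
#' @param grid deposition grid for curve/band.
#' @param ... passed to [graphics::plot()].
#' @export
plot_metric_response <- function(deposition, metric, curve = NULL,
                                 band = NULL, grid = NULL, ...) {
  pal <- grDevices::hcl.colors(20, "viridis")
  col <- pal[cut(metric, 20, labels = FALSE, include.lowest = TRUE)]
  graphics::plot(deposition, metric, pch = 16, cex = 0.5, col = col,
                 xlab = "Total deposition (kg ha-1 yr-1)",
                 ylab = "Metric value", ...)
  if (!is.null(curve)) {
    if (is.null(grid)) grid <- seq(min(deposition), max(deposition),
                                   length.out = 200)
    graphics::lines(grid, pmax(poly_eval(.curve_coefs(curve), grid), 0),
                    col = "blue", lwd = 2)
    if (!is.null(band)) {
      graphics::lines(grid, pmax(band$lower, 0), col = "black", lty = 2)
      graphics::lines(grid, pmax(band$upper, 0), col = "black", lty = 2)
    }
  }
  invisible(NULL)
}
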