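# Species-level extirpation risk from detection-frequency profiles.
#
# For a rated species, the deposition at its peak detection frequency is
# its sensitivity rating; extirpation risk is quantified by the depositions
# at which detection frequency has declined 20, 50 and 90% from the peak on
# the descending limb of the frequency curve.

#' Extirpation thresholds from a detection-frequency curve
#'
#' Finds the peak of a detection-frequency curve and, for each decline
#' level, the smallest deposition at or beyond the peak where the
#' frequency has fallen to `(1 - level)` of the peak frequency (linear
#' interpolation between grid points). Only the descending limb beyond the
#' peak is searched: the low-deposition side of a hump-shaped species is
#' not an extirpation signal. Levels never reached within the observed
#' range are `NA` (the blank cells of a published risk table).
#'
#' @param curve data.frame with columns `deposition` (increasing) and
#'   `frequency`, e.g. the `curve` element of [rate_sensitivity()].
#' @param levels fractional declines in detection frequency.
#' @param n_occurrences detection count carried into the profile; the
#'   profile requires at least `min_detections` support.
#' @param min_detections minimum supporting detections.
#' @return list of class `"extirpation_profile"`: `peak_deposition`,
#'   `peak_frequency`, `thresholds` (named by percent level), `shape`
#'   (`"increaser"` when the maximum sits at the top of the range, in
#'   which case thresholds are undefined), `n_occurrences`.
#' @export
extirpation_thresholds <- function(curve, levels = c(0.20, 0.50, 0.90),
                                   n_occurrences = NA_integer_,
                                   min_detections = 8) {
  stopifnot(is.data.frame(curve),
            all(c("deposition", "frequency") %in% names(curve)))
  f <- curve$frequency
  x <- curve$deposition
  if (diff(range(f)) <= .Machine$double.eps * max(abs(f), 1)) {
    stop("flat detection-frequency curve: no identifiable maximum")
  }
  if (!is.na(n_occurrences) && n_occurrences < min_detections) {
    stop("profile needs at least ", min_detections,
         " supporting detections")
  }
  i_pk <- which.max(f)
  out <- list(peak_deposition = x[i_pk], peak_frequency = f[i_pk],
              thresholds = stats::setNames(rep(NA_real_, length(levels)),
                                           paste0(100 * levels, "%")),
              shape = "hump", n_occurrences = n_occurrences)
  class(out) <- "extirpation_profile"
  if (i_pk > 0.9 * length(f)) {
    out$shape <- "increaser"
    return(out)
  }
  if (i_pk <= 0.1 * length(f)) out$shape <- "decreaser"
  fd <- f[i_pk:length(f)]
  xd <- x[i_pk:length(x)]
  for (k in seq_along(levels)) {
    targ <- (1 - levels[k]) * f[i_pk]
    below <- which(fd <= targ)
    if (!length(below)) next
    j <- below[1]
    if (j == 1) {
      out$thresholds[k] <- xd[1]
    } else {
      # linear interpolation within the bracketing grid interval
      w <- (fd[j - 1] - targ) / (fd[j - 1] - fd[j])
      out$thresholds[k] <- xd[j - 1] + w * (xd[j] - xd[j - 1])
    }
  }
  out
}

#' Build an extirpation profile directly from threshold depositions
#'
#' For working from published per-species threshold tables (deposition at
#' peak and at 20/50/90% detection-frequency declines) rather than from a
#' fitted curve.
#'
#' @param peak_deposition deposition at maximum detection frequency.
#' @param t20,t50,t90 depositions at 20, 50, 90% declines (`NA` = never
#'   reached within the observed range).
#' @param n_occurrences detection count.
#' @export
extirpation_profile <- function(peak_deposition, t20 = NA, t50 = NA,
                                t90 = NA, n_occurrences = NA_integer_) {
  th <- c("20%" = as.numeric(t20), "50%" = as.numeric(t50),
          "90%" = as.numeric(t90))
  ok <- !is.na(th)
  if (any(th[ok] < peak_deposition)) {
    stop("thresholds must not precede the peak deposition")
  }
  if (is.unsorted(th[ok], strictly = FALSE)) {
    stop("thresholds must be nondecreasing with decline level")
  }
  structure(list(peak_deposition = peak_deposition, peak_frequency = NA,
                 thresholds = th, shape = "hump",
                 n_occurrences = n_occurrences),
            class = "extirpation_profile")
}

#' Classify a species' extirpation risk at a given deposition
#'
#' Low until the 20% detection-frequency decline threshold, moderate from
#' 20%, high from 50%, very high from 90% (boundaries belong to the upper
#' class). Thresholds the species never reached within the observed range
#' cap the attainable class.
#'
#' @param profile an `"extirpation_profile"`.
#' @param deposition deposition value(s), kg ha-1 yr-1.
#' @return character vector of risk classes.
#' @export
classify_extirpation_risk <- function(profile, deposition) {
  stopifnot(inherits(profile, "extirpation_profile"))
  if (any(deposition < 0)) stop("deposition must be non-negative")
  if (identical(profile$shape, "increaser")) {
    stop("profile is an increaser: extirpation thresholds undefined")
  }
  th <- profile$thresholds
  out <- rep("low", length(deposition))
  if (!is.na(th[["20%"]])) out[deposition >= th[["20%"]]] <- "moderate"
  if (!is.na(th[["50%"]])) out[deposition >= th[["50%"]]] <- "high"
  if (!is.na(th[["90%"]])) out[deposition >= th[["90%"]]] <- "very_high"
  out
}

#' Load the packaged rare-species extirpation-threshold table
#'
#' Twelve nationally rare species with published depositions at 0, 20, 50
#' and 90% declines in detection frequency, transcribed from the national
#' risk assessment this package's workflow mirrors; used as worked-example
#' input.
#'
#' @return data.frame with one row per species x pollutant.
#' @export
rare_species_thresholds <- function() {
  path <- system.file("extdata", "rare_species_thresholds.csv",
                      package = "lichenrisk")
  if (path == "") path <- file.path("inst", "extdata",
                                    "rare_species_thresholds.csv")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Tabulate extirpation risk for a set of species at one deposition
#'
#' @param thresholds data.frame in the layout of
#'   [rare_species_thresholds()].
#' @param deposition deposition at which to classify each species.
#' @return the input with a `risk` column appended.
#' @export
extirpation_risk_table <- function(thresholds, deposition) {
  risk <- vapply(seq_len(nrow(thresholds)), function(i) {
    pr <- extirpation_profile(thresholds$peak_dep[i], thresholds$t20[i],
                              thresholds$t50[i], thresholds$t90[i],
                              thresholds$occurrences[i])
    classify_extirpation_risk(pr, deposition)
  }, character(1))
  cbind(thresholds, risk = risk)
}
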