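# Analysis-of-means comparisons of sensitivity-rating distributions among
# functional groups and between rare and common species.
#
# Sensitivity ratings are bounded by the deposition range and heavy-tailed,
# so group means are compared non-parametrically: observations are rank
# transformed over all groups, each group's mean rank is compared to the
# grand mean rank with simultaneous decision limits. Spread is compared the
# same way on Levene absolute-deviation-from-median (ADM) values.

.anom_core <- function(values, groups, alpha, label) {
  groups <- as.character(groups)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- groups[keep]
  tab <- table(groups)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warning("group(s) with fewer than 2 observations excluded: ",
            paste(small, collapse = ", "))
    keep <- !groups %in% small
    values <- values[keep]
    groups <- groups[keep]
    tab <- table(groups)
  }
  k <- length(tab)
  if (k < 2) stop("need at least 2 groups with n >= 2")
  N <- length(values)
  grand <- mean(values)
  means <- tapply(values, groups, mean)
  ni <- as.numeric(tab)[match(names(means), names(tab))]
  # pooled within-group variance (one-way ANOVA mean square error)
  sse <- sum(tapply(values, groups,
                    function(v) sum((v - mean(v))^2)))
  s <- sqrt(sse / (N - k))
  # Bonferroni-adjusted normal critical value for k simultaneous
  # group-vs-grand comparisons (conservative stand-in for exact ANOM
  # tables)
  crit <- stats::qnorm(1 - alpha / (2 * k))
  half <- crit * s * sqrt((N - ni) / (N * ni))
  res <- data.frame(
    group = names(means),
    n = ni,
    mean = as.numeric(means),
    lower_limit = grand - half,
    upper_limit = grand + half,
    stringsAsFactors = FALSE
  )
  res$flag <- ifelse(res$mean > res$upper_limit, "above",
                     ifelse(res$mean < res$lower_limit, "below", "none"))
  structure(list(statistic = label, grand_mean = grand, s = s,
                 alpha = alpha, critical = crit, groups = res,
                 any_flag = any(res$flag != "none")),
            class = "anom_comparison")
}

#' @export
print.anom_comparison <- function(x, ...) {
  cat(sprintf("Analysis of means (%s), alpha = %g, grand mean = %.3f\n",
              x$statistic, x$alpha, x$grand_mean))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Non-parametric analysis of means on rank-transformed ratings
#'
#' Ranks all ratings over all groups, then compares each group's mean rank
#' to the grand mean rank with simultaneous decision limits
#' `grand +/- c * s * sqrt((N - n_i) / (N * n_i))`, `c` a
#' Bonferroni-adjusted normal quantile at `alpha / (2k)`. Invariant under
#' any strictly monotone transform of the ratings.
#'
#' @param ratings numeric vector of sensitivity ratings.
#' @param groups group labels (same length).
#' @param alpha family-wise significance level.
#' @return an `"anom_comparison"` with per-group means, limits and flags.
#' @export
anom_ranks <- function(ratings, groups, alpha = 0.05) {
  keep <- !is.na(ratings)
  r <- rep(NA_real_, length(ratings))
  r[keep] <- rank(ratings[keep])
  .anom_core(r, groups, alpha, "rank means")
}

#' Analysis of means for variances via Levene ADM
#'
#' Each observation is replaced by its absolute deviation from its group's
#' median (ADM); group mean ADMs are then compared to the grand mean ADM
#' with the same simultaneous limits as [anom_ranks()]. Flags indicate
#' groups whose spread differs from the pooled spread.
#'
#' @inheritParams anom_ranks
#' @export
anom_variances_adm <- function(ratings, groups, alpha = 0.05) {
  groups <- as.character(groups)
  med <- tapply(ratings, groups, stats::median, na.rm = TRUE)
  adm <- abs(ratings - as.numeric(med[groups]))
  .anom_core(adm, groups, alpha, "ADM means (Levene)")
}

#' Compare rare vs common species' sensitivity ratings
#'
#' Two-group analysis of means on rank-transformed ratings (location) and
#' on ADM values (spread). Species of intermediate rarity are ignored.
#'
#' @param ratings sensitivity ratings.
#' @param rarity rarity classes from [classify_rarity()].
#' @param alpha family-wise significance level.
#' @return list with elements `means` and `variances`, each an
#'   `"anom_comparison"` (or `NULL` with a warning when a class has fewer
#'   than 2 rated species).
#' @export
compare_rare_common <- function(ratings, rarity, alpha = 0.05) {
  keep <- rarity %in% c("rare", "common") & !is.na(ratings)
  if (!any(rarity == "rare") || !any(rarity == "common")) {
    stop("both a rare and a common class are required")
  }
  r <- ratings[keep]
  g <- rarity[keep]
  if (min(table(g)) < 2) {
    warning("a rarity class has fewer than 2 rated species; ",
            "comparison skipped")
    return(list(means = NULL, variances = NULL))
  }
  list(means = anom_ranks(r, g, alpha),
       variances = anom_variances_adm(r, g, alpha))
}

#' Species counts (gamma diversity) per functional group and region
#'
#' @param species species-attribute data.frame with `functional_group` and
#'   per-region detection counts `n_detections_east`, `n_detections_west`
#'   (a species counts toward a region when detected there at least once).
#' @return data.frame of counts per group and region, plus regional totals
#'   as an attribute.
#' @export
gamma_diversity <- function(species) {
  out <- do.call(rbind, lapply(c("East", "West"), function(rg) {
    col <- paste0("n_detections_", tolower(rg))
    present <- species[[col]] > 0
    counts <- table(factor(species$functional_group[present]))
    data.frame(region = rg, functional_group = names(counts),
               n_species = as.integer(counts), stringsAsFactors = FALSE)
  }))
  totals <- tapply(out$n_species, out$region, sum)
  attr(out, "regional_totals") <- totals
  out
}

#' Compare a functional group's share of the flora between regions
#'
#' Standard two-proportion test of the fraction of each region's species
#' belonging to a group.
#'
#' @param k_east,k_west species in the group, per region.
#' @param n_east,n_west total species per region.
#' @return `htest` from [stats::prop.test()].
#' @export
compare_region_proportions <- function(k_east, n_east, k_west, n_west) {
  stats::prop.test(c(k_east, k_west), c(n_east, n_west))
}
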