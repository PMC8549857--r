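# Independent oracles the implementation is checked against.

# Exhaustive search over all p-point interpolating fits: an optimal
# quantile-regression solution interpolates p observations, so the minimum
# pinball objective over all such fits is the LP optimum.
brute_force_pinball <- function(X, y, tau) {
  n <- nrow(X)
  p <- ncol(X)
  best <- Inf
  idx <- utils::combn(n, p)
  for (j in seq_len(ncol(idx))) {
    h <- idx[, j]
    b <- tryCatch(solve(X[h, , drop = FALSE], y[h]),
                  error = function(e) NULL)
    if (is.null(b) || !all(is.finite(b))) next
    v <- pinball_loss(y - drop(X %*% b), tau)
    if (v < best) best <- v
  }
  best
}

# Plain bisection for the smallest x >= x_min with
# f(x) = (1 - decline) * f(x_min), independent of the package's
# quadratic-formula and grid-based root finders.
bisect_decline <- function(curve, x_min, decline, upper, tol = 1e-9) {
  target <- (1 - decline) * poly_eval(curve, x_min)
  g <- function(x) poly_eval(curve, x) - target
  grid <- seq(x_min, upper, length.out = 20000L)
  gv <- g(grid)
  below <- which(gv <= 0)
  if (!length(below)) return(NA_real_)
  i <- below[1]
  if (i == 1) return(x_min)
  lo <- grid[i - 1]
  hi <- grid[i]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Minimal species-attribute table for metric tests.
make_species <- function(ids, fg = "matrix_med_large",
                         n_east = NA_real_, n_west = NA_real_,
                         s_east = NA_real_, s_west = NA_real_) {
  data.frame(species_id = ids, genus = "Parmelia",
             growth_form = "foliose-large", photobiont = "green",
             functional_group = rep_len(fg, length(ids)),
             n_rating_east = rep_len(n_east, length(ids)),
             n_rating_west = rep_len(n_west, length(ids)),
             s_rating_east = rep_len(s_east, length(ids)),
             s_rating_west = rep_len(s_west, length(ids)),
             stringsAsFactors = FALSE)
}

make_sites <- function(ids, region = "West") {
  data.frame(site_id = ids, region = rep_len(region, length(ids)),
             stringsAsFactors = FALSE)
}
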