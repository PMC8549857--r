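# Quantile regression by interior-point linear programming.
#
# The tau-th regression quantile minimizes the pinball (check) objective
#   V(b) = sum_i rho_tau(y_i - x_i'b),  rho_tau(u) = u * (tau - 1[u < 0]).
# The minimizer solves a bounded-variable LP whose dual is
#   max y'a  s.t.  X'a = (1 - tau) X'1,  a in [0, 1]^n,
# and the coefficient vector is (minus) the multiplier of the equality
# constraints. The solver below is a Mehrotra predictor-corrector
# (Frisch-Newton) method on that dual, followed by a vertex "polish" that
# exploits the exact-fit property: an optimal basic solution interpolates
# p observations.

# Mehrotra predictor-corrector for: min c'x s.t. A x = b, 0 <= x <= u.
# A is p x n. Returns the equality-constraint dual vector `y`.
.lp_fnm <- function(A, cc, b, u, x, tol = 1e-10, max_iter = 100) {
  step_frac <- 0.9995
  n <- length(cc)
  s <- u - x
  # least-squares start for the dual, via the normal equations
  yy <- tryCatch(solve(tcrossprod(A), drop(A %*% cc)),
                 error = function(e) rep(0, nrow(A)))
  r <- cc - drop(crossprod(A, yy))
  r[abs(r) < .Machine$double.eps] <- 0.001
  z <- pmax(r, 0)
  w <- z - r
  gap <- sum(cc * x) - sum(yy * b) + sum(w * u)
  it <- 0L

  max_step <- function(v, dv) {
    neg <- dv < 0
    if (any(neg)) min(-v[neg] / dv[neg]) else Inf
  }

  while (gap > tol && it < max_iter) {
    it <- it + 1L
    q <- 1 / (z / x + w / s)
    r <- z - w
    Aq <- A * rep(q, each = nrow(A))
    AQA <- tcrossprod(Aq, A)
    rhs <- drop(A %*% (q * r))
    dy <- solve(AQA, rhs)
    dx <- q * (drop(crossprod(A, dy)) - r)
    ds <- -dx
    dz <- -z * (1 + dx / x)
    dw <- -w * (1 + ds / s)
    fp <- min(step_frac * min(max_step(x, dx), max_step(s, ds)), 1)
    fd <- min(step_frac * min(max_step(z, dz), max_step(w, dw)), 1)
    if (min(fp, fd) < 1) {
      # Mehrotra second-order correction
      mu <- sum(z * x) + sum(w * s)
      g <- sum((z + fd * dz) * (x + fp * dx)) +
        sum((w + fd * dw) * (s + fp * ds))
      mu <- mu * (g / mu)^3 / (2 * n)
      dxdz <- dx * dz
      dsdw <- ds * dw
      xinv <- 1 / x
      sinv <- 1 / s
      xi <- mu * (xinv - sinv)
      rhs <- rhs + drop(A %*% (q * (dxdz - dsdw - xi)))
      dy <- solve(AQA, rhs)
      dx <- q * (drop(crossprod(A, dy)) + xi - r - (dxdz - dsdw))
      ds <- -dx
      dz <- mu * xinv - z - xinv * z * dx - dxdz
      dw <- mu * sinv - w - sinv * w * ds - dsdw
      fp <- min(step_frac * min(max_step(x, dx), max_step(s, ds)), 1)
      fd <- min(step_frac * min(max_step(z, dz), max_step(w, dw)), 1)
    }
    x <- x + fp * dx
    s <- s + fp * ds
    yy <- yy + fd * dy
    z <- z + fd * dz
    w <- w + fd * dw
    gap <- sum(cc * x) - sum(yy * b) + sum(w * u)
  }
  list(y = yy, a = x, gap = gap, iterations = it)
}

#' Pinball (check) loss
#'
#' @param u numeric vector of residuals.
#' @param tau quantile level in (0, 1).
#' @return `sum(rho_tau(u))`.
#' @export
pinball_loss <- function(u, tau) {
  sum(u * (tau - (u < 0)))
}

#' Fit a quantile regression by interior-point linear programming
#'
#' Minimizes the pinball objective `sum(rho_tau(y - X b))` exactly (to LP
#' optimality) with a Frisch-Newton interior-point method followed by a
#' vertex polish. No external LP or quantile-regression solver is used.
#'
#' @param X design matrix (including an intercept column if wanted).
#' @param y response vector.
#' @param tau quantile level, default 0.9 (the upper envelope of metric
#'   responses attributable to deposition alone).
#' @param tol duality-gap convergence tolerance.
#' @param check_rank if `TRUE`, stop on rank-deficient designs, naming the
#'   collinear columns. Can be disabled inside resampling loops.
#' @return an object of class `"quantile_fit"`: coefficients, fitted values,
#'   residuals, the pinball objective `objective`, `tau`, `n`, `p`, and
#'   convergence information.
#' @export
fit_quantile_regression <- function(X, y, tau = 0.9, tol = 1e-10,
                                    check_rank = TRUE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("non-finite values in design matrix or response")
  }
  if (n < p) stop("need at least as many observations as parameters")
  if (tau <= 0 || tau >= 1) stop("tau must be in (0, 1)")
  if (check_rank) {
    qrX <- qr(X)
    if (qrX$rank < p) {
      bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
      stop("design matrix is rank deficient; collinear column(s): ",
           paste(bad, collapse = ", "))
    }
  }

  if (n == p) {
    # square system: the quantile fit interpolates
    beta <- solve(X, y)
    obj <- 0
    sol <- list(gap = 0, iterations = 0L)
  } else {
    u <- rep(1, n)
    a0 <- rep(1 - tau, n)
    sol <- .lp_fnm(t(X), -y, drop(crossprod(X, a0)), u, a0, tol = tol)
    beta <- -sol$y
    obj <- pinball_loss(y - drop(X %*% beta), tau)
  }

  # Vertex polish: an optimal basic solution interpolates p observations;
  # try the p observations with the smallest absolute residuals.
  res <- y - drop(X %*% beta)
  h <- order(abs(res))[seq_len(p)]
  bpol <- tryCatch(solve(X[h, , drop = FALSE], y[h]), error = function(e) NULL)
  if (!is.null(bpol) && all(is.finite(bpol))) {
    opol <- pinball_loss(y - drop(X %*% bpol), tau)
    if (opol <= obj + 1e-12 * (1 + abs(obj))) {
      beta <- bpol
      obj <- opol
    }
  }

  beta <- drop(beta)
  names(beta) <- colnames(X)
  fitted <- drop(X %*% beta)
  out <- list(
    coefficients = beta,
    fitted = fitted,
    residuals = y - fitted,
    objective = obj,
    tau = tau,
    n = n,
    p = p,
    converged = sol$gap <= max(tol, 1e-7 * (1 + abs(obj))),
    dual_gap = sol$gap,
    iterations = sol$iterations
  )
  class(out) <- "quantile_fit"
  out
}

#' @export
print.quantile_fit <- function(x, ...) {
  cat(sprintf("Quantile regression fit (tau = %g, n = %d, p = %d)\n",
              x$tau, x$n, x$p))
  print(x$coefficients)
  cat(sprintf("pinball objective: %.6g\n", x$objective))
  invisible(x)
}

#' @export
coef.quantile_fit <- function(object, ...) object$coefficients

#' Predict from a quantile regression fit
#'
#' @param object a `"quantile_fit"`.
#' @param newdata design matrix with the same columns the fit used.
#' @param truncate if `TRUE`, negative predictions are set to 0 (counts and
#'   abundance indices cannot be negative).
#' @param ... unused.
#' @export
predict.quantile_fit <- function(object, newdata, truncate = FALSE, ...) {
  pred <- drop(as.matrix(newdata) %*% object$coefficients)
  if (truncate) pred <- pmax(pred, 0)
  pred
}

#' Check the quantile-regression subgradient (residual-sign) condition
#'
#' At an LP optimum the number of strictly negative residuals is at most
#' `n * tau` and the number of strictly positive residuals is at most
#' `n * (1 - tau)`.
#'
#' @param fit a `"quantile_fit"`.
#' @param zero_tol residuals within this of 0 count as zero.
#' @return logical.
#' @export
residual_sign_condition <- function(fit, zero_tol = NULL) {
  r <- fit$residuals
  if (is.null(zero_tol)) zero_tol <- 1e-7 * (1 + max(abs(fit$fitted), 1))
  n_neg <- sum(r < -zero_tol)
  n_pos <- sum(r > zero_tol)
  (n_neg <= fit$n * fit$tau + 1e-9) &&
    (n_pos <= fit$n * (1 - fit$tau) + 1e-9)
}

#' R1 goodness of fit for quantile regression
#'
#' One minus the ratio of the fitted model's pinball objective to the
#' intercept-only model's, the quantile-regression analogue of R squared.
#' Ranges from 0 (the predictors add nothing) to 1 (perfect interpolation).
#'
#' @param fit a `"quantile_fit"` with predictors.
#' @param null_fit the intercept-only `"quantile_fit"` on the same response
#'   and tau.
#' @return numeric in \[0, 1\], or `NA` with a warning when the null
#'   objective is 0 (constant response).
#' @export
r1_statistic <- function(fit, null_fit) {
  if (!identical(fit$tau, null_fit$tau)) stop("fits must share tau")
  if (fit$n != null_fit$n) stop("fits must share the response")
  if (null_fit$objective <= 0) {
    warning("intercept-only objective is 0; R1 undefined")
    return(NA_real_)
  }
  1 - fit$objective / null_fit$objective
}

#' AIC for a quantile regression fit
#'
#' Uses the asymmetric-Laplace pseudo-log-likelihood
#' `L = n * (log(tau * (1 - tau)) - 1 - log(V / n))` with `V` the pinball
#' objective, so `AIC = -2 L + 2 p`. Only differences between nested fits on
#' the same response are meaningful.
#'
#' @param fit a `"quantile_fit"`.
#' @return numeric; `-Inf` (with attribute `degenerate = TRUE`) when the fit
#'   interpolates (`V = 0`).
#' @export
qr_aic <- function(fit) {
  v <- fit$objective
  if (v <= 0) {
    out <- -Inf
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  ll <- fit$n * (log(fit$tau * (1 - fit$tau)) - 1 - log(v / fit$n))
  -2 * ll + 2 * fit$p
}

#' Select among nested quantile-regression fits by a large-AIC-drop rule
#'
#' Starting from the simplest fit, a richer nested model is adopted only
#' when its AIC improves on the currently selected model's by more than
#' `threshold` (default 25), a deliberately strict hurdle for the large
#' survey samples these models are fit to.
#'
#' @param fits named list of `"quantile_fit"` objects on the same response,
#'   ordered simplest to richest.
#' @param threshold minimum AIC improvement to adopt a richer model.
#' @return list with `selected` (name), `aic` (named vector) and
#'   `delta_aic` (improvement of each fit over the previous one).
#' @export
compare_models <- function(fits, threshold = 25) {
  stopifnot(length(fits) >= 2)
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- paste0("model", seq_along(fits))
  }
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1) stop("fits must share the response")
  aics <- vapply(fits, qr_aic, numeric(1))
  sel <- 1L
  for (i in 2:length(fits)) {
    if (aics[sel] - aics[i] > threshold) sel <- i
  }
  deltas <- c(NA_real_, -diff(aics))
  names(deltas) <- names(fits)
  list(selected = names(fits)[sel], aic = aics, delta_aic = deltas,
       threshold = threshold)
}

#' Pairs (site) bootstrap of a quantile regression
#'
#' Resamples rows of `(y, X)` with replacement and refits. Replicates whose
#' resampled design is degenerate are dropped and counted; more than 10%
#' dropped is an error.
#'
#' @param X design matrix.
#' @param y response.
#' @param tau quantile level.
#' @param n_reps number of bootstrap replicates (the headline analysis used
#'   10,000; tests and examples use far fewer).
#' @param seed integer seed; the same seed reproduces the replicates.
#' @return class `"qr_bootstrap"`: `coefficients` (n_kept x p matrix),
#'   `n_dropped`, `seed`, `tau`.
#' @export
bootstrap_fits <- function(X, y, tau = 0.9, n_reps = 10000, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n_reps < 2) stop("n_reps must be at least 2")
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_reps, replace = TRUE), nrow = n)
  coefs <- matrix(NA_real_, n_reps, ncol(X),
                  dimnames = list(NULL, colnames(X)))
  for (b in seq_len(n_reps)) {
    i <- idx[, b]
    fit <- tryCatch(
      fit_quantile_regression(X[i, , drop = FALSE], y[i], tau = tau,
                              check_rank = FALSE),
      error = function(e) NULL
    )
    if (!is.null(fit) && all(is.finite(fit$coefficients))) {
      coefs[b, ] <- fit$coefficients
    }
  }
  keep <- stats::complete.cases(coefs)
  if (mean(!keep) > 0.10) {
    stop(sprintf("%d of %d bootstrap replicates degenerate", sum(!keep),
                 n_reps))
  }
  out <- list(coefficients = coefs[keep, , drop = FALSE],
              n_dropped = sum(!keep), n_reps = n_reps, seed = seed,
              tau = tau)
  class(out) <- "qr_bootstrap"
  out
}

#' Bootstrap percentile band for the fitted quantile curve
#'
#' @param boot a `"qr_bootstrap"`.
#' @param newX design matrix of grid points.
#' @param level confidence level (default 0.95: 2.5/97.5 percentiles).
#' @return data.frame with columns `lower` and `upper`, one row per grid
#'   point; `lower <= upper` everywhere.
#' @export
bootstrap_band <- function(boot, newX, level = 0.95) {
  preds <- as.matrix(newX) %*% t(boot$coefficients)
  alpha <- (1 - level) / 2
  qs <- apply(preds, 1L, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  data.frame(lower = qs[1, ], upper = qs[2, ])
}

#' Build a polynomial deposition design matrix
#'
#' Raw (non-orthogonalized) powers of deposition, so the coefficients map
#' directly onto the decline-curve algebra used for critical loads, with
#' optional climate covariates appended.
#'
#' @param deposition deposition vector (kg ha-1 yr-1).
#' @param degree polynomial degree (1, 2 or 3); default 2.
#' @param climate optional data.frame/matrix of climate covariates.
#' @return design matrix with an intercept column.
#' @export
deposition_design <- function(deposition, degree = 2, climate = NULL) {
  stopifnot(degree %in% 1:3)
  X <- cbind(intercept = 1,
             vapply(seq_len(degree), function(k) deposition^k,
                    numeric(length(deposition))))
  colnames(X) <- c("intercept", paste0("dep", seq_len(degree)))[
    seq_len(degree + 1)]
  colnames(X)[2] <- "dep"
  if (!is.null(climate)) {
    climate <- as.matrix(climate)
    X <- cbind(X, climate)
  }
  X
}
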