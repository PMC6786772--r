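## Regression engines for the regime models: OLS, WLS, partially-ridge (PRR),
## the admissible ridge-tuning range, and error-variance estimation.

# condition-number threshold beyond which a cross-product matrix is treated as
# super-collinear (singular for practical purposes)
.COND_TOL <- 1e12

new_linear_fit <- function(b, H, v, sigma_sq_hat, method, n_obs,
                           sigma_approx = FALSE, weights = NULL) {
  structure(list(b = as.numeric(b), H = H, v = v,
                 sigma_sq_hat = sigma_sq_hat, method = method,
                 n_obs = n_obs, sigma_approx = sigma_approx,
                 weights = weights),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("linear fit (%s%s): %d coefficient(s), n_obs = %d\n",
              x$method, if (x$v > 0) sprintf(", v = %g", x$v) else "",
              length(x$b), x$n_obs))
  print(x$b)
  if (!is.na(x$sigma_sq_hat))
    cat(sprintf("  sigma^2 hat = %.6g%s\n", x$sigma_sq_hat,
                if (x$sigma_approx) " (approximate, ridge divisor n)" else ""))
  invisible(x)
}

# solve H b = g for a symmetric PSD H, raising a classed super-collinearity
# error when H is singular or ill-conditioned
solve_spd <- function(H, g, remedy = "fit_prr") {
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > .COND_TOL)
    stop_subpred("supercollinearity",
                 sprintf("cross-product matrix is singular or ill-conditioned (condition number > %g); use %s",
                         .COND_TOL, remedy))
  drop(solve(H, g))
}

check_xy <- function(X_s, y_s) {
  X_s <- as.matrix(X_s)
  y_s <- as.numeric(y_s)
  if (nrow(X_s) != length(y_s))
    stop_subpred("invalid_spec", "X_s and y_s dimensions do not conform")
  list(X = X_s, y = y_s)
}

#' Ordinary least squares fit
#'
#' Solves the normal equations `(X'X) b = X'y`. Raises a super-collinearity
#' error (pointing at [fit_prr()]) when `X'X` is singular or ill-conditioned,
#' e.g. when the fitting sample has fewer rows than coefficients.
#'
#' @param X_s design matrix of the fitting sample (intercept column included).
#' @param y_s outcome vector of the fitting sample.
#' @return a `linear_fit` with coefficients `b`, cross-product matrix `H`,
#'   and `sigma_sq_hat = RSS / (n - p - 1)` when `n > p + 1` (else `NA`).
#' @export
fit_ols <- function(X_s, y_s) {
  d <- check_xy(X_s, y_s)
  n <- nrow(d$X); q <- ncol(d$X)
  if (n < q)
    stop_subpred("supercollinearity",
                 sprintf("%d observation(s) cannot identify %d coefficients; use fit_prr", n, q))
  H <- crossprod(d$X)
  b <- solve_spd(H, crossprod(d$X, d$y))
  rss <- sum((d$y - drop(d$X %*% b))^2)
  new_linear_fit(b, H, v = 0,
                 sigma_sq_hat = if (n > q) rss / (n - q) else NA_real_,
                 method = "ols", n_obs = n)
}

#' Weighted least squares fit
#'
#' Computes `b = (X' V^-1 X)^-1 X' V^-1 y` for a known diagonal variance
#' structure `V` (given as the vector of its diagonal).
#'
#' @param X_s,y_s fitting sample.
#' @param V_s strictly positive per-observation variance (diagonal of V).
#' @return a `linear_fit` with `sigma_sq_hat` the weighted RSS over `n - p - 1`.
#' @export
fit_wls <- function(X_s, y_s, V_s) {
  d <- check_xy(X_s, y_s)
  V_s <- as.numeric(V_s)
  if (length(V_s) != nrow(d$X))
    stop_subpred("invalid_spec", "V_s must have one entry per observation")
  if (any(V_s <= 0))
    stop_subpred("invalid_weights", "all variance entries must be strictly positive")
  n <- nrow(d$X); q <- ncol(d$X)
  if (n < q)
    stop_subpred("supercollinearity",
                 sprintf("%d observation(s) cannot identify %d coefficients; use fit_prr", n, q))
  w <- 1 / V_s
  H <- crossprod(d$X, d$X * w)
  H <- (H + t(H)) / 2
  b <- solve_spd(H, crossprod(d$X, d$y * w))
  res <- d$y - drop(d$X %*% b)
  new_linear_fit(b, H, v = 0,
                 sigma_sq_hat = if (n > q) sum(w * res^2) / (n - q) else NA_real_,
                 method = "wls", n_obs = n, weights = w)
}

#' Partially ridge regression fit
#'
#' The ad-hoc super-collinearity fix: replaces the cross-product matrix `H` by
#' `H(v) = H + v I` and solves `b = H(v)^-1 X'y`. A strictly positive tuning
#' parameter `v` yields a defined estimator even when the fitting sample has
#' fewer observations than coefficients.
#'
#' @param X_s,y_s fitting sample.
#' @param v nonnegative ridge tuning parameter; `v = 0` requires full rank and
#'   reproduces [fit_ols()].
#' @param penalize_intercept penalize all `p + 1` diagonal entries including
#'   the intercept (the default, matching `H + v I_{p+1}`); set `FALSE` to
#'   leave the intercept unpenalized.
#' @return a `linear_fit`; `sigma_sq_hat` uses the approximate divisor `n`
#'   (no ridge effective-df correction) and is flagged via `sigma_approx`.
#' @export
fit_prr <- function(X_s, y_s, v, penalize_intercept = TRUE) {
  d <- check_xy(X_s, y_s)
  if (v < 0) stop_subpred("invalid_spec", "tuning parameter v must be nonnegative")
  n <- nrow(d$X); q <- ncol(d$X)
  D <- diag(q)
  if (!penalize_intercept) D[1L, 1L] <- 0
  H <- crossprod(d$X) + v * D
  b <- solve_spd(H, crossprod(d$X, d$y),
                 remedy = "a strictly positive v")
  rss <- sum((d$y - drop(d$X %*% b))^2)
  new_linear_fit(b, H, v = v, sigma_sq_hat = rss / n,
                 method = "prr", n_obs = n, sigma_approx = TRUE)
}

#' Admissible range for the ridge tuning parameter
#'
#' Computes `psi2`, the minimum eigenvalue of `H^-1 - beta2 beta2' / sigma2_sq`,
#' and the upper end `2 * (-min(0, psi2))` of the tuning-parameter interval
#' `(0, upper)` within which the ridge predictor's model MSE is below the OLS
#' predictor's model variance. `upper = 0` (empty interval) exactly when the
#' matrix is positive semi-definite.
#'
#' @param H nonsingular cross-product matrix of the non-respondent sub-sample.
#' @param beta2 non-respondent regime coefficient vector (true or plug-in).
#' @param sigma2_sq positive non-respondent error variance.
#' @return an object of class `ridge_range` with fields `psi2` and `upper`.
#' @export
ridge_admissible_range <- function(H, beta2, sigma2_sq) {
  if (sigma2_sq <= 0) stop_subpred("invalid_spec", "sigma2_sq must be positive")
  H <- as.matrix(H)
  beta2 <- as.numeric(beta2)
  if (nrow(H) != ncol(H) || length(beta2) != nrow(H))
    stop_subpred("invalid_spec", "H and beta2 dimensions do not conform")
  Hinv <- tryCatch(solve(H), error = function(e)
    stop_subpred("supercollinearity", "H is singular: admissible range undefined"))
  M <- Hinv - tcrossprod(beta2) / sigma2_sq
  M <- (M + t(M)) / 2
  psi2 <- min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  structure(list(psi2 = psi2, upper = 2 * (-min(0, psi2))), class = "ridge_range")
}

#' @export
print.ridge_range <- function(x, ...) {
  cat(sprintf("ridge admissible range: psi2 = %.6g, interval (0, %.6g)%s\n",
              x$psi2, x$upper,
              if (x$upper == 0) " [empty: matrix is PSD]" else ""))
  invisible(x)
}

#' Select the ridge tuning parameter by leave-one-out cross-validation
#'
#' Evaluates each candidate `v` by the leave-one-out squared prediction error
#' of [fit_prr()] (computed via the ridge hat diagonal) and returns the
#' minimizer; ties break to the smallest candidate. When `range_cap` is given
#' (typically the `upper` end of [ridge_admissible_range()] with plug-in
#' estimates), the grid is truncated to `(0, range_cap]` first.
#'
#' @param X_s,y_s fitting sample with at least 2 rows.
#' @param grid vector of candidate tuning values, each `>= 0`.
#' @param range_cap optional upper bound on admissible candidates.
#' @return the selected tuning value (scalar).
#' @export
select_tuning <- function(X_s, y_s, grid, range_cap = NULL) {
  d <- check_xy(X_s, y_s)
  n <- nrow(d$X); q <- ncol(d$X)
  if (n < 2L) stop_subpred("invalid_spec", "LOOCV needs at least 2 observations")
  grid <- sort(unique(as.numeric(grid)))
  if (length(grid) == 0L) stop_subpred("selection", "empty tuning grid")
  if (any(grid < 0)) stop_subpred("invalid_spec", "tuning candidates must be nonnegative")
  if (!is.null(range_cap)) grid <- grid[grid > 0 & grid <= range_cap]
  cv <- vapply(grid, function(v) {
    H <- crossprod(d$X) + v * diag(q)
    Hinv <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(Hinv)) return(Inf)
    b <- drop(Hinv %*% crossprod(d$X, d$y))
    h <- rowSums((d$X %*% Hinv) * d$X)
    denom <- 1 - h
    if (any(abs(denom) < 1e-12)) return(Inf)
    mean(((d$y - drop(d$X %*% b)) / denom)^2)
  }, numeric(1))
  if (all(!is.finite(cv)))
    stop_subpred("selection", "no feasible tuning value in the grid")
  grid[which.min(cv)]
}

# default candidate grid for automatic tuning
default_tuning_grid <- function() 10^seq(-4, 4, length.out = 17)

#' Estimate the error variance of a fitted regime model
#'
#' OLS: `RSS / (n - p - 1)`; WLS: weighted RSS over the same divisor; PRR:
#' the approximate `RSS / n` (no ridge effective-df correction), flagged via
#' attribute `approximate`.
#'
#' @param fit a `linear_fit`.
#' @param X_s,y_s the sample the fit was trained on.
#' @return scalar variance estimate.
#' @export
estimate_error_variance <- function(fit, X_s, y_s) {
  d <- check_xy(X_s, y_s)
  n <- nrow(d$X); q <- ncol(d$X)
  res <- d$y - drop(d$X %*% fit$b)
  if (fit$method == "prr") {
    return(structure(sum(res^2) / n, approximate = TRUE))
  }
  if (n <= q)
    stop_subpred("degrees_of_freedom",
                 sprintf("n_obs = %d leaves no residual degrees of freedom for %d coefficients", n, q))
  if (fit$method == "wls") {
    w <- fit$weights %||% rep(1, n)
    return(sum(w * res^2) / (n - q))
  }
  sum(res^2) / (n - q)
}
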