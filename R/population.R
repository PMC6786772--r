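## Finite populations and the two-regime superpopulation generator.

#' Construct a finite population container
#'
#' A `finite_population` holds the universe a survey draws from: the realized
#' outcome vector `y`, the known design matrix `X` (intercept column first),
#' an optional response-stratum indicator `R` (1 = respondent stratum), and the
#' prediction weights `W` (all 1 for a total, all 1/N for a mean).
#'
#' @param y numeric outcome vector of length N.
#' @param X numeric N x (p+1) matrix whose first column is all ones.
#' @param R optional integer/logical vector of length N in \{0, 1\};
#'   `NULL` when the response stratification has not been assigned yet.
#' @param W prediction-weight vector of length N; defaults to all ones (total).
#' @param meta list of generator truth carried for evaluation (regime
#'   coefficients, error variances, model mean `mu`, the true total, ...).
#' @return an object of class `finite_population` with fields `y`, `X`, `R`,
#'   `W`, `N`, `N1`, `N2`, `lambda1`, `lambda2`, `meta`.
#' @export
finite_population <- function(y, X, R = NULL, W = NULL, meta = list()) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  N <- length(y)
  if (nrow(X) != N)
    stop_subpred("invalid_spec", sprintf("nrow(X) = %d but length(y) = %d", nrow(X), N))
  if (N == 0L) stop_subpred("invalid_spec", "population has no units")
  if (any(X[, 1L] != 1))
    stop_subpred("invalid_spec", "first column of X must be the intercept (all ones)")
  if (is.null(W)) W <- rep(1, N)
  if (length(W) != N)
    stop_subpred("invalid_spec", "length(W) must equal length(y)")
  if (!is.null(R)) {
    R <- as.integer(R)
    if (length(R) != N || !all(R %in% c(0L, 1L)))
      stop_subpred("invalid_spec", "R must be a binary vector of length N")
  }
  N1 <- if (is.null(R)) NA_integer_ else sum(R == 1L)
  N2 <- if (is.null(R)) NA_integer_ else N - N1
  structure(list(
    y = y, X = X, R = R, W = as.numeric(W),
    N = N, N1 = N1, N2 = N2,
    lambda1 = if (is.null(R)) NA_real_ else N1 / N,
    lambda2 = if (is.null(R)) NA_real_ else N2 / N,
    meta = meta
  ), class = "finite_population")
}

#' @export
print.finite_population <- function(x, ...) {
  p <- ncol(x$X) - 1L
  cat(sprintf("finite population: N = %d units, p = %d covariate(s)\n", x$N, p))
  if (is.null(x$R)) {
    cat("  response stratification: unset\n")
  } else {
    cat(sprintf("  respondents N1 = %d (lambda1 = %.3f), non-respondents N2 = %d (lambda2 = %.3f)\n",
                x$N1, x$lambda1, x$N2, x$lambda2))
  }
  cat(sprintf("  weighted total sum(W*y) = %.6g\n", sum(x$W * x$y)))
  invisible(x)
}

#' @export
as.data.frame.finite_population <- function(x, ...) {
  covs <- x$X[, -1L, drop = FALSE]
  if (is.null(colnames(covs)) && ncol(covs) > 0)
    colnames(covs) <- paste0("x", seq_len(ncol(covs)))
  out <- data.frame(y = x$y, covs, check.names = FALSE)
  if (!is.null(x$R)) out$R <- x$R
  out
}

# weighted total of the realized outcome
true_total <- function(pop) sum(pop$W * pop$y)

#' Specify a two-regime linear superpopulation model
#'
#' Respondent-stratum units follow `Y = x' beta_r + eps1`, non-respondent units
#' `Y = x' beta_nr + eps2`, with independent mean-zero errors of variance
#' `sigma1_sq` / `sigma2_sq` (or per-unit variances via `var_structure_*`).
#'
#' @param beta_r,beta_nr coefficient vectors of length p+1 (intercept first).
#' @param sigma1_sq,sigma2_sq nonnegative error variances for the two regimes.
#' @param var_structure_r,var_structure_nr optional functions of a covariate row
#'   (excluding the intercept) returning a strictly positive per-unit variance
#'   multiplier; when given, the unit error variance is `sigma_sq * v(x_i)`.
#' @param covariate_law function of `n` returning an `n x p` covariate matrix;
#'   defaults to iid standard normal columns.
#' @return an object of class `two_regime_spec`.
#' @export
two_regime_spec <- function(beta_r, beta_nr, sigma1_sq = 1, sigma2_sq = 1,
                            var_structure_r = NULL, var_structure_nr = NULL,
                            covariate_law = NULL) {
  beta_r <- as.numeric(beta_r); beta_nr <- as.numeric(beta_nr)
  if (length(beta_r) != length(beta_nr))
    stop_subpred("invalid_spec", "beta_r and beta_nr must have the same length")
  if (length(beta_r) < 1L)
    stop_subpred("invalid_spec", "coefficient vectors must contain at least the intercept")
  if (sigma1_sq < 0 || sigma2_sq < 0)
    stop_subpred("invalid_spec", "error variances must be nonnegative")
  p <- length(beta_r) - 1L
  if (is.null(covariate_law))
    covariate_law <- function(n) matrix(rnorm(n * p), nrow = n, ncol = p)
  structure(list(beta_r = beta_r, beta_nr = beta_nr, p = p,
                 sigma1_sq = sigma1_sq, sigma2_sq = sigma2_sq,
                 var_structure_r = var_structure_r,
                 var_structure_nr = var_structure_nr,
                 covariate_law = covariate_law),
            class = "two_regime_spec")
}

# per-unit error sd for one regime of a two_regime_spec
regime_sd <- function(sigma_sq, var_structure, Xcov) {
  n <- nrow(Xcov)
  if (is.null(var_structure)) return(rep(sqrt(sigma_sq), n))
  v <- apply(Xcov, 1L, var_structure)
  if (any(v <= 0))
    stop_subpred("invalid_spec", "variance structure must be strictly positive")
  sqrt(sigma_sq * v)
}

#' Generate a finite population from a two-regime model
#'
#' Draws covariates from the spec's covariate law, places the first `N1` units
#' in the respondent regime and the remaining `N2` in the non-respondent
#' regime, and realizes outcomes from the corresponding linear models.
#'
#' @param spec a [two_regime_spec()].
#' @param N1,N2 stratum sizes.
#' @param seed optional integer seed; the caller's RNG stream is preserved.
#' @return a [finite_population()] with `R` set and generator truth in `meta`
#'   (`beta_r`, `beta_nr`, `sigma1_sq`, `sigma2_sq`, `mu`, `unit_sd`,
#'   `total_true`).
#' @export
make_two_regime_population <- function(spec, N1, N2, seed = NULL) {
  if (!inherits(spec, "two_regime_spec"))
    stop_subpred("invalid_spec", "spec must be a two_regime_spec")
  N1 <- as.integer(N1); N2 <- as.integer(N2)
  if (N1 < 0 || N2 < 0 || N1 + N2 == 0L)
    stop_subpred("invalid_spec", "need N1 + N2 >= 1 with nonnegative stratum sizes")
  with_seed(seed, {
    X1 <- spec$covariate_law(N1)
    X2 <- spec$covariate_law(N2)
    if (spec$p == 0L) {
      X1 <- matrix(numeric(0), nrow = N1, ncol = 0L)
      X2 <- matrix(numeric(0), nrow = N2, ncol = 0L)
    }
    Xcov <- rbind(X1, X2)
    if (ncol(Xcov) != spec$p)
      stop_subpred("invalid_spec", "covariate law dimension does not match coefficients")
    X <- cbind(1, Xcov)
    colnames(X) <- c("(Intercept)", if (spec$p > 0) paste0("x", seq_len(spec$p)))
    R <- c(rep(1L, N1), rep(0L, N2))
    mu <- numeric(N1 + N2)
    if (N1 > 0) mu[seq_len(N1)] <- drop(X[seq_len(N1), , drop = FALSE] %*% spec$beta_r)
    if (N2 > 0) mu[N1 + seq_len(N2)] <- drop(X[N1 + seq_len(N2), , drop = FALSE] %*% spec$beta_nr)
    unit_sd <- c(regime_sd(spec$sigma1_sq, spec$var_structure_r, X1),
                 regime_sd(spec$sigma2_sq, spec$var_structure_nr, X2))
    y <- mu + rnorm(N1 + N2, 0, unit_sd)
    pop <- finite_population(y, X, R = R,
                             meta = list(beta_r = spec$beta_r, beta_nr = spec$beta_nr,
                                         sigma1_sq = spec$sigma1_sq,
                                         sigma2_sq = spec$sigma2_sq,
                                         mu = mu, unit_sd = unit_sd))
    pop$meta$total_true <- true_total(pop)
    pop
  })
}

#' Stratify a population into respondents and non-respondents by outcome quantile
#'
#' Marks a fraction `1 - lambda2` of the units as respondents according to the
#' outcome: `tail = "upper"` marks the top `1 - lambda2` fraction (non-response
#' concentrated in low outcomes), `tail = "lower"` the bottom fraction. Units
#' exactly at the threshold join the respondent stratum; if that rule cannot
#' separate the strata at all (all outcomes equal), a tie-degenerate error is
#' raised rather than randomizing.
#'
#' @param y outcome vector.
#' @param lambda2 non-response rate, in `[0, 1)`.
#' @param tail `"upper"` or `"lower"`: which tail of `y` responds.
#' @return integer indicator vector (1 = respondent).
#' @export
assign_response_by_quantile <- function(y, lambda2, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  if (lambda2 < 0 || lambda2 >= 1)
    stop_subpred("invalid_spec", "lambda2 must lie in [0, 1)")
  N <- length(y)
  if (lambda2 == 0) return(rep(1L, N))
  if (diff(range(y)) == 0)
    stop_subpred("tie_degenerate", "all outcomes equal: cannot stratify by quantile")
  n_resp <- ceiling((1 - lambda2) * N)
  ys <- sort(y, decreasing = (tail == "upper"))
  threshold <- ys[n_resp]
  R <- if (tail == "upper") as.integer(y >= threshold) else as.integer(y <= threshold)
  if (all(R == 1L))
    stop_subpred("tie_degenerate",
                 "ties at the threshold absorb every unit into the respondent stratum")
  R
}

#' Load a population from a CSV file
#'
#' Reads a header-ed, decimal-point CSV, prepends the intercept column, and
#' sets prediction weights for a total (all 1) or a mean (all 1/N). The
#' response indicator is left unset; assign it later, e.g. with
#' [assign_response_by_quantile()].
#'
#' @param path CSV file path.
#' @param outcome_col name of the outcome column.
#' @param covariate_cols character vector of covariate column names (order kept).
#' @param weight_mode `"total"` (W = 1) or `"mean"` (W = 1/N).
#' @param response_col optional name of a 0/1 response-stratum column.
#' @return a [finite_population()].
#' @export
load_population_csv <- function(path, outcome_col, covariate_cols,
                                weight_mode = c("total", "mean"),
                                response_col = NULL) {
  weight_mode <- match.arg(weight_mode)
  if (!file.exists(path))
    stop_subpred("parse", sprintf("population file not found: %s", path))
  df <- tryCatch(read.csv(path, comment.char = "#"),
                 error = function(e) stop_subpred("parse",
                   sprintf("cannot parse %s: %s", path, conditionMessage(e))))
  if (nrow(df) == 0L) stop_subpred("parse", sprintf("population file %s is empty", path))
  needed <- c(outcome_col, covariate_cols, response_col)
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0)
    stop_subpred("parse", sprintf("missing column(s) in %s: %s", path,
                                  paste(missing_cols, collapse = ", ")))
  for (cn in needed) {
    if (!is.numeric(df[[cn]]))
      stop_subpred("parse", sprintf("column '%s' contains non-numeric values", cn))
    if (anyNA(df[[cn]]))
      stop_subpred("parse", sprintf("column '%s' contains missing values", cn))
  }
  N <- nrow(df)
  X <- cbind(1, as.matrix(df[covariate_cols]))
  colnames(X) <- c("(Intercept)", covariate_cols)
  W <- if (weight_mode == "total") rep(1, N) else rep(1 / N, N)
  R <- if (is.null(response_col)) NULL else df[[response_col]]
  finite_population(df[[outcome_col]], X, R = R, W = W,
                    meta = list(source = path, weight_mode = weight_mode))
}
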