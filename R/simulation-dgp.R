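## Simulation-study data-generating process: near-collinear Gaussian covariates
## with a coefficient vector built from the averaged leading eigenvectors of the
## covariate cross-product matrix.

#' Configure a simulation study
#'
#' Bundles the population size, design parameters and replication counts of one
#' simulation configuration. Defaults mirror the full-scale study (N = 10000,
#' p = 8, 2000 outer by 500 inner replications); evaluation harnesses are
#' usually run at reduced counts.
#'
#' @param N population size.
#' @param n first-call sample size.
#' @param p number of covariates.
#' @param k sub-sampling divisor (sub-sample size is about `n2 / k`), `k >= 1`.
#' @param lambda2 population non-response rate in `[0, 1)`.
#' @param rho covariate construction parameter in `[0, 1]` (see
#'   [generate_simulation_population()]).
#' @param sigma_sq outcome error variance.
#' @param reps_outer,reps_inner outer (fresh sample) and inner (sub-sample
#'   redraw) replication counts.
#' @param seed optional integer seed.
#' @param dgp_variant `"literal"`: covariates are `((1-rho)^0.5 + rho) * z`, a
#'   pure rescaling of the iid N(100,1) draws; `"latent"`: `sqrt(1-rho^2) * z +
#'   rho * z_shared`, the standard construction in which a shared latent column
#'   induces cross-covariate correlation `rho^2`.
#' @param response_tail which outcome tail responds (`"lower"` is this design's
#'   convention: respondents fall below the `(1-lambda2)` quantile).
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(N = 10000, n = 100, p = 8, k = 2, lambda2 = 0.2,
                              rho = 0.5, sigma_sq = 0.01,
                              reps_outer = 2000, reps_inner = 500, seed = NULL,
                              dgp_variant = c("literal", "latent"),
                              response_tail = c("lower", "upper")) {
  dgp_variant <- match.arg(dgp_variant)
  response_tail <- match.arg(response_tail)
  if (k < 1) stop_subpred("invalid_spec", "k must be >= 1")
  if (lambda2 < 0 || lambda2 >= 1) stop_subpred("invalid_spec", "lambda2 must lie in [0, 1)")
  if (n > N) stop_subpred("invalid_spec", "n must not exceed N")
  if (reps_outer < 1 || reps_inner < 1) stop_subpred("invalid_spec", "replication counts must be >= 1")
  if (sigma_sq < 0) stop_subpred("invalid_spec", "sigma_sq must be nonnegative")
  if (p < 1) stop_subpred("invalid_spec", "p must be >= 1")
  structure(list(N = as.integer(N), n = as.integer(n), p = as.integer(p),
                 k = k, lambda2 = lambda2, rho = rho, sigma_sq = sigma_sq,
                 reps_outer = as.integer(reps_outer),
                 reps_inner = as.integer(reps_inner),
                 seed = seed, dgp_variant = dgp_variant,
                 response_tail = response_tail),
            class = "simulation_config")
}

# averaged leading eigenvectors of H = x'x over covariate columns only:
# unit-norm eigenvectors with eigenvalue > 1, each sign-fixed so its
# largest-magnitude entry is positive, averaged element-wise
eigen_averaged_coefficients <- function(Xcov) {
  H <- crossprod(Xcov)
  ee <- eigen(H, symmetric = TRUE)
  keep <- ee$values > 1
  if (!any(keep))
    stop_subpred("degenerate_gamma",
                 "no eigenvalue of x'x exceeds 1: coefficient vector undefined")
  V <- ee$vectors[, keep, drop = FALSE]
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  rowMeans(V)
}

#' Generate the simulation-study population
#'
#' Draws `z` as an `N x p` matrix of iid N(100, 1) variates, builds the
#' covariate matrix `x` per `dgp_variant`, sets the coefficient vector `gamma`
#' to the element-wise average of the unit-norm eigenvectors of `H = x'x` with
#' eigenvalue above 1 (signs fixed so each eigenvector's largest-magnitude
#' entry is positive), realizes `y = x gamma + eps` with
#' `eps ~ N(0, sigma_sq I)`, and stratifies response by outcome quantile at
#' rate `1 - lambda2` on the configured tail.
#'
#' @param config a [simulation_config()].
#' @return a [finite_population()] with `gamma`, `rho`, `sigma_sq`, `mu` and
#'   the true total stored in `meta`. Note `gamma` has no intercept; the
#'   fitted models include one (its true value is 0).
#' @export
generate_simulation_population <- function(config) {
  if (!inherits(config, "simulation_config"))
    stop_subpred("invalid_spec", "config must be a simulation_config")
  with_seed(config$seed, {
    N <- config$N; p <- config$p; rho <- config$rho
    z <- matrix(rnorm(N * p, mean = 100, sd = 1), nrow = N, ncol = p)
    x <- switch(config$dgp_variant,
      literal = (sqrt(1 - rho) + rho) * z,
      latent  = {
        z_shared <- rnorm(N, mean = 100, sd = 1)
        sqrt(1 - rho^2) * z + rho * z_shared
      })
    gamma <- eigen_averaged_coefficients(x)
    mu <- drop(x %*% gamma)
    y <- mu + rnorm(N, 0, sqrt(config$sigma_sq))
    R <- assign_response_by_quantile(y, config$lambda2, tail = config$response_tail)
    X <- cbind(1, x)
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(p)))
    pop <- finite_population(y, X, R = R,
                             meta = list(gamma = gamma, rho = rho,
                                         sigma_sq = config$sigma_sq,
                                         dgp_variant = config$dgp_variant,
                                         beta_r = c(0, gamma), beta_nr = c(0, gamma),
                                         sigma1_sq = config$sigma_sq,
                                         sigma2_sq = config$sigma_sq,
                                         mu = mu,
                                         unit_sd = rep(sqrt(config$sigma_sq), N)))
    pop$meta$total_true <- true_total(pop)
    pop
  })
}
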