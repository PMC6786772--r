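## Closed-form model bias / variance / MSE of the predictors, their
## design-expectation by Monte Carlo over sample draws, and an empirical
## (error-redraw) audit of the same moments.

new_error_decomposition <- function(bias_m, var_m, mse_m,
                                    expected_var_d = NA_real_, mc_reps = 0L,
                                    mc_se = NA_real_) {
  structure(list(bias_m = bias_m, var_m = var_m, mse_m = mse_m,
                 expected_var_d = expected_var_d, mc_reps = mc_reps,
                 mc_se = mc_se),
            class = "error_decomposition")
}

#' @export
print.error_decomposition <- function(x, ...) {
  cat(sprintf("error decomposition: bias = %.6g, variance = %.6g, MSE = %.6g\n",
              x$bias_m, x$var_m, x$mse_m))
  if (x$mc_reps > 0)
    cat(sprintf("  Monte Carlo: %d replication(s), SE(bias) = %.3g\n", x$mc_reps, x$mc_se))
  invisible(x)
}

#' Model bias of the respondent-only predictor
#'
#' `W2' X2 (beta1 - beta2)`: the bias incurred by extrapolating the respondent
#' regime to the non-respondent stratum. Zero when the regimes coincide or the
#' non-respondent stratum is empty.
#'
#' @param W2 weights of the non-respondent stratum (length N2).
#' @param X2 design matrix of the non-respondent stratum (N2 x (p+1)).
#' @param beta1,beta2 regime coefficient vectors.
#' @return scalar bias.
#' @export
bias_respondents_only <- function(W2, X2, beta1, beta2) {
  X2 <- as.matrix(X2)
  if (nrow(X2) == 0L) return(0)
  if (length(W2) != nrow(X2) || length(beta1) != ncol(X2) ||
      length(beta2) != ncol(X2))
    stop_subpred("invalid_spec", "W2, X2 and coefficient dimensions do not conform")
  sum(W2 * drop(X2 %*% (beta1 - beta2)))
}

# quadratic form (W[idx]' X[idx])' Hinv (W[idx]' X[idx])
wq_form <- function(pop, idx, Hinv) {
  v <- wx_sum(pop, idx)
  drop(v %*% Hinv %*% v)
}

hessian_inv <- function(pop, idx, label) {
  H <- crossprod(pop$X[idx, , drop = FALSE])
  tryCatch(solve(H), error = function(e)
    stop_subpred("supercollinearity", sprintf("%s is singular", label)))
}

#' Model MSE of the respondent-only predictor
#'
#' Assembles the closed-form decomposition: bias `W2' X2 (beta1 - beta2)`,
#' variance `sigma1_sq * (n1 + W_{s1bar}' X_{s1bar} H_{s1}^-1 X_{s1bar}'
#' W_{s1bar}) + sigma2_sq * W2' X2 H_{s1}^-1 X2' W2` (the printed form, which
#' takes unit prediction weights for the observed part), and
#' `MSE = bias^2 + variance`.
#'
#' @param pop a [finite_population()] with `R` assigned.
#' @param draw a [sample_draw()].
#' @param sigma1_sq,sigma2_sq regime error variances.
#' @param beta1,beta2 regime coefficient vectors.
#' @return an `error_decomposition`.
#' @export
mse_respondents_only <- function(pop, draw, sigma1_sq, sigma2_sq, beta1, beta2) {
  if (sigma1_sq < 0 || sigma2_sq < 0)
    stop_subpred("invalid_spec", "variances must be nonnegative")
  Hinv <- hessian_inv(pop, draw$s1, "H_s1")
  U2 <- which(pop$R == 0L)
  var_m <- sigma1_sq * (draw$n1 + wq_form(pop, draw$s1_bar, Hinv)) +
    sigma2_sq * wq_form(pop, U2, Hinv)
  bias_m <- bias_respondents_only(pop$W[U2], pop$X[U2, , drop = FALSE], beta1, beta2)
  new_error_decomposition(bias_m, var_m, bias_m^2 + var_m)
}

#' Model variance of the sub-sampling predictor
#'
#' The closed form
#' `n1 sigma1_sq + n2' sigma2_sq + sigma1_sq * W_{s1bar}' X_{s1bar} H_{s1}^-1
#' X_{s1bar}' W_{s1bar} + sigma2_sq * W_{s2'bar}' X_{s2'bar} H_{s2'}^-1
#' X_{s2'bar}' W_{s2'bar}`, as printed (leading terms use the observed unit
#' counts). See [empirical_prediction_moments()] for the empirical variance of
#' the prediction error, which targets `Var(T_hat - T_y)` and can differ.
#'
#' @param pop a [finite_population()] with `R` assigned.
#' @param draw a [sample_draw()].
#' @param sigma1_sq,sigma2_sq regime error variances.
#' @return scalar model variance.
#' @export
var_subsampling <- function(pop, draw, sigma1_sq, sigma2_sq) {
  if (sigma1_sq < 0 || sigma2_sq < 0)
    stop_subpred("invalid_spec", "variances must be nonnegative")
  Hinv1 <- hessian_inv(pop, draw$s1, "H_s1")
  q1 <- wq_form(pop, draw$s1_bar, Hinv1)
  q2 <- if (draw$n2_prime > 0L) {
    Hinv2 <- hessian_inv(pop, draw$s2_prime, "H_s2'")
    wq_form(pop, draw$s2_prime_bar, Hinv2)
  } else 0
  draw$n1 * sigma1_sq + draw$n2_prime * sigma2_sq +
    sigma1_sq * q1 + sigma2_sq * q2
}

#' Design-expected model variance of the sub-sampling predictor
#'
#' Monte-Carlo average of [var_subsampling()] over independent SRSWOR samples
#' and sub-samples (no closed form over the design is available). Draws whose
#' regime hessians are singular are rejected and redrawn; the rejected count
#' is attached as attribute `rejected`.
#'
#' @param pop a [finite_population()] with `R` assigned.
#' @param n first-call sample size.
#' @param k sub-sampling divisor.
#' @param sigma1_sq,sigma2_sq regime error variances.
#' @param reps number of design replications.
#' @param seed optional integer seed.
#' @return scalar Monte-Carlo mean with attributes `mc_se` and `rejected`.
#' @export
expected_var_subsampling <- function(pop, n, k, sigma1_sq, sigma2_sq,
                                     reps = 500, seed = NULL) {
  if (reps < 1) stop_subpred("invalid_spec", "reps must be >= 1")
  with_seed(seed, {
    vals <- numeric(reps)
    rejected <- 0L
    for (r in seq_len(reps)) {
      repeat {
        draw <- sample_draw(pop, draw_srswor(pop$N, n), k = k)
        v <- tryCatch(var_subsampling(pop, draw, sigma1_sq, sigma2_sq),
                      subpred_supercollinearity = function(e) NULL)
        if (!is.null(v)) break
        rejected <- rejected + 1L
        if (rejected > 50L * reps)
          stop_subpred("estimation", "design draws are persistently singular")
      }
      vals[r] <- v
    }
    structure(mean(vals), mc_se = sd(vals) / sqrt(reps), rejected = rejected)
  })
}

#' Design-expected model variance of the full-response predictor
#'
#' Monte-Carlo average over SRSWOR draws of
#' `sigma_sq * (W_{sbar}' X_{sbar} H_s^-1 X_{sbar}' W_{sbar} +
#' sum_{sbar} W_i^2)`, the same machinery as [expected_var_subsampling()]
#' applied to the no-nonresponse case.
#'
#' @param pop a [finite_population()].
#' @param n sample size.
#' @param sigma_sq error variance.
#' @param reps,seed Monte-Carlo controls.
#' @return scalar with attributes `mc_se` and `rejected`.
#' @export
expected_var_full <- function(pop, n, sigma_sq, reps = 500, seed = NULL) {
  if (reps < 1) stop_subpred("invalid_spec", "reps must be >= 1")
  with_seed(seed, {
    vals <- numeric(reps)
    rejected <- 0L
    for (r in seq_len(reps)) {
      repeat {
        s <- draw_srswor(pop$N, n)
        s_bar <- setdiff(seq_len(pop$N), s)
        Hinv <- tryCatch(hessian_inv(pop, s, "H_s"),
                         subpred_supercollinearity = function(e) NULL)
        if (!is.null(Hinv)) break
        rejected <- rejected + 1L
        if (rejected > 50L * reps)
          stop_subpred("estimation", "design draws are persistently singular")
      }
      vals[r] <- sigma_sq * (wq_form(pop, s_bar, Hinv) + sum(pop$W[s_bar]^2))
    }
    structure(mean(vals), mc_se = sd(vals) / sqrt(reps), rejected = rejected)
  })
}

#' Empirical prediction moments by model-error redraws
#'
#' The Monte-Carlo oracle for the analytic moments: holding the sample draw
#' fixed, redraws the model errors of every population unit from the
#' generator truth stored in `pop$meta` (`mu` and `unit_sd`), recomputes the
#' outcomes and the (random) true total, refits and re-predicts, and returns
#' the empirical bias, variance and MSE of `estimate - T_y`.
#'
#' @param pop a synthetic [finite_population()] whose `meta` carries `mu` and
#'   `unit_sd` (populations from [make_two_regime_population()] or
#'   [generate_simulation_population()] do).
#' @param draw a [sample_draw()], held fixed.
#' @param fitter function `(pop, draw) -> total_estimate`; defaults to the
#'   sub-sampling predictor via [auto_fit_and_predict()].
#' @param error_reps number of error redraws.
#' @param seed optional integer seed.
#' @return an `error_decomposition` with `mc_reps` and the Monte-Carlo
#'   standard error of the bias. The variance uses divisor `error_reps`, so
#'   `mse = bias^2 + variance` holds exactly.
#' @export
empirical_prediction_moments <- function(pop, draw, fitter = NULL,
                                         error_reps = 2000, seed = NULL) {
  mu <- pop$meta$mu; unit_sd <- pop$meta$unit_sd
  if (is.null(mu) || is.null(unit_sd))
    stop_subpred("contract",
                 "population meta lacks generator truth (mu, unit_sd); use a synthetic population")
  if (is.null(fitter))
    fitter <- function(p, d) auto_fit_and_predict(p, d)
  with_seed(seed, {
    diffs <- numeric(error_reps)
    pop2 <- pop
    for (r in seq_len(error_reps)) {
      y_new <- mu + rnorm(pop$N, 0, unit_sd)
      pop2$y <- y_new
      est <- fitter(pop2, draw)
      diffs[r] <- est$total - sum(pop$W * y_new)
    }
    bias <- mean(diffs)
    vr <- mean((diffs - bias)^2)
    new_error_decomposition(bias, vr, mean(diffs^2),
                            mc_reps = error_reps,
                            mc_se = sd(diffs) / sqrt(error_reps))
  })
}
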