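## Evaluation harnesses: the bootstrap protocol on a fixed population, the
## nested simulation study, and the RB / RMSE metrics.

#' Relative (or absolute) bias and mean squared error of replicated estimates
#'
#' Relative mode: `mean((est - T_y) / T_y)` and `mean(((est - T_y) / T_y)^2)`.
#' Absolute mode (used when the generated values are already standardized):
#' `mean(est - T_y)` and `mean((est - T_y)^2)`.
#'
#' @param estimates vector of replicated total estimates.
#' @param T_y true total.
#' @param relative divide by `T_y` (must be nonzero) or not.
#' @return list with components `bias` and `mse`.
#' @export
relative_bias_and_rmse <- function(estimates, T_y, relative = TRUE) {
  if (relative && T_y == 0)
    stop_subpred("invalid_spec", "relative metrics undefined for T_y = 0")
  d <- estimates - T_y
  if (relative) d <- d / T_y
  list(bias = mean(d), mse = mean(d^2))
}

# fast cholesky OLS coefficients; NULL when the cross-product is singular
fast_coef <- function(Xs, ys) {
  H <- crossprod(Xs)
  ch <- tryCatch(chol(H), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  drop(backsolve(ch, forwardsolve(t(ch), crossprod(Xs, ys))))
}

# regime-2 coefficients with automatic ridge fallback; returns list(b, v)
fit2_coef <- function(Xs, ys, q, grid, force_prr = FALSE, v_fixed = NULL) {
  if (is.null(v_fixed) && !force_prr && nrow(Xs) > q) {
    b <- fast_coef(Xs, ys)
    if (!is.null(b)) return(list(b = b, v = 0))
  }
  v <- v_fixed %||% (if (nrow(Xs) >= 2L) select_tuning(Xs, ys, grid) else 1)
  list(b = drop(solve(crossprod(Xs) + v * diag(q), crossprod(Xs, ys))), v = v)
}

new_eval_row <- function(...) {
  row <- data.frame(..., check.names = FALSE)
  if (any(stats::na.omit(c(row$rmse_resp_only, row$rmse_substar,
                           row$abs_mse_substar, row$abs_mse_prr)) < 0))
    stop_subpred("invalid_spec", "mean squared errors cannot be negative")
  row
}

#' Bootstrap evaluation of the predictors on a fixed population
#'
#' Repeatedly draws first-call SRSWOR samples from a fixed population whose
#' response strata are set by outcome quantile at rate `lambda2`, and for each
#' outer draw re-draws the second-call sub-sample `reps_inner` times. The
#' respondent-only predictor is computed once per outer draw (sub-sampling
#' does not alter it); the sub-sampling predictor is recomputed per inner
#' draw. Reports relative bias and relative MSE for both predictors.
#'
#' Outer draws with too few respondents to fit the regime model
#' (`n1 <= p_used`), with no non-respondents while `lambda2 > 0`, or with a
#' singular respondent fit are rejected, redrawn, and counted.
#'
#' @param pop a [finite_population()].
#' @param n first-call sample size.
#' @param lambda2 non-response rate used to (re)assign the response strata;
#'   `NULL` keeps the population's existing `R`.
#' @param k sub-sampling divisor.
#' @param p_used number of covariates used in the fits (taken in column order
#'   unless `covariate_idx` names them explicitly).
#' @param covariate_idx optional covariate indices (into the non-intercept
#'   columns of `pop$X`) overriding `p_used`.
#' @param reps_outer,reps_inner replication counts.
#' @param seed optional integer seed.
#' @param tail which outcome tail responds (the application convention is
#'   `"upper"`: high-outcome units respond on first call).
#' @return one-row `data.frame` (an evaluation row) echoing the configuration
#'   and carrying `rb_resp_only`, `rb_substar`, `rmse_resp_only`,
#'   `rmse_substar`, rejected-draw count and seed.
#' @export
bootstrap_protocol <- function(pop, n, lambda2, k, p_used = 2,
                               covariate_idx = NULL,
                               reps_outer = 300, reps_inner = 300,
                               seed = NULL, tail = "upper") {
  covariate_idx <- covariate_idx %||% seq_len(p_used)
  p_used <- length(covariate_idx)
  R <- if (is.null(lambda2)) {
    if (is.null(pop$R)) stop_subpred("invalid_spec", "population has no R and no lambda2 given")
    pop$R
  } else assign_response_by_quantile(pop$y, lambda2, tail = tail)
  X <- pop$X[, c(1L, 1L + covariate_idx), drop = FALSE]
  W <- pop$W; y <- pop$y; N <- pop$N
  q <- p_used + 1L
  T_y <- sum(W * y)
  U1 <- which(R == 1L); U2 <- which(R == 0L)
  cs_U1 <- colSums(W[U1] * X[U1, , drop = FALSE])
  cs_U2 <- if (length(U2)) colSums(W[U2] * X[U2, , drop = FALSE]) else numeric(q)
  grid <- default_tuning_grid()

  with_seed(seed, {
    rel1 <- numeric(reps_outer)
    rel2 <- numeric(reps_outer * reps_inner)
    rejected <- 0L
    for (r in seq_len(reps_outer)) {
      repeat {
        s <- draw_srswor(N, n)
        s1 <- s[R[s] == 1L]; s2 <- s[R[s] == 0L]
        n1 <- length(s1); n2 <- length(s2)
        ok <- n1 > p_used && !(n2 == 0L && !is.null(lambda2) && lambda2 > 0)
        b1 <- if (ok) fast_coef(X[s1, , drop = FALSE], y[s1]) else NULL
        if (!is.null(b1)) break
        rejected <- rejected + 1L
        if (rejected > 50L * reps_outer)
          stop_subpred("estimation", "outer draws are persistently degenerate")
      }
      obs1 <- sum(W[s1] * y[s1])
      cs_s1bar <- cs_U1 - colSums(W[s1] * X[s1, , drop = FALSE])
      base1 <- obs1 + sum(cs_s1bar * b1)
      t_hat1 <- base1 + sum(cs_U2 * b1)
      rel1[r] <- (t_hat1 - T_y) / T_y
      for (j in seq_len(reps_inner)) {
        idx <- (r - 1L) * reps_inner + j
        if (n2 == 0L) { rel2[idx] <- rel1[r]; next }
        s2p <- subsample_nonrespondents(s2, k)
        f2 <- fit2_coef(X[s2p, , drop = FALSE], y[s2p], q, grid)
        cs_s2pbar <- cs_U2 - colSums(W[s2p] * X[s2p, , drop = FALSE])
        t_star <- base1 + sum(W[s2p] * y[s2p]) + sum(cs_s2pbar * f2$b)
        rel2[idx] <- (t_star - T_y) / T_y
      }
    }
    new_eval_row(
      protocol = "bootstrap", n = n, k = k,
      lambda2 = lambda2 %||% (length(U2) / N), rho = NA_real_,
      sigma_sq = NA_real_, p = p_used,
      rb_resp_only = mean(rel1), rb_substar = mean(rel2),
      rmse_resp_only = mean(rel1^2), rmse_substar = mean(rel2^2),
      abs_bias_substar = NA_real_, abs_mse_substar = NA_real_,
      abs_bias_prr = NA_real_, abs_mse_prr = NA_real_,
      reps_outer = reps_outer, reps_inner = reps_inner,
      reps_used = reps_outer, rejected = rejected,
      seed = seed %||% NA_integer_)
  })
}

#' Nested simulation study on a generated population
#'
#' Generates one population from the simulation design, then runs the nested
#' replication: each outer replication draws a fresh first-call sample and
#' fits the respondent regime; each inner replication re-draws the sub-sample,
#' fits the non-respondent regime (OLS with automatic PRR fallback) and
#' predicts the total; inner estimates are averaged before the outer-level
#' moments are taken. Reports absolute bias and MSE (the generated values are
#' treated as standardized) for the sub-sampling predictor and, when
#' `prr = TRUE`, for the always-ridge PRR variant whose tuning parameter is
#' re-selected from each sub-sample.
#'
#' @param config a [simulation_config()].
#' @param prr also evaluate the PRR variant.
#' @return one-row `data.frame` with `abs_bias_substar`, `abs_mse_substar`
#'   and, when requested, `abs_bias_prr`, `abs_mse_prr`.
#' @export
run_simulation_study <- function(config, prr = TRUE) {
  if (!inherits(config, "simulation_config"))
    stop_subpred("invalid_spec", "config must be a simulation_config")
  with_seed(config$seed, {
    cfg <- config; cfg$seed <- NULL
    pop <- generate_simulation_population(cfg)
    X <- pop$X; W <- pop$W; y <- pop$y; N <- pop$N
    q <- config$p + 1L
    T_y <- sum(W * y)
    U1 <- which(pop$R == 1L); U2 <- which(pop$R == 0L)
    cs_U1 <- colSums(W[U1] * X[U1, , drop = FALSE])
    cs_U2 <- if (length(U2)) colSums(W[U2] * X[U2, , drop = FALSE]) else numeric(q)
    grid <- default_tuning_grid()
    est_star <- numeric(config$reps_outer)
    est_prr <- numeric(config$reps_outer)
    rejected <- 0L
    for (r in seq_len(config$reps_outer)) {
      repeat {
        s <- draw_srswor(N, config$n)
        s1 <- s[pop$R[s] == 1L]; s2 <- s[pop$R[s] == 0L]
        n1 <- length(s1); n2 <- length(s2)
        ok <- n1 > config$p && !(n2 == 0L && config$lambda2 > 0)
        b1 <- if (ok) fast_coef(X[s1, , drop = FALSE], y[s1]) else NULL
        if (!is.null(b1)) break
        rejected <- rejected + 1L
        if (rejected > 50L * config$reps_outer)
          stop_subpred("estimation", "outer draws are persistently degenerate")
      }
      base1 <- sum(W[s1] * y[s1]) +
        sum((cs_U1 - colSums(W[s1] * X[s1, , drop = FALSE])) * b1)
      inner_star <- numeric(config$reps_inner)
      inner_prr <- numeric(config$reps_inner)
      for (j in seq_len(config$reps_inner)) {
        if (n2 == 0L) {
          inner_star[j] <- base1 + sum(cs_U2 * b1)
          inner_prr[j] <- inner_star[j]
          next
        }
        s2p <- subsample_nonrespondents(s2, config$k)
        X2p <- X[s2p, , drop = FALSE]; y2p <- y[s2p]
        obs2 <- sum(W[s2p] * y2p)
        cs_s2pbar <- cs_U2 - colSums(W[s2p] * X2p)
        f2 <- fit2_coef(X2p, y2p, q, grid)
        inner_star[j] <- base1 + obs2 + sum(cs_s2pbar * f2$b)
        if (prr) {
          f2v <- fit2_coef(X2p, y2p, q, grid, force_prr = TRUE)
          inner_prr[j] <- base1 + obs2 + sum(cs_s2pbar * f2v$b)
        }
      }
      est_star[r] <- mean(inner_star)
      if (prr) est_prr[r] <- mean(inner_prr)
    }
    m_star <- relative_bias_and_rmse(est_star, T_y, relative = FALSE)
    m_prr <- if (prr) relative_bias_and_rmse(est_prr, T_y, relative = FALSE)
             else list(bias = NA_real_, mse = NA_real_)
    new_eval_row(
      protocol = "simulation", n = config$n, k = config$k,
      lambda2 = config$lambda2, rho = config$rho, sigma_sq = config$sigma_sq,
      p = config$p,
      rb_resp_only = NA_real_, rb_substar = NA_real_,
      rmse_resp_only = NA_real_, rmse_substar = NA_real_,
      abs_bias_substar = m_star$bias, abs_mse_substar = m_star$mse,
      abs_bias_prr = m_prr$bias, abs_mse_prr = m_prr$mse,
      reps_outer = config$reps_outer, reps_inner = config$reps_inner,
      reps_used = config$reps_outer, rejected = rejected,
      seed = config$seed %||% NA_integer_)
  })
}

#' Run a grid of evaluation configurations
#'
#' Applies the chosen protocol to each configuration and stacks the
#' evaluation rows into one long-format table; per-configuration failures are
#' recorded (attribute `failures`) and the sweep continues.
#'
#' @param configs nonempty list; for `protocol = "bootstrap"` each element is
#'   an argument list for [bootstrap_protocol()]; for `"simulation"` each is a
#'   [simulation_config()] (or an argument list for [simulation_config()]).
#' @param protocol `"bootstrap"` or `"simulation"`.
#' @param out optional CSV path; the table is written with `write.csv`.
#' @param prr passed to [run_simulation_study()].
#' @return `data.frame` of evaluation rows.
#' @export
sweep_evaluations <- function(configs, protocol = c("bootstrap", "simulation"),
                              out = NULL, prr = TRUE) {
  protocol <- match.arg(protocol)
  if (length(configs) == 0L) stop_subpred("invalid_spec", "no configurations given")
  failures <- list()
  rows <- list()
  for (i in seq_along(configs)) {
    cf <- configs[[i]]
    res <- tryCatch({
      if (protocol == "bootstrap") do.call(bootstrap_protocol, cf)
      else run_simulation_study(
        if (inherits(cf, "simulation_config")) cf else do.call(simulation_config, cf),
        prr = prr)
    }, error = function(e) e)
    if (inherits(res, "error")) failures[[as.character(i)]] <- conditionMessage(res)
    else rows[[length(rows) + 1L]] <- res
  }
  tab <- do.call(rbind, rows)
  if (!is.null(out)) write.csv(tab, out, row.names = FALSE)
  attr(tab, "failures") <- failures
  tab
}
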