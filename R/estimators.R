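## Total predictors: full-response, respondent-only, and sub-sampling (with
## OLS / WLS / PRR regime fits), plus the automatic fit-and-predict policy.

new_total_estimate <- function(total, components, method, draw = NULL, v = NA_real_) {
  stopifnot(abs(total - sum(components)) <= 1e-8 * max(1, abs(total)))
  structure(list(total = total, components = components, method = method,
                 n = draw$n %||% NA_integer_, n1 = draw$n1 %||% NA_integer_,
                 n2 = draw$n2 %||% NA_integer_,
                 n2_prime = draw$n2_prime %||% NA_integer_, v = v),
            class = "total_estimate")
}

#' @export
print.total_estimate <- function(x, ...) {
  cat(sprintf("predicted population total: %.6g  [%s]\n", x$total, x$method))
  for (nm in names(x$components))
    cat(sprintf("  %-28s %.6g\n", nm, x$components[[nm]]))
  if (!is.na(x$n))
    cat(sprintf("  n = %d, n1 = %d, n2 = %d, n2' = %d%s\n", x$n, x$n1, x$n2,
                x$n2_prime, if (!is.na(x$v)) sprintf(", v = %g", x$v) else ""))
  invisible(x)
}

#' Flatten a total estimate to a one-row data frame
#'
#' @param x a `total_estimate`.
#' @param ... unused.
#' @return one-row `data.frame` with the method, total, components and sizes.
#' @export
as.data.frame.total_estimate <- function(x, ...) {
  comp <- as.list(x$components)
  names(comp) <- gsub("[^a-z0-9]+", "_", tolower(names(comp)))
  data.frame(method = x$method, total = x$total, comp,
             n = x$n, n1 = x$n1, n2 = x$n2, n2_prime = x$n2_prime, v = x$v,
             check.names = FALSE)
}

# weighted column aggregate W[idx]' X[idx, ]
wx_sum <- function(pop, idx) {
  if (length(idx) == 0L) return(numeric(ncol(pop$X)))
  colSums(pop$W[idx] * pop$X[idx, , drop = FALSE])
}

wy_sum <- function(pop, idx) if (length(idx) == 0L) 0 else sum(pop$W[idx] * pop$y[idx])

#' Predict the population total under full response
#'
#' The baseline prediction estimator: observed weighted sample sum plus the
#' model prediction for every non-sampled unit,
#' `sum_{i in s} W_i y_i + sum_{i not in s} W_i x_i' b`.
#'
#' @param pop a [finite_population()].
#' @param s sample index set.
#' @param fit a `linear_fit` trained on rows `s`.
#' @return a `total_estimate` with components `observed` and `predicted`.
#' @export
predict_total_full <- function(pop, s, fit) {
  s <- sort(unique(as.integer(s)))
  if (length(s) == 0L) stop_subpred("estimation", "empty sample")
  s_bar <- setdiff(seq_len(pop$N), s)
  comps <- c(observed  = wy_sum(pop, s),
             predicted = sum(wx_sum(pop, s_bar) * fit$b))
  new_total_estimate(sum(comps), comps, method = paste0("full/", fit$method),
                     draw = list(n = length(s), n1 = NA_integer_,
                                 n2 = NA_integer_, n2_prime = NA_integer_),
                     v = fit$v)
}

#' Predict the total from first-call respondents only
#'
#' The comparison baseline: the respondent-regime fit `b1` is extrapolated to
#' every unobserved unit, including the entire non-respondent stratum. Its
#' model bias is `W2' X2 (beta1 - beta2)` (see [bias_respondents_only()]),
#' vanishing only when the two regimes share their coefficients.
#'
#' @param pop a [finite_population()] with `R` assigned.
#' @param draw a [sample_draw()].
#' @param fit1 a `linear_fit` trained on rows `s1`.
#' @return a `total_estimate` with components `observed_respondents`,
#'   `predicted_unsampled_resp` and `predicted_nonrespondents`.
#' @export
predict_total_respondents_only <- function(pop, draw, fit1) {
  U2 <- which(pop$R == 0L)
  comps <- c(observed_respondents     = wy_sum(pop, draw$s1),
             predicted_unsampled_resp = sum(wx_sum(pop, draw$s1_bar) * fit1$b),
             predicted_nonrespondents = sum(wx_sum(pop, U2) * fit1$b))
  new_total_estimate(sum(comps), comps,
                     method = paste0("respondents_only/", fit1$method),
                     draw = draw, v = fit1$v)
}

#' Predict the total with sub-sampled non-respondents
#'
#' The sub-sampling predictor: observed first-call respondents plus the
#' respondent-regime prediction of unsampled respondents, plus observed
#' second-call sub-sample plus the non-respondent-regime prediction of the
#' remaining non-respondent stratum,
#' `sum_{s1} W y + W_{s1bar}' X_{s1bar} b1 + sum_{s2'} W y +
#'  W_{s2'bar}' X_{s2'bar} b2`.
#' With `fit2` from [fit_prr()] this is the partially-ridge (PRR) variant;
#' with [fit_wls()] fits it is the WLS variant.
#'
#' @param pop a [finite_population()] with `R` assigned.
#' @param draw a [sample_draw()].
#' @param fit1 `linear_fit` trained on `s1`.
#' @param fit2 `linear_fit` trained on `s2_prime`; may be `NULL` only when the
#'   sample contains no non-respondents.
#' @return a `total_estimate` with the four additive components.
#' @export
predict_total_subsampling <- function(pop, draw, fit1, fit2) {
  if (draw$n2 > 0L && draw$n2_prime == 0L)
    stop_subpred("estimation", "non-respondents present but the sub-sample is empty")
  if (is.null(fit2) && draw$n2 > 0L)
    stop_subpred("contract", "fit2 is required when the sample contains non-respondents")
  b2 <- if (is.null(fit2)) rep(0, ncol(pop$X)) else fit2$b
  comps <- c(observed_respondents     = wy_sum(pop, draw$s1),
             predicted_unsampled_resp = sum(wx_sum(pop, draw$s1_bar) * fit1$b),
             observed_subsample       = wy_sum(pop, draw$s2_prime),
             predicted_remaining_nr   = sum(wx_sum(pop, draw$s2_prime_bar) * b2))
  method2 <- if (is.null(fit2)) "none" else fit2$method
  new_total_estimate(sum(comps), comps,
                     method = sprintf("subsampling/%s+%s", fit1$method, method2),
                     draw = draw,
                     v = if (is.null(fit2)) NA_real_ else fit2$v)
}

#' Fit both regimes and predict the total, with automatic ridge fallback
#'
#' Fits the respondent regime on `s1` by OLS (or WLS when a variance structure
#' is supplied) and the non-respondent regime on the sub-sample `s2_prime` by
#' OLS when `n2' > p + 1`, switching automatically to PRR — with the tuning
#' parameter chosen by [select_tuning()] unless fixed — when the sub-sample is
#' too small or super-collinear. The method string of the returned estimate
#' records any fallback taken.
#'
#' @param pop a [finite_population()] with `R` assigned.
#' @param draw a [sample_draw()].
#' @param ridge_policy list with optional entries `force` (logical: always use
#'   PRR for regime 2), `v` (fixed tuning value) and `grid` (candidate grid
#'   for [select_tuning()]).
#' @param weight_structures optional list with entries `V1` and/or `V2`:
#'   per-unit variance vectors over the whole population, switching the
#'   corresponding regime fit to WLS.
#' @return a `total_estimate`; attribute `fits` carries the two `linear_fit`s.
#' @export
auto_fit_and_predict <- function(pop, draw, ridge_policy = list(),
                                 weight_structures = NULL) {
  if (draw$n1 == 0L)
    stop_subpred("no_respondents", "the sample contains no respondents")
  q <- ncol(pop$X)
  force_prr <- isTRUE(ridge_policy$force)
  grid <- ridge_policy$grid %||% default_tuning_grid()

  X1 <- pop$X[draw$s1, , drop = FALSE]; y1 <- pop$y[draw$s1]
  fit1 <- if (!is.null(weight_structures$V1))
    fit_wls(X1, y1, weight_structures$V1[draw$s1]) else fit_ols(X1, y1)

  fit2 <- NULL
  if (draw$n2 > 0L) {
    X2 <- pop$X[draw$s2_prime, , drop = FALSE]; y2 <- pop$y[draw$s2_prime]
    use_ols <- draw$n2_prime > q && !force_prr && is.null(ridge_policy$v)
    if (use_ols) {
      fit2 <- tryCatch(
        if (!is.null(weight_structures$V2))
          fit_wls(X2, y2, weight_structures$V2[draw$s2_prime]) else fit_ols(X2, y2),
        subpred_supercollinearity = function(e) NULL)
    }
    if (is.null(fit2)) {
      v <- ridge_policy$v %||%
        (if (draw$n2_prime >= 2L) select_tuning(X2, y2, grid) else 1)
      fit2 <- fit_prr(X2, y2, v)
    }
  }
  est <- predict_total_subsampling(pop, draw, fit1, fit2)
  attr(est, "fits") <- list(fit1 = fit1, fit2 = fit2)
  est
}
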