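# Fixture builders and independent brute-force oracles used across the suite.
# The oracles deliberately use naive dense matrix products and element loops so
# they share no code path with the package implementations they check.

# small two-regime population with a single deterministic covariate (the unit
# index), respondents first
toy_population <- function(N1 = 6, N2 = 4, beta1 = c(0, 1), beta2 = c(10, 1),
                           sigma1_sq = 0, sigma2_sq = 0, seed = 1,
                           covariate_law = NULL) {
  spec <- two_regime_spec(beta_r = beta1, beta_nr = beta2,
                          sigma1_sq = sigma1_sq, sigma2_sq = sigma2_sq,
                          covariate_law = covariate_law %||%
                            function(n) matrix(seq_len(n), ncol = 1))
  make_two_regime_population(spec, N1, N2, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# element-loop evaluation of W2' X2 (beta1 - beta2)
oracle_bias_resp_only <- function(pop, beta1, beta2) {
  tot <- 0
  for (i in which(pop$R == 0L))
    tot <- tot + pop$W[i] * sum(pop$X[i, ] * (beta1 - beta2))
  tot
}

# naive quadratic form W[idx]' X[idx] (X[hidx]'X[hidx])^-1 X[idx]' W[idx]
oracle_qform <- function(pop, idx, hidx) {
  if (length(idx) == 0L) return(0)
  Xh <- pop$X[hidx, , drop = FALSE]
  H <- t(Xh) %*% Xh
  Xi <- pop$X[idx, , drop = FALSE]
  Wi <- matrix(pop$W[idx], ncol = 1)
  drop(t(Wi) %*% Xi %*% solve(H) %*% t(Xi) %*% Wi)
}

# printed respondent-only variance / MSE, assembled independently
oracle_mse_resp_only <- function(pop, draw, s1sq, s2sq, beta1, beta2) {
  U2 <- which(pop$R == 0L)
  v <- s1sq * (draw$n1 + oracle_qform(pop, draw$s1_bar, draw$s1)) +
    s2sq * oracle_qform(pop, U2, draw$s1)
  b <- oracle_bias_resp_only(pop, beta1, beta2)
  list(bias = b, var = v, mse = b^2 + v)
}

# printed sub-sampling variance, assembled independently
oracle_var_subsampling <- function(pop, draw, s1sq, s2sq) {
  draw$n1 * s1sq + draw$n2_prime * s2sq +
    s1sq * oracle_qform(pop, draw$s1_bar, draw$s1) +
    s2sq * oracle_qform(pop, draw$s2_prime_bar, draw$s2_prime)
}

# four-term sub-sampling predictor computed with lm() fits and explicit sums
oracle_total_subsampling <- function(pop, draw) {
  d <- data.frame(y = pop$y, pop$X[, -1, drop = FALSE])
  names(d)[-1] <- paste0("x", seq_len(ncol(pop$X) - 1L))
  f <- stats::as.formula(paste("y ~", paste(names(d)[-1], collapse = "+")))
  b1 <- unname(stats::coef(stats::lm(f, data = d[draw$s1, ])))
  b2 <- unname(stats::coef(stats::lm(f, data = d[draw$s2_prime, ])))
  term <- function(idx, b) {
    tot <- 0
    for (i in idx) tot <- tot + pop$W[i] * sum(pop$X[i, ] * b)
    tot
  }
  sum(pop$W[draw$s1] * pop$y[draw$s1]) + term(draw$s1_bar, b1) +
    sum(pop$W[draw$s2_prime] * pop$y[draw$s2_prime]) + term(draw$s2_prime_bar, b2)
}

expect_rel_equal <- function(actual, expected, tol = 1e-9) {
  scale <- max(abs(expected), 1e-12)
  expect_lt(abs(actual - expected) / scale, tol)
}
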