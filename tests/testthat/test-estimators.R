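test_that("full-response predictor: census is exact, noise-free models are recovered", {
  pop <- toy_population(N1 = 8, N2 = 4, beta1 = c(1, 2), beta2 = c(1, 2),
                        sigma1_sq = 1, sigma2_sq = 1, seed = 6)
  s_all <- seq_len(pop$N)
  fit <- fit_ols(pop$X, pop$y)
  est <- predict_total_full(pop, s_all, fit)
  expect_equal(est$total, sum(pop$W * pop$y))
  expect_equal(unname(est$components["predicted"]), 0)

  pop0 <- toy_population(N1 = 8, N2 = 4, beta1 = c(1, 2), beta2 = c(1, 2))
  s <- c(2, 5, 9, 11)
  f0 <- fit_ols(pop0$X[s, ], pop0$y[s])
  expect_equal(predict_total_full(pop0, s, f0)$total, sum(pop0$W * pop0$y),
               tolerance = 1e-10)
  expect_error(predict_total_full(pop0, integer(0), f0), class = "subpred_estimation")
})

test_that("full-response predictor matches a hand OLS computation on six units", {
  x <- 1:6
  pop <- finite_population(y = c(1, 2, 3, 4, 5, 6) + c(0, .3, -.2, .1, 0, -.4),
                           X = cbind(1, x))
  s <- c(1, 3, 5)
  fit <- fit_ols(pop$X[s, ], pop$y[s])
  est <- predict_total_full(pop, s, fit)
  b_or <- unname(coef(lm(pop$y[s] ~ x[s])))
  manual <- sum(pop$y[s]) + sum(b_or[1] + b_or[2] * x[c(2, 4, 6)])
  expect_equal(est$total, manual, tolerance = 1e-10)
})

test_that("respondent-only predictor carries exactly the closed-form regime-gap bias", {
  # identical regimes, no noise: unbiased and exact
  pop_eq <- toy_population(N1 = 6, N2 = 4, beta1 = c(2, 1), beta2 = c(2, 1))
  draw <- sample_draw(pop_eq, s = c(1, 3, 5, 7, 9), k = 2, s2_prime = c(7, 9))
  fit1 <- fit_ols(pop_eq$X[draw$s1, ], pop_eq$y[draw$s1])
  expect_equal(predict_total_respondents_only(pop_eq, draw, fit1)$total,
               sum(pop_eq$W * pop_eq$y), tolerance = 1e-9)

  # intercept gap of 10 over N2 = 4 units: total misses by exactly -40
  pop <- toy_population(N1 = 6, N2 = 4, beta1 = c(0, 1), beta2 = c(10, 1))
  draw2 <- sample_draw(pop, s = c(1, 2, 4, 8, 10), k = 2, s2_prime = c(8, 10))
  f1 <- fit_ols(pop$X[draw2$s1, ], pop$y[draw2$s1])
  est <- predict_total_respondents_only(pop, draw2, f1)
  expect_equal(est$total, sum(pop$W * pop$y) - 40, tolerance = 1e-9)
  expect_equal(est$total - sum(pop$W * pop$y),
               oracle_bias_resp_only(pop, c(0, 1), c(10, 1)), tolerance = 1e-9)
})

test_that("respondent-only predictor equals the full predictor when everyone responds", {
  spec <- two_regime_spec(beta_r = c(1, 2), beta_nr = c(1, 2), sigma1_sq = 1, sigma2_sq = 1)
  pop <- make_two_regime_population(spec, N1 = 12, N2 = 0, seed = 4)
  s <- c(1, 4, 6, 9)
  draw <- sample_draw(pop, s, k = 2)
  fit1 <- fit_ols(pop$X[draw$s1, ], pop$y[draw$s1])
  expect_equal(predict_total_respondents_only(pop, draw, fit1)$total,
               predict_total_full(pop, s, fit1)$total)
})

test_that("sub-sampling predictor is exact for censuses and noise-free regimes", {
  pop <- toy_population(N1 = 7, N2 = 5, beta1 = c(1, 2), beta2 = c(8, -1),
                        sigma1_sq = 0.5, sigma2_sq = 0.5, seed = 10)
  draw <- sample_draw(pop, seq_len(pop$N), k = 1)
  expect_equal(draw$s2_prime, draw$s2)
  fit1 <- fit_ols(pop$X[draw$s1, ], pop$y[draw$s1])
  fit2 <- fit_ols(pop$X[draw$s2_prime, ], pop$y[draw$s2_prime])
  est <- predict_total_subsampling(pop, draw, fit1, fit2)
  expect_equal(est$total, sum(pop$W * pop$y), tolerance = 1e-10)

  pop0 <- toy_population(N1 = 10, N2 = 8, beta1 = c(0, 1), beta2 = c(10, 3))
  draw0 <- sample_draw(pop0, s = c(1, 2, 3, 11, 12, 13, 14), k = 2,
                       s2_prime = c(11, 13))
  f1 <- fit_ols(pop0$X[draw0$s1, ], pop0$y[draw0$s1])
  f2 <- fit_ols(pop0$X[draw0$s2_prime, ], pop0$y[draw0$s2_prime])
  expect_equal(predict_total_subsampling(pop0, draw0, f1, f2)$total,
               sum(pop0$W * pop0$y), tolerance = 1e-9)
})

test_that("sub-sampling predictor equals the brute-force four-term evaluation", {
  pop <- toy_population(N1 = 7, N2 = 5, beta1 = c(2, 1.5), beta2 = c(-3, 4),
                        sigma1_sq = 2, sigma2_sq = 3, seed = 23)
  draw <- sample_draw(pop, s = c(1, 3, 4, 6, 8, 9, 11), k = 2, s2_prime = c(9, 11))
  fit1 <- fit_ols(pop$X[draw$s1, ], pop$y[draw$s1])
  fit2 <- fit_ols(pop$X[draw$s2_prime, ], pop$y[draw$s2_prime])
  est <- predict_total_subsampling(pop, draw, fit1, fit2)
  expect_rel_equal(est$total, oracle_total_subsampling(pop, draw), 1e-9)
  # the four stored components add up to the total
  expect_rel_equal(sum(est$components), est$total, 1e-9)
  expect_length(est$components, 4L)
})

test_that("sub-sampling predictor enforces its contracts", {
  pop <- toy_population(N1 = 6, N2 = 4, sigma1_sq = 1, sigma2_sq = 1, seed = 2)
  draw <- sample_draw(pop, s = c(1, 2, 3, 8, 9), k = 2, s2_prime = c(8, 9))
  fit1 <- fit_ols(pop$X[draw$s1, ], pop$y[draw$s1])
  expect_error(predict_total_subsampling(pop, draw, fit1, NULL),
               class = "subpred_contract")
  draw_empty <- draw
  draw_empty$s2_prime <- integer(0)
  draw_empty$n2_prime <- 0L
  expect_error(predict_total_subsampling(pop, draw_empty, fit1, fit1),
               class = "subpred_estimation")
})

test_that("automatic fitting falls back to ridge exactly when the sub-sample is too small", {
  spec <- two_regime_spec(beta_r = c(1, 1, 1, 1), beta_nr = c(2, -1, 0.5, 1),
                          sigma1_sq = 0.5, sigma2_sq = 0.5)
  pop <- make_two_regime_population(spec, N1 = 40, N2 = 20, seed = 31)

  # ample sub-sample: plain OLS for regime 2
  set.seed(1)
  draw_big <- sample_draw(pop, c(1:20, 41:54), k = 2)
  expect_gte(draw_big$n2_prime, 6L)
  est_big <- auto_fit_and_predict(pop, draw_big)
  expect_match(est_big$method, "\\+ols$")

  # n2' = 2 < p + 1 = 4: forced PRR with a selected tuning value
  draw_small <- sample_draw(pop, c(1:20, 41:44), k = 2, s2_prime = c(41, 42))
  est_small <- auto_fit_and_predict(pop, draw_small)
  expect_match(est_small$method, "\\+prr$")
  expect_gt(est_small$v, 0)

  # forcing v = 0 on ample data reproduces the plain estimator
  est_v0 <- auto_fit_and_predict(pop, draw_big, ridge_policy = list(v = 0))
  expect_equal(est_v0$total, est_big$total, tolerance = 1e-9)

  expect_error(auto_fit_and_predict(pop, sample_draw(pop, 41:50, k = 2)),
               class = "subpred_no_respondents")
})

test_that("weight structures switch the regime fits to WLS", {
  spec <- two_regime_spec(beta_r = c(1, 2), beta_nr = c(3, -1),
                          sigma1_sq = 1, sigma2_sq = 1)
  pop <- make_two_regime_population(spec, N1 = 30, N2 = 20, seed = 12)
  set.seed(2)
  draw <- sample_draw(pop, c(1:15, 31:40), k = 2)
  V1 <- exp(pop$X[, 2] / 2)
  est <- auto_fit_and_predict(pop, draw, weight_structures = list(V1 = V1))
  expect_match(est$method, "subsampling/wls")
  fits <- attr(est, "fits")
  expect_equal(fits$fit1$b,
               fit_wls(pop$X[draw$s1, ], pop$y[draw$s1], V1[draw$s1])$b)
})
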