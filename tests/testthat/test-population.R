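test_that("two-regime generator realizes the stated linear models", {
  # degenerate noise-free case: identical regimes, constant covariate
  spec <- two_regime_spec(beta_r = c(2, 3), beta_nr = c(2, 3),
                          sigma1_sq = 0, sigma2_sq = 0,
                          covariate_law = function(n) matrix(1, n, 1))
  pop <- make_two_regime_population(spec, N1 = 5, N2 = 5, seed = 1)
  expect_equal(pop$y, rep(5, 10))
  expect_equal(sum(pop$W * pop$y), 50)
  expect_equal(pop$N1, 5L)
  expect_equal(pop$lambda2, 0.5)

  # regime separation: the intercept gap shows up exactly in the residuals
  pop2 <- toy_population(N1 = 5, N2 = 5, beta1 = c(0, 1), beta2 = c(10, 1))
  res <- pop2$y - pop2$X[, 2]
  expect_equal(unname(res[pop2$R == 1]), rep(0, 5))
  expect_equal(unname(res[pop2$R == 0]), rep(10, 5))
})

test_that("generated errors follow the specified variance", {
  spec <- two_regime_spec(beta_r = c(1, 2), beta_nr = c(3, -1),
                          sigma1_sq = 4, sigma2_sq = 1)
  pop <- make_two_regime_population(spec, N1 = 2000, N2 = 2000, seed = 7)
  r1 <- pop$y[pop$R == 1] - drop(pop$X[pop$R == 1, ] %*% spec$beta_r)
  expect_lt(abs(var(r1) - 4), 0.3)
  r2 <- pop$y[pop$R == 0] - drop(pop$X[pop$R == 0, ] %*% spec$beta_nr)
  expect_lt(abs(var(r2) - 1), 0.15)
})

test_that("noise-free populations lie exactly on their regression planes", {
  spec <- two_regime_spec(beta_r = c(1, 2, -1), beta_nr = c(0, 1, 4),
                          sigma1_sq = 0, sigma2_sq = 0)
  pop <- make_two_regime_population(spec, N1 = 30, N2 = 20, seed = 3)
  mu <- ifelse(pop$R == 1, drop(pop$X %*% spec$beta_r), drop(pop$X %*% spec$beta_nr))
  expect_lt(max(abs(pop$y - mu)), 1e-10)
})

test_that("invalid two-regime specs are rejected", {
  expect_error(two_regime_spec(c(1, 2), c(1, 2), sigma1_sq = -1),
               class = "subpred_invalid_spec")
  expect_error(two_regime_spec(c(1, 2), c(1, 2, 3)),
               class = "subpred_invalid_spec")
  spec <- two_regime_spec(c(1, 2), c(1, 2))
  expect_error(make_two_regime_population(spec, 0, 0),
               class = "subpred_invalid_spec")
})

test_that("quantile response assignment marks the stated tail", {
  y <- 1:10
  up <- assign_response_by_quantile(y, 0.5, tail = "upper")
  expect_equal(which(up == 1L), 6:10)
  lo <- assign_response_by_quantile(y, 0.5, tail = "lower")
  expect_equal(which(lo == 1L), 1:5)
  expect_equal(assign_response_by_quantile(y, 0), rep(1L, 10))
  expect_error(assign_response_by_quantile(rep(3, 10), 0.4),
               class = "subpred_tie_degenerate")
})

test_that("respondent fraction tracks 1 - lambda2 for tie-free outcomes", {
  set.seed(11)
  for (lambda2 in c(0.1, 0.25, 0.5, 0.8)) {
    for (tail in c("upper", "lower")) {
      y <- rnorm(173)
      R <- assign_response_by_quantile(y, lambda2, tail = tail)
      expect_lte(abs(mean(R) - (1 - lambda2)), 1 / length(y))
    }
  }
})

test_that("CSV loader builds the population container faithfully", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("y,x1\n1,2\n3,4\n5,6", path)
  pop <- load_population_csv(path, "y", "x1")
  expect_equal(pop$N, 3L)
  expect_equal(dim(pop$X), c(3L, 2L))
  expect_equal(unname(pop$X[, 1]), rep(1, 3))
  expect_equal(pop$W, rep(1, 3))
  expect_null(pop$R)

  popm <- load_population_csv(path, "y", "x1", weight_mode = "mean")
  expect_equal(popm$W, rep(1 / 3, 3))

  expect_error(load_population_csv(path, "y", "nope"), class = "subpred_parse")
  expect_error(load_population_csv(file.path(tempdir(), "absent.csv"), "y", "x1"),
               class = "subpred_parse")
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("y,x1\n1,a\n2,b", bad)
  expect_error(load_population_csv(bad, "y", "x1"), class = "subpred_parse")
})

test_that("blood-donor emulator is a fixed-size deterministic synthetic table", {
  pop <- emulate_blood_population(seed = 5)
  expect_equal(pop$N, 748L)
  expect_true(isTRUE(pop$meta$synthetic))
  df <- as.data.frame(pop)
  expect_gt(cor(df$y, df$frequency), abs(cor(df$y, df$recency)))
  expect_gt(cor(df$y, df$time), abs(cor(df$y, df$recency)))
  pop2 <- emulate_blood_population(seed = 5)
  expect_identical(pop$y, pop2$y)
  expect_identical(pop$X, pop2$X)
  pop3 <- emulate_blood_population(seed = 6)
  expect_false(identical(pop$y, pop3$y))
})

test_that("simulation design generates N(100,1)-based covariates and a quantile split", {
  cfg <- simulation_config(N = 10000, n = 100, p = 8, lambda2 = 0.2,
                           rho = 0.5, sigma_sq = 0.01, seed = 21,
                           reps_outer = 1, reps_inner = 1)
  pop <- generate_simulation_population(cfg)
  # under the literal variant x is a pure rescaling of z
  scale <- sqrt(1 - cfg$rho) + cfg$rho
  zbar <- colMeans(pop$X[, -1]) / scale
  expect_true(all(abs(zbar - 100) < 0.05))
  expect_equal(sum(pop$R), as.integer(ceiling(0.8 * cfg$N)))
  # noise-free outcomes sit exactly on x %*% gamma
  cfg0 <- simulation_config(N = 2000, p = 4, sigma_sq = 0, seed = 9,
                            reps_outer = 1, reps_inner = 1)
  pop0 <- generate_simulation_population(cfg0)
  expect_lt(max(abs(pop0$y - drop(pop0$X[, -1] %*% pop0$meta$gamma))), 1e-9)
})

test_that("simulation design is bit-reproducible and the latent variant correlates covariates", {
  cfg <- simulation_config(N = 1500, p = 5, seed = 33, reps_outer = 1, reps_inner = 1)
  a <- generate_simulation_population(cfg)
  b <- generate_simulation_population(cfg)
  expect_identical(a$y, b$y)
  expect_identical(a$meta$gamma, b$meta$gamma)

  lat <- simulation_config(N = 4000, p = 5, rho = 0.9, seed = 33,
                           dgp_variant = "latent", reps_outer = 1, reps_inner = 1)
  popl <- generate_simulation_population(lat)
  cl <- cor(popl$X[, -1])
  off <- cl[upper.tri(cl)]
  expect_lt(abs(mean(off) - 0.81), 0.05)
  lit <- generate_simulation_population(simulation_config(
    N = 4000, p = 5, rho = 0.9, seed = 33, reps_outer = 1, reps_inner = 1))
  cli <- cor(lit$X[, -1])
  expect_lt(max(abs(cli[upper.tri(cli)])), 0.1)
})

test_that("a covariate matrix with no dominant eigenvalue is rejected", {
  expect_error(subpred:::eigen_averaged_coefficients(matrix(0.1)),
               class = "subpred_degenerate_gamma")
})
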