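## Synthetic stand-in for the 748-donor blood-donation table used in the
## application study. The generator is calibrated once to the public Blood
## Transfusion Service Center summary statistics; it is synthetic data, not
## the original records.

#' Emulate the 748-donor blood-donation population
#'
#' Returns a fully synthetic population of 748 blood donors with the variables
#' of the application data set: `time` (months since first donation),
#' `recency` (months since last donation), `frequency` (number of donations)
#' and the outcome `monetary` (total blood donated in c.c., 250 c.c. per
#' donation). The joint structure mirrors the real table qualitatively: the
#' outcome is an exact multiple of frequency, strongly associated with time
#' (long-standing donors have donated more) and weakly negatively associated
#' with recency (frequent donors donated recently).
#'
#' Used as the offline drop-in for the application data; analyses of the real
#' table should load it with [load_population_csv()] instead.
#'
#' @param seed integer seed; equal seeds give identical tables.
#' @param weight_mode `"total"` or `"mean"` prediction weights.
#' @return a [finite_population()] with covariate order `time`, `recency`,
#'   `frequency` and `meta$synthetic = TRUE`.
#' @export
emulate_blood_population <- function(seed = 1L, weight_mode = c("total", "mean")) {
  weight_mode <- match.arg(weight_mode)
  N <- 748L
  with_seed(seed, {
    frequency <- pmin(1L + rnbinom(N, size = 1.2, mu = 4.5), 50L)
    # donation span: at least ~2 months between donations, plus idle history
    time <- round(pmin(2 * frequency + rgamma(N, shape = 1.6, scale = 12), 98))
    time <- pmax(time, 2)
    # recency shrinks with donation frequency (active donors donated recently)
    recency_mean <- 3 + 14 / (1 + 0.25 * frequency)
    recency <- round(rgamma(N, shape = 1.3, scale = recency_mean / 1.3))
    recency <- pmin(pmax(recency, 0), time)
    monetary <- 250 * frequency
    X <- cbind(1, time, recency, frequency)
    colnames(X) <- c("(Intercept)", "time", "recency", "frequency")
    W <- if (weight_mode == "total") rep(1, N) else rep(1 / N, N)
    pop <- finite_population(monetary, X, W = W,
                             meta = list(synthetic = TRUE, seed = seed,
                                         weight_mode = weight_mode))
    pop$meta$total_true <- true_total(pop)
    pop
  })
}
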