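## Sampling design primitives and the sample-draw container.

#' Simple random sampling without replacement
#'
#' @param N population size.
#' @param n sample size, `0 < n <= N`.
#' @return sorted integer index vector of length `n`.
#' @export
draw_srswor <- function(N, n) {
  if (n < 1 || n > N)
    stop_subpred("invalid_spec", sprintf("need 0 < n <= N, got n = %d, N = %d", n, N))
  if (n == N) return(seq_len(N))
  sort(sample.int(N, n))
}

#' Split a sample into respondents and non-respondents
#'
#' @param s index set of the first-call sample.
#' @param R population response indicator (1 = respondent stratum).
#' @return list with order-stable components `s1` (respondents) and `s2`.
#' @export
split_by_response <- function(s, R) {
  if (any(s < 1L) || any(s > length(R)))
    stop_subpred("invalid_spec", "sample indices outside the population")
  list(s1 = s[R[s] == 1L], s2 = s[R[s] == 0L])
}

# sub-sample size for n2 first-call non-respondents under divisor k
subsample_size <- function(n2, k) {
  if (n2 == 0L) return(0L)
  max(1L, as.integer(half_up(n2 / k)))
}

#' Sub-sample the first-call non-respondents
#'
#' Draws an SRSWOR of size `max(1, round_half_up(n2 / k))` from the `n2`
#' non-responding sampled units (the second-call follow-up set). `k = 1`
#' returns `s2` unchanged; an empty `s2` gives an empty sub-sample.
#'
#' @param s2 indices of the first-call non-respondents in the sample.
#' @param k sub-sampling divisor, `k >= 1`.
#' @return sorted index vector, a subset of `s2`.
#' @export
subsample_nonrespondents <- function(s2, k) {
  if (k < 1) stop_subpred("invalid_spec", "k must be >= 1")
  n2 <- length(s2)
  size <- subsample_size(n2, k)
  if (size >= n2) return(s2)
  sort(sample_from(s2, size))
}

#' Construct a sample draw with its response split and sub-sample
#'
#' Records the first-call sample `s`, its split into respondents `s1` and
#' non-respondents `s2`, the second-call sub-sample `s2_prime` (drawn here via
#' [subsample_nonrespondents()] unless supplied), and the complements needed
#' by the predictors: `s_bar = U - s`, `s1_bar = U1 - s1`, and
#' `s2_prime_bar = U2 - s2_prime`.
#'
#' @param pop a [finite_population()] with `R` assigned.
#' @param s first-call sample index set.
#' @param k sub-sampling divisor.
#' @param s2_prime optional explicit sub-sample (must be a subset of `s2`).
#' @return an object of class `sample_draw`.
#' @export
sample_draw <- function(pop, s, k = 2, s2_prime = NULL) {
  if (is.null(pop$R))
    stop_subpred("invalid_spec", "population has no response stratification")
  s <- sort(unique(as.integer(s)))
  if (length(s) == 0L) stop_subpred("estimation", "empty sample")
  if (any(s < 1L) || any(s > pop$N))
    stop_subpred("invalid_spec", "sample indices outside the population")
  sp <- split_by_response(s, pop$R)
  if (is.null(s2_prime)) {
    s2_prime <- subsample_nonrespondents(sp$s2, k)
  } else {
    s2_prime <- sort(unique(as.integer(s2_prime)))
    if (!all(s2_prime %in% sp$s2))
      stop_subpred("invalid_spec", "s2_prime must be a subset of s2")
  }
  U1 <- which(pop$R == 1L)
  U2 <- which(pop$R == 0L)
  structure(list(
    s = s, s1 = sp$s1, s2 = sp$s2, s2_prime = s2_prime, k = k,
    s_bar = setdiff(seq_len(pop$N), s),
    s1_bar = setdiff(U1, sp$s1),
    s2_prime_bar = setdiff(U2, s2_prime),
    n = length(s), n1 = length(sp$s1), n2 = length(sp$s2),
    n2_prime = length(s2_prime), N = pop$N
  ), class = "sample_draw")
}

#' @export
print.sample_draw <- function(x, ...) {
  cat(sprintf("sample draw: n = %d (n1 = %d respondents, n2 = %d non-respondents)\n",
              x$n, x$n1, x$n2))
  cat(sprintf("  second-call sub-sample: n2' = %d (k = %g)\n", x$n2_prime, x$k))
  invisible(x)
}
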