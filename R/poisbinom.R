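#' Per-site detection probability under the binomial model
#'
#' Under `n_j ~ Binomial(t_j, f)` a site is detected (>= 1 mutant duplex)
#' with probability `p_j = 1 - (1 - f)^{t_j}`, computed as
#' `-expm1(t_j * log1p(-f))` for numerical stability at small `f`.
#'
#' @param t non-negative integer vector of per-site total duplex counts.
#' @param f tumor fraction in \[0, 1\].
#' @return Vector of per-site detection probabilities.
#' @export
site_detection_prob <- function(t, f) {
  if (length(f) != 1L || is.na(f) || f < 0 || f > 1) {
    stop("f must be a single value in [0, 1]", call. = FALSE)
  }
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  t <- as.numeric(t)
  if (f == 0) return(rep(0, length(t)))
  if (f == 1) return(as.numeric(t > 0))
  # t = 0 sites: 0 * -Inf never occurs since log1p(-f) is finite for f < 1
  -expm1(t * log1p(-f))
}

# Tail P(K >= k) of the Poisson-binomial distribution by truncated
# dynamic-programming convolution over sites: state vector holds
# P(K_so_far = 0..k-1) plus an absorbing >= k cell, O(S * k) time.
poisbinom_tail <- function(p, k) {
  k <- as.integer(k)
  if (k <= 0L) return(1)
  if (length(p) == 0L) return(0)
  state <- c(1, numeric(k))  # state[j] = P(K = j - 1), state[k+1] = P(K >= k)
  for (pj in p) {
    if (pj == 0) next
    shifted <- c(0, state[seq_len(k)])
    shifted[k + 1L] <- shifted[k + 1L] + state[k + 1L]
    state <- state * (1 - pj) + shifted * pj
  }
  min(max(state[k + 1L], 0), 1)
}

#' Exact detection probability of the SNV-count classifier
#'
#' Computes `P(#detected sites >= threshold)` exactly for a sample whose
#' per-site total duplex counts are `t` and whose tumor fraction is `f`.
#' Sites are independent with detection probabilities
#' `p_j = 1 - (1 - f)^{t_j}`, so the number of detected sites follows a
#' Poisson-binomial distribution; the tail is evaluated by a
#' dynamic-programming convolution over sites (no approximation).
#'
#' This is the analytic oracle that Monte-Carlo sensitivity estimates
#' (simulate mutants, classify, average) must converge to.
#'
#' @param t non-negative integer vector of per-site total duplex counts.
#' @param f tumor fraction in \[0, 1\].
#' @param threshold integer >= 0; minimum number of distinct detected SNVs.
#' @return Probability in \[0, 1\]. `threshold = 0` gives 1;
#'   `threshold > length(t)` with `f < 1` gives a value in \[0, 1) —
#'   possibly 0 — not an error.
#' @export
#' @examples
#' exact_detection_probability(t = c(10, 10, 10), f = 0.1, threshold = 2)
exact_detection_probability <- function(t, f, threshold) {
  if (length(threshold) != 1L || is.na(threshold) || threshold < 0) {
    stop("threshold must be a single integer >= 0", call. = FALSE)
  }
  p <- site_detection_prob(t, f)
  poisbinom_tail(p, threshold)
}

#' Full probability mass function of the detected-SNV count
#'
#' Exact Poisson-binomial PMF of the number of detected sites, by the full
#' (untruncated) dynamic-programming convolution. Mostly useful for plotting
#' and for validating [exact_detection_probability()] on small panels.
#'
#' @inheritParams exact_detection_probability
#' @return Numeric vector of length `length(t) + 1`; entry `k + 1` is
#'   `P(#detected sites = k)`.
#' @export
detected_snv_pmf <- function(t, f) {
  p <- site_detection_prob(t, f)
  pmf <- 1
  for (pj in p) {
    pmf <- c(pmf * (1 - pj), 0) + c(0, pmf * pj)
  }
  pmf
}
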