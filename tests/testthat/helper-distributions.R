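# Shared fixtures: small closed-form laws and random PMF generators.

# P(0) = 0.2, P(2) = 0.8: supercritical with extinction probability exactly
# 0.25 (smallest root of 0.8 q^2 - q + 0.2 = 0).
binary_fission <- function() {
  make_empirical_pmf(c(0, 2), c(1, 4), label = "binary-fission")
}

# Critical geometric P(k) = 0.5^(k+1): the classical law with the closed
# form q_n = n / (n + 1). Built with explicit weights to k = 200 so the
# truncated tail (~1e-60) is far below machine precision and the mean is
# exactly 1 in double arithmetic.
critical_geometric <- function() {
  make_empirical_pmf(0:200, 0.5^(1:201), label = "critical-geometric")
}

always_zero <- function() make_empirical_pmf(0, 1, label = "no-daughters")
always_one <- function() make_empirical_pmf(1, 1, label = "one-daughter")

# Random PMF on {0, ..., K}; optionally rescaled so the mean is at most
# `mean_below` by shifting weight onto zero.
random_pmf <- function(max_count = 6, mean_below = NULL) {
  K <- sample(1:max_count, 1)
  w <- stats::runif(K + 1)
  if (!is.null(mean_below)) {
    m <- sum((0:K) * w) / sum(w)
    if (m > mean_below) {
      # add zero-weight so the mean drops strictly below the cap
      extra <- sum(w) * (m / mean_below - 1) * 1.05
      w[1] <- w[1] + extra
    }
  }
  make_empirical_pmf(0:K, w, label = "random")
}

# Brute-force summation of E[T] = sum_{n>=0} (1 - q_n), independent of
# mean_extinction_time's tail extrapolation.
brute_force_mean_T <- function(dist, horizon = 1e5, tol = 1e-14) {
  q <- 0
  total <- 0
  for (n in 0:horizon) {
    total <- total + (1 - q)
    q <- pgf_eval(dist, q)
    if (1 - q < tol) break
  }
  total + (1 - q)
}
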