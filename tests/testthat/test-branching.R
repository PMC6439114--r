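test_that("PGF evaluation matches closed forms and respects its domain", {
  set.seed(41)
  for (i in 1:10) {
    d <- random_pmf()
    expect_equal(pgf_eval(d, 1), 1, tolerance = 1e-12)
    expect_equal(pgf_eval(d, 0), d$probabilities[d$support == 0][1])
  }
  pois <- parametric_pmf("poisson", 0.95)
  # Poisson PGF closed form exp(lambda (s - 1)); truncation error is far
  # below this tolerance
  expect_equal(pgf_eval(pois, 0.5), exp(-0.475), tolerance = 1e-9)
  expect_error(pgf_eval(pois, 1.01), class = "matriline_validation_error")
  expect_error(pgf_eval(pois, -0.1), class = "matriline_validation_error")
})

test_that("criticality classification follows the offspring mean", {
  expect_identical(classify_criticality(parametric_pmf("poisson", 0.95)),
                   "subcritical")
  expect_identical(classify_criticality(always_one()), "degenerate_unit")
  expect_identical(classify_criticality(binary_fission()), "supercritical")
  expect_identical(classify_criticality(critical_geometric()), "critical")
  expect_identical(classify_criticality(make_empirical_pmf(0:2, c(1, 2, 1))),
                   "critical")
})

test_that("extinction is certain iff the mean is at most one (excluding the unit law)", {
  set.seed(51)
  for (i in 1:25) {
    d <- random_pmf(max_count = 7, mean_below = 1)
    expect_identical(extinction_probability(d), 1)
  }
  expect_identical(extinction_probability(critical_geometric()), 1)
  expect_identical(extinction_probability(always_one()), 0)
})

test_that("supercritical extinction probability is the smallest PGF fixed point", {
  # closed form: smallest root of 0.8 q^2 - q + 0.2 = 0 via the quadratic
  # formula
  q_closed <- (1 - sqrt(1 - 4 * 0.8 * 0.2)) / (2 * 0.8)
  expect_equal(extinction_probability(binary_fission()), q_closed,
               tolerance = 1e-10)
  expect_equal(q_closed, 0.25)

  # independent root-finder oracle on random supercritical laws
  set.seed(61)
  found <- 0
  while (found < 10) {
    d <- random_pmf(max_count = 6)
    if (d$mean <= 1.05) next
    found <- found + 1
    q_impl <- extinction_probability(d)
    q_oracle <- stats::uniroot(function(s) pgf_eval(d, s) - s,
                               c(0, 1 - 1e-9), tol = 1e-14)$root
    expect_equal(q_impl, q_oracle, tolerance = 1e-8)
    expect_lt(q_impl, 1)
    # fixed-point consistency
    expect_lt(abs(pgf_eval(d, q_impl) - q_impl), 10 * 1e-12)
  }
})

test_that("extinction curve matches the critical-geometric closed form", {
  curve <- extinction_cdf(critical_geometric(), horizon = 100)
  n <- 0:100
  expect_lt(max(abs(curve$q - n / (n + 1))), 1e-12)
  expect_identical(curve$q[1], 0)
  expect_false(curve$converged)   # critical laws approach 1 only slowly
})

test_that("extinction curve matches hand iteration and stays monotone below q*", {
  expect_equal(extinction_cdf(always_zero(), horizon = 3)$q,
               c(0, 1, 1, 1))

  pois <- parametric_pmf("poisson", 0.95)
  curve <- extinction_cdf(pois, horizon = 2)
  expect_equal(curve$q[2], exp(-0.95), tolerance = 1e-9)
  expect_equal(curve$q[3], exp(0.95 * (exp(-0.95) - 1)), tolerance = 1e-9)

  set.seed(71)
  for (i in 1:15) {
    d <- random_pmf(max_count = 6)
    curve <- extinction_cdf(d, horizon = 200)
    expect_true(all(diff(curve$q) >= -1e-15))
    expect_true(all(curve$q >= 0 & curve$q <= 1))
    expect_true(all(curve$q <= curve$q_star + 1e-12))
  }

  long <- extinction_cdf(pois, horizon = 1000)
  expect_true(long$converged)
})

test_that("the supercritical curve matches its subcritical dual", {
  d <- binary_fission()
  qs <- extinction_probability(d)
  dual <- make_empirical_pmf(d$support,
                             d$probabilities * qs^(d$support - 1),
                             label = "dual")
  expect_lt(dual$mean, 1)   # the dual of a supercritical law is subcritical
  q_dual <- extinction_cdf(dual, horizon = 100)$q
  q_orig <- extinction_cdf(d, horizon = 100)$q
  expect_lt(max(abs(q_dual - q_orig / qs)), 1e-9)
})

test_that("mean extinction time matches brute-force summation for subcritical laws", {
  expect_equal(mean_extinction_time(always_zero()), 1)

  pois5 <- parametric_pmf("poisson", 0.5)
  oracle5 <- brute_force_mean_T(pois5)
  expect_equal(mean_extinction_time(pois5), oracle5, tolerance = 1e-6)
  expect_equal(oracle5, 1.74, tolerance = 0.005)   # about 1.74

  geo8 <- parametric_pmf("geometric", 0.8)
  expect_equal(mean_extinction_time(geo8), brute_force_mean_T(geo8),
               tolerance = 1e-6)

  pois95 <- parametric_pmf("poisson", 0.95)
  expect_equal(mean_extinction_time(pois95), brute_force_mean_T(pois95),
               tolerance = 1e-6)
})

test_that("mean extinction time diverges at criticality and conditions on extinction above it", {
  expect_identical(mean_extinction_time(critical_geometric()), Inf)
  expect_identical(mean_extinction_time(always_one()), Inf)

  # supercritical: mean conditioned on extinction equals the dual's mean
  d <- binary_fission()
  qs <- extinction_probability(d)
  dual <- make_empirical_pmf(d$support, d$probabilities * qs^(d$support - 1))
  expect_equal(mean_extinction_time(d), brute_force_mean_T(dual),
               tolerance = 1e-6)
})

test_that("extinction quantiles follow the smallest-n convention", {
  curve <- extinction_cdf(critical_geometric(), horizon = 10)
  expect_identical(extinction_quantile(curve, 0.8), 4L)   # q_4 = 0.8 exactly
  expect_identical(extinction_quantile(curve, 0.5), 1L)
  expect_identical(extinction_quantile(extinction_cdf(always_zero(), 2), 0.5),
                   1L)
  expect_error(extinction_quantile(curve, 0.999),
               class = "matriline_quantile_error")
  expect_error(extinction_quantile(curve, 1.5),
               class = "matriline_validation_error")
})
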