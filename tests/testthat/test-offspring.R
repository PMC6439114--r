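test_that("empirical constructor normalizes, sorts, and computes moments", {
  d <- make_empirical_pmf(0, 1)
  expect_identical(d$support, 0L)
  expect_equal(d$probabilities, 1)
  expect_equal(d$mean, 0)

  d <- make_empirical_pmf(c(2, 0), c(4, 1))   # unsorted input
  expect_identical(d$support, c(0L, 2L))
  expect_equal(d$probabilities, c(0.2, 0.8))
  expect_equal(d$mean, 1.6)
  expect_equal(d$variance, 0.64)

  d <- make_empirical_pmf(0:2, c(1, 1, 1))
  expect_equal(d$probabilities, rep(1 / 3, 3))
  expect_equal(d$mean, 1)
})

test_that("constructor rejects invalid input, naming the offender", {
  expect_error(make_empirical_pmf(integer(0), numeric(0)),
               class = "matriline_validation_error")
  expect_error(make_empirical_pmf(c(0, 1.5), c(1, 1)), "1.5",
               class = "matriline_validation_error")
  expect_error(make_empirical_pmf(c(0, -1), c(1, 1)),
               class = "matriline_validation_error")
  expect_error(make_empirical_pmf(c(0, 1, 1), c(1, 1, 1)), "duplicate count 1",
               class = "matriline_validation_error")
  expect_error(make_empirical_pmf(c(0, 2), c(1, -3)), "negative weight",
               class = "matriline_validation_error")
  expect_error(make_empirical_pmf(c(0, 2), c(0, 0)),
               class = "matriline_validation_error")
  expect_error(make_empirical_pmf(c(0, 2), 1),
               class = "matriline_validation_error")
})

test_that("every constructor yields a normalized PMF with matching moments", {
  set.seed(11)
  for (i in 1:30) {
    d <- random_pmf(max_count = 8)
    expect_lt(abs(sum(d$probabilities) - 1), 1e-9)
    mm <- moments(d)
    expect_equal(unname(mm["mean"]), d$mean, tolerance = 1e-9)
    expect_equal(unname(mm["variance"]), d$variance, tolerance = 1e-9)
  }
})

test_that("parametric families hit their closed-form masses and means", {
  pois <- parametric_pmf("poisson", mean = 0.95)
  expect_equal(pois$probabilities[1], exp(-0.95), tolerance = 1e-9)
  expect_lt(abs(pois$mean - 0.95), 1e-6)

  geo <- parametric_pmf("geometric", mean = 1)
  expect_equal(geo$probabilities[1:2], c(0.5, 0.25), tolerance = 1e-9)
  expect_lt(abs(geo$mean - 1), 1e-6)

  nb <- parametric_pmf("negative_binomial", mean = 0.95, dispersion = 2)
  expect_lt(abs(nb$mean - 0.95), 1e-6)
  # dnbinom(0) = (size/(size+mu))^size
  expect_equal(nb$probabilities[1], (2 / 2.95)^2, tolerance = 1e-9)
})

test_that("parametric truncation keeps the tail below tolerance", {
  tolv <- 1e-9
  pois <- parametric_pmf("poisson", mean = 0.95, tail_mass_tol = tolv)
  K <- max(pois$support)
  expect_lt(ppois(K, 0.95, lower.tail = FALSE), tolv)
  expect_gte(ppois(K - 1, 0.95, lower.tail = FALSE), tolv)  # K is smallest
  expect_lt(abs(sum(pois$probabilities) - 1), 1e-9)
})

test_that("parametric constructor rejects bad parameters", {
  expect_error(parametric_pmf("zeta", mean = 1),
               class = "matriline_validation_error")
  expect_error(parametric_pmf("poisson", mean = -1),
               class = "matriline_validation_error")
  expect_error(parametric_pmf("negative_binomial", mean = 1),
               "dispersion", class = "matriline_validation_error")
  expect_error(parametric_pmf("poisson", mean = 1, tail_mass_tol = 1e-3),
               class = "matriline_validation_error")
})

test_that("binomial thinning matches its closed forms and edge cases", {
  two <- make_empirical_pmf(2, 1)
  d <- thin_to_daughters(two, 0.5)
  expect_identical(d$support, 0:2)
  expect_equal(d$probabilities, c(0.25, 0.5, 0.25), tolerance = 1e-12)

  set.seed(21)
  any_pmf <- random_pmf(max_count = 5)
  expect_equal(thin_to_daughters(any_pmf, 0)$probabilities, 1)
  expect_identical(thin_to_daughters(any_pmf, 0)$support, 0L)
  ident <- thin_to_daughters(any_pmf, 1)
  expect_identical(ident$support, any_pmf$support)
  expect_equal(ident$probabilities, any_pmf$probabilities, tolerance = 1e-12)

  expect_error(thin_to_daughters(any_pmf, 1.2),
               class = "matriline_validation_error")
})

test_that("thinning is linear in the mean and matches brute-force enumeration", {
  set.seed(31)
  for (i in 1:20) {
    children <- random_pmf(max_count = 6)
    p <- stats::runif(1)
    daughters <- thin_to_daughters(children, p)
    expect_lt(abs(daughters$mean - p * children$mean), 1e-9)

    # independent oracle: explicit sum over all (c, d) pairs
    full <- numeric(max(children$support) + 1)
    for (ci in seq_along(children$support)) {
      cc <- children$support[ci]
      for (dd in 0:cc) {
        full[dd + 1] <- full[dd + 1] +
          children$probabilities[ci] * choose(cc, dd) * p^dd * (1 - p)^(cc - dd)
      }
    }
    got <- numeric(max(children$support) + 1)
    got[daughters$support + 1] <- daughters$probabilities
    expect_lt(max(abs(got - full)), 1e-12)
  }
})

test_that("synthetic census-like law hits the target mean deterministically", {
  d1 <- synth_census_like(mean_daughters = 0.95, seed = 7)
  d2 <- synth_census_like(mean_daughters = 0.95, seed = 7)
  expect_identical(d1, d2)
  expect_lt(abs(d1$mean - 0.95), 1e-6)

  d3 <- synth_census_like(mean_daughters = 0.95, seed = 8)
  expect_false(isTRUE(all.equal(d1$probabilities, d3$probabilities)))
  expect_lt(abs(d3$mean - 0.95), 1e-6)

  # a different target mean works too, and the label records parameters
  d4 <- synth_census_like(mean_daughters = 0.6, seed = 7)
  expect_lt(abs(d4$mean - 0.6), 1e-6)
  expect_match(d4$label, "synthetic-census")
  expect_match(d4$label, "seed=7")

  expect_error(synth_census_like(mean_daughters = 5, p_daughter = 0.5,
                                 max_children = 8),
               "infeasible", class = "matriline_validation_error")
})

test_that("moments recomputes mean and variance from the mass function", {
  expect_equal(moments(always_zero()), c(mean = 0, variance = 0))
  expect_equal(moments(always_one()), c(mean = 1, variance = 0))
  expect_equal(moments(binary_fission()), c(mean = 1.6, variance = 0.64))
})
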