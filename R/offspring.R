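#' Offspring (daughter-count) distributions
#'
#' An `offspring_distribution` is a probability mass function over
#' non-negative integer offspring counts. In the matrilineal setting the
#' "offspring" of a woman are her daughters, because only daughters transmit
#' mitochondrial DNA. The object stores the (strictly ascending) support, the
#' aligned probabilities, the mean number of daughters per woman `m`, the
#' offspring variance, and a free-text provenance label.
#'
#' Constructors normalize their input, drop support points carrying zero
#' probability, and guarantee that probabilities sum to one within 1e-9 and
#' that the stored moments match the stored mass function.
#'
#' @param support Vector of distinct non-negative integer offspring counts.
#' @param weights Non-negative weights aligned with `support`; they are
#'   normalized to probabilities and need not sum to one.
#' @param label Free-text provenance label, e.g. `"synthetic-census"`.
#'
#' @return An object of class `offspring_distribution` with fields
#'   `support`, `probabilities`, `mean`, `variance`, and `label`.
#'
#' @examples
#' make_empirical_pmf(c(0, 2), c(1, 4))       # mean 1.6, variance 0.64
#' make_empirical_pmf(0:2, c(1, 1, 1))        # uniform on {0,1,2}, mean 1
#' @export
make_empirical_pmf <- function(support, weights, label = "empirical") {
  if (length(support) == 0L) {
    abort_validation("'support' must be non-empty")
  }
  if (!is.numeric(support) || anyNA(support)) {
    abort_validation("'support' must be numeric with no missing values")
  }
  bad <- which(support < 0 | support != trunc(support))
  if (length(bad)) {
    abort_validation(sprintf(
      "'support' entries must be non-negative integers; offending entry %s at position %d",
      format(support[bad[1L]]), bad[1L]))
  }
  dup <- which(duplicated(support))
  if (length(dup)) {
    abort_validation(sprintf("duplicate count %d in 'support'",
                             as.integer(support[dup[1L]])))
  }
  if (length(weights) != length(support)) {
    abort_validation("'weights' must have the same length as 'support'")
  }
  if (!is.numeric(weights) || anyNA(weights)) {
    abort_validation("'weights' must be numeric with no missing values")
  }
  neg <- which(weights < 0)
  if (length(neg)) {
    abort_validation(sprintf(
      "negative weight %s for count %d", format(weights[neg[1L]]),
      as.integer(support[neg[1L]])))
  }
  if (sum(weights) <= 0) {
    abort_validation("'weights' sum to zero; at least one must be positive")
  }
  new_offspring_distribution(support, weights, label)
}

# Internal constructor: sorts, drops zero-mass points, normalizes, and
# computes moments. All public constructors funnel through here so the
# class invariants hold everywhere.
new_offspring_distribution <- function(support, weights, label) {
  keep <- weights > 0
  support <- as.integer(support[keep])
  weights <- as.numeric(weights[keep])
  o <- order(support)
  support <- support[o]
  probabilities <- weights[o] / sum(weights[o])
  m <- sum(support * probabilities)
  v <- sum(support^2 * probabilities) - m^2
  structure(
    list(support = support, probabilities = probabilities,
         mean = m, variance = max(v, 0), label = as.character(label)[1L]),
    class = "offspring_distribution")
}

#' @export
print.offspring_distribution <- function(x, ...) {
  cat("Offspring distribution:", x$label, "\n")
  cat(sprintf("  mean %.6g, variance %.6g, support {%s}\n",
              x$mean, x$variance,
              paste(x$support, collapse = ", ")))
  tab <- data.frame(count = x$support, probability = signif(x$probabilities, 6))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Parametric offspring distributions
#'
#' Builds a Poisson, negative-binomial, or geometric offspring law with a
#' given mean, truncated at the smallest count `K` whose upper tail mass
#' falls below `tail_mass_tol` and then renormalized. The geometric family
#' uses the form `P(k) = (1 - b) * b^k` with `b = mean / (1 + mean)`.
#'
#' With the default tolerance the truncation shifts the realized mean by far
#' less than 1e-6 from the requested mean.
#'
#' @param family One of `"poisson"`, `"negative_binomial"`, `"geometric"`.
#' @param mean Positive target mean (daughters per woman).
#' @param dispersion Size parameter of the negative binomial (required for
#'   that family; ignored otherwise). Smaller values give more
#'   over-dispersion.
#' @param tail_mass_tol Upper-tail probability retained beyond the truncation
#'   point, in `(0, 1e-6]`. Default `1e-9`.
#'
#' @return An [offspring_distribution][make_empirical_pmf].
#' @examples
#' parametric_pmf("poisson", mean = 0.95)   # P(0) = exp(-0.95)
#' parametric_pmf("geometric", mean = 1)    # P(k) = 0.5^(k+1)
#' @export
parametric_pmf <- function(family = c("poisson", "negative_binomial", "geometric"),
                           mean, dispersion = NULL, tail_mass_tol = 1e-9) {
  if (!is.character(family) || !all(family %in% c("poisson", "negative_binomial",
                                                  "geometric"))) {
    abort_validation(sprintf("unknown offspring family '%s'",
                             paste(family[1L], collapse = "")))
  }
  family <- match.arg(family)
  if (!is.numeric(mean) || length(mean) != 1L || is.na(mean) || mean <= 0) {
    abort_validation("'mean' must be a single positive number")
  }
  if (!is.numeric(tail_mass_tol) || length(tail_mass_tol) != 1L ||
      is.na(tail_mass_tol) || tail_mass_tol <= 0 || tail_mass_tol > 1e-6) {
    abort_validation("'tail_mass_tol' must lie in (0, 1e-6]")
  }
  if (family == "negative_binomial") {
    if (is.null(dispersion)) {
      abort_validation("'dispersion' is required for the negative binomial family")
    }
    if (!is.numeric(dispersion) || length(dispersion) != 1L ||
        is.na(dispersion) || dispersion <= 0) {
      abort_validation("'dispersion' must be a single positive number")
    }
  }
  dens <- switch(family,
    poisson = function(k) stats::dpois(k, lambda = mean),
    negative_binomial = function(k) stats::dnbinom(k, size = dispersion, mu = mean),
    geometric = function(k) stats::dgeom(k, prob = 1 / (1 + mean)))
  tail <- switch(family,
    poisson = function(k) stats::ppois(k, lambda = mean, lower.tail = FALSE),
    negative_binomial = function(k) stats::pnbinom(k, size = dispersion, mu = mean,
                                                   lower.tail = FALSE),
    geometric = function(k) stats::pgeom(k, prob = 1 / (1 + mean),
                                         lower.tail = FALSE))
  qfun <- switch(family,
    poisson = function(p) stats::qpois(p, lambda = mean),
    negative_binomial = function(p) stats::qnbinom(p, size = dispersion, mu = mean),
    geometric = function(p) stats::qgeom(p, prob = 1 / (1 + mean)))

  # smallest K with upper tail mass < tail_mass_tol
  K <- qfun(1 - tail_mass_tol)
  while (tail(K) >= tail_mass_tol) K <- K + 1L
  while (K > 0L && tail(K - 1L) < tail_mass_tol) K <- K - 1L

  lbl <- switch(family,
    poisson = sprintf("poisson(%g)", mean),
    negative_binomial = sprintf("negative_binomial(mean=%g, size=%g)",
                                mean, dispersion),
    geometric = sprintf("geometric(mean=%g)", mean))
  new_offspring_distribution(0:K, dens(0:K), lbl)
}

#' Binomial sex-ratio thinning of a children-count distribution
#'
#' Converts a distribution of completed family size (children of both sexes)
#' into a daughter-count distribution by marking each child independently as
#' female with probability `p_daughter`:
#' `P(D = d) = sum_{c >= d} P(C = c) * choose(c, d) * p^d * (1 - p)^(c - d)`.
#' The mean of the result is exactly `p_daughter` times the input mean.
#'
#' @param children An [offspring_distribution][make_empirical_pmf] of
#'   children counts.
#' @param p_daughter Probability a child is female, in `[0, 1]`. The package
#'   default elsewhere is 0.4878 (about 100 girls per 105 boys).
#'
#' @return An `offspring_distribution` of daughter counts.
#' @examples
#' two_children <- make_empirical_pmf(2, 1, label = "two-child families")
#' thin_to_daughters(two_children, 0.5)   # Binomial(2, 0.5)
#' @export
thin_to_daughters <- function(children, p_daughter) {
  stopifnot(inherits(children, "offspring_distribution"))
  if (!is_probability(p_daughter)) {
    abort_validation("'p_daughter' must be a probability in [0, 1]")
  }
  d <- 0:max(children$support)
  probs <- vapply(d, function(dd) {
    sum(children$probabilities *
          stats::dbinom(dd, size = children$support, prob = p_daughter))
  }, numeric(1))
  new_offspring_distribution(
    d, probs,
    sprintf("%s thinned(p_daughter=%g)", children$label, p_daughter))
}

#' Synthetic census-like completed-fertility distribution
#'
#' Generates a stand-in for a census/natality extract of completed fertility
#' (children ever born per woman), then thins it to daughters. The children
#' law is a zero-inflated negative binomial on `{0, ..., max_children}`:
#' completed-fertility data show excess childlessness and over-dispersion
#' relative to a Poisson law, which this family captures. The default
#' `zero_inflation` and `size` are calibrated so that, at the default target
#' mean, the children law matches published US completed-fertility margins:
#' roughly 15-17% of women childless and a children variance of about 2.2
#' (the negative binomial's own zero mass already covers most childlessness,
#' so the explicit inflation term is small). A small seeded
#' multiplicative jitter on the cell probabilities emulates the sampling
#' noise of a tabulated extract, and an exponential tilt
#' `w_k -> w_k * t^k` is then solved (monotone in `t`, via [stats::uniroot])
#' so that the thinned mean equals `mean_daughters` to within 1e-6.
#'
#' The same parameters and seed always yield the identical distribution.
#'
#' @param mean_daughters Target mean daughters per woman. Default 0.95, the
#'   2016 US value used throughout the package examples.
#' @param max_children Largest completed family size retained. Default 12.
#' @param p_daughter Probability a child is female. Default 0.4878.
#' @param zero_inflation Extra probability mass at zero children beyond the
#'   negative binomial, emulating lifetime childlessness. Default 0.02.
#' @param size Negative-binomial size (dispersion) parameter. Default 20.
#' @param jitter_sd Standard deviation of the log-normal jitter applied to
#'   the cell weights. Default 0.02; set 0 for the unjittered law.
#' @param seed Integer seed controlling the jitter.
#'
#' @return An [offspring_distribution][make_empirical_pmf] of daughter
#'   counts with mean `mean_daughters` (within 1e-6); the label records all
#'   parameters and the seed.
#' @examples
#' d <- synth_census_like(mean_daughters = 0.95, seed = 1)
#' d$mean   # 0.95
#' @export
synth_census_like <- function(mean_daughters = 0.95, max_children = 12L,
                              p_daughter = 0.4878, zero_inflation = 0.02,
                              size = 20, jitter_sd = 0.02, seed = 1L) {
  if (!is.numeric(mean_daughters) || length(mean_daughters) != 1L ||
      is.na(mean_daughters) || mean_daughters <= 0) {
    abort_validation("'mean_daughters' must be a single positive number")
  }
  if (!is_count(max_children)) {
    abort_validation("'max_children' must be a positive integer")
  }
  if (!is_probability(p_daughter) || p_daughter <= 0) {
    abort_validation("'p_daughter' must be a probability in (0, 1]")
  }
  if (!is_probability(zero_inflation) || zero_inflation >= 1) {
    abort_validation("'zero_inflation' must lie in [0, 1)")
  }
  if (!is.numeric(size) || length(size) != 1L || is.na(size) || size <= 0) {
    abort_validation("'size' must be a single positive number")
  }
  if (!is.numeric(jitter_sd) || length(jitter_sd) != 1L || is.na(jitter_sd) ||
      jitter_sd < 0) {
    abort_validation("'jitter_sd' must be non-negative")
  }
  target_children <- mean_daughters / p_daughter
  if (target_children > max_children) {
    abort_validation(sprintf(
      "mean_daughters/p_daughter = %.4g exceeds max_children = %d; the target mean is infeasible",
      target_children, as.integer(max_children)))
  }

  k <- 0:as.integer(max_children)
  mu0 <- target_children / (1 - zero_inflation)
  w <- (1 - zero_inflation) * stats::dnbinom(k, size = size, mu = mu0)
  w[1L] <- w[1L] + zero_inflation

  if (jitter_sd > 0) {
    restore <- local_seed(seed)
    on.exit(restore(), add = TRUE)
    w <- w * exp(stats::rnorm(length(w), mean = 0, sd = jitter_sd))
  }

  # exponential tilt to hit the target children mean exactly
  tilted_mean <- function(log_t) {
    wt <- w * exp(log_t * k)
    sum(k * wt) / sum(wt)
  }
  root <- stats::uniroot(function(lt) tilted_mean(lt) - target_children,
                         interval = c(-1, 1), extendInt = "yes",
                         tol = 1e-14)
  w <- w * exp(root$root * k)

  children <- new_offspring_distribution(
    k, w,
    sprintf(paste0("synthetic-census(mean_daughters=%g, p_daughter=%g, ",
                   "max_children=%d, zero_inflation=%g, size=%g, ",
                   "jitter_sd=%g, seed=%d)"),
            mean_daughters, p_daughter, as.integer(max_children),
            zero_inflation, size, jitter_sd, as.integer(seed)))
  daughters <- thin_to_daughters(children, p_daughter)
  daughters$label <- children$label
  daughters
}

#' Mean and variance of an offspring distribution
#'
#' @param dist An [offspring_distribution][make_empirical_pmf].
#' @return Named numeric vector `c(mean = , variance = )`, recomputed from
#'   the stored mass function.
#' @examples
#' moments(make_empirical_pmf(c(0, 2), c(1, 4)))   # mean 1.6, variance 0.64
#' @export
moments <- function(dist) {
  stopifnot(inherits(dist, "offspring_distribution"))
  m <- sum(dist$support * dist$probabilities)
  v <- sum(dist$support^2 * dist$probabilities) - m^2
  c(mean = m, variance = max(v, 0))
}
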