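#' Probability generating function of an offspring distribution
#'
#' Evaluates `f(s) = sum_k p_k s^k` for `s` in `[0, 1]`. The PGF is the
#' workhorse of Galton-Watson theory: its smallest fixed point on `[0, 1]`
#' is the extinction probability, and iterating it from 0 gives the
#' per-generation extinction curve.
#'
#' @param dist An [offspring_distribution][make_empirical_pmf].
#' @param s Numeric vector of evaluation points in `[0, 1]`.
#' @return `f(s)`, a probability (vectorized over `s`).
#' @examples
#' d <- parametric_pmf("poisson", 0.95)
#' pgf_eval(d, 0)     # P(X = 0)
#' pgf_eval(d, 1)     # 1
#' @export
pgf_eval <- function(dist, s) {
  stopifnot(inherits(dist, "offspring_distribution"))
  if (!is.numeric(s) || anyNA(s) || any(s < 0 | s > 1)) {
    abort_validation("'s' must lie in [0, 1]")
  }
  vapply(s, function(si) sum(dist$probabilities * si^dist$support), numeric(1))
}

#' Criticality class of a Galton-Watson offspring law
#'
#' A lineage driven by an offspring law with mean `m` dies out with
#' certainty when `m <= 1` (subcritical or critical), survives forever with
#' positive probability when `m > 1` (supercritical), and never dies in the
#' degenerate case `P(X = 1) = 1` where every woman has exactly one
#' daughter. The critical boundary is detected within 1e-12 of `m = 1`.
#'
#' @param dist An [offspring_distribution][make_empirical_pmf].
#' @return One of `"subcritical"`, `"critical"`, `"supercritical"`,
#'   `"degenerate_unit"`.
#' @examples
#' classify_criticality(parametric_pmf("poisson", 0.95))   # subcritical
#' classify_criticality(make_empirical_pmf(1, 1))          # degenerate_unit
#' @export
classify_criticality <- function(dist) {
  stopifnot(inherits(dist, "offspring_distribution"))
  if (length(dist$support) == 1L && dist$support == 1L) {
    return("degenerate_unit")
  }
  m <- dist$mean
  if (abs(m - 1) <= 1e-12) "critical"
  else if (m < 1) "subcritical"
  else "supercritical"
}

#' Eventual extinction probability of a matrilineal line
#'
#' Returns the probability `q*` that a lineage founded by a single female
#' eventually has no living members: the smallest root of `f(s) = s` on
#' `[0, 1]`. For subcritical and critical laws (mean at most one, excluding
#' the one-daughter degenerate law) extinction is certain and `q* = 1`; for
#' the degenerate law `q* = 0`. For supercritical laws the root is found by
#' iterating `s <- f(s)` from `s = 0`, which converges monotonically to the
#' smallest fixed point.
#'
#' @param dist An [offspring_distribution][make_empirical_pmf].
#' @param tol Convergence tolerance on successive iterates. Default 1e-12.
#' @param max_iter Iteration cap. Default 1e6.
#' @return The extinction probability `q*`.
#' @examples
#' extinction_probability(parametric_pmf("poisson", 0.95))      # 1
#' extinction_probability(make_empirical_pmf(c(0, 2), c(1, 4))) # 0.25
#' @export
extinction_probability <- function(dist, tol = 1e-12, max_iter = 1e6) {
  stopifnot(inherits(dist, "offspring_distribution"))
  if (!is.numeric(tol) || length(tol) != 1L || is.na(tol) || tol <= 0) {
    abort_validation("'tol' must be a single positive number")
  }
  cls <- classify_criticality(dist)
  if (cls == "degenerate_unit") return(0)
  if (cls %in% c("subcritical", "critical")) return(1)
  s <- 0
  for (i in seq_len(max_iter)) {
    s_new <- pgf_eval(dist, s)
    if (abs(s_new - s) < tol) {
      # The monotone iteration approaches the root from below and stops one
      # step short; polish to machine precision with Newton steps (safe
      # here: f'(q*) < 1 at the smallest root of a supercritical law).
      s <- s_new
      for (j in 1:5) {
        deriv <- sum(dist$probabilities * dist$support *
                       s^pmax(dist$support - 1L, 0L))
        step <- (pgf_eval(dist, s) - s) / (deriv - 1)
        s_next <- min(max(s - step, 0), 1)
        if (abs(s_next - s) < .Machine$double.eps) break
        s <- s_next
      }
      return(s)
    }
    s <- s_new
  }
  abort_convergence(
    sprintf("fixed-point iteration did not converge in %g iterations; last iterate %.15g, bracketed in [%.15g, 1]",
            max_iter, s, s),
    last_iterate = s)
}

#' Per-generation extinction curve
#'
#' Computes `q_n`, the probability that the lineage founded by one female at
#' generation 0 is extinct at or before generation `n`, by the recursion
#' `q_0 = 0`, `q_{n+1} = f(q_n)`. The sequence increases monotonically to
#' the eventual extinction probability `q*`; the extinction-generation
#' distribution is read off as `P(T = n) = q_n - q_{n-1}` and quantiles come
#' from [extinction_quantile()].
#'
#' @param dist An [offspring_distribution][make_empirical_pmf].
#' @param horizon Largest generation computed. Default 1000.
#' @param tol Tolerance used for the convergence flag (and passed to
#'   [extinction_probability()]). Default 1e-12.
#' @return An object of class `extinction_curve`: list with `q` (numeric
#'   vector of length `horizon + 1`, `q[n + 1]` holding `q_n`), `q_star`,
#'   `horizon`, `converged` (whether `|q_horizon - q*| < tol`), and
#'   `source_dist_label`. Near-critical laws that have not converged by
#'   `horizon` are reported via `converged = FALSE`, not an error.
#' @examples
#' crit_geo <- parametric_pmf("geometric", mean = 1)
#' curve <- extinction_cdf(crit_geo, horizon = 10)
#' curve$q[2:5]   # n/(n+1): 0.5, 2/3, 0.75, 0.8
#' @export
extinction_cdf <- function(dist, horizon = 1000L, tol = 1e-12) {
  stopifnot(inherits(dist, "offspring_distribution"))
  if (!is_count(horizon)) {
    abort_validation("'horizon' must be a positive integer")
  }
  horizon <- as.integer(horizon)
  q <- numeric(horizon + 1L)
  for (n in seq_len(horizon)) {
    q[n + 1L] <- pgf_eval(dist, q[n])
  }
  q_star <- extinction_probability(dist, tol = tol)
  structure(
    list(q = q, q_star = q_star, horizon = horizon,
         converged = abs(q[horizon + 1L] - q_star) < tol,
         source_dist_label = dist$label, tol = tol),
    class = "extinction_curve")
}

#' @export
print.extinction_curve <- function(x, ...) {
  cat("Extinction curve:", x$source_dist_label, "\n")
  cat(sprintf("  q* = %.6g, horizon %d, converged: %s\n",
              x$q_star, x$horizon, x$converged))
  nshow <- min(x$horizon, 10L)
  cat("  q_1..q_", nshow, ": ",
      paste(signif(x$q[2:(nshow + 1L)], 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Mean number of generations until lineage extinction
#'
#' For a subcritical law the mean extinction generation is
#' `E[T] = sum_{n >= 0} (1 - q_n)`, summed until either the survival
#' probability is negligible or the geometric decay ratio
#' `(1 - q_{n+1}) / (1 - q_n)` (which tends to the offspring mean `m`) has
#' stabilized, at which point the remaining tail is added in closed form as
#' `(1 - q_{N+1}) / (1 - r)`. Critical and degenerate-unit laws have
#' infinite expected time and return `Inf`. For a supercritical law the
#' mean is conditioned on extinction, computed on the dual subcritical
#' process with PGF `f(q* s) / q*` (offspring weights `p_k q*^(k-1)`).
#'
#' Generation convention: the founder is generation 0 and counts as one
#' individual; `T` is the first generation with zero population, so a
#' founder with no daughters has `T = 1`.
#'
#' @param dist An [offspring_distribution][make_empirical_pmf].
#' @param tol Fixed-point tolerance forwarded to
#'   [extinction_probability()]. Default 1e-12.
#' @param horizon Summation cap before the tail must have stabilized.
#'   Default 1e5.
#' @return Mean generations to extinction; `Inf` flags divergence.
#' @examples
#' mean_extinction_time(make_empirical_pmf(0, 1))        # 1
#' mean_extinction_time(parametric_pmf("poisson", 0.5))  # about 1.74
#' @export
mean_extinction_time <- function(dist, tol = 1e-12, horizon = 1e5) {
  stopifnot(inherits(dist, "offspring_distribution"))
  cls <- classify_criticality(dist)
  if (cls %in% c("critical", "degenerate_unit")) return(Inf)
  if (cls == "supercritical") {
    q_star <- extinction_probability(dist, tol = tol)
    dual <- new_offspring_distribution(
      dist$support, dist$probabilities * q_star^(dist$support - 1),
      sprintf("dual(%s)", dist$label))
    return(mean_extinction_time(dual, tol = tol, horizon = horizon))
  }
  # Survival recursion 1 - q_{n+1} = 1 - f(1 - surv_n), evaluated in
  # survival form (expm1/log1p) so tiny survival probabilities do not
  # cancel: 1 - (1 - s)^k = -expm1(k * log1p(-s)).
  survival_step <- function(s) {
    if (s > 0.1) return(1 - pgf_eval(dist, 1 - s))
    sum(dist$probabilities * (-expm1(dist$support * log1p(-s))))
  }
  total <- 0
  surv <- 1              # 1 - q_0
  r_prev <- NA_real_
  stable <- 0L
  for (n in 0:horizon) {
    total <- total + surv
    surv_next <- survival_step(surv)
    if (surv_next <= 1e-15 * max(total, 1)) {
      return(total + surv_next)
    }
    r <- surv_next / surv
    if (!is.na(r_prev) && abs(r - r_prev) < 1e-9) {
      stable <- stable + 1L
    } else {
      stable <- 0L
    }
    r_prev <- r
    if (stable >= 50L && r < 1) {
      return(total + surv_next / (1 - r))
    }
    surv <- surv_next
  }
  abort_convergence(sprintf(
    "tail decay ratio did not stabilize within horizon %g (last survival %.3g, last ratio %.12g); increase 'horizon'",
    horizon, surv, r_prev))
}

#' Generation at which the extinction curve reaches a given probability
#'
#' Returns the smallest generation `n` with `q_n >= p`: the generation by
#' which a fraction `p` of lineages has died out. This is the quantile of
#' the extinction-generation distribution under the convention that a
#' founder with no daughters is extinct at generation 1.
#'
#' @param curve An [extinction_curve][extinction_cdf].
#' @param p Probability in `(0, 1]`; must not exceed the maximum `q`
#'   attained on the curve.
#' @return Non-negative integer generation.
#' @examples
#' crit_geo <- parametric_pmf("geometric", mean = 1)
#' extinction_quantile(extinction_cdf(crit_geo, horizon = 10), 0.8)  # 4
#' @export
extinction_quantile <- function(curve, p) {
  stopifnot(inherits(curve, "extinction_curve"))
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p > 1) {
    abort_validation("'p' must be a probability in (0, 1]")
  }
  q_max <- max(curve$q)
  if (p > q_max) {
    abort_quantile(sprintf(
      "requested probability %.6g exceeds the maximum extinction probability %.6g attained by generation %d",
      p, q_max, curve$horizon), attained = q_max)
  }
  as.integer(which(curve$q >= p)[1L] - 1L)
}
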