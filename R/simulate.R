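# Monte-Carlo forward simulation of matrilineal lineages.
#
# Each replicate starts from a single female founder at generation 0; every
# generation each living individual is replaced by an independent draw from
# the daughter-count law. The recorded extinction generation T is the first
# generation with zero population (a founder with no daughters has T = 1).

# Total daughters of n mothers. Below `threshold` mothers each one is
# sampled individually; above it the sum is drawn through a single
# multinomial allocation of mothers to support points, which has exactly the
# distribution of the sum of n i.i.d. draws.
draw_offspring_total <- function(dist, n, threshold = 1e4) {
  if (n == 0) return(0)
  k <- length(dist$support)
  if (k == 1L) return(n * dist$support)
  if (n <= threshold) {
    idx <- sample.int(k, size = n, replace = TRUE, prob = dist$probabilities)
    sum(dist$support[idx])
  } else {
    counts <- stats::rmultinom(1L, size = n, prob = dist$probabilities)
    sum(dist$support * counts)
  }
}

#' Simulate the extinction generation of a single lineage
#'
#' Runs one forward replicate of the branching process using R's current
#' random-number stream (seed it with [set.seed()] or use
#' [simulate_cohort()] for a fully seeded batch).
#'
#' @param dist An [offspring_distribution][make_empirical_pmf] of daughters
#'   per woman.
#' @param max_gen Generation cap; a lineage still alive at `max_gen` is
#'   censored. Default 1e4.
#' @param overflow Population bound above which the run aborts (reachable
#'   only for supercritical laws). Default 1e9.
#' @return The extinction generation (integer in `[1, max_gen]`), or
#'   `NA_integer_` for a censored lineage.
#' @examples
#' set.seed(1)
#' simulate_extinction_generation(parametric_pmf("poisson", 0.5))
#' @export
simulate_extinction_generation <- function(dist, max_gen = 1e4, overflow = 1e9) {
  stopifnot(inherits(dist, "offspring_distribution"))
  if (!is_count(max_gen)) abort_validation("'max_gen' must be a positive integer")
  pop <- 1
  for (gen in seq_len(max_gen)) {
    pop <- draw_offspring_total(dist, pop)
    if (pop == 0) return(as.integer(gen))
    if (pop > overflow) {
      abort_validation(sprintf(
        "population %g exceeded the overflow bound %g at generation %d",
        pop, overflow, gen))
    }
  }
  NA_integer_
}

#' Simulate a cohort of independent matrilineal lineages
#'
#' Runs `n_reps` independent replicates of the branching process under a
#' fixed seed and summarizes the extinction generations. Summaries (mean,
#' standard deviation, percentiles) are computed over extinct replicates
#' only; lineages still alive at `max_gen` are reported as censored, never
#' silently dropped, and the mean is flagged unreliable when the censored
#' fraction exceeds 0.1%. Identical inputs always reproduce the identical
#' result.
#'
#' Empirical percentiles use the smallest recorded generation `g` with
#' `fraction(T <= g) >= p`, matching the analytic convention of
#' [extinction_quantile()].
#'
#' @param dist An [offspring_distribution][make_empirical_pmf].
#' @param n_reps Number of replicates.
#' @param seed Integer seed; all randomness flows through it.
#' @param max_gen Generation cap per replicate. Default 1e4.
#' @param overflow Per-replicate population bound. Default 1e9.
#' @return An object of class `simulation_result`: list with
#'   `extinction_generations` (integer vector, one entry per extinct
#'   replicate), `censored_count`, `n_reps`, `seed`, `max_gen`, `dist_label`,
#'   and `summaries` (mean, sd, p50/p90/p95, `extinct_fraction`,
#'   `mean_reliable`).
#' @examples
#' d <- parametric_pmf("poisson", 0.5)
#' simulate_cohort(d, n_reps = 1000, seed = 42)
#' @export
simulate_cohort <- function(dist, n_reps, seed, max_gen = 1e4, overflow = 1e9) {
  stopifnot(inherits(dist, "offspring_distribution"))
  if (!is_count(n_reps)) abort_validation("'n_reps' must be a positive integer")
  if (!is_count(max_gen)) abort_validation("'max_gen' must be a positive integer")
  n_reps <- as.integer(n_reps)
  max_gen <- as.integer(max_gen)
  restore <- local_seed(seed)
  on.exit(restore(), add = TRUE)

  k <- length(dist$support)
  pop <- rep(1, n_reps)          # double: populations can exceed int range
  extinct_gen <- rep(NA_integer_, n_reps)
  alive <- seq_len(n_reps)
  big_threshold <- 1e4

  for (gen in seq_len(max_gen)) {
    if (length(alive) == 0L) break
    cur <- pop[alive]
    newpop <- numeric(length(alive))
    small <- which(cur <= big_threshold)
    if (length(small)) {
      if (k == 1L) {
        newpop[small] <- cur[small] * dist$support
      } else {
        ntot <- sum(cur[small])
        idx <- sample.int(k, size = ntot, replace = TRUE,
                          prob = dist$probabilities)
        grp <- rep.int(seq_along(small), cur[small])
        newpop[small] <- as.vector(rowsum(dist$support[idx], grp))
      }
    }
    big <- which(cur > big_threshold)
    for (j in big) {
      newpop[j] <- draw_offspring_total(dist, cur[j], threshold = big_threshold)
    }
    if (any(newpop > overflow)) {
      abort_validation(sprintf(
        "population %g exceeded the overflow bound %g at generation %d",
        max(newpop), overflow, gen))
    }
    died <- newpop == 0
    extinct_gen[alive[died]] <- gen
    pop[alive] <- newpop
    alive <- alive[!died]
  }

  ext <- extinct_gen[!is.na(extinct_gen)]
  censored <- n_reps - length(ext)
  summaries <- if (length(ext)) {
    qs <- stats::quantile(ext, c(0.5, 0.9, 0.95), type = 1, names = FALSE)
    list(mean = mean(ext),
         sd = if (length(ext) > 1L) stats::sd(ext) else 0,
         p50 = as.integer(qs[1L]), p90 = as.integer(qs[2L]),
         p95 = as.integer(qs[3L]),
         extinct_fraction = length(ext) / n_reps,
         mean_reliable = censored / n_reps <= 1e-3)
  } else {
    list(mean = NA_real_, sd = NA_real_, p50 = NA_integer_,
         p90 = NA_integer_, p95 = NA_integer_, extinct_fraction = 0,
         mean_reliable = FALSE)
  }
  structure(
    list(extinction_generations = as.integer(ext), censored_count = censored,
         n_reps = n_reps, seed = as.integer(seed), max_gen = max_gen,
         summaries = summaries, dist_label = dist$label),
    class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("Lineage extinction simulation:", x$dist_label, "\n")
  cat(sprintf("  %d replicates (seed %d, cap %d generations), %d censored\n",
              x$n_reps, x$seed, x$max_gen, x$censored_count))
  s <- x$summaries
  cat(sprintf("  extinct fraction %.4g; mean T %.4g (sd %.4g)%s\n",
              s$extinct_fraction, s$mean, s$sd,
              if (isTRUE(s$mean_reliable)) "" else " [mean unreliable: censoring]"))
  cat(sprintf("  percentiles: 50%% = %s, 90%% = %s, 95%% = %s\n",
              s$p50, s$p90, s$p95))
  invisible(x)
}

#' Histogram of simulated extinction generations
#'
#' Tabulates extinct replicates by generation, one row per generation
#' `1..max_bin` plus an overflow row (`generation = NA`) for extinctions
#' beyond `max_bin`. Frequencies are relative to the number of extinct
#' replicates and sum to one.
#'
#' @param result A [simulation_result][simulate_cohort].
#' @param max_bin Largest generation given its own bin. Default 40.
#' @return A `data.frame` with columns `generation`, `count`, `frequency`.
#' @examples
#' d <- parametric_pmf("poisson", 0.5)
#' extinction_histogram(simulate_cohort(d, 1000, seed = 1), max_bin = 10)
#' @export
extinction_histogram <- function(result, max_bin = 40L) {
  stopifnot(inherits(result, "simulation_result"))
  if (!is_count(max_bin)) abort_validation("'max_bin' must be a positive integer")
  max_bin <- as.integer(max_bin)
  ext <- result$extinction_generations
  counts <- tabulate(ext[ext <= max_bin], nbins = max_bin)
  over <- sum(ext > max_bin)
  n_ext <- length(ext)
  data.frame(
    generation = c(seq_len(max_bin), NA_integer_),
    count = c(counts, over),
    frequency = if (n_ext > 0) c(counts, over) / n_ext else rep(0, max_bin + 1L))
}

#' Maximum discrepancy between simulated and analytic extinction CDFs
#'
#' Compares the empirical cumulative fraction of lineages extinct by each
#' generation (censored replicates counted as still alive) with the analytic
#' curve `q_n`, over generations up to the smaller of the curve horizon and
#' the simulation cap. Both inputs must carry the same distribution label.
#'
#' @param result A [simulation_result][simulate_cohort].
#' @param curve An [extinction_curve][extinction_cdf] for the same
#'   distribution.
#' @return The maximum absolute CDF difference, a number in `[0, 1]`.
#' @examples
#' d <- parametric_pmf("poisson", 0.5)
#' sim <- simulate_cohort(d, 5000, seed = 1)
#' compare_to_analytic(sim, extinction_cdf(d, horizon = 100))
#' @export
compare_to_analytic <- function(result, curve) {
  stopifnot(inherits(result, "simulation_result"),
            inherits(curve, "extinction_curve"))
  if (!identical(result$dist_label, curve$source_dist_label)) {
    abort_validation(sprintf(
      "distribution labels differ: simulation '%s' vs curve '%s'",
      result$dist_label, curve$source_dist_label))
  }
  nmax <- min(curve$horizon, result$max_gen)
  emp <- cumsum(tabulate(result$extinction_generations, nbins = nmax)) /
    result$n_reps
  max(abs(emp - curve$q[1L + seq_len(nmax)]))
}
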