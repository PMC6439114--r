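#' Configuration for a full lineage-extinction run
#'
#' Validates every knob of the pipeline up front and records it, so that a
#' run report echoes a fully resolved configuration and any number in it can
#' be regenerated. Exactly one distribution source must be given: a PMF TSV
#' path (`pmf`) or a list of [synth_census_like()] arguments (`synth`).
#'
#' @param pmf Path to a PMF TSV ([read_pmf_tsv()]), or `NULL`.
#' @param synth Named list of arguments for [synth_census_like()], or
#'   `NULL`. An empty list requests the defaults.
#' @param p_daughter Sex ratio used when `pmf` holds a children-count table.
#' @param n_reps Simulation replicates. Default 1e5.
#' @param seed Integer seed for the simulation.
#' @param max_gen Simulation generation cap. Default 1e4.
#' @param horizon Analytic curve horizon. Default 1000.
#' @param tol Fixed-point tolerance. Default 1e-12.
#' @param max_bin Largest histogram bin. Default 40.
#' @param out_report Optional path for the JSON report.
#' @param out_histogram Optional path for the histogram TSV.
#' @return An object of class `run_config`.
#' @export
run_config <- function(pmf = NULL, synth = NULL, p_daughter = NULL,
                       n_reps = 1e5, seed = 1L, max_gen = 1e4,
                       horizon = 1000L, tol = 1e-12, max_bin = 40L,
                       out_report = NULL, out_histogram = NULL) {
  if (is.null(pmf) == is.null(synth)) {
    abort_validation("exactly one of 'pmf' and 'synth' must be supplied")
  }
  if (!is.null(pmf) && (!is.character(pmf) || length(pmf) != 1L)) {
    abort_validation("'pmf' must be a single file path")
  }
  if (!is.null(synth) && !is.list(synth)) {
    abort_validation("'synth' must be a (possibly empty) named list of synth_census_like() arguments")
  }
  if (!is.null(p_daughter) && !is_probability(p_daughter)) {
    abort_validation("'p_daughter' must be a probability in [0, 1]")
  }
  if (!is_count(n_reps)) abort_validation("'n_reps' must be a positive integer")
  if (!is_count(max_gen)) abort_validation("'max_gen' must be a positive integer")
  if (!is_count(horizon)) abort_validation("'horizon' must be a positive integer")
  if (!is_count(max_bin)) abort_validation("'max_bin' must be a positive integer")
  if (!is.numeric(tol) || length(tol) != 1L || is.na(tol) || tol <= 0) {
    abort_validation("'tol' must be a single positive number")
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != trunc(seed)) {
    abort_validation("'seed' must be a single integer")
  }
  structure(
    list(pmf = pmf, synth = synth, p_daughter = p_daughter,
         n_reps = as.integer(n_reps), seed = as.integer(seed),
         max_gen = as.integer(max_gen), horizon = as.integer(horizon),
         tol = tol, max_bin = as.integer(max_bin),
         out_report = out_report, out_histogram = out_histogram),
    class = "run_config")
}

#' Run the full extinction-analysis pipeline
#'
#' Resolves the daughter-count distribution, runs the exact PGF analytics
#' (criticality, extinction probability, extinction curve, mean and
#' quantiles of the extinction generation) and the Monte-Carlo simulation on
#' the same distribution, cross-validates the two with
#' [compare_to_analytic()], and assembles a single self-describing report.
#' Output files are written only after every stage has succeeded, so a
#' failed run never leaves partial outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `report` (the JSON-ready report list),
#'   `histogram` (data frame), `distribution`, `curve`, and `simulation`.
#' @examples
#' cfg <- run_config(synth = list(), n_reps = 2000, seed = 7)
#' res <- run_pipeline(cfg)
#' res$report$analytic$mean_extinction_generations
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dist <- if (!is.null(config$pmf)) {
    read_pmf_tsv(config$pmf, p_daughter = config$p_daughter)
  } else {
    do.call(synth_census_like, config$synth)
  }
  criticality <- classify_criticality(dist)
  q_star <- extinction_probability(dist, tol = config$tol)
  curve <- extinction_cdf(dist, horizon = config$horizon, tol = config$tol)
  mean_t <- mean_extinction_time(dist, tol = config$tol)
  quantile_or_na <- function(p) {
    tryCatch(extinction_quantile(curve, p),
             matriline_quantile_error = function(e) NA_integer_)
  }
  analytic <- list(
    mean_extinction_generations = if (is.finite(mean_t)) mean_t else NA_real_,
    mean_divergent = !is.finite(mean_t),
    p50 = quantile_or_na(0.5), p90 = quantile_or_na(0.9),
    p95 = quantile_or_na(0.95))

  sim <- simulate_cohort(dist, n_reps = config$n_reps, seed = config$seed,
                         max_gen = config$max_gen)
  discrepancy <- compare_to_analytic(sim, curve)
  hist <- extinction_histogram(sim, max_bin = config$max_bin)

  report <- list(
    package = "matriline",
    version = as.character(utils::packageVersion("matriline")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    distribution = list(label = dist$label, support = dist$support,
                        probabilities = dist$probabilities,
                        mean = dist$mean, variance = dist$variance),
    criticality = criticality,
    q_star = q_star,
    analytic = analytic,
    simulation = c(list(n_reps = sim$n_reps, seed = sim$seed,
                        max_gen = sim$max_gen,
                        censored_count = sim$censored_count),
                   sim$summaries),
    max_cdf_discrepancy = discrepancy,
    histogram_path = config$out_histogram)

  if (!is.null(config$out_histogram)) {
    gen_col <- ifelse(is.na(hist$generation),
                      paste0(">", config$max_bin), hist$generation)
    lines <- c("generation\tcount\tfrequency",
               paste(gen_col, hist$count,
                     formatC(hist$frequency, format = "g", digits = 17),
                     sep = "\t"))
    writeLines(lines, config$out_histogram)
  }
  if (!is.null(config$out_report)) {
    jsonlite::write_json(report, config$out_report, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
  }
  invisible(list(report = report, histogram = hist, distribution = dist,
                 curve = curve, simulation = sim))
}
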