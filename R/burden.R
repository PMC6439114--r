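#' Population burden of pathogenic mtDNA carriers
#'
#' Chains the published prevalence arithmetic: starting from a total
#' population, remove the fraction in fair-to-poor health to get the healthy
#' population, apply the carrier rate for pathogenic mtDNA mutations (about
#' 1 in 200 healthy people), take the female half, and finally the fraction
#' of reproductive age. Exact (unrounded) values are always retained; a
#' reporting rule rounds them the way such figures are quoted (healthy
#' population to the nearest million, carriers to 2 significant figures,
#' female carriers and the reproductive-age stratum to 1 and 2 significant
#' figures respectively).
#'
#' With the defaults (2012 US population of 314 million, 10.3% in
#' fair-to-poor health, 1/200 carrier rate) the reported chain is 282
#' million healthy, 1.4 million carriers, 700,000 female carriers.
#'
#' @param total_population Total persons. Default 314e6.
#' @param fair_poor_fraction Fraction of all ages in fair-to-poor health.
#'   Default 0.103.
#' @param carrier_rate Pathogenic-mtDNA carriers per healthy person.
#'   Default 1/200.
#' @param female_fraction Fraction of carriers who are female. Default 0.5.
#' @param reproductive_fraction Fraction of female carriers of reproductive
#'   age. Default 1/3.
#' @return An object of class `carrier_burden`: the inputs plus `exact` and
#'   `reported` lists of `healthy`, `carriers`, `female_carriers`,
#'   `reproductive_age_female_carriers`, and the `rounding_rule` text.
#' @examples
#' estimate_burden()
#' @export
estimate_burden <- function(total_population = 314e6,
                            fair_poor_fraction = 0.103,
                            carrier_rate = 1 / 200,
                            female_fraction = 0.5,
                            reproductive_fraction = 1 / 3) {
  if (!is.numeric(total_population) || length(total_population) != 1L ||
      is.na(total_population) || total_population <= 0) {
    abort_validation("'total_population' must be a single positive number")
  }
  for (nm in c("fair_poor_fraction", "carrier_rate", "female_fraction",
               "reproductive_fraction")) {
    val <- get(nm)
    if (!is_probability(val)) {
      abort_validation(sprintf("'%s' must lie in [0, 1]; got %s",
                               nm, format(val)))
    }
  }
  healthy <- total_population * (1 - fair_poor_fraction)
  carriers <- healthy * carrier_rate
  female <- carriers * female_fraction
  reproductive <- female * reproductive_fraction
  structure(
    list(total_population = total_population,
         fair_poor_fraction = fair_poor_fraction,
         carrier_rate = carrier_rate,
         female_fraction = female_fraction,
         reproductive_fraction = reproductive_fraction,
         exact = list(healthy = healthy, carriers = carriers,
                      female_carriers = female,
                      reproductive_age_female_carriers = reproductive),
         reported = list(healthy = round(healthy / 1e6) * 1e6,
                         carriers = signif(carriers, 2),
                         female_carriers = signif(female, 1),
                         reproductive_age_female_carriers = signif(reproductive, 2)),
         rounding_rule = paste("healthy: nearest million;",
                               "carriers: 2 significant figures;",
                               "female carriers: 1 significant figure;",
                               "reproductive-age: 2 significant figures")),
    class = "carrier_burden")
}

#' @export
print.carrier_burden <- function(x, ...) {
  fmt <- function(v) formatC(v, format = "fg", big.mark = ",")
  cat("mtDNA pathogenic-carrier burden\n")
  cat(sprintf("  total population            %s\n", fmt(x$total_population)))
  cat(sprintf("  healthy (%.1f%% fair/poor)   %s  (exact %s)\n",
              100 * x$fair_poor_fraction, fmt(x$reported$healthy),
              fmt(round(x$exact$healthy))))
  cat(sprintf("  carriers (rate %.4g)       %s  (exact %s)\n",
              x$carrier_rate, fmt(x$reported$carriers),
              fmt(round(x$exact$carriers))))
  cat(sprintf("  female carriers             %s  (exact %s)\n",
              fmt(x$reported$female_carriers),
              fmt(round(x$exact$female_carriers))))
  cat(sprintf("  of reproductive age         %s  (exact %s)\n",
              fmt(x$reported$reproductive_age_female_carriers),
              fmt(round(x$exact$reproductive_age_female_carriers))))
  invisible(x)
}
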