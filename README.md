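# matriline

Galton–Watson branching-process tools for the fate of a matrilineal
mitochondrial DNA line founded by a single female — for example a donor
mtDNA line introduced by mitochondrial replacement therapy (MRT). Because
mtDNA passes only from mother to child and only daughters transmit it
further, such a line persists exactly as long as an unbroken chain of
daughters does. The package answers *how long that is expected to be*, for
researchers and analysts working on mtDNA inheritance, reproductive
medicine policy, or branching-process demography.

## The model

Each woman independently bears a random number of daughters from an
offspring law with mass function $p_k$ and mean $m$. With PGF
$f(s)=\sum_k p_k s^k$, the probability $q_n$ that the line founded by one
woman is extinct by generation $n$ satisfies

$$q_0 = 0,\qquad q_{n+1} = f(q_n) \;\uparrow\; q^\*,$$

where $q^\*$ is the smallest fixed point of $f$ on $[0,1]$. If $m \le 1$
(and the law is not the degenerate "always exactly one daughter"),
extinction is certain; if $m>1$ the line may survive forever. With the
contemporary US figure of $m = 0.95$ daughters per woman the interesting
quantities are the mean extinction generation
$E[T]=\sum_{n\ge 0}(1-q_n)$ and the quantiles of $T$ read off the curve
$q_n$ (founder = generation 0; a founder with no daughters has $T=1$).

The package provides

* offspring-law constructors: empirical (`make_empirical_pmf`,
  `read_pmf_tsv`), parametric (`parametric_pmf`), binomial sex-ratio
  thinning of children counts to daughters (`thin_to_daughters`), and a
  census-like synthetic completed-fertility generator
  (`synth_census_like`), calibrated to published US fertility margins;
* exact analytics: `pgf_eval`, `classify_criticality`,
  `extinction_probability`, `extinction_cdf`, `mean_extinction_time`,
  `extinction_quantile`;
* seeded Monte-Carlo simulation with censoring: `simulate_cohort`,
  `extinction_histogram`, `compare_to_analytic`;
* the mtDNA pathogenic-carrier population arithmetic: `estimate_burden`;
* a one-call pipeline (`run_config` + `run_pipeline`) and a thin CLI
  (`inst/cli/matriline`, subcommands `synth`, `analyze`, `simulate`,
  `burden`, `run`).

## Worked example

```r
library(matriline)

d <- synth_census_like(mean_daughters = 0.95, seed = 1)
classify_criticality(d)       # "subcritical"
extinction_probability(d)     # 1  — extinction is certain

curve <- extinction_cdf(d, horizon = 2000)
mean_extinction_time(d)       # 4.987442
extinction_quantile(curve, 0.9)   # 12

sim <- simulate_cohort(d, n_reps = 1e5, seed = 2)
sim
#> Lineage extinction simulation: synthetic-census(mean_daughters=0.95, ...)
#>   100000 replicates (seed 2, cap 10000 generations), 0 censored
#>   extinct fraction 1; mean T 5.052 (sd 8.84)
#>   percentiles: 50% = 2, 90% = 12, 95% = 20
compare_to_analytic(sim, curve)   # 0.00422952
```

A new mtDNA line under this daughter law goes extinct with certainty, after
about 5 generations on average; half of all lines are gone within 2
generations and 90% within 12. The simulated cohort reproduces the analytic
extinction curve to within ~0.4% at every generation.

The carrier arithmetic:

```r
estimate_burden()
#> mtDNA pathogenic-carrier burden
#>   total population            314,000,000
#>   healthy (10.3% fair/poor)   282,000,000  (exact 281,658,000)
#>   carriers (rate 0.005)       1,400,000  (exact 1,408,290)
#>   female carriers             700,000  (exact 704,145)
#>   of reproductive age         230,000  (exact 234,715)
```

See `vignettes/lineage-extinction.Rmd` for the model assumptions, the
synthetic-census calibration, and the numerical choices.

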