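# cavitrace

Estimating xylem cavitation resistance from the rate of acoustic
emissions.

## The problem

When the water column in a xylem conduit breaks under drought tension
(cavitation), the abrupt relaxation releases an ultrasonic click — an
acoustic emission (AE). Counting AE hits during the dehydration of a cut
branch is a noninvasive way to watch embolism form, but cumulative AE
counts keep rising long after the xylem is hydraulically dead, because
fibres, rays and shrinking wood also emit. That late-stage signal makes
it hard to translate cumulative counts into the standard hydraulic
vulnerability parameters.

`cavitrace` implements a rate-based alternative: instead of cumulative
counts, it tracks **acoustic activity** — hits per minute, averaged over
a 15-min sliding window at 1-min steps — smooths it with a
Savitzky–Golay filter (order 5, window 7), finds the activity peak, and
linearly interpolates the xylem water potential at that moment. The
result, **P_maxrate** (MPa), marks the water potential at which most
cavitation happens per unit time, and tracks the classical hydraulic
**P50** (the Ψ at 50% loss of conductivity) across species. Late-stage
noise arrives after the peak and simply does not matter.

The package provides, for users working on plant hydraulics:

- readers/writers for AE hit logs, water-potential series, PLC tables
  and species summary tables (`read_hits`, `read_psi`,
  `read_vuln_table`, `read_species_summary`);
- the AE-rate pipeline (`filter_hits`, `compute_rate_series`,
  `smooth_rates`, `find_max_rate_time`, `interpolate_psi`, composed by
  `estimate_pmaxrate`);
- reparameterized Weibull vulnerability-curve fitting with percentile
  bootstrap or normal-theory CIs (`weibull_plc`, `fit_vulnerability`,
  `bootstrap_ci`, `mean_ci`, `aggregate_fits`, `psi_at_plc`);
- the cross-method regression of P_maxrate on P50 with influence
  diagnostics (`compare_methods`, `sensitivity_refit`,
  `summarize_table`);
- a dehydration simulator with known ground truth
  (`simulate_dehydration`, `simulate_hydraulic_dataset`,
  `simulate_species_panel`);
- a command-line interface (`cavitrace_main`, `run_pipeline`; launcher
  script in `inst/exec/cavitrace`).

## The models

**Vulnerability curve.** Percent loss of conductivity follows the
Weibull curve in tension magnitude P = |Ψ|, reparameterized by Px (the
tension at x% loss) and Sx (the slope there, % MPa⁻¹):

    relK(P) = (1 − x/100)^((P/Px)^((Px·Sx)/V)),   V = (x − 100)·ln(1 − x/100)
    PLC(P)  = 100·(1 − relK(P))

so PLC(Px) = x and dPLC/dP|Px = Sx exactly. P50 is the curve's
inflection point.

**AE-rate estimate.** Scaled to [0, 1], the PLC curve is the CDF of the
per-conduit cavitation-threshold distribution. Under a steady Ψ decline
the AE rate is proportional to the threshold density along the
trajectory, so the activity peak falls at the density's mode — near the
steepest part of the vulnerability curve, i.e. near P50.

## Worked example

```r
library(cavitrace)

# a simulated dehydration with known ground truth
sim <- simulate_dehydration(sim_config(seed = 42))
sim$truth$threshold_mode_mpa
#> [1] -3.460862

res <- estimate_pmaxrate(sim$ae, sim$psi)
res
#> Pmaxrate estimate for 'simulated'
#>   Pmaxrate: -3.40 MPa (QC passed)
#>   peak activity: 6.91 hits/min at t = 512 min (4456 hits used)

# the published 18-species comparison shipped with the package
summ <- read_species_summary(system.file("extdata",
        "species_summary.csv", package = "cavitrace"))
compare_methods(summ)
#> Pmaxrate ~ P50 regression (tension magnitudes, n = 18)
#>   slope      1.195  (SE 0.170, p = 2.9e-06)
#>   intercept -0.116  (SE 0.651, p = 0.86)
#>   R-squared  0.755
```

The simulated branch's activity peak lands 0.06 MPa from the analytic
mode of its cavitation-threshold distribution, and across the 18-species
table the acoustic estimate tracks the hydraulic one nearly 1:1
(slope 1.195) with R² = 0.755.

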