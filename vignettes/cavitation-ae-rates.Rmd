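---
title: "Rate-based acoustic estimation of xylem cavitation resistance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rate-based acoustic estimation of xylem cavitation resistance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cavitrace)
```

## The method and its assumptions

A dehydrating branch emits ultrasonic acoustic emissions (AE) as its
xylem conduits cavitate. The classical acoustic approach accumulates
hit counts against water potential (Ψ) and reads vulnerability
parameters off the cumulative curve; its chronic problem is that AE
does not stop when the xylem is fully embolized — fibres, ray cells and
shrinkage microfractures keep emitting at late stages, inflating the
count-based parameters.

`cavitrace` works in the time domain instead. Acoustic activity is the
hit rate (hits min⁻¹) in a 15-min window slid at 1-min increments; the
activity curve is smoothed with a Savitzky–Golay filter and the Ψ at
the global activity peak — interpolated linearly between the bracketing
pressure-chamber readings — is reported as P~maxrate~. The underlying
assumptions are:

1. **One hit per cavitation event.** Each conduit contributes a single
   AE when it cavitates. Under this assumption the per-conduit
   threshold distribution has the vulnerability curve (PLC/100) as its
   CDF, and the AE rate traces the threshold *density* along the
   drying trajectory.
2. **Approximately steady Ψ decline.** With a roughly constant drying
   rate, the time of maximum activity maps to the mode of the threshold
   density in Ψ — near the inflection point (P50) of the S-shaped
   vulnerability curve. When the Ψ trajectory is strongly nonlinear,
   a rate peak can reflect a change of drying pace instead;
   `estimate_pmaxrate()` warns when the Ψ series is far from linear in
   time (linear R² < 0.8) but applies no correction.
3. **Late noise arrives late.** Non-cavitation AE concentrates beyond
   the physiologically relevant Ψ range, after the cavitation peak, so
   a global-maximum search with an earliest-time tie rule is
   insensitive to it.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_amplitude_db` | 45 | dB | conventional analysis threshold for cavitation-related AE with 150 kHz resonant sensors; hits at the threshold are kept (≥) |
| `window_min` | 15 | min | activity averaging window; long enough to tame Poisson counting noise, short against the peak width |
| `sg_order`, `sg_window` | 5, 7 | – | Savitzky–Golay polynomial order and window; 7 is the conventional minimal window for order 5 |
| `qc_tol_mpa` | 0.3 | MPa | interpolation quality flag: the interpolated Ψ must sit within this distance of the nearest measured reading |

The window is **centered** on each grid time and truncated at the
recording boundaries, dividing by the actual width so units stay
hits min⁻¹ everywhere. A centered window pairs naturally with the
symmetric smoothing filter and introduces no systematic lag in the
peak time; windows are half-open (`[lo, hi)`), so a hit on a window
edge is counted exactly once per covering window and total counts are
conserved. Smoothing is applied to the 15-min-averaged series, not the
raw 1-min counts. Negative smoothed values (possible near sharp
features of a polynomial fit) are floored at zero with a logged count.

Ties at the maximum break toward the **earliest** time, because late
activity is the documented artifact regime. Ψ is never extrapolated:
a peak outside the span of the Ψ readings is an error, not a guess. A
failed 0.3-MPa QC check flags the result rather than rejecting it —
the flag marks Ψ sampling too sparse around the peak, and the decision
is left to the user.

## Vulnerability curves and confidence intervals

The Weibull vulnerability curve is parameterized by Px and Sx (the Ψ at
x% loss and the slope there), with the classic scale/shape pair (b, c)
available through `weibull_to_classic()`; the two forms are exactly
interconvertible. Fitting is unweighted nonlinear least squares on PLC
against Ψ (Levenberg–Marquardt), with data-driven starting values: Px
from the measurement whose PLC is nearest x, Sx from a local linear
fit around it. PLC values outside [0, 100] — possible with noisy flow
ratios — are clipped on input with a warning, since the bounded model
cannot chase them.

Two CI workflows mirror the two measurement designs:

- **Pooled data** (destructive benchtop drying, one point per sample):
  case-resampling percentile bootstrap, default 999 replicates;
  non-converged replicates are dropped and counted, with a warning
  above 10%. Percentile intervals are the minimal-assumption choice
  for a nonlinear fit.
- **Per-sample curves** (centrifuge technique): fit each sample, then
  average Px across samples with a normal-theory CI
  (mean ± 1.96·SE). No CI is reported below n = 3, where SE is not
  meaningfully estimable.

## The cross-method regression

`compare_methods()` regresses |P~maxrate~| on |P50| in tension
magnitudes across species, by ordinary least squares with hat-value
leverages, Cook's distances and a 95% confidence band. Two choices
deserve explanation:

- **Orientation.** The acoustic estimate is the response and the
  hydraulic reference the predictor: the question the regression
  answers is how well the acoustic method predicts the reference.
- **Magnitude space.** The slope and R² are identical whether the fit
  uses signed Ψ or tension magnitudes; only the intercept flips sign.
  The magnitude-space intercept is reported as `intercept`, its signed
  counterpart as `intercept_signed`, so either convention can be read
  off directly.

`sensitivity_refit()` repeats the fit without the most influential
observation (highest leverage or Cook's distance) or without species
with fewer than three acoustic samples, reporting coefficient deltas.

## The simulator

`simulate_dehydration()` emulates one benchtop-drying AE experiment:

- **Cavitation source.** Each of `n_conduits` draws a tension
  threshold by inverse-CDF sampling from the generating vulnerability
  curve and emits exactly one hit when the trajectory first crosses
  it. No re-emission.
- **Trajectory.** Exponential plateau
  Ψ(t) = Ψ_min + (Ψ₀ − Ψ_min)·e^(−t/τ) by default, because benchtop
  drying decelerates as the branch equilibrates; a linear constant-rate
  override supports analytic checks, where the activity peak must land
  on the closed-form mode of the Weibull threshold density,
  b·((c−1)/c)^(1/c).
- **Noise source.** Late-stage AE is an inhomogeneous Poisson process
  with intensity rate_max·logistic((Ψ_onset − Ψ(t))/width), simulated
  by thinning. This captures the phenomenology (noise switching on
  beyond the physiological range) without claiming a mechanism; the
  parameters are configuration, not constants, and their defaults are
  plausibility choices.
- **Amplitudes.** Truncated-normal in [35, 99] dB. Amplitude carries no
  information in this analysis beyond the 45-dB filter; the model
  exists to exercise the filtering stage. Amplitudes are drawn per
  source, immediately after that source's event times, so the
  cavitation component of a seeded run is bit-identical whether or not
  the noise source is enabled.
- **Ψ sampling.** Readings at a fixed interval (default 30 min) with
  Gaussian reading noise (default 0.05 MPa), always including the
  recording end time.

Defaults describe a mid-range temperate angiosperm: P50 = −3.5 MPa,
S50 = 30 % MPa⁻¹ (the species-mean scale of the comparison table),
5000 conduits, drying from −0.3 toward −9 MPa with τ = 1200 min
(about a day to pass the vulnerable range), late noise at 2 hits min⁻¹
with onset −6.5 MPa. The linear-trajectory rate default,
0.005 MPa min⁻¹, covers the same range on a similar timescale.

**What the simulator does not emulate:** acoustic propagation and
attenuation in the heterogeneous wood medium, sensor-coupling
variability, temperature effects, nanobubble-related emissions, and
conduit-size heterogeneity in hit amplitude or hydraulic weight.
Passing the recovery tests therefore shows that the estimator chain is
correct for the stated generative model — not that a real branch's
P~maxrate~ equals its P50; on real data the two differ by
species-dependent offsets, which is exactly why the cross-method
regression exists.

## Numerical choices and degenerate inputs

- Time is stored in seconds internally; the 1-min analysis grid is
  built downstream. Canonical Ψ is signed (negative MPa) at every API
  boundary, with `tension_magnitude()` as the documented
  magnitude view; the Weibull math runs on magnitudes internally.
- `fit_vulnerability()` refuses fewer than 4 points and warns when the
  data do not bracket the target loss fraction (Px then extrapolates).
- An all-zero smoothed activity series is an error ("no acoustic
  activity"), as is a recording shorter than the averaging window.
- Bootstrap replicates that fail to converge are dropped, never
  imputed.
- All stochastic components are reproducible bit-exactly under a fixed
  seed.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle:
brute-force interval counting for the sliding-window rates, the
convolution form of the Savitzky–Golay kernel for smoothing,
`approx()` for Ψ interpolation, explicit hat-matrix algebra and
leave-one-out refits for the influence diagnostics, and closed-form
threshold-density modes for end-to-end recovery. Recovery simulations
use 20–50 seeded runs of 20 000 cavitation events each; bootstrap
coverage uses 200 simulated datasets with 199 replicates (nominal
95% coverage, checked within ±4 points).

## Known limitations

- **Peak localization on flat densities.** Near its mode the Weibull
  threshold density is flat, so the argmax of the smoothed activity
  curve carries irreducible per-run scatter even with tens of
  thousands of hits; recovery of the mode is unbiased, and the
  validation criteria are therefore stated on errors averaged across
  seeded runs. Species with steeper vulnerability curves (larger Sx)
  localize better; shallow curves localize worse.
- **Nonsteady drying.** The method assumes the Ψ decline is roughly
  constant; the package warns but does not correct when it is not.
- **No absolute calibration.** P~maxrate~ estimates P50 up to a
  species-dependent offset (more negative than P50 in most
  angiosperms, less negative in conifers in the shipped table);
  precise comparisons between species of similar vulnerability still
  need hydraulic measurements.
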