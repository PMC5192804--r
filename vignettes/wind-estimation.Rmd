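---
title: "Estimating wind from thermalling flight: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating wind from thermalling flight: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermalwind)
```

## The estimation problem

A bird circling in a thermal moves, relative to the air, in nearly closed
loops at a nearly constant airspeed. A horizontal wind adds a constant
vector to every ground-velocity sample, so the observed ground speed of a
circling bird oscillates with its heading: faster downwind, slower upwind.
`thermalwind` inverts this: the wind vector is the value which, subtracted
from every observed ground-velocity vector, makes the remaining scalar
airspeeds as close to constant as the data allow.

"As close to constant as the data allow" is made precise by a stationary
AR(1) model for the scalar airspeed along the compensated track,

$$a_i = (1-\varphi)\,a + \varphi\,a_{i-1} + N(\sigma^2), \qquad
  \operatorname{var}(a_i) = \frac{\sigma^2}{1-\varphi^2},$$

which captures the bird being pushed off its preferred airspeed by
small-scale turbulence and gradually returning to it. Given a candidate
wind $w$ and the autocorrelation $\varphi$, the airspeeds
$\tilde a_i = \lVert g_i' - w\rVert$ have a closed-form maximum-likelihood
mean

$$\hat a = \frac{\tilde a_1 + (1-\varphi)\sum_{i=2}^{n-1}\tilde a_i
           + \tilde a_n}{2 + (n-2)(1-\varphi)},$$

and the Bessel-corrected residual variance around the AR(1) prediction,
$s^2(G, w)$, is the quantity minimised over $w$ (`estimate_wind()`). The
error covariance is the inverse Hessian of the profile negative log
likelihood, $\Sigma = [\,n/(2\hat\sigma^2)\, \partial^2 s^2/\partial w^2
\,]^{-1}$, with the Hessian computed by symmetric central differences.

### Assumptions, and what breaks them

* **Locally constant wind** over the ~18 s window. Vertical shear within a
  window maps into extra residual variance and a slightly inflated
  $\hat\sigma^2$.
* **Sustained turning.** The wind component along the flight direction is
  only identified by heading change; straight flight leaves it
  unidentified. The estimator flags this (`cov_valid = FALSE`) when the
  Hessian is not positive definite, and event detection only accepts
  windows turning by more than 180° on each side of the window centre.
* **Random airspeed variation.** Behaviourally driven airspeed modulation
  locked to the heading (faster upwind than downwind, say) is
  indistinguishable from wind: a sinusoidal modulation of amplitude $a_c$
  biases the wind estimate by about $a_c/2$ along the modulation axis. The
  simulator can inject exactly this term (`modulation_amp`), and the test
  suite confirms the $a_c/2$ bias law; the heading-occupancy histogram
  (`heading_wind_histogram()`) is the corresponding diagnostic on data.
* **GPS error absorbed into the innovation variance.** Velocity
  measurement error $\sigma_g$ enters the compensated airspeed as an
  *independent additive* term, so the compensated series is strictly an
  ARMA(1,1), not an AR(1); the package follows the model's absorption of
  $\sigma_g$ into $\sigma^2$ and treats the mismatch as a model
  approximation. Consequences are quantified below.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `window_length` | 19 fixes (18 s at 1 Hz) | — | upper tail of observed time per circle (~16.3 s) plus a margin, so a window covers at least one full circle |
| `phi` | `"estimate"` | — | two-pass: detect with 0, profile the summed likelihood, re-detect |
| `max_sd` (quality) | 1.0 | m/s | events with residual airspeed sd above this are poor fits; threshold applied to $\sqrt{\hat\sigma^2}$ |
| `optimizer` | Nelder–Mead, abstol 1e-14 on the $s^2$ spread, one restart, 1000 iterations | — | the restart polishes the simplex collapse; 1e-14 keeps noiseless recovery at ~1e-7 m/s |
| `hessian.step` | 1e-3 | m/s | central differences; $s^2$ is smooth at this scale |
| aerodynamics | $C_{D,ni}$ 0.033, $K$ 0.81, $S$ 0.57 m², $A_R$ 7.21, $m$ 3.63 kg, $\rho$ 1.15 kg/m³, $g$ 9.81 m/s² | | default soaring-stork parameters; overridable via `stork_params()` |

Sign conventions: x east, y north; headings are compass degrees at I/O and
mathematical radians internally; turn angles positive counterclockwise.
Sink rate $a_z$ is positive downward; thermal strength is
$w_z = g_z + a_z$ (observed climb plus sink relative to the air), positive
upward. The verbal phrasing "subtracting the sink from the climb" in
common use is ambiguous about the sign of the climb term; this package
fixes $w_z = g_z + a_z$ and documents it here prominently.

## The synthetic-data generator

`simulate_track()` forward-simulates exactly the assumed generative
process: heading advancing at a constant angular rate, stationary AR(1)
airspeed (with optional deterministic heading-locked modulation), constant
horizontal wind, circular bivariate normal GPS velocity error, and linear
climb. Defaults are the observed median conditions for thermalling white
storks: airspeed 9.37 m/s, time per circle 13.65 s (radius ≈ 20 m),
airspeed-noise sd 0.46 m/s with $\varphi = 0.47$, GPS velocity error sd
0.3 m/s, climb 0.92 m/s, drift ≈ 2.2 m/s, 1 Hz bursts. Positions integrate
the *observed* velocities, so position differences and the Doppler
speed/heading columns agree exactly and both carry the modelled error
(an optional independent position-noise mode exists, off by default).
`simulate_pair()` adds co-circling pairs sharing a wind (plus optional
per-bird turbulence $\sigma_T$), and `simulate_thermal_column()` a flock
climbing through a height-structured wind/updraft profile.
`sample_airspeed_sd()` draws per-event airspeed variability from a
lognormal matched to the observed quantiles (0.26/0.46/0.84 m/s at
5/50/95%), because populations of real circling events are heterogeneous —
several calibration analyses are only meaningful under that heterogeneity.

What the generator does *not* emulate: spatially structured turbulence,
wind shear within a window, behavioural adaptation (except the sinusoidal
modulation term), GPS position error with receiver-filter autocorrelation,
or fix dropouts. Passing tests on simulated data therefore demonstrate
correctness of the estimator under its own assumptions and its documented
robustness margins — not performance on any particular field dataset.

## Numerical choices and degenerate inputs

* Optimiser initialisation is the mean ground velocity of the window (the
  drift of the circle), which is close to the optimum and avoids the
  degenerate basin around zero airspeed.
* $\hat\sigma^2 = 0$ (noiseless input) would put a zero in the covariance
  scaling; the covariance is then reported as the zero matrix with
  `degenerate = TRUE`.
* Hessian positive definiteness is checked via eigenvalues (relative
  threshold 1e-10); failures mark the covariance invalid but keep the
  point estimate.
* The $\varphi$ profile is maximised by golden-section search on
  [0, 0.99] (tolerance 1e-3) with per-segment warm starts; the tabulated
  profile is returned alongside.
* A zero turn angle fails the same-sign circling test (strict), and the
  climb criterion is a strict inequality.
* Overlap removal is greedy earliest-first; all binning (raster cells,
  time bins, radius groups, angular bins) uses half-open intervals
  [lo, hi).
* Median (τ = 0.5) regressions are computed by iteratively reweighted
  least squares with bootstrap standard errors.
* Chord-versus-arc correction for position-derived speeds is **not**
  applied; at $\omega \approx 0.46$ rad/s and 1 Hz the chord factor
  $2\sin(\omega\Delta t/2)/(\omega\Delta t)$ shortens speeds by ≈ 0.9%,
  which is documented rather than corrected, keeping position-mode and
  Doppler-mode estimates comparable.

## Findings from the package's own validation

Numbers below are computed by the test suite at fixed seeds.

* **Exact recovery.** On a noiseless drifting circle the wind is recovered
  to ~1e-7 m/s with $\hat\sigma^2$ at machine-noise level.
* **Calibration.** Over 1,000 19-fix windows at the default noise scales,
  nominal 95% ellipses from the Hessian covariance cover the true wind
  ~94% of the time; pairwise partial deviances from 2,000 simulated
  opposite-direction pairs give an observed-vs-predicted variance slope
  statistically indistinguishable from 1 with intercept near 0.
* **$\sigma^2$ accuracy.** With GPS noise off the residual variance is
  unbiased for $\sigma_a^2$ within ~5% at n = 100. With GPS noise on, the
  innovation variance of the compensated series is
  $\sigma_a^2 + \sigma_g^2(1+\varphi^2)$ (the ARMA effect), slightly above
  the absorbed $\sigma^2 \equiv \sigma_a^2 + \sigma_g^2(1-\varphi^2)$;
  coverage is nevertheless maintained because the covariance scales with
  the *fitted* residual variance.
* **$\varphi$ attenuation.** The profile-likelihood estimate of $\varphi$
  from 19-fix windows is strongly attenuated: fitting the wind removes the
  once-per-circle Fourier component of the airspeed series — precisely
  where an AR(1) concentrates its spectral power — and GPS noise dilutes
  the lag-1 autocorrelation further. On data generated with
  $\varphi = 0.47$ the profile peaks near 0.05–0.15 (it grows toward the
  generative value as windows lengthen). The profile still correctly
  exceeds its $\varphi = 0$ value whenever the data are autocorrelated,
  and white-noise airspeeds yield $\hat\varphi \approx 0$, so the
  two-pass detection remains sound; but $\hat\varphi$ from short windows
  should be read as a lower bound on the airspeed autocorrelation, not an
  unbiased estimate.
* **Bias law.** A heading-locked sinusoidal airspeed modulation of
  amplitude 1 m/s biases the mean wind estimate by ≈ 0.5 m/s against the
  designated direction, matching the integral-average prediction.
* **Detection.** On bursts alternating circling and straight glides at
  default noise, window-level sensitivity and precision are ≥ 0.9.

Problem sizes in the suite (1,000 coverage replicates, 500 bias
replicates, 200 windows for the $\varphi$ profile, 2,000 calibration
pairs, 12-bird thermal columns) were chosen to pin each stochastic check
well inside its tolerance at a fixed seed.

## Known limitations

* The wind is assumed constant per window; no within-window shear model.
* $\hat\varphi$ attenuation at short windows (above).
* The error covariance is a plug-in (Hessian at the optimum with fitted
  $\hat\sigma^2$); occasional windows with underestimated
  $\hat\sigma^2$ produce overconfident ellipses, visible as heavy tails
  beyond the 95% contour. The quality filter removes the worst fits but
  is one-sided.
* Aerodynamic quantities inherit the fixed default parameters; they are
  species- and posture-dependent and should be overridden for other taxa.
* Heights are used only through differences; no geoid/DEM handling.
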