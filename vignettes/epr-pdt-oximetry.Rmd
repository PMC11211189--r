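---
title: "EPR oximetry after photodynamic therapy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EPR oximetry after photodynamic therapy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eproximetry)
```

This vignette documents the models behind `eproximetry`, the assumptions
they rest on, and the numerical and design choices made where more than
one sound option existed. It is the companion to the function reference:
the reference says *what* each function computes, this document says *why
it computes it that way*.

## The measurement model

### Lineshape

A particulate oxygen probe such as lithium phthalocyanine has, to a good
approximation in the physiological range, a single Lorentzian EPR
absorption line

$$L(B) = \frac{A\,\Gamma^2}{(B - B_0)^2 + \Gamma^2},$$

whose half-width at half-maximum $\Gamma$ grows linearly with the oxygen
partial pressure at the crystal. Continuous-wave spectrometers record the
first derivative $dL/dB$, whose two lobes peak at $B_0 \mp \Gamma/\sqrt3$;
the measured quantity is their separation, the peak-to-peak linewidth
$\Delta B_{pp} = 2\Gamma/\sqrt3$.

The package models the line as a *pure* Lorentzian derivative. Field
modulation and microwave power broaden real lines, but a calibration
measured on the same instrument with the same settings absorbs those
instrumental contributions into its slope and intercept, so modelling them
separately would add parameters without adding accuracy. Hyperfine
structure, saturation and multi-line spectra are out of scope.
`simulate_spectrum()` defaults mirror a typical S-band acquisition: a 5 Gs
(5000 mG) sweep sampled at 1024 field points, with i.i.d. Gaussian noise.
An optional linear baseline term can be co-fitted
(`fit_linewidth_least_squares(..., baseline = TRUE)`); it is off by
default because simulated and baseline-corrected spectra have none.

### Linewidth estimation

Two estimators are provided, deliberately independent of each other:

* **Extrema** (`estimate_pp_width_extrema()`): locate the raw maximum and
  minimum, then refine each by a local cubic least-squares fit over a
  window of ±30% of the lobe separation. A plain 3-point quadratic through
  the bracketing samples is exact in the noiseless limit but fragile on
  this grid: at the default resolution a line of 50–150 mG spans only
  20–60 points, and per-point noise of 1% of the lobe height moves the raw
  argmax several grid steps, giving errors of several percent. A *wide*
  symmetric quadratic window is no better, because the Lorentzian
  derivative lobe is asymmetric (it falls more slowly on the outside) and
  the parabola's vertex is biased outward by several percent. The local
  cubic keeps the wide window's noise averaging while its third-order term
  absorbs the asymmetry; its noiseless bias is below 0.5% and it degrades
  gracefully with noise. For lines only a few grid points wide the window
  collapses and the 3-point quadratic is used as the fallback.
* **Least squares** (`fit_linewidth_least_squares()`): Levenberg–Marquardt
  fit of the analytic derivative lineshape, started from the extrema
  estimate ($B_0$ from the lobe midpoint, $\Gamma$ from the extrema width,
  $A$ from the lobe height) with $\Gamma$ bounded in $(0,\,\mathrm{span}/2]$.
  The model functions carry analytic gradients built with `deriv()`;
  numeric differentiation fails when a start value — typically the center
  of a symmetric spectrum — is exactly zero. Non-convergence raises a
  fit-failure condition that carries the extrema estimate as a fallback,
  so a pipeline can degrade rather than die.

A spectrum qualifies as having a resonance only if its maximum precedes
its minimum, both are interior and of opposite sign, and the peak-to-peak
excursion exceeds ten times the noise level estimated from first
differences (the median absolute successive difference divided by
$\sqrt2$, which a smooth signal barely inflates). Pure noise, flat,
monotone and inverted inputs all fail this gate with a no-resonance error
rather than returning a number.

### Calibration

Linewidth and pO₂ are related linearly,
$\Delta B_{pp} = \text{intercept} + \text{slope} \cdot \mathrm{pO_2}$,
with the built-in LiPc line at 5.79 mG/mmHg and a 47.25 mG anoxic
intercept (standard errors 0.42 and 5.25). The default line is the
*printed regression coefficients* of the probe batch's gas-mixture
calibration, not digitized calibration points. `fit_calibration()` refits
a line from `(pO₂, linewidth)` points by OLS of linewidth on pO₂ — the
gas-mixture design sets oxygen and measures linewidth, so that is the
correct regression direction.

Conversion back to pO₂ clamps linewidths up to 3 mG below the intercept to
0 mmHg: at near-zero oxygen, estimation noise routinely lands a fitted
width slightly below the anoxic value, and treating those as anoxic is the
physically sensible reading. Widths further below the intercept indicate a
bad fit or the wrong probe and raise an error instead. Calibration
uncertainty is carried on the line object (standard errors) but not
propagated into per-measurement pO₂ error bars; the calibration
temperature is likewise taken as matching the in vivo measurement, as the
conversion is applied in the source setting.

## Tumor response

Caliper volumetry uses the ellipsoid formula $V = (\pi/6)\,abc$ over three
perpendicular diameters in mm. Two derived endpoints:

* **Response**: percent volume change from the irradiation day to day 5,
  with responders defined by $\Delta V(5\,\mathrm{d}) < 100\%$, strictly —
  the boundary case is a non-responder, as the rule is printed with a
  strict inequality. Day 5 is the earliest day at which treatment-induced
  swelling no longer confounds caliper volumes, which is why no
  swelling correction is attempted earlier. If day 0 or 5 was not
  measured, the nearest measurement within ±1 day is used, else log-linear
  interpolation between flanking visits — measurement schedules are not
  guaranteed daily.
* **Time to progression**: first day the volume reaches 400 mm³ (about
  30% of the maximal burden an animal may carry). Between visits the
  crossing is located by linear interpolation of *log*-volume: tumor
  growth is multiplicative, so exponential growth between visits is the
  natural interpolant (linear interpolation of raw volume would
  systematically date crossings later). Series that never cross are
  right-censored at the end of follow-up; a baseline volume already above
  threshold is flagged as progressed at baseline with time zero. Time is
  counted from the irradiation day, not implantation — the quantity of
  interest is time gained by treatment.

## The outcome biomarker

$\Delta \mathrm{pO_2}$ is the pO₂ 5 min after irradiation minus 5 min
before (the single pre-irradiation reading, not a multi-day baseline),
reported absolute and as a percent of the pre value; a 2.5-fold post/pre
ratio equals a 150% increase, and the percent form is canonical in code.
The favorable-oxygenation predictor is the disjunction
$\mathrm{pO_2^{post}} > 20\ \mathrm{mmHg}$ **or**
$\Delta \mathrm{pO_2} > 150\%$, both strict as printed. Its evaluation
uses:

* `through_origin_slope()` — least squares of post on pre with no
  intercept, $b = \sum x_i y_i / \sum x_i^2$: zero oxygen before
  irradiation must map to zero after, so the line is forced through the
  origin and its slope reads directly as the mean fold-change.
* `pearson_correlation()`, `two_sample_t()` — standard Pearson r with the
  t-transform p-value, and the classical pooled-variance Student t-test
  (Welch available by flag), matching the study designs these reports use.
* `km_median_and_logrank()` — Kaplan–Meier medians (first time survival
  reaches 0.5) and the log-rank test, delegated to the `survival` package,
  with ties handled by the standard hypergeometric variance and
  non-progressors right-censored. One numerical guard is local: when the
  pooled design is so degenerate that the log-rank variance is exactly
  zero (for instance a single shared event time split evenly between
  arms), `survdiff`'s linear solve fails; the package then evaluates the
  observed-minus-expected sum directly and returns $\chi^2 = 0$ when
  observed equals expected.

Percentages of counts are reported to the nearest integer; rounding to the
nearest ten (used in prose for figures like "150%" or "70%") exists only
as a formatting helper, `round_percent(..., nearest = 10)`, and never
enters a computation. No multiple-testing correction is applied across the
correlations, matching the analysis style the pipeline reproduces.

## The synthetic cohort generator

`generate_cohort()` emulates four arms — dark control, light control, PDT
responder, PDT non-responder — with the reported statistical structure,
so pipeline claims can be tested against known ground truth:

* Pre-irradiation pO₂ uniform on 1–15 mmHg in every arm (treatment groups
  did not differ before irradiation).
* Post-irradiation pO₂ = slope · pre + N(0, 1.5 mmHg), with through-origin
  slopes 2.5 (responders), 1.7 (non-responders), 1.5 (light controls — a
  ~50% mean rise from irradiation alone) and 1.0 (dark controls), floored
  at 0. The light-control and dark-control slopes are the generator's own
  choices: no control slope is reported, and 1.5 matches the reported mean
  control increase.
* A physiological ceiling of 20 mmHg outside the responder arm (40 mmHg
  inside) enforced by **rejection**: the (pre, noise) pair is redrawn
  until the post value respects the ceiling. A hard `min()` cap would
  also respect the ceiling, but it pins a fifth of the non-responder arm
  exactly at 20 mmHg and — because the through-origin estimator weights
  by pre² — biases the recoverable slope about 7% below the generating
  1.7, making the generator internally inconsistent with its own declared
  slope. Rejection keeps the conditional relation intact over the
  accepted range at the cost of mildly thinning high-pre draws.
* Growth: per-animal exponential volume, $V(t) = V_0 e^{rt}$, with
  $V_0$ lognormal (median 60 mm³, sdlog 0.25 — a ~5 mm tumor at
  treatment), rates $r \sim N(0.10, 0.012)$/day in responders,
  $N(0.19, 0.02)$ in non-responders and $N(0.20, 0.03)$ in controls, 3%
  multiplicative caliper noise per diameter and a fixed mild per-animal
  anisotropy. These rates place the median responder day-5 change near
  65% and the non-responder near 160%, the median times to progression
  near 19 and 10–11 days, and — with the caliper noise included in the
  error budget, which matters as much as the rate spread itself — make
  the day-5 rule recover the generating labels in well over 95% of PDT
  animals. Responders additionally swell transiently (+50% volume at
  day 1, linearly gone by day 5), which perturbs early volumes but not
  the day-5 endpoint — mirroring why the response rule waits until day 5.
* Photosensitizer fluorescence: lognormal (sdlog 0.4) around 300 a.u. in
  responders, 100 a.u. in non-responders and dark controls (drug given,
  threefold responder ratio), 5 a.u. background in light controls. In
  responders the latent normal is correlated (ρ = 0.7) with the *realized*
  percent oxygenation change. An earlier design made the generating slope
  itself heterogeneous and coupled to fluorescence; that version biased
  the recoverable through-origin slope well below its nominal value
  (pre²-weighting plus the ceiling select against high-slope animals) and
  was replaced — correlating with the realized change leaves the
  generating slope clean.
* Edema/erythema: the 0–3 ordinal scale is driven by percent ΔpO₂ bins
  (<50 → 0, 50–150 → 1, 150–300 → 2, >300 → 3) with a one-step ordinal
  perturbation at probability 0.2, so the score correlates with ΔpO₂% as
  the outcome analysis expects. The scale is implemented as the four-level
  0–3 grading of its methods definition.
* Daily pO₂ series: baseline plus N(0, 0.8 mmHg) from two days before
  irradiation, the 5-min pre/post pair at day 0, and a return to baseline
  from day +1 onward.

All randomness descends from one master seed through named substreams per
data type, so generating spectra does not perturb the growth draws, and
identical seeds give identical cohorts byte for byte.

**What the generator does not emulate.** Reported group *medians* of
ΔpO₂% (~350% in responders) are not reproducible from a through-origin
slope of 2.5 with additive noise — a slope of 2.5 puts the median percent
change near 150% — and the two printed figures are mutually inconsistent
under any such model; the generator follows the slopes, which the recovery
tests check. It also ignores spatial heterogeneity of tumor oxygenation
(the probe reports one location), perfusion dynamics, photosensitizer
pharmacokinetics, and any dependence between pre-pO₂ and treatment arm.
Passing recovery tests therefore show that the *pipeline* is faithful, not
that real cohorts satisfy these generative assumptions.

## Problem sizes and tolerances

The recovery tests and the acceptance script use 200 animals per arm —
large enough that the through-origin slopes are recovered within a few
percent and the fluorescence ratio within ~10%, small enough that the full
simulate → fit-spectra → calibrate → analyze run (1600 spectrum fits of
1024 points each) completes in well under a minute. Monte-Carlo checks of
the linewidth estimators use 50–200 replicate spectra at 512–1024 points.
Interchange CSVs are written with 6 significant digits, which makes
repeated runs diffable while keeping far more precision than any
downstream statistic resolves; spectrum CSVs use 15 significant digits so
a write/read cycle is lossless at text precision.

## Known limitations

* The linewidth–pO₂ relation is treated as linear over the whole working
  range; nonlinear regimes and temperature corrections are out of scope.
* Calibration uncertainty is not propagated into pO₂ error bars.
* The log-rank comparison is two-arm only; no multivariable survival
  modelling.
* The equivalence of `fit_linewidth_least_squares()` with any particular
  proprietary spectrometer fitting software cannot be verified; the
  nonlinear least-squares lineshape fit is this package's own choice, and
  the two built-in estimators checking each other is the substitute for
  that missing oracle.
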