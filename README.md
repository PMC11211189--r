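# eproximetry

Analysis tools for preclinical photodynamic-therapy (PDT) studies that
monitor tumor oxygenation by **EPR oximetry**. In such studies a lithium
phthalocyanine (LiPc) microcrystal implanted in the tumor reports the local
oxygen partial pressure (pO₂): its single EPR line broadens linearly with
oxygen, so the peak-to-peak linewidth of the first-derivative spectrum,
ΔB_pp, converts to pO₂ through a calibration line. Measured minutes before
and after light irradiation, the oxygenation change ΔpO₂ turns out to be an
early predictor of whether the tumor will respond to the therapy — weeks
before growth curves can tell.

The package implements that whole pipeline for statisticians and
spectroscopists working with this kind of data:

- **Lineshape**: first-derivative Lorentzian spectra
  (dL/dB for L(B) = AΓ²/((B−B₀)² + Γ²), with ΔB_pp = 2Γ/√3), simulated on a
  realistic acquisition grid, and ΔB_pp estimated either from the signal
  extrema or by nonlinear least squares
  (`simulate_spectrum()`, `estimate_pp_width_extrema()`,
  `fit_linewidth_least_squares()`).
- **Calibration**: ΔB_pp = intercept + slope · pO₂, with the built-in LiPc
  line (slope 5.79 mG/mmHg, anoxic linewidth 47.25 mG) and OLS refitting
  from gas-mixture points (`lipc_calibration()`, `po2_from_linewidth()`,
  `fit_calibration()`).
- **Tumor response**: caliper volumetry V = (π/6)·a·b·c, the day-5
  responder rule ΔV(5 d) < 100%, and time to progression past 400 mm³ with
  log-linear interpolation and right-censoring (`classify_response()`,
  `time_to_progression()`, `summarize_growth()`).
- **Outcome biomarker**: ΔpO₂ metrics, the favorable-oxygenation predictor
  (post-PDT pO₂ > 20 mmHg **or** ΔpO₂ > 150%), through-origin regression of
  post on pre pO₂, per-clause predictor fractions, Kaplan–Meier medians and
  log-rank tests, Student t-tests and Pearson correlations
  (`delta_po2()`, `favorable_predictor()`, `analyze_study()`).
- **Synthetic cohorts**: a seeded generator that emulates the four study
  arms (dark control, light control, PDT responder, PDT non-responder) with
  the reported statistical structure, so every stage is testable without
  animal data (`generate_cohort()`, `generate_spectra_for_cohort()`).

## Worked example

Estimate pO₂ from a noisy simulated spectrum, then analyze a synthetic
four-arm cohort end to end:

```r
library(eproximetry)

## one spectrum: linewidth -> pO2
s <- simulate_spectrum(
  lorentzian_params(gamma_hwhm = gamma_from_pp_width(105.15), amplitude = 105),
  noise_sd = 0.01, seed = 7
)
fit_linewidth_least_squares(s)
#> Peak-to-peak linewidth: 105.4686 mG (least_squares, rms residual 0.00979)
po2_from_linewidth(fit_linewidth_least_squares(s))
#> [1] 10.05502

## a cohort: simulate, then analyze growth + oxygenation together
coh <- generate_cohort(n_per_group = 50, seed = 1)
analyze_study(coh$animals, coh$growth)
#> Tumor oxygenation after PDT: outcome analysis
#>   200 animals in 4 group(s); predictor: pO2 > 20 mmHg or dpO2 > 150%
#>
#> Group summary (means):
#>   dark_control       n= 50  pO2 pre  8.58 -> post  8.51 mmHg  (d -0.07 mmHg,   +3.2%)  responders 0
#>   light_control      n= 50  pO2 pre  7.82 -> post 11.20 mmHg  (d +3.38 mmHg,  +40.6%)  responders 4
#>   pdt_nonresponder   n= 50  pO2 pre  6.52 -> post 10.50 mmHg  (d +3.97 mmHg,  +61.4%)  responders 0
#>   pdt_responder      n= 50  pO2 pre  8.91 -> post 22.60 mmHg  (d +13.69 mmHg, +152.5%)  responders 48
#>
#> Through-origin slope of post vs pre pO2:
#>   responder      slope 2.550 (se 0.022, n=48)
#>   non_responder  slope 1.708 (se 0.047, n=52)
#>
#> Predictor clauses among responders:
#>   po2_gt_cut   27/48 (56%)
#>   delta_gt_cut 26/48 (54%)
#>   either       33/48 (69%)
#>
#> Time to progression (favorable vs unfavorable oxygenation): medians 19.4 vs 10.5 days (+85%), log-rank p = 7.75e-07
#> t-test delta_abs_responder_vs_nonresponder: t = 8.73, p = 6.96e-14
#> t-test delta_abs_pdt_vs_light_control: t = 5.52, p = 1.48e-07
#> correlation delta_pct_vs_fluorescence_responders: r = 0.594, p = 8.4e-06 (n=48)
#> correlation delta_pct_vs_edema: r = 0.678, p = 9.39e-15 (n=100)
```

The example reads as follows. The spectrum's fitted linewidth of ~105 mG
converts to ~10 mmHg through the LiPc line. In the cohort, the fitted
post-versus-pre pO₂ slope is ~2.5 in tumors later classified (from their
growth curves alone) as responders and ~1.7 in non-responders: responder
oxygenation roughly 2.5-folds during irradiation. Animals with favorable
oxygenation (post-PDT pO₂ > 20 mmHg or ΔpO₂ > 150%) progress past 400 mm³
about nine days later than the rest, and ΔpO₂% correlates with both
photosensitizer fluorescence (responders) and the edema/erythema score.

Responder/non-responder labels in the report are always re-derived from the
growth data via the ΔV(5 d) < 100% rule — the analysis never uses the
generator's arm labels.

A thin command-line front end wrapping `simulate_study()`,
`fit_spectrum_files()`, `fit_calibration()` and `analyze_study()` is
installed at `system.file("scripts", "epr-pdt-pipeline.R")` with
subcommands `simulate | fit-spectra | calibrate | analyze | report`.

See `vignettes/epr-pdt-oximetry.Rmd` for the model, the generator's
assumptions, and the numerical choices.

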