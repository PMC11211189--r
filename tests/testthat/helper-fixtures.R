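# Shared fixtures: all built in code at test time.

# Unit-lobe-height Lorentzian-derivative parameters for a target
# peak-to-peak width.
params_for_pp <- function(pp_width) {
  g <- gamma_from_pp_width(pp_width)
  lorentzian_params(gamma_hwhm = g, amplitude = 8 * sqrt(3) * g / 9)
}

# Independent oracle for the extrema separation: locate the extrema of the
# analytic derivative numerically on a dense grid (1e5 points), without any
# package estimator.
oracle_extrema_separation <- function(gamma_hwhm, center = 0, amplitude = 1,
                                      span = NULL) {
  if (is.null(span)) span <- 12 * gamma_hwhm
  x <- seq(center - span / 2, center + span / 2, length.out = 1e5)
  db <- x - center
  y <- -2 * amplitude * gamma_hwhm^2 * db / (db^2 + gamma_hwhm^2)^2
  x[which.min(y)] - x[which.max(y)]
}

# A clean growth series: exponential volume growth from v0 at rate r/day.
exp_growth_series <- function(v0, r, days = 0:20, ...) {
  growth_series(days, volume = v0 * exp(r * days), ...)
}
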