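test_that("derivative extrema sit at the analytic separation 2*Gamma/sqrt(3)", {
  # oracle: numeric extrema of the analytic derivative on a dense grid
  expect_equal(oracle_extrema_separation(sqrt(3) / 2), 1.0, tolerance = 1e-3)
  expect_equal(oracle_extrema_separation(40.92), 47.25, tolerance = 1e-3)

  set.seed(41)
  for (g in runif(20, 0.5, 300)) {
    expect_equal(oracle_extrema_separation(g), 2 * g / sqrt(3),
                 tolerance = 1e-3)
  }
})

test_that("derivative_lorentzian is antisymmetric and zero at the center", {
  p <- lorentzian_params(gamma_hwhm = 25, center = 10, amplitude = 2)
  expect_equal(derivative_lorentzian(p, 10), 0)
  off <- seq(-80, 80, length.out = 101)
  expect_equal(derivative_lorentzian(p, 10 + off),
               -derivative_lorentzian(p, 10 - off))
})

test_that("parameter validation rejects non-positive width and amplitude", {
  expect_error(lorentzian_params(gamma_hwhm = 0), class = "eproximetry_invalid_parameter")
  expect_error(lorentzian_params(gamma_hwhm = -3), class = "eproximetry_invalid_parameter")
  expect_error(lorentzian_params(gamma_hwhm = 1, amplitude = 0),
               class = "eproximetry_invalid_parameter")
})

test_that("simulate_spectrum is exact when noiseless and deterministic under a seed", {
  p <- lorentzian_params(gamma_hwhm = 50)
  s <- simulate_spectrum(p, noise_sd = 0)
  expect_equal(s$amplitude, derivative_lorentzian(p, s$field_mG))

  s1 <- simulate_spectrum(p, noise_sd = 0.01, seed = 7)
  s2 <- simulate_spectrum(p, noise_sd = 0.01, seed = 7)
  expect_identical(s1$amplitude, s2$amplitude)
  expect_false(identical(
    s1$amplitude,
    simulate_spectrum(p, noise_sd = 0.01, seed = 8)$amplitude
  ))

  expect_error(simulate_spectrum(p, span = -1), class = "eproximetry_invalid_grid")
  expect_error(simulate_spectrum(p, n_points = 16), class = "eproximetry_invalid_grid")
})

test_that("extrema estimator recovers noiseless widths to sub-grid accuracy", {
  # narrow line on a tight sweep: within one grid step of 1.0 mG
  s <- simulate_spectrum(lorentzian_params(gamma_hwhm = sqrt(3) / 2),
                         span = 10, n_points = 1024, noise_sd = 0)
  step <- diff(s$field_mG[1:2])
  expect_lt(abs(estimate_pp_width_extrema(s)$pp_width - 1.0), step)

  # acquisition-scale line: 76.2 mG within 0.5%
  s <- simulate_spectrum(params_for_pp(76.2), noise_sd = 0)
  expect_equal(estimate_pp_width_extrema(s)$pp_width, 76.2, tolerance = 0.005)
})

test_that("extrema estimator stays within 2% at 1% peak noise", {
  p <- params_for_pp(105.15) # unit lobe height
  s <- simulate_spectrum(p, noise_sd = 0.01, seed = 11)
  expect_equal(estimate_pp_width_extrema(s)$pp_width, 105.15, tolerance = 0.02)
})

test_that("spectra without a resolvable resonance raise a no-resonance error", {
  grid <- seq(-2500, 2500, length.out = 256)
  noise <- epr_spectrum(grid, withr::with_seed(5, rnorm(256, 0, 1)))
  expect_error(estimate_pp_width_extrema(noise), class = "eproximetry_no_resonance")

  flat <- epr_spectrum(grid, rep(0, 256))
  expect_error(estimate_pp_width_extrema(flat), class = "eproximetry_no_resonance")

  monotone <- epr_spectrum(grid, seq(-1, 1, length.out = 256))
  expect_error(estimate_pp_width_extrema(monotone), class = "eproximetry_no_resonance")

  inverted <- simulate_spectrum(params_for_pp(100), noise_sd = 0)
  inverted$amplitude <- -inverted$amplitude
  expect_error(estimate_pp_width_extrema(inverted), class = "eproximetry_no_resonance")
})

test_that("least-squares fit recovers the generating width", {
  # noiseless: to 0.1%, and agrees with the extrema method within 0.5%
  s <- simulate_spectrum(params_for_pp(105.15), noise_sd = 0)
  ls <- fit_linewidth_least_squares(s)
  ex <- estimate_pp_width_extrema(s)
  expect_equal(ls$pp_width, 105.15, tolerance = 0.001)
  expect_equal(ls$pp_width, ex$pp_width, tolerance = 0.005)
  expect_lt(ls$fit_residual, 1e-8)

  s <- simulate_spectrum(lorentzian_params(gamma_hwhm = sqrt(3) / 2),
                         span = 10, noise_sd = 0)
  expect_equal(fit_linewidth_least_squares(s)$pp_width, 1.0, tolerance = 0.001)
})

test_that("least-squares estimate is unbiased over noisy replicates", {
  # 5%-of-peak noise, 200 replicates: mean within 1% of truth
  p <- params_for_pp(105.15)
  est <- vapply(seq_len(200), function(i) {
    s <- simulate_spectrum(p, n_points = 512, noise_sd = 0.05, seed = 9000 + i)
    fit_linewidth_least_squares(s)$pp_width
  }, numeric(1))
  expect_equal(mean(est), 105.15, tolerance = 0.01)
})

test_that("linewidth estimators are invariant to amplitude scale and field shift", {
  base <- simulate_spectrum(params_for_pp(90), noise_sd = 0)
  ref_ex <- estimate_pp_width_extrema(base)$pp_width
  ref_ls <- fit_linewidth_least_squares(base)$pp_width

  scaled <- epr_spectrum(base$field_mG, base$amplitude * 37)
  expect_equal(estimate_pp_width_extrema(scaled)$pp_width, ref_ex)
  expect_equal(fit_linewidth_least_squares(scaled)$pp_width, ref_ls,
               tolerance = 1e-6)

  shifted <- simulate_spectrum(
    lorentzian_params(gamma_hwhm = gamma_from_pp_width(90), center = 400),
    noise_sd = 0
  )
  # the shifted line is sampled at different grid phases: sub-grid agreement
  expect_equal(estimate_pp_width_extrema(shifted)$pp_width, ref_ex,
               tolerance = 1e-3)
  expect_equal(fit_linewidth_least_squares(shifted)$pp_width, ref_ls,
               tolerance = 1e-6)
})

test_that("estimator bias shrinks as the noise level shrinks", {
  p <- params_for_pp(105.15)
  bias_at <- function(noise) {
    est <- vapply(seq_len(50), function(i) {
      s <- simulate_spectrum(p, n_points = 512, noise_sd = noise,
                             seed = 1000 * noise * 1e3 + i)
      fit_linewidth_least_squares(s)$pp_width
    }, numeric(1))
    abs(mean(est) - 105.15)
  }
  b <- vapply(c(0.04, 0.02, 0.005), bias_at, numeric(1))
  expect_lt(b[3], b[1])
  expect_lt(b[3], 0.2) # mG, ~0.2% of the width at the lowest level
})

test_that("spectrum CSV round-trips through write and read", {
  s <- simulate_spectrum(params_for_pp(80), n_points = 64, noise_sd = 0.02,
                         seed = 4)
  f <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(s, f)
  r <- read_spectrum(f)
  expect_equal(r$field_mG, s$field_mG, tolerance = 1e-12)
  expect_equal(r$amplitude, s$amplitude, tolerance = 1e-12)
  # idempotent at the chosen text precision
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(r, f2)
  expect_identical(readLines(f), readLines(f2))
})
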