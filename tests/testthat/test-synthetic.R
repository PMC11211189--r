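test_that("cohort generation is deterministic given the master seed", {
  a <- generate_cohort(n_per_group = 6, seed = 5)
  b <- generate_cohort(n_per_group = 6, seed = 5)
  expect_identical(a$animals, b$animals)
  expect_identical(a$growth, b$growth)
  expect_identical(a$po2_series, b$po2_series)
  c <- generate_cohort(n_per_group = 6, seed = 6)
  expect_false(identical(a$animals, c$animals))
})

test_that("configuration errors are raised for invalid arms and sizes", {
  expect_error(group_params("treatment_arm"), class = "eproximetry_config")
  expect_error(generate_cohort(n_per_group = 0), class = "eproximetry_config")
  expect_error(generate_cohort(params = list(1, 2)), class = "eproximetry_config")
  expect_error(group_params("dark_control", pre_po2_range = c(5, 45)),
               class = "eproximetry_config")
})

test_that("generated oxygenation respects the reported ranges and ceilings", {
  coh <- generate_cohort(n_per_group = 150, seed = 19)
  a <- coh$animals
  expect_true(all(a$po2_pre_mmHg >= 1 & a$po2_pre_mmHg <= 15))
  expect_true(all(a$po2_post_mmHg >= 0))
  # post-PDT pO2 never exceeds 20 mmHg outside the responder arm
  non_resp <- a$group %in% c("pdt_nonresponder", "light_control", "dark_control")
  expect_lte(max(a$po2_post_mmHg[non_resp]), 20)
  expect_lte(max(a$po2_post_mmHg), 40)
})

test_that("analysis modules recover the generating group structure at n = 200", {
  coh <- generate_cohort(n_per_group = 200, seed = 29)
  a <- coh$animals
  slope_of <- function(g) {
    x <- a[a$group == g, ]
    through_origin_slope(x$po2_pre_mmHg, x$po2_post_mmHg)$estimate
  }
  expect_equal(slope_of("pdt_responder"), 2.5, tolerance = 0.05)
  expect_equal(slope_of("pdt_nonresponder"), 1.7, tolerance = 0.05)

  # threefold fluorescence ratio of responders to non-responders
  ratio <- mean(a$fluorescence_au[a$group == "pdt_responder"]) /
    mean(a$fluorescence_au[a$group == "pdt_nonresponder"])
  expect_equal(ratio, 3, tolerance = 0.15)

  # median TTP ordering: responders progress later
  gs <- summarize_growth(coh$growth)
  km <- km_median_and_logrank(
    gs$ttp_days[gs$group == "pdt_nonresponder"],
    gs$ttp_days[gs$group == "pdt_responder"],
    !gs$censored[gs$group == "pdt_nonresponder"],
    !gs$censored[gs$group == "pdt_responder"]
  )
  expect_gt(km$medians[[2]], km$medians[[1]])
})

test_that("day +1 onward the pO2 series returns to the pre-irradiation baseline", {
  coh <- generate_cohort(n_per_group = 40, seed = 37)
  s <- coh$po2_series
  after <- merge(
    s[s$day >= 1 & s$timepoint == "daily", ],
    coh$animals[, c("animal_id", "po2_pre_mmHg")]
  )
  # within noise of baseline: small mean deviation, bounded spread
  dev <- after$po2_mmHg - after$po2_pre_mmHg
  expect_lt(abs(mean(dev)), 0.3)
  expect_lt(max(abs(dev)), 5)
  expect_true(all(s$po2_mmHg >= 0))
})

test_that("responder labels are recoverable from the growth data", {
  coh <- generate_cohort(n_per_group = 200, seed = 43)
  gs <- summarize_growth(coh$growth)
  pdt <- gs[gs$group %in% c("pdt_responder", "pdt_nonresponder"), ]
  agreement <- mean((pdt$group == "pdt_responder") == pdt$responder)
  expect_gte(agreement, 0.95)
  # responders miss the 100% cutoff with probability >= 0.9
  expect_gte(mean(gs$responder[gs$group == "pdt_responder"]), 0.9)
  # non-responders and controls largely double to sextuple by day 5
  ctrl <- gs[gs$group != "pdt_responder", ]
  expect_gte(mean(ctrl$dv5_pct >= 100 & ctrl$dv5_pct <= 500), 0.9)
})

test_that("cohort spectra encode pO2 through the calibration line", {
  coh <- generate_cohort(n_per_group = 3, seed = 7)
  cal <- lipc_calibration()

  # noiseless round trip is exact to well under 0.1 mmHg
  sp0 <- generate_spectra_for_cohort(coh, cal, noise_frac = 0, seed = 1)
  fits0 <- fit_cohort_spectra(sp0, cal)
  expect_lt(max(abs(fits0$po2_mmHg - fits0$po2_true)), 0.1)

  # pO2 = 0 maps to the anoxic linewidth
  anox <- data.frame(animal_id = "x", po2_pre_mmHg = 0, po2_post_mmHg = 10)
  sp <- generate_spectra_for_cohort(anox, cal, noise_frac = 0)
  lw <- estimate_pp_width_extrema(sp$spectra[[1]])
  expect_equal(lw$pp_width, 47.25, tolerance = 0.005)

  # determinism
  s1 <- generate_spectra_for_cohort(coh, cal, noise_frac = 0.02, seed = 9)
  s2 <- generate_spectra_for_cohort(coh, cal, noise_frac = 0.02, seed = 9)
  expect_identical(s1$spectra[[4]]$amplitude, s2$spectra[[4]]$amplitude)
})

test_that("noisy spectra recover pO2 = 10 mmHg without systematic error", {
  tab <- data.frame(animal_id = sprintf("m%02d", 1:50),
                    po2_pre_mmHg = 10, po2_post_mmHg = 10)
  sp <- generate_spectra_for_cohort(tab, noise_frac = 0.02, seed = 51)
  fits <- fit_cohort_spectra(sp)
  expect_equal(mean(fits$po2_mmHg), 10, tolerance = 0.05) # 100 spectra, 0.5 mmHg
})
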