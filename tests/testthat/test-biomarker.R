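test_that("delta_po2 reproduces the group-mean arithmetic", {
  expect_equal(delta_po2(4.7, 11.6)$delta_abs, 6.9)   # PDT group means
  expect_equal(delta_po2(5.2, 15.4)$delta_abs, 10.2)  # responders
  expect_equal(delta_po2(5, 5)$delta_abs, 0)
  expect_equal(delta_po2(5, 5)$delta_pct, 0)
  expect_warning(
    out <- delta_po2(c(0, 4), c(5, 8)),
    class = "eproximetry_undefined_percent"
  )
  expect_equal(out$delta_abs, c(5, 4)) # absolute change still returned
  expect_true(is.na(out$delta_pct[1]))
  expect_equal(out$delta_pct[2], 100)
})

test_that("the favorable predictor applies strict clauses and is monotone in post pO2", {
  expect_true(favorable_predictor(15, 21))        # pO2 clause
  expect_true(favorable_predictor(4, 11))         # 175% > 150%
  expect_false(favorable_predictor(4, 9))         # 125%, post < 20
  expect_true(favorable_predictor(5.2, 15.4))     # 196% > 150%
  expect_false(favorable_predictor(8, 20))        # both boundaries: strict

  withr::with_seed(17, {
    for (i in seq_len(50)) {
      pre <- runif(1, 1, 15)
      post <- runif(1, 0, 40)
      if (favorable_predictor(pre, post)) {
        expect_true(favorable_predictor(pre, post + runif(1, 0, 20)))
      }
    }
  })
})

test_that("predictor_fractions reports per-clause counts and rounded percents", {
  # 13 responders: 7 pass only the percent clause (175%), 1 only the pO2
  # clause (110%), 3 pass both, 2 pass neither -> 4, 10 and 11 of 13
  pre <- c(rep(4, 7), 10, rep(5, 3), rep(8, 2))
  post <- c(rep(11, 7), 21, rep(22, 3), rep(12, 2))
  fr <- predictor_fractions(pre, post, rep(TRUE, 13))
  expect_equal(fr$count[fr$clause == "po2_gt_cut"], 4)
  expect_equal(fr$count[fr$clause == "delta_gt_cut"], 10)
  expect_equal(fr$count[fr$clause == "either"], 11)
  expect_equal(fr$percent_rounded[fr$clause == "po2_gt_cut"], 31)
  expect_equal(fr$percent_rounded[fr$clause == "delta_gt_cut"], 77)
  expect_equal(fr$percent_rounded[fr$clause == "either"], 85)
  # clause fractions never exceed the disjunction's
  either <- fr$percent[fr$clause == "either"]
  expect_true(all(fr$percent[fr$clause != "either"] <= either))

  expect_error(predictor_fractions(numeric(0), numeric(0), logical(0)),
               class = "eproximetry_empty_input")
  expect_error(predictor_fractions(1:3, 2:4, rep(FALSE, 3)),
               class = "eproximetry_empty_input")
})

test_that("through_origin_slope equals the closed form and matches lm", {
  expect_equal(through_origin_slope(c(1, 2, 4), c(2.5, 5, 10))$estimate, 2.5)
  x <- c(3, 7, 1)
  expect_equal(through_origin_slope(x, x)$estimate, 1)

  withr::with_seed(13, {
    for (i in seq_len(10)) {
      x <- runif(30, 1, 15)
      y <- 2 * x + rnorm(30)
      ours <- through_origin_slope(x, y)
      ref <- lm(y ~ x + 0) # independent route to the same estimator
      expect_equal(ours$estimate, unname(coef(ref)), tolerance = 1e-12)
      expect_equal(ours$se, unname(sqrt(diag(vcov(ref)))), tolerance = 1e-12)
    }
  })
  expect_error(through_origin_slope(c(0, 0), c(1, 2)),
               class = "eproximetry_singular_fit")
})

test_that("through_origin_slope recovers a generative slope from seeded pairs", {
  withr::with_seed(23, {
    pre <- runif(100, 1, 15)
    post <- 2.5 * pre + rnorm(100, 0, 1.5)
  })
  est <- through_origin_slope(pre, post)$estimate
  expect_equal(est, 2.5, tolerance = 0.05)
})

test_that("pearson_correlation behaves at the exact, null and generative cases", {
  x <- 1:10
  expect_equal(pearson_correlation(x, 2 * x + 1)$estimate, 1)

  withr::with_seed(3, {
    a <- rnorm(1000)
    b <- sample(a) # permutation destroys association
  })
  expect_lt(abs(pearson_correlation(a, b)$estimate), 0.1)

  withr::with_seed(8, {
    x <- rnorm(200)
    y <- 0.8 * x + sqrt(1 - 0.8^2) * rnorm(200)
  })
  ct <- pearson_correlation(x, y)
  expect_equal(ct$estimate, 0.8, tolerance = 0.125)
  expect_lt(ct$p_value, 0.001)

  expect_error(pearson_correlation(rep(1, 5), 1:5),
               class = "eproximetry_undefined_correlation")
  expect_error(pearson_correlation(1:2, 2:3),
               class = "eproximetry_insufficient_data")
})

test_that("the pooled t-test covers identity, separation and power", {
  same <- c(1, 2, 3, 4)
  tt <- two_sample_t(same, same)
  expect_equal(tt$estimate, 0)
  expect_equal(tt$p_value, 1)

  a <- c(0, 0, 0, 0) + c(1, -1, 2, -2) * 1e-6
  b <- c(1, 1, 1, 1) + c(-1, 1, -2, 2) * 1e-6
  expect_lt(two_sample_t(a, b)$p_value, 1e-10)

  # power against a 1-sd shift at n = 30 per arm
  rejections <- withr::with_seed(77, {
    mean(vapply(seq_len(500), function(i) {
      two_sample_t(rnorm(30), rnorm(30, 1))$p_value < 0.05
    }, logical(1)))
  })
  expect_gte(rejections, 0.9)

  expect_error(two_sample_t(1, c(2, 3)), class = "eproximetry_insufficient_data")
})

test_that("KM medians and the log-rank test match hand-computable cases", {
  # medians: S(t) drops to 1/3 at the 2nd of 3 events
  km <- km_median_and_logrank(c(1, 2, 3), c(11, 12, 13))
  expect_equal(unname(km$medians), c(2, 12))
  expect_lt(km$p_value, 0.05)
  expect_equal(km$pct_increase, 100 * (12 - 2) / 2)

  # identical arms: no signal
  km <- km_median_and_logrank(c(2, 5, 9), c(2, 5, 9))
  expect_equal(km$chisq, 0, tolerance = 1e-12)
  expect_equal(km$p_value, 1, tolerance = 1e-6)

  # a single shared event time split evenly: observed = expected
  km <- km_median_and_logrank(c(5, 5), c(5, 5))
  expect_equal(km$chisq, 0, tolerance = 1e-12)
})

test_that("log-rank handles censoring, time rescaling and an all-censored arm", {
  t_a <- c(3, 5, 8, 10, 12)
  e_a <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  t_b <- c(9, 14, 17, 20, 20)
  e_b <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  km1 <- km_median_and_logrank(t_a, t_b, e_a, e_b)
  km2 <- km_median_and_logrank(3 * t_a, 3 * t_b, e_a, e_b)
  expect_equal(km1$chisq, km2$chisq)
  expect_gte(km1$chisq, 0)

  all_cens <- km_median_and_logrank(c(20, 20, 20), t_b,
                                    event_a = c(FALSE, FALSE, FALSE),
                                    event_b = e_b)
  expect_true(all_cens$undefined_median[["a"]])
  expect_true(is.na(all_cens$medians[["a"]]))
  expect_true(is.finite(all_cens$chisq)) # log-rank still computed

  expect_error(km_median_and_logrank(numeric(0), t_b),
               class = "eproximetry_insufficient_data")
})

test_that("round_percent matches reporting conventions", {
  expect_equal(round_percent(100 * 4 / 13), 31)
  expect_equal(round_percent(100 * 10 / 13), 77)
  expect_equal(round_percent(100 * 11 / 13), 85)
  expect_equal(round_percent(146.8, nearest = 10), 150)
})
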