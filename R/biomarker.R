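#' Analysis thresholds for the oxygenation predictor
#'
#' Bundles the cutoffs used throughout the outcome analysis: the absolute
#' post-irradiation oxygen cutoff (mmHg), the relative oxygen-increase
#' cutoff (% of the pre value; 150% is the percent form of a 2.5-fold
#' post/pre ratio), the progression volume (mm^3) and the day-5 responder
#' cutoff (%). All comparisons against these cutoffs are strict.
#'
#' @param po2_cut Post-PDT pO2 cutoff, mmHg (default 20).
#' @param delta_pct_cut Percent oxygen-increase cutoff (default 150).
#' @param progression_volume Progression threshold, mm^3 (default 400).
#' @param response_dv5 Day-5 responder cutoff, percent (default 100).
#' @return An object of class `analysis_thresholds`.
#' @export
analysis_thresholds <- function(po2_cut = 20, delta_pct_cut = 150,
                                progression_volume = 400, response_dv5 = 100) {
  for (nm in c("po2_cut", "delta_pct_cut", "progression_volume", "response_dv5")) {
    stopifnot_number(get(nm), nm, positive = TRUE)
  }
  structure(
    list(po2_cut = po2_cut, delta_pct_cut = delta_pct_cut,
         progression_volume = progression_volume, response_dv5 = response_dv5),
    class = "analysis_thresholds"
  )
}

#' Oxygenation change around irradiation
#'
#' The treatment-induced oxygenation change is pO2 measured 5 min after
#' irradiation minus pO2 5 min before, reported both absolute (mmHg) and as
#' a percent of the pre value. A non-positive pre value leaves the percent
#' form undefined (`NA`, with a warning); the absolute change is still
#' returned.
#'
#' @param po2_pre,po2_post Pre- and post-irradiation pO2, mmHg; vectors of
#'   equal length.
#' @return Data frame with columns `delta_abs` (mmHg) and `delta_pct` (%).
#' @examples
#' delta_po2(4.7, 11.6) # mean PDT-group change: +6.9 mmHg
#' @export
delta_po2 <- function(po2_pre, po2_post) {
  if (length(po2_pre) != length(po2_post)) {
    abort("`po2_pre` and `po2_post` must have equal length",
          "eproximetry_invalid_parameter")
  }
  delta_abs <- po2_post - po2_pre
  bad <- po2_pre <= 0
  if (any(bad)) {
    warn("percent change undefined where po2_pre <= 0; returning NA there",
         "eproximetry_undefined_percent")
  }
  delta_pct <- ifelse(bad, NA_real_, 100 * delta_abs / po2_pre)
  data.frame(delta_abs = delta_abs, delta_pct = delta_pct)
}

#' Favorable-oxygenation predictor
#'
#' A tumor's post-irradiation oxygenation is called favorable when
#' `po2_post > po2_cut` (default 20 mmHg) or the percent increase exceeds
#' `delta_pct_cut` (default 150%, i.e. more than a 2.5-fold post/pre
#' ratio). Both inequalities are strict. The predictor is monotone in
#' `po2_post`: raising the post value can never turn a favorable call
#' unfavorable.
#'
#' @inheritParams delta_po2
#' @param thresholds An [analysis_thresholds()].
#' @return Logical vector.
#' @export
favorable_predictor <- function(po2_pre, po2_post,
                                thresholds = analysis_thresholds()) {
  dp <- suppressWarnings(delta_po2(po2_pre, po2_post))
  (po2_post > thresholds$po2_cut) |
    (!is.na(dp$delta_pct) & dp$delta_pct > thresholds$delta_pct_cut)
}

#' Predictor clause fractions among responders
#'
#' For the animals whose tumors responded, tabulates how many satisfied
#' each clause of the favorable-oxygenation predictor and their
#' disjunction — the per-clause sensitivities of the predictor. Percentages
#' are reported unrounded and rounded to the nearest integer.
#'
#' @inheritParams favorable_predictor
#' @param responder Logical vector: the day-5 response call per animal.
#' @return Data frame with one row per clause (`po2_gt_cut`,
#'   `delta_gt_cut`, `either`) and columns `count`, `n`, `percent`,
#'   `percent_rounded`.
#' @export
predictor_fractions <- function(po2_pre, po2_post, responder,
                                thresholds = analysis_thresholds()) {
  if (length(responder) != length(po2_pre)) {
    abort("`responder` must match the cohort length", "eproximetry_invalid_parameter")
  }
  if (length(po2_pre) == 0L) {
    abort("empty cohort", "eproximetry_empty_input")
  }
  keep <- which(responder)
  if (!length(keep)) {
    abort("no responders in cohort; clause fractions undefined",
          "eproximetry_empty_input")
  }
  pre <- po2_pre[keep]
  post <- po2_post[keep]
  dp <- suppressWarnings(delta_po2(pre, post))
  c1 <- post > thresholds$po2_cut
  c2 <- !is.na(dp$delta_pct) & dp$delta_pct > thresholds$delta_pct_cut
  counts <- c(po2_gt_cut = sum(c1), delta_gt_cut = sum(c2), either = sum(c1 | c2))
  n <- length(keep)
  data.frame(
    clause = names(counts),
    count = as.integer(counts),
    n = n,
    percent = 100 * counts / n,
    percent_rounded = round(100 * counts / n),
    row.names = NULL
  )
}

#' Round a percentage for reporting
#'
#' Formatting helper: percentages of counts round to the nearest integer;
#' `nearest = 10` reproduces round-ten figures sometimes used in prose.
#' Never used inside any computation.
#'
#' @param x Percentages.
#' @param nearest Rounding grain (1 or 10).
#' @return Rounded percentages.
#' @export
round_percent <- function(x, nearest = 1) {
  round(x / nearest) * nearest
}

#' Statistic-with-p container
#' @noRd
stat_result <- function(estimate, p_value, n, method, ...) {
  structure(list(estimate = estimate, p_value = p_value, n = n,
                 method = method, ...),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: estimate %.4g, p = %.3g, n = %s\n",
              x$method, x$estimate, x$p_value, paste(x$n, collapse = "+")))
  invisible(x)
}

#' Least-squares slope through the origin
#'
#' Fits `y = b * x` with no intercept: `b = sum(x*y) / sum(x^2)`. Used for
#' the post- versus pre-irradiation pO2 relation, where the line is forced
#' through (0, 0) and its slope is the average fold-change in oxygenation.
#' The p-value is the two-sided t-test of `b = 0` on `n - 1` degrees of
#' freedom.
#'
#' @param x,y Numeric vectors of equal length (>= 2).
#' @return A `stat_result` with `estimate` (slope), `se`, `p_value`, `n`.
#' @export
through_origin_slope <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    abort("`x` and `y` must have equal length >= 2", "eproximetry_invalid_parameter")
  }
  if (all(x == 0)) {
    abort("all x are zero: through-origin slope is undefined",
          "eproximetry_singular_fit")
  }
  n <- length(x)
  b <- sum(x * y) / sum(x^2)
  se <- sqrt(sum((y - b * x)^2) / (n - 1) / sum(x^2))
  tval <- b / se
  stat_result(
    estimate = b,
    p_value = 2 * stats::pt(abs(tval), df = n - 1, lower.tail = FALSE),
    n = n, method = "through_origin_slope", se = se
  )
}

#' Pearson correlation with t-based p-value
#'
#' Sample Pearson correlation with the usual two-sided p-value from the t
#' transform (via [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return A `stat_result` with `estimate` (r), `p_value`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3L) {
    abort("Pearson correlation needs n >= 3 complete pairs",
          "eproximetry_insufficient_data")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("correlation undefined: a series has zero variance",
          "eproximetry_undefined_correlation")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  stat_result(estimate = unname(ct$estimate), p_value = ct$p.value,
              n = length(x), method = "pearson_correlation")
}

#' Two-sample Student t-test
#'
#' Classical pooled-variance two-sided Student t-test of a difference in
#' means (via [stats::t.test()]); `welch = TRUE` switches to the Welch
#' unequal-variance form.
#'
#' @param group_a,group_b Numeric vectors, each with n >= 2.
#' @param welch Use the Welch correction instead of pooled variance.
#' @return A `stat_result` with `estimate` (t statistic), `p_value`,
#'   per-group `n`, and the `mean_difference`.
#' @export
two_sample_t <- function(group_a, group_b, welch = FALSE) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    abort("each group needs n >= 2", "eproximetry_insufficient_data")
  }
  tt <- stats::t.test(group_a, group_b, var.equal = !welch)
  stat_result(
    estimate = unname(tt$statistic), p_value = tt$p.value,
    n = c(length(group_a), length(group_b)),
    method = if (welch) "welch_t" else "student_t",
    mean_difference = unname(diff(rev(tt$estimate)))
  )
}

# Direct log-rank statistic (observed minus expected over pooled event
# times, hypergeometric variance). Used only when survdiff's linear solve
# degenerates — e.g. a single shared event time split evenly, where the
# variance is exactly zero and observed equals expected, so chi^2 = 0.
logrank_chisq <- function(time, event, in_b) {
  O <- E <- V <- 0
  for (t in sort(unique(time[event == 1L]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n_b <- sum(at_risk & in_b)
    d <- sum(time == t & event == 1L)
    d_b <- sum(time == t & event == 1L & in_b)
    O <- O + d_b
    E <- E + d * n_b / n
    if (n > 1L) {
      V <- V + d * (n_b / n) * (1 - n_b / n) * (n - d) / (n - 1L)
    }
  }
  if (V == 0) {
    if (abs(O - E) < sqrt(.Machine$double.eps)) 0 else NaN
  } else {
    (O - E)^2 / V
  }
}

#' Kaplan-Meier medians and log-rank comparison of two arms
#'
#' Computes the Kaplan-Meier median time to progression of each arm (the
#' first time the survival curve drops to 0.5 or below) and the log-rank
#' test between the arms, handling ties with the standard hypergeometric
#' variance and treating animals whose tumors never progressed as
#' right-censored at the end of follow-up. Both pieces are delegated to the
#' \pkg{survival} package ([survival::survfit()], [survival::survdiff()]).
#'
#' An arm with no uncensored events has an undefined median (`NA`); the
#' log-rank statistic is still computed.
#'
#' @param time_a,time_b Times to progression (days) per arm.
#' @param event_a,event_b Logical/0-1 event indicators (`TRUE` =
#'   progressed, `FALSE` = censored). Default: all events.
#' @param labels Length-2 character vector naming the arms.
#' @return An object of class `km_logrank`: list with named `medians`,
#'   `pct_increase` (second arm vs first), `chisq`, `p_value`, and `n`.
#' @examples
#' km_median_and_logrank(c(1, 2, 3), c(11, 12, 13))
#' @export
km_median_and_logrank <- function(time_a, time_b,
                                  event_a = rep(TRUE, length(time_a)),
                                  event_b = rep(TRUE, length(time_b)),
                                  labels = c("a", "b")) {
  if (!length(time_a) || !length(time_b)) {
    abort("both arms must be non-empty", "eproximetry_insufficient_data")
  }
  time <- c(time_a, time_b)
  event <- as.integer(c(event_a, event_b))
  arm <- factor(rep(labels, c(length(time_a), length(time_b))), levels = labels)
  fit <- survival::survfit(survival::Surv(time, event) ~ arm)
  tab <- summary(fit)$table
  med <- unname(tab[, "median"])
  if (all(event == 0)) {
    abort("no events in either arm: log-rank undefined",
          "eproximetry_insufficient_data")
  }
  chisq <- tryCatch(
    unname(survival::survdiff(survival::Surv(time, event) ~ arm)$chisq),
    error = function(e) logrank_chisq(time, event, arm == labels[2L])
  )
  pval <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  structure(
    list(
      medians = stats::setNames(med, labels),
      pct_increase = if (all(is.finite(med)) && med[1L] > 0) {
        100 * (med[2L] - med[1L]) / med[1L]
      } else {
        NA_real_
      },
      chisq = chisq, p_value = pval,
      n = stats::setNames(c(length(time_a), length(time_b)), labels),
      undefined_median = stats::setNames(is.na(med), labels)
    ),
    class = "km_logrank"
  )
}

#' @export
print.km_logrank <- function(x, ...) {
  cat(sprintf(
    "KM medians: %s = %.3g, %s = %.3g days (change %+.3g%%); log-rank chi^2 = %.3g, p = %.3g\n",
    names(x$medians)[1], x$medians[1], names(x$medians)[2], x$medians[2],
    x$pct_increase, x$chisq, x$p_value
  ))
  invisible(x)
}
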