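#' Linewidth–oxygen calibration line
#'
#' A linear map between the peak-to-peak EPR linewidth of a particulate
#' oxygen probe and the oxygen partial pressure at the probe:
#' `linewidth = intercept + slope * pO2`. The intercept is the anoxic
#' linewidth of the probe (its linewidth at zero oxygen).
#'
#' @param slope Sensitivity in mG per mmHg (> 0).
#' @param intercept Anoxic linewidth in mG (> 0).
#' @param r_squared Coefficient of determination of the fit that produced
#'   the line (`NA` when not derived from data).
#' @param slope_se,intercept_se Standard errors, when known.
#' @param n Number of calibration points, when known.
#' @return An object of class `calibration_line`.
#' @seealso [lipc_calibration()], [fit_calibration()]
#' @export
calibration_line <- function(slope, intercept, r_squared = NA_real_,
                             slope_se = NA_real_, intercept_se = NA_real_,
                             n = NA_integer_) {
  stopifnot_number(slope, "slope", positive = TRUE)
  stopifnot_number(intercept, "intercept", positive = TRUE)
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1)) {
    abort("`r_squared` must lie in [0, 1]", "eproximetry_invalid_parameter")
  }
  structure(
    list(slope = slope, intercept = intercept, r_squared = r_squared,
         slope_se = slope_se, intercept_se = intercept_se, n = n),
    class = "calibration_line"
  )
}

#' @export
print.calibration_line <- function(x, ...) {
  cat(sprintf("Calibration line: linewidth = %.4g + %.4g * pO2 [mG, mmHg]\n",
              x$intercept, x$slope))
  if (!is.na(x$r_squared)) cat(sprintf("  R^2 = %.4g on n = %s points\n",
                                       x$r_squared, x$n))
  invisible(x)
}

#' Built-in LiPc calibration line
#'
#' The default lithium phthalocyanine (LiPc) calibration used for in vivo
#' conversion: slope 5.79 mG/mmHg (se 0.42) and anoxic linewidth
#' 47.25 mG (se 5.25), from a gas-mixture linear-regression calibration of
#' the probe batch.
#'
#' @return A [calibration_line()].
#' @export
lipc_calibration <- function() {
  calibration_line(slope = 5.79, intercept = 47.25,
                   slope_se = 0.42, intercept_se = 5.25)
}

#' Convert peak-to-peak linewidth to oxygen partial pressure
#'
#' Inverts the calibration line: `pO2 = (linewidth - intercept) / slope`.
#' Linewidths slightly below the anoxic intercept (within `tolerance`) are
#' treated as anoxic and clamp to 0 mmHg — at near-zero oxygen, noise in the
#' linewidth estimate routinely lands a few mG below the intercept.
#' Linewidths below `intercept - tolerance` signal a bad fit or the wrong
#' probe and raise a below-anoxic-linewidth error.
#'
#' @param pp_width Peak-to-peak linewidth(s) in mG, or a `linewidth_estimate`.
#' @param cal A [calibration_line()]; defaults to [lipc_calibration()].
#' @param tolerance Clamp band below the intercept, mG.
#' @return Oxygen partial pressure(s), mmHg.
#' @examples
#' po2_from_linewidth(105.15) # 10 mmHg under the default LiPc line
#' @export
po2_from_linewidth <- function(pp_width, cal = lipc_calibration(), tolerance = 3) {
  if (inherits(pp_width, "linewidth_estimate")) pp_width <- pp_width$pp_width
  if (!is.numeric(pp_width) || any(!is.finite(pp_width))) {
    abort("`pp_width` must be finite numeric", "eproximetry_invalid_parameter")
  }
  low <- pp_width < cal$intercept - tolerance
  if (any(low)) {
    abort(
      sprintf(
        "linewidth %.4g mG is more than %.3g mG below the anoxic intercept %.4g mG; check the fit or the calibration",
        min(pp_width[low]), tolerance, cal$intercept
      ),
      "eproximetry_below_anoxic_linewidth"
    )
  }
  pmax((pp_width - cal$intercept) / cal$slope, 0)
}

#' Convert oxygen partial pressure to peak-to-peak linewidth
#'
#' Forward calibration relation `linewidth = intercept + slope * pO2`;
#' composes with [po2_from_linewidth()] to the identity for `pO2 >= 0`.
#'
#' @param po2 Oxygen partial pressure(s), mmHg (>= 0).
#' @inheritParams po2_from_linewidth
#' @return Linewidth(s) in mG.
#' @export
linewidth_from_po2 <- function(po2, cal = lipc_calibration()) {
  if (!is.numeric(po2) || any(!is.finite(po2))) {
    abort("`po2` must be finite numeric", "eproximetry_invalid_parameter")
  }
  if (any(po2 < 0)) {
    abort("`po2` must be >= 0 mmHg", "eproximetry_invalid_input")
  }
  cal$intercept + cal$slope * po2
}

#' Fit a calibration line from (pO2, linewidth) points
#'
#' Ordinary least squares of linewidth on pO2 (the gas-mixture calibration
#' design: oxygen is set, linewidth is measured). Two points give the exact
#' interpolating line.
#'
#' @param po2 Oxygen partial pressures, mmHg, or a data frame with columns
#'   `po2_mmHg` and `linewidth_mG`.
#' @param linewidth Peak-to-peak linewidths, mG (omit when `po2` is a data
#'   frame).
#' @return A [calibration_line()] with `r_squared`, standard errors and `n`.
#' @export
fit_calibration <- function(po2, linewidth = NULL) {
  if (is.data.frame(po2)) {
    need <- c("po2_mmHg", "linewidth_mG")
    miss <- setdiff(need, names(po2))
    if (length(miss)) {
      abort(sprintf("calibration data lacks column(s): %s",
                    paste(miss, collapse = ", ")),
            "eproximetry_validation")
    }
    linewidth <- po2$linewidth_mG
    po2 <- po2$po2_mmHg
  }
  if (length(po2) != length(linewidth) || length(po2) < 2L) {
    abort("need at least 2 (po2, linewidth) points of equal length",
          "eproximetry_singular_fit")
  }
  if (length(unique(po2)) < 2L) {
    abort("calibration design is degenerate: all pO2 values are equal",
          "eproximetry_singular_fit")
  }
  fit <- stats::lm(linewidth ~ po2)
  # exact synthetic lines are legitimate inputs: silence lm's perfect-fit note
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  co <- stats::coef(sm)
  calibration_line(
    slope = co["po2", "Estimate"],
    intercept = co["(Intercept)", "Estimate"],
    r_squared = sm$r.squared,
    slope_se = co["po2", "Std. Error"],
    intercept_se = co["(Intercept)", "Std. Error"],
    n = length(po2)
  )
}

#' Read calibration points from CSV
#'
#' Expects columns `po2_mmHg` and `linewidth_mG`.
#'
#' @param path File path.
#' @return A data frame of calibration points.
#' @export
read_calibration_points <- function(path) {
  df <- utils::read.csv(path)
  miss <- setdiff(c("po2_mmHg", "linewidth_mG"), names(df))
  if (length(miss)) {
    abort(sprintf("calibration file %s lacks column(s): %s", path,
                  paste(miss, collapse = ", ")),
          "eproximetry_validation")
  }
  df
}
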