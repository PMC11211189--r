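#' Ellipsoid tumor volume from caliper diameters
#'
#' Standard three-diameter caliper volumetry:
#' \eqn{V = (\pi/6)\, a \, b \, c} for perpendicular diameters of the
#' ellipsoid approximating the tumor.
#'
#' @param a,b,c Perpendicular diameters in mm (> 0); vectors recycle as usual.
#' @return Volume(s) in mm^3.
#' @examples
#' ellipsoid_volume(2, 2, 2) # sphere of diameter 2 mm
#' @export
ellipsoid_volume <- function(a, b, c) {
  d <- cbind(a, b, c)
  if (!is.numeric(d) || any(!is.finite(d)) || any(d <= 0)) {
    abort("diameters a, b, c must be finite and > 0 mm",
          "eproximetry_invalid_measurement")
  }
  (pi / 6) * a * b * c
}

#' Longitudinal tumor growth series for one animal
#'
#' Holds time-ordered caliper measurements relative to the day of
#' irradiation (day 0). Supply either the three diameters or precomputed
#' volumes.
#'
#' @param day Integer-valued measurement days, strictly increasing.
#' @param a,b,c Perpendicular diameters per day, mm.
#' @param volume Alternatively, volumes in mm^3 (used as-is).
#' @param animal_id,group Optional labels carried through to summaries.
#' @param followup_end Last observed day; defaults to the last measurement.
#' @return An object of class `growth_series`.
#' @export
growth_series <- function(day, a = NULL, b = NULL, c = NULL, volume = NULL,
                          animal_id = NA_character_, group = NA_character_,
                          followup_end = NULL) {
  if (length(day) < 1L || any(!is.finite(day))) {
    abort("`day` must be finite and non-empty", "eproximetry_invalid_measurement")
  }
  if (any(diff(day) <= 0)) {
    abort("measurement days must be strictly increasing",
          "eproximetry_invalid_measurement")
  }
  if (is.null(volume)) {
    if (is.null(a) || is.null(b) || is.null(c)) {
      abort("supply either diameters a, b, c or `volume`",
            "eproximetry_invalid_measurement")
    }
    volume <- ellipsoid_volume(a, b, c)
  } else {
    if (any(!is.finite(volume)) || any(volume <= 0)) {
      abort("volumes must be finite and > 0 mm^3", "eproximetry_invalid_measurement")
    }
  }
  if (length(volume) != length(day)) {
    abort("`day` and measurements must have equal length",
          "eproximetry_invalid_measurement")
  }
  if (is.null(followup_end)) followup_end <- max(day)
  structure(
    list(animal_id = animal_id, group = group,
         data = data.frame(day = day, volume = volume),
         followup_end = followup_end),
    class = "growth_series"
  )
}

#' @export
print.growth_series <- function(x, ...) {
  cat(sprintf("Growth series %s (%s): %d measurements, days %g..%g\n",
              x$animal_id, x$group, nrow(x$data), min(x$data$day),
              max(x$data$day)))
  invisible(x)
}

# Volume at an arbitrary day: the measurement nearest `day` within
# +/- window, else log-linear interpolation between the flanking
# measurements (growth is treated as exponential between visits).
volume_at <- function(series, day, window = 1) {
  d <- series$data$day
  v <- series$data$volume
  if (day < min(d) || day > max(d)) {
    abort(sprintf("series does not span day %g (observed days %g..%g)",
                  day, min(d), max(d)),
          "eproximetry_insufficient_followup")
  }
  gap <- abs(d - day)
  if (min(gap) <= window) {
    return(v[which.min(gap)])
  }
  i <- findInterval(day, d)
  exp(stats::approx(d[c(i, i + 1L)], log(v[c(i, i + 1L)]), xout = day)$y)
}

#' Classify the five-day tumor response
#'
#' The percent volume change from the day of irradiation to day 5,
#' `dv5_pct = 100 * (V(5) - V(0)) / V(0)`, classifies a tumor as a
#' responder when `dv5_pct` is strictly below the cutoff (default 100%).
#' Day 5 is used because treatment-induced swelling confounds caliper
#' volumes earlier; the boundary value itself is a non-responder.
#'
#' Volumes at days 0 and 5 are the measurements nearest those days within
#' \eqn{\pm 1} day, else log-linear interpolation between flanking visits.
#'
#' @param series A [growth_series()] spanning days 0 and 5.
#' @param response_dv5 Responder cutoff on the percent change (default 100).
#' @return An object of class `response_call`: list with `dv5_pct` and
#'   logical `responder`.
#' @export
classify_response <- function(series, response_dv5 = 100) {
  if (!inherits(series, "growth_series")) {
    abort("`series` must be a growth_series", "eproximetry_invalid_parameter")
  }
  v0 <- volume_at(series, 0)
  v5 <- volume_at(series, 5)
  dv5 <- 100 * (v5 - v0) / v0
  structure(list(dv5_pct = dv5, responder = dv5 < response_dv5),
            class = "response_call")
}

#' @export
print.response_call <- function(x, ...) {
  cat(sprintf("dV(5 d) = %.1f%% -> %s\n", x$dv5_pct,
              if (x$responder) "responder" else "non-responder"))
  invisible(x)
}

#' Time to tumor progression
#'
#' The first day the tumor volume reaches the progression threshold
#' (default 400 mm^3, about 30% of the maximal burden an animal may carry).
#' Between measurement days the crossing is located by linear interpolation
#' of log-volume, i.e. assuming exponential growth between visits. Series
#' that never reach the threshold are right-censored at the end of
#' follow-up. A baseline volume already above the threshold yields
#' `ttp_days = 0` with `progressed_at_baseline = TRUE`.
#'
#' @param series A [growth_series()] with at least 2 measurements.
#' @param threshold Progression threshold, mm^3.
#' @return An object of class `progression_time`: list with `ttp_days`,
#'   logical `censored`, and logical `progressed_at_baseline`.
#' @export
time_to_progression <- function(series, threshold = 400) {
  if (!inherits(series, "growth_series")) {
    abort("`series` must be a growth_series", "eproximetry_invalid_parameter")
  }
  d <- series$data$day
  v <- series$data$volume
  if (length(d) < 2L) {
    abort("time to progression needs at least 2 measurements",
          "eproximetry_insufficient_followup")
  }
  out <- function(ttp, censored, baseline = FALSE) {
    structure(list(ttp_days = ttp, censored = censored,
                   progressed_at_baseline = baseline),
              class = "progression_time")
  }
  if (v[1L] > threshold) {
    return(out(0, FALSE, baseline = TRUE))
  }
  j <- which(v >= threshold)
  if (!length(j)) {
    return(out(series$followup_end, TRUE))
  }
  j <- j[1L]
  if (v[j] == threshold) {
    return(out(d[j], FALSE))
  }
  # log-linear crossing between the flanking measurements
  ttp <- d[j - 1L] + (log(threshold) - log(v[j - 1L])) /
    (log(v[j]) - log(v[j - 1L])) * (d[j] - d[j - 1L])
  out(ttp, FALSE)
}

#' @export
print.progression_time <- function(x, ...) {
  cat(sprintf("Time to progression: %.2f days%s\n", x$ttp_days,
              if (x$censored) " (censored)" else ""))
  invisible(x)
}

#' Per-animal growth summary for a cohort table
#'
#' Applies volumetry, the day-5 response rule and the progression-threshold
#' analysis to a long growth table and returns one row per animal.
#'
#' @param growth Data frame with columns `animal_id`, `group`, `day`, and
#'   either `a_mm`, `b_mm`, `c_mm` or `volume_mm3`.
#' @param threshold Progression threshold, mm^3.
#' @param response_dv5 Responder cutoff on the day-5 percent change.
#' @return Data frame with columns `animal_id`, `group`, `baseline_volume_mm3`,
#'   `dv5_pct`, `responder`, `ttp_days`, `censored`.
#' @export
summarize_growth <- function(growth, threshold = 400, response_dv5 = 100) {
  validate_table(growth, "growth",
                 req = c("animal_id", "group", "day"),
                 numeric_cols = intersect(
                   c("day", "a_mm", "b_mm", "c_mm", "volume_mm3"),
                   names(growth)
                 ))
  has_diam <- all(c("a_mm", "b_mm", "c_mm") %in% names(growth))
  if (!has_diam && !("volume_mm3" %in% names(growth))) {
    abort("growth table needs a_mm/b_mm/c_mm or volume_mm3 columns",
          "eproximetry_validation")
  }
  ids <- unique(growth$animal_id)
  rows <- lapply(ids, function(id) {
    g <- growth[growth$animal_id == id, , drop = FALSE]
    g <- g[order(g$day), , drop = FALSE]
    ser <- if (has_diam) {
      growth_series(g$day, g$a_mm, g$b_mm, g$c_mm,
                    animal_id = id, group = g$group[1L])
    } else {
      growth_series(g$day, volume = g$volume_mm3,
                    animal_id = id, group = g$group[1L])
    }
    resp <- classify_response(ser, response_dv5 = response_dv5)
    ttp <- time_to_progression(ser, threshold = threshold)
    data.frame(
      animal_id = id, group = g$group[1L],
      baseline_volume_mm3 = volume_at(ser, 0),
      dv5_pct = resp$dv5_pct, responder = resp$responder,
      ttp_days = ttp$ttp_days, censored = ttp$censored
    )
  })
  do.call(rbind, rows)
}
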