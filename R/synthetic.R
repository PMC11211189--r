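#' Generative parameters for one study arm
#'
#' Describes how animals of one arm are simulated: the uniform range of
#' pre-irradiation tumor pO2, the through-origin slope and noise relating
#' the 5-min-post pO2 to the pre value (with a physiological ceiling
#' enforced by resampling), exponential tumor-growth kinetics, transient
#' post-treatment swelling, photosensitizer fluorescence, and the ordinal
#' mapping from percent oxygenation change to the 0-3 edema/erythema score.
#'
#' @param name One of `"dark_control"`, `"light_control"`,
#'   `"pdt_responder"`, `"pdt_nonresponder"`.
#' @param pre_po2_range Uniform bounds of pre-irradiation pO2, mmHg.
#' @param post_slope Through-origin slope of post- vs pre-irradiation pO2.
#' @param post_noise_sd SD of additive noise on the post value, mmHg.
#' @param post_cap Ceiling on the post value, mmHg; draws above it are
#'   rejected and redrawn rather than truncated, so the slope seen in the
#'   generated data stays at `post_slope`.
#' @param growth_rate_mean,growth_rate_sd Per-animal log-volume growth rate
#'   (per day), normal across animals, truncated at 0.01.
#' @param baseline_volume_meanlog,baseline_volume_sdlog Lognormal baseline
#'   (day-0) tumor volume, mm^3.
#' @param swelling Peak fractional volume inflation from treatment edema at
#'   day 1; decays linearly to zero by day 5.
#' @param fluor_mean Mean photosensitizer fluorescence, a.u.
#' @param fluor_sdlog Lognormal spread of fluorescence across animals.
#' @param fluor_delta_cor Correlation (on the latent normal scale) between
#'   an animal's photosensitizer fluorescence and its realized percent
#'   oxygenation change (0 = uncoupled).
#' @param edema_breaks Upper bin edges on the percent oxygenation change
#'   mapping to edema scores 0-3.
#' @param edema_noise Probability of a one-step ordinal perturbation of the
#'   edema score.
#' @param diameter_noise Multiplicative caliper noise per diameter (sd of
#'   log).
#' @return An object of class `group_params`.
#' @seealso [default_group_params()], [generate_cohort()]
#' @export
group_params <- function(name,
                         pre_po2_range = c(1, 15),
                         post_slope = 1,
                         post_noise_sd = 1.5,
                         post_cap = 20,
                         growth_rate_mean = 0.20,
                         growth_rate_sd = 0.03,
                         baseline_volume_meanlog = log(60),
                         baseline_volume_sdlog = 0.25,
                         swelling = 0,
                         fluor_mean = 100,
                         fluor_sdlog = 0.4,
                         fluor_delta_cor = 0,
                         edema_breaks = c(50, 150, 300),
                         edema_noise = 0.2,
                         diameter_noise = 0.03) {
  valid <- c("dark_control", "light_control", "pdt_responder", "pdt_nonresponder")
  if (!is.character(name) || length(name) != 1L || !(name %in% valid)) {
    abort(sprintf("group name must be one of: %s", paste(valid, collapse = ", ")),
          "eproximetry_config")
  }
  if (length(pre_po2_range) != 2L || pre_po2_range[1L] <= 0 ||
      pre_po2_range[2L] >= 40 || diff(pre_po2_range) <= 0) {
    abort("`pre_po2_range` must be increasing bounds within (0, 40) mmHg",
          "eproximetry_config")
  }
  stopifnot_number(post_slope, "post_slope", positive = TRUE)
  stopifnot_number(post_cap, "post_cap", positive = TRUE)
  if (abs(fluor_delta_cor) > 1) {
    abort("`fluor_delta_cor` must lie in [-1, 1]", "eproximetry_config")
  }
  structure(
    list(name = name, pre_po2_range = pre_po2_range, post_slope = post_slope,
         post_noise_sd = post_noise_sd, post_cap = post_cap,
         growth_rate_mean = growth_rate_mean, growth_rate_sd = growth_rate_sd,
         baseline_volume_meanlog = baseline_volume_meanlog,
         baseline_volume_sdlog = baseline_volume_sdlog,
         swelling = swelling, fluor_mean = fluor_mean,
         fluor_sdlog = fluor_sdlog,
         fluor_delta_cor = fluor_delta_cor,
         edema_breaks = edema_breaks, edema_noise = edema_noise,
         diameter_noise = diameter_noise),
    class = "group_params"
  )
}

#' Default generative parameters for the four study arms
#'
#' The defaults emulate the reported structure of a chlorophyllide-PDT
#' melanoma study: pre-irradiation pO2 uniform on 1-15 mmHg everywhere;
#' post/pre through-origin slopes of 2.5 (responders), 1.7
#' (non-responders), 1.5 (light controls, a ~50% mean rise from the
#' irradiation alone) and 1.0 (dark controls); a 20 mmHg post-irradiation
#' ceiling except in responders (40 mmHg); threefold higher photosensitizer
#' fluorescence in responders than non-responders, correlated within
#' responders with the realized percent oxygenation change; slowed
#' responder growth such that the day-5 volume change stays below 100% for
#' the large majority of responders while non-responders and controls
#' roughly double to sextuple; and marked, transient swelling in
#' responders.
#'
#' @return Named list of four [group_params()] objects.
#' @export
default_group_params <- function() {
  list(
    dark_control = group_params(
      "dark_control", post_slope = 1.0, post_cap = 20,
      growth_rate_mean = 0.20, growth_rate_sd = 0.03,
      fluor_mean = 100, swelling = 0
    ),
    light_control = group_params(
      "light_control", post_slope = 1.5, post_cap = 20,
      growth_rate_mean = 0.20, growth_rate_sd = 0.03,
      fluor_mean = 5, swelling = 0.1
    ),
    pdt_nonresponder = group_params(
      "pdt_nonresponder", post_slope = 1.7, post_cap = 20,
      growth_rate_mean = 0.19, growth_rate_sd = 0.02,
      fluor_mean = 100, swelling = 0.15
    ),
    pdt_responder = group_params(
      "pdt_responder", post_slope = 2.5, post_cap = 40,
      growth_rate_mean = 0.10, growth_rate_sd = 0.012,
      fluor_mean = 300, swelling = 0.5, fluor_delta_cor = 0.7
    )
  )
}

# One (pre, post) pair under the ceiling: joint rejection of (pre, noise)
# keeps the conditional mean of post at slope*pre over the accepted range.
draw_po2_pair <- function(p, slope_i) {
  for (i in seq_len(10000L)) {
    pre <- stats::runif(1L, p$pre_po2_range[1L], p$pre_po2_range[2L])
    post <- slope_i * pre + stats::rnorm(1L, 0, p$post_noise_sd)
    if (post <= p$post_cap) {
      return(c(pre = pre, post = max(post, 0)))
    }
  }
  abort(sprintf("could not draw a post pO2 under the %g mmHg ceiling for group %s",
                p$post_cap, p$name),
        "eproximetry_config")
}

#' Generate a seeded synthetic study cohort
#'
#' Simulates the four study arms (dark control, light control, PDT
#' responder, PDT non-responder) with the statistical structure described
#' in [default_group_params()]: per-animal pre/post irradiation pO2, a
#' daily pO2 series that returns to baseline from day +1, exponential
#' tumor growth with treatment-dependent kinetics and transient swelling,
#' photosensitizer fluorescence, and an ordinal edema/erythema score
#' driven by the percent oxygenation change.
#'
#' All randomness flows from `seed` through named substreams per data type
#' (latent animal factors, pO2, growth, edema), so generating one block is
#' unaffected by whether another is consumed.
#'
#' @param n_per_group Animals per arm (>= 1).
#' @param seed Integer master seed (`NULL` = use the current RNG stream).
#' @param params Named list of [group_params()]; see
#'   [default_group_params()].
#' @param measurement_days Caliper measurement days relative to PDT.
#' @param po2_series_days Days of the daily pO2 series (day 0 additionally
#'   carries the 5-min pre and post readings).
#' @return An object of class `synthetic_cohort`: list with data frames
#'   `animals` (`animal_id`, `group`, `po2_pre_mmHg`, `po2_post_mmHg`,
#'   `fluorescence_au`, `edema_score`), `growth` (long caliper table), and
#'   `po2_series`, plus the `seed` and `params` used.
#' @examples
#' coh <- generate_cohort(n_per_group = 5, seed = 1)
#' head(coh$animals)
#' @export
generate_cohort <- function(n_per_group = 12, seed = NULL,
                            params = default_group_params(),
                            measurement_days = 0:20,
                            po2_series_days = -2:5) {
  if (!is.numeric(n_per_group) || length(n_per_group) != 1L || n_per_group < 1) {
    abort("`n_per_group` must be >= 1", "eproximetry_config")
  }
  n_per_group <- as.integer(n_per_group)
  if (!is.list(params) || !length(params)) {
    abort("`params` must be a non-empty list of group_params", "eproximetry_config")
  }
  for (p in params) {
    if (!inherits(p, "group_params")) {
      abort("every element of `params` must be a group_params object",
            "eproximetry_config")
    }
  }
  groups <- unname(vapply(params, `[[`, character(1L), "name"))
  ids <- unname(unlist(lapply(
    groups, function(g) sprintf("%s_%03d", g, seq_len(n_per_group))
  )))
  grp_of <- rep(groups, each = n_per_group)
  n_total <- length(ids)

  po2 <- with_seed(substream_seed(seed, "po2"), {
    out <- matrix(0, n_total, 2L)
    for (i in seq_len(n_total)) {
      p <- params[[match(grp_of[i], groups)]]
      out[i, ] <- draw_po2_pair(p, p$post_slope)
    }
    out
  })
  pre <- po2[, 1L]
  post <- po2[, 2L]
  dpct <- 100 * (post - pre) / pre

  # photosensitizer load: lognormal around the group mean, with a latent
  # correlation to the realized oxygenation change (strong in responders:
  # more photosensitizer, stronger photodynamic oxygen surge)
  fluor <- with_seed(substream_seed(seed, "fluorescence"), {
    out <- numeric(n_total)
    for (g in groups) {
      p <- params[[match(g, groups)]]
      idx <- which(grp_of == g)
      eps <- stats::rnorm(length(idx))
      rho <- p$fluor_delta_cor
      z_dp <- if (length(idx) > 1L && stats::sd(dpct[idx]) > 0) {
        as.numeric(scale(dpct[idx]))
      } else {
        rep(0, length(idx))
      }
      z <- rho * z_dp + sqrt(1 - rho^2) * eps
      s <- p$fluor_sdlog
      out[idx] <- p$fluor_mean * exp(s * z - s^2 / 2)
    }
    out
  })

  edema <- with_seed(substream_seed(seed, "edema"), {
    vapply(seq_len(n_total), function(i) {
      p <- params[[match(grp_of[i], groups)]]
      score <- findInterval(dpct[i], p$edema_breaks)
      if (stats::runif(1L) < p$edema_noise) {
        score <- score + sample(c(-1L, 1L), 1L)
      }
      min(max(score, 0L), 3L)
    }, integer(1L))
  })

  growth <- with_seed(substream_seed(seed, "growth"), {
    rows <- vector("list", n_total)
    for (i in seq_len(n_total)) {
      p <- params[[match(grp_of[i], groups)]]
      r <- max(stats::rnorm(1L, p$growth_rate_mean, p$growth_rate_sd), 0.01)
      v0 <- stats::rlnorm(1L, p$baseline_volume_meanlog, p$baseline_volume_sdlog)
      t <- measurement_days
      swell <- ifelse(t >= 1, p$swelling * pmax(0, 1 - t / 5), 0)
      v <- v0 * exp(r * t) * (1 + swell)
      # fixed mild anisotropy per animal, product of shape factors = 1
      f <- exp(stats::rnorm(3L, 0, 0.08))
      f <- f / prod(f)^(1 / 3)
      d_eq <- (6 * v / pi)^(1 / 3)
      noise <- matrix(exp(stats::rnorm(3L * length(t), 0, p$diameter_noise)),
                      ncol = 3L)
      rows[[i]] <- data.frame(
        animal_id = ids[i], group = grp_of[i], day = t,
        a_mm = d_eq * f[1L] * noise[, 1L],
        b_mm = d_eq * f[2L] * noise[, 2L],
        c_mm = d_eq * f[3L] * noise[, 3L]
      )
    }
    do.call(rbind, rows)
  })

  po2_series <- with_seed(substream_seed(seed, "po2_series"), {
    rows <- vector("list", n_total)
    for (i in seq_len(n_total)) {
      days <- po2_series_days
      base <- pmax(pre[i] + stats::rnorm(length(days), 0, 0.8), 0)
      df <- data.frame(
        animal_id = ids[i], day = days, timepoint = "daily",
        po2_mmHg = base
      )
      # the 5-min peri-irradiation readings at day 0
      df$po2_mmHg[df$day == 0] <- pre[i]
      df$timepoint[df$day == 0] <- "pre_pdt"
      rows[[i]] <- rbind(
        df,
        data.frame(animal_id = ids[i], day = 0, timepoint = "post_pdt",
                   po2_mmHg = post[i])
      )
    }
    out <- do.call(rbind, rows)
    out[order(out$animal_id, out$day), ]
  })

  animals <- data.frame(
    animal_id = ids, group = grp_of,
    po2_pre_mmHg = pre, po2_post_mmHg = post,
    fluorescence_au = fluor, edema_score = edema
  )
  structure(
    list(animals = animals, growth = growth, po2_series = po2_series,
         seed = seed, n_per_group = n_per_group, params = params),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d animals (%d per group: %s), seed %s\n",
              nrow(x$animals), x$n_per_group,
              paste(unique(x$animals$group), collapse = ", "),
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

#' Generate EPR spectra for every pO2 reading of a cohort
#'
#' Maps each pre- and post-irradiation pO2 value through the calibration
#' line to a generating peak-to-peak linewidth, and simulates a noisy
#' first-derivative spectrum for it. Spectra are normalized to unit lobe
#' height, so `noise_frac` is the noise level as a fraction of the peak
#' amplitude.
#'
#' @param cohort A [generate_cohort()] result, or a data frame with columns
#'   `animal_id`, `po2_pre_mmHg`, `po2_post_mmHg`.
#' @param cal A [calibration_line()].
#' @param noise_frac Gaussian noise sd as a fraction of the lobe height.
#' @param span,n_points Acquisition grid passed to [simulate_spectrum()].
#' @param seed Integer master seed; each spectrum draws from its own
#'   substream.
#' @return An object of class `cohort_spectra`: list with `index` (data
#'   frame `animal_id`, `timepoint`, `po2_true`) and `spectra` (list of
#'   [epr_spectrum()], in index order).
#' @export
generate_spectra_for_cohort <- function(cohort, cal = lipc_calibration(),
                                        noise_frac = 0.02, span = 5000,
                                        n_points = 1024, seed = NULL) {
  animals <- if (inherits(cohort, "synthetic_cohort")) cohort$animals else cohort
  validate_table(animals, "cohort",
                 req = c("animal_id", "po2_pre_mmHg", "po2_post_mmHg"),
                 numeric_cols = c("po2_pre_mmHg", "po2_post_mmHg"))
  idx <- data.frame(
    animal_id = rep(animals$animal_id, each = 2L),
    timepoint = rep(c("pre", "post"), nrow(animals)),
    po2_true = as.vector(rbind(animals$po2_pre_mmHg, animals$po2_post_mmHg))
  )
  spectra <- lapply(seq_len(nrow(idx)), function(i) {
    gamma <- gamma_from_pp_width(linewidth_from_po2(idx$po2_true[i], cal))
    par <- lorentzian_params(gamma_hwhm = gamma,
                             amplitude = 8 * sqrt(3) * gamma / 9)
    simulate_spectrum(
      par, span = span, n_points = n_points,
      noise_sd = noise_frac, # unit lobe height by construction
      seed = substream_seed(seed, paste(idx$animal_id[i], idx$timepoint[i]))
    )
  })
  structure(list(index = idx, spectra = spectra), class = "cohort_spectra")
}

#' @export
print.cohort_spectra <- function(x, ...) {
  cat(sprintf("Cohort spectra: %d spectra for %d animals\n",
              length(x$spectra), length(unique(x$index$animal_id))))
  invisible(x)
}

#' Re-estimate pO2 from cohort spectra
#'
#' Runs a linewidth estimator over every spectrum and converts the
#' estimates back to pO2 through the calibration line — the measurement
#' arm of the pipeline.
#'
#' @param spectra A [generate_spectra_for_cohort()] result.
#' @param cal A [calibration_line()].
#' @param method `"least_squares"` (lineshape fit) or `"extrema"`.
#' @param tolerance Clamp band passed to [po2_from_linewidth()].
#' @return Data frame: `animal_id`, `timepoint`, `po2_true`,
#'   `pp_width_mG`, `po2_mmHg`.
#' @export
fit_cohort_spectra <- function(spectra, cal = lipc_calibration(),
                               method = c("least_squares", "extrema"),
                               tolerance = 3) {
  method <- match.arg(method)
  if (!inherits(spectra, "cohort_spectra")) {
    abort("`spectra` must come from generate_spectra_for_cohort()",
          "eproximetry_invalid_parameter")
  }
  est <- vapply(spectra$spectra, function(s) {
    lw <- switch(method,
      least_squares = fit_linewidth_least_squares(s),
      extrema = estimate_pp_width_extrema(s)
    )
    lw$pp_width
  }, numeric(1L))
  out <- spectra$index
  out$pp_width_mG <- est
  out$po2_mmHg <- po2_from_linewidth(est, cal, tolerance = tolerance)
  out
}

#' Reshape fitted spectra into per-animal pre/post pO2 columns
#'
#' @param fits A [fit_cohort_spectra()] result.
#' @return Data frame: `animal_id`, `po2_pre_mmHg`, `po2_post_mmHg`.
#' @export
measured_po2_table <- function(fits) {
  pre <- fits[fits$timepoint == "pre", c("animal_id", "po2_mmHg")]
  post <- fits[fits$timepoint == "post", c("animal_id", "po2_mmHg")]
  names(pre)[2L] <- "po2_pre_mmHg"
  names(post)[2L] <- "po2_post_mmHg"
  merge(pre, post, by = "animal_id", sort = FALSE)
}
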