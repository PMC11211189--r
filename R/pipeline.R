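#' Write a simulated study to disk
#'
#' Generates a seeded synthetic cohort and writes the interchange files
#' consumed by the analysis stage: `cohort.csv` (one row per animal),
#' `growth.csv` (long caliper table), `po2_series.csv`, optional
#' per-measurement spectrum CSVs under `spectra/`, and a `manifest.json`
#' recording the seed and generator settings. Numeric fields are written
#' with 6 significant digits, so re-running with the same seed reproduces
#' the files byte for byte.
#'
#' @param out_dir Output directory (created if needed).
#' @inheritParams generate_cohort
#' @param spectra Also simulate and write an EPR spectrum per pre/post pO2
#'   reading (slower, many files).
#' @param cal Calibration line used when `spectra = TRUE`.
#' @param spectra_noise_frac Spectrum noise as a fraction of lobe height.
#' @return Invisibly, a list with the generated `cohort` and the written
#'   file `paths`.
#' @seealso [analyze_study()]
#' @export
simulate_study <- function(out_dir, n_per_group = 12, seed = 1,
                           params = default_group_params(),
                           spectra = FALSE, cal = lipc_calibration(),
                           spectra_noise_frac = 0.02) {
  cohort <- generate_cohort(n_per_group = n_per_group, seed = seed,
                            params = params)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2L) != 0L) {
    abort(sprintf("output directory %s is not writable", out_dir),
          "eproximetry_io")
  }
  paths <- list(
    cohort = file.path(out_dir, "cohort.csv"),
    growth = file.path(out_dir, "growth.csv"),
    po2_series = file.path(out_dir, "po2_series.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_table_csv(cohort$animals, paths$cohort)
  write_table_csv(cohort$growth, paths$growth)
  write_table_csv(cohort$po2_series, paths$po2_series)
  spectrum_files <- character()
  if (spectra) {
    sp <- generate_spectra_for_cohort(cohort, cal = cal,
                                      noise_frac = spectra_noise_frac,
                                      seed = substream_seed(seed, "spectra"))
    spdir <- file.path(out_dir, "spectra")
    dir.create(spdir, showWarnings = FALSE)
    spectrum_files <- vapply(seq_along(sp$spectra), function(i) {
      f <- file.path(spdir, sprintf("%s_%s.csv", sp$index$animal_id[i],
                                    sp$index$timepoint[i]))
      write_spectrum(sp$spectra[[i]], f)
      f
    }, character(1L))
  }
  manifest <- list(
    seed = seed,
    n_per_group = cohort$n_per_group,
    groups = vapply(cohort$params, `[[`, character(1L), "name"),
    post_slopes = vapply(cohort$params, `[[`, numeric(1L), "post_slope"),
    spectra = spectra,
    package = "eproximetry",
    version = as.character(utils::packageVersion("eproximetry")),
    files = c(unlist(paths[c("cohort", "growth", "po2_series")]),
              spectrum_files)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(cohort = cohort, paths = paths))
}

# CSV writer at the pipeline's declared text precision (6 significant
# digits) so outputs are diffable across runs.
write_table_csv <- function(df, path, digits = 6) {
  for (col in names(df)) {
    if (is.double(df[[col]])) df[[col]] <- sprintf("%.*g", digits, df[[col]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fit linewidths and pO2 for a set of spectrum files
#'
#' Runs a linewidth estimator over each two-column spectrum CSV and
#' converts the widths to pO2 through the calibration line.
#'
#' @param paths Character vector of spectrum CSV paths.
#' @param cal A [calibration_line()].
#' @param method `"least_squares"` or `"extrema"`.
#' @return Data frame: `file`, `pp_width_mG`, `fit_residual`, `po2_mmHg`.
#' @export
fit_spectrum_files <- function(paths, cal = lipc_calibration(),
                               method = c("least_squares", "extrema")) {
  method <- match.arg(method)
  if (!length(paths)) {
    abort("no spectrum files given", "eproximetry_validation")
  }
  rows <- lapply(paths, function(f) {
    s <- read_spectrum(f)
    lw <- switch(method,
      least_squares = fit_linewidth_least_squares(s),
      extrema = estimate_pp_width_extrema(s)
    )
    data.frame(file = f, pp_width_mG = lw$pp_width,
               fit_residual = lw$fit_residual,
               po2_mmHg = po2_from_linewidth(lw$pp_width, cal))
  })
  do.call(rbind, rows)
}

read_table_arg <- function(x, what, req, numeric_cols) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) {
      abort(sprintf("%s file not found: %s", what, x), "eproximetry_io")
    }
    x <- utils::read.csv(x)
  }
  validate_table(x, what, req = req, numeric_cols = numeric_cols)
}

#' Run the outcome analysis over a cohort
#'
#' Drives the full evaluation of the oxygenation biomarker on an
#' animal-level cohort table: group means of pre/post pO2 and their
#' change, through-origin post-vs-pre slopes per arm and per recovered
#' response status, the favorable-oxygenation predictor and its per-clause
#' fractions among responders, Kaplan-Meier medians and the log-rank test
#' for favorable versus unfavorable oxygenation, response-status survival,
#' Student t-tests of the oxygen change, and the correlations of the
#' percent oxygen change with photosensitizer fluorescence (responders)
#' and with the edema score.
#'
#' Response calls and progression times are always re-derived from the
#' growth table via [summarize_growth()] — the analysis never trusts
#' generator labels. With a single experimental group the between-group
#' statistics are skipped with a warning.
#'
#' @param animals Animal-level data frame or CSV path with columns
#'   `animal_id`, `group`, `po2_pre_mmHg`, `po2_post_mmHg` and optionally
#'   `fluorescence_au`, `edema_score`.
#' @param growth Long caliper table or CSV path (see [summarize_growth()]).
#'   Optional if `animals` already carries `responder`, `ttp_days`,
#'   `censored` columns.
#' @param thresholds An [analysis_thresholds()].
#' @param pdt_groups Group labels that received photodynamic treatment.
#' @param control_group Label of the irradiated (light) control arm, used
#'   for the treatment-vs-control t-test when present.
#' @return An object of class `pdt_report`; print it for a plain-text
#'   summary, or persist it with [write_report()].
#' @examples
#' coh <- generate_cohort(n_per_group = 8, seed = 42)
#' rep <- analyze_study(coh$animals, coh$growth)
#' rep$slopes_by_response
#' @export
analyze_study <- function(animals, growth = NULL,
                          thresholds = analysis_thresholds(),
                          pdt_groups = c("pdt_responder", "pdt_nonresponder"),
                          control_group = "light_control") {
  animals <- read_table_arg(
    animals, "cohort",
    req = c("animal_id", "group", "po2_pre_mmHg", "po2_post_mmHg"),
    numeric_cols = c("po2_pre_mmHg", "po2_post_mmHg")
  )
  if (!is.null(growth)) {
    growth <- read_table_arg(growth, "growth",
                             req = c("animal_id", "group", "day"),
                             numeric_cols = "day")
    gsum <- summarize_growth(growth,
                             threshold = thresholds$progression_volume,
                             response_dv5 = thresholds$response_dv5)
    animals <- merge(animals,
                     gsum[, c("animal_id", "dv5_pct", "responder",
                              "ttp_days", "censored")],
                     by = "animal_id", sort = FALSE)
  }
  need_surv <- c("responder", "ttp_days", "censored")
  if (!all(need_surv %in% names(animals))) {
    abort("no growth data: supply `growth` or responder/ttp_days/censored columns",
          "eproximetry_validation")
  }

  dp <- suppressWarnings(delta_po2(animals$po2_pre_mmHg, animals$po2_post_mmHg))
  animals$delta_abs <- dp$delta_abs
  animals$delta_pct <- dp$delta_pct
  animals$favorable <- favorable_predictor(animals$po2_pre_mmHg,
                                           animals$po2_post_mmHg, thresholds)

  groups <- unique(animals$group)
  single_group <- length(groups) < 2L
  if (single_group) {
    warning("cohort has a single group; between-group statistics skipped")
  }

  group_summary <- do.call(rbind, lapply(groups, function(g) {
    a <- animals[animals$group == g, , drop = FALSE]
    data.frame(
      group = g, n = nrow(a),
      mean_po2_pre = mean(a$po2_pre_mmHg),
      mean_po2_post = mean(a$po2_post_mmHg),
      mean_delta_abs = mean(a$delta_abs),
      mean_delta_pct = mean(a$delta_pct, na.rm = TRUE),
      responders = sum(a$responder)
    )
  }))

  slope_rows <- lapply(groups, function(g) {
    a <- animals[animals$group == g, , drop = FALSE]
    if (nrow(a) < 2L) return(NULL)
    s <- through_origin_slope(a$po2_pre_mmHg, a$po2_post_mmHg)
    data.frame(group = g, slope = s$estimate, se = s$se,
               p_value = s$p_value, n = s$n)
  })
  slopes_by_group <- do.call(rbind, slope_rows)

  pdt <- animals[animals$group %in% pdt_groups, , drop = FALSE]
  if (!nrow(pdt)) {
    # no explicitly treated arms: fall back to analyzing every animal
    pdt <- animals
  }

  slopes_by_response <- NULL
  fractions <- NULL
  survival_by_predictor <- NULL
  survival_by_response <- NULL
  t_tests <- list()
  correlations <- list()

  resp <- pdt[pdt$responder, , drop = FALSE]
  nonresp <- pdt[!pdt$responder, , drop = FALSE]
  if (nrow(resp) >= 2L && nrow(nonresp) >= 2L) {
    sr <- through_origin_slope(resp$po2_pre_mmHg, resp$po2_post_mmHg)
    sn <- through_origin_slope(nonresp$po2_pre_mmHg, nonresp$po2_post_mmHg)
    slopes_by_response <- data.frame(
      status = c("responder", "non_responder"),
      slope = c(sr$estimate, sn$estimate),
      se = c(sr$se, sn$se),
      p_value = c(sr$p_value, sn$p_value),
      n = c(sr$n, sn$n)
    )
    t_tests$delta_abs_responder_vs_nonresponder <-
      two_sample_t(resp$delta_abs, nonresp$delta_abs)
  }
  if (nrow(resp)) {
    fractions <- predictor_fractions(pdt$po2_pre_mmHg, pdt$po2_post_mmHg,
                                     pdt$responder, thresholds)
  }

  fav <- pdt[pdt$favorable, , drop = FALSE]
  unfav <- pdt[!pdt$favorable, , drop = FALSE]
  if (nrow(fav) && nrow(unfav)) {
    survival_by_predictor <- km_median_and_logrank(
      unfav$ttp_days, fav$ttp_days,
      event_a = !unfav$censored, event_b = !fav$censored,
      labels = c("unfavorable", "favorable")
    )
  }
  if (nrow(resp) && nrow(nonresp)) {
    survival_by_response <- km_median_and_logrank(
      nonresp$ttp_days, resp$ttp_days,
      event_a = !nonresp$censored, event_b = !resp$censored,
      labels = c("non_responder", "responder")
    )
  }

  if (!single_group && control_group %in% animals$group && nrow(pdt) >= 2L) {
    ctrl <- animals[animals$group == control_group, , drop = FALSE]
    if (nrow(ctrl) >= 2L) {
      t_tests$delta_abs_pdt_vs_light_control <-
        two_sample_t(pdt$delta_abs, ctrl$delta_abs)
    }
  }

  if ("fluorescence_au" %in% names(pdt) && nrow(resp) >= 3L) {
    correlations$delta_pct_vs_fluorescence_responders <-
      pearson_correlation(resp$fluorescence_au, resp$delta_pct)
  }
  if ("edema_score" %in% names(pdt) && nrow(pdt) >= 3L &&
      stats::sd(pdt$edema_score) > 0) {
    correlations$delta_pct_vs_edema <-
      pearson_correlation(pdt$delta_pct, pdt$edema_score)
  }

  structure(
    list(
      animals = animals,
      thresholds = thresholds,
      group_summary = group_summary,
      slopes_by_group = slopes_by_group,
      slopes_by_response = slopes_by_response,
      predictor_fractions = fractions,
      survival_by_predictor = survival_by_predictor,
      survival_by_response = survival_by_response,
      t_tests = t_tests,
      correlations = correlations,
      single_group = single_group
    ),
    class = "pdt_report"
  )
}

format_report <- function(x) {
  th <- x$thresholds
  out <- c(
    "Tumor oxygenation after PDT: outcome analysis",
    sprintf("  %d animals in %d group(s); predictor: pO2 > %g mmHg or dpO2 > %g%%",
            nrow(x$animals), nrow(x$group_summary), th$po2_cut, th$delta_pct_cut),
    "",
    "Group summary (means):"
  )
  gs <- x$group_summary
  out <- c(out, sprintf(
    "  %-18s n=%3d  pO2 pre %5.2f -> post %5.2f mmHg  (d %+5.2f mmHg, %+6.1f%%)  responders %d",
    gs$group, gs$n, gs$mean_po2_pre, gs$mean_po2_post, gs$mean_delta_abs,
    gs$mean_delta_pct, gs$responders
  ))
  if (!is.null(x$slopes_by_response)) {
    sb <- x$slopes_by_response
    out <- c(out, "", "Through-origin slope of post vs pre pO2:")
    out <- c(out, sprintf("  %-14s slope %.3f (se %.3f, n=%d)",
                          sb$status, sb$slope, sb$se, sb$n))
  }
  if (!is.null(x$predictor_fractions)) {
    fr <- x$predictor_fractions
    out <- c(out, "", "Predictor clauses among responders:")
    out <- c(out, sprintf("  %-12s %d/%d (%.0f%%)", fr$clause, fr$count, fr$n,
                          fr$percent))
  }
  if (!is.null(x$survival_by_predictor)) {
    sv <- x$survival_by_predictor
    out <- c(out, "", sprintf(
      "Time to progression (favorable vs unfavorable oxygenation): medians %.3g vs %.3g days (%+.0f%%), log-rank p = %.3g",
      sv$medians[["favorable"]], sv$medians[["unfavorable"]],
      sv$pct_increase, sv$p_value
    ))
  }
  for (nm in names(x$t_tests)) {
    tt <- x$t_tests[[nm]]
    out <- c(out, sprintf("t-test %s: t = %.3g, p = %.3g", nm, tt$estimate,
                          tt$p_value))
  }
  for (nm in names(x$correlations)) {
    ct <- x$correlations[[nm]]
    out <- c(out, sprintf("correlation %s: r = %.3g, p = %.3g (n=%d)", nm,
                          ct$estimate, ct$p_value, ct$n))
  }
  out
}

#' @export
print.pdt_report <- function(x, ...) {
  cat(paste(format_report(x), collapse = "\n"), "\n")
  invisible(x)
}

#' Persist an analysis report
#'
#' Writes a tidy statistics CSV (`report_stats.csv`), the per-animal table
#' with derived columns (`animals_derived.csv`), and the plain-text summary
#' (`summary.txt`).
#'
#' @param report A [analyze_study()] result.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  if (!inherits(report, "pdt_report")) {
    abort("`report` must come from analyze_study()", "eproximetry_invalid_parameter")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  add <- function(section, name, estimate, p_value = NA_real_, n = NA_real_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      section = section, name = name, estimate = estimate,
      p_value = p_value, n = n
    )
  }
  gs <- report$group_summary
  for (i in seq_len(nrow(gs))) {
    add("group_means", paste0(gs$group[i], ".delta_abs"), gs$mean_delta_abs[i],
        n = gs$n[i])
    add("group_means", paste0(gs$group[i], ".delta_pct"), gs$mean_delta_pct[i],
        n = gs$n[i])
  }
  if (!is.null(report$slopes_by_response)) {
    sb <- report$slopes_by_response
    for (i in seq_len(nrow(sb))) {
      add("through_origin_slope", sb$status[i], sb$slope[i], sb$p_value[i],
          sb$n[i])
    }
  }
  if (!is.null(report$predictor_fractions)) {
    fr <- report$predictor_fractions
    for (i in seq_len(nrow(fr))) {
      add("predictor_fraction_pct", fr$clause[i], fr$percent[i], n = fr$n[i])
    }
  }
  if (!is.null(report$survival_by_predictor)) {
    sv <- report$survival_by_predictor
    add("ttp_median_days", "unfavorable", sv$medians[["unfavorable"]],
        n = sv$n[["unfavorable"]])
    add("ttp_median_days", "favorable", sv$medians[["favorable"]],
        n = sv$n[["favorable"]])
    add("logrank", "favorable_vs_unfavorable", sv$chisq, sv$p_value,
        sum(sv$n))
  }
  for (nm in names(report$t_tests)) {
    tt <- report$t_tests[[nm]]
    add("t_test", nm, tt$estimate, tt$p_value, sum(tt$n))
  }
  for (nm in names(report$correlations)) {
    ct <- report$correlations[[nm]]
    add("correlation", nm, ct$estimate, ct$p_value, ct$n)
  }
  stats_df <- do.call(rbind, rows)
  paths <- list(
    stats = file.path(out_dir, "report_stats.csv"),
    animals = file.path(out_dir, "animals_derived.csv"),
    summary = file.path(out_dir, "summary.txt")
  )
  write_table_csv(stats_df, paths$stats)
  write_table_csv(report$animals, paths$animals)
  writeLines(format_report(report), paths$summary)
  invisible(paths)
}
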