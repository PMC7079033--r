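#' Analysis parameters
#'
#' Thresholds of the bias analysis, bundled so every stage and the output
#' metadata see the same values.
#'
#' @param min_fixation_ms Minimum fixation duration, ms.
#' @param merge_gap_ms Maximum merged interruption, ms.
#' @param unchanged_tol Unchanged tolerance for adjustment classification, days.
#' @param discordance_denominator `"max"` or `"mean"`.
#' @param include_intermediate Include intermediate-look values in EFW
#'   candidate sets.
#' @param repeat_unit `"measurement"` or `"series"` for [repeat_comparison()].
#' @param ci_method `"wald"` or `"wilson"` for swing-proportion intervals.
#' @return List of class `analysis_params`.
#' @export
analysis_params <- function(min_fixation_ms = 100, merge_gap_ms = 400,
                            unchanged_tol = 0.25,
                            discordance_denominator = "max",
                            include_intermediate = FALSE,
                            repeat_unit = "measurement",
                            ci_method = "wald") {
  structure(list(min_fixation_ms = min_fixation_ms, merge_gap_ms = merge_gap_ms,
                 unchanged_tol = unchanged_tol,
                 discordance_denominator = discordance_denominator,
                 include_intermediate = include_intermediate,
                 repeat_unit = repeat_unit, ci_method = ci_method),
            class = "analysis_params")
}

#' Run the full expected-value-bias analysis on a cohort
#'
#' Ties the stages together: fixation detection and bias events per episode,
#' repeat grouping, deviation records, the cohort incidence table, paired
#' before/after tests with the variance-reduction (Levene) test, the
#' repeated-vs-not comparison, covariate-adjusted models (when BMI and
#' experience are available), and the EFW-bounds clinical impact.
#'
#' @param cohort Either a [simulate_cohort()] result or a list with tibbles
#'   `sessions`, `episodes`, `gaze`.
#' @param std A [growth_standard()].
#' @param params An [analysis_params()] bundle.
#' @param quiet Suppress per-stage log lines.
#' @return Object of class `scanbias_analysis`: list with `records`,
#'   `incidence`, `before_after`, `repeats`, `models` (or `NULL`), `efw`,
#'   `params`, `n_scans`.
#' @export
analyze_cohort <- function(cohort, std = default_growth_standard(),
                           params = analysis_params(), quiet = FALSE) {
  sessions <- cohort$sessions; episodes <- cohort$episodes; gaze <- cohort$gaze
  if (is.null(sessions) || !nrow(sessions)) abort("no sessions to analyze")
  if (is.null(episodes) || !nrow(episodes)) abort("no measurement episodes to analyze")
  if (is.null(gaze) || !nrow(gaze)) abort("no gaze samples to analyze")
  say <- function(...) if (!quiet) inform(paste0("[scanbias] ", ...))
  say("input: ", nrow(sessions), " sessions, ", nrow(episodes), " episodes, ",
      nrow(gaze), " gaze samples")

  events <- detect_bias_events(episodes, gaze, params$min_fixation_ms,
                               params$merge_gap_ms)
  say("bias events: ", sum(events$biased), "/", nrow(events), " episodes biased")

  records <- deviation_records(episodes, sessions, gaze, std,
                               params$min_fixation_ms, params$merge_gap_ms,
                               params$unchanged_tol)
  incidence <- incidence_table(records, n_scans = nrow(sessions))
  before_after <- before_after_tests(records)
  repeats <- repeat_comparison(records, unit = params$repeat_unit)
  models <- if (all(c("bmi", "experience_years") %in% names(records)) &&
                sum(records$biased) >= 5L) {
    tryCatch(adjusted_models(records), error = function(e) {
      say("adjusted models skipped: ", conditionMessage(e)); NULL
    })
  } else NULL
  impact <- efw_impact(events, sessions, std,
                       denominator = params$discordance_denominator,
                       include_intermediate = params$include_intermediate,
                       ci_method = params$ci_method)
  say("EFW impact: ", impact$cohort$n_scans, " scans summarized, ",
      impact$cohort$n_excluded, " excluded")

  structure(list(records = records, incidence = incidence,
                 before_after = before_after, repeats = repeats,
                 models = models, efw = impact, params = params,
                 n_scans = nrow(sessions)),
            class = "scanbias_analysis")
}

#' @export
print.scanbias_analysis <- function(x, ...) {
  tot <- x$incidence[x$incidence$plane == "Total", ]
  cat("Expected-value bias analysis:", x$n_scans, "scans,", tot$n_saved,
      "saved measurements\n")
  cat(sprintf("  biased: %.1f%%  toward: %.1f%%  away: %.1f%%  mean adjustment: %.1f d\n",
              tot$pct_biased, tot$pct_toward, tot$pct_away, tot$adjustment_mean))
  cat(sprintf("  EFW discordance: %.1f%% +/- %.1f%%; Z difference %.2f +/- %.2f\n",
              x$efw$cohort$discordance_mean, x$efw$cohort$discordance_sd,
              x$efw$cohort$z_diff_mean, x$efw$cohort$z_diff_sd))
  invisible(x)
}

#' @describeIn analyze_cohort Tidy method: the per-measurement deviation
#'   records.
#' @param x A `scanbias_analysis`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.scanbias_analysis <- function(x, ...) x$records

#' @describeIn analyze_cohort Glance method: one-row cohort summary.
#' @exportS3Method generics::glance
glance.scanbias_analysis <- function(x, ...) {
  tot <- x$incidence[x$incidence$plane == "Total", ]
  pooled <- x$before_after[x$before_after$plane == "Pooled", ]
  tibble::tibble(
    n_scans = x$n_scans, n_saved = tot$n_saved, n_repeat = tot$n_repeat,
    pct_biased = tot$pct_biased, pct_toward = tot$pct_toward,
    pct_away = tot$pct_away, adjustment_mean = tot$adjustment_mean,
    adjustment_sd = tot$adjustment_sd,
    wilcoxon_p = pooled$wilcoxon_p, levene_p = pooled$levene_p,
    discordance_mean = x$efw$cohort$discordance_mean,
    discordance_sd = x$efw$cohort$discordance_sd,
    z_diff_mean = x$efw$cohort$z_diff_mean,
    pct_sga_aga_swing = x$efw$cohort$pct_sga_aga_swing,
    pct_aga_lga_swing = x$efw$cohort$pct_aga_lga_swing
  )
}

#' Deviation distributions before and after the bias event
#'
#' Per-plane distributions of the signed deviation of observed from expected
#' GA at the first look at the measurement box and at save, for biased
#' measurements.
#'
#' @param records Deviation records.
#' @return A ggplot object.
#' @export
plot_before_after <- function(records) {
  df <- records %>%
    dplyr::filter(.data$biased) %>%
    dplyr::select("plane", "d_before", "d_after") %>%
    tidyr::pivot_longer(c("d_before", "d_after"), names_to = "stage",
                        values_to = "deviation") %>%
    dplyr::mutate(stage = factor(.data$stage, levels = c("d_before", "d_after"),
                                 labels = c("first look", "saved")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$deviation, fill = .data$stage)) +
    ggplot2::geom_density(alpha = 0.45, colour = NA) +
    ggplot2::facet_wrap(~plane, scales = "free_y") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(x = "observed - expected GA (days)", y = "density",
                  fill = NULL,
                  title = "Deviation from expected GA before and after bias event") +
    ggplot2::theme_minimal()
}

#' Deviation distributions for repeated vs non-repeated measurements
#'
#' @param records Deviation records.
#' @return A ggplot object.
#' @export
plot_repeat_deviation <- function(records) {
  df <- records %>%
    dplyr::mutate(repeated = ifelse(.data$is_repeat, "repeated", "not repeated"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$repeated, y = .data$abs_d_after,
                                   fill = .data$repeated)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, show.legend = FALSE) +
    ggplot2::facet_wrap(~plane) +
    ggplot2::labs(x = NULL, y = "|observed - expected GA| (days)",
                  title = "Deviation from expected GA by repeat status") +
    ggplot2::theme_minimal()
}

#' @describeIn analyze_cohort Autoplot method; `type` selects
#'   `"before_after"` (default) or `"repeats"`.
#' @param object A `scanbias_analysis`.
#' @param type Which figure to draw.
#' @exportS3Method ggplot2::autoplot
autoplot.scanbias_analysis <- function(object, type = c("before_after", "repeats"),
                                       ...) {
  type <- match.arg(type)
  switch(type,
         before_after = plot_before_after(object$records),
         repeats = plot_repeat_deviation(object$records))
}

#' Run the pipeline from a configuration file
#'
#' The run configuration (YAML or JSON file, or an equivalent list) either
#' names input files (`input: {sessions, episodes, gaze}`) or carries a
#' `simulate:` block of [simulation_config()] fields; exactly one of the two
#' must be present. Optional blocks: `standard: {path, name}` selecting the
#' growth standard, `params:` with [analysis_params()] fields, `seed` (for the
#' simulate block) and `output_dir`.
#'
#' Outputs written to `output_dir`: `cohort_summary.csv` (incidence table),
#' `scan_summaries.csv` (per-scan EFW bounds), `tests.json` (all test
#' statistics, p-values and CIs), `run_metadata.json` (config hash, seed,
#' parameter defaults in force, package version) and the two figures as PNG.
#' Nothing is written until the whole analysis has succeeded; any data error
#' aborts the run.
#'
#' @param config Path to a YAML/JSON run configuration, or a list.
#' @param output_dir Overrides the configured output directory.
#' @param quiet Suppress stage logging.
#' @return The `scanbias_analysis`, invisibly, with the output directory in
#'   attribute `"output_dir"`.
#' @export
run_pipeline <- function(config, output_dir = NULL, quiet = FALSE) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    } else {
      yaml::read_yaml(config)
    }
  }
  has_input <- !is.null(config$input); has_sim <- !is.null(config$simulate)
  if (has_input == has_sim) {
    abort("run config must have exactly one of `input` or `simulate`")
  }
  std <- if (!is.null(config$standard$path)) {
    read_growth_standard(config$standard$path, config$standard$name)
  } else {
    default_growth_standard()
  }
  params <- do.call(analysis_params, config$params %||% list())

  if (has_sim) {
    sim_args <- config$simulate
    if (!is.null(config$seed)) sim_args$seed <- config$seed
    cfg <- do.call(simulation_config, sim_args)
    cohort <- simulate_cohort(cfg, std)
    seed_used <- cfg$seed
  } else {
    cohort <- list(sessions = read_sessions_csv(config$input$sessions),
                   episodes = read_episodes_jsonl(config$input$episodes),
                   gaze = read_gaze_csv(config$input$gaze))
    seed_used <- config$seed %||% NA
  }

  analysis <- analyze_cohort(cohort, std, params, quiet = quiet)

  out_dir <- output_dir %||% config$output_dir
  if (!is.null(out_dir)) {
    write_results(analysis, out_dir, config = config, seed = seed_used,
                  std_name = std$name)
  }
  attr(analysis, "output_dir") <- out_dir
  invisible(analysis)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  unname(tools::md5sum(tmp))
}

#' Write an analysis result bundle to disk
#'
#' @param analysis A `scanbias_analysis`.
#' @param dir Output directory (created if needed).
#' @param config The run configuration that produced the analysis (hashed into
#'   the metadata).
#' @param seed Seed used for any simulation.
#' @param std_name Growth-standard identifier.
#' @return `dir`, invisibly.
#' @export
write_results <- function(analysis, dir, config = list(), seed = NA,
                          std_name = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  stamp <- function(df) dplyr::mutate(df, config_hash = hash, seed = seed)
  readr::write_csv(stamp(tibble::as_tibble(analysis$incidence)),
                   file.path(dir, "cohort_summary.csv"))
  readr::write_csv(stamp(analysis$efw$scan_summaries),
                   file.path(dir, "scan_summaries.csv"))
  tests <- list(
    config_hash = hash, seed = seed,
    before_after = analysis$before_after,
    repeat_comparison = analysis$repeats,
    models = if (!is.null(analysis$models)) {
      list(regression = analysis$models$regression, anova = analysis$models$anova,
           n_dropped = analysis$models$n_dropped)
    },
    efw_cohort = analysis$efw$cohort,
    swing_ci = analysis$efw$swing_ci,
    multiple_testing_correction = "none (per-comparison reporting)"
  )
  jsonlite::write_json(tests, file.path(dir, "tests.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")
  meta <- list(config_hash = hash, seed = seed, standard = std_name,
               params = unclass(analysis$params),
               package_version = as.character(utils::packageVersion("scanbias")),
               r_version = as.character(getRversion()))
  jsonlite::write_json(meta, file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  suppressMessages({
    ggplot2::ggsave(file.path(dir, "deviation_before_after.png"),
                    plot_before_after(analysis$records), width = 8, height = 4, dpi = 120)
    ggplot2::ggsave(file.path(dir, "repeat_deviation.png"),
                    plot_repeat_deviation(analysis$records), width = 8, height = 4, dpi = 120)
  })
  invisible(dir)
}
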