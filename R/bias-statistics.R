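#' Cohort incidence table
#'
#' Per-plane and total counts of saved and repeat measurements, measurements
#' per scan (mean and SD across scans, scans without the plane counting zero),
#' the proportion of biased measurements, the proportions adjusted toward and
#' away from the expected GA, and the mean adjustment toward the expected GA in
#' gestational days. Percentages toward/away are reported against two
#' denominators: all saved measurements (`pct_toward`, `pct_away`) and biased
#' measurements only (`pct_toward_biased`, `pct_away_biased`). The mean
#' adjustment is likewise reported over biased measurements
#' (`adjustment_mean`, `adjustment_sd`) and over all saved measurements with
#' unbiased ones contributing zero (`adjustment_mean_all`). The `p_value`
#' column is the paired Wilcoxon signed-rank test of `|d_before|` vs
#' `|d_after|` among biased measurements.
#'
#' @param records Deviation records from [deviation_records()].
#' @param n_scans Number of scans in the cohort; defaults to the number of
#'   distinct `scan_id`s in `records`.
#' @return Tibble with one row per plane plus a `Total` row.
#' @export
incidence_table <- function(records, n_scans = dplyr::n_distinct(records$scan_id)) {
  if (!nrow(records)) abort("no deviation records supplied")
  scans <- unique(records$scan_id)
  one_block <- function(df, label) {
    per_scan <- table(factor(df$scan_id, levels = scans))
    bi <- df[df$biased, , drop = FALSE]
    pw <- paired_wilcoxon_p(bi$abs_d_before, bi$abs_d_after)
    tibble::tibble(
      plane = label,
      n_saved = nrow(df),
      n_repeat = sum(df$is_repeat),
      per_scan_mean = nrow(df) / n_scans,
      per_scan_sd = stats::sd(as.numeric(per_scan)),
      pct_biased = 100 * mean(df$biased),
      pct_toward = 100 * mean(df$adjustment == "toward"),
      pct_away = 100 * mean(df$adjustment == "away"),
      pct_toward_biased = 100 * mean(bi$adjustment == "toward"),
      pct_away_biased = 100 * mean(bi$adjustment == "away"),
      adjustment_mean = mean(bi$adjustment_days),
      adjustment_sd = stats::sd(bi$adjustment_days),
      adjustment_mean_all = sum(bi$adjustment_days) / nrow(df),
      p_value = pw
    )
  }
  out <- records %>%
    dplyr::group_by(.data$plane) %>%
    dplyr::group_map(~ one_block(.x %>% dplyr::mutate(plane = .y$plane), .y$plane)) %>%
    dplyr::bind_rows() %>%
    dplyr::arrange(match(.data$plane, PLANES))
  out <- dplyr::bind_rows(out, one_block(records, "Total"))
  class(out) <- c("scanbias_incidence", class(out))
  out
}

two_sided_or_na <- function(expr) {
  tryCatch(suppressWarnings(expr), error = function(e) NA_real_)
}

# All-zero paired differences carry no evidence of a shift: p = 1.
paired_wilcoxon_p <- function(before, after) {
  if (length(before) < 2L) return(NA_real_)
  d <- before - after
  if (all(d == 0)) return(1)
  if (stats::sd(d) == 0) return(NA_real_)
  two_sided_or_na(stats::wilcox.test(before, after, paired = TRUE)$p.value)
}

paired_t_p <- function(before, after) {
  if (length(before) < 2L) return(NA_real_)
  d <- before - after
  if (all(d == 0)) return(1)
  if (stats::sd(d) == 0) return(NA_real_)
  two_sided_or_na(stats::t.test(before, after, paired = TRUE)$p.value)
}

#' Paired before/after deviation tests
#'
#' Among biased measurements, compares the absolute deviation of the observed
#' from the expected GA at the first look (`|d_before|`) with that at save
#' (`|d_after|`), per plane and pooled: paired t-test and paired Wilcoxon
#' signed-rank test for location, and a Levene test (centered at the median) of
#' the signed deviations `d_before` vs `d_after` for the variance reduction
#' once the operator is biased. `effect_dz` is the paired Cohen's d (mean
#' paired difference over the SD of differences).
#'
#' @param records Deviation records; only biased rows enter.
#' @param by_plane Also compute per-plane rows (default `TRUE`; a pooled row is
#'   always included).
#' @return Tibble with columns `plane`, `n_pairs`, means and SDs before/after,
#'   `mean_adjustment`, `t_p`, `wilcoxon_p`, `levene_p`, `effect_dz`,
#'   `var_before`, `var_after`. Groups with fewer than 2 pairs yield `NA`
#'   statistics.
#' @export
before_after_tests <- function(records, by_plane = TRUE) {
  bi <- records[records$biased, , drop = FALSE]
  one <- function(df, label) {
    n <- nrow(df)
    if (n < 2L) {
      return(tibble::tibble(plane = label, n_pairs = n, mean_abs_before = NA_real_,
                            sd_abs_before = NA_real_, mean_abs_after = NA_real_,
                            sd_abs_after = NA_real_, mean_adjustment = NA_real_,
                            t_p = NA_real_, wilcoxon_p = NA_real_, levene_p = NA_real_,
                            effect_dz = NA_real_, var_before = NA_real_, var_after = NA_real_))
    }
    diffs <- df$abs_d_before - df$abs_d_after
    t_p <- paired_t_p(df$abs_d_before, df$abs_d_after)
    w_p <- paired_wilcoxon_p(df$abs_d_before, df$abs_d_after)
    lev <- levene_two_group(df$d_before, df$d_after)
    tibble::tibble(
      plane = label, n_pairs = n,
      mean_abs_before = mean(df$abs_d_before), sd_abs_before = stats::sd(df$abs_d_before),
      mean_abs_after = mean(df$abs_d_after), sd_abs_after = stats::sd(df$abs_d_after),
      mean_adjustment = mean(diffs),
      t_p = t_p, wilcoxon_p = w_p, levene_p = lev,
      effect_dz = if (stats::sd(diffs) > 0) mean(diffs) / stats::sd(diffs) else NA_real_,
      var_before = stats::var(df$d_before), var_after = stats::var(df$d_after)
    )
  }
  out <- list()
  if (by_plane) {
    out <- bi %>%
      dplyr::group_by(.data$plane) %>%
      dplyr::group_map(~ one(.x, .y$plane)) %>%
      dplyr::bind_rows() %>%
      dplyr::arrange(match(.data$plane, PLANES)) %>%
      list()
  }
  dplyr::bind_rows(c(out, list(one(bi, "Pooled"))))
}

levene_two_group <- function(before, after) {
  vals <- c(before, after)
  grp <- factor(rep(c("before", "after"), c(length(before), length(after))))
  if (length(before) < 2L || stats::sd(vals) == 0) return(NA_real_)
  two_sided_or_na(car::leveneTest(vals ~ grp, center = stats::median)[1, "Pr(>F)"])
}

#' Repeated vs non-repeated measurement comparison
#'
#' Per plane, the mean and SD of the absolute deviation of observed from
#' expected GA (`|d_after|`, i.e. of the saved value) for measurements that
#' belong to a repeated series vs those that do not, with an unpaired
#' Mann-Whitney U test. Each saved measurement contributes its own deviation;
#' "repeated" follows [group_repeats()] (all measurements after the first of a
#' plane within a scan). With `unit = "series"` the alternative grouping is
#' used: every measurement of a plane measured more than once in the scan
#' (including the first) counts as repeated.
#'
#' @param records Deviation records.
#' @param unit `"measurement"` (default) or `"series"`; see Details.
#' @return Tibble with per-plane and pooled rows; a group without observations
#'   is marked by `NA` statistics and its `n` of 0.
#' @export
repeat_comparison <- function(records, unit = c("measurement", "series")) {
  unit <- match.arg(unit)
  rec <- records
  if (unit == "series") {
    rec <- rec %>%
      dplyr::group_by(.data$scan_id, .data$plane) %>%
      dplyr::mutate(is_repeat = dplyr::n() > 1L) %>%
      dplyr::ungroup()
  }
  one <- function(df, label) {
    rep_d <- df$abs_d_after[df$is_repeat]
    non_d <- df$abs_d_after[!df$is_repeat]
    p <- if (length(rep_d) >= 1L && length(non_d) >= 1L &&
             stats::sd(c(rep_d, non_d)) > 0) {
      two_sided_or_na(stats::wilcox.test(rep_d, non_d)$p.value)
    } else NA_real_
    tibble::tibble(
      plane = label,
      n_repeated = length(rep_d), n_not_repeated = length(non_d),
      mean_repeated = if (length(rep_d)) mean(rep_d) else NA_real_,
      sd_repeated = if (length(rep_d) > 1) stats::sd(rep_d) else NA_real_,
      mean_not_repeated = if (length(non_d)) mean(non_d) else NA_real_,
      sd_not_repeated = if (length(non_d) > 1) stats::sd(non_d) else NA_real_,
      mann_whitney_p = p
    )
  }
  per <- rec %>%
    dplyr::group_by(.data$plane) %>%
    dplyr::group_map(~ one(.x, .y$plane)) %>%
    dplyr::bind_rows() %>%
    dplyr::arrange(match(.data$plane, PLANES))
  dplyr::bind_rows(per, one(rec, "Pooled"))
}

#' Covariate-adjusted models
#'
#' Two models mirroring the study's multivariable analyses, both adjusted for
#' maternal BMI and operator scanning experience:
#' a multiple linear regression of the saved deviation on the first-look
#' deviation among biased measurements
#' (`d_after ~ d_before + bmi + experience_years`), and a multifactor ANOVA of
#' the absolute saved deviation on repeat status plus the covariates. Rows with
#' missing covariates are dropped listwise and counted.
#'
#' @param records Deviation records with `bmi` and `experience_years`.
#' @return List of class `scanbias_models` with elements `regression` (tidy
#'   coefficient table with 95% CIs), `anova` (tidy ANOVA table), `n_dropped`
#'   (rows lost to missing covariates) and the fitted objects `fit_regression`,
#'   `fit_anova`.
#' @export
adjusted_models <- function(records) {
  need <- c("bmi", "experience_years")
  miss <- setdiff(need, names(records))
  if (length(miss)) abort(paste0("records missing covariate column(s): ", paste(miss, collapse = ", ")))
  bi <- records[records$biased, , drop = FALSE]
  cc <- stats::complete.cases(bi[, c("d_before", "d_after", need)])
  n_dropped <- sum(!cc)
  bi <- bi[cc, , drop = FALSE]
  if (nrow(bi) < 5L) abort("too few complete biased records to fit adjusted models")
  for (v in c("d_before", need)) {
    if (stats::sd(bi[[v]]) == 0) {
      abort(paste0("singular design: predictor `", v, "` has zero variance"))
    }
  }
  fit <- stats::lm(d_after ~ d_before + bmi + experience_years, data = bi)
  if (fit$qr$rank < ncol(stats::model.matrix(fit))) {
    abort("singular design: regression model matrix is rank deficient")
  }
  cf <- summary(fit)$coefficients
  ci <- stats::confint(fit)
  regression <- tibble::tibble(
    term = rownames(cf), estimate = as.numeric(cf[, 1]),
    std_error = as.numeric(cf[, 2]), statistic = as.numeric(cf[, 3]),
    p_value = as.numeric(cf[, 4]),
    conf_low = as.numeric(ci[, 1]), conf_high = as.numeric(ci[, 2])
  )

  rec_cc <- records[stats::complete.cases(records[, c("abs_d_after", need)]), , drop = FALSE]
  fit_aov <- stats::aov(abs_d_after ~ is_repeat + bmi + experience_years, data = rec_cc)
  aovtab <- summary(fit_aov)[[1]]
  anova_tbl <- tibble::tibble(
    term = trimws(rownames(aovtab)), df = aovtab[, "Df"],
    sum_sq = aovtab[, "Sum Sq"], mean_sq = aovtab[, "Mean Sq"],
    statistic = aovtab[, "F value"], p_value = aovtab[, "Pr(>F)"]
  )
  structure(list(regression = regression, anova = anova_tbl,
                 n_dropped = n_dropped, fit_regression = fit, fit_anova = fit_aov),
            class = "scanbias_models")
}

#' @export
print.scanbias_models <- function(x, ...) {
  cat("Adjusted models (", x$n_dropped, " row(s) dropped for missing covariates)\n",
      sep = "")
  cat("\nRegression: d_after ~ d_before + bmi + experience_years\n")
  print(x$regression)
  cat("\nANOVA: abs_d_after ~ is_repeat + bmi + experience_years\n")
  print(x$anova)
  invisible(x)
}

#' Binomial proportion confidence interval
#'
#' Wald and Wilson 95% (or `conf`-level) intervals for `k` successes out of
#' `n`; the method used is recorded in the output.
#'
#' @param k Number of successes, `0 <= k <= n`.
#' @param n Number of trials, `> 0`.
#' @param method `"wald"` or `"wilson"`.
#' @param conf Confidence level.
#' @return One-row tibble with `k`, `n`, `estimate`, `lower`, `upper`, `method`.
#' @export
proportion_ci <- function(k, n, method = c("wald", "wilson"), conf = 0.95) {
  method <- match.arg(method)
  stopifnot(length(k) == 1L, length(n) == 1L, n > 0, k >= 0, k <= n)
  p <- k / n
  z <- stats::qnorm(1 - (1 - conf) / 2)
  if (method == "wald") {
    half <- z * sqrt(p * (1 - p) / n)
    lo <- max(0, p - half); hi <- min(1, p + half)
  } else {
    denom <- 1 + z^2 / n
    center <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    lo <- center - half; hi <- center + half
  }
  tibble::tibble(k = k, n = n, estimate = p, lower = lo, upper = hi, method = method)
}

#' Clinical impact of bias on estimated fetal weight
#'
#' For every scan with all three planes measured, the smallest and largest
#' candidate HC, AC and FL (see [candidate_values()]) give the lowest and
#' highest possible EFW. The per-scan summary reports the EFW bounds, the
#' percentage discordance `100 * (efw_max - efw_min) / efw_max` (denominator
#' configurable to the pairwise mean), the EFW-for-GA Z-scores of both bounds
#' at the expected GA and their difference, the size classes of both bounds,
#' and the reclassification swing (`SGA<->AGA`, `AGA<->LGA`, `none`, or
#' `other` for a swing crossing both cutoffs). Scans missing a plane are
#' excluded and counted.
#'
#' @param events Episode tibble from [detect_bias_events()] (deviation-record
#'   pipelines can pass their episode events).
#' @param sessions Session metadata with `scan_id` and `expected_ga_days`.
#' @param std A [growth_standard()] with EFW formula and reference.
#' @param denominator `"max"` (twin-discordance convention, default) or
#'   `"mean"`.
#' @param include_intermediate Passed to [candidate_values()].
#' @param ci_method Method for swing-proportion confidence intervals.
#' @return List of class `scanbias_efw`: `scan_summaries` (per-scan tibble),
#'   `cohort` (one-row aggregate tibble), `swing_ci` (per-swing-type binomial
#'   CIs), `excluded` (tibble of excluded scans with reasons).
#' @export
efw_impact <- function(events, sessions, std = default_growth_standard(),
                       denominator = c("max", "mean"),
                       include_intermediate = FALSE,
                       ci_method = c("wald", "wilson")) {
  denominator <- match.arg(denominator)
  ci_method <- match.arg(ci_method)
  cand <- candidate_values(events, include_intermediate)
  wide <- cand %>%
    tidyr::pivot_wider(id_cols = "scan_id", names_from = "plane",
                       values_from = c("min_mm", "max_mm"))
  need <- c("min_mm_HC", "min_mm_AC", "min_mm_FL", "max_mm_HC", "max_mm_AC", "max_mm_FL")
  for (col in setdiff(need, names(wide))) wide[[col]] <- NA_real_
  complete <- stats::complete.cases(wide[need])
  excluded <- tibble::tibble(
    scan_id = wide$scan_id[!complete],
    reason = vapply(which(!complete), function(i) {
      missing_planes <- PLANES[is.na(wide[i, paste0("min_mm_", PLANES)])]
      paste0("missing plane(s): ", paste(missing_planes, collapse = ", "))
    }, character(1))
  )
  wide <- wide[complete, , drop = FALSE]
  wide <- dplyr::inner_join(wide, sessions[c("scan_id", "expected_ga_days")],
                            by = "scan_id")
  efw_min <- efw(wide$min_mm_HC, wide$min_mm_AC, wide$min_mm_FL, std)
  efw_max <- efw(wide$max_mm_HC, wide$max_mm_AC, wide$max_mm_FL, std)
  denom <- if (denominator == "max") efw_max else (efw_max + efw_min) / 2
  disc <- 100 * (efw_max - efw_min) / denom
  z_min <- efw_zscore(efw_min, wide$expected_ga_days, std)
  z_max <- efw_zscore(efw_max, wide$expected_ga_days, std)
  class_min <- classify_size(efw_min, wide$expected_ga_days, std)
  class_max <- classify_size(efw_max, wide$expected_ga_days, std)
  swing <- dplyr::case_when(
    class_min == class_max ~ "none",
    class_min == "SGA" & class_max == "AGA" ~ "SGA<->AGA",
    class_min == "AGA" & class_max == "LGA" ~ "AGA<->LGA",
    TRUE ~ "other"
  )
  scan_summaries <- tibble::tibble(
    scan_id = wide$scan_id, expected_ga_days = wide$expected_ga_days,
    efw_min = efw_min, efw_max = efw_max, discordance_pct = disc,
    z_min = z_min, z_max = z_max, z_diff = z_max - z_min,
    class_min = class_min, class_max = class_max, swing = swing
  )
  n <- nrow(scan_summaries)
  swing_types <- c("SGA<->AGA", "AGA<->LGA", "other")
  swing_ci <- dplyr::bind_rows(lapply(swing_types, function(s) {
    dplyr::mutate(proportion_ci(sum(swing == s), n, method = ci_method), swing = s,
      .before = 1)
  }))
  cohort <- tibble::tibble(
    n_scans = n, n_excluded = nrow(excluded),
    discordance_mean = mean(disc), discordance_sd = stats::sd(disc),
    z_diff_mean = mean(scan_summaries$z_diff), z_diff_sd = stats::sd(scan_summaries$z_diff),
    pct_sga_aga_swing = 100 * mean(swing == "SGA<->AGA"),
    pct_aga_lga_swing = 100 * mean(swing == "AGA<->LGA"),
    pct_other_swing = 100 * mean(swing == "other"),
    denominator = denominator
  )
  structure(list(scan_summaries = scan_summaries, cohort = cohort,
                 swing_ci = swing_ci, excluded = excluded),
            class = "scanbias_efw")
}

#' @export
print.scanbias_efw <- function(x, ...) {
  cat("EFW impact on", x$cohort$n_scans, "scans (", x$cohort$n_excluded, "excluded )\n")
  cat(sprintf("  discordance %%: %.1f +/- %.1f; Z-score difference: %.2f +/- %.2f\n",
              x$cohort$discordance_mean, x$cohort$discordance_sd,
              x$cohort$z_diff_mean, x$cohort$z_diff_sd))
  print(x$swing_ci)
  invisible(x)
}
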