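# Minimal deviation-record builder for statistics tests: the statistics layer
# only sees the tidy record table, so records can be constructed directly.
make_records <- function(n, d_before, d_after, biased = TRUE, plane = "AC",
                         scan_id = paste0("s", seq_len(n)), is_repeat = FALSE,
                         bmi = 25, experience = 5, tol = 0.25) {
  adj <- abs(d_before) - abs(d_after)
  tibble::tibble(
    scan_id = rep_len(scan_id, n), plane = rep_len(plane, n),
    is_repeat = rep_len(is_repeat, n), biased = rep_len(biased, n),
    d_before = ifelse(rep_len(biased, n), d_before, NA_real_),
    d_after = d_after,
    abs_d_before = abs(ifelse(rep_len(biased, n), d_before, NA_real_)),
    abs_d_after = abs(d_after),
    adjustment_days = ifelse(rep_len(biased, n), adj, NA_real_),
    adjustment = factor(
      ifelse(!rep_len(biased, n), "unbiased",
             ifelse(adj > tol, "toward", ifelse(adj < -tol, "away", "unchanged"))),
      levels = c("toward", "away", "unchanged", "unbiased")),
    bmi = rep_len(bmi, n), experience_years = rep_len(experience, n)
  )
}

test_that("incidence table reproduces simple count arithmetic", {
  # 4 scans, each 1 HC + 2 AC + 1 FL: 4.0 measurements per scan overall
  rec <- dplyr::bind_rows(lapply(1:4, function(s) {
    make_records(4, d_before = c(-8, 5, 3, -2), d_after = c(-3, 2, 5, -2),
                 plane = c("HC", "AC", "AC", "FL"), scan_id = paste0("s", s),
                 is_repeat = c(FALSE, FALSE, TRUE, FALSE))
  }))
  tab <- incidence_table(rec)
  tot <- tab[tab$plane == "Total", ]
  expect_equal(tot$n_saved, 16L)
  expect_equal(tot$per_scan_mean, 4.0)
  expect_equal(tot$n_repeat, 4L)
  expect_equal(tab$per_scan_mean[tab$plane == "AC"], 2.0)
  expect_equal(tab$per_scan_sd[tab$plane == "AC"], 0)
  expect_equal(tot$pct_biased, 100)

  all_toward <- make_records(6, d_before = rep(-10, 6), d_after = rep(-2, 6))
  tab2 <- incidence_table(all_toward)
  expect_equal(tab2$pct_toward[tab2$plane == "Total"], 100)
  expect_equal(tab2$pct_away[tab2$plane == "Total"], 0)
  expect_error(incidence_table(rec[0, ]), "no deviation records")
})

test_that("incidence table equals an independent aggregation on a simulated cohort", {
  sim <- simulate_cohort(simulation_config(n_scans = 25, seed = 404))
  rec <- deviation_records(sim$episodes, sim$sessions, sim$gaze)
  tab <- incidence_table(rec, n_scans = 25)
  # hand-rolled base-R aggregation
  for (pl in c("HC", "AC", "FL")) {
    sub <- rec[rec$plane == pl, ]
    row <- tab[tab$plane == pl, ]
    expect_equal(row$n_saved, nrow(sub))
    expect_equal(row$n_repeat, sum(sub$is_repeat))
    expect_equal(row$per_scan_mean, nrow(sub) / 25)
    expect_equal(row$pct_biased, 100 * sum(sub$biased) / nrow(sub))
    expect_equal(row$pct_toward, 100 * sum(sub$adjustment == "toward") / nrow(sub))
    expect_equal(row$adjustment_mean, mean(sub$adjustment_days[sub$biased]))
    expect_equal(row$adjustment_sd, sd(sub$adjustment_days[sub$biased]))
  }
  tot <- tab[tab$plane == "Total", ]
  expect_equal(tot$n_saved, nrow(rec))
  expect_equal(tot$per_scan_sd, sd(table(factor(rec$scan_id, levels = unique(rec$scan_id)))))
})

test_that("identical before/after deviations give p = 1 and zero adjustment", {
  d <- c(-9, -4, 2, 5, 11, -1, 3, 6)
  rec <- make_records(8, d_before = d, d_after = d)
  bb <- before_after_tests(rec, by_plane = FALSE)
  expect_equal(bb$wilcoxon_p, 1)
  expect_equal(bb$t_p, 1)
  expect_equal(bb$mean_adjustment, 0)
  expect_equal(bb$levene_p, 1, tolerance = 1e-9)
})

test_that("an exact multiplicative shrink is detected by the variance test", {
  withr::local_seed(12)
  d_before <- rnorm(400, 0, 10)
  rec <- make_records(400, d_before = d_before, d_after = 0.5 * d_before)
  bb <- before_after_tests(rec, by_plane = FALSE)
  expect_lt(bb$levene_p, 0.001)
  expect_lt(bb$wilcoxon_p, 0.001)
  expect_lt(bb$var_after, bb$var_before)
  # pair order must not matter
  bb2 <- before_after_tests(rec[sample(400), ], by_plane = FALSE)
  expect_equal(bb$wilcoxon_p, bb2$wilcoxon_p)
  expect_equal(bb$levene_p, bb2$levene_p)
})

test_that("fewer than two pairs yields a not-computable marker", {
  rec <- make_records(1, d_before = 5, d_after = 2)
  bb <- before_after_tests(rec, by_plane = FALSE)
  expect_equal(bb$n_pairs, 1L)
  expect_true(is.na(bb$wilcoxon_p))
})

test_that("repeat comparison separates shifted groups and is label-symmetric", {
  withr::local_seed(8)
  base <- abs(rnorm(200, 8, 3))
  rec <- make_records(200, d_before = base + 2, d_after = base,
                      is_repeat = rep(c(TRUE, FALSE), each = 100))
  rec$abs_d_after[rec$is_repeat] <- rec$abs_d_after[rec$is_repeat] + 5
  rc <- repeat_comparison(rec)
  pooled <- rc[rc$plane == "Pooled", ]
  expect_gt(pooled$mean_repeated, pooled$mean_not_repeated)
  expect_lt(pooled$mann_whitney_p, 0.001)
  # swapping the group labels swaps the group means
  swapped <- rec; swapped$is_repeat <- !swapped$is_repeat
  rs <- repeat_comparison(swapped)[rc$plane == "Pooled", ]
  expect_equal(rs$mean_repeated, pooled$mean_not_repeated)
  expect_equal(rs$mean_not_repeated, pooled$mean_repeated)

  # all deviations equal: means equal, no significance
  flat <- make_records(40, d_before = 6, d_after = 4,
                       is_repeat = rep(c(TRUE, FALSE), 20))
  rf <- repeat_comparison(flat)
  pooled_f <- rf[rf$plane == "Pooled", ]
  expect_equal(pooled_f$mean_repeated, pooled_f$mean_not_repeated)
  expect_true(is.na(pooled_f$mann_whitney_p) || pooled_f$mann_whitney_p > 0.05)

  # a plane with no repeats is marked empty
  none <- make_records(10, d_before = 3, d_after = 2, is_repeat = FALSE)
  rn <- repeat_comparison(none)
  expect_equal(rn$n_repeated[rn$plane == "Pooled"], 0L)
  expect_true(is.na(rn$mean_repeated[rn$plane == "Pooled"]))
})

test_that("the series grouping counts all measurements of multi-measured planes", {
  rec <- make_records(3, d_before = c(1, 2, 3), d_after = c(1, 2, 3),
                      plane = c("AC", "AC", "HC"), scan_id = "s1",
                      is_repeat = c(FALSE, TRUE, FALSE))
  rc <- repeat_comparison(rec, unit = "series")
  pooled <- rc[rc$plane == "Pooled", ]
  expect_equal(pooled$n_repeated, 2L)  # both AC measurements
  expect_equal(pooled$n_not_repeated, 1L)
})

test_that("adjusted regression recovers a known shrink slope with null covariates", {
  withr::local_seed(21)
  n <- 500
  d_before <- rnorm(n, 0, 10)
  d_after <- 0.6 * d_before + rnorm(n, 0, 1)
  rec <- make_records(n, d_before = d_before, d_after = d_after,
                      is_repeat = runif(n) < 0.3,
                      bmi = rnorm(n, 26, 4), experience = runif(n, 1, 12))
  m <- adjusted_models(rec)
  est <- m$regression$estimate[m$regression$term == "d_before"]
  expect_equal(est, 0.6, tolerance = 0.03)
  cov_p <- m$regression$p_value[m$regression$term %in% c("bmi", "experience_years")]
  cov_est <- m$regression$estimate[m$regression$term %in% c("bmi", "experience_years")]
  expect_true(all(abs(cov_est) < 0.1))
  # row order invariance
  m2 <- adjusted_models(rec[sample(n), ])
  expect_equal(sort(m$regression$estimate), sort(m2$regression$estimate))
  # ANOVA table includes repeat status and covariates
  expect_setequal(setdiff(m$anova$term, "Residuals"),
                  c("is_repeat", "bmi", "experience_years"))
})

test_that("zero-variance covariates raise a singular-design error", {
  rec <- make_records(50, d_before = rnorm(50), d_after = rnorm(50),
                      bmi = 25, experience = runif(50, 1, 10))
  expect_error(adjusted_models(rec), "singular design")
})

test_that("binomial proportion intervals match the closed forms", {
  expect_equal(proportion_ci(0, 20, "wald")$lower, 0)
  expect_equal(proportion_ci(20, 20, "wald")$upper, 1)
  # textbook evaluation at k = 46, n = 272
  p <- 46 / 272
  half <- qnorm(0.975) * sqrt(p * (1 - p) / 272)
  ci <- proportion_ci(46, 272, "wald")
  expect_equal(ci$lower, p - half, tolerance = 1e-12)
  expect_equal(ci$upper, p + half, tolerance = 1e-12)
  # Wilson never collapses to a point at the boundary
  wil <- proportion_ci(0, 20, "wilson")
  expect_gt(wil$upper, 0)
  expect_equal(wil$lower, 0, tolerance = 1e-12)
  expect_error(proportion_ci(5, 0), "n > 0")
})

test_that("EFW impact on an all-unbiased cohort is exactly null", {
  # p_repeat = 0 so each plane is a single unbiased save: candidate min = max
  sim <- simulate_cohort(simulation_config(n_scans = 15, p_look = 0, p_repeat = 0,
                                           seed = 63))
  ev <- detect_bias_events(sim$episodes, sim$gaze)
  expect_false(any(ev$biased))
  imp <- efw_impact(ev, sim$sessions)
  expect_true(all(imp$scan_summaries$discordance_pct == 0))
  expect_true(all(imp$scan_summaries$z_diff == 0))
  expect_true(all(imp$scan_summaries$swing == "none"))
  expect_equal(imp$cohort$pct_sga_aga_swing, 0)
})

test_that("EFW impact equals brute-force recomputation from candidate sets", {
  std <- default_growth_standard()
  sim <- simulate_cohort(simulation_config(n_scans = 20, beta = 0.6, seed = 99))
  ev <- detect_bias_events(sim$episodes, sim$gaze)
  imp <- efw_impact(ev, sim$sessions, std)
  ss <- imp$scan_summaries
  for (r in seq_len(nrow(ss))) {
    rows <- ev[ev$scan_id == ss$scan_id[r], ]
    bound <- function(pl, f) {
      sub <- rows[rows$plane == pl, ]
      f(c(sub$saved_value_mm, sub$value_at_first_look[sub$biased]))
    }
    lo <- efw(bound("HC", min), bound("AC", min), bound("FL", min), std)
    hi <- efw(bound("HC", max), bound("AC", max), bound("FL", max), std)
    expect_equal(ss$efw_min[r], lo, tolerance = 1e-9)
    expect_equal(ss$efw_max[r], hi, tolerance = 1e-9)
    expect_equal(ss$discordance_pct[r], 100 * (hi - lo) / hi, tolerance = 1e-9)
    e <- sim$sessions$expected_ga_days[sim$sessions$scan_id == ss$scan_id[r]]
    expect_equal(ss$z_diff[r], efw_zscore(hi, e, std) - efw_zscore(lo, e, std),
                 tolerance = 1e-9)
  }
  expect_equal(imp$cohort$pct_sga_aga_swing,
               100 * sum(ss$swing == "SGA<->AGA") / nrow(ss))
  expect_equal(imp$cohort$discordance_mean, mean(ss$discordance_pct))
})

test_that("scans missing a plane are excluded with a logged reason", {
  sim <- simulate_cohort(simulation_config(n_scans = 6, seed = 3))
  ev <- detect_bias_events(sim$episodes, sim$gaze)
  drop_scan <- ev$scan_id[1]
  ev2 <- ev[!(ev$scan_id == drop_scan & ev$plane == "FL"), ]
  imp <- efw_impact(ev2, sim$sessions)
  expect_equal(imp$excluded$scan_id, drop_scan)
  expect_match(imp$excluded$reason, "FL")
  expect_equal(imp$cohort$n_scans, 5)
})
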