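#' Simulation configuration
#'
#' Ground-truth parameters of the synthetic scan-session generator. The
#' generator encodes the behavioural model under study: for each plane the
#' fetus has a true GA-equivalent size, the initial caliper placement observes
#' it with noise, the operator looks at the measurement box with probability
#' `p_look`, and a look closes a fraction `beta` of the gap between the
#' observed and the expected GA (plus jitter) before saving; measurements
#' still far from the expected value may trigger a repeat.
#'
#' Defaults reflect a routine third-trimester growth-scan cohort: 272 scans by
#' 16 operators with expected GA 196-280 days; dispersion components
#' (`sigma_fetal` 7 d between fetuses, `sigma_plane` 5 d between planes,
#' `sigma_meas` 4 d caliper noise) give observed-minus-expected spreads of
#' about 1.5 weeks; `p_look = 0.91` matches the observed incidence of box
#' looks, and `beta = 0.3` with `sigma_adj = 1` d produces mean corrections of
#' the observed 2-3 day order.
#'
#' @param n_scans Number of scan sessions.
#' @param n_operators Number of operators.
#' @param expected_ga_range Expected-GA range at scan, days.
#' @param sigma_fetal SD of the per-fetus GA offset, days.
#' @param sigma_plane SD of the per-plane offset, days.
#' @param sigma_meas SD of the caliper-placement noise, days (re-drawn per
#'   attempt; repeats share the plane's true size).
#' @param p_look Probability a measurement is accompanied by a box fixation
#'   before save.
#' @param beta Bias strength in `[0, 1]`: fraction of the expected-observed
#'   gap closed after a look.
#' @param sigma_adj SD of the post-look adjustment jitter, days.
#' @param repeat_threshold Deviation (days) beyond which a repeat is considered.
#' @param p_repeat Probability of actually repeating when beyond the threshold.
#' @param max_attempts Cap on attempts per plane per scan.
#' @param gaze_hz Gaze sample rate.
#' @param distractor_rate Rate (per second) of sub-threshold distractor
#'   glances at the box; their dwell is capped at 80 ms so they never reach
#'   the 100 ms fixation threshold.
#' @param tracker_loss_rate Rate (per second) of short tracker-loss gaps.
#' @param seed Integer seed fixing the entire stream.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_scans = 272, n_operators = 16,
                              expected_ga_range = c(196, 280),
                              sigma_fetal = 7, sigma_plane = 5, sigma_meas = 4,
                              p_look = 0.91, beta = 0.3, sigma_adj = 1,
                              repeat_threshold = 10, p_repeat = 0.7,
                              max_attempts = 4L,
                              gaze_hz = 60, distractor_rate = 0.1,
                              tracker_loss_rate = 0.05, seed = 1L) {
  cfg <- list(n_scans = as.integer(n_scans), n_operators = as.integer(n_operators),
              expected_ga_range = as.numeric(expected_ga_range),
              sigma_fetal = sigma_fetal, sigma_plane = sigma_plane,
              sigma_meas = sigma_meas, p_look = p_look, beta = beta,
              sigma_adj = sigma_adj, repeat_threshold = repeat_threshold,
              p_repeat = p_repeat, max_attempts = as.integer(max_attempts),
              gaze_hz = gaze_hz, distractor_rate = distractor_rate,
              tracker_loss_rate = tracker_loss_rate, seed = as.integer(seed))
  with(cfg, {
    if (n_scans < 1 || n_operators < 1) abort("n_scans and n_operators must be >= 1")
    if (any(c(sigma_fetal, sigma_plane, sigma_meas, sigma_adj) < 0)) {
      abort("all noise SDs must be >= 0")
    }
    if (p_look < 0 || p_look > 1 || p_repeat < 0 || p_repeat > 1) {
      abort("p_look and p_repeat must be in [0, 1]")
    }
    if (beta < 0 || beta > 1) abort("beta must be in [0, 1]")
    if (length(expected_ga_range) != 2L || diff(expected_ga_range) < 0) {
      abort("expected_ga_range must be an increasing length-2 vector (days)")
    }
    if (gaze_hz <= 0 || distractor_rate < 0 || tracker_loss_rate < 0) {
      abort("gaze_hz must be > 0; rates must be >= 0")
    }
  })
  structure(cfg, class = "simulation_config")
}

# screen geometry of the synthetic scanner UI (pixels)
SIM_SCREEN <- list(width = 1280, height = 1024,
                   box = list(left = 1000, top = 840, right = 1230, bottom = 940))

#' Simulate a cohort of scan sessions
#'
#' Generates session metadata, measurement-episode logs and gaze streams in
#' exactly the formats the analysis pipeline consumes, together with a ground
#' truth table that the pipeline never sees. The same configuration and seed
#' always produce identical output.
#'
#' For each scan, the expected GA `E` is uniform over the configured range; a
#' plane's true GA-equivalent is `E + delta_scan + eps_plane`; each attempt
#' observes it as `O0 = T + eta`. With probability `p_look` a box fixation of
#' 150-600 ms is scripted during caliper adjustment and the saved value becomes
#' `O1 = O0 + beta * (E - O0) + nu`; otherwise `O1 = O0`. If `|O1 - E|`
#' exceeds the repeat threshold, another attempt follows with probability
#' `p_repeat` (sharing the plane's true size, re-drawing the caliper noise).
#' GA-equivalents are converted to mm via the growth standard's forward curve.
#' Gaze streams contain the scripted fixations, out-of-box wander,
#' sub-threshold distractor glances (dwell <= 80 ms, kept >= 500 ms clear of
#' any other in-box interval) and short tracker-loss gaps.
#'
#' @param cfg A [simulation_config()].
#' @param std A [growth_standard()].
#' @return List of class `scanbias_cohort` with tibbles `sessions`, `episodes`,
#'   `gaze`, `truth`, plus the `config`.
#' @export
simulate_cohort <- function(cfg = simulation_config(), std = default_growth_standard()) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  dt <- 1000 / cfg$gaze_hz
  box <- SIM_SCREEN$box

  operators <- tibble::tibble(
    operator_id = sprintf("op%02d", seq_len(cfg$n_operators)),
    experience_years = round(runif(cfg$n_operators, 0.3, 14), 1)
  )
  sessions <- tibble::tibble(
    scan_id = sprintf("scan%04d", seq_len(cfg$n_scans)),
    operator_id = sample(operators$operator_id, cfg$n_scans, replace = TRUE),
    expected_ga_days = round(runif(cfg$n_scans, cfg$expected_ga_range[1],
                                   cfg$expected_ga_range[2])),
    bmi = round(pmax(15, rnorm(cfg$n_scans, 25.8, 5.3)), 1)
  ) %>%
    dplyr::left_join(operators, by = "operator_id")

  ep_rows <- list(); gaze_rows <- list(); truth_rows <- list()
  ep_counter <- 0L
  for (s in seq_len(cfg$n_scans)) {
    scan_id <- sessions$scan_id[s]
    E <- sessions$expected_ga_days[s]
    delta_scan <- rnorm(1, 0, cfg$sigma_fetal)
    t_clock <- round(runif(1, 30000, 90000))
    for (plane in PLANES) {
      T_plane <- E + delta_scan + rnorm(1, 0, cfg$sigma_plane)
      attempt <- 0L
      repeat {
        attempt <- attempt + 1L
        O0 <- T_plane + rnorm(1, 0, cfg$sigma_meas)
        looked <- runif(1) < cfg$p_look
        O1 <- if (looked) O0 + cfg$beta * (E - O0) + rnorm(1, 0, cfg$sigma_adj) else O0
        ep_counter <- ep_counter + 1L
        ep <- simulate_episode(scan_id, sprintf("ep%06d", ep_counter), plane,
                               t_clock, O0, O1, looked, cfg, std, dt, box)
        ep_rows[[ep_counter]] <- ep$episode
        gaze_rows[[ep_counter]] <- ep$gaze
        truth_rows[[ep_counter]] <- tibble::tibble(
          scan_id = scan_id, episode_id = sprintf("ep%06d", ep_counter),
          plane = plane, attempt = attempt, is_repeat = attempt > 1L,
          expected_ga_days = E, true_ga_days = T_plane,
          looked = looked, o0_ga_days = O0, o1_ga_days = O1
        )
        t_clock <- ep$t_end + round(runif(1, 2000, 6000))
        if (abs(O1 - E) <= cfg$repeat_threshold || attempt >= cfg$max_attempts ||
            runif(1) >= cfg$p_repeat) break
      }
    }
  }
  structure(
    list(sessions = sessions, episodes = dplyr::bind_rows(ep_rows),
         gaze = dplyr::bind_rows(gaze_rows), truth = dplyr::bind_rows(truth_rows),
         config = cfg),
    class = "scanbias_cohort"
  )
}

simulate_episode <- function(scan_id, episode_id, plane, t0, O0, O1, looked,
                             cfg, std, dt, box) {
  dur <- round(runif(1, 5000, 9000))
  t_save <- t0 + dur
  mm0 <- measurement_from_ga(plane, O0, std)
  traj <- tibble::tibble(t_ms = t0, value_mm = mm0)
  fix_start <- fix_end <- NA_real_
  if (looked) {
    fix_start <- t0 + runif(1, 0.25, 0.5) * dur
    fix_end <- fix_start + runif(1, 150, 600)
    if (abs(O1 - O0) > 1e-12) {
      mm1 <- measurement_from_ga(plane, O1, std)
      traj <- dplyr::bind_rows(traj, tibble::tibble(
        t_ms = min(fix_end + runif(1, 100, 300), t_save - 50), value_mm = mm1))
    }
  }
  saved_mm <- traj$value_mm[nrow(traj)]

  t_samp <- seq(t0, t_save - 1, by = dt)
  n <- length(t_samp)
  x <- runif(n, 20, box$left - 80)
  y <- runif(n, 20, SIM_SCREEN$height - 20)
  valid <- rep(TRUE, n)
  in_box <- function(idx) {
    x[idx] <<- runif(length(idx), box$left + 5, box$right - 5)
    y[idx] <<- runif(length(idx), box$top + 5, box$bottom - 5)
  }
  busy <- matrix(numeric(0), ncol = 2)  # in-box intervals incl. scripted fixation
  if (looked) {
    idx <- which(t_samp >= fix_start & t_samp <= fix_end)
    in_box(idx)
    busy <- rbind(busy, c(fix_start, fix_end))
  }

  # sub-threshold distractor glances: dwell capped at 80 ms and >= 500 ms away
  # from any other in-box interval, so merging can never promote them
  k_d <- floor(80 / dt)
  n_distract <- rpois(1, cfg$distractor_rate * dur / 1000)
  if (k_d >= 1L && n_distract > 0L) {
    for (j in seq_len(n_distract)) {
      for (try in 1:10) {
        cand <- runif(1, t0 + 600, t_save - 700)
        if (!nrow(busy) || all(cand > busy[, 2] + 500 | cand + 100 < busy[, 1] - 500)) {
          i0 <- which(t_samp >= cand)[1]
          idx <- i0:min(i0 + k_d - 1L, n)
          in_box(idx)
          busy <- rbind(busy, c(t_samp[idx[1]], t_samp[idx[length(idx)]]))
          break
        }
      }
    }
  }

  # tracker-loss gaps (kept clear of the scripted fixation)
  n_loss <- rpois(1, cfg$tracker_loss_rate * dur / 1000)
  if (n_loss > 0L) {
    for (j in seq_len(n_loss)) {
      cand <- runif(1, t0, t_save - 400)
      if (looked && cand > fix_start - 600 && cand < fix_end + 600) next
      len <- runif(1, 100, 300)
      valid[t_samp >= cand & t_samp <= cand + len] <- FALSE
    }
  }

  list(
    episode = tibble::tibble(
      scan_id = scan_id, episode_id = episode_id, plane = plane,
      box_left = box$left, box_top = box$top, box_right = box$right,
      box_bottom = box$bottom, t_box_appear = t0, t_save = t_save,
      saved_value_mm = saved_mm, trajectory = list(traj)
    ),
    gaze = tibble::tibble(scan_id = scan_id, t_ms = t_samp,
                          x = round(x, 1), y = round(y, 1), valid = valid),
    t_end = t_save
  )
}

#' @export
print.scanbias_cohort <- function(x, ...) {
  cat("<scanbias_cohort> ", nrow(x$sessions), " scans, ", nrow(x$episodes),
      " episodes, ", nrow(x$gaze), " gaze samples (seed ", x$config$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Write a simulated cohort to disk in the pipeline's input formats
#'
#' Writes `sessions.csv`, `episodes.jsonl`, `gaze.csv` and — separately, never
#' read by the pipeline — `ground_truth.csv`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(cohort$sessions, file.path(dir, "sessions.csv"))
  write_episodes_jsonl(cohort$episodes, file.path(dir, "episodes.jsonl"))
  readr::write_csv(cohort$gaze, file.path(dir, "gaze.csv"))
  readr::write_csv(cohort$truth, file.path(dir, "ground_truth.csv"))
  invisible(dir)
}

#' Estimate simulator parameters back from pipeline output
#'
#' Parameter-recovery check: the bias strength is estimated as the slope of
#' `d_before - d_after` on `d_before` among biased measurements (under the
#' generative model `d_after = (1 - beta) * d_before + noise`), and the
#' detected bias incidence, toward/away proportions and, when ground truth is
#' supplied, the true look rate are reported alongside.
#'
#' @param records Deviation records from the pipeline.
#' @param truth Optional ground-truth tibble from [simulate_cohort()].
#' @param cfg Optional [simulation_config()] for the true parameter values.
#' @return One-row tibble with `beta_hat`, `beta_se`, `incidence_hat`,
#'   `pct_toward`, `pct_away`, `n_biased`, and when available `beta_true`,
#'   `p_look_true`, `incidence_truth`.
#' @export
parameter_recovery <- function(records, truth = NULL, cfg = NULL) {
  bi <- records[records$biased, , drop = FALSE]
  if (nrow(bi) < 3L) abort("too few biased records to estimate bias strength")
  fit <- stats::lm(I(d_before - d_after) ~ d_before, data = bi)
  out <- tibble::tibble(
    beta_hat = unname(stats::coef(fit)["d_before"]),
    beta_se = summary(fit)$coefficients["d_before", "Std. Error"],
    incidence_hat = mean(records$biased),
    pct_toward = 100 * mean(records$adjustment == "toward"),
    pct_away = 100 * mean(records$adjustment == "away"),
    n_biased = nrow(bi)
  )
  if (!is.null(cfg)) {
    out$beta_true <- cfg$beta
    out$p_look_true <- cfg$p_look
  }
  if (!is.null(truth)) out$incidence_truth <- mean(truth$looked)
  out
}
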