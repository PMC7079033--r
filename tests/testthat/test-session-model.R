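toy <- toy_standard(slope = 0.5)  # ga_days = value_mm / 2
box <- list(left = 100, top = 100, right = 200, bottom = 150)

test_that("episode invariants are enforced", {
  ep <- make_episode()
  expect_silent(validate_episodes(ep))
  bad <- ep; bad$trajectory <- list(tibble::tibble(t_ms = numeric(), value_mm = numeric()))
  expect_error(validate_episodes(bad), "empty value trajectory")
  bad2 <- ep; bad2$saved_value_mm <- 999
  expect_error(validate_episodes(bad2), "saved value")
  bad3 <- ep; bad3$trajectory <- list(tibble::tibble(t_ms = 9000, value_mm = 300))
  expect_error(validate_episodes(bad3), "outside")
  bad4 <- ep; bad4$plane <- "BPD"
  expect_error(validate_episodes(bad4), "unknown plane")
})

test_that("episodes with no in-window fixation stay unbiased; the first-look value uses step-function lookup", {
  traj <- tibble::tibble(t_ms = c(0, 2000, 4000), value_mm = c(310, 320, 330))
  ep <- make_episode(trajectory = traj, t_save = 5000)
  # gaze entirely outside the box
  g_out <- gaze_dwell("s1", 0, 4900, box, inside = FALSE)
  ev <- detect_bias_events(ep, g_out)
  expect_false(ev$biased)
  expect_equal(ev$n_looks, 0L)
  expect_true(is.na(ev$value_at_first_look))

  # a 300 ms dwell starting at t=1000: value in force is still 310 mm
  g_in <- dplyr::arrange(dplyr::bind_rows(
    gaze_dwell("s1", 0, 950, box, inside = FALSE),
    gaze_dwell("s1", 1000, 1300, box, inside = TRUE),
    gaze_dwell("s1", 1350, 4900, box, inside = FALSE)), t_ms)
  ev2 <- detect_bias_events(ep, g_in)
  expect_true(ev2$biased)
  expect_equal(ev2$value_at_first_look, 310)
  expect_lt(ev2$t_first_look, 2000)
  # dwell after the second update sees 320 mm
  g_late <- dplyr::arrange(dplyr::bind_rows(
    gaze_dwell("s1", 0, 2450, box, inside = FALSE),
    gaze_dwell("s1", 2500, 2800, box, inside = TRUE),
    gaze_dwell("s1", 2850, 4900, box, inside = FALSE)), t_ms)
  expect_equal(detect_bias_events(ep, g_late)$value_at_first_look, 320)
})

test_that("fixations at or after the save never create a bias event", {
  ep <- make_episode(t_save = 2000,
                     trajectory = tibble::tibble(t_ms = 0, value_mm = 300))
  g <- gaze_dwell("s1", 2100, 2600, box, inside = TRUE)
  expect_false(detect_bias_events(ep, g)$biased)
})

test_that("adjustment classification matches its defining arithmetic", {
  # E = 200 d; first look at d_before, saved at d_after (toy: mm = 2 * days)
  mk <- function(d_before, d_after, id) {
    traj <- tibble::tibble(t_ms = c(0, 3000), value_mm = 2 * (200 + c(d_before, d_after)))
    make_episode(episode_id = id, trajectory = traj, t_save = 5000)
  }
  eps <- dplyr::bind_rows(mk(-10, -4, "e1"), mk(3, 8, "e2"), mk(6, 6, "e3"))
  g <- dplyr::bind_rows(gaze_dwell("s1", 500, 900, box), gaze_dwell("s1", 4000, 4900, box, inside = FALSE))
  ev <- detect_bias_events(eps, g)
  ev$expected_ga_days <- 200
  cl <- classify_adjustment(ev, toy)
  expect_equal(as.character(cl$adjustment), c("toward", "away", "unchanged"))
  expect_equal(cl$adjustment_days, c(6, -5, 0), tolerance = 1e-9)
  expect_equal(cl$d_before, c(-10, 3, 6), tolerance = 1e-9)
  expect_equal(cl$d_after, c(-4, 8, 6), tolerance = 1e-9)
})

test_that("repeat grouping counts extra saves of the same plane", {
  eps <- dplyr::bind_rows(
    make_episode(episode_id = "a1", plane = "AC", t_box_appear = 0, t_save = 1000,
                 trajectory = tibble::tibble(t_ms = 0, value_mm = 300)),
    make_episode(episode_id = "a2", plane = "AC", t_box_appear = 2000, t_save = 3000,
                 trajectory = tibble::tibble(t_ms = 2000, value_mm = 305)),
    make_episode(episode_id = "a3", plane = "AC", t_box_appear = 4000, t_save = 5000,
                 trajectory = tibble::tibble(t_ms = 4000, value_mm = 310)),
    make_episode(episode_id = "h1", plane = "HC", t_box_appear = 6000, t_save = 7000,
                 trajectory = tibble::tibble(t_ms = 6000, value_mm = 290))
  )
  gr <- group_repeats(eps)
  expect_equal(sum(gr$is_repeat), 2L)
  expect_false(gr$is_repeat[gr$episode_id == "a1"])
  one_each <- group_repeats(dplyr::bind_rows(
    make_episode(episode_id = "x1", plane = "HC"),
    make_episode(episode_id = "x2", plane = "AC"),
    make_episode(episode_id = "x3", plane = "FL")))
  expect_equal(sum(one_each$is_repeat), 0L)
})

test_that("total repeats equal the per-plane counting identity on random sessions", {
  withr::local_seed(31)
  for (i in 1:20) {
    n <- sample(1:8, 1)
    planes <- sample(c("HC", "AC", "FL"), n, replace = TRUE)
    eps <- dplyr::bind_rows(lapply(seq_len(n), function(j) {
      make_episode(episode_id = paste0("e", j), plane = planes[j],
                   t_box_appear = j * 1000, t_save = j * 1000 + 500,
                   trajectory = tibble::tibble(t_ms = j * 1000, value_mm = 300))
    }))
    gr <- group_repeats(eps)
    expected <- sum(pmax(0, table(planes) - 1))
    expect_equal(sum(gr$is_repeat), expected)
  }
})

test_that("candidate bounds enumerate first-look and saved values", {
  traj <- tibble::tibble(t_ms = c(0, 3000), value_mm = c(300, 310))
  ep <- make_episode(trajectory = traj, t_save = 5000)
  g <- gaze_dwell("s1", 500, 900, box)
  ev <- detect_bias_events(ep, g)
  cv <- candidate_values(ev)
  expect_equal(c(cv$min_mm, cv$max_mm), c(300, 310))

  # unbiased: saved value bounds both ends
  ev_u <- detect_bias_events(ep, gaze_dwell("s1", 500, 900, box, inside = FALSE))
  cv_u <- candidate_values(ev_u)
  expect_equal(c(cv_u$min_mm, cv_u$max_mm), c(310, 310))
})

test_that("candidate bounds equal brute-force enumeration on a simulated cohort", {
  sim <- simulate_cohort(simulation_config(n_scans = 12, seed = 204))
  ev <- detect_bias_events(sim$episodes, sim$gaze)
  cv <- candidate_values(ev)
  for (r in sample(nrow(cv), 10)) {
    rows <- ev[ev$scan_id == cv$scan_id[r] & ev$plane == cv$plane[r], ]
    vals <- c(rows$saved_value_mm, rows$value_at_first_look[rows$biased])
    expect_equal(cv$min_mm[r], min(vals))
    expect_equal(cv$max_mm[r], max(vals))
    expect_true(all(cv$min_mm[r] <= rows$saved_value_mm &
                      rows$saved_value_mm <= cv$max_mm[r]))
  }
})

test_that("every saved measurement gets exactly one adjustment class and incidence is order-invariant", {
  sim <- simulate_cohort(simulation_config(n_scans = 10, seed = 77))
  rec <- deviation_records(sim$episodes, sim$sessions, sim$gaze)
  expect_false(any(is.na(rec$adjustment)))
  expect_equal(sum(table(rec$adjustment)), nrow(rec))
  expect_true(all(is.na(rec$d_before) == !rec$biased))

  shuffled <- sim$episodes[sample(nrow(sim$episodes)), ]
  rec2 <- deviation_records(shuffled, sim$sessions, sim$gaze)
  expect_equal(mean(rec2$biased), mean(rec$biased))
})

test_that("episode logs survive a JSON-lines round trip and bad logs name the line", {
  sim <- simulate_cohort(simulation_config(n_scans = 3, seed = 5))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_episodes_jsonl(sim$episodes, path)
  back <- read_episodes_jsonl(path)
  expect_equal(nrow(back), nrow(sim$episodes))
  expect_equal(back$saved_value_mm, sim$episodes$saved_value_mm, tolerance = 1e-9)
  expect_equal(back$trajectory[[5]]$value_mm, sim$episodes$trajectory[[5]]$value_mm,
               tolerance = 1e-9)

  writeLines(c(readLines(path)[1], "{not json"), path)
  expect_error(read_episodes_jsonl(path), "line 2")
})

test_that("session metadata reader enforces the plausible GA window", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(scan_id = "s1", operator_id = "op1",
                                  expected_ga_days = 240, bmi = 24,
                                  experience_years = 3), path)
  expect_equal(nrow(read_sessions_csv(path)), 1L)
  readr::write_csv(tibble::tibble(scan_id = "s1", expected_ga_days = 120), path)
  expect_error(read_sessions_csv(path), "plausible window")
})
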