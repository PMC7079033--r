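#' Scan-session event model
#'
#' A scan session couples session metadata (expected GA from dating, maternal
#' BMI, operator experience) with a sequence of measurement episodes and a gaze
#' stream. One *measurement episode* is a single caliper-measurement attempt:
#' the measurement box appears at `t_box_appear` with a box rectangle (the
#' fixation AOI), the displayed value follows a timestamped trajectory while
#' the calipers are adjusted, and the operator saves at `t_save`. The saved
#' value is the last trajectory value.
#'
#' A measurement is *biased* when the operator fixates the measurement box at
#' any point of the caliper-adjustment interval `[t_box_appear, t_save)` before
#' saving; the value in force at the first such fixation is the "before"
#' snapshot, the saved value the "after".
#'
#' @name session-model
NULL

PLANES <- c("HC", "AC", "FL")

#' Validate a measurement-episode table
#'
#' Checks the episode invariants: known planes, non-empty value trajectories
#' with timestamps inside `[t_box_appear, t_save]`, and a saved value equal to
#' the last trajectory value.
#'
#' @param episodes Episode tibble (see [read_episodes_jsonl()] for the schema).
#' @return `episodes`, invisibly, or an error describing the first violation.
#' @export
validate_episodes <- function(episodes) {
  req <- c("scan_id", "episode_id", "plane", "box_left", "box_top", "box_right",
           "box_bottom", "t_box_appear", "t_save", "saved_value_mm", "trajectory")
  miss <- setdiff(req, names(episodes))
  if (length(miss)) abort(paste0("episode table missing columns: ", paste(miss, collapse = ", ")))
  bad <- !episodes$plane %in% PLANES
  if (any(bad)) abort(paste0("unknown plane(s): ", paste(unique(episodes$plane[bad]), collapse = ", ")))
  for (i in seq_len(nrow(episodes))) {
    tr <- episodes$trajectory[[i]]
    id <- episodes$episode_id[i]
    if (is.null(tr) || !nrow(tr)) abort(paste0("episode ", id, " has an empty value trajectory"))
    if (any(tr$t_ms < episodes$t_box_appear[i]) || any(tr$t_ms > episodes$t_save[i])) {
      abort(paste0("episode ", id, " has trajectory timestamps outside [t_box_appear, t_save]"))
    }
    if (any(diff(tr$t_ms) < 0)) abort(paste0("episode ", id, " trajectory is not time-ordered"))
    last_val <- tr$value_mm[nrow(tr)]
    if (abs(last_val - episodes$saved_value_mm[i]) > 1e-6) {
      abort(paste0("episode ", id, " saved value does not equal its last trajectory value"))
    }
  }
  invisible(episodes)
}

# Step-function lookup: value in force at time t (last update at or before t;
# before the first update, the first value).
trajectory_value_at <- function(trajectory, t) {
  idx <- findInterval(t, trajectory$t_ms)
  trajectory$value_mm[pmax(idx, 1L)]
}

#' Detect bias events in measurement episodes
#'
#' Runs fixation detection on each episode's measurement-box AOI over the
#' caliper-adjustment interval `[t_box_appear, t_save)` and emits one bias
#' event per episode with at least one qualifying fixation starting before the
#' save. Episodes without a qualifying fixation are labelled unbiased.
#'
#' @param episodes Episode tibble (validated with [validate_episodes()]).
#' @param gaze Gaze tibble with `scan_id`, `t_ms`, `x`, `y`, `valid`.
#' @param min_fixation_ms,merge_gap_ms Fixation thresholds, see
#'   [detect_fixations()].
#' @return `episodes` with added columns `biased` (logical), `t_first_look`,
#'   `value_at_first_look` (mm; the trajectory value in force at the first
#'   fixation's start), `n_looks`, and `look_values_mm` (list column with the
#'   value in force at each fixation start, first included).
#' @export
detect_bias_events <- function(episodes, gaze, min_fixation_ms = 100,
                               merge_gap_ms = 400) {
  validate_episodes(episodes)
  gaze_by_scan <- split(gaze, gaze$scan_id)
  n <- nrow(episodes)
  biased <- logical(n)
  t_first <- rep(NA_real_, n)
  v_first <- rep(NA_real_, n)
  n_looks <- integer(n)
  look_vals <- vector("list", n)
  for (i in seq_len(n)) {
    g <- gaze_by_scan[[as.character(episodes$scan_id[i])]]
    if (is.null(g)) { look_vals[[i]] <- numeric(); next }
    t0 <- episodes$t_box_appear[i]; t1 <- episodes$t_save[i]
    box <- aoi(episodes$box_left[i], episodes$box_top[i],
               episodes$box_right[i], episodes$box_bottom[i],
               t_start = t0, t_end = t1)
    g <- g[g$t_ms >= t0 - 2 * merge_gap_ms & g$t_ms <= t1 + 2 * merge_gap_ms, , drop = FALSE]
    fx <- detect_fixations(g, box, min_fixation_ms, merge_gap_ms)
    fx <- fx[fx$t_start < t1, , drop = FALSE]
    n_looks[i] <- nrow(fx)
    tr <- episodes$trajectory[[i]]
    look_vals[[i]] <- if (nrow(fx)) trajectory_value_at(tr, fx$t_start) else numeric()
    if (nrow(fx)) {
      biased[i] <- TRUE
      t_first[i] <- fx$t_start[1L]
      v_first[i] <- look_vals[[i]][1L]
    }
  }
  episodes$biased <- biased
  episodes$t_first_look <- t_first
  episodes$value_at_first_look <- v_first
  episodes$n_looks <- n_looks
  episodes$look_values_mm <- look_vals
  episodes
}

#' Classify a caliper adjustment relative to the expected GA
#'
#' For each biased measurement, let `d_before` and `d_after` be the signed
#' deviations (days) of the observed GA from the expected GA at the first look
#' and at save. The adjustment is `toward` when `|d_after|` is smaller than
#' `|d_before|` by more than `tol`, `away` when larger by more than `tol`, and
#' `unchanged` otherwise (`tol` absorbs the weeks+days display rounding).
#' Unbiased measurements are classed `unbiased`. The signed magnitude
#' `adjustment_days = |d_before| - |d_after|` is positive for adjustments
#' toward the expected value.
#'
#' @param events Episode tibble from [detect_bias_events()], with an
#'   `expected_ga_days` column (join the session metadata first).
#' @param std A [growth_standard()] used to convert mm to observed GA.
#' @param tol Unchanged tolerance in days (default 0.25).
#' @return `events` with added columns `observed_ga_before`, `observed_ga_saved`,
#'   `oor_before`, `oor_saved`, `d_before`, `d_after`, `adjustment_days`,
#'   `adjustment` (factor `toward`/`away`/`unchanged`/`unbiased`).
#' @export
classify_adjustment <- function(events, std = default_growth_standard(), tol = 0.25) {
  if (!"expected_ga_days" %in% names(events)) {
    abort("events must carry `expected_ga_days`; join the session metadata first")
  }
  saved <- observed_ga(events$plane, events$saved_value_mm, std)
  events$observed_ga_saved <- saved$ga_days
  events$oor_saved <- saved$oor
  events$observed_ga_before <- NA_real_
  events$oor_before <- NA
  bi <- which(events$biased)
  if (length(bi)) {
    before <- observed_ga(events$plane[bi], events$value_at_first_look[bi], std)
    events$observed_ga_before[bi] <- before$ga_days
    events$oor_before[bi] <- before$oor
  }
  events$d_after <- events$observed_ga_saved - events$expected_ga_days
  events$d_before <- events$observed_ga_before - events$expected_ga_days
  adj <- abs(events$d_before) - abs(events$d_after)
  events$adjustment_days <- ifelse(events$biased, adj, NA_real_)
  cls <- ifelse(!events$biased, "unbiased",
                ifelse(adj > tol, "toward", ifelse(adj < -tol, "away", "unchanged")))
  events$adjustment <- factor(cls, levels = c("toward", "away", "unchanged", "unbiased"))
  events
}

#' Flag repeat measurements
#'
#' Within each scan and plane, the first saved measurement (by save time) is
#' the original; any further saved measurement of the same plane in the same
#' scan is a repeat.
#'
#' @param episodes Episode tibble.
#' @return `episodes` with added columns `measurement_index` (1-based order of
#'   saves within scan and plane) and `is_repeat`.
#' @export
group_repeats <- function(episodes) {
  episodes %>%
    dplyr::group_by(.data$scan_id, .data$plane) %>%
    dplyr::mutate(measurement_index = rank(.data$t_save, ties.method = "first"),
                  is_repeat = .data$measurement_index > 1L) %>%
    dplyr::ungroup()
}

#' Candidate measurement bounds per scan and plane
#'
#' The candidate set of a plane within a scan contains, for every biased
#' episode, both the value at first look and the saved value, and for every
#' unbiased episode its saved value only (a plane with no bias therefore
#' contributes its saved value to both bounds). With
#' `include_intermediate = TRUE` the values at intermediate looks also enter
#' the set.
#'
#' @param events Episode tibble from [detect_bias_events()].
#' @param include_intermediate Include intermediate-look values (default off:
#'   the before/after two-point set).
#' @return Tibble with `scan_id`, `plane`, `min_mm`, `max_mm`, `n_episodes`.
#' @export
candidate_values <- function(events, include_intermediate = FALSE) {
  events %>%
    dplyr::group_by(.data$scan_id, .data$plane) %>%
    dplyr::summarise(
      min_mm = min(candidate_set(.data$saved_value_mm, .data$value_at_first_look,
                                 .data$biased, .data$look_values_mm, include_intermediate)),
      max_mm = max(candidate_set(.data$saved_value_mm, .data$value_at_first_look,
                                 .data$biased, .data$look_values_mm, include_intermediate)),
      n_episodes = dplyr::n(),
      .groups = "drop"
    )
}

candidate_set <- function(saved, first_look, biased, look_values, include_intermediate) {
  vals <- c(saved, first_look[biased])
  if (include_intermediate) vals <- c(vals, unlist(look_values))
  vals[!is.na(vals)]
}

#' Build per-measurement deviation records
#'
#' The central tidy table of the analysis: one row per saved measurement with
#' its bias status, signed and absolute deviations of observed from expected GA
#' before and after the bias event, the adjustment class and magnitude, the
#' repeat flag and the session covariates.
#'
#' @param episodes Episode tibble.
#' @param sessions Session metadata tibble with `scan_id`, `expected_ga_days`,
#'   and optionally `operator_id`, `bmi`, `experience_years`.
#' @param gaze Gaze tibble covering the episodes' AOI active windows.
#' @param std A [growth_standard()].
#' @param min_fixation_ms,merge_gap_ms Fixation thresholds.
#' @param tol Unchanged tolerance (days) for [classify_adjustment()].
#' @return Tibble with one row per saved measurement.
#' @export
deviation_records <- function(episodes, sessions, gaze,
                              std = default_growth_standard(),
                              min_fixation_ms = 100, merge_gap_ms = 400,
                              tol = 0.25) {
  if (!all(c("scan_id", "expected_ga_days") %in% names(sessions))) {
    abort("sessions must have columns scan_id and expected_ga_days")
  }
  meta_cols <- intersect(c("scan_id", "operator_id", "expected_ga_days", "bmi",
                           "experience_years"), names(sessions))
  events <- episodes %>%
    detect_bias_events(gaze, min_fixation_ms, merge_gap_ms) %>%
    group_repeats() %>%
    dplyr::inner_join(sessions[meta_cols], by = "scan_id") %>%
    classify_adjustment(std, tol)
  events %>%
    dplyr::mutate(abs_d_before = abs(.data$d_before),
                  abs_d_after = abs(.data$d_after)) %>%
    dplyr::select(dplyr::any_of(c(
      "scan_id", "episode_id", "operator_id", "plane", "measurement_index",
      "is_repeat", "biased", "n_looks", "expected_ga_days",
      "value_at_first_look", "saved_value_mm", "observed_ga_before",
      "observed_ga_saved", "oor_before", "oor_saved", "d_before", "d_after",
      "abs_d_before", "abs_d_after", "adjustment_days", "adjustment",
      "bmi", "experience_years")))
}

#' Read a measurement-episode JSON-lines log
#'
#' One JSON object per line with fields `scan_id`, `episode_id`, `plane`, `box`
#' (`left`, `top`, `right`, `bottom`), `t_box_appear`, `t_save`, `trajectory`
#' (array of `[t_ms, value_mm]` pairs or of objects) and `saved_value_mm`
#' (optional; defaults to the last trajectory value).
#'
#' @param path JSON-lines file.
#' @return Validated episode tibble.
#' @export
read_episodes_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort(paste0("empty episode log: ", path))
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) abort(paste0("malformed episode log at line ", i,
                                                     " of ", path, ": ", conditionMessage(e))))
    tr <- rec$trajectory
    if (is.matrix(tr)) {
      tr <- tibble::tibble(t_ms = tr[, 1], value_mm = tr[, 2])
    } else if (is.data.frame(tr)) {
      tr <- tibble::as_tibble(tr)
    } else {
      abort(paste0("episode log line ", i, ": unrecognized trajectory encoding"))
    }
    recs[[i]] <- tibble::tibble(
      scan_id = rec$scan_id, episode_id = rec$episode_id, plane = rec$plane,
      box_left = rec$box$left, box_top = rec$box$top,
      box_right = rec$box$right, box_bottom = rec$box$bottom,
      t_box_appear = rec$t_box_appear, t_save = rec$t_save,
      saved_value_mm = rec$saved_value_mm %||% tr$value_mm[nrow(tr)],
      trajectory = list(tr)
    )
  }
  validate_episodes(dplyr::bind_rows(recs))
}

#' Write a measurement-episode table as JSON-lines
#'
#' @param episodes Episode tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_episodes_jsonl <- function(episodes, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(episodes))) {
    tr <- episodes$trajectory[[i]]
    rec <- list(
      scan_id = episodes$scan_id[i], episode_id = episodes$episode_id[i],
      plane = episodes$plane[i],
      box = list(left = episodes$box_left[i], top = episodes$box_top[i],
                 right = episodes$box_right[i], bottom = episodes$box_bottom[i]),
      t_box_appear = episodes$t_box_appear[i], t_save = episodes$t_save[i],
      saved_value_mm = episodes$saved_value_mm[i],
      trajectory = unname(as.matrix(tr[c("t_ms", "value_mm")]))
    )
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read session metadata CSV
#'
#' Expects columns `scan_id`, `operator_id`, `expected_ga_days`, `bmi`,
#' `experience_years`. Expected GA is checked against a plausible growth-scan
#' window.
#'
#' @param path CSV file.
#' @param ga_window Plausible expected-GA window in days.
#' @return Tibble of session metadata.
#' @export
read_sessions_csv <- function(path, ga_window = c(154, 301)) {
  s <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("scan_id", "expected_ga_days")
  miss <- setdiff(req, names(s))
  if (length(miss)) abort(paste0("session metadata missing columns: ", paste(miss, collapse = ", ")))
  out_of_window <- s$expected_ga_days < ga_window[1] | s$expected_ga_days > ga_window[2]
  if (any(out_of_window)) {
    abort(paste0(sum(out_of_window), " session(s) have expected GA outside the plausible window [",
                 ga_window[1], ", ", ga_window[2], "] days"))
  }
  s
}
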