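# Independent brute-force oracles and fixture builders shared across tests.

# Rasterization oracle for fixation detection: attribute every grid cell of the
# stream's support to the sample covering it (midpoint boundaries, matching the
# documented sample->interval semantics), run-length the in/out sequence, merge
# gaps <= merge_gap_ms, then threshold. With integer sample timestamps all
# episode boundaries are multiples of 0.5 ms, so a 0.5 ms grid (cell midpoints
# at 0.25 offsets) makes the rasterization exact, not approximate.
oracle_fixations <- function(gaze, box, min_fixation_ms = 100, merge_gap_ms = 400,
                             cell = 0.5) {
  empty <- tibble::tibble(t_start = numeric(), t_end = numeric(),
                          duration_ms = numeric())
  if (!nrow(gaze)) return(empty)
  t <- as.numeric(gaze$t_ms)
  n <- length(t)
  inside <- gaze$valid & gaze$x >= box$left & gaze$x <= box$right &
    gaze$y >= box$top & gaze$y <= box$bottom
  inside[is.na(inside)] <- FALSE
  lo <- max(t[1], box$t_start)
  hi <- min(t[n], box$t_end)
  if (hi <= lo) return(empty)
  mids <- seq(lo + cell / 2, hi, by = cell)
  mids <- mids[mids < hi]
  if (!length(mids)) return(empty)
  b <- if (n == 1L) c(t, t) else c(t[1], (t[-1] + t[-n]) / 2, t[n])
  covering <- findInterval(mids, b, rightmost.closed = TRUE)
  covering <- pmin(pmax(covering, 1L), n)
  cell_in <- inside[covering]
  r <- rle(as.logical(cell_in))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep)) return(empty)
  ep_start <- lo + (starts[keep] - 1L) * cell
  ep_end <- lo + ends[keep] * cell
  ep_end <- pmin(ep_end, hi)
  # merge interruptions <= merge_gap_ms
  ms <- ep_start[1]; me <- ep_end[1]; k <- 1L
  for (i in seq_along(ep_start)[-1]) {
    if (ep_start[i] - me[k] <= merge_gap_ms) me[k] <- ep_end[i]
    else { k <- k + 1L; ms[k] <- ep_start[i]; me[k] <- ep_end[i] }
  }
  dur <- me - ms
  ok <- dur >= min_fixation_ms
  tibble::tibble(t_start = ms[ok], t_end = me[ok], duration_ms = dur[ok])
}

# Random gaze stream with integer timestamps, clustered in/out runs (two-state
# Markov chain) and tracker-loss samples. `box` gives the AOI rectangle.
random_gaze_stream <- function(hz, duration_ms, box, p_stay = 0.92, p_loss = 0.05) {
  dt <- 1000 / hz
  n <- max(2L, round(duration_ms / dt))
  steps <- pmax(1L, round(rnorm(n, dt, dt * 0.15)))
  t <- cumsum(steps)
  state <- logical(n)
  state[1] <- runif(1) < 0.5
  for (i in 2:n) {
    state[i] <- if (runif(1) < p_stay) state[i - 1] else !state[i - 1]
  }
  x <- ifelse(state, runif(n, box$left, box$right), runif(n, 0, box$left - 10))
  y <- ifelse(state, runif(n, box$top, box$bottom), runif(n, 0, box$top - 10))
  tibble::tibble(t_ms = t, x = x, y = y, valid = runif(n) > p_loss)
}

# Toy growth standard with linear curves on the day/mm scale:
# measurement(mm) = slope_inv * GA(days) per plane, i.e. ga = value / slope_inv.
toy_standard <- function(slope = 0.5) {
  plane <- function() list(coefficients = c(0, slope), measurement_unit = "mm",
                           ga_unit = "days", valid_ga_days = c(100, 300))
  growth_standard(
    "toy-linear",
    planes = list(HC = plane(), AC = plane(), FL = plane()),
    efw = list(type = "log10_cm",
               coefficients = list(intercept = 1.326, hc = 0.0107, ac = 0.0438,
                                   fl = 0.158, ac_fl = -0.00326)),
    efw_reference = list(type = "log_quadratic_weeks",
                         mean_coefficients = c(0.578, 0.332, -0.00354),
                         log_sd = 0.127, valid_ga_days = c(70, 294))
  )
}

# Hand-built measurement episode for session-model tests.
make_episode <- function(scan_id = "s1", episode_id = "e1", plane = "HC",
                         t_box_appear = 0, t_save = 5000,
                         trajectory = tibble::tibble(t_ms = 0, value_mm = 300),
                         box = list(left = 100, top = 100, right = 200, bottom = 150)) {
  tibble::tibble(
    scan_id = scan_id, episode_id = episode_id, plane = plane,
    box_left = box$left, box_top = box$top, box_right = box$right,
    box_bottom = box$bottom, t_box_appear = t_box_appear, t_save = t_save,
    saved_value_mm = trajectory$value_mm[nrow(trajectory)],
    trajectory = list(trajectory)
  )
}

# Gaze samples forming a dwell inside an episode's box over [t0, t1] at `hz`.
gaze_dwell <- function(scan_id, t0, t1, box, hz = 100, inside = TRUE) {
  t <- seq(t0, t1, by = 1000 / hz)
  n <- length(t)
  tibble::tibble(
    scan_id = scan_id, t_ms = t,
    x = if (inside) runif(n, box$left, box$right) else runif(n, 0, box$left - 20),
    y = if (inside) runif(n, box$top, box$bottom) else runif(n, 0, box$top - 20),
    valid = TRUE
  )
}
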