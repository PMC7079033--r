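#' Area of interest (AOI)
#'
#' A screen rectangle with an active time interval, used as the dwell target
#' for fixation detection — in this pipeline, the scanner's measurement box
#' while it is displayed.
#'
#' @param left,top,right,bottom Rectangle in screen pixels; `left < right`,
#'   `top < bottom`. A gaze sample on the boundary counts as inside.
#' @param t_start,t_end Active interval `[t_start, t_end)` in ms since scan
#'   start.
#' @return A list of class `aoi`.
#' @export
aoi <- function(left, top, right, bottom, t_start, t_end) {
  stopifnot(left < right, top < bottom, t_start < t_end)
  structure(list(left = left, top = top, right = right, bottom = bottom,
                 t_start = t_start, t_end = t_end), class = "aoi")
}

empty_fixations <- function() {
  tibble::tibble(t_start = numeric(), t_end = numeric(), duration_ms = numeric())
}

# Sample coverage intervals: interior boundaries at midpoints between
# consecutive timestamps; the stream's support is [t_first, t_last].
sample_boundaries <- function(t) {
  n <- length(t)
  if (n == 1L) return(c(t, t))
  c(t[1L], (t[-1L] + t[-n]) / 2, t[n])
}

#' Detect eye fixations on an area of interest
#'
#' Converts a raw gaze-sample stream into dwell episodes on the AOI rectangle
#' and applies the standard fixation rule: interruptions of at most
#' `merge_gap_ms` (400 ms) join adjacent dwells into a single fixation episode,
#' and only merged episodes lasting at least `min_fixation_ms` (100 ms) are
#' kept. Merging is applied before the duration threshold.
#'
#' A sample is "in AOI" iff the tracker signal is valid and the point lies
#' inside the rectangle (boundary inclusive); invalid (tracker-loss) samples
#' count as out-of-AOI and their gaps participate in the merge rule like any
#' other interruption. Each sample covers the interval between the midpoints to
#' its neighbours (the first and last samples are bounded by their own
#' timestamps), and episodes are clipped to the AOI's active interval, so a
#' fixation's duration spans merged gaps: 80 ms in, a 50 ms glance away, and
#' 80 ms back yields one 210 ms fixation.
#'
#' @param gaze Data frame with columns `t_ms` (strictly increasing), `x`, `y`
#'   (pixels) and `valid` (logical).
#' @param box An [aoi()].
#' @param min_fixation_ms Minimum merged episode duration, ms.
#' @param merge_gap_ms Maximum interruption joined into one episode, ms.
#' @return Tibble with columns `t_start`, `t_end`, `duration_ms`, sorted and
#'   non-overlapping; consecutive rows are separated by more than
#'   `merge_gap_ms`.
#' @export
detect_fixations <- function(gaze, box, min_fixation_ms = 100, merge_gap_ms = 400) {
  stopifnot(inherits(box, "aoi"), min_fixation_ms >= 0, merge_gap_ms >= 0)
  req <- c("t_ms", "x", "y", "valid")
  if (!all(req %in% names(gaze))) {
    abort(paste0("gaze stream must have columns: ", paste(req, collapse = ", ")))
  }
  n <- nrow(gaze)
  if (n == 0L) return(empty_fixations())
  t <- as.numeric(gaze$t_ms)
  if (n > 1L && any(diff(t) <= 0)) {
    abort("gaze stream timestamps must be strictly increasing")
  }
  inside <- gaze$valid &
    gaze$x >= box$left & gaze$x <= box$right &
    gaze$y >= box$top & gaze$y <= box$bottom
  inside[is.na(inside)] <- FALSE
  if (!any(inside)) return(empty_fixations())

  b <- sample_boundaries(t)
  r <- rle(as.logical(inside))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  ep_start <- b[starts[keep]]
  ep_end <- b[ends[keep] + 1L]

  # clip to the AOI active interval
  ep_start <- pmax(ep_start, box$t_start)
  ep_end <- pmin(ep_end, box$t_end)
  ok <- ep_end > ep_start
  ep_start <- ep_start[ok]; ep_end <- ep_end[ok]
  if (!length(ep_start)) return(empty_fixations())

  merged <- merge_episodes(ep_start, ep_end, merge_gap_ms)
  dur <- merged$end - merged$start
  keep <- dur >= min_fixation_ms
  tibble::tibble(t_start = merged$start[keep], t_end = merged$end[keep],
                 duration_ms = dur[keep])
}

merge_episodes <- function(start, end, gap) {
  out_s <- start[1L]; out_e <- end[1L]
  k <- 1L
  for (i in seq_along(start)[-1L]) {
    if (start[i] - out_e[k] <= gap) {
      out_e[k] <- max(out_e[k], end[i])
    } else {
      k <- k + 1L
      out_s[k] <- start[i]; out_e[k] <- end[i]
    }
  }
  list(start = out_s, end = out_e)
}

#' Select fixations overlapping a time window
#'
#' @param fixations Tibble from [detect_fixations()].
#' @param t0,t1 Window `[t0, t1)`, `t0 < t1`.
#' @param clip If `TRUE`, returned fixations are clipped to the window and
#'   `duration_ms` recomputed; if `FALSE` (default) overlapping fixations are
#'   returned whole.
#' @return Tibble of the fixations that overlap the window.
#' @export
fixations_in_window <- function(fixations, t0, t1, clip = FALSE) {
  stopifnot(t0 < t1)
  hit <- fixations$t_start < t1 & fixations$t_end > t0
  out <- fixations[hit, , drop = FALSE]
  if (clip && nrow(out)) {
    out$t_start <- pmax(out$t_start, t0)
    out$t_end <- pmin(out$t_end, t1)
    out$duration_ms <- out$t_end - out$t_start
  }
  out
}

#' Read a gaze-stream CSV
#'
#' Expects columns `t_ms`, `x`, `y`, `valid` and optionally `scan_id`.
#'
#' @param path CSV file path.
#' @return Tibble of gaze samples.
#' @export
read_gaze_csv <- function(path) {
  g <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("t_ms", "x", "y", "valid")
  if (!all(req %in% names(g))) {
    abort(paste0("gaze CSV must have columns: ", paste(req, collapse = ", ")))
  }
  g$valid <- as.logical(g$valid)
  g
}
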