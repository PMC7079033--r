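#' Fetal growth standards
#'
#' A growth standard bundles, for each biometric plane (head circumference HC,
#' abdominal circumference AC, femur length FL), an invertible curve linking the
#' measurement (mm) to a gestational age ("observed GA", days), together with an
#' estimated-fetal-weight (EFW) formula and an EFW-for-GA reference used for
#' Z-scores, centiles and SGA/AGA/LGA classification.
#'
#' Coefficients are never hard-coded in package logic: they are read from a
#' structured YAML registry (see
#' `system.file("extdata", "growth_standards.yaml", package = "scanbias")` for
#' the shipped Hadlock-type default) or supplied programmatically via
#' [growth_standard()].
#'
#' The GA-from-measurement curve is a polynomial in the measurement, declared
#' with explicit units; the forward (measurement-from-GA) direction is obtained
#' by numerical root finding on the same curve, so any strictly increasing
#' polynomial works without an analytic inverse. Outside the declared valid GA
#' range the curve is extrapolated, never clamped, and results carry an
#' out-of-range (`oor`) flag; this mirrors scanner behaviour where off-table
#' values are computed from the original formula.
#'
#' @name growth-standards
NULL

GA_BRACKET_MM <- c(1e-3, 3000)

#' Construct a growth standard
#'
#' @param name Identifier for the standard.
#' @param planes Named list (names among `"HC"`, `"AC"`, `"FL"`); each element a
#'   list with `coefficients` (polynomial, intercept first), `measurement_unit`
#'   (`"mm"` or `"cm"`), `ga_unit` (`"days"` or `"weeks"`) and `valid_ga_days`
#'   (length-2 numeric).
#' @param efw List with `type = "log10_cm"` and named `coefficients`
#'   (`intercept`, `hc`, `ac`, `fl`, `ac_fl`) for
#'   `log10(EFW g) = intercept + hc*HC + ac*AC + fl*FL + ac_fl*AC*FL` (cm).
#' @param efw_reference List with `type = "log_quadratic_weeks"`,
#'   `mean_coefficients` (quadratic in GA weeks for mean `ln(EFW)`), `log_sd`
#'   (SD of `ln(EFW)` at fixed GA) and `valid_ga_days`.
#' @param centile_cutoffs Named list/vector with `sga` and `lga` centile
#'   cutoffs as proportions (defaults 0.10 and 0.90).
#'
#' @return An object of class `growth_standard`.
#' @export
growth_standard <- function(name, planes, efw = NULL, efw_reference = NULL,
                            centile_cutoffs = list(sga = 0.10, lga = 0.90)) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!length(planes) || is.null(names(planes))) {
    stop("`planes` must be a named list of per-plane curve definitions", call. = FALSE)
  }
  bad <- setdiff(names(planes), c("HC", "AC", "FL"))
  if (length(bad)) {
    stop("unknown plane(s) in standard '", name, "': ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  planes <- lapply(planes, function(p) {
    p$measurement_unit <- match.arg(p$measurement_unit, c("mm", "cm"))
    p$ga_unit <- match.arg(p$ga_unit, c("days", "weeks"))
    coefs <- as.numeric(p$coefficients)
    if (length(coefs) < 2L || any(coefs[-1L] < 0) || all(coefs[-1L] == 0)) {
      stop("curve coefficients must define a strictly increasing polynomial ",
           "(non-intercept coefficients >= 0, at least one > 0)", call. = FALSE)
    }
    p$coefficients <- coefs
    p$valid_ga_days <- as.numeric(p$valid_ga_days)
    stopifnot(length(p$valid_ga_days) == 2L, diff(p$valid_ga_days) > 0)
    p
  })
  std <- structure(
    list(name = name, planes = planes, efw = efw, efw_reference = efw_reference,
         centile_cutoffs = as.list(centile_cutoffs)),
    class = "growth_standard"
  )
  for (pl in names(planes)) {
    g <- seq(planes[[pl]]$valid_ga_days[1], planes[[pl]]$valid_ga_days[2], length.out = 25)
    m <- measurement_from_ga(pl, g, std)
    if (any(diff(m) <= 0)) {
      stop("measurement-from-GA curve for plane ", pl,
           " is not strictly increasing over its valid range", call. = FALSE)
    }
  }
  std
}

#' @export
print.growth_standard <- function(x, ...) {
  cat("<growth_standard> ", x$name, "\n", sep = "")
  for (pl in names(x$planes)) {
    p <- x$planes[[pl]]
    cat(sprintf("  %s: ga(%s->%s) poly deg %d, valid GA %g-%g days\n",
                pl, p$measurement_unit, p$ga_unit,
                length(p$coefficients) - 1L, p$valid_ga_days[1], p$valid_ga_days[2]))
  }
  if (!is.null(x$efw)) cat("  EFW: ", x$efw$type, "\n", sep = "")
  if (!is.null(x$efw_reference)) cat("  EFW-for-GA reference: ", x$efw_reference$type, "\n", sep = "")
  invisible(x)
}

#' Read growth standards from a YAML/JSON registry
#'
#' @param path Path to a registry file with a top-level `standards` map.
#' @param name Which standard to load; defaults to the first listed.
#' @return A [growth_standard()] object.
#' @export
read_growth_standard <- function(path, name = NULL) {
  if (!file.exists(path)) stop("no such standards file: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$standards)) stop("registry has no `standards` block", call. = FALSE)
  if (is.null(name)) name <- names(raw$standards)[1L]
  s <- raw$standards[[name]]
  if (is.null(s)) stop("standard '", name, "' not found in ", path, call. = FALSE)
  growth_standard(
    name = name, planes = s$planes, efw = s$efw, efw_reference = s$efw_reference,
    centile_cutoffs = s$centile_cutoffs %||% list(sga = 0.10, lga = 0.90)
  )
}

#' The shipped default growth standard
#'
#' Loads the Hadlock-type default (dating polynomials, three-parameter log10
#' EFW formula, log-quadratic EFW-for-GA reference) from the package registry.
#'
#' @return A [growth_standard()] object.
#' @export
default_growth_standard <- function() {
  std <- the$default_standard
  if (is.null(std)) {
    path <- system.file("extdata", "growth_standards.yaml", package = "scanbias")
    std <- read_growth_standard(path, "hadlock")
    the$default_standard <- std
  }
  std
}

the <- new.env(parent = emptyenv())

plane_def <- function(std, plane) {
  p <- std$planes[[plane]]
  if (is.null(p)) {
    stop("growth standard '", std$name, "' has no coefficients for plane '",
         plane, "'", call. = FALSE)
  }
  p
}

# Evaluate the GA-from-measurement polynomial; x in mm, result in days.
ga_curve_days <- function(p, value_mm) {
  x <- if (p$measurement_unit == "cm") value_mm / 10 else value_mm
  ga <- 0
  for (i in seq_along(p$coefficients)) ga <- ga + p$coefficients[i] * x^(i - 1L)
  if (p$ga_unit == "weeks") ga * 7 else ga
}

#' Observed gestational age from a biometric measurement
#'
#' Converts measurements (mm) to the gestational age the growth standard's
#' curve implies — the "observed value" shown in the scanner's measurement box.
#' Values mapping outside the standard's tabulated GA range are computed by
#' extrapolating the same curve (never clamped, never missing) and flagged
#' `oor = TRUE`.
#'
#' @param plane Character vector of planes (`"HC"`, `"AC"`, `"FL"`), recycled
#'   against `value_mm`.
#' @param value_mm Positive measurement(s) in millimetres.
#' @param std A [growth_standard()].
#' @return A tibble with columns `plane`, `value_mm`, `ga_days`, `oor`.
#' @examples
#' observed_ga("HC", 300)
#' @export
observed_ga <- function(plane, value_mm, std = default_growth_standard()) {
  n <- max(length(plane), length(value_mm))
  plane <- as.character(rep_len(plane, n))
  value_mm <- rep_len(as.numeric(value_mm), n)
  if (any(!is.finite(value_mm) | value_mm <= 0)) {
    stop("all measurement values must be finite and > 0", call. = FALSE)
  }
  ga <- numeric(n)
  oor <- logical(n)
  for (pl in unique(plane)) {
    p <- plane_def(std, pl)
    idx <- which(plane == pl)
    ga[idx] <- ga_curve_days(p, value_mm[idx])
    oor[idx] <- ga[idx] < p$valid_ga_days[1] | ga[idx] > p$valid_ga_days[2]
  }
  tibble::tibble(plane = plane, value_mm = value_mm, ga_days = ga, oor = oor)
}

#' Measurement from gestational age (forward curve)
#'
#' Inverts the GA-from-measurement curve numerically (bisection via
#' [stats::uniroot()], tolerance well below 0.01 day) to obtain the measurement
#' in mm whose observed GA equals `ga_days`. Used by the simulator and for
#' round-trip validation.
#'
#' @inheritParams observed_ga
#' @param ga_days Gestational age(s) in days.
#' @return Numeric vector of measurements in mm.
#' @export
measurement_from_ga <- function(plane, ga_days, std = default_growth_standard()) {
  n <- max(length(plane), length(ga_days))
  plane <- as.character(rep_len(plane, n))
  ga_days <- rep_len(as.numeric(ga_days), n)
  out <- numeric(n)
  for (pl in unique(plane)) {
    p <- plane_def(std, pl)
    idx <- which(plane == pl)
    lo <- ga_curve_days(p, GA_BRACKET_MM[1])
    hi <- ga_curve_days(p, GA_BRACKET_MM[2])
    for (i in idx) {
      g <- ga_days[i]
      if (g <= lo || g >= hi) {
        stop("cannot invert curve for plane ", pl, " at GA ", g,
             " days: outside the search bracket", call. = FALSE)
      }
      out[i] <- stats::uniroot(function(x) ga_curve_days(p, x) - g,
                               interval = GA_BRACKET_MM, tol = 1e-4)$root
    }
  }
  out
}

#' Estimated fetal weight from HC, AC and FL
#'
#' Evaluates the standard's configured EFW formula (default: Hadlock-type
#' three-parameter, log10 scale, inputs in cm) and returns the weight in grams.
#' Strictly increasing in each measurement within the physiologic domain.
#'
#' @param hc_mm,ac_mm,fl_mm Measurements in millimetres; all three required.
#' @param std A [growth_standard()] with an `efw` block.
#' @return Numeric vector of weights in grams.
#' @examples
#' efw(300, 300, 60)
#' @export
efw <- function(hc_mm, ac_mm, fl_mm, std = default_growth_standard()) {
  if (is.null(std$efw)) stop("standard '", std$name, "' has no EFW formula", call. = FALSE)
  n <- max(length(hc_mm), length(ac_mm), length(fl_mm))
  hc <- rep_len(as.numeric(hc_mm), n)
  ac <- rep_len(as.numeric(ac_mm), n)
  fl <- rep_len(as.numeric(fl_mm), n)
  if (any(is.na(hc) | is.na(ac) | is.na(fl))) {
    stop("EFW requires all three planes (HC, AC, FL); missing values present",
         call. = FALSE)
  }
  if (any(hc <= 0 | ac <= 0 | fl <= 0)) {
    stop("EFW inputs must all be > 0", call. = FALSE)
  }
  if (std$efw$type != "log10_cm") {
    stop("unsupported EFW formula type: ", std$efw$type, call. = FALSE)
  }
  cf <- std$efw$coefficients
  l10 <- cf$intercept + cf$hc * hc / 10 + cf$ac * ac / 10 + cf$fl * fl / 10 +
    cf$ac_fl * (ac / 10) * (fl / 10)
  10^l10
}

efw_ref_mean_sd <- function(std, ga_days) {
  ref <- std$efw_reference
  if (is.null(ref)) {
    stop("standard '", std$name, "' has no EFW-for-GA reference", call. = FALSE)
  }
  if (ref$type != "log_quadratic_weeks") {
    stop("unsupported EFW reference type: ", ref$type, call. = FALSE)
  }
  w <- ga_days / 7
  cf <- as.numeric(ref$mean_coefficients)
  mu <- cf[1] + cf[2] * w + cf[3] * w^2
  list(mean_log = mu, sd_log = ref$log_sd,
       oor = ga_days < ref$valid_ga_days[1] | ga_days > ref$valid_ga_days[2])
}

#' EFW Z-score and centile for gestational age
#'
#' `Z = (ln(EFW) - mean ln(EFW) at GA) / SD(ln EFW)` against the standard's
#' EFW-for-GA reference; the centile is `pnorm(Z)`. GAs outside the reference
#' range are extrapolated (flagged when `details = TRUE`).
#'
#' @param efw_g EFW in grams.
#' @param ga_days Gestational age in days (the expected GA at scan).
#' @param std A [growth_standard()] with an `efw_reference` block.
#' @param details If `TRUE` return a tibble with `z`, `centile` and `ga_oor`;
#'   otherwise (default) the numeric Z-scores.
#' @export
efw_zscore <- function(efw_g, ga_days, std = default_growth_standard(),
                       details = FALSE) {
  n <- max(length(efw_g), length(ga_days))
  efw_g <- rep_len(as.numeric(efw_g), n)
  ga_days <- rep_len(as.numeric(ga_days), n)
  stopifnot(all(efw_g > 0))
  ref <- efw_ref_mean_sd(std, ga_days)
  z <- (log(efw_g) - ref$mean_log) / ref$sd_log
  if (!details) return(z)
  tibble::tibble(z = z, centile = stats::pnorm(z), ga_oor = ref$oor)
}

#' @rdname efw_zscore
#' @export
efw_centile <- function(efw_g, ga_days, std = default_growth_standard()) {
  stats::pnorm(efw_zscore(efw_g, ga_days, std))
}

#' Classify fetal size (SGA / AGA / LGA)
#'
#' SGA iff the EFW centile is strictly below the lower cutoff, LGA iff strictly
#' above the upper cutoff, otherwise AGA; a centile exactly at a cutoff is AGA.
#' Cutoffs default to the standard's configured values (10th/90th centile).
#'
#' @inheritParams efw_zscore
#' @param cutoffs Length-2 numeric `(sga, lga)` centile cutoffs as proportions.
#' @return Factor with levels `SGA`, `AGA`, `LGA`.
#' @export
classify_size <- function(efw_g, ga_days, std = default_growth_standard(),
                          cutoffs = NULL) {
  if (is.null(cutoffs)) {
    cutoffs <- c(std$centile_cutoffs$sga %||% 0.10, std$centile_cutoffs$lga %||% 0.90)
  }
  stopifnot(length(cutoffs) == 2L, cutoffs[1] < cutoffs[2])
  cent <- efw_centile(efw_g, ga_days, std)
  cls <- ifelse(cent < cutoffs[1], "SGA", ifelse(cent > cutoffs[2], "LGA", "AGA"))
  factor(cls, levels = c("SGA", "AGA", "LGA"))
}

#' Present gestational age in days as weeks + days
#'
#' @param ga_days Gestational age in days.
#' @return Character vector like `"34+2"`.
#' @export
format_ga <- function(ga_days) {
  d <- round(ga_days)
  sprintf("%d+%d", d %/% 7L, d %% 7L)
}
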