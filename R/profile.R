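#' Discrete temperature profile
#'
#' A temperature profile is the model's forcing function: a series of
#' discrete temperature points at uniformly spaced times starting at zero.
#' It is stored as a tibble with columns `time_min` and `temp_C`, carrying
#' the applied heating rate (if any) as an attribute. The uniform spacing is
#' what the per-interval Simpson accumulation assumes; non-uniform series
#' are rejected (see [resample_profile()] to regrid them explicitly).
#'
#' @param time_min Strictly increasing times (min), uniformly spaced,
#'   starting at 0.
#' @param temp_C Temperatures (deg C), same length as `time_min`.
#' @param heating_rate Optional applied constant ramp rate (deg C/min),
#'   recorded as experiment metadata. It is *not* inferred from the series.
#'
#' @return A tibble of class `temp_profile`.
#' @examples
#' temp_profile(time_min = seq(0, 10, by = 1/60),
#'              temp_C = 54.75 + 1.64 * seq(0, 10, by = 1/60),
#'              heating_rate = 1.64)
#' @export
temp_profile <- function(time_min, temp_C, heating_rate = NULL) {
  out <- tibble(time_min = as.double(time_min), temp_C = as.double(temp_C))
  if (!is.null(heating_rate)) check_scalar(heating_rate, "heating_rate", positive = TRUE)
  attr(out, "heating_rate") <- heating_rate
  class(out) <- c("temp_profile", class(tibble()))
  validate_profile(out)
}

#' @rdname temp_profile
#' @param profile Object to validate as a temperature profile.
#' @export
validate_profile <- function(profile) {
  if (!is.data.frame(profile) ||
      !all(c("time_min", "temp_C") %in% names(profile))) {
    stop_geeraerd("A temperature profile needs `time_min` and `temp_C` columns.",
                  "geeraerd_invalid_profile")
  }
  t <- profile$time_min
  temp <- profile$temp_C
  if (length(t) < 2L) {
    stop_geeraerd("A temperature profile needs at least 2 points.",
                  "geeraerd_invalid_profile")
  }
  if (any(!is.finite(t)) || any(!is.finite(temp))) {
    stop_geeraerd("Non-finite value in temperature profile.",
                  "geeraerd_invalid_profile")
  }
  if (abs(t[1L]) > 1e-12) {
    stop_geeraerd("Profile times must start at 0.", "geeraerd_invalid_profile")
  }
  steps <- diff(t)
  dt <- steps[1L]
  if (dt <= 0 || any(abs(steps - dt) > 1e-9 * max(dt, 1))) {
    bad <- which(abs(steps - dt) > 1e-9 * max(dt, 1))[1L]
    stop_geeraerd(
      sprintf("Profile times must be strictly increasing with uniform spacing; first offending row: %d.",
              if (dt <= 0) 2L else bad + 1L),
      "geeraerd_nonuniform_grid")
  }
  profile
}

# uniform step of a validated profile
profile_dt <- function(profile) {
  profile$time_min[2L] - profile$time_min[1L]
}

#' Resample a temperature series onto a uniform grid
#'
#' Linear interpolation of temperature onto a uniform grid of step `dt`,
#' producing a valid [temp_profile()]. Use this to regularise measured
#' series whose logging interval drifted; the quadrature itself only accepts
#' uniform grids.
#'
#' @param data A data frame with `time_min` and `temp_C` columns (strictly
#'   increasing times, not necessarily uniform).
#' @param dt Target uniform step (min).
#' @param heating_rate Optional metadata ramp rate carried to the result.
#'
#' @return A `temp_profile` tibble.
#' @export
resample_profile <- function(data, dt, heating_rate = NULL) {
  stopifnot(is.data.frame(data), all(c("time_min", "temp_C") %in% names(data)))
  check_scalar(dt, "dt", positive = TRUE)
  t <- data$time_min
  if (is.unsorted(t, strictly = TRUE)) {
    stop_geeraerd("`time_min` must be strictly increasing before resampling.",
                  "geeraerd_invalid_profile")
  }
  grid <- seq(0, max(t), by = dt)
  f <- approxfun(t, data$temp_C, rule = 2)
  temp_profile(grid, f(grid), heating_rate = heating_rate)
}

#' @export
print.temp_profile <- function(x, ...) {
  hr <- attr(x, "heating_rate")
  cat(sprintf("<temp_profile> %d points, dt = %.6g min, span %.6g min, %.6g-%.6g degC%s\n",
              nrow(x), profile_dt(x), max(x$time_min), min(x$temp_C), max(x$temp_C),
              if (is.null(hr)) "" else sprintf(", heating rate %g degC/min", hr)))
  NextMethod()
}

#' Plot a temperature profile
#'
#' @param object A `temp_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.temp_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_min, y = .data$temp_C)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(x = "Time (min)", y = "Temperature (°C)")
}
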