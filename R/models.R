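#' Bigelow specific inactivation rate
#'
#' Evaluates the Bigelow secondary model
#' \deqn{k_{max}(T) = \frac{\ln 10}{AsymD_{ref}}
#'       \exp\!\left(\frac{\ln 10}{z}(T - T_{ref})\right)}
#' mapping temperature to the specific inactivation rate (1/min). The rate is
#' strictly positive and increases 10-fold for every `z` degrees above
#' `T_ref`.
#'
#' @param temp_C Temperature(s) in deg C; vectorised.
#' @param bigelow A [bigelow_params()] object.
#'
#' @return Numeric vector of rates (1/min), same length as `temp_C`.
#' @examples
#' p <- bigelow_params(asym_D_ref = 8, T_ref = 60, z = 5)
#' bigelow_kmax(60, p)          # ln(10)/8
#' bigelow_kmax(65, p) / bigelow_kmax(60, p)  # 10
#' @export
bigelow_kmax <- function(temp_C, bigelow) {
  stopifnot(inherits(bigelow, "bigelow_params"))
  if (!is.numeric(temp_C) || length(temp_C) == 0L || any(!is.finite(temp_C))) {
    stop_geeraerd("`temp_C` must be finite: non-finite temperature is an invalid profile point.",
                  "geeraerd_invalid_profile")
  }
  (LN10 / bigelow$asym_D_ref) * exp((LN10 / bigelow$z) * (temp_C - bigelow$T_ref))
}

#' Heating-rate adaptation factor
#'
#' Physiological adaptation to mild heat stress reduces the effective
#' inactivation rate when heating is slow. The factor is
#' \deqn{k = \frac{k_1 \, r}{k_2 + r}}
#' where `r` is the applied constant heating rate (deg C/min). It is monotone
#' increasing in `r`, bounded by `k1`, and equals `k1 / 2` at `r = k2`. Fast
#' heating leaves no time for adaptation, so `k -> k1` (and the model family
#' argues `k1 = 1`) as `r` grows.
#'
#' @param heating_rate Applied constant heating rate (deg C/min); must be
#'   strictly positive (the factor is defined only for an applied ramp).
#' @param adaptation An [adaptation_params()] object.
#'
#' @return The dimensionless factor `k` in `(0, k1]`.
#' @examples
#' a <- adaptation_params(k1 = 0.969, k2 = 0.060)
#' adaptation_factor(1.64, a)
#' @export
adaptation_factor <- function(heating_rate, adaptation) {
  stopifnot(inherits(adaptation, "adaptation_params"))
  if (!is.numeric(heating_rate) || any(!is.finite(heating_rate)) ||
      any(heating_rate <= 0)) {
    stop_geeraerd("`heating_rate` must be > 0: the adaptation factor is defined only for an applied heating ramp.",
                  "geeraerd_invalid_rate")
  }
  adaptation$k1 * heating_rate / (adaptation$k2 + heating_rate)
}

#' Estimate the heating rate of a ramp segment
#'
#' Ordinary least-squares slope of temperature against time over the ramp
#' portion of a profile. This is a convenience for data exploration only: the
#' adaptation factor uses the *applied* heating rate recorded as experiment
#' metadata, not a value inferred from the measured profile.
#'
#' @param profile A temperature profile (see [temp_profile()]).
#' @param t_max Optional end of the ramp segment (min); rows with
#'   `time_min > t_max` are ignored (use this to exclude a holding phase).
#'
#' @return Estimated slope (deg C/min).
#' @export
estimate_heating_rate <- function(profile, t_max = NULL) {
  profile <- validate_profile(profile)
  if (!is.null(t_max)) profile <- profile[profile$time_min <= t_max, ]
  if (nrow(profile) < 2L) {
    stop_geeraerd("Need at least two profile points to estimate a heating rate.",
                  "geeraerd_invalid_profile")
  }
  unname(stats::coef(stats::lm(temp_C ~ time_min, data = profile))[2L])
}
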