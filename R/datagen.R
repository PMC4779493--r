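#' Construct standard temperature profiles
#'
#' Generates the discrete uniform-grid temperature profiles used in
#' nonisothermal inactivation experiments: a linear heating ramp, a ramp
#' followed by an isothermal hold (continuous at the junction), or a
#' sinusoidal oscillation.
#'
#' @param kind `"linear_ramp"`, `"ramp_hold"` or `"sine"`.
#' @param T_start Starting temperature (deg C; ramp kinds).
#' @param rate Heating rate (deg C/min; ramp kinds); recorded as the
#'   profile's `heating_rate` metadata.
#' @param T_hold Holding temperature (deg C; `ramp_hold`). The ramp reaches
#'   `T_hold` at `t_ramp_end = (T_hold - T_start) / rate`, which must lie
#'   within `duration`.
#' @param mean,amplitude,period Sine parameters: `T(t) = mean + amplitude *
#'   sin(2 * pi * t / period)`.
#' @param duration Total span (min).
#' @param dt Grid step (min); default 1/60 min.
#'
#' @return A [temp_profile()].
#' @examples
#' make_profile("linear_ramp", T_start = 35, rate = 1.64, duration = 12)
#' @export
make_profile <- function(kind = c("linear_ramp", "ramp_hold", "sine"),
                         T_start = NULL, rate = NULL, T_hold = NULL,
                         mean = NULL, amplitude = NULL, period = NULL,
                         duration, dt = 1/60) {
  kind <- match.arg(kind)
  check_scalar(duration, "duration", positive = TRUE)
  check_scalar(dt, "dt", positive = TRUE)
  t <- seq(0, duration, by = dt)
  if (length(t) < 2L) {
    stop_geeraerd("`duration`/`dt` must give at least 2 grid points.",
                  "geeraerd_invalid_profile")
  }
  switch(kind,
    linear_ramp = {
      check_scalar(T_start, "T_start"); check_scalar(rate, "rate", positive = TRUE)
      temp_profile(t, T_start + rate * t, heating_rate = rate)
    },
    ramp_hold = {
      check_scalar(T_start, "T_start"); check_scalar(rate, "rate", positive = TRUE)
      check_scalar(T_hold, "T_hold")
      t_ramp_end <- (T_hold - T_start) / rate
      if (t_ramp_end <= 0 || t_ramp_end > duration) {
        stop_geeraerd("`T_hold` is unreachable at the given rate within `duration`.",
                      "geeraerd_invalid_profile")
      }
      temp_profile(t, pmin(T_start + rate * t, T_hold), heating_rate = rate)
    },
    sine = {
      check_scalar(mean, "mean"); check_scalar(amplitude, "amplitude", nonnegative = TRUE)
      check_scalar(period, "period", positive = TRUE)
      temp_profile(t, mean + amplitude * sin(2 * pi * t / period))
    }
  )
}

#' Generate noisy synthetic survival observations
#'
#' Forward-simulates the survival curve along a profile with the explicit
#' closed-form solution and draws observations at `n_obs` times with
#' additive Gaussian noise on the log10 scale — the homoscedastic
#' log10-count noise model that unweighted least squares on log counts
#' assumes. Observation times are restricted to the span where the predicted
#' density stays at or above 1 CFU/mL (log10 N >= 0) so fixtures remain
#' physically countable; reproducible bit-for-bit per seed.
#'
#' @inheritParams simulate_survival
#' @param sigma Noise standard deviation (log10 CFU/mL); >= 0.
#' @param n_obs Number of observations (>= 3).
#' @param seed Integer seed.
#' @param sampling `"uniform"` (equally spaced in time, default) or
#'   `"log"` (log-spaced, denser early).
#' @param label Dataset label.
#'
#' @return A [survival_dataset()] observing `log10_N` when the parameter set
#'   carries `log10_N0`, `log10_S` otherwise.
#' @export
simulate_observations <- function(profile, bigelow, geeraerd,
                                  adaptation = NULL, heating_rate = NULL,
                                  k = NULL, sigma = 0.1, n_obs = 12,
                                  seed = 0, sampling = c("uniform", "log"),
                                  label = "synthetic") {
  sampling <- match.arg(sampling)
  check_scalar(sigma, "sigma", nonnegative = TRUE)
  if (n_obs < 3L) {
    stop_geeraerd("`n_obs` must be >= 3.", "geeraerd_invalid_dataset")
  }
  k <- resolve_adaptation_k(adaptation, heating_rate, k, profile)
  curve <- simulate_survival(profile, bigelow, geeraerd, k = k)
  t_max <- max(profile$time_min)
  if (!is.null(geeraerd$log10_N0)) {
    ok <- curve$log10_N >= 0
    if (any(!ok)) t_max <- curve$time_min[max(which(ok))]
  }
  times <- if (sampling == "uniform") {
    seq(0, t_max, length.out = n_obs)
  } else {
    exp(seq(log(max(t_max / n_obs^2, 1e-3)), log(t_max), length.out = n_obs))
  }
  dt <- profile_dt(profile)
  idx <- nearest_grid_index(times, dt, n_max = nrow(curve) - 1L)
  truth <- if (!is.null(geeraerd$log10_N0)) curve$log10_N[idx + 1L]
           else curve$log10_S[idx + 1L]
  noise <- withr::with_seed(seed, rnorm(n_obs, 0, sigma))
  obs <- tibble(time_min = curve$time_min[idx + 1L])
  obs[[if (!is.null(geeraerd$log10_N0)) "log10_N" else "log10_S"]] <- truth + noise
  survival_dataset(obs, profile,
                   heating_rate = if (!is.null(heating_rate)) heating_rate
                                  else attr(profile, "heating_rate"),
                   label = label)
}

#' Default synthetic multi-rate fixture suites
#'
#' Builds the standard simulation designs used for parameter-recovery
#' studies: `"original"` gives three datasets at heating rates 1.64, 0.43
#' and 0.15 deg C/min with shared kinetics and per-dataset initial
#' densities; `"modified"` gives six rates (1.64, 0.82, 0.55, 0.40, 0.20,
#' 0.15 deg C/min) with the heating-rate adaptation factor applied. Each
#' treatment ramps from 30 deg C to the reference temperature at its
#' applied rate and then holds there, the mild come-up typical of
#' water-bath inactivation experiments; the hold is long enough
#' (`hold` min) for the survival curve to traverse shoulder, log-linear
#' decline and approach the countable limit.
#'
#' @param variant `"original"` or `"modified"`.
#' @param bigelow,geeraerd,adaptation Generating parameters; defaults are a
#'   realistic mild-heat pasteurisation scenario (see Details).
#' @param log10_N0 Vector of initial densities, recycled across datasets.
#' @param sigma,n_obs,seed Noise level, observations per dataset, base seed
#'   (dataset i uses `seed + i`).
#' @param T_start Ramp start temperature (deg C).
#' @param hold Holding time at the reference temperature (min).
#' @param dt Grid step (min).
#'
#' @details The default kinetic parameters (`asym_D_ref` 10.35 min at
#'   54.75 deg C, `z` 4.97 deg C, `Cc0` 70.13) and adaptation constants
#'   (`k1` 0.969, `k2` 0.060 deg C/min) are representative fitted values for
#'   *E. coli* K12 under mild heat treatments.
#'
#' @return A list of [survival_dataset()] objects.
#' @export
make_fixture_suite <- function(variant = c("original", "modified"),
                               bigelow = bigelow_params(10.35, 54.75, 4.97),
                               geeraerd = geeraerd_params(Cc0 = 70.13),
                               adaptation = adaptation_params(0.969, 0.060),
                               log10_N0 = c(9.48, 9.23, 9.32),
                               sigma = 0.1, n_obs = 15, seed = 0,
                               T_start = 30, hold = 130, dt = 1/60) {
  variant <- match.arg(variant)
  rates <- if (variant == "original") c(1.64, 0.43, 0.15)
           else c(1.64, 0.82, 0.55, 0.40, 0.20, 0.15)
  log10_N0 <- rep_len(log10_N0, length(rates))
  purrr::imap(rates, function(rate, i) {
    prof <- make_profile("ramp_hold", T_start = T_start, rate = rate,
                         T_hold = bigelow$T_ref,
                         duration = (bigelow$T_ref - T_start) / rate + hold,
                         dt = dt)
    g <- geeraerd_params(Cc0 = geeraerd$Cc0, log10_N0 = log10_N0[[i]],
                         log10_Nres_ratio = geeraerd$log10_Nres_ratio)
    simulate_observations(
      prof, bigelow, g,
      adaptation = if (variant == "modified") adaptation else NULL,
      sigma = sigma, n_obs = n_obs, seed = seed + i,
      label = sprintf("ramp_%g", rate)
    )
  })
}
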