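#' @rdname simulate_survival
#' @param integral A profile tibble with a `kmax_integral` column, as
#'   returned by [cumulative_inactivation()].
#' @export
explicit_survival_original <- function(integral, geeraerd) {
  explicit_survival_modified(integral, geeraerd, k = 1)
}

#' @rdname simulate_survival
#' @export
explicit_survival_modified <- function(integral, geeraerd, k) {
  stopifnot(inherits(geeraerd, "geeraerd_params"))
  check_scalar(k, "k", positive = TRUE)
  if (!is.data.frame(integral) || !"kmax_integral" %in% names(integral)) {
    stop_geeraerd("`integral` must carry a `kmax_integral` column; see cumulative_inactivation().",
                  "geeraerd_invalid_integral")
  }
  out <- as_tibble(integral)
  out$log10_S <- log10_survival_from_integral(
    out$kmax_integral, geeraerd$Cc0, tail_ratio(geeraerd), k
  )
  if (!is.null(geeraerd$log10_N0)) out$log10_N <- geeraerd$log10_N0 + out$log10_S
  class(out) <- c("survival_curve", class(tibble()))
  out
}

# Closed-form log10 survival ratio from the cumulative integral I.
#
# With Q = (1 + Cc0) / (Cc0 + e^I) and R = Nres/N(0), the modified model
# gives S = Q^k + (1 - Q^k) R; k = 1 recovers the original model
# S = (1 + Cc0 + (e^I - 1) R) / (Cc0 + e^I). e^I is never formed: everything
# is expressed through E = e^{-I} <= 1 and log Q = log1p(Cc0) - I -
# log1p(Cc0 E), so I = 1e4 neither overflows nor loses the tail limit.
log10_survival_from_integral <- function(I, Cc0, R, k = 1) {
  E <- exp(-I)
  logQ <- log1p(Cc0) - I - log1p(Cc0 * E)
  if (R == 0) {
    k * logQ / LN10
  } else {
    log10(R + (1 - R) * exp(k * logQ))
  }
}

#' Simulate a nonisothermal survival curve
#'
#' Computes the log10 survival ratio along a discrete temperature profile
#' from the closed-form solution of the Geeraerd model, with the cumulative
#' inactivation integral accumulated by the per-interval Simpson rule. When
#' an adaptation model is supplied (or `k` given directly) the modified
#' model — inactivation rate damped by the heating-rate adaptation factor —
#' is used; `k = 1` is exactly the original model.
#'
#' `explicit_survival_original()` and `explicit_survival_modified()` are the
#' lower-level entry points operating on a precomputed integral table.
#'
#' @param profile A [temp_profile()].
#' @param bigelow A [bigelow_params()] object.
#' @param geeraerd A [geeraerd_params()] object.
#' @param adaptation Optional [adaptation_params()]; requires a heating rate
#'   (argument or profile metadata) to evaluate the adaptation factor.
#' @param heating_rate Applied constant heating rate (deg C/min); defaults
#'   to the profile's metadata value.
#' @param k Optional adaptation factor supplied directly (overrides
#'   `adaptation`); `k = 1` or leaving both `NULL` gives the original model.
#'
#' @return A tibble of class `survival_curve` with columns `time_min`,
#'   `temp_C`, `kmax`, `kmax_integral`, `log10_S` and, when the parameter
#'   set carries `log10_N0`, `log10_N`.
#' @examples
#' prof <- make_profile("linear_ramp", T_start = 35, rate = 1.64,
#'                      duration = 15, dt = 1/60)
#' curve <- simulate_survival(
#'   prof,
#'   bigelow_params(asym_D_ref = 8, T_ref = 60, z = 5),
#'   geeraerd_params(Cc0 = 1, log10_Nres_ratio = -7)
#' )
#' head(curve)
#' @export
simulate_survival <- function(profile, bigelow, geeraerd, adaptation = NULL,
                              heating_rate = NULL, k = NULL) {
  k <- resolve_adaptation_k(adaptation, heating_rate, k, profile)
  integral <- cumulative_inactivation(profile, bigelow)
  explicit_survival_modified(integral, geeraerd, k = k)
}

resolve_adaptation_k <- function(adaptation, heating_rate, k, profile = NULL) {
  if (!is.null(k)) {
    check_scalar(k, "k", positive = TRUE)
    return(k)
  }
  if (is.null(adaptation)) return(1)
  if (is.null(heating_rate) && !is.null(profile)) {
    heating_rate <- attr(profile, "heating_rate")
  }
  if (is.null(heating_rate)) {
    stop_geeraerd("The modified model needs a heating rate (argument or profile metadata) to evaluate the adaptation factor.",
                  "geeraerd_invalid_rate")
  }
  adaptation_factor(heating_rate, adaptation)
}

#' Adaptive ODE reference solution
#'
#' Integrates the Geeraerd model in its differential form
#' \deqn{dS/dt = -k_{max}(T(t))\,\frac{k}{1 + C_c}\,(S - R), \qquad
#'       dC_c/dt = -k_{max}(T(t))\,C_c}
#' with an adaptive solver at tight tolerances, interpolating temperature
#' linearly between profile grid points. This is a validation utility — an
#' independent route to the survival curve used to cross-check the explicit
#' closed-form path — not the production solver.
#'
#' @inheritParams simulate_survival
#' @param rtol,atol Relative and absolute solver tolerances.
#'
#' @return A `survival_curve` tibble on the profile grid with columns
#'   `time_min`, `temp_C`, `log10_S`, `Cc` (and `log10_N` when available).
#' @export
ode_oracle <- function(profile, bigelow, geeraerd, adaptation = NULL,
                       heating_rate = NULL, k = NULL,
                       rtol = 1e-10, atol = 1e-12) {
  profile <- validate_profile(profile)
  stopifnot(inherits(bigelow, "bigelow_params"), inherits(geeraerd, "geeraerd_params"))
  k <- resolve_adaptation_k(adaptation, heating_rate, k, profile)
  R <- tail_ratio(geeraerd)
  temp_at <- approxfun(profile$time_min, profile$temp_C, rule = 2)
  rhs <- function(t, y, parms) {
    km <- bigelow_kmax(temp_at(t), bigelow)
    list(c(
      S  = -km * k * (y[["S"]] - R) / (1 + y[["Cc"]]),
      Cc = -km * y[["Cc"]]
    ))
  }
  sol <- deSolve::ode(
    y = c(S = 1, Cc = geeraerd$Cc0), times = profile$time_min,
    func = rhs, parms = NULL, method = "lsoda", rtol = rtol, atol = atol
  )
  if (nrow(sol) < nrow(profile)) {
    stop_geeraerd(
      sprintf("ODE solver failed at t = %.6g min.", sol[nrow(sol), "time"]),
      "geeraerd_solver_failure")
  }
  out <- as_tibble(profile)
  out$log10_S <- log10(pmax(sol[, "S"], .Machine$double.xmin))
  out$Cc <- sol[, "Cc"]
  if (!is.null(geeraerd$log10_N0)) out$log10_N <- geeraerd$log10_N0 + out$log10_S
  class(out) <- c("survival_curve", class(tibble()))
  out
}

#' Select a time step for the Simpson accumulation
#'
#' Implements the step-size selection rule for discretising a continuous (or
#' densely measured) temperature history: starting from a small base step,
#' the step is doubled and the survival curve recomputed until the root mean
#' squared difference in `log10_S` between two consecutive calculations
#' (compared on the coarser grid) falls below `tol`. The first step
#' satisfying the criterion is returned, with the ladder trace attached as
#' the `"trace"` attribute.
#'
#' @param temp_fn A function of time (min) returning temperature (deg C), or
#'   a data frame with `time_min`/`temp_C` columns that is interpolated
#'   linearly.
#' @param duration Time span to cover (min); required when `temp_fn` is a
#'   function, defaults to the series' span otherwise.
#' @inheritParams simulate_survival
#' @param tol Error tolerance on log10 survival (log10 units); > 0.
#' @param dt_base Base (smallest) step of the doubling ladder (min).
#'
#' @return The selected step (min) with attribute `"trace"`, a tibble of the
#'   tested steps and their RMS differences.
#' @export
select_time_step <- function(temp_fn, duration = NULL, bigelow, geeraerd,
                             adaptation = NULL, heating_rate = NULL, k = NULL,
                             tol, dt_base = 1/600) {
  check_scalar(tol, "tol", positive = TRUE)
  check_scalar(dt_base, "dt_base", positive = TRUE)
  if (is.data.frame(temp_fn)) {
    if (is.null(duration)) duration <- max(temp_fn$time_min)
    temp_fn <- approxfun(temp_fn$time_min, temp_fn$temp_C, rule = 2)
  }
  check_scalar(duration, "duration", positive = TRUE)
  k <- resolve_adaptation_k(adaptation, heating_rate, k)

  curve_at <- function(dt) {
    grid <- seq(0, duration, by = dt)
    prof <- temp_profile(grid, temp_fn(grid))
    simulate_survival(prof, bigelow, geeraerd, k = k)
  }
  prev <- curve_at(dt_base)
  trace <- list()
  dt <- dt_base
  repeat {
    dt_next <- 2 * dt
    if (duration / dt_next < 2) break  # coarser grids cannot resolve the span
    cur <- curve_at(dt_next)
    # doubling ladder: the coarse grid times are every other fine grid time
    shared <- seq_len(nrow(cur))
    rms <- sqrt(mean((cur$log10_S - prev$log10_S[2L * shared - 1L])^2))
    trace[[length(trace) + 1L]] <- tibble(dt = dt_next, rms_diff = rms)
    if (rms < tol) {
      out <- dt_next
      attr(out, "trace") <- dplyr::bind_rows(trace)
      return(out)
    }
    prev <- cur
    dt <- dt_next
  }
  stop_geeraerd("No ladder step met the tolerance; measure the temperature profile at denser time intervals.",
                "geeraerd_step_selection_failure")
}

#' Plot a survival curve
#'
#' @param object A `survival_curve` tibble.
#' @param ... Unused.
#' @return A ggplot object with log10 survival against time.
#' @export
autoplot.survival_curve <- function(object, ...) {
  y <- if ("log10_N" %in% names(object)) "log10_N" else "log10_S"
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_min, y = .data[[y]])) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Time (min)",
      y = if (y == "log10_N") expression(log[10] ~ N ~ (CFU/mL))
          else expression(log[10] ~ S)
    )
}
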