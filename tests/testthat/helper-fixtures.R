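# Shared fixtures: the printed validation parameter set (decimal reduction
# time 8 min at 60 degC, z = 5 degC, tail ratio -7, Cc0 = 1) and small
# standard profiles.

fig_bigelow <- function() bigelow_params(asym_D_ref = 8, T_ref = 60, z = 5)

fig_geeraerd <- function() geeraerd_params(Cc0 = 1, log10_Nres_ratio = -7)

ramp_profile <- function(duration = 25, rate = 1.64, T_start = 35, dt = 1/60) {
  make_profile("linear_ramp", T_start = T_start, rate = rate,
               duration = duration, dt = dt)
}

sine_profile <- function(duration = 30, mean = 57, amplitude = 4,
                         period = 10, dt = 1/60) {
  make_profile("sine", mean = mean, amplitude = amplitude, period = period,
               duration = duration, dt = dt)
}

iso_profile <- function(temp = 60, duration = 5, dt = 1/60) {
  temp_profile(seq(0, duration, by = dt),
               rep(temp, length(seq(0, duration, by = dt))))
}

# fine-grid trapezoid reference for the cumulative rate integral,
# independent of the Simpson path under test
trapezoid_integral <- function(temp_fn, rate_fn, t_end, n = 2e5) {
  t <- seq(0, t_end, length.out = n + 1)
  f <- rate_fn(temp_fn(t))
  h <- t[2] - t[1]
  sum((f[-1] + f[-length(f)]) / 2) * h
}

# reference integral for a DISCRETE profile: fine trapezoid over its
# piecewise-linear interpolant (the package's between-grid-point temperature
# convention), isolating quadrature error from profile-sampling error
plin_reference <- function(prof, rate_fn, n_sub = 2000) {
  f <- stats::approxfun(prof$time_min, prof$temp_C)
  trapezoid_integral(f, rate_fn, max(prof$time_min),
                     n = n_sub * (nrow(prof) - 1))
}
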