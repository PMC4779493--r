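test_that("explicit solution has the exact analytic limits", {
  p <- fig_bigelow()
  prof <- ramp_profile(10)
  ci <- cumulative_inactivation(prof, p)

  # at t = 0 the survival ratio is 1 for any parameter set
  for (g in list(fig_geeraerd(), geeraerd_params(Cc0 = 0),
                 geeraerd_params(Cc0 = 500, log10_Nres_ratio = -4))) {
    expect_identical(explicit_survival_original(ci, g)$log10_S[1], 0)
  }

  # no shoulder, no tail: pure log-linear decline, log10 S = -I / ln 10
  cv <- explicit_survival_original(ci, geeraerd_params(Cc0 = 0))
  expect_equal(cv$log10_S, -ci$kmax_integral / log(10), tolerance = 1e-14)

  # tail limit: huge integral pins the curve at the residual ratio, no overflow
  big <- tibble::tibble(time_min = c(0, 1), temp_C = c(60, 60),
                        kmax_integral = c(0, 1e4))
  cv_big <- explicit_survival_original(big, fig_geeraerd())
  expect_equal(cv_big$log10_S[2], -7, tolerance = 1e-6)
  expect_true(all(is.finite(cv_big$log10_S)))
})

test_that("modified solution reduces to the original at k = 1 and is stable for large I", {
  prof <- sine_profile(15)
  ci <- cumulative_inactivation(prof, fig_bigelow())
  for (g in list(fig_geeraerd(), geeraerd_params(Cc0 = 30),
                 geeraerd_params(Cc0 = 0, log10_Nres_ratio = -5))) {
    orig <- explicit_survival_original(ci, g)
    mod1 <- explicit_survival_modified(ci, g, k = 1)
    expect_equal(mod1$log10_S, orig$log10_S, tolerance = 1e-12)
  }
  # I = 0 gives log10 S = 0 for any k
  one <- tibble::tibble(time_min = 0:1, temp_C = c(60, 60), kmax_integral = c(0, 0))
  expect_equal(explicit_survival_modified(one, fig_geeraerd(), k = 0.7)$log10_S,
               c(0, 0))
  # large I with a tail: floor attained without overflow under k < 1
  big <- tibble::tibble(time_min = 0:1, temp_C = c(60, 60), kmax_integral = c(0, 1e4))
  expect_equal(explicit_survival_modified(big, fig_geeraerd(), 0.8)$log10_S[2],
               -7, tolerance = 1e-6)
  expect_error(explicit_survival_modified(big, fig_geeraerd(), 0),
               class = "geeraerd_invalid_param")
})

test_that("ODE oracle reproduces closed forms under isothermal first-order conditions", {
  p <- fig_bigelow()
  prof <- iso_profile(temp = 58, duration = 8)
  g <- geeraerd_params(Cc0 = 0)
  oracle <- ode_oracle(prof, p, g)
  D58 <- 8 * 10^((60 - 58) / 5)  # decimal reduction time at 58 degC
  expect_equal(oracle$log10_S, -prof$time_min / D58, tolerance = 1e-6)
})

test_that("the physiological-state variable decays as exp(-I) along any run", {
  p <- fig_bigelow()
  prof <- ramp_profile(12)
  g <- geeraerd_params(Cc0 = 5, log10_Nres_ratio = -6)
  oracle <- ode_oracle(prof, p, g)
  ci <- cumulative_inactivation(prof, p)
  expect_equal(oracle$Cc, 5 * exp(-ci$kmax_integral), tolerance = 1e-6)
})

test_that("explicit and ODE routes agree across profiles and parameter sets", {
  p <- fig_bigelow()
  profiles <- list(
    ramp = ramp_profile(20),
    ramp_hold = make_profile("ramp_hold", T_start = 40, rate = 2, T_hold = 60,
                             duration = 25, dt = 1/60),
    sine = sine_profile(20)
  )
  params <- list(fig_geeraerd(), geeraerd_params(Cc0 = 20, log10_Nres_ratio = -5))
  for (prof in profiles) {
    for (g in params) {
      ex <- simulate_survival(prof, p, g)
      or <- ode_oracle(prof, p, g)
      expect_lt(max(abs(ex$log10_S - or$log10_S)), 1e-3)
    }
  }
})

test_that("modified-model curve agrees with the adapted ODE at a slow heating rate", {
  p <- fig_bigelow()
  g <- fig_geeraerd()
  a <- adaptation_params(k1 = 0.969, k2 = 0.060)
  prof <- make_profile("ramp_hold", T_start = 40, rate = 0.15, T_hold = 58,
                       duration = 150, dt = 1/60)
  ex <- simulate_survival(prof, p, g, adaptation = a, heating_rate = 0.15)
  or <- ode_oracle(prof, p, g, adaptation = a, heating_rate = 0.15)
  expect_lt(max(abs(ex$log10_S - or$log10_S)), 1e-3)
})

test_that("survival curves decay monotonically and respect the tail floor", {
  p <- fig_bigelow()
  for (prof in list(ramp_profile(25), sine_profile(40))) {
    cv <- simulate_survival(prof, p, fig_geeraerd())
    expect_true(all(diff(cv$log10_S) <= 1e-12))
    expect_true(all(cv$log10_S >= -7 - 1e-9))
  }
})

test_that("a large shoulder keeps early survival flat until I approaches log(Cc0)", {
  p <- fig_bigelow()
  g <- geeraerd_params(Cc0 = 150)
  prof <- ramp_profile(30, rate = 1, T_start = 45)
  cv <- simulate_survival(prof, p, g)
  early <- cv$kmax_integral < log(150) / 2
  expect_true(all(cv$log10_S[early] > -0.1))
})

test_that("step selection follows the doubling ladder and its tolerance rule", {
  p <- fig_bigelow()
  g <- fig_geeraerd()
  fn <- function(t) 45 + 1.5 * t

  # huge tolerance: the first ladder step above the base is accepted at once
  dt_big <- select_time_step(fn, duration = 10, bigelow = p, geeraerd = g,
                             tol = 10, dt_base = 1/600)
  expect_equal(as.numeric(dt_big), 2 / 600)

  # isothermal profile: consecutive curves are identical (Simpson exact),
  # so the first (coarsest tested) ladder step is returned with zero RMS
  dt_iso <- select_time_step(function(t) rep(58, length(t)), duration = 10,
                             bigelow = p, geeraerd = geeraerd_params(Cc0 = 0),
                             tol = 1e-12, dt_base = 1/600)
  expect_equal(attr(dt_iso, "trace")$rms_diff[1], 0)

  # practical tolerance: the returned step's curve is within 2 tol (RMS) of
  # its half-step curve by construction of the ladder
  tol <- 1e-3
  dt_sel <- select_time_step(fn, duration = 10, bigelow = p, geeraerd = g,
                             tol = tol, dt_base = 1/600)
  grid_c <- seq(0, 10, by = as.numeric(dt_sel))
  grid_f <- seq(0, 10, by = as.numeric(dt_sel) / 2)
  cv_c <- simulate_survival(temp_profile(grid_c, fn(grid_c)), p, g)
  cv_f <- simulate_survival(temp_profile(grid_f, fn(grid_f)), p, g)
  shared <- cv_f$log10_S[seq(1, nrow(cv_f), by = 2)][seq_len(nrow(cv_c))]
  expect_lt(sqrt(mean((cv_c$log10_S - shared)^2)), 2 * tol)

  # an unmeetable tolerance ends with a diagnostic error
  expect_error(select_time_step(fn, duration = 10, bigelow = p, geeraerd = g,
                                tol = 1e-18, dt_base = 1/600),
               class = "geeraerd_step_selection_failure")
})
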