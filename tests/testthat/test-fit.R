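test_that("nearest grid index uses spreadsheet rounding with away-from-zero ties", {
  expect_identical(nearest_grid_index(0.5, 1/60), 30L)
  expect_identical(nearest_grid_index(0, 1/60), 0L)
  # tie exactly halfway between grid points rounds up (away from zero)
  expect_identical(nearest_grid_index(10.5 * 0.25, 0.25), 11L)
  expect_identical(nearest_grid_index(c(0.1, 0.2, 0.26), 0.2), c(1L, 1L, 1L))
  expect_error(nearest_grid_index(-0.1, 1/60), class = "geeraerd_invalid_dataset")
  expect_warning(idx <- nearest_grid_index(10, 1, n_max = 5), "clipped")
  expect_identical(idx, 5L)
})

test_that("predictions at observations read the grid curve at the nearest index", {
  p <- fig_bigelow()
  g <- geeraerd_params(Cc0 = 1, log10_N0 = 8, log10_Nres_ratio = -7)
  prof <- ramp_profile(10)
  curve <- simulate_survival(prof, p, g)

  # observations exactly on grid times reproduce the direct evaluation
  on_grid <- tibble::tibble(time_min = prof$time_min[c(1, 61, 301)],
                            log10_N = c(8, 7.9, 7.5))
  ds <- survival_dataset(on_grid, prof)
  pred <- predict_at_observations(ds, p, g)
  expect_equal(pred$.fitted, curve$log10_N[c(1, 61, 301)], tolerance = 1e-12)

  # an off-grid time lands on its nearest neighbour: 0.013 min -> index 1
  off <- tibble::tibble(time_min = c(0, 0.013, 1), log10_S = c(0, 0, -0.1))
  ds_off <- survival_dataset(off, prof)
  pred_off <- predict_at_observations(ds_off, p, geeraerd_params(Cc0 = 1, log10_Nres_ratio = -7))
  expect_equal(pred_off$.fitted[2], curve$log10_S[2], tolerance = 1e-12)
})

test_that("zero-noise observations are self-consistent with the forward model", {
  suite <- make_fixture_suite("original", sigma = 0, seed = 3)
  bg <- bigelow_params(10.35, 54.75, 4.97)
  for (i in seq_along(suite)) {
    g <- geeraerd_params(Cc0 = 70.13, log10_N0 = c(9.48, 9.23, 9.32)[i])
    pred <- predict_at_observations(suite[[i]], bg, g)
    expect_equal(pred$.fitted, pred$value, tolerance = 1e-9)
  }
})

test_that("the overall SSE is additive and invariant to dataset order", {
  suite <- make_fixture_suite("original", sigma = 0.1, seed = 11)
  spec <- fit_spec("original", T_ref = 54.75)
  params <- list(asym_D_ref = 9, z = 5.2, Cc0 = 40,
                 log10_N0 = c(9.4, 9.2, 9.3))
  sse_all <- objective_sse(suite, params, spec)
  sse_each <- sapply(seq_along(suite), function(i) {
    objective_sse(suite[[i]],
                  modifyList(params, list(log10_N0 = params$log10_N0[i])), spec)
  })
  expect_equal(sse_all, sum(sse_each), tolerance = 1e-12)
  perm <- objective_sse(suite[c(3, 1, 2)],
                        modifyList(params, list(log10_N0 = params$log10_N0[c(3, 1, 2)])),
                        spec)
  expect_equal(perm, sse_all, tolerance = 1e-12)
})

test_that("simple residual arithmetic gives the expected SSE and RMSE", {
  prof <- iso_profile(temp = 54.75, duration = 60, dt = 1/60)
  bg <- bigelow_params(10.35, 54.75, 4.97)
  g <- geeraerd_params(Cc0 = 0, log10_N0 = 9)
  truth <- predict_at_observations(
    survival_dataset(tibble::tibble(time_min = c(0, 10, 20), log10_N = c(9, 8, 7)),
                     prof), bg, g)
  obs <- tibble::tibble(time_min = c(0, 10, 20),
                        log10_N = truth$.fitted + c(0.1, -0.1, 0))
  ds <- survival_dataset(obs, prof)
  spec <- fit_spec("original", T_ref = 54.75)
  sse <- objective_sse(list(ds), list(asym_D_ref = 10.35, z = 4.97, Cc0 = 0,
                                      log10_N0 = 9), spec)
  expect_equal(sse, 0.02, tolerance = 1e-9)
  expect_equal(rmse(0.02, 2, 0), 0.1)
  expect_equal(rmse(0, 10, 3), 0)
  expect_equal(rmse_naive(0.02, 2), 0.1)
  expect_error(rmse(1, 3, 3), class = "geeraerd_invalid_rmse")
})

test_that("fitting zero-noise data from the true guess returns the generator exactly", {
  suite <- make_fixture_suite("original", sigma = 0, seed = 5)
  spec <- fit_spec("original", T_ref = 54.75,
                   initial = list(asym_D_ref = 10.35, z = 4.97, Cc0 = 70.13,
                                  log10_N0 = 9.3),
                   n_starts = 1)
  fit <- fit_model(suite, spec)
  expect_lt(fit$sse_total, 1e-12)
  expect_equal(unname(fit$shared_estimates["asym_D_ref"]), 10.35, tolerance = 1e-6)
  expect_equal(unname(fit$shared_estimates["z"]), 4.97, tolerance = 1e-6)
  expect_equal(unname(fit$shared_estimates["Cc0"]), 70.13, tolerance = 1e-4)
  expect_equal(fit$per_dataset$log10_N0, c(9.48, 9.23, 9.32), tolerance = 1e-6)
  # stored diagnostics are mutually consistent
  expect_equal(fit$sse_total, sum(fit$per_dataset$sse), tolerance = 1e-15)
  expect_equal(fit$rmse, rmse(fit$sse_total, fit$n_obs_total, fit$n_free_params))
})

test_that("perturbing any recovered parameter increases the zero-noise SSE", {
  suite <- make_fixture_suite("original", sigma = 0, seed = 5)
  spec <- fit_spec("original", T_ref = 54.75)
  truth <- list(asym_D_ref = 10.35, z = 4.97, Cc0 = 70.13,
                log10_N0 = c(9.48, 9.23, 9.32))
  sse0 <- objective_sse(suite, truth, spec)
  for (nm in c("asym_D_ref", "z", "Cc0")) {
    bumped <- truth
    bumped[[nm]] <- truth[[nm]] * 1.1
    expect_gt(objective_sse(suite, bumped, spec), sse0 + 1e-6)
  }
})

test_that("fit results carry tidy/glance/augment views with consistent numbers", {
  suite <- make_fixture_suite("original", sigma = 0.05, seed = 21, n_obs = 10)
  spec <- fit_spec("original", T_ref = 54.75, n_starts = 4, seed = 1,
                   initial = list(asym_D_ref = 8, z = 5, Cc0 = 30, log10_N0 = 9))
  fit <- fit_model(suite, spec)
  td <- tidy(fit)
  expect_setequal(td$term[td$shared], c("asym_D_ref", "z", "Cc0"))
  expect_equal(sum(!td$shared), 3L)  # one log10_N0 per dataset
  gl <- glance(fit)
  expect_equal(gl$sse, fit$sse_total)
  expect_equal(gl$n_obs, 30L)
  au <- augment(fit)
  expect_equal(nrow(au), 30L)
  expect_equal(sum(au$.resid^2), fit$sse_total, tolerance = 1e-12)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("the modified variant requires heating-rate metadata", {
  suite <- make_fixture_suite("original", sigma = 0, seed = 2)
  suite[[1]]$heating_rate <- NULL
  spec <- fit_spec("modified", T_ref = 54.75)
  expect_error(fit_model(suite, spec), class = "geeraerd_invalid_spec")
  expect_error(fit_spec("original", T_ref = 54.75, shared = "z",
                        per_dataset = "z"),
               class = "geeraerd_invalid_spec")
})

test_that("multi-start records are reproducible for a given seed", {
  suite <- make_fixture_suite("original", sigma = 0.1, seed = 9, n_obs = 8)
  spec <- fit_spec("original", T_ref = 54.75, n_starts = 4, seed = 123)
  f1 <- fit_model(suite, spec)
  f2 <- fit_model(suite, spec)
  expect_identical(f1$multistart_records, f2$multistart_records)
  expect_identical(f1$estimates, f2$estimates)
  expect_equal(nrow(f1$multistart_records), 4L)
})
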