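#' Observed nonisothermal survival dataset
#'
#' Binds survival observations to the temperature profile (and applied
#' heating rate) under which they were measured. Observations are either
#' absolute densities (`log10_N`, log10 CFU/mL) or survival ratios
#' (`log10_S`); the response type is inferred from the column present.
#'
#' @param observations Data frame with `time_min` and one of `log10_N` /
#'   `log10_S`; at least 3 rows, times within the profile span.
#' @param profile The [temp_profile()] of the treatment.
#' @param heating_rate Applied constant heating rate (deg C/min); required
#'   metadata for fitting the modified (adaptation) model. Defaults to the
#'   profile's metadata value.
#' @param label Dataset identifier.
#'
#' @return An object of class `survival_dataset`.
#' @export
survival_dataset <- function(observations, profile,
                             heating_rate = attr(profile, "heating_rate"),
                             label = "dataset") {
  profile <- validate_profile(profile)
  stopifnot(is.data.frame(observations), "time_min" %in% names(observations))
  response <- intersect(c("log10_N", "log10_S"), names(observations))
  if (length(response) != 1L) {
    stop_geeraerd("Observations must have exactly one of `log10_N` or `log10_S`.",
                  "geeraerd_invalid_dataset")
  }
  obs <- tibble(time_min = as.double(observations$time_min),
                value = as.double(observations[[response]]))
  if (nrow(obs) < 3L) {
    stop_geeraerd("A survival dataset needs at least 3 observations.",
                  "geeraerd_invalid_dataset")
  }
  if (any(obs$time_min < 0) || any(obs$time_min > max(profile$time_min) + 1e-9)) {
    stop_geeraerd("Observation times must lie within [0, max profile time].",
                  "geeraerd_invalid_dataset")
  }
  structure(
    list(obs = obs, response = response, profile = profile,
         heating_rate = heating_rate, label = as.character(label)),
    class = "survival_dataset"
  )
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat(sprintf("<survival_dataset> '%s': %d obs (%s), profile span %.6g min%s\n",
              x$label, nrow(x$obs), x$response, max(x$profile$time_min),
              if (is.null(x$heating_rate)) ""
              else sprintf(", heating rate %g degC/min", x$heating_rate)))
  invisible(x)
}

#' Nearest grid index of an observation time
#'
#' Maps an observation time to the nearest index of a uniform time grid of
#' step `dt`, counting from 0 at time zero. Ties at exactly half a step are
#' rounded away from zero (the spreadsheet rounding convention). Indices
#' beyond the grid are clipped to the last index with a warning.
#'
#' @param t_obs Observation time(s), min; nonnegative.
#' @param dt Grid step (min).
#' @param n_max Optional largest valid index; results above it are clipped.
#'
#' @return Integer vector of 0-based grid indices.
#' @examples
#' nearest_grid_index(0.5, 1/60) # 30
#' @export
nearest_grid_index <- function(t_obs, dt, n_max = NULL) {
  check_scalar(dt, "dt", positive = TRUE)
  if (any(!is.finite(t_obs)) || any(t_obs < 0)) {
    stop_geeraerd("Observation times must be finite and >= 0.",
                  "geeraerd_invalid_dataset")
  }
  idx <- floor(t_obs / dt + 0.5)  # half-up = away from zero for t >= 0
  if (!is.null(n_max) && any(idx > n_max)) {
    warn(sprintf("%d observation time(s) beyond the profile grid; clipped to the last grid point.",
                 sum(idx > n_max)))
    idx <- pmin(idx, n_max)
  }
  as.integer(idx)
}

#' Model predictions at observation times
#'
#' Simulates the survival curve over the dataset's full profile grid once,
#' then reads the value at the grid index nearest each observation time.
#' Densities are predicted when the parameter set carries `log10_N0` and the
#' dataset observes `log10_N`; survival ratios otherwise.
#'
#' @param dataset A [survival_dataset()].
#' @inheritParams simulate_survival
#'
#' @return The observation tibble with a `.fitted` column appended.
#' @export
predict_at_observations <- function(dataset, bigelow, geeraerd,
                                    adaptation = NULL, k = NULL) {
  stopifnot(inherits(dataset, "survival_dataset"))
  k <- resolve_adaptation_k(adaptation, dataset$heating_rate, k)
  curve <- simulate_survival(dataset$profile, bigelow, geeraerd, k = k)
  dt <- profile_dt(dataset$profile)
  idx <- nearest_grid_index(dataset$obs$time_min, dt, n_max = nrow(curve) - 1L)
  pred <- curve$log10_S[idx + 1L]
  if (dataset$response == "log10_N") {
    if (is.null(geeraerd$log10_N0)) {
      stop_geeraerd("`log10_N0` is needed to predict log10_N observations.",
                    "geeraerd_invalid_param")
    }
    pred <- pred + geeraerd$log10_N0
  }
  out <- dataset$obs
  out$.fitted <- pred
  out
}

# ---- fit specification ------------------------------------------------------

PARAM_UNIVERSE <- c("asym_D_ref", "z", "Cc0", "log10_Nres_ratio",
                    "log10_N0", "k1", "k2")
# strictly-positive scale parameters are searched on a log10 internal scale
LOG_SCALE_PARAMS <- c("asym_D_ref", "Cc0", "k2")

DEFAULT_BOUNDS <- list(
  asym_D_ref = c(1e-2, 1e3), z = c(0.5, 50), Cc0 = c(1e-3, 1e6),
  log10_Nres_ratio = c(-12, 0), log10_N0 = c(0, 15),
  k1 = c(0.1, 2), k2 = c(1e-4, 10)
)

DEFAULT_INITIAL <- list(
  asym_D_ref = 10, z = 5, Cc0 = 1, log10_Nres_ratio = -6,
  log10_N0 = 8, k1 = 1, k2 = 0.1
)

#' Specify a simultaneous fit
#'
#' Declares which parameters are shared across datasets, which are estimated
#' per dataset, which are frozen, and the bounds/initial guesses of the free
#' ones. The defaults mirror the standard simultaneous-fitting designs: for
#' the original model one `asym_D_ref`, `z` and `Cc0` across all heating
#' rates with a per-dataset `log10_N0`; for the modified model additionally
#' the adaptation constants `k1` and `k2` (typically with the kinetic
#' parameters fixed from a prior study).
#'
#' @param variant `"original"` or `"modified"`.
#' @param T_ref Reference temperature (deg C) at which `asym_D_ref` applies.
#' @param shared Names of parameters shared across all datasets.
#' @param per_dataset Names of parameters estimated separately per dataset.
#' @param fixed Named list of frozen parameter values (e.g. `log10_N0`
#'   measured at time zero, or kinetic parameters from a previous report).
#'   A scalar fixes the value for every dataset; for `log10_N0` a vector of
#'   one value per dataset is also accepted.
#' @param bounds Named list of `c(lo, hi)` overriding the default bounds.
#' @param initial Named list overriding the default initial guesses.
#' @param tail `TRUE` to include a tail (`log10_Nres_ratio` as a shared free
#'   parameter unless fixed); `FALSE` (default) for the tail-free model
#'   (Nres = 0).
#' @param n_starts Number of multi-starts; the first start is the supplied
#'   initial guess, the rest are sampled log-uniformly within bounds.
#' @param seed Seed for multi-start sampling.
#'
#' @return An object of class `fit_spec`.
#' @export
fit_spec <- function(variant = c("original", "modified"), T_ref,
                     shared = NULL, per_dataset = "log10_N0",
                     fixed = list(), bounds = list(), initial = list(),
                     tail = FALSE, n_starts = 16, seed = 0) {
  variant <- match.arg(variant)
  check_scalar(T_ref, "T_ref")
  if (is.null(shared)) {
    shared <- c("asym_D_ref", "z", "Cc0")
    if (tail) shared <- c(shared, "log10_Nres_ratio")
    if (variant == "modified") shared <- c(shared, "k1", "k2")
  }
  all_named <- union(shared, per_dataset)
  unknown <- setdiff(c(all_named, names(fixed)), PARAM_UNIVERSE)
  if (length(unknown)) {
    stop_geeraerd(sprintf("Unknown parameter(s): %s.", paste(unknown, collapse = ", ")),
                  "geeraerd_invalid_spec")
  }
  if (length(intersect(shared, per_dataset))) {
    stop_geeraerd("`shared` and `per_dataset` must be disjoint.",
                  "geeraerd_invalid_spec")
  }
  bounds <- modifyList(DEFAULT_BOUNDS, bounds)
  initial <- modifyList(DEFAULT_INITIAL, initial)
  structure(
    list(variant = variant, T_ref = T_ref, shared = shared,
         per_dataset = per_dataset, fixed = fixed, bounds = bounds,
         initial = initial, tail = tail,
         n_starts = as.integer(n_starts), seed = as.integer(seed)),
    class = "fit_spec"
  )
}

free_param_names <- function(spec, n_datasets) {
  shared_free <- setdiff(spec$shared, names(spec$fixed))
  per_free <- setdiff(spec$per_dataset, names(spec$fixed))
  list(
    shared = shared_free,
    per = per_free,
    theta = c(shared_free,
              unlist(lapply(per_free, function(p) paste0(p, "..", seq_len(n_datasets)))))
  )
}

base_name <- function(theta_names) sub("\\.\\.[0-9]+$", "", theta_names)

to_internal <- function(x, names) ifelse(base_name(names) %in% LOG_SCALE_PARAMS, log10(x), x)
from_internal <- function(x, names) ifelse(base_name(names) %in% LOG_SCALE_PARAMS, 10^x, x)

# per-dataset full parameter list (natural scale) from the theta vector
dataset_params <- function(theta, nm, spec, i) {
  p <- spec$fixed
  if ("log10_N0" %in% names(p) && length(p$log10_N0) > 1L) {
    p$log10_N0 <- p$log10_N0[[i]]
  }
  for (s in nm$shared) p[[s]] <- theta[[s]]
  for (s in nm$per) p[[s]] <- theta[[paste0(s, "..", i)]]
  p
}

# ---- objective --------------------------------------------------------------

# Builds a fast residual closure over all datasets. Grid temperatures,
# Simpson weights for the current z, and observation indices are cached per
# dataset; when z is unchanged between calls only the 1/asym_D_ref scaling
# is redone.
build_residual_fn <- function(datasets, spec) {
  nm <- free_param_names(spec, length(datasets))
  caches <- lapply(datasets, function(ds) {
    prof <- ds$profile
    dt <- profile_dt(prof)
    temp <- prof$temp_C
    n <- length(temp)
    idx <- nearest_grid_index(ds$obs$time_min, dt, n_max = n - 1L) + 1L
    env <- new.env(parent = emptyenv())
    env$z <- NA_real_
    list(temp = temp, mid = (temp[-n] + temp[-1L]) / 2, dt = dt,
         idx = idx, obs = ds$obs$value, response = ds$response,
         heating_rate = ds$heating_rate, cache = env)
  })
  integral_at_obs <- function(cc, D, z, T_ref) {
    if (!identical(cc$cache$z, z)) {
      b <- LN10 / z
      u <- (cc$dt / 6) * (exp(b * (cc$temp[-length(cc$temp)] - T_ref)) +
                          4 * exp(b * (cc$mid - T_ref)) +
                          exp(b * (cc$temp[-1L] - T_ref)))
      cc$cache$z <- z
      cc$cache$I1 <- c(0, cumsum(u))  # integral for asym_D_ref = ln10, i.e. / (ln10/D)
    }
    (LN10 / D) * cc$cache$I1[cc$idx]
  }
  function(theta) {
    theta <- setNames(as.numeric(theta), nm$theta)
    res <- vector("list", length(caches))
    for (i in seq_along(caches)) {
      cc <- caches[[i]]
      p <- dataset_params(theta, nm, spec, i)
      I_obs <- integral_at_obs(cc, p$asym_D_ref, p$z, spec$T_ref)
      k <- if (spec$variant == "modified") {
        adaptation_factor(cc$heating_rate, adaptation_params(p$k1, p$k2))
      } else 1
      R <- if (!is.null(p$log10_Nres_ratio)) 10^p$log10_Nres_ratio else 0
      pred <- log10_survival_from_integral(I_obs, p$Cc0, R, k)
      if (cc$response == "log10_N") pred <- pred + p$log10_N0
      res[[i]] <- cc$obs - pred
    }
    r <- unlist(res)
    if (any(!is.finite(r))) r[!is.finite(r)] <- 1e6  # penalty keeps optimiser feasible
    r
  }
}

#' Overall sum of squared errors
#'
#' Sum over datasets and observations of the squared difference between
#' observed and predicted log10 values, the objective minimised by
#' [fit_model()].
#'
#' @param datasets A list of [survival_dataset()] objects.
#' @param params Named list of parameter values on the natural scale. Shared
#'   parameters are scalars; `log10_N0` may be a vector of one value per
#'   dataset.
#' @param spec A [fit_spec()]; only its variant, `T_ref` and fixed values
#'   are used here.
#'
#' @return The overall SSE (scalar).
#' @export
objective_sse <- function(datasets, params, spec) {
  datasets <- as_dataset_list(datasets)
  spec2 <- spec
  spec2$fixed <- modifyList(spec$fixed, params)
  resid_fn <- build_residual_fn(datasets, spec2)
  sum(resid_fn(numeric(0))^2)
}

as_dataset_list <- function(datasets) {
  if (inherits(datasets, "survival_dataset")) datasets <- list(datasets)
  stopifnot(all(vapply(datasets, inherits, logical(1), "survival_dataset")))
  datasets
}

# ---- fitting ----------------------------------------------------------------

#' Fit the Geeraerd model to one or more nonisothermal datasets
#'
#' Simultaneous bounded nonlinear least-squares identification of the model
#' parameters from dynamic survival data: the overall SSE across all
#' datasets and observations is minimised by Levenberg-Marquardt
#' ([minpack.lm::nls.lm()]) from each of a set of starting points (the
#' supplied initial guess plus `n_starts - 1` log-uniform draws within
#' bounds, seeded for reproducibility), and the best solution is returned.
#' Strictly-positive scale parameters (`asym_D_ref`, `Cc0`, `k2`) are
#' searched on a log10 internal scale and reported on the natural scale.
#'
#' @param datasets A [survival_dataset()] or list of them. For the modified
#'   variant every dataset must carry its applied heating rate.
#' @param spec A [fit_spec()].
#'
#' @return An object of class `geeraerd_fit`: estimates, per-dataset and
#'   overall SSE, RMSE (residual degrees of freedom n - p, plus the naive
#'   n-denominator version), convergence diagnostics and the multi-start
#'   records. Supports [tidy()], [glance()], [augment()] and [autoplot()].
#' @export
fit_model <- function(datasets, spec) {
  stopifnot(inherits(spec, "fit_spec"))
  datasets <- as_dataset_list(datasets)
  if (spec$variant == "modified" &&
      any(vapply(datasets, function(d) is.null(d$heating_rate), logical(1)))) {
    stop_geeraerd("Every dataset needs a heating rate to fit the modified model.",
                  "geeraerd_invalid_spec")
  }
  nm <- free_param_names(spec, length(datasets))
  if (!length(nm$theta)) {
    stop_geeraerd("No free parameters to fit.", "geeraerd_invalid_spec")
  }
  bn <- base_name(nm$theta)
  lower_nat <- vapply(spec$bounds[bn], `[[`, numeric(1), 1L)
  upper_nat <- vapply(spec$bounds[bn], `[[`, numeric(1), 2L)
  lower <- to_internal(lower_nat, nm$theta)
  upper <- to_internal(upper_nat, nm$theta)
  start0 <- to_internal(vapply(spec$initial[bn], `[[`, numeric(1), 1L), nm$theta)
  start0 <- pmin(pmax(start0, lower), upper)

  starts <- list(start0)
  if (spec$n_starts > 1L) {
    extra <- withr::with_seed(spec$seed, {
      lapply(seq_len(spec$n_starts - 1L), function(j) {
        runif(length(nm$theta), lower, upper)  # log-uniform where log-scaled
      })
    })
    starts <- c(starts, extra)
  }

  resid_fn <- build_residual_fn(datasets, spec)
  resid_internal <- function(th) resid_fn(from_internal(th, nm$theta))

  records <- vector("list", length(starts))
  best <- NULL
  for (s in seq_along(starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = starts[[s]], fn = resid_internal,
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 500, ptol = 1e-12,
                                             ftol = 1e-12)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      records[[s]] <- tibble(start = s, sse = NA_real_, converged = FALSE, n_iter = NA_integer_)
      next
    }
    sse <- sum(resid_internal(fit$par)^2)
    conv <- fit$info %in% 1:4
    records[[s]] <- tibble(start = s, sse = sse, converged = conv,
                           n_iter = fit$niter)
    if (conv && (is.null(best) || sse < best$sse)) {
      best <- list(fit = fit, sse = sse, start = s)
    }
  }
  records <- dplyr::bind_rows(records)
  if (is.null(best)) {
    stop_geeraerd(
      paste0("No multi-start converged. Best partial SSE: ",
             format(suppressWarnings(min(records$sse, na.rm = TRUE)))),
      "geeraerd_fit_failure")
  }

  theta_hat <- setNames(from_internal(best$fit$par, nm$theta), nm$theta)
  per_ds <- lapply(seq_along(datasets), function(i) {
    p <- dataset_params(theta_hat, nm, spec, i)
    r <- resid_for_dataset(datasets[[i]], p, spec)
    list(params = p, sse = sum(r^2), n = length(r))
  })
  sse_total <- sum(vapply(per_ds, `[[`, numeric(1), "sse"))
  n_obs_total <- sum(vapply(per_ds, `[[`, numeric(1), "n"))
  n_free <- length(nm$theta)

  structure(
    list(
      estimates = theta_hat,
      shared_estimates = theta_hat[nm$shared],
      per_dataset = tibble(
        label = vapply(datasets, `[[`, character(1), "label"),
        sse = vapply(per_ds, `[[`, numeric(1), "sse"),
        n_obs = vapply(per_ds, function(x) as.integer(x$n), integer(1)),
        !!!per_dataset_cols(per_ds, nm$per)
      ),
      sse_total = sse_total,
      rmse = rmse(sse_total, n_obs_total, n_free),
      rmse_naive = rmse_naive(sse_total, n_obs_total),
      n_obs_total = n_obs_total,
      n_free_params = n_free,
      converged = TRUE,
      n_iter = best$fit$niter,
      best_start = best$start,
      multistart_records = records,
      spec = spec,
      datasets = datasets,
      free_names = nm
    ),
    class = "geeraerd_fit"
  )
}

per_dataset_cols <- function(per_ds, per_free) {
  cols <- lapply(per_free, function(p) {
    vapply(per_ds, function(x) x$params[[p]], numeric(1))
  })
  setNames(cols, per_free)
}

resid_for_dataset <- function(ds, p, spec) {
  bg <- bigelow_params(p$asym_D_ref, spec$T_ref, p$z)
  gg <- geeraerd_params(Cc0 = p$Cc0, log10_N0 = p$log10_N0,
                        log10_Nres_ratio = p$log10_Nres_ratio)
  k <- if (spec$variant == "modified") {
    adaptation_factor(ds$heating_rate, adaptation_params(p$k1, p$k2))
  } else 1
  pred <- predict_at_observations(ds, bg, gg, k = k)
  pred$value - pred$.fitted
}

#' Root mean squared error of a fit
#'
#' `rmse()` uses the residual degrees of freedom, `sqrt(SSE / (n - p))`, the
#' regression convention; `rmse_naive()` divides by `n` alone, for
#' comparability with reports that use the plain mean.
#'
#' @param sse_total Overall sum of squared errors.
#' @param n_obs_total Total number of observations.
#' @param n_free_params Number of free parameters; must be < `n_obs_total`.
#'
#' @return The RMSE (log10 CFU/mL when fitting densities).
#' @export
rmse <- function(sse_total, n_obs_total, n_free_params) {
  if (n_obs_total <= n_free_params) {
    stop_geeraerd("RMSE needs more observations than free parameters.",
                  "geeraerd_invalid_rmse")
  }
  sqrt(sse_total / (n_obs_total - n_free_params))
}

#' @rdname rmse
#' @export
rmse_naive <- function(sse_total, n_obs_total) {
  stopifnot(n_obs_total > 0)
  sqrt(sse_total / n_obs_total)
}
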