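#' @export
print.geeraerd_fit <- function(x, ...) {
  cat(sprintf("<geeraerd_fit> %s model, %d dataset(s), %d obs, %d free parameter(s)\n",
              x$spec$variant, nrow(x$per_dataset), x$n_obs_total, x$n_free_params))
  cat(sprintf("  SSE = %.6g, RMSE = %.4g (n - p), %.4g (naive)\n",
              x$sse_total, x$rmse, x$rmse_naive))
  sh <- x$shared_estimates
  if (length(sh)) {
    cat("  shared: ", paste(sprintf("%s = %.4g", names(sh), sh), collapse = ", "), "\n")
  }
  cat(sprintf("  converged in %d iteration(s), best of %d start(s)\n",
              x$n_iter, nrow(x$multistart_records)))
  invisible(x)
}

#' Tidy a fitted Geeraerd model
#'
#' @param x A `geeraerd_fit`.
#' @param ... Unused.
#' @return A tibble with one row per estimated parameter: `term`,
#'   `estimate`, `shared` (logical) and `dataset` (the label for
#'   per-dataset terms, `NA` for shared ones).
#' @export
tidy.geeraerd_fit <- function(x, ...) {
  nm <- x$free_names
  labels <- x$per_dataset$label
  nms <- names(x$estimates)
  is_per <- grepl("\\.\\.[0-9]+$", nms)
  ds <- rep(NA_character_, length(nms))
  ds[is_per] <- labels[as.integer(sub("^.*\\.\\.", "", nms[is_per]))]
  tibble(
    term = base_name(nms),
    estimate = unname(x$estimates),
    shared = !is_per,
    dataset = ds
  )
}

#' Fit-level summary of a fitted Geeraerd model
#'
#' @param x A `geeraerd_fit`.
#' @param ... Unused.
#' @return A one-row tibble: SSE, RMSE (both conventions), counts and
#'   convergence diagnostics.
#' @export
glance.geeraerd_fit <- function(x, ...) {
  tibble(
    sse = x$sse_total, rmse = x$rmse, rmse_naive = x$rmse_naive,
    n_obs = x$n_obs_total, n_free_params = x$n_free_params,
    n_datasets = nrow(x$per_dataset),
    converged = x$converged, n_iter = x$n_iter,
    n_starts = nrow(x$multistart_records), best_start = x$best_start
  )
}

#' Observations with fitted values and residuals
#'
#' @param x A `geeraerd_fit`.
#' @param ... Unused.
#' @return A tibble of all observations across datasets with `label`,
#'   `.fitted` and `.resid` columns.
#' @export
augment.geeraerd_fit <- function(x, ...) {
  purrr::map2_dfr(x$datasets, seq_along(x$datasets), function(ds, i) {
    p <- dataset_params(x$estimates, x$free_names, x$spec, i)
    pred <- predict_at_observations(
      ds,
      bigelow_params(p$asym_D_ref, x$spec$T_ref, p$z),
      geeraerd_params(Cc0 = p$Cc0, log10_N0 = p$log10_N0,
                      log10_Nres_ratio = p$log10_Nres_ratio),
      k = if (x$spec$variant == "modified") {
        adaptation_factor(ds$heating_rate, adaptation_params(p$k1, p$k2))
      } else 1
    )
    dplyr::mutate(pred, label = ds$label, .resid = .data$value - .data$.fitted,
                  .before = 1)
  })
}

#' Plot observed data and fitted survival curves
#'
#' @param object A `geeraerd_fit`.
#' @param ... Unused.
#' @return A ggplot object, one facet per dataset.
#' @export
autoplot.geeraerd_fit <- function(object, ...) {
  curves <- purrr::map2_dfr(object$datasets, seq_along(object$datasets),
                            function(ds, i) {
    p <- dataset_params(object$estimates, object$free_names, object$spec, i)
    cv <- simulate_survival(
      ds$profile,
      bigelow_params(p$asym_D_ref, object$spec$T_ref, p$z),
      geeraerd_params(Cc0 = p$Cc0, log10_N0 = p$log10_N0,
                      log10_Nres_ratio = p$log10_Nres_ratio),
      k = if (object$spec$variant == "modified") {
        adaptation_factor(ds$heating_rate, adaptation_params(p$k1, p$k2))
      } else 1
    )
    y <- if (ds$response == "log10_N") cv$log10_N else cv$log10_S
    tibble(label = ds$label, time_min = cv$time_min, value = y)
  })
  obs <- augment(object)
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time_min, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = obs, shape = 21, fill = "grey40") +
    ggplot2::facet_wrap(~label, scales = "free_x") +
    ggplot2::labs(x = "Time (min)", y = expression(log[10] ~ "count or survival"))
}
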