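#' Bigelow secondary-model parameters
#'
#' Container for the parameters of the Bigelow model mapping temperature to
#' the specific inactivation rate `kmax` (see [bigelow_kmax()]).
#'
#' @param asym_D_ref Asymptotic decimal reduction time (min) at the reference
#'   temperature; strictly positive.
#' @param T_ref Reference temperature (deg C).
#' @param z Temperature increment (deg C) producing a 10-fold change in the
#'   decimal reduction time; strictly positive.
#'
#' @return An object of class `bigelow_params` (a named list).
#' @examples
#' bigelow_params(asym_D_ref = 8, T_ref = 60, z = 5)
#' @export
bigelow_params <- function(asym_D_ref, T_ref, z) {
  check_scalar(asym_D_ref, "asym_D_ref", positive = TRUE)
  check_scalar(T_ref, "T_ref")
  check_scalar(z, "z", positive = TRUE)
  structure(
    list(asym_D_ref = asym_D_ref, T_ref = T_ref, z = z),
    class = "bigelow_params"
  )
}

#' Geeraerd primary-model state and shape parameters
#'
#' The shoulder parameter `Cc0` is the initial value of the dimensionless
#' physiological-state variable: larger values produce a longer shoulder
#' before log-linear decline. The tail is parameterised as the log10 ratio of
#' the residual density to the initial density, `log10(Nres / N(0))`, a
#' nonpositive number; leave it `NULL` for a tail-free model (Nres = 0).
#'
#' @param Cc0 Nonnegative dimensionless shoulder parameter.
#' @param log10_N0 Optional log10 initial density (log10 CFU/mL); needed only
#'   when absolute densities (rather than survival ratios) are simulated.
#' @param log10_Nres_ratio Optional nonpositive log10(Nres / N(0)); `NULL`
#'   means no tail (Nres = 0).
#'
#' @return An object of class `geeraerd_params`.
#' @examples
#' geeraerd_params(Cc0 = 1, log10_Nres_ratio = -7)
#' geeraerd_params(Cc0 = 70.13, log10_N0 = 9.48) # tail-free
#' @export
geeraerd_params <- function(Cc0, log10_N0 = NULL, log10_Nres_ratio = NULL) {
  check_scalar(Cc0, "Cc0", nonnegative = TRUE)
  if (!is.null(log10_N0)) check_scalar(log10_N0, "log10_N0")
  if (!is.null(log10_Nres_ratio)) {
    check_scalar(log10_Nres_ratio, "log10_Nres_ratio")
    if (log10_Nres_ratio > 0) {
      stop_geeraerd("`log10_Nres_ratio` must be <= 0 (Nres cannot exceed N(0)).",
                    "geeraerd_invalid_param")
    }
  }
  structure(
    list(Cc0 = Cc0, log10_N0 = log10_N0, log10_Nres_ratio = log10_Nres_ratio),
    class = "geeraerd_params"
  )
}

#' Heat-stress adaptation parameters
#'
#' Parameters of the heating-rate adaptation factor `k = k1 * r / (k2 + r)`
#' (see [adaptation_factor()]), where `r` is the applied constant heating
#' rate. `k2 = 0` is allowed and gives `k = k1` for every positive rate (the
#' degenerate no-adaptation-lag case).
#'
#' @param k1 Dimensionless positive constant (the high-rate limit of `k`).
#' @param k2 Nonnegative heating-rate constant (deg C/min).
#'
#' @return An object of class `adaptation_params`.
#' @examples
#' adaptation_params(k1 = 0.969, k2 = 0.060)
#' @export
adaptation_params <- function(k1, k2) {
  check_scalar(k1, "k1", positive = TRUE)
  check_scalar(k2, "k2", nonnegative = TRUE)
  structure(list(k1 = k1, k2 = k2), class = "adaptation_params")
}

# residual survival ratio R = Nres/N(0); 0 when the tail is absent
tail_ratio <- function(g) {
  if (is.null(g$log10_Nres_ratio)) 0 else 10^g$log10_Nres_ratio
}

check_scalar <- function(x, name, positive = FALSE, nonnegative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_geeraerd(sprintf("`%s` must be a single finite number.", name),
                  "geeraerd_invalid_param")
  }
  if (positive && x <= 0) {
    stop_geeraerd(sprintf("`%s` must be > 0.", name), "geeraerd_invalid_param")
  }
  if (nonnegative && x < 0) {
    stop_geeraerd(sprintf("`%s` must be >= 0.", name), "geeraerd_invalid_param")
  }
  invisible(x)
}

#' @export
print.bigelow_params <- function(x, ...) {
  cat(sprintf("<bigelow_params> asym_D_ref = %g min at T_ref = %g degC, z = %g degC\n",
              x$asym_D_ref, x$T_ref, x$z))
  invisible(x)
}

#' @export
print.geeraerd_params <- function(x, ...) {
  tail <- if (is.null(x$log10_Nres_ratio)) "absent (Nres = 0)"
          else sprintf("log10(Nres/N0) = %g", x$log10_Nres_ratio)
  n0 <- if (is.null(x$log10_N0)) "" else sprintf(", log10_N0 = %g", x$log10_N0)
  cat(sprintf("<geeraerd_params> Cc0 = %g%s, tail %s\n", x$Cc0, n0, tail))
  invisible(x)
}

#' @export
print.adaptation_params <- function(x, ...) {
  cat(sprintf("<adaptation_params> k1 = %g, k2 = %g degC/min\n", x$k1, x$k2))
  invisible(x)
}
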