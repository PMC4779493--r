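#' Read and write temperature-profile CSV files
#'
#' Profiles are stored as plain CSV with header `time_min,temp_C`. Reading
#' validates the uniform grid; the first offending row is named in the
#' error. Writers emit 15 significant digits so round-trips are lossless at
#' working precision.
#'
#' @param path File path.
#' @param heating_rate Optional metadata ramp rate attached on read.
#'
#' @return `read_profile_csv()` returns a [temp_profile()];
#'   `write_profile_csv()` returns `path` invisibly.
#' @export
read_profile_csv <- function(path, heating_rate = NULL) {
  df <- read_checked_csv(path, c("time_min", "temp_C"), min_rows = 2L)
  temp_profile(df$time_min, df$temp_C, heating_rate = heating_rate)
}

#' @rdname read_profile_csv
#' @param profile A [temp_profile()].
#' @export
write_profile_csv <- function(profile, path) {
  profile <- validate_profile(profile)
  write_csv_full_digits(profile[, c("time_min", "temp_C")], path)
}

#' Read and write survival-observation CSV files
#'
#' Observations are stored as CSV with header `time_min,log10_N` (absolute
#' densities) or `time_min,log10_S` (survival ratios); the response mode is
#' inferred from the header.
#'
#' @param path File path.
#' @return `read_survival_csv()` returns a tibble of observations with the
#'   response column named as in the file.
#' @export
read_survival_csv <- function(path) {
  df <- suppressMessages(readr::read_csv(path, show_col_types = FALSE))
  if (!"time_min" %in% names(df) ||
      length(intersect(c("log10_N", "log10_S"), names(df))) != 1L) {
    stop_geeraerd(sprintf("'%s': header must be time_min plus exactly one of log10_N / log10_S.", path),
                  "geeraerd_invalid_csv")
  }
  if (nrow(df) < 3L) {
    stop_geeraerd(sprintf("'%s': need at least 3 observation rows.", path),
                  "geeraerd_invalid_csv")
  }
  check_numeric_cols(df, path)
  if (any(df$time_min < 0)) {
    stop_geeraerd(sprintf("'%s': negative observation time at row %d.",
                          path, which(df$time_min < 0)[1L]),
                  "geeraerd_invalid_csv")
  }
  as_tibble(df)
}

#' @rdname read_survival_csv
#' @param observations Data frame with `time_min` and `log10_N`/`log10_S`.
#' @export
write_survival_csv <- function(observations, path) {
  write_csv_full_digits(observations, path)
}

#' @rdname read_survival_csv
#' @param curve A `survival_curve` tibble.
#' @export
write_curve_csv <- function(curve, path) {
  keep <- intersect(c("time_min", "temp_C", "log10_S", "log10_N"), names(curve))
  write_csv_full_digits(curve[, keep], path)
}

read_checked_csv <- function(path, required, min_rows) {
  if (!file.exists(path)) {
    stop_geeraerd(sprintf("File not found: '%s'.", path), "geeraerd_invalid_csv")
  }
  df <- suppressMessages(readr::read_csv(path, show_col_types = FALSE))
  if (!all(required %in% names(df))) {
    stop_geeraerd(sprintf("'%s': missing required column(s) %s.", path,
                          paste(setdiff(required, names(df)), collapse = ", ")),
                  "geeraerd_invalid_csv")
  }
  if (nrow(df) < min_rows) {
    stop_geeraerd(sprintf("'%s': need at least %d data rows.", path, min_rows),
                  "geeraerd_invalid_csv")
  }
  check_numeric_cols(df[, required], path)
  df
}

check_numeric_cols <- function(df, path) {
  for (col in names(df)) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1L]
      stop_geeraerd(sprintf("'%s': non-numeric value in column '%s' at row %s.",
                            path, col, ifelse(is.na(bad), "?", bad)),
                    "geeraerd_invalid_csv")
    }
    if (any(is.na(df[[col]]))) {
      stop_geeraerd(sprintf("'%s': missing value in column '%s' at row %d.",
                            path, col, which(is.na(df[[col]]))[1L]),
                    "geeraerd_invalid_csv")
    }
  }
  invisible(df)
}

write_csv_full_digits <- function(df, path) {
  df <- dplyr::mutate(as_tibble(df), dplyr::across(
    dplyr::where(is.numeric), ~ formatC(.x, digits = 15, format = "g")
  ))
  readr::write_csv(df, path)
  invisible(path)
}

#' Read a run configuration file
#'
#' Parses a YAML (or JSON) run configuration describing one simulation or
#' fitting run: model variant, time step, parameter values / bounds /
#' initial guesses / fixed and shared sets, the dataset manifest (profile
#' and survival CSV paths with heating rates and labels), seed and
#' multi-start count. Manifest paths are resolved relative to the config
#' file and must exist.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return A named list with class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop_geeraerd(sprintf("Config file not found: '%s'.", path),
                  "geeraerd_invalid_config")
  }
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$variant)) cfg$variant <- "original"
  if (!cfg$variant %in% c("original", "modified")) {
    stop_geeraerd("config$variant: must be 'original' or 'modified'.",
                  "geeraerd_invalid_config")
  }
  if (is.null(cfg$dt)) cfg$dt <- 1/60
  if (cfg$dt <= 0) {
    stop_geeraerd("config$dt: must be > 0.", "geeraerd_invalid_config")
  }
  base <- dirname(normalizePath(path))
  for (i in seq_along(cfg$datasets)) {
    for (field in c("profile", "survival")) {
      p <- cfg$datasets[[i]][[field]]
      if (!is.null(p)) {
        if (!file.exists(p)) p <- file.path(base, p)
        if (!file.exists(p)) {
          stop_geeraerd(sprintf("config$datasets[[%d]]$%s: file '%s' not found.",
                                i, field, cfg$datasets[[i]][[field]]),
                        "geeraerd_invalid_config")
        }
        cfg$datasets[[i]][[field]] <- p
      }
    }
  }
  structure(cfg, class = "run_config")
}

#' Load the datasets listed in a run configuration
#'
#' @param config A [read_run_config()] result.
#' @return A list of [survival_dataset()] objects.
#' @export
load_config_datasets <- function(config) {
  purrr::imap(config$datasets, function(d, i) {
    prof <- read_profile_csv(d$profile, heating_rate = d$heating_rate)
    obs <- read_survival_csv(d$survival)
    survival_dataset(obs, prof, heating_rate = d$heating_rate,
                     label = d$label %||% sprintf("dataset_%d", i))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
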