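# Windowed linear trends on annual climate series.
#
# An annual series holds (year, mean temperature degC, total rainfall mm).
# A trend window is summarised by the OLS line value ~ year fitted on the
# in-window years: slope, fitted values at the window bounds, their
# difference (the "delta" a narrative like "increased by 0.5 degC, from
# 15.4 to 15.9" refers to) and the window mean.

#' Validate an annual climate series
#'
#' @param series data.frame with columns `year`, and any of `temp_c`,
#'   `rain_mm`; years strictly increasing, temperatures in (-20, 50),
#'   rainfall non-negative. Missing years are allowed (they are simply
#'   absent rows) and `NA` values are allowed and flagged downstream.
#' @return `series`, invisibly.
#' @export
validate_climate_series <- function(series) {
  stopifnot(is.data.frame(series), "year" %in% names(series))
  if (is.unsorted(series$year, strictly = TRUE)) {
    stop("years must be strictly increasing", call. = FALSE)
  }
  if ("temp_c" %in% names(series)) {
    bad <- stats::na.omit(series$temp_c)
    if (any(bad <= -20 | bad >= 50)) {
      stop("temperatures outside plausible range (-20, 50) degC", call. = FALSE)
    }
  }
  if ("rain_mm" %in% names(series)) {
    if (any(stats::na.omit(series$rain_mm) < 0)) {
      stop("rainfall must be non-negative", call. = FALSE)
    }
  }
  invisible(series)
}

#' OLS trend over one window of an annual series
#'
#' Fits `value ~ year` by ordinary least squares on the years falling in
#' `[start_year, end_year]` and summarises the window.
#'
#' @param series annual climate data.frame (see
#'   [validate_climate_series()]).
#' @param variable column to analyse, e.g. `"temp_c"` or `"rain_mm"`.
#' @param start_year,end_year window bounds (inclusive), start < end.
#' @return one-row `data.frame`: `variable, start_year, end_year, n,
#'   coverage, slope, fitted_start, fitted_end, delta, window_mean,
#'   low_coverage` (flag set when fewer than 80% of window years have
#'   data). `delta = slope * (end_year - start_year)` is the fitted
#'   endpoint difference.
#' @export
window_trend <- function(series, variable, start_year, end_year) {
  validate_climate_series(series)
  stopifnot(variable %in% names(series), start_year < end_year)
  inw <- series$year >= start_year & series$year <= end_year &
    !is.na(series[[variable]])
  n <- sum(inw)
  if (n < 3) {
    stop(sprintf("window %d-%d has %d usable year(s); need >= 3",
                 start_year, end_year, n), call. = FALSE)
  }
  yr <- series$year[inw]
  val <- series[[variable]][inw]
  fit <- stats::lm(val ~ yr)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  f0 <- intercept + slope * start_year
  f1 <- intercept + slope * end_year
  span <- end_year - start_year + 1
  data.frame(
    variable = variable, start_year = start_year, end_year = end_year,
    n = n, coverage = n / span,
    slope = slope, fitted_start = f0, fitted_end = f1, delta = f1 - f0,
    window_mean = mean(val), low_coverage = n / span < 0.8,
    stringsAsFactors = FALSE
  )
}

#' Default 90-year analysis windows
#'
#' The three consecutive 30-year climatological normals 1931-1960,
#' 1961-1990, 1991-2020, plus the full 1931-2020 period.
#'
#' @return data.frame with columns `start_year`, `end_year`.
#' @export
default_windows <- function() {
  data.frame(start_year = c(1931, 1961, 1991, 1931),
             end_year = c(1960, 1990, 2020, 2020))
}

#' Window-trend table for several windows and variables
#'
#' Applies [window_trend()] to each window and variable; windows failing
#' the >= 3 usable years precondition are reported with `NA` summaries and
#' an `error` message rather than aborting the batch.
#'
#' @inheritParams window_trend
#' @param windows data.frame with `start_year`, `end_year` (default
#'   [default_windows()]).
#' @param variables columns to analyse; defaults to those of `temp_c`,
#'   `rain_mm` present in `series`.
#' @return data.frame, one row per window x variable, with an extra
#'   `error` column (`NA` when the fit succeeded).
#' @export
summarize_windows <- function(series, windows = default_windows(),
                              variables = intersect(c("temp_c", "rain_mm"),
                                                    names(series))) {
  rows <- list()
  for (v in variables) {
    for (w in seq_len(nrow(windows))) {
      res <- tryCatch(
        cbind(window_trend(series, v, windows$start_year[w],
                           windows$end_year[w]),
              error = NA_character_, stringsAsFactors = FALSE),
        error = function(e) {
          data.frame(variable = v, start_year = windows$start_year[w],
                     end_year = windows$end_year[w], n = NA_integer_,
                     coverage = NA_real_, slope = NA_real_,
                     fitted_start = NA_real_, fitted_end = NA_real_,
                     delta = NA_real_, window_mean = NA_real_,
                     low_coverage = NA, error = conditionMessage(e),
                     stringsAsFactors = FALSE)
        }
      )
      rows <- c(rows, list(res))
    }
  }
  if (!length(rows)) {
    return(data.frame(variable = character(), start_year = integer(),
                      end_year = integer(), n = integer(),
                      coverage = numeric(), slope = numeric(),
                      fitted_start = numeric(), fitted_end = numeric(),
                      delta = numeric(), window_mean = numeric(),
                      low_coverage = logical(), error = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read an annual climate series from CSV
#'
#' Expects columns `year`, `temp_c`, `rain_mm` ("NA" for missing values).
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_climate_series <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"year" %in% names(d)) {
    stop(path, " must have a `year` column", call. = FALSE)
  }
  d <- d[order(d$year), ]
  validate_climate_series(d)
  d
}
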