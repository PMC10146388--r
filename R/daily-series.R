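#' Date-indexed daily series
#'
#' A thin container for one daily value per calendar day: strictly
#' increasing dates at daily spacing, with missing days carried explicitly
#' as `NA` (never silently dropped and never imputed as zero).
#'
#' @param dates `Date` vector, strictly increasing, spacing one day.
#' @param values numeric vector, same length; `NA` marks a missing day.
#' @param name series label.
#' @param n_obs optional per-day observation counts (e.g. tweets per day).
#' @return a `daily_series` object (data.frame with columns `date`, `value`
#'   and optionally `n`, plus a `name` attribute).
#' @export
daily_series <- function(dates, values, name = "series", n_obs = NULL) {
  dates <- as.Date(dates)
  stopifnot(length(dates) == length(values))
  if (length(dates) > 1) {
    d <- as.integer(diff(dates))
    if (any(d != 1)) stop("dates must be strictly increasing with daily spacing")
  }
  df <- data.frame(date = dates, value = as.numeric(values))
  if (!is.null(n_obs)) df$n <- as.integer(n_obs)
  structure(df, class = c("daily_series", "data.frame"), name = name)
}

#' @export
print.daily_series <- function(x, ...) {
  v <- x$value
  cat(sprintf("<daily_series> '%s': %d days (%s to %s), %d missing, mean %.4g\n",
              attr(x, "name"), nrow(x), min(x$date), max(x$date),
              sum(is.na(v)), mean(v, na.rm = TRUE)))
  invisible(x)
}

series_values <- function(x) {
  if (inherits(x, "daily_series")) x$value else as.numeric(x)
}

#' Align daily series on their common date range
#'
#' @param ... two or more `daily_series`.
#' @param na_action `"interpolate"` fills interior missing values linearly
#'   (with a warning stating how many), `"drop"` removes days missing in any
#'   series, `"none"` leaves `NA`s in place.
#' @return a data.frame with a `date` column and one value column per series.
#' @export
align_series <- function(..., na_action = c("interpolate", "drop", "none")) {
  na_action <- match.arg(na_action)
  ss <- list(...)
  stopifnot(length(ss) >= 2)
  lo <- max(as.Date(vapply(ss, function(s) as.character(min(s$date)), "")))
  hi <- min(as.Date(vapply(ss, function(s) as.character(max(s$date)), "")))
  if (lo > hi) stop("series have no overlapping dates")
  dates <- seq(lo, hi, by = "day")
  out <- data.frame(date = dates)
  for (s in ss) {
    v <- s$value[match(dates, s$date)]
    if (na_action == "interpolate" && anyNA(v)) {
      nmiss <- sum(is.na(v))
      v <- stats::approx(seq_along(v)[!is.na(v)], v[!is.na(v)],
                         xout = seq_along(v), rule = 2)$y
      warning(sprintf("series '%s': %d missing day(s) linearly interpolated",
                      attr(s, "name"), nmiss))
    }
    out[[attr(s, "name")]] <- v
  }
  if (na_action == "drop") out <- out[stats::complete.cases(out), , drop = FALSE]
  out
}

#' Write / read a daily series as `date,value,n` delimited text
#'
#' @param series a [daily_series()].
#' @param path file path.
#' @return `write_daily_series` returns `path` invisibly; `read_daily_series`
#'   returns a [daily_series()].
#' @export
write_daily_series <- function(series, path) {
  df <- as.data.frame(series)
  df$date <- as.character(df$date)
  df$value <- sprintf("%.15g", df$value)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_daily_series
#' @export
read_daily_series <- function(path, name = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  daily_series(as.Date(df$date), as.numeric(df$value),
               name = name %||% sub("\\.[^.]+$", "", basename(path)),
               n_obs = df$n)
}
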