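# Degree-day accumulation from daily min/max temperatures
# (single sine method, dual thresholds, horizontal cutoff).

#' Degree-day calculation parameters
#'
#' Lower and upper development thresholds for the single sine degree-day
#' calculation. Defaults are the classic oriental fruit moth thresholds:
#' lower 7.2 degC, upper 32.2 degC, horizontal cutoff (development proceeds
#' at its maximal rate above the upper threshold, it is not reduced).
#'
#' @param lower Lower development threshold (degC).
#' @param upper Upper development threshold (degC); must exceed `lower`.
#' @param cutoff Cutoff rule at the upper threshold. Only `"horizontal"`
#'   is implemented.
#' @return An object of class `dd_params`.
#' @examples
#' dd_params()            # 7.2 / 32.2 degC defaults
#' dd_params(10, 30)
#' @export
dd_params <- function(lower = 7.2, upper = 32.2, cutoff = "horizontal") {
  cutoff <- match.arg(cutoff, "horizontal")
  stopifnot(is.numeric(lower), is.numeric(upper),
            length(lower) == 1L, length(upper) == 1L,
            is.finite(lower), is.finite(upper))
  if (lower >= upper)
    stop("dd_params: `lower` (", lower, ") must be strictly below `upper` (",
         upper, ")")
  structure(list(lower = lower, upper = upper, cutoff = cutoff),
            class = "dd_params")
}

#' @export
print.dd_params <- function(x, ...) {
  cat("Degree-day parameters: lower ", x$lower, " degC, upper ", x$upper,
      " degC, ", x$cutoff, " cutoff\n", sep = "")
  invisible(x)
}

#' Daily temperature series
#'
#' Container for one station's daily minimum/maximum temperatures. Dates
#' must be strictly increasing and `tmin <= tmax` on every day.
#'
#' @param date `Date` vector, strictly increasing.
#' @param tmin,tmax Daily minimum / maximum temperature (degC).
#' @param station_id Station label.
#' @return A data frame of class `temperature_series` with columns
#'   `date`, `tmin`, `tmax` and a `station_id` attribute.
#' @export
temperature_series <- function(date, tmin, tmax, station_id = "station") {
  date <- as.Date(date)
  stopifnot(length(date) == length(tmin), length(tmin) == length(tmax))
  if (anyNA(date)) stop("temperature_series: dates contain NA")
  if (length(date) > 1L && any(diff(date) <= 0))
    stop("temperature_series: dates must be strictly increasing")
  if (any(!is.finite(tmin) | !is.finite(tmax)))
    stop("temperature_series: non-finite temperatures")
  bad <- which(tmin > tmax)
  if (length(bad))
    stop("temperature_series: tmin > tmax on ",
         paste(format(date[bad[seq_len(min(3L, length(bad)))]]),
               collapse = ", "),
         if (length(bad) > 3L) " ..." else "")
  structure(
    data.frame(date = date, tmin = as.numeric(tmin), tmax = as.numeric(tmax)),
    station_id = station_id,
    class = c("temperature_series", "data.frame"))
}

#' Read a daily weather CSV
#'
#' Expects a UTF-8 CSV with header `date,tmin_C,tmax_C` and ISO-8601 dates,
#' one station per file. The series invariants are validated on ingestion.
#'
#' @param path Path to the CSV file.
#' @param station_id Station label; defaults to the file name.
#' @return A [temperature_series()].
#' @export
read_weather_csv <- function(path, station_id = NULL) {
  if (!file.exists(path)) stop("weather file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "tmin_C", "tmax_C")
  if (!all(need %in% names(df)))
    stop("weather CSV must have columns ", paste(need, collapse = ","))
  if (is.null(station_id))
    station_id <- sub("\\.csv$", "", basename(path))
  temperature_series(df$date, df$tmin_C, df$tmax_C, station_id = station_id)
}

#' Write a degree-day series to CSV
#'
#' @param dds A [dd_series] as returned by [accumulate_dd()].
#' @param path Output path; columns `date,daily_dd,cumulative_dd`.
#' @export
write_dd_csv <- function(dds, path) {
  utils::write.csv(
    data.frame(date = format(dds$date), daily_dd = dds$daily_dd,
               cumulative_dd = dds$cumulative_dd),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Single-day degree days by the single sine method
#'
#' Models the daily temperature course as one sine wave through the daily
#' minimum and maximum, `T(t) = (tmin+tmax)/2 + ((tmax-tmin)/2) sin(2*pi*t)`,
#' and returns the area (degC x day) between the lower threshold and the
#' curve after clipping it above at the upper threshold (horizontal cutoff)
#' and below at the lower threshold. The closed form covers the six
#' threshold regimes (fully below, spanning lower only, fully between,
#' spanning upper only, spanning both, fully above); it is vectorised over
#' `tmin`/`tmax`.
#'
#' @param tmin,tmax Daily minimum / maximum temperature (degC),
#'   `tmin <= tmax` elementwise.
#' @param params A [dd_params()].
#' @return Degree days for the day, in `[0, upper - lower]`.
#' @examples
#' single_day_dd(10, 25)                 # partially below lower threshold
#' single_day_dd(7.2, 32.2)              # spans both thresholds: 12.5
#' @export
single_day_dd <- function(tmin, tmax, params = dd_params()) {
  stopifnot(inherits(params, "dd_params"))
  n <- max(length(tmin), length(tmax))
  tmin <- rep_len(as.numeric(tmin), n)
  tmax <- rep_len(as.numeric(tmax), n)
  if (any(!is.finite(tmin) | !is.finite(tmax)))
    stop("single_day_dd: non-finite temperature")
  if (any(tmin > tmax))
    stop("single_day_dd: tmin > tmax")
  L <- params$lower; U <- params$upper
  m <- (tmin + tmax) / 2
  A <- (tmax - tmin) / 2
  out <- numeric(n)

  below  <- tmax <= L                       # whole day below lower
  above  <- tmin >= U                       # whole day above upper
  inside <- !below & !above & tmin >= L & tmax <= U
  lowcut <- !below & !above & tmin <  L & tmax <= U
  upcut  <- !below & !above & tmin >= L & tmax >  U
  both   <- !below & !above & tmin <  L & tmax >  U

  out[above]  <- U - L
  out[inside] <- m[inside] - L
  if (any(lowcut)) {
    th1 <- asin((L - m[lowcut]) / A[lowcut])
    out[lowcut] <- ((m[lowcut] - L) * (pi / 2 - th1) +
                      A[lowcut] * cos(th1)) / pi
  }
  if (any(upcut)) {
    th2 <- asin((U - m[upcut]) / A[upcut])
    out[upcut] <- ((m[upcut] - L) * (th2 + pi / 2) +
                     (U - L) * (pi / 2 - th2) -
                     A[upcut] * cos(th2)) / pi
  }
  if (any(both)) {
    th1 <- asin((L - m[both]) / A[both])
    th2 <- asin((U - m[both]) / A[both])
    out[both] <- ((m[both] - L) * (th2 - th1) +
                    A[both] * (cos(th1) - cos(th2)) +
                    (U - L) * (pi / 2 - th2)) / pi
  }
  # guard against tiny negative round-off
  pmin(pmax(out, 0), U - L)
}

#' Accumulate degree days over a temperature series
#'
#' Applies [single_day_dd()] to every day and forms the running sum within
#' each calendar year, restarting at zero on 1 January (the biofix for the
#' forecast model). A series that starts after 1 January of its first year
#' yields a warning and the result is flagged `partial_year`: its cumulative
#' sums are lower bounds for the true accumulation.
#'
#' @param series A [temperature_series()].
#' @param params A [dd_params()].
#' @return A data frame of class `dd_series` with columns `date`,
#'   `daily_dd`, `cumulative_dd`; attributes `station_id`, `partial_year`.
#' @export
accumulate_dd <- function(series, params = dd_params()) {
  stopifnot(inherits(series, "temperature_series"))
  daily <- single_day_dd(series$tmin, series$tmax, params)
  yr <- as.integer(format(series$date, "%Y"))
  cum <- stats::ave(daily, yr, FUN = cumsum)
  first <- series$date[1L]
  partial <- format(first, "%m-%d") != "01-01"
  if (partial)
    warning("series starts ", format(first),
            " (after 1 January): cumulative DD are lower bounds",
            call. = FALSE)
  structure(
    data.frame(date = series$date, daily_dd = daily, cumulative_dd = cum),
    station_id = attr(series, "station_id"),
    partial_year = partial,
    params = params,
    class = c("dd_series", "data.frame"))
}

#' First date at which a degree-day target is reached
#'
#' @param dds A `dd_series` from [accumulate_dd()].
#' @param target Cumulative degree-day target (>= 0).
#' @param year Calendar year to search.
#' @return The first `Date` in `year` whose cumulative DD is `>= target`.
#'   Errors with class `ddphen_not_reached` if the year never reaches it.
#' @export
date_at_dd <- function(dds, target, year) {
  stopifnot(inherits(dds, "dd_series"), target >= 0)
  yr <- as.integer(format(dds$date, "%Y"))
  sel <- yr == year
  if (!any(sel)) stop("date_at_dd: no data for year ", year)
  cum <- dds$cumulative_dd[sel]
  idx <- which(cum >= target)
  if (!length(idx)) {
    stop(structure(
      class = c("ddphen_not_reached", "error", "condition"),
      list(message = sprintf(
        "target %.1f DD not reached in %d (season total %.1f DD)",
        target, year, cum[length(cum)]), call = sys.call(-1))))
  }
  dds$date[sel][idx[1L]]
}

#' Fill short gaps in a daily temperature series
#'
#' Missing calendar days inside the series span are filled by linear
#' interpolation of `tmin` and `tmax` separately, provided no run of
#' consecutive missing days exceeds `max_gap`. Longer gaps abort: degree-day
#' errors compound over generations, so guessing across long gaps is unsafe.
#'
#' @param series A [temperature_series()] (its dates may have holes).
#' @param max_gap Longest run of missing days that may be interpolated.
#' @return A gap-free [temperature_series()].
#' @export
fill_missing <- function(series, max_gap = 3L) {
  stopifnot(inherits(series, "temperature_series"))
  d <- series$date
  if (length(d) < 2L) return(series)
  full <- seq(d[1L], d[length(d)], by = "day")
  if (length(full) == length(d)) return(series)
  miss <- !(full %in% d)
  runs <- rle(miss)
  if (any(runs$values & runs$lengths > max_gap)) {
    ends <- cumsum(runs$lengths)
    i <- which(runs$values & runs$lengths > max_gap)[1L]
    from <- full[ends[i] - runs$lengths[i] + 1L]
    stop(structure(
      class = c("ddphen_unfillable_gap", "error", "condition"),
      list(message = sprintf(
        "gap of %d missing days starting %s exceeds max_gap = %d",
        runs$lengths[i], format(from), max_gap), call = sys.call(-1))))
  }
  x <- as.numeric(d)
  xf <- as.numeric(full)
  tmin <- stats::approx(x, series$tmin, xout = xf)$y
  tmax <- stats::approx(x, series$tmax, xout = xf)$y
  temperature_series(full, tmin, tmax,
                     station_id = attr(series, "station_id"))
}
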