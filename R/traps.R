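# Weekly pheromone-trap captures: per-area aggregation and transformation
# onto the accumulated degree-day axis.

#' Weekly trap-catch series for one area-year
#'
#' @param check_date `Date` vector of weekly trap checks, strictly
#'   increasing.
#' @param mean_catch Mean moths/trap/week across traps.
#' @param se Standard error of the weekly mean (0 allowed when
#'   `n_traps == 1`).
#' @param n_traps Number of traps reporting that week.
#' @param area,year Area label and calendar year.
#' @return Data frame of class `trap_catch_series`.
#' @export
trap_catch_series <- function(check_date, mean_catch, se, n_traps,
                              area = "area", year = NULL) {
  check_date <- as.Date(check_date)
  stopifnot(length(check_date) == length(mean_catch),
            length(mean_catch) == length(se),
            length(se) == length(n_traps))
  if (length(check_date) > 1L && any(diff(check_date) <= 0))
    stop("trap_catch_series: check dates must be strictly increasing")
  if (any(mean_catch < 0)) stop("trap_catch_series: negative mean_catch")
  if (any(se < 0)) stop("trap_catch_series: negative se")
  if (any(n_traps < 1)) stop("trap_catch_series: n_traps must be >= 1")
  if (is.null(year))
    year <- if (length(check_date)) as.integer(format(check_date[1L], "%Y"))
            else NA_integer_
  structure(
    data.frame(check_date = check_date, mean_catch = as.numeric(mean_catch),
               se = as.numeric(se), n_traps = as.integer(n_traps)),
    area = area, year = year,
    class = c("trap_catch_series", "data.frame"))
}

#' Aggregate per-trap weekly counts to area means
#'
#' For each check date, the weekly mean catch per trap is the arithmetic
#' mean over the traps reporting that week and the SE is the sample
#' standard deviation divided by `sqrt(n)`. Weeks with zero reporting traps
#' are omitted with a warning. Traps may enter or leave mid-season, so the
#' number of traps can vary week to week.
#'
#' @param raw Data frame with columns `check_date`, `trap_id`,
#'   `catch_count` (non-negative integer counts); optionally `area`, `year`.
#' @param area,year Labels; taken from `raw` when present.
#' @return A [trap_catch_series()].
#' @examples
#' raw <- data.frame(check_date = as.Date("2019-05-06"),
#'                   trap_id = c("a", "b"), catch_count = c(2L, 4L))
#' aggregate_traps(raw)    # mean 3, se 1, n 2
#' @export
aggregate_traps <- function(raw, area = NULL, year = NULL) {
  need <- c("check_date", "trap_id", "catch_count")
  if (!all(need %in% names(raw)))
    stop("aggregate_traps: need columns ", paste(need, collapse = ","))
  if (any(raw$catch_count < 0 | raw$catch_count != round(raw$catch_count),
          na.rm = TRUE))
    stop("aggregate_traps: counts must be non-negative integers")
  if (is.null(area)) area <- if ("area" %in% names(raw)) raw$area[1L] else "area"
  if (is.null(year) && "year" %in% names(raw)) year <- raw$year[1L]
  raw$check_date <- as.Date(raw$check_date)
  drop <- is.na(raw$catch_count)
  all_weeks <- format(unique(raw$check_date))
  if (any(drop)) raw <- raw[!drop, , drop = FALSE]
  empty <- setdiff(all_weeks, format(unique(raw$check_date)))
  if (length(empty))
    warning("weeks with no reporting traps omitted: ",
            paste(empty, collapse = ", "), call. = FALSE)
  sp <- split(raw$catch_count, format(raw$check_date))
  dates <- as.Date(names(sp))
  o <- order(dates)
  sp <- sp[o]; dates <- dates[o]
  n <- lengths(sp)
  m <- vapply(sp, mean, numeric(1))
  se <- vapply(sp, function(x) if (length(x) > 1L)
    stats::sd(x) / sqrt(length(x)) else 0, numeric(1))
  trap_catch_series(dates, m, se, n, area = area, year = year)
}

#' Read a trap-capture CSV
#'
#' Accepts either per-trap records (`area,year,check_date,trap_id,
#' catch_count`), which are aggregated per area-year, or pre-aggregated
#' records (`area,year,check_date,mean_catch,se,n_traps`).
#'
#' @param path Path to the CSV file.
#' @return A list of [trap_catch_series()], one per area-year.
#' @export
read_traps_csv <- function(path) {
  if (!file.exists(path)) stop("trap file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  key <- interaction(df$area, df$year, drop = TRUE)
  if (all(c("trap_id", "catch_count") %in% names(df))) {
    lapply(split(df, key), function(g)
      aggregate_traps(g, area = g$area[1L], year = g$year[1L]))
  } else if (all(c("mean_catch", "se", "n_traps") %in% names(df))) {
    lapply(split(df, key), function(g)
      trap_catch_series(g$check_date, g$mean_catch, g$se, g$n_traps,
                        area = g$area[1L], year = g$year[1L]))
  } else {
    stop("trap CSV must be per-trap (trap_id,catch_count) or ",
         "pre-aggregated (mean_catch,se,n_traps)")
  }
}

#' Re-express a weekly catch series on the degree-day axis
#'
#' Each weekly record is keyed by the cumulative DD at its check date (the
#' end of the exposure week, the only date the monitoring protocol
#' records). Ordering is preserved; a check date missing from the weather
#' coverage is an error naming the date.
#'
#' @param series A [trap_catch_series()].
#' @param dds A `dd_series` from [accumulate_dd()].
#' @return Data frame of class `dd_catch_series` with columns
#'   `cumulative_dd`, `mean_catch`, `se`, `n_traps`, `check_date`.
#' @export
to_dd_axis <- function(series, dds) {
  stopifnot(inherits(series, "trap_catch_series"), inherits(dds, "dd_series"))
  idx <- match(series$check_date, dds$date)
  if (anyNA(idx)) {
    missing <- series$check_date[is.na(idx)]
    stop(structure(
      class = c("ddphen_missing_weather", "error", "condition"),
      list(message = paste0("no weather coverage for check date(s): ",
                            paste(format(missing), collapse = ", ")),
           call = sys.call(-1))))
  }
  structure(
    data.frame(cumulative_dd = dds$cumulative_dd[idx],
               mean_catch = series$mean_catch, se = series$se,
               n_traps = series$n_traps, check_date = series$check_date),
    area = attr(series, "area"), year = attr(series, "year"),
    class = c("dd_catch_series", "data.frame"))
}
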