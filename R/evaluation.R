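# Comparison of observed flights with predicted generation windows, and
# the two standard plot styles (calendar axis with SE ribbon and boundary
# lines; DD axis with shaded predicted windows).

#' Fraction of catches falling inside predicted windows
#'
#' Total catches (weekly mean x traps) whose DD key lies inside any
#' predicted generation window, divided by the season total. Windows are
#' half-open, so a catch exactly on a boundary belongs to the later
#' window. Invariant to uniform rescaling of catch magnitudes.
#'
#' @param ddcatch A `dd_catch_series`.
#' @param windows A `generation_windows` data frame.
#' @return Coverage fraction in `[0, 1]`, or `NA` (with a warning) for an
#'   empty or all-zero catch series.
#' @export
coverage_score <- function(ddcatch, windows) {
  stopifnot(inherits(ddcatch, "dd_catch_series"), nrow(windows) >= 1)
  w <- ddcatch$mean_catch * ddcatch$n_traps
  if (!nrow(ddcatch) || sum(w) == 0) {
    warning("coverage_score: empty catch series, not applicable",
            call. = FALSE)
    return(NA_real_)
  }
  inside <- rep(FALSE, nrow(ddcatch))
  for (i in seq_len(nrow(windows)))
    inside <- inside | (ddcatch$cumulative_dd >= windows$dd_start[i] &
                          ddcatch$cumulative_dd < windows$dd_end[i])
  sum(w[inside]) / sum(w)
}

#' Degree-day offsets between observed flights and predicted windows
#'
#' Flights are matched to windows by rank order (generations are read
#' ordinally) and the offset is `dd_start(flight k) - dd_start(window k)`:
#' positive when the observed flight starts later than predicted. Offsets
#' at flight starts are the reproducible choice; peak-based offsets are
#' available with `at = "peak"` (DD of the week with the maximum catch
#' inside each flight). A flight/window count mismatch yields partial
#' offsets and a flag.
#'
#' @param segments A `flight_segments` data frame.
#' @param windows A `generation_windows` data frame.
#' @param at `"start"` (default) or `"peak"`.
#' @return List with `offsets_dd` (length `min(n flights, n windows)`),
#'   `count_mismatch`, `n_flights`, `n_windows`.
#' @export
boundary_offsets <- function(segments, windows, at = c("start", "peak")) {
  at <- match.arg(at)
  stopifnot(inherits(segments, "flight_segments"))
  n <- min(nrow(segments), nrow(windows))
  obs <- if (at == "start") segments$dd_start else {
    series <- attr(segments, "series")
    vapply(seq_len(nrow(segments)), function(k) {
      in_seg <- series$cumulative_dd >= segments$dd_start[k] &
        series$cumulative_dd <= segments$dd_end[k]
      dd <- series$cumulative_dd[in_seg]
      dd[which.max(series$mean_catch[in_seg])]
    }, numeric(1))
  }
  list(offsets_dd = obs[seq_len(n)] - windows$dd_start[seq_len(n)],
       count_mismatch = nrow(segments) != nrow(windows),
       n_flights = nrow(segments), n_windows = nrow(windows))
}

#' Assemble a fit report for one area-year
#'
#' @param ddcatch A `dd_catch_series`.
#' @param segments A `flight_segments` data frame for the same series.
#' @param windows A `generation_windows` data frame.
#' @return List with `coverage`, `offsets_dd`, `count_mismatch`,
#'   `n_flights`, `n_windows`.
#' @export
fit_report <- function(ddcatch, segments, windows) {
  off <- boundary_offsets(segments, windows)
  c(list(coverage = coverage_score(ddcatch, windows)), off)
}

#' Plot observed dynamics against predicted generations
#'
#' `style = "calendar"`: weekly mean catches with a shaded SE ribbon and
#' dotted vertical lines at the detected flight boundaries. `style = "dd"`:
#' mean catches against accumulated DD with the predicted generation
#' windows shaded in alternating tints. Draws on the current device (open
#' a `png()`/`svg()` device to write a file). Empty input yields empty
#' axes without error.
#'
#' @param series A `dd_catch_series`.
#' @param windows Optional `generation_windows` (dd style shading).
#' @param segments Optional `flight_segments` (calendar boundary lines).
#' @param style `"dd"` or `"calendar"`.
#' @param main Plot title.
#' @return Invisibly, `NULL`.
#' @export
plot_dynamics <- function(series, windows = NULL, segments = NULL,
                          style = c("dd", "calendar"), main = "") {
  style <- match.arg(style)
  stopifnot(inherits(series, "dd_catch_series"))
  empty <- nrow(series) == 0L
  if (style == "dd") {
    xlim <- if (empty) c(0, 1) else range(series$cumulative_dd)
    ylim <- c(0, if (empty) 1 else max(series$mean_catch + series$se) * 1.05)
    plot(NA, xlim = xlim, ylim = ylim, xlab = "Accumulated degree days",
         ylab = "Moths / trap / week", main = main)
    if (!is.null(windows)) {
      cols <- rep(c("#ffe4b3", "#d6ecd2"), length.out = nrow(windows))
      for (i in seq_len(nrow(windows)))
        graphics::rect(windows$dd_start[i], ylim[1], windows$dd_end[i],
                       ylim[2], col = cols[i], border = NA)
    }
    if (!empty) {
      graphics::polygon(c(series$cumulative_dd, rev(series$cumulative_dd)),
                        c(series$mean_catch + series$se,
                          rev(pmax(series$mean_catch - series$se, 0))),
                        col = grDevices::adjustcolor("grey40", 0.3),
                        border = NA)
      graphics::lines(series$cumulative_dd, series$mean_catch, lwd = 1.5)
    }
  } else {
    xlim <- if (empty) as.Date(c("2000-01-01", "2000-12-31"))
            else range(series$check_date)
    ylim <- c(0, if (empty) 1 else max(series$mean_catch + series$se) * 1.05)
    plot(NA, xlim = as.numeric(xlim), ylim = ylim, xaxt = "n",
         xlab = "Date", ylab = "Moths / trap / week", main = main)
    graphics::axis.Date(1, at = seq(xlim[1], xlim[2], by = "month"),
                        format = "%b")
    if (!empty) {
      graphics::polygon(as.numeric(c(series$check_date,
                                     rev(series$check_date))),
                        c(series$mean_catch + series$se,
                          rev(pmax(series$mean_catch - series$se, 0))),
                        col = grDevices::adjustcolor("grey40", 0.3),
                        border = NA)
      graphics::lines(series$check_date, series$mean_catch, lwd = 1.5)
    }
    if (!is.null(segments) && nrow(segments) > 1L)
      graphics::abline(v = as.numeric(segments$end_week[-nrow(segments)]),
                       lty = 3)
  }
  invisible(NULL)
}
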