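# Flight segmentation: split a season's capture series into flights at the
# minima between peaks, reconcile ambiguous boundaries across years, and
# express flight durations in degree days (the operational adult-to-adult
# generation time).

#' Centered moving-average smoothing of a DD catch series
#'
#' Light smoothing approximates the visual judgement used when splitting
#' weekly mean curves by eye, reproducibly. Endpoints use shrunken
#' (truncated) windows; `window = 1` is the identity.
#'
#' @param series A `dd_catch_series` (see [to_dd_axis()]).
#' @param window Odd window width in weeks (>= 1).
#' @return The series with `mean_catch` smoothed.
#' @export
smooth_series <- function(series, window = 3L) {
  stopifnot(inherits(series, "dd_catch_series"),
            window >= 1, window %% 2 == 1)
  if (window == 1L || nrow(series) == 0L) return(series)
  h <- (window - 1L) %/% 2L
  x <- series$mean_catch
  n <- length(x)
  out <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    mean(x[lo:hi])
  }, numeric(1))
  series$mean_catch <- out
  series
}

# Topographic prominence of each local maximum: height above the highest
# saddle separating it from any higher maximum.
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    left <- x[seq_len(p)]
    higher_l <- which(left > x[p])
    sad_l <- if (length(higher_l)) min(x[max(higher_l):p]) else min(left)
    right <- x[p:length(x)]
    higher_r <- which(right > x[p])
    sad_r <- if (length(higher_r)) min(right[1:min(higher_r)]) else min(right)
    x[p] - max(sad_l, sad_r)
  }, numeric(1))
}

#' Detect flight-period peaks
#'
#' Local maxima of `mean_catch` whose topographic prominence is at least
#' `min_prominence_frac` times the series maximum. The prominence floor
#' suppresses the bimodal sub-peaks sometimes present within one flight
#' from being read as separate generations. Plateau maxima report their
#' first index. An all-zero series yields no peaks.
#'
#' @param series A `dd_catch_series` (usually pre-smoothed with
#'   [smooth_series()]).
#' @param min_prominence_frac Fraction of the series maximum that a peak's
#'   prominence must reach, in (0, 1].
#' @return Integer vector of peak row indices.
#' @export
detect_peaks <- function(series, min_prominence_frac = 0.15) {
  stopifnot(inherits(series, "dd_catch_series"),
            min_prominence_frac > 0, min_prominence_frac <= 1)
  x <- series$mean_catch
  n <- length(x)
  if (n == 0L || max(x) <= 0) return(integer(0))
  # local maxima, plateaus collapsed to their first index
  cand <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && x[j + 1L] == x[i]) j <- j + 1L   # plateau [i, j]
    left_ok <- i == 1L || x[i - 1L] < x[i]
    right_ok <- j == n || x[j + 1L] < x[i]
    if (left_ok && right_ok && x[i] > 0 && !(i == 1L && j == n))
      cand <- c(cand, i)
    i <- j + 1L
  }
  if (!length(cand)) return(integer(0))
  prom <- peak_prominence(x, cand)
  cand[prom >= min_prominence_frac * max(x)]
}

#' Split a capture series into flights at the minima between peaks
#'
#' Between each pair of consecutive peaks the boundary is placed at the
#' week of the minimum catch (ties resolved to the earliest week). The
#' boundary week closes the earlier flight; the next flight opens on the
#' following check date, but both share the boundary's cumulative DD so
#' that flight durations tile the season span exactly. The first flight
#' starts at the first week with a nonzero catch and the last ends at the
#' last such week. With no peaks the nonzero span is returned as a single
#' segment flagged `unsplit`.
#'
#' A season that opens on a descending curve (the first flight's start was
#' missed) or closes on a rising one is split at the minimum adjacent to
#' the truncated flight, so the well-observed flights are not absorbed
#' into it.
#'
#' Completeness: the first flight is `complete` only when trap coverage
#' started before it (a zero-catch week precedes the first catch — a season
#' opening on an already-descending curve means the flight start was
#' missed); the last flight only when a zero-catch week follows the last
#' catch.
#'
#' @param series A `dd_catch_series`; raw weekly values, used for the
#'   nonzero span and the DD endpoints.
#' @param peaks Peak indices from [detect_peaks()].
#' @param smoothed Optional smoothed copy of `series` on which minima are
#'   located; defaults to `series` itself.
#' @return Data frame of class `flight_segments` with one row per flight:
#'   `flight_order`, `start_week`, `end_week`, `dd_start`, `dd_end`,
#'   `duration_dd`, `complete`, `imputed_boundary`; attributes `area`,
#'   `year`, `unsplit`, `series`.
#' @export
split_at_minima <- function(series, peaks, smoothed = series) {
  stopifnot(inherits(series, "dd_catch_series"),
            nrow(smoothed) == nrow(series))
  nz <- which(series$mean_catch > 0)
  if (!length(nz))
    return(flight_segments_df(series, integer(0), integer(0),
                              unsplit = TRUE))
  first <- nz[1L]; last <- nz[length(nz)]
  peaks <- sort(unique(as.integer(peaks)))
  if (length(peaks) < 1L) {
    return(flight_segments_df(series, first, last, unsplit = TRUE))
  }
  # a season opening on a descending curve is the tail of a flight whose
  # start was missed: treat the opening week as a truncated-flight peak
  # (and symmetrically a season ending on a rising curve)
  sm <- smoothed$mean_catch
  if (first == 1L && peaks[1L] > 1L && sm[1L] > sm[2L])
    peaks <- c(1L, peaks)
  n <- nrow(series)
  if (last == n && peaks[length(peaks)] < n && sm[n] > sm[n - 1L])
    peaks <- c(peaks, n)
  bounds <- integer(0)
  if (length(peaks) > 1L) {
    for (i in seq_len(length(peaks) - 1L)) {
      span <- (peaks[i] + 1L):(peaks[i + 1L] - 1L)
      if (length(span) == 0L) span <- peaks[i]     # adjacent peaks
      m <- smoothed$mean_catch[span]
      bounds <- c(bounds, span[which.min(m)])      # which.min = earliest tie
    }
  }
  flight_segments_df(series, first, last, bounds = bounds, unsplit = FALSE)
}

# Build the flight_segments frame from the nonzero span and boundary weeks.
flight_segments_df <- function(series, first, last, bounds = integer(0),
                               unsplit = FALSE, imputed = logical(0)) {
  if (!length(first)) {
    segs <- data.frame(flight_order = integer(0), start_week = as.Date(character(0)),
                       end_week = as.Date(character(0)), dd_start = numeric(0),
                       dd_end = numeric(0), duration_dd = numeric(0),
                       complete = logical(0), imputed_boundary = logical(0))
    return(structure(segs, area = attr(series, "area"),
                     year = attr(series, "year"), unsplit = unsplit,
                     series = series, class = c("flight_segments", "data.frame")))
  }
  if (!length(imputed)) imputed <- rep(FALSE, length(bounds))
  keep <- bounds > first & bounds < last
  bounds <- bounds[keep]
  imputed <- imputed[keep]
  starts <- c(first, bounds + 1L)        # week ownership: boundary week
  ends <- c(bounds, last)                # closes the earlier flight
  dd <- series$cumulative_dd
  dd_start <- dd[c(first, bounds)]       # DD boundary shared by both flights
  dd_end <- dd[c(bounds, last)]
  k <- length(starts)
  head_zero <- first > 1L                # coverage before first catch
  tail_zero <- last < nrow(series)       # coverage after last catch
  complete <- rep(TRUE, k)
  complete[1L] <- head_zero
  complete[k] <- complete[k] && tail_zero
  segs <- data.frame(
    flight_order = seq_len(k),
    start_week = series$check_date[starts],
    end_week = series$check_date[ends],
    dd_start = dd_start, dd_end = dd_end,
    duration_dd = dd_end - dd_start,
    complete = complete,
    imputed_boundary = c(FALSE, imputed))   # flag on the flight a boundary opens
  structure(segs, area = attr(series, "area"), year = attr(series, "year"),
            unsplit = unsplit, series = series,
            boundary_weeks = bounds,
            class = c("flight_segments", "data.frame"))
}

#' Segment one season's capture series into flights
#'
#' Convenience wrapper: smooth, detect peaks, split at minima. Peaks and
#' minima are located on the smoothed series; the raw series provides the
#' nonzero span and the DD endpoints.
#'
#' @param series A `dd_catch_series`.
#' @param smooth_window Odd moving-average width in weeks (default 3).
#' @param min_prominence_frac Peak prominence floor (default 0.15).
#' @return A `flight_segments` data frame (see [split_at_minima()]).
#' @export
segment_flights <- function(series, smooth_window = 3L,
                            min_prominence_frac = 0.15) {
  sm <- smooth_series(series, smooth_window)
  peaks <- detect_peaks(sm, min_prominence_frac)
  split_at_minima(series, peaks, smoothed = sm)
}

#' Reconcile flight boundaries across years of one area
#'
#' When overlap between flights hides a minimum in one year, the same
#' transition in the other years of that area locates the most probable
#' shift. Years whose detected boundary count falls short of the area
#' maximum get their missing boundaries imputed at the median DD of the
#' same boundary (by rank) across the fully segmented years, re-splitting
#' the series at the week nearest that DD. Imputed boundaries are flagged.
#' If no year resolves any boundary the input is returned with an
#' `unresolved` attribute.
#'
#' @param segmentations List of `flight_segments`, one per year of one
#'   area (each must carry its source series, as [segment_flights()]
#'   arranges).
#' @return List of `flight_segments` with boundaries imputed where needed.
#' @export
reconcile_across_years <- function(segmentations) {
  stopifnot(length(segmentations) >= 2L,
            all(vapply(segmentations, inherits, logical(1), "flight_segments")))
  n_bounds <- vapply(segmentations, function(s) max(0L, nrow(s) - 1L),
                     integer(1))
  K <- max(n_bounds)
  if (K == 0L) {
    attr(segmentations, "unresolved") <- TRUE
    warning("no flight boundary detected in any year; unresolved",
            call. = FALSE)
    return(segmentations)
  }
  full <- segmentations[n_bounds == K]
  ref <- vapply(seq_len(K), function(j)
    stats::median(vapply(full, function(s) s$dd_end[j], numeric(1))),
    numeric(1))
  out <- segmentations
  for (i in which(n_bounds < K)) {
    s <- segmentations[[i]]
    series <- attr(s, "series")
    have <- if (nrow(s) > 1L) s$dd_end[-nrow(s)] else numeric(0)
    assign_idx <- align_boundaries(have, ref)
    miss <- setdiff(seq_len(K), assign_idx)
    # impute at the median reference DD of the other years
    imput_dd <- ref[miss]
    wk_old <- attr(s, "boundary_weeks")
    if (is.null(wk_old)) wk_old <- integer(0)
    wk_new <- vapply(imput_dd, function(d)
      which.min(abs(series$cumulative_dd - d)), integer(1))
    bounds <- sort(unique(c(wk_old, wk_new)))
    imputed <- bounds %in% setdiff(wk_new, wk_old)
    nz <- which(series$mean_catch > 0)
    out[[i]] <- flight_segments_df(series, nz[1L], nz[length(nz)],
                                   bounds = bounds, imputed = imputed)
  }
  attr(out, "unresolved") <- FALSE
  out
}

# Order-preserving assignment of m detected boundaries to K reference
# slots minimizing total absolute DD discrepancy (K is small: enumerate).
align_boundaries <- function(have, ref) {
  m <- length(have); K <- length(ref)
  if (m == 0L) return(integer(0))
  if (m >= K) return(seq_len(K))
  combos <- utils::combn(K, m)
  costs <- apply(combos, 2L, function(s) sum(abs(have - ref[s])))
  combos[, which.min(costs)]
}

#' Tabulate generation durations across areas and years
#'
#' One record per complete flight: the first flight of a season is dropped
#' when its start was unobserved (traps deployed onto an already-descending
#' catch curve) and the last flight when its end was unobserved, so only
#' seasons with full coverage of those periods contribute those flights.
#'
#' @param segmentations List of `flight_segments` (any areas/years).
#' @param province_map Named character vector mapping area to province.
#' @return Data frame with columns `province`, `area`, `year`,
#'   `flight_order`, `duration_dd`.
#' @export
duration_table <- function(segmentations, province_map) {
  recs <- lapply(segmentations, function(s) {
    if (!nrow(s)) return(NULL)
    area <- attr(s, "area")
    keep <- s$complete
    if (!any(keep)) return(NULL)
    data.frame(province = unname(province_map[area]), area = area,
               year = attr(s, "year"),
               flight_order = s$flight_order[keep],
               duration_dd = s$duration_dd[keep])
  })
  out <- do.call(rbind, recs)
  if (is.null(out))
    out <- data.frame(province = character(0), area = character(0),
                      year = integer(0), flight_order = integer(0),
                      duration_dd = numeric(0))
  rownames(out) <- NULL
  out
}
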