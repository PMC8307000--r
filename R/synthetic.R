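# Synthetic weather and trap-catch generator with known ground truth.
# Emergence kernels live on the degree-day axis — development is
# temperature-driven, so true generation durations are exact in DD by
# construction — and weekly per-trap counts are negative binomial to
# emulate trap-to-trap heterogeneity.

#' Synthetic climate configuration
#'
#' Sinusoidal seasonal daily-mean temperature with its minimum in
#' mid-January, a fixed diurnal range and independent Gaussian noise on
#' tmin and tmax. Presets (see [scenario_preset()]) are calibrated so the
#' March-September means of the daily minima and maxima match the
#' Mediterranean study areas (about 12.4/24.5 degC for the humid coastal
#' "girona_like" preset, 11.4/28.1 degC for the dry continental
#' "lleida_like" one).
#'
#' @param annual_mean Annual mean of the daily mean temperature (degC).
#' @param annual_amplitude Half peak-to-trough seasonal swing (degC).
#' @param diurnal_range Mean tmax - tmin (degC), > 0.
#' @param noise_sd SD of the independent daily noise on tmin and tmax
#'   (degC), >= 0. Default 1.5 degC, a typical day-to-day synoptic
#'   variability.
#' @param seed Integer RNG seed.
#' @return Object of class `climate_config`.
#' @export
climate_config <- function(annual_mean, annual_amplitude, diurnal_range,
                           noise_sd = 1.5, seed = 1L) {
  stopifnot(diurnal_range > 0, noise_sd >= 0)
  structure(list(annual_mean = annual_mean,
                 annual_amplitude = annual_amplitude,
                 diurnal_range = diurnal_range, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "climate_config")
}

#' Synthetic population configuration
#'
#' One Gaussian emergence kernel per generation on the cumulative-DD axis.
#' Weekly expected catch per trap is each kernel's probability mass in the
#' week's DD interval times that generation's abundance; per-trap weekly
#' counts are negative binomial.
#'
#' @param flight_centers_dd Strictly increasing kernel centers (DD).
#' @param flight_sd_dd Common kernel SD (DD). Larger values overlap the
#'   flights, eventually merging them.
#' @param abundance Expected season-total moths per trap for each
#'   generation (same length as centers, >= 0).
#' @param n_traps Number of traps (>= 1).
#' @param dispersion Negative-binomial size parameter for weekly counts
#'   (smaller = more trap-to-trap heterogeneity). Default 1.5.
#' @param seed Integer RNG seed.
#' @return Object of class `population_config`.
#' @export
population_config <- function(flight_centers_dd, flight_sd_dd = 80,
                              abundance, n_traps = 25L, dispersion = 1.5,
                              seed = 1L) {
  stopifnot(length(flight_centers_dd) >= 1,
            all(diff(flight_centers_dd) > 0),
            length(abundance) == length(flight_centers_dd),
            all(abundance >= 0), n_traps >= 1, flight_sd_dd > 0,
            dispersion > 0)
  structure(list(n_generations = length(flight_centers_dd),
                 flight_centers_dd = flight_centers_dd,
                 flight_sd_dd = flight_sd_dd, abundance = abundance,
                 n_traps = as.integer(n_traps), dispersion = dispersion,
                 seed = as.integer(seed)),
            class = "population_config")
}

#' Scenario presets
#'
#' Two bundled scenarios mirror the study provinces' phenomenology:
#' `girona_like` — humid coastal climate, 4 generations spaced 626 DD,
#' low abundance (weekly peaks under ~10 moths/trap); `lleida_like` — dry
#' continental climate, 5 generations spaced 528 DD, weekly peaks up to
#' ~50 moths/trap. In both, the second generation is less abundant than
#' the first and abundance rises from the third onward. Centers start half
#' a spacing beyond the 126 DD first-catch point.
#'
#' @param name `"girona_like"` or `"lleida_like"`.
#' @param seed Integer seed applied to both climate and population.
#' @return List with elements `climate` ([climate_config()]) and
#'   `population` ([population_config()]).
#' @export
scenario_preset <- function(name = c("girona_like", "lleida_like"),
                            seed = 1L) {
  name <- match.arg(name)
  if (name == "girona_like") {
    clim <- climate_config(annual_mean = 14.83, annual_amplitude = 8,
                           diurnal_range = 12.11, noise_sd = 1.5,
                           seed = seed)
    centers <- 126 + 626 * (seq_len(4) - 0.5)       # 439 1065 1691 2317
    pop <- population_config(centers, flight_sd_dd = 80,
                             abundance = c(18, 12, 22, 28),
                             n_traps = 25L, dispersion = 1.5, seed = seed)
  } else {
    clim <- climate_config(annual_mean = 16.15, annual_amplitude = 8,
                           diurnal_range = 16.68, noise_sd = 1.5,
                           seed = seed)
    centers <- 126 + 528 * (seq_len(5) - 0.5)       # 390 ... 2502
    pop <- population_config(centers, flight_sd_dd = 80,
                             abundance = c(80, 50, 100, 120, 130),
                             n_traps = 25L, dispersion = 1.5, seed = seed)
  }
  list(name = name, climate = clim, population = pop)
}

#' Generate one year of synthetic daily weather
#'
#' Daily mean follows `annual_mean - annual_amplitude * cos(2*pi*(doy - 15)
#' / 365)` (minimum on 15 January); tmin/tmax sit half a diurnal range
#' below/above with independent Gaussian noise; days where noise inverts
#' the pair are redrawn. Bit-reproducible for a fixed seed.
#'
#' @param config A [climate_config()].
#' @param year Calendar year.
#' @return A [temperature_series()] covering the full year.
#' @export
generate_weather <- function(config, year = 2019L) {
  stopifnot(inherits(config, "climate_config"))
  set.seed(config$seed)
  dates <- seq(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-12-31", year)), by = "day")
  doy <- seq_along(dates)
  mean_t <- config$annual_mean -
    config$annual_amplitude * cos(2 * pi * (doy - 15) / 365)
  half <- config$diurnal_range / 2
  n <- length(dates)
  tmin <- mean_t - half + stats::rnorm(n, 0, config$noise_sd)
  tmax <- mean_t + half + stats::rnorm(n, 0, config$noise_sd)
  bad <- which(tmin > tmax)
  while (length(bad)) {                   # redraw inverted pairs
    tmin[bad] <- mean_t[bad] - half + stats::rnorm(length(bad), 0, config$noise_sd)
    tmax[bad] <- mean_t[bad] + half + stats::rnorm(length(bad), 0, config$noise_sd)
    bad <- bad[tmin[bad] > tmax[bad]]
  }
  temperature_series(dates, tmin, tmax,
                     station_id = sprintf("synthetic-%d", year))
}

#' Generate synthetic weekly trap catches with ground truth
#'
#' Trap checks run weekly (every 7th day of the DD series). The expected
#' weekly catch per trap sums, over generations, the Gaussian kernel mass
#' falling in the week's DD interval times that generation's abundance;
#' per-trap counts are drawn negative binomial and aggregated to weekly
#' means. The returned ground truth places the true flight boundaries at
#' the minima of the mixture intensity between consecutive kernel centers,
#' with the season edges mirrored around the first and last centers so
#' each generation has a true duration.
#'
#' @param pop A [population_config()].
#' @param dds A `dd_series` covering the season (from [accumulate_dd()]).
#' @return List with `catches` (a [trap_catch_series()]), `raw` (the
#'   per-trap weekly counts), and `truth` (list: `boundaries_dd`,
#'   `durations_dd`, `n_generations`, `centers_dd`, `expected_weekly`).
#' @export
generate_catches <- function(pop, dds) {
  stopifnot(inherits(pop, "population_config"), inherits(dds, "dd_series"))
  season_dd <- max(dds$cumulative_dd)
  if (any(pop$flight_centers_dd > season_dd))
    stop(structure(class = c("ddphen_invalid_config", "error", "condition"),
                   list(message = sprintf(
                     "flight center %.0f DD beyond season total %.0f DD",
                     max(pop$flight_centers_dd), season_dd),
                     call = sys.call())))
  set.seed(pop$seed)
  wk <- seq(7L, nrow(dds), by = 7L)          # weekly checks
  dd_hi <- dds$cumulative_dd[wk]
  dd_lo <- c(0, dd_hi[-length(dd_hi)])
  mu <- rep(0, length(wk))
  for (k in seq_len(pop$n_generations)) {
    mass <- stats::pnorm(dd_hi, pop$flight_centers_dd[k], pop$flight_sd_dd) -
      stats::pnorm(dd_lo, pop$flight_centers_dd[k], pop$flight_sd_dd)
    mu <- mu + pop$abundance[k] * mass
  }
  counts <- matrix(stats::rnbinom(length(wk) * pop$n_traps,
                                  mu = rep(mu, each = pop$n_traps),
                                  size = pop$dispersion),
                   nrow = pop$n_traps)
  raw <- data.frame(
    check_date = rep(dds$date[wk], each = pop$n_traps),
    trap_id = rep(sprintf("T%02d", seq_len(pop$n_traps)), length(wk)),
    catch_count = as.vector(counts))
  catches <- aggregate_traps(raw, area = "synthetic",
                             year = as.integer(format(dds$date[1L], "%Y")))
  truth <- kernel_truth(pop)
  truth$expected_weekly <- mu
  list(catches = catches, raw = raw, truth = truth)
}

# True boundaries = minima of the mixture intensity between consecutive
# centers; season edges mirrored so every generation has a duration.
kernel_truth <- function(pop) {
  K <- pop$n_generations
  cen <- pop$flight_centers_dd
  s <- pop$flight_sd_dd
  a <- pop$abundance
  dens <- function(x) {
    out <- 0
    for (k in seq_len(K)) out <- out + a[k] * stats::dnorm(x, cen[k], s)
    out
  }
  boundaries <- if (K > 1L)
    vapply(seq_len(K - 1L), function(k)
      stats::optimize(dens, c(cen[k], cen[k + 1L]))$minimum, numeric(1))
  else numeric(0)
  edges <- c(if (K > 1L) cen[1L] - (boundaries[1L] - cen[1L])
             else cen[1L] - 3 * s,
             boundaries,
             if (K > 1L) cen[K] + (cen[K] - boundaries[K - 1L])
             else cen[K] + 3 * s)
  list(boundaries_dd = boundaries, durations_dd = diff(edges),
       n_generations = K, centers_dd = cen, flight_sd_dd = s)
}

#' Write a simulated scenario to plain-text files
#'
#' Convenience used by the command-line `simulate` subcommand: writes the
#' weather CSV (`date,tmin_C,tmax_C`), the per-trap catches CSV
#' (`area,year,check_date,trap_id,catch_count`) and the ground-truth JSON.
#'
#' @param scenario Output of [scenario_preset()].
#' @param year Calendar year to simulate.
#' @param out_weather,out_catches,out_truth Output paths (NULL to skip).
#' @return Invisibly, the list from [generate_catches()] plus the weather.
#' @export
simulate_scenario <- function(scenario, year = 2019L, out_weather = NULL,
                              out_catches = NULL, out_truth = NULL) {
  wx <- generate_weather(scenario$climate, year)
  dds <- accumulate_dd(wx)
  sim <- generate_catches(scenario$population, dds)
  if (!is.null(out_weather))
    utils::write.csv(data.frame(date = format(wx$date), tmin_C = wx$tmin,
                                tmax_C = wx$tmax),
                     out_weather, row.names = FALSE, quote = FALSE)
  if (!is.null(out_catches)) {
    raw <- sim$raw
    raw$area <- scenario$name
    raw$year <- year
    utils::write.csv(raw[c("area", "year", "check_date", "trap_id",
                           "catch_count")],
                     out_catches, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(out_truth))
    jsonlite::write_json(sim$truth[c("boundaries_dd", "durations_dd",
                                     "n_generations")],
                         out_truth, auto_unbox = TRUE, digits = NA)
  invisible(c(sim, list(weather = wx, dd = dds)))
}
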