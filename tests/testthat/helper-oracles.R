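# Independent oracles and small fixture builders used across tests.

# Numerical quadrature of the clipped daily sine: the reference against
# which the closed-form single sine degree days are judged.
quad_dd <- function(tmin, tmax, lower = 7.2, upper = 32.2, n = 2e5) {
  t <- (seq_len(n) - 0.5) / n
  temp <- (tmin + tmax) / 2 + (tmax - tmin) / 2 * sin(2 * pi * t)
  mean(pmax(0, pmin(temp, upper) - lower))
}

# Build a dd_catch_series directly from weekly catches, with a constant
# DD increment per week (default 1 DD/week keeps the axes trivial).
make_ddcatch <- function(mean_catch, dd = NULL, se = 0, n_traps = 1L,
                         area = "test", year = 2019L,
                         start = as.Date("2019-03-04")) {
  k <- length(mean_catch)
  if (is.null(dd)) dd <- seq_len(k)
  structure(
    data.frame(cumulative_dd = dd, mean_catch = mean_catch,
               se = rep_len(se, k), n_traps = rep_len(as.integer(n_traps), k),
               check_date = start + 7 * (seq_len(k) - 1L)),
    area = area, year = year,
    class = c("dd_catch_series", "data.frame"))
}

# A constant-temperature year: every day accrues the same DD.
make_constant_year <- function(t = 10, year = 2019L) {
  d <- seq(as.Date(sprintf("%d-01-01", year)),
           as.Date(sprintf("%d-12-31", year)), by = "day")
  temperature_series(d, rep(t, length(d)), rep(t, length(d)),
                     station_id = "const")
}

# Run one synthetic scenario through the segmentation pipeline.
recover_scenario <- function(name, seed) {
  sc <- scenario_preset(name, seed = seed)
  dds <- accumulate_dd(generate_weather(sc$climate))
  sim <- generate_catches(sc$population, dds)
  segs <- segment_flights(to_dd_axis(sim$catches, dds))
  list(segments = segs, truth = sim$truth, dd = dds)
}
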