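test_that("smooth_series: identity at window 1, shrunken endpoints, convolution oracle", {
  s <- make_ddcatch(c(0, 3, 0))
  expect_identical(smooth_series(s, 1L), s)
  expect_equal(smooth_series(s, 3L)$mean_catch, c(1.5, 1.0, 1.5))

  set.seed(3)
  r <- make_ddcatch(runif(40))
  sm <- smooth_series(r, 3L)$mean_catch
  x <- r$mean_catch
  oracle <- vapply(seq_along(x), function(i)
    mean(x[max(1, i - 1):min(length(x), i + 1)]), numeric(1))
  expect_equal(sm, oracle)
})

test_that("detect_peaks finds isolated maxima and rejects monotone/flat series", {
  expect_equal(detect_peaks(make_ddcatch(c(0, 5, 0))), 2L)
  expect_length(detect_peaks(make_ddcatch(c(1, 2, 3, 4, 5))), 0L)
  expect_length(detect_peaks(make_ddcatch(rep(0, 10))), 0L)
  # plateau peak reports its first index
  expect_equal(detect_peaks(make_ddcatch(c(0, 4, 4, 0))), 2L)
})

test_that("two noisy Gaussian bumps yield exactly two peaks near the centers", {
  set.seed(17)
  x <- seq_len(40)
  y <- 10 * exp(-(x - 10)^2 / 8) + 12 * exp(-(x - 28)^2 / 8) +
    abs(rnorm(40, 0, 0.3))
  s <- make_ddcatch(y)
  p <- detect_peaks(smooth_series(s, 3L), 0.15)
  expect_length(p, 2L)
  expect_lte(abs(p[1] - 10), 1)
  expect_lte(abs(p[2] - 28), 1)
})

test_that("prominence floor suppresses bimodal sub-peaks within a flight", {
  # a main flight with a shallow dip (bimodal peak) and a second flight
  y <- c(0, 2, 8, 7.6, 8.2, 2, 0.5, 1, 6, 9, 2, 0)
  s <- make_ddcatch(y)
  expect_length(detect_peaks(s, 0.15), 2L)       # dip of 0.6 is ignored
  expect_length(detect_peaks(s, 0.01), 3L)       # but is a real local max
})

test_that("split_at_minima places the boundary at the minimum between peaks", {
  y <- c(0, 2, 8, 3, 1, 0, 1, 4, 9, 2, 0)
  s <- make_ddcatch(y, dd = 10 * seq_along(y))
  segs <- split_at_minima(s, peaks = c(3L, 9L))
  # brute-force scan between the peaks finds the 0 at index 6
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$dd_start, c(20, 60))         # shared boundary DD
  expect_equal(segs$dd_end, c(60, 100))
  expect_equal(segs$start_week,
               s$check_date[c(2L, 7L)])          # later flight: next week
  expect_equal(segs$end_week, s$check_date[c(6L, 10L)])
  # durations tile the nonzero span
  expect_equal(sum(segs$duration_dd),
               segs$dd_end[2] - segs$dd_start[1])
})

test_that("ties between equal minima resolve to the earlier week", {
  y <- c(0, 5, 1, 2, 1, 6, 0)
  s <- make_ddcatch(y)
  segs <- split_at_minima(s, peaks = c(2L, 6L))
  expect_equal(segs$end_week[1], s$check_date[3])   # first of the two 1s
})

test_that("single peak gives one segment; no peaks flag unsplit", {
  s <- make_ddcatch(c(0, 1, 5, 2, 0))
  one <- split_at_minima(s, peaks = 3L)
  expect_equal(nrow(one), 1L)
  expect_false(attr(one, "unsplit"))
  none <- split_at_minima(s, peaks = integer(0))
  expect_equal(nrow(none), 1L)
  expect_true(attr(none, "unsplit"))
})

test_that("completeness requires zero-catch coverage on both sides", {
  covered <- segment_flights(make_ddcatch(c(0, 1, 6, 1, 0, 2, 7, 1, 0)))
  expect_true(all(covered$complete))
  # season opens on a descending curve: flight 1 start unobserved
  late <- segment_flights(make_ddcatch(c(6, 3, 1, 0, 2, 7, 1, 0)))
  expect_false(late$complete[1])
  expect_true(late$complete[nrow(late)])
  # flight continuing past the last check: last flight incomplete
  open_end <- segment_flights(make_ddcatch(c(0, 1, 6, 1, 0, 2, 7, 8)))
  expect_false(open_end$complete[nrow(open_end)])
})

test_that("boundary placement is invariant to uniform catch rescaling", {
  set.seed(23)
  x <- seq_len(45)
  y <- 8 * exp(-(x - 12)^2 / 18) + 10 * exp(-(x - 32)^2 / 18) +
    abs(rnorm(45, 0, 0.2))
  a <- segment_flights(make_ddcatch(y))
  b <- segment_flights(make_ddcatch(y * 37.5))
  expect_equal(a$dd_start, b$dd_start)
  expect_equal(a$dd_end, b$dd_end)
})

test_that("reconcile_across_years imputes missing boundaries at the median DD", {
  mk_year <- function(two_flights, year) {
    y <- if (two_flights) c(0, 2, 8, 3, 0.5, 1, 4, 9, 2, 0)
         else c(0, 2, 8, 6, 5, 5.5, 6, 9, 2, 0)     # overlap: no minimum
    make_ddcatch(y, dd = 10 * seq_along(y), year = year)
  }
  segs <- lapply(1:5, function(i) segment_flights(mk_year(i < 5, 2014 + i)))
  expect_equal(nrow(segs[[5]]), 1L)                 # merged flights
  rec <- reconcile_across_years(segs)
  expect_equal(nrow(rec[[5]]), 2L)
  expect_true(any(rec[[5]]$imputed_boundary))
  # imputed at the median boundary DD of the other years (all at 50)
  expect_equal(rec[[5]]$dd_end[1], 50)
  # years with a clear boundary are untouched
  expect_equal(rec[[1]]$dd_end, segs[[1]]$dd_end)
  expect_false(any(rec[[1]]$imputed_boundary))

  # boundary missing in all years: unresolved
  flat <- lapply(1:3, function(i) segment_flights(
    make_ddcatch(c(0, 1, 5, 1, 0), year = 2014 + i)))
  expect_warning(un <- reconcile_across_years(flat), "unresolved")
  expect_true(attr(un, "unresolved"))
})

test_that("duration_table keeps only complete flights and maps provinces", {
  s1 <- segment_flights(make_ddcatch(
    c(0, 1, 6, 1, 0.5, 2, 7, 1, 0, 1, 8, 1, 0, 2, 9, 1, 0),
    dd = 10 * 1:17, area = "AE", year = 2018L))
  expect_equal(nrow(s1), 4L)
  tab <- duration_table(list(s1), c(AE = "Girona"))
  expect_equal(nrow(tab), 4L)
  expect_equal(unique(tab$province), "Girona")

  # descending opening: flight 1 excluded from the table
  s2 <- segment_flights(make_ddcatch(c(6, 3, 1, 0, 2, 7, 1, 0),
                                     area = "ST", year = 2019L))
  tab2 <- duration_table(list(s2), c(ST = "Lleida"))
  expect_false(1L %in% tab2$flight_order)
})

test_that("segment durations within a year sum to the full observed span", {
  r <- recover_scenario("lleida_like", seed = 4)
  segs <- r$segments
  expect_equal(sum(segs$duration_dd),
               segs$dd_end[nrow(segs)] - segs$dd_start[1])
})

test_that("increasing kernel overlap merges flights (degradation)", {
  n_flights <- function(sd_dd) {
    sc <- scenario_preset("lleida_like", seed = 12)
    sc$population$flight_sd_dd <- sd_dd
    dds <- accumulate_dd(generate_weather(sc$climate))
    sim <- generate_catches(sc$population, dds)
    nrow(segment_flights(to_dd_axis(sim$catches, dds)))
  }
  tight <- n_flights(80)
  loose <- n_flights(260)
  expect_equal(tight, 5L)
  expect_lt(loose, tight)
})
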