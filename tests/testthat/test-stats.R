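test_that("jackknife SE of the mean equals s/sqrt(n) exactly", {
  expect_equal(jackknife_se(c(1, 2, 3, 4, 5)), sqrt(2.5 / 5))  # 0.7071...
  expect_equal(jackknife_se(rep(4.2, 10)), 0)
  set.seed(8)
  for (i in 1:100) {
    x <- rnorm(sample(2:40, 1), sd = runif(1, 0.1, 50))
    expect_equal(jackknife_se(x), sd(x) / sqrt(length(x)),
                 tolerance = 1e-12)
  }
  expect_error(jackknife_se(1), class = "ddphen_insufficient_data")
})

test_that("jackknife matches direct leave-one-out for a non-linear statistic", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  loo <- vapply(seq_along(x), function(i) median(x[-i]), numeric(1))
  expect_equal(jackknife_se(x, statistic = median),
               sqrt(7 / 8 * sum((loo - mean(loo))^2)))
})

test_that("balanced one-factor ANOVA equals the brute-force SS oracle", {
  set.seed(21)
  g <- gl(3, 10, labels = c("a", "b", "c"))
  y <- rnorm(30, mean = c(5, 6, 8)[as.integer(g)])
  rec <- data.frame(duration_dd = y, province = g)
  res <- anova_stepwise(rec, factors = "province")
  # oracle: between/within sums of squares from first principles
  gm <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  F_oracle <- (ssb / 2) / (ssw / 27)
  expect_equal(res$table$F[res$table$term == "province"], F_oracle)
  expect_equal(res$table$df_num, 2L)
  expect_equal(res$table$df_den, 27L)
})

test_that("two-level balanced factor: F equals the squared t statistic", {
  set.seed(31)
  y1 <- rnorm(12, 5); y2 <- rnorm(12, 7)
  rec <- data.frame(duration_dd = c(y1, y2),
                    province = rep(c("G", "L"), each = 12))
  res <- anova_stepwise(rec, factors = "province")
  tt <- t.test(y1, y2, var.equal = TRUE)
  expect_equal(res$table$F[1], unname(tt$statistic)^2)
  expect_equal(res$table$p[1], tt$p.value)
})

test_that("stepwise removal keeps a real effect and drops noise factors", {
  set.seed(41)
  n <- 60
  rec <- data.frame(
    duration_dd = rep(c(600, 500), each = n / 2) + rnorm(n, 0, 10),
    province = rep(c("G", "L"), each = n / 2),
    year = sample(2015:2019, n, replace = TRUE),
    flight_order = sample(1:4, n, replace = TRUE))
  res <- suppressWarnings(anova_stepwise(rec,
    factors = c("province", "year", "flight_order")))
  expect_true("province" %in% res$table$term)
  expect_false(any(c("year", "flight_order") %in% res$table$term))
  expect_true(all(res$table$p < 0.05))
  expect_true(all(res$removed$p_at_removal >= 0.05, na.rm = TRUE))
})

test_that("under the null, all factors are removed at roughly rate alpha", {
  set.seed(51)
  kept <- replicate(40, {
    rec <- data.frame(duration_dd = rnorm(40, 550, 30),
                      province = rep(c("G", "L"), 20),
                      flight_order = rep(1:4, each = 10))
    res <- suppressWarnings(anova_stepwise(
      rec, factors = c("province", "flight_order")))
    nrow(res$table) > 0
  })
  # familywise retention under the null stays near the nominal level
  expect_lt(mean(kept), 0.3)
})

test_that("fully confounded factors are flagged, with an error on request", {
  rec <- data.frame(duration_dd = rnorm(20, 550, 10),
                    province = rep(c("G", "L"), each = 10),
                    twin = rep(c("g", "l"), each = 10))   # alias of province
  expect_error(
    suppressWarnings(anova_stepwise(rec, factors = c("province", "twin"),
                                    on_alias = "error")),
    class = "ddphen_aliased")
  res <- suppressWarnings(anova_stepwise(rec,
                                         factors = c("province", "twin")))
  expect_true("twin" %in% res$aliased || "province:twin" %in% res$aliased)
})

test_that("province effect at field-like magnitudes is detected with high power", {
  set.seed(61)
  hits <- replicate(40, {
    rec <- data.frame(
      duration_dd = c(rnorm(40, 625.6, 45), rnorm(60, 528.1, 45)),
      province = rep(c("Girona", "Lleida"), c(40, 60)))
    res <- anova_stepwise(rec, factors = "province")
    "province" %in% res$table$term
  })
  expect_gt(mean(hits), 0.9)
})

test_that("two-group Tukey equals the pooled two-sample t-test", {
  set.seed(71)
  rec <- data.frame(duration_dd = c(rnorm(10, 500, 20), rnorm(12, 540, 20)),
                    province = "L", flight_order = rep(1:2, c(10, 12)))
  tg <- tukey_by_province(rec, "L")
  p_t <- t.test(duration_dd ~ flight_order, data = rec,
                var.equal = TRUE)$p.value
  expect_lt(abs(attr(tg, "pairwise")[1, 2] - p_t), 1e-8)
})

test_that("compact letter display separates shifted groups only", {
  set.seed(81)
  rec <- data.frame(
    duration_dd = c(rnorm(12, 500, 5), rnorm(12, 502, 5), rnorm(12, 700, 5)),
    province = "G", flight_order = rep(1:3, each = 12))
  tg <- tukey_by_province(rec, "G")
  expect_equal(tg$letters[1], tg$letters[2])       # indistinguishable pair
  expect_false(tg$letters[3] %in% tg$letters[1:2]) # shifted group separate

  same <- data.frame(duration_dd = rnorm(30, 600, 1e-3) + 600,
                     province = "G", flight_order = rep(1:3, each = 10))
  tg2 <- tukey_by_province(same, "G")
  expect_equal(length(unique(tg2$letters)), 1L)    # all share one letter
})

test_that("flight orders with fewer than two observations are excluded", {
  rec <- data.frame(duration_dd = c(rnorm(10, 500, 10), 650),
                    province = "G", flight_order = rep(c(1, 2, 9),
                                                       c(5, 5, 1)))
  expect_warning(tg <- tukey_by_province(rec, "G"), "excluded")
  expect_false("9" %in% tg$flight_order)
})
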