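mk_series <- function(values, start = as.Date("2024-01-01")) {
  tibble::tibble(date = start + seq_along(values) - 1L, value = values)
}

test_that("decomposition preserves constants and straight lines exactly", {
  const <- extract_trend(rep(42, 28))
  expect_equal(const$trend, rep(42, 28))
  expect_equal(const$seasonal, rep(0, 28))
  t <- 1:35
  line <- extract_trend(100 + 3 * t)
  expect_equal(line$trend, 100 + 3 * t, tolerance = 1e-9)
})

test_that("decomposition removes weekly seasonality and recovers the trend line", {
  t <- 1:56
  y <- 500 + 2 * t + 80 * sin(2 * pi * t / 7)
  dec <- extract_trend(y, period = 7)
  expect_lt(max(abs(dec$trend - (500 + 2 * t))), 1.0)
  expect_lt(abs(mean(dec$remainder)), 1e-8)
  expect_error(extract_trend(rep(1, 10), period = 7), "at least 14")
  expect_error(extract_trend(c(rep(1, 20), NA)), "NA")
})

test_that("piecewise fit recovers single lines and exact breakpoints", {
  t <- 1:40
  one <- fit_piecewise_segments(5 + 2.5 * t, max_segments = 1)
  expect_equal(nrow(one), 1L)
  expect_equal(one$slope, 2.5, tolerance = 1e-10)
  flat <- fit_piecewise_segments(rep(7, 30), max_segments = 3)
  expect_true(all(abs(flat$slope) < 1e-10))
  # +10/day then -10/day: breakpoint within a day of the kink
  y <- c(10 * (1:30), 300 - 10 * (1:30))
  segs <- fit_piecewise_segments(y, max_segments = 2, penalty = 0)
  expect_equal(nrow(segs), 2L)
  expect_lte(abs(segs$start[2] - 31), 1)
  expect_equal(segs$slope[1], 10, tolerance = 0.2)
  expect_equal(segs$slope[2], -10, tolerance = 0.2)
  expect_error(fit_piecewise_segments(y, max_segments = 0), ">= 1")
})

test_that("dynamic programme attains the brute-force SSE minimum", {
  set.seed(11)
  for (case in 1:6) {
    n <- sample(12:40, 1)
    y <- cumsum(rnorm(n)) + rnorm(n)
    for (k in 1:3) {
      segs <- fit_piecewise_segments(y, max_segments = k, penalty = 0)
      got <- sum(segs$sse)
      expect_equal(nrow(segs), k)
      expect_equal(got, bf_piecewise_sse(y, k), tolerance = 1e-7)
    }
  }
})

test_that("segment fits are shift-invariant and scale-equivariant", {
  set.seed(3)
  y <- 50 + cumsum(rnorm(30))
  base <- fit_piecewise_segments(y, 2, penalty = 0)
  shifted <- fit_piecewise_segments(y + 1000, 2, penalty = 0)
  scaled <- fit_piecewise_segments(y * 3, 2, penalty = 0)
  expect_equal(shifted$slope, base$slope, tolerance = 1e-8)
  expect_equal(shifted$start, base$start)
  expect_equal(scaled$slope, 3 * base$slope, tolerance = 1e-8)
})

test_that("slopes classify into the four types by magnitude and harm direction", {
  cfg <- detector_config("steps", min_slope = 100, max_slope = 2000,
                         harm_direction = "descending_is_harmful")
  expect_equal(as.character(classify_slope(0, cfg)), "no_risk")
  expect_equal(as.character(classify_slope(-300, cfg)), "descending_unhealthy")
  expect_equal(as.character(classify_slope(-5000, cfg)), "ignored_too_steep")
  expect_equal(as.character(classify_slope(300, cfg)), "no_risk")
  up <- detector_config("sedentary", harm_direction = "ascending_is_harmful")
  expect_equal(as.character(classify_slope(300, up)), "ascending_unhealthy")
})

test_that("the reference point is the start of the latest unhealthy segment", {
  segs <- tibble::tibble(start = c(1L, 20L, 40L), end = c(19L, 39L, 60L),
                         slope = c(0, -300, -250), intercept = 0, sse = 0)
  cls <- factor(c("no_risk", "descending_unhealthy", "descending_unhealthy"),
                levels = c("ascending_unhealthy", "descending_unhealthy",
                           "ignored_too_steep", "no_risk"))
  expect_equal(find_reference_point(segs, cls), 40L)
  dates <- as.Date("2024-01-01") + 0:59
  expect_equal(find_reference_point(segs, cls, dates), dates[40])
  all_ok <- factor(rep("no_risk", 3), levels = levels(cls))
  expect_true(is.na(find_reference_point(segs, all_ok)))
})

test_that("forecasting extrapolates the final segment's line exactly", {
  t <- 1:30
  segs <- fit_piecewise_segments(10 + 2 * t, max_segments = 1)
  expect_equal(forecast_values(segs, 30, 5), 10 + 2 * (31:35),
               tolerance = 1e-9)
  segs_c <- fit_piecewise_segments(rep(5, 30), max_segments = 1)
  expect_equal(forecast_values(segs_c, 30, 3), rep(5, 3), tolerance = 1e-9)
  # two-piece trend: only the final segment matters
  y <- c(rep(100, 30), 100 - 4 * (1:30))
  segs2 <- fit_piecewise_segments(y, max_segments = 2, penalty = 0)
  last <- segs2[2, ]
  expect_equal(forecast_values(segs2, 60, 4),
               last$intercept + last$slope * (61:64), tolerance = 1e-9)
  expect_error(forecast_values(segs2, 10, 4), "inside")
})

test_that("a flat healthy series yields no_risk and no reference point", {
  set.seed(21)
  res <- detect_risk(mk_series(pmax(8000 + rnorm(60, 0, 800), 0)))
  expect_s3_class(res, "risk_detection")
  expect_equal(res$verdict, "no_risk")
  expect_true(is.na(res$reference_point))
  expect_null(res$forecast)
})

test_that("an injected decline is detected near its changepoint and confirmed by forecast", {
  set.seed(31)
  t <- 1:60
  y <- pmax(8000 - pmax(0, t - 30) * 250 + rnorm(60, 0, 800), 0)
  res <- detect_risk(mk_series(y))
  expect_true(res$verdict %in% c("unhealthy_trend_confirmed_by_forecast",
                                 "unhealthy_trend_not_confirmed"))
  ref_day <- as.integer(res$reference_point - as.Date("2024-01-01")) + 1L
  expect_lte(abs(ref_day - 30), 2)
  expect_equal(nrow(res$forecast), 7L)
  # decline continues into the forecast window
  expect_equal(res$verdict, "unhealthy_trend_confirmed_by_forecast")
  expect_lt(res$forecast$value[7], res$forecast$value[1])
})

test_that("a single-day dropout to zero is rejected as a too-steep artifact", {
  y <- rep(8000, 60)
  y[30] <- 0
  res <- detect_risk(mk_series(y))
  expect_true("ignored_too_steep" %in% as.character(res$segments$class))
  expect_equal(res$verdict, "no_risk")
})

test_that("detection is deterministic and tolerant of short gaps", {
  set.seed(41)
  y <- pmax(8000 + rnorm(60, 0, 500), 0)
  y[c(15, 16)] <- NA # 2-day gap: interpolated
  r1 <- detect_risk(mk_series(y))
  r2 <- detect_risk(mk_series(y))
  expect_identical(tidy(r1), tidy(r2))
  expect_equal(nrow(r1$data), 60L)
  # a long gap splits the series; only the recent run is analysed
  y2 <- y
  y2[20:26] <- NA
  r3 <- detect_risk(mk_series(y2))
  expect_equal(nrow(r3$data), 34L)
  expect_equal(r3$data$date[1], as.Date("2024-01-01") + 26)
})

test_that("tidy, glance and autoplot expose the detection results", {
  set.seed(51)
  res <- detect_risk(mk_series(pmax(8000 + rnorm(60, 0, 500), 0)))
  td <- tidy(res)
  expect_true(all(c("segment", "start", "end", "slope", "class") %in% names(td)))
  g <- glance(res)
  expect_equal(g$n_days, 60L)
  expect_equal(g$verdict, res$verdict)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})
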