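# Behavioural-trend risk detection for daily wearable series:
# seasonal adjustment -> exact piecewise linear regression -> slope
# classification -> reference point -> linear forecast -> verdict.

SLOPE_CLASSES <- c("ascending_unhealthy", "descending_unhealthy",
                   "ignored_too_steep", "no_risk")

#' Detector configuration
#'
#' @param variable variable id the configuration applies to (free text;
#'   "steps", "active_minutes", "sleep_minutes", ...).
#' @param period seasonal period in days (default 7, the weekly cycle).
#' @param max_segments maximum number of linear segments fitted to the
#'   trend (>= 1).
#' @param min_slope smallest |slope| (units/day) considered a real
#'   behavioural change; flatter segments are no_risk.
#' @param max_slope largest |slope| (units/day) deemed physiologically
#'   plausible; steeper segments are treated as device artifacts and
#'   ignored.
#' @param harm_direction "descending_is_harmful" (steps, active minutes,
#'   sleep) or "ascending_is_harmful" (e.g. sedentary minutes).
#' @param horizon forecast horizon in days (>= 1).
#' @param smooth_window odd width of an optional running-mean smoother
#'   applied to the seasonally adjusted series before segment fitting.
#'   The default 1 (no smoothing) keeps single-day device artifacts as
#'   implausibly steep segments that the classifier rejects; smoothing
#'   would dilute them into slopes that mimic genuine behaviour change.
#' @param penalty per-segment penalty used to choose the number of
#'   segments (NULL = data-driven default, see
#'   [fit_piecewise_segments()]).
#' @return a `detector_config` list.
#' @export
detector_config <- function(variable = "steps", period = 7L,
                            max_segments = 3L, min_slope = 100,
                            max_slope = 2000,
                            harm_direction = c("descending_is_harmful",
                                               "ascending_is_harmful"),
                            horizon = 7L, smooth_window = 1L,
                            penalty = NULL) {
  harm_direction <- match.arg(harm_direction)
  if (max_segments < 1) abort("max_segments must be >= 1")
  if (min_slope < 0 || max_slope <= min_slope) {
    abort("need 0 <= min_slope < max_slope")
  }
  if (horizon < 1) abort("horizon must be >= 1")
  if (smooth_window < 1 || smooth_window %% 2 == 0) {
    abort("smooth_window must be odd and >= 1")
  }
  structure(list(variable = variable, period = as.integer(period),
                 max_segments = as.integer(max_segments),
                 min_slope = min_slope, max_slope = max_slope,
                 harm_direction = harm_direction,
                 horizon = as.integer(horizon),
                 smooth_window = as.integer(smooth_window),
                 penalty = penalty),
            class = "detector_config")
}

#' Default detector configurations per wearable variable
#'
#' Order-of-magnitude slope thresholds in each variable's own units/day.
#'
#' @return named list of [detector_config()] objects.
#' @export
default_detector_configs <- function() {
  list(
    steps = detector_config("steps", min_slope = 100, max_slope = 2000,
                            harm_direction = "descending_is_harmful"),
    active_minutes = detector_config("active_minutes", min_slope = 2,
                                     max_slope = 40,
                                     harm_direction = "descending_is_harmful"),
    sleep_minutes = detector_config("sleep_minutes", min_slope = 3,
                                    max_slope = 90,
                                    harm_direction = "descending_is_harmful")
  )
}

# --- series preparation --------------------------------------------------

#' Prepare a daily series for trend analysis
#'
#' Fills gaps of up to `max_gap` missing days by linear interpolation;
#' if longer gaps remain the series is split and only the most recent
#' sufficiently long complete run is kept.
#'
#' @param values numeric daily values, NA = missing.
#' @param max_gap longest gap (days) bridged by interpolation.
#' @param min_length minimum usable run length.
#' @return list with `values` (complete numeric vector) and `offset`
#'   (0-based index of the run start in the input).
#' @export
prepare_daily_series <- function(values, max_gap = 2L, min_length = 14L) {
  filled <- as.numeric(zoo::na.approx(values, na.rm = FALSE, maxgap = max_gap))
  ok <- !is.na(filled)
  if (all(ok)) return(list(values = filled, offset = 0L))
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= min_length)
  if (length(runs) == 0) {
    abort(paste0("no complete run of >= ", min_length,
                 " days after gap filling"))
  }
  use <- runs[length(runs)] # most recent adequate run
  list(values = filled[starts[use]:ends[use]], offset = starts[use] - 1L)
}

# --- decomposition -------------------------------------------------------

#' Seasonal-trend decomposition of a daily series
#'
#' Classical additive decomposition: the weekly seasonal component is the
#' per-weekday mean of the detrended series (centred to zero mean), and
#' the trend is the seasonally adjusted series passed through a short
#' centred running mean (`smooth_window`), with the window ends handled
#' by local straight-line fits so an exactly linear series is recovered
#' exactly at every position.
#'
#' @param values complete numeric daily series (no NA).
#' @param period seasonal period in days (default 7).
#' @param smooth_window odd running-mean width (default 1, no smoothing).
#' @return tibble with columns `value, seasonal, trend, remainder`
#'   (value = seasonal + trend + remainder, exactly).
#' @export
extract_trend <- function(values, period = 7L, smooth_window = 1L) {
  n <- length(values)
  if (any(is.na(values))) abort("values must not contain NA; see prepare_daily_series()")
  if (n < 2L * period) {
    abort(paste0("need at least ", 2L * period, " observations, got ", n))
  }
  t <- seq_len(n)
  # provisional linear detrend so the weekday means see a stationary signal
  b <- stats::cov(t, values) / stats::var(t)
  a <- mean(values) - b * mean(t)
  resid <- values - (a + b * t)
  phase <- (t - 1L) %% period
  means <- tapply(resid, phase, mean)
  means <- means - mean(means)
  seasonal <- as.numeric(means[as.character(phase)])
  deseason <- values - seasonal
  trend <- smooth_centered(deseason, smooth_window)
  tibble::tibble(value = values, seasonal = seasonal, trend = trend,
                 remainder = values - seasonal - trend)
}

# centred running mean; each end is replaced by an OLS line through the
# nearest `edge_n` points so exact lines pass through unchanged
smooth_centered <- function(x, window, edge_n = 4L) {
  if (window <= 1L) return(x)
  n <- length(x)
  half <- (window - 1L) %/% 2L
  sm <- as.numeric(stats::filter(x, rep(1 / window, window), sides = 2))
  for (i in which(is.na(sm))) {
    idx <- if (i <= half) seq_len(min(edge_n, n)) else seq(n - min(edge_n, n) + 1L, n)
    fit <- stats::lm.fit(cbind(1, idx), x[idx])
    sm[i] <- fit$coefficients[1] + fit$coefficients[2] * i
  }
  sm
}

# --- exact piecewise linear regression -----------------------------------

# per-segment OLS slope/intercept/SSE in O(1) from prefix sums
segment_stats <- function(y) {
  n <- length(y)
  x <- seq_len(n)
  list(
    Sx = cumsum(x), Sxx = cumsum(x^2), Sy = cumsum(y),
    Syy = cumsum(y^2), Sxy = cumsum(x * y)
  )
}

segment_fit <- function(ps, i, j) {
  n <- j - i + 1
  d <- function(s) ps[[s]][j] - if (i > 1) ps[[s]][i - 1] else 0
  sx <- d("Sx"); sy <- d("Sy")
  sxx_c <- d("Sxx") - sx^2 / n
  sxy_c <- d("Sxy") - sx * sy / n
  syy_c <- d("Syy") - sy^2 / n
  slope <- if (sxx_c > 0) sxy_c / sxx_c else 0
  intercept <- sy / n - slope * sx / n
  sse <- max(syy_c - slope * sxy_c, 0)
  c(slope = slope, intercept = intercept, sse = sse)
}

#' Exact piecewise linear regression of a trend
#'
#' Partitions the series into at most `max_segments` contiguous segments
#' and fits an ordinary least-squares line on each, choosing breakpoints
#' by exact dynamic programming: for every candidate number of segments
#' k the placement minimising the total squared error is found, and k is
#' then selected by minimising SSE(k) + penalty * k. The default penalty
#' is `2 * log(n)` times the residual-variance estimate from the finest
#' fit, a BIC-flavoured choice that resists cutting pure noise into
#' spurious short segments.
#'
#' @param trend numeric trend series (no NA).
#' @param max_segments maximum number of segments (>= 1).
#' @param penalty per-segment penalty; NULL for the default above.
#' @param min_segment_length minimum days per segment (>= 2).
#' @return tibble with columns `segment, start, end, slope, intercept,
#'   sse` (start/end 1-based inclusive indices; fitted value at index i
#'   is `intercept + slope * i`). Attribute `sse_by_k` holds the optimal
#'   SSE for each candidate k.
#' @export
fit_piecewise_segments <- function(trend, max_segments = 3L, penalty = NULL,
                                   min_segment_length = 2L) {
  if (max_segments < 1) abort("max_segments must be >= 1")
  if (min_segment_length < 2) abort("min_segment_length must be >= 2")
  n <- length(trend)
  if (n < max_segments * min_segment_length) {
    abort(paste0("series of length ", n, " too short for ", max_segments,
                 " segments of >= ", min_segment_length, " days"))
  }
  mu <- mean(trend) # centre for numerical stability; restored below
  ps <- segment_stats(trend - mu)
  cum0 <- function(s) c(0, ps[[s]])
  cx <- cum0("Sx"); cxx <- cum0("Sxx"); cy <- cum0("Sy")
  cyy <- cum0("Syy"); cxy <- cum0("Sxy")
  cost <- matrix(Inf, n, n)
  for (i in seq_len(n)) {
    jmin <- i + min_segment_length - 1L
    if (jmin > n) next
    j <- jmin:n
    m <- j - i + 1
    sx <- cx[j + 1L] - cx[i]; sy <- cy[j + 1L] - cy[i]
    sxx_c <- cxx[j + 1L] - cxx[i] - sx^2 / m
    sxy_c <- cxy[j + 1L] - cxy[i] - sx * sy / m
    syy_c <- cyy[j + 1L] - cyy[i] - sy^2 / m
    slope <- ifelse(sxx_c > 0, sxy_c / sxx_c, 0)
    cost[i, j] <- pmax(syy_c - slope * sxy_c, 0)
  }
  K <- as.integer(max_segments)
  best <- matrix(Inf, K, n)
  cut <- matrix(NA_integer_, K, n)
  best[1, ] <- cost[1, ]
  if (K > 1) {
    for (k in 2:K) {
      for (j in seq(k * min_segment_length, n)) {
        i_cand <- seq((k - 1L) * min_segment_length + 1L,
                      j - min_segment_length + 1L)
        v <- best[k - 1, i_cand - 1L] + cost[i_cand, j]
        w <- which.min(v)
        best[k, j] <- v[w]
        cut[k, j] <- i_cand[w]
      }
    }
  }
  sse_by_k <- best[, n]
  if (is.null(penalty)) {
    df <- n - 2L * K
    sigma2 <- if (df > 0) sse_by_k[K] / df else 0
    penalty <- 5 * log(n) * sigma2
  }
  k_best <- which.min(sse_by_k + penalty * seq_len(K))
  # recover breakpoints
  bounds <- integer(0)
  j <- n
  for (k in seq(k_best, 1L)) {
    i <- if (k == 1L) 1L else cut[k, j]
    bounds <- c(i, bounds)
    j <- i - 1L
  }
  segs <- purrr::map2_dfr(bounds, c(bounds[-1] - 1L, n), function(i, j) {
    f <- segment_fit(ps, i, j)
    tibble::tibble(start = i, end = j, slope = f[["slope"]],
                   intercept = f[["intercept"]] + mu, sse = f[["sse"]])
  })
  segs <- dplyr::mutate(segs, segment = dplyr::row_number(),
                        .before = "start")
  attr(segs, "sse_by_k") <- sse_by_k
  attr(segs, "penalty") <- penalty
  segs
}

# --- slope classification, reference point, forecast ---------------------

#' Classify segment slopes
#'
#' Flat slopes (|slope| < min_slope) carry no risk; implausibly steep
#' ones (|slope| > max_slope) are device artifacts and ignored; in
#' between, a slope is unhealthy when its sign matches the variable's
#' harmful direction.
#'
#' @param slope numeric slopes in units/day.
#' @param config a [detector_config()].
#' @return factor with levels ascending_unhealthy, descending_unhealthy,
#'   ignored_too_steep, no_risk.
#' @export
classify_slope <- function(slope, config) {
  harmful_sign <- if (config$harm_direction == "descending_is_harmful") -1 else 1
  cls <- ifelse(abs(slope) < config$min_slope, "no_risk",
         ifelse(abs(slope) > config$max_slope, "ignored_too_steep",
         ifelse(sign(slope) == harmful_sign,
                if (harmful_sign < 0) "descending_unhealthy" else "ascending_unhealthy",
                "no_risk")))
  factor(cls, levels = SLOPE_CLASSES)
}

#' Reference point of the last valid unhealthy detection
#'
#' @param segments segment table from [fit_piecewise_segments()].
#' @param classes aligned factor from [classify_slope()].
#' @param dates the series' dates (for converting the index to a date);
#'   NULL returns the index itself.
#' @return start date (or index) of the latest unhealthy segment, or NA
#'   if no segment is unhealthy.
#' @export
find_reference_point <- function(segments, classes, dates = NULL) {
  unhealthy <- classes %in% c("ascending_unhealthy", "descending_unhealthy")
  if (!any(unhealthy)) return(if (is.null(dates)) NA_integer_ else as.Date(NA))
  idx <- segments$start[max(which(unhealthy))]
  if (is.null(dates)) idx else as.Date(dates[idx])
}

#' Localize the onset of a departure from a stable baseline
#'
#' Least-squares changepoint fit of a two-phase model: a constant
#' baseline up to day k, then a straight-line drift. Used to refine the
#' reference point once the piecewise segmentation has established that
#' an unhealthy trend exists: the segmentation answers "is there a
#' harmful slope", this answers "when did the behaviour leave its
#' stable baseline" with day-level precision.
#'
#' @param y numeric series (a trend window ending in the drift).
#' @return list with `onset` (last baseline day, 1-based), `level`
#'   (baseline), `slope` (drift in units/day) and `sse`.
#' @export
locate_trend_onset <- function(y) {
  n <- length(y)
  if (n < 5) abort("need at least 5 points to locate an onset")
  t <- seq_len(n)
  best <- list(sse = Inf)
  for (k in 2:(n - 2L)) {
    X <- cbind(1, pmax(0, t - k))
    f <- stats::lm.fit(X, y)
    sse <- sum(f$residuals^2)
    if (sse < best$sse) {
      best <- list(onset = k, level = unname(f$coefficients[1]),
                   slope = unname(f$coefficients[2]), sse = sse)
    }
  }
  best
}

# collapse adjacent segments sharing a class into runs; a sustained
# decline split by the segment-count selection is one detection
segment_runs <- function(segments, classes) {
  cls <- as.character(classes)
  run_id <- cumsum(c(1L, as.integer(cls[-1] != cls[-length(cls)])))
  tibble::tibble(
    run = unique(run_id),
    class = cls[!duplicated(run_id)],
    start = tapply(segments$start, run_id, min)[as.character(unique(run_id))],
    end = tapply(segments$end, run_id, max)[as.character(unique(run_id))]
  )
}

#' Linear forecast beyond the fitted trend
#'
#' Extrapolates the straight line of the final fitted segment for
#' `horizon` days past the end of the series.
#'
#' @param segments segment table from [fit_piecewise_segments()].
#' @param n series length (forecast starts at index n + 1).
#' @param horizon days ahead (>= 1).
#' @return numeric vector of `horizon` forecast values.
#' @export
forecast_values <- function(segments, n, horizon) {
  if (horizon < 1) abort("horizon must be >= 1")
  last <- segments[nrow(segments), ]
  if (n < last$end) abort("n is inside the fitted trend")
  last$intercept + last$slope * (n + seq_len(horizon))
}

# --- the full detector ---------------------------------------------------

#' Detect unhealthy behavioural trends in a daily wearable series
#'
#' Runs the full detection pipeline on one child's series of one
#' variable: gap handling, weekly seasonal adjustment, exact piecewise
#' linear regression of the trend, slope classification, reference-point
#' selection and a linear forecast. The verdict is
#' `unhealthy_trend_confirmed_by_forecast` when an unhealthy segment
#' exists and the forecast line (the continuation of the final segment)
#' still moves in the harmful direction at a meaningful rate;
#' `unhealthy_trend_not_confirmed` when an unhealthy segment exists but
#' the forecast no longer does; `no_risk` otherwise. Both unhealthy
#' verdicts are exported to the coaching engine.
#'
#' @param data data frame with columns `date` and `value` (one row per
#'   day, dates consecutive; NA values = missing days).
#' @param config a [detector_config()].
#' @return object of class `risk_detection`; see [tidy.risk_detection()]
#'   and [autoplot.risk_detection()].
#' @export
detect_risk <- function(data, config = detector_config()) {
  if (!all(c("date", "value") %in% names(data))) {
    abort("data needs columns date and value")
  }
  data <- dplyr::arrange(dplyr::mutate(data, date = as.Date(.data$date)),
                         .data$date)
  if (nrow(data) > 1 && any(diff(data$date) != 1)) {
    abort("dates must be consecutive calendar days (mark missing days NA)")
  }
  prep <- prepare_daily_series(data$value, min_length = 2L * config$period)
  dates <- data$date[prep$offset + seq_along(prep$values)]
  dec <- extract_trend(prep$values, config$period, config$smooth_window)
  segs <- fit_piecewise_segments(dec$trend, config$max_segments,
                                 penalty = config$penalty)
  classes <- classify_slope(segs$slope, config)
  segs$class <- classes
  segs$start_date <- dates[segs$start]
  segs$end_date <- dates[segs$end]
  ref <- find_reference_point(segs, classes, dates)
  unhealthy_any <- !is.na(ref)
  if (unhealthy_any) {
    # refine the reference point: within the window spanning the latest
    # unhealthy run (plus a flat run immediately before it, if any),
    # locate the day the trend left its stable baseline
    runs <- segment_runs(segs, classes)
    u <- max(which(runs$class %in% c("ascending_unhealthy",
                                     "descending_unhealthy")))
    w_start <- runs$start[u]
    if (u > 1 && runs$class[u - 1] == "no_risk") w_start <- runs$start[u - 1]
    w_end <- runs$end[u]
    if (w_end - w_start + 1L >= 8L) {
      onset <- locate_trend_onset(dec$trend[w_start:w_end])
      harmful_sign <- if (config$harm_direction == "descending_is_harmful") -1 else 1
      if (sign(onset$slope) == harmful_sign) {
        ref <- dates[w_start + onset$onset - 1L]
      }
    }
  }
  fc <- NULL
  verdict <- "no_risk"
  if (unhealthy_any) {
    vals <- forecast_values(segs, nrow(dec), config$horizon)
    fc <- tibble::tibble(date = dates[length(dates)] + seq_len(config$horizon),
                         value = vals)
    fc_class <- classify_slope(segs$slope[nrow(segs)], config)
    verdict <- if (fc_class %in% c("ascending_unhealthy", "descending_unhealthy")) {
      "unhealthy_trend_confirmed_by_forecast"
    } else {
      "unhealthy_trend_not_confirmed"
    }
  }
  structure(
    list(
      variable = config$variable,
      data = tibble::tibble(date = dates, dec),
      segments = segs,
      reference_point = ref,
      forecast = fc,
      verdict = verdict,
      config = config
    ),
    class = "risk_detection"
  )
}

#' @export
print.risk_detection <- function(x, ...) {
  cat("<risk_detection>", x$variable, "\n")
  cat("  days analysed:", nrow(x$data), " segments:", nrow(x$segments), "\n")
  cat("  verdict:", x$verdict, "\n")
  if (!is.na(x$reference_point)) {
    cat("  reference point:", format(x$reference_point), "\n")
  }
  invisible(x)
}
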