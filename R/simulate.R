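# Synthetic-cohort simulator: profiles, anthropometry with exact
# classification ground truth, daily wearable series with injected
# changepoints and device artifacts, weekly behaviour values drawn from
# known risk bands, and a simple adherence model for the weekly loop.

#' Simulation configuration
#'
#' Defaults emulate the baseline conditions of a school-based cohort of
#' 9-12 year olds: 58.7% girls, nutritional-status prevalences of 11.7%
#' obesity, 17.1% overweight, 3% thinness and 0.7% severe thinness, and
#' a mean daily step count of 5170. Wearable noise, weekend seasonality,
#' changepoint injection (slope -250 steps/day from a day uniform in
#' 20-40, in 30% of children) and a 1%/day single-day dropout artifact
#' rate complete the generative model.
#'
#' @param n_children cohort size (>= 1).
#' @param seed integer seed; all randomness flows from it.
#' @param n_days length of each wearable series (default 60).
#' @param start_date first monitored day (Date or ISO string).
#' @param status_prevalence named probabilities over the five
#'   nutritional statuses (must sum to 1).
#' @param variables per-variable generative parameters: baseline mean and
#'   between-child sd, daily noise sd, weekly seasonal amplitude and
#'   changepoint slope (units/day).
#' @param changepoint_fraction fraction of children receiving an injected
#'   trend changepoint.
#' @param changepoint_range days between which the changepoint falls.
#' @param artifact_rate per-day probability of a single-day dropout to 0.
#' @param band_probs probabilities that a weekly behaviour value is drawn
#'   from the green / yellow / red band.
#' @param adherence probability a planned mission shifts its target
#'   variable (default 0.74, the completion rate the coaching model is
#'   designed around).
#' @param effects per-variable shift toward the green band applied when a
#'   mission is adhered to, in the variable's weekly units.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_children = 30L, seed = 1L, n_days = 60L,
                              start_date = "2024-01-08",
                              status_prevalence = c(
                                severe_thinness = 0.007, thinness = 0.030,
                                normal = 0.675, overweight = 0.171,
                                obesity = 0.117),
                              variables = list(
                                steps = list(mean = 5170, sd = 1200,
                                             noise_sd = 800, seasonal_amp = 500,
                                             change_slope = -250),
                                active_minutes = list(mean = 35, sd = 12,
                                                      noise_sd = 10,
                                                      seasonal_amp = 5,
                                                      change_slope = -2),
                                sleep_minutes = list(mean = 510, sd = 35,
                                                     noise_sd = 30,
                                                     seasonal_amp = 10,
                                                     change_slope = -5)),
                              changepoint_fraction = 0.3,
                              changepoint_range = c(20L, 40L),
                              artifact_rate = 0.01,
                              band_probs = c(green = 0.40, yellow = 0.35,
                                             red = 0.25),
                              adherence = 0.74,
                              effects = c(steps = 800, active_minutes = 10,
                                          sleep_minutes = 20,
                                          fruit_per_week = 2,
                                          vegetables_per_week = 2,
                                          sweets_per_week = 1.5,
                                          paqc_score = 0.4,
                                          education_score = 0.15)) {
  if (n_children < 1) abort("n_children must be >= 1")
  if (abs(sum(status_prevalence) - 1) > 1e-8) {
    abort("status_prevalence must sum to 1")
  }
  if (any(status_prevalence < 0) || any(band_probs < 0) ||
      abs(sum(band_probs) - 1) > 1e-8) {
    abort("probabilities must be non-negative and band_probs sum to 1")
  }
  if (artifact_rate < 0 || artifact_rate > 1 || adherence < 0 || adherence > 1) {
    abort("rates must be probabilities in [0, 1]")
  }
  if (any(vapply(variables, function(v) v$sd < 0 || v$noise_sd < 0, TRUE))) {
    abort("standard deviations must be >= 0")
  }
  structure(list(n_children = as.integer(n_children), seed = as.integer(seed),
                 n_days = as.integer(n_days),
                 start_date = as.Date(start_date),
                 status_prevalence = status_prevalence[STATUS_LEVELS],
                 variables = variables,
                 changepoint_fraction = changepoint_fraction,
                 changepoint_range = as.integer(changepoint_range),
                 artifact_rate = artifact_rate, band_probs = band_probs,
                 adherence = adherence, effects = effects),
            class = "simulation_config")
}

#' Simulate one child's daily wearable series
#'
#' Baseline + weekly sinusoidal seasonality + piecewise-linear trend (a
#' slope change at `change_day`, if given) + Gaussian noise, clipped at
#' zero, with single-day dropout artifacts. Uses the current RNG state;
#' seed at the caller.
#'
#' @param cfg a [simulation_config()].
#' @param variable one of the configured variable ids.
#' @param baseline child-specific baseline level; NULL draws one from the
#'   variable's between-child distribution.
#' @param change_day day of the injected slope change; NA for none; NULL
#'   draws per `changepoint_fraction` and `changepoint_range`.
#' @return list with `series` (tibble `date, value, clipped, artifact`)
#'   and `changepoint` (day index or NA).
#' @export
simulate_child_series <- function(cfg, variable = "steps", baseline = NULL,
                                  change_day = NULL) {
  v <- cfg$variables[[variable]]
  if (is.null(v)) abort(paste0("no generative parameters for ", variable))
  n <- cfg$n_days
  t <- seq_len(n)
  if (is.null(baseline)) {
    baseline <- max(rnorm(1, v$mean, v$sd), v$mean / 10)
  }
  if (is.null(change_day)) {
    change_day <- if (runif(1) < cfg$changepoint_fraction) {
      sample(seq(cfg$changepoint_range[1], cfg$changepoint_range[2]), 1)
    } else {
      NA_integer_
    }
  }
  mu <- baseline + v$seasonal_amp * sin(2 * pi * t / 7)
  if (!is.na(change_day)) {
    mu <- mu + pmax(0, t - change_day) * v$change_slope
  }
  raw <- mu + rnorm(n, 0, v$noise_sd)
  artifact <- runif(n) < cfg$artifact_rate
  raw[artifact] <- 0
  value <- pmax(raw, 0)
  list(
    series = tibble::tibble(date = cfg$start_date + t - 1L, value = value,
                            clipped = raw < 0, artifact = artifact),
    changepoint = change_day
  )
}

# value ranges used when inverting a stratification rule into bands
variable_ranges <- function() {
  c(steps = 20000, active_minutes = 180, sleep_minutes = 720,
    paqc_score = 5, fruit_per_week = 35, vegetables_per_week = 35,
    sweets_per_week = 21, education_score = 1)
}

#' Draw a value from a chosen risk band of a rule
#'
#' Inverts a stratification rule: given the flag the value should
#' receive, draws uniformly within that band (bounded by the variable's
#' plausible range), so flag ground truth is known by construction.
#'
#' @param rule one-row rule (variable_id, direction, green_yellow,
#'   yellow_red).
#' @param flag "green", "yellow" or "red".
#' @return numeric value; `stratify_variable()` maps it back to `flag`.
#' @export
sample_value_in_band <- function(rule, flag) {
  hi <- unname(variable_ranges()[rule$variable_id])
  if (is.na(hi)) hi <- max(rule$green_yellow, rule$yellow_red) * 3
  gy <- rule$green_yellow; yr <- rule$yellow_red
  eps <- 1e-6 * max(abs(c(gy, yr, 1)))
  lims <- if (rule$direction == "higher_is_worse") {
    switch(flag, green = c(0, gy), yellow = c(gy + eps, yr),
           red = c(yr + eps, hi))
  } else {
    switch(flag, green = c(gy, hi), yellow = c(yr, gy - eps),
           red = c(0, yr - eps))
  }
  runif(1, lims[1], lims[2])
}

#' Simulate a full synthetic cohort
#'
#' Generates child profiles (ages uniform on 9-12 years), anthropometry
#' in z-space through an LMS table (so nutritional-status ground truth is
#' exact), one wearable series per configured variable and child with
#' known changepoints, and first-week behaviour values drawn from known
#' risk bands. Fully deterministic given `cfg$seed`.
#'
#' @param cfg a [simulation_config()].
#' @param lms LMS table (default the bundled synthetic table).
#' @param rules stratification rules used to invert bands.
#' @param include which data blocks to generate besides profiles;
#'   subset of "anthropometrics", "wearable", "weekly_values".
#' @return list of class `synthetic_cohort`: `profiles`,
#'   `anthropometrics`, `wearable` (long tibble), `weekly_values`,
#'   and `ground_truth` (`status`, `changepoints`, `bands`).
#' @export
simulate_cohort <- function(cfg = simulation_config(),
                            lms = synthetic_lms_table(),
                            rules = default_stratification_rules(),
                            include = c("anthropometrics", "wearable",
                                        "weekly_values")) {
  set.seed(cfg$seed)
  n <- cfg$n_children
  ids <- sprintf("c%04d", seq_len(n))
  age_years <- runif(n, 9, 12)
  profiles <- tibble::tibble(
    child_id = ids,
    sex = ifelse(runif(n) < 0.587, "female", "male"),
    birth_date = cfg$start_date - round(age_years * 365.25)
  )
  include <- match.arg(include, several.ok = TRUE)
  # anthropometry in z-space: sample a status, then a z inside its band
  status <- sample(STATUS_LEVELS, n, replace = TRUE,
                   prob = cfg$status_prevalence)
  z <- vapply(status, function(s) {
    switch(s,
           severe_thinness = runif(1, -3.8, -3.02),
           thinness = runif(1, -2.98, -2.02),
           normal = runif(1, -1.98, 0.98),
           overweight = runif(1, 1.02, 1.98),
           obesity = runif(1, 2.02, 3.5))
  }, numeric(1))
  meas_date <- cfg$start_date
  anthropometrics <- NULL
  if ("anthropometrics" %in% include) {
    age_months <- age_in_months(profiles$birth_date, meas_date)
    par <- lms_interpolate(lms, profiles$sex, age_months)
    bmi <- lms_inverse(z, par$L, par$M, par$S)
    height <- pmax(rnorm(n, 1.33 + 0.005 * (age_months - 108), 0.05), 1.05)
    anthropometrics <- tibble::tibble(
      child_id = ids, date = meas_date,
      weight_kg = round(bmi * height^2, 2), height_m = round(height, 3)
    )
  }
  # wearable series with known changepoints
  wearable <- NULL; changepoints <- NULL
  if ("wearable" %in% include) {
    wearable <- list(); changepoints <- list()
    for (v in names(cfg$variables)) {
      for (i in seq_len(n)) {
        sim <- simulate_child_series(cfg, v)
        wearable[[length(wearable) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(child_id = ids[i], variable_id = v), sim$series
        )
        changepoints[[length(changepoints) + 1L]] <- tibble::tibble(
          child_id = ids[i], variable_id = v, change_day = sim$changepoint
        )
      }
    }
    wearable <- dplyr::bind_rows(wearable)
    changepoints <- dplyr::bind_rows(changepoints)
  }
  # first-week behaviour values from known bands
  bands <- NULL
  if ("weekly_values" %in% include) {
    week1 <- iso_week(cfg$start_date)
    bands <- list()
    for (i in seq_len(n)) {
      for (r in seq_len(nrow(rules))) {
        flag <- sample(names(cfg$band_probs), 1, prob = cfg$band_probs)
        bands[[length(bands) + 1L]] <- tibble::tibble(
          child_id = ids[i], week = week1,
          variable_id = rules$variable_id[r],
          value = sample_value_in_band(rules[r, ], flag), true_flag = flag
        )
      }
    }
    bands <- dplyr::bind_rows(bands)
  }
  structure(list(
    profiles = profiles,
    anthropometrics = anthropometrics,
    wearable = wearable,
    weekly_values = if (!is.null(bands)) dplyr::select(bands, -"true_flag"),
    ground_truth = list(
      status = tibble::tibble(child_id = ids, z = z,
                              status = factor(status, STATUS_LEVELS,
                                              ordered = TRUE)),
      changepoints = changepoints,
      bands = bands
    ),
    config = cfg
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", nrow(x$profiles), "children,",
      if (!is.null(x$wearable)) length(unique(x$wearable$variable_id)) else 0,
      "wearable variables,", x$config$n_days, "days\n")
  invisible(x)
}

#' Apply one week of intervention response
#'
#' For every planned mission, a Bernoulli(adherence) draw decides whether
#' the child acts on it; if so the mission's target variable moves toward
#' its green band by the configured effect size. Draws are returned as
#' ground truth.
#'
#' @param weekly_values tibble `child_id, week, variable_id, value` for
#'   the current week.
#' @param plans row-bound coaching plans for that week (one per child).
#' @param behaviours behaviour catalogue (maps missions to variables).
#' @param rules stratification rules (direction of "toward green").
#' @param adherence probability in [0, 1].
#' @param effects named per-variable effect sizes.
#' @return list with `values` (next week's tibble) and `draws`
#'   (`child_id, mission_id, variable_id, adhered`).
#' @export
simulate_intervention_response <- function(weekly_values, plans,
                                           behaviours = default_behaviours(),
                                           rules = default_stratification_rules(),
                                           adherence = 0.74,
                                           effects = simulation_config()$effects) {
  if (adherence < 0 || adherence > 1) abort("adherence must be in [0, 1]")
  nxt <- weekly_values
  nxt$week <- vapply(nxt$week, next_iso_week, character(1))
  draws <- list()
  for (i in seq_len(nrow(plans))) {
    p <- plans[i, ]
    var <- behaviours$variable_id[behaviours$behaviour_id == p$behaviour_id]
    if (length(var) != 1) next
    adhered <- runif(1) < adherence
    draws[[length(draws) + 1L]] <- tibble::tibble(
      child_id = p$child_id, mission_id = p$mission_id,
      variable_id = var, adhered = adhered
    )
    if (!adhered) next
    rule <- rules[rules$variable_id == var, ]
    eff <- unname(effects[var])
    if (is.na(eff) || nrow(rule) != 1) next
    sel <- nxt$child_id == p$child_id & nxt$variable_id == var
    shift <- if (rule$direction == "lower_is_worse") eff else -eff
    nxt$value[sel] <- pmax(nxt$value[sel] + shift, 0)
  }
  list(values = nxt, draws = dplyr::bind_rows(draws))
}

#' Run the weekly assess-plan-respond loop
#'
#' Simulates the closed coaching loop for several weeks: assess each
#' child's flags from the week's behaviour values, generate the coaching
#' plan, apply the adherence model, and carry the shifted values into the
#' next week. Children not adhering keep their values unchanged.
#'
#' @param cohort a [simulate_cohort()] result (supplies week-1 values).
#' @param n_weeks number of assessment weeks (>= 1).
#' @param adherence probability a mission is acted on.
#' @param behaviours,rules,catalogue engine configuration.
#' @param seed integer seed for the adherence draws.
#' @return list with `flags` (tibble `child_id, week, behaviour_id,
#'   dimension, flag`), `plans` (all generated plans) and `draws`.
#' @export
run_intervention_loop <- function(cohort, n_weeks = 8L, adherence = 0.74,
                                  behaviours = default_behaviours(),
                                  rules = default_stratification_rules(),
                                  catalogue = default_mission_catalogue(),
                                  seed = cohort$config$seed + 1L) {
  set.seed(seed)
  values <- cohort$weekly_values
  ids <- unique(values$child_id)
  all_flags <- list(); all_plans <- list(); all_draws <- list()
  history <- list()
  for (w in seq_len(n_weeks)) {
    week <- unique(values$week)
    stopifnot(length(week) == 1)
    plans_w <- list()
    for (id in ids) {
      vals <- values[values$child_id == id, c("variable_id", "value")]
      flags <- assess_weekly_flags(vals, behaviours, rules)
      all_flags[[length(all_flags) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(child_id = id, week = week),
        flags[, c("behaviour_id", "dimension", "flag")]
      )
      hist_id <- dplyr::bind_rows(history[names(history) == id])
      plan <- generate_coaching_plan(id, week, flags, hist_id, catalogue)
      plans_w[[length(plans_w) + 1L]] <- plan
      history[[length(history) + 1L]] <- tibble::tibble(
        behaviour_id = flags$behaviour_id, week = week,
        flag = as.character(flags$flag)
      )
      names(history)[length(history)] <- id
    }
    plans_w <- dplyr::bind_rows(plans_w)
    all_plans[[w]] <- plans_w
    resp <- simulate_intervention_response(values, plans_w, behaviours,
                                           rules, adherence,
                                           cohort$config$effects)
    values <- resp$values
    all_draws[[w]] <- resp$draws
  }
  list(flags = dplyr::bind_rows(all_flags),
       plans = dplyr::bind_rows(all_plans),
       draws = dplyr::bind_rows(all_draws))
}
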