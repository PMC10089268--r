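test_that("a noiseless, artifact-free configuration yields a constant series", {
  cfg <- simulation_config(seed = 1, variables = list(
    steps = list(mean = 6000, sd = 0, noise_sd = 0, seasonal_amp = 0,
                 change_slope = -250)),
    changepoint_fraction = 0, artifact_rate = 0)
  set.seed(1)
  sim <- simulate_child_series(cfg, "steps")
  expect_true(all(sim$series$value == 6000))
  expect_true(is.na(sim$changepoint))
})

test_that("series generation is deterministic under a fixed seed", {
  cfg <- simulation_config(seed = 42)
  set.seed(42); a <- simulate_child_series(cfg, "steps")
  set.seed(42); b <- simulate_child_series(cfg, "steps")
  expect_identical(a, b)
  c1 <- simulate_cohort(simulation_config(n_children = 4, seed = 9))
  c2 <- simulate_cohort(simulation_config(n_children = 4, seed = 9))
  expect_identical(c1$wearable, c2$wearable)
  expect_identical(c1$ground_truth, c2$ground_truth)
})

test_that("the injected slope is recovered by post-change OLS", {
  cfg <- simulation_config(seed = 1)
  slopes <- numeric(60)
  set.seed(123)
  for (r in 1:60) {
    sim <- simulate_child_series(cfg, "steps", baseline = 8000,
                                 change_day = 30)
    post <- sim$series$value[31:60]
    ok <- post > 0 & !sim$series$artifact[31:60]
    t <- (31:60)[ok]
    slopes[r] <- unname(coef(lm(post[ok] ~ t))[2])
  }
  # mean recovered slope within 3 standard errors of -250
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - (-250)), 3 * se + 15)
})

test_that("cohort prevalences match the configured targets at large n", {
  cfg <- simulation_config(n_children = 5000, seed = 202)
  cohort <- simulate_cohort(cfg, include = "anthropometrics")
  lms <- synthetic_lms_table()
  out <- bmi_for_age(cohort$anthropometrics, cohort$profiles, lms)
  prev <- table(out$status) / nrow(out) * 100
  expect_lt(abs(prev[["obesity"]] - 11.7), 1.5)
  expect_lt(abs(prev[["overweight"]] - 17.1), 1.5)
  # rounding weight/height to storage precision never flips a class
  expect_equal(as.character(out$status),
               as.character(cohort$ground_truth$status$status))
  # ages uniform on 9-12 years
  age <- age_in_months(cohort$profiles$birth_date, cfg$start_date) / 12
  expect_gte(min(age), 8.99)
  expect_lte(max(age), 12.01)
  expect_error(simulation_config(n_children = 0), ">= 1")
})

test_that("zero configured obesity prevalence yields no obese children", {
  cfg <- simulation_config(n_children = 300, seed = 7, status_prevalence = c(
    severe_thinness = 0, thinness = 0.05, normal = 0.80,
    overweight = 0.15, obesity = 0))
  cohort <- simulate_cohort(cfg, include = "anthropometrics")
  out <- bmi_for_age(cohort$anthropometrics, cohort$profiles,
                     synthetic_lms_table())
  expect_equal(sum(out$status == "obesity"), 0L)
})

test_that("band-inverted weekly values reproduce their flag ground truth", {
  cohort <- simulate_cohort(simulation_config(n_children = 12, seed = 31),
                            include = "weekly_values")
  rules <- default_stratification_rules()
  gt <- cohort$ground_truth$bands
  flags <- vapply(seq_len(nrow(gt)), function(i) {
    r <- rules[rules$variable_id == gt$variable_id[i], ]
    as.character(stratify_variable(gt$value[i], r$direction,
                                   r$green_yellow, r$yellow_red))
  }, character(1))
  expect_equal(flags, gt$true_flag)
})

test_that("adherence drives the intervention response", {
  cohort <- simulate_cohort(simulation_config(n_children = 6, seed = 8),
                            include = "weekly_values")
  vals <- cohort$weekly_values
  flags1 <- assess_weekly_flags(
    vals[vals$child_id == vals$child_id[1], c("variable_id", "value")])
  plan <- generate_coaching_plan(vals$child_id[1], unique(vals$week), flags1)
  # adherence 0: nothing moves
  set.seed(1)
  r0 <- simulate_intervention_response(vals, plan, adherence = 0)
  expect_equal(r0$values$value, vals$value)
  expect_false(any(r0$draws$adhered))
  # adherence 1 with an effect reaching the green band flips the flag
  vals2 <- tibble::tibble(child_id = "k", week = "2024-W02",
                          variable_id = "fruit_per_week", value = 13)
  flags2 <- assess_weekly_flags(
    vals2[, c("variable_id", "value")],
    default_behaviours()[default_behaviours()$variable_id == "fruit_per_week", ])
  plan2 <- tibble::tibble(child_id = "k", mission_id = 4L,
                          behaviour_id = "D1")
  set.seed(2)
  r1 <- simulate_intervention_response(vals2, plan2, adherence = 1)
  expect_equal(r1$values$value, 15)
  r <- default_stratification_rules()
  r <- r[r$variable_id == "fruit_per_week", ]
  expect_equal(as.character(stratify_variable(r1$values$value, r$direction,
                                              r$green_yellow, r$yellow_red)),
               "green")
})

test_that("the shifted fraction matches the adherence probability", {
  vals <- tibble::tibble(child_id = sprintf("c%04d", 1:1000),
                         week = "2024-W02", variable_id = "steps",
                         value = 5000)
  plans <- tibble::tibble(child_id = vals$child_id, mission_id = 1L,
                          behaviour_id = "P1")
  set.seed(99)
  resp <- simulate_intervention_response(vals, plans, adherence = 0.5)
  frac <- mean(resp$draws$adhered)
  expect_lt(abs(frac - 0.5), 0.05)
  expect_equal(sum(resp$values$value > 5000), sum(resp$draws$adhered))
})

test_that("generated artifacts pass the io validators unchanged", {
  cohort <- simulate_cohort(simulation_config(n_children = 3, seed = 55,
                                              n_days = 21))
  dir <- withr::local_tempdir()
  wide <- tidyr::pivot_wider(
    cohort$wearable[, c("child_id", "date", "variable_id", "value")],
    names_from = "variable_id", values_from = "value")
  write_csv_atomic(wide, file.path(dir, "wearable.csv"))
  back <- read_wearable_csv(file.path(dir, "wearable.csv"))
  expect_equal(nrow(back), nrow(cohort$wearable))
  write_csv_atomic(cohort$anthropometrics, file.path(dir, "anthro.csv"))
  a <- read_anthropometrics_csv(file.path(dir, "anthro.csv"))
  expect_equal(a$weight_kg, cohort$anthropometrics$weight_kg)
  write_csv_atomic(cohort$weekly_values, file.path(dir, "weekly.csv"))
  w <- read_weekly_values_csv(file.path(dir, "weekly.csv"))
  expect_equal(w$value, cohort$weekly_values$value)
})
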