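test_that("weekly assessment flags every behaviour through its rule", {
  vals <- c(steps = 10000, active_minutes = 70, sleep_minutes = 560,
            fruit_per_week = 16, vegetables_per_week = 15,
            sweets_per_week = 1, education_score = 0.9)
  flags <- assess_weekly_flags(vals)
  expect_equal(nrow(flags), nrow(default_behaviours()))
  expect_true(all(flags$flag == "green"))
  # sweets in the red band turns its diet behaviour red
  vals["sweets_per_week"] <- 7
  flags <- assess_weekly_flags(vals)
  expect_equal(as.character(flags$flag[flags$variable_id == "sweets_per_week"]),
               "red")
  expect_true(all(flags$flag[flags$variable_id != "sweets_per_week"] == "green"))
})

test_that("missing variables follow the missing-data policy", {
  vals <- c(steps = 10000) # everything else absent
  expect_warning(flags <- assess_weekly_flags(vals), "missing data")
  expect_true(all(flags$flag[flags$variable_id != "steps"] == "yellow"))
  expect_error(
    suppressWarnings(assess_weekly_flags(vals, missing_policy = "error")),
    "no data"
  )
})

test_that("a red behaviour is prioritised over yellow and green", {
  ids <- c("D1", "D2", "D3")
  cat <- mini_catalogue(ids)
  flags <- mini_flags(ids, c("yellow", "red", "green"))
  pick <- select_mission_for_dimension(flags, NULL, cat, "diet")
  expect_equal(pick$behaviour_id, "D2")
  expect_equal(pick$mission_id, 2L)
})

test_that("ties are broken by the longest run of recent red weeks, then order", {
  ids <- c("D1", "D2", "D3")
  cat <- mini_catalogue(ids)
  flags <- mini_flags(ids, c("red", "red", "red"))
  # D2 red for 2 past weeks, D1 red only longer ago, D3 never
  hist <- mini_history(ids, rbind(c("red", "green", "green"),
                                  c("green", "red", "red"),
                                  c("green", "green", "green")))
  pick <- select_mission_for_dimension(flags, hist, cat, "diet")
  expect_equal(pick$behaviour_id, "D2")
  expect_equal(pick$red_run, 3L)
  # all-green falls back to the configured (row) order
  green <- mini_flags(ids, c("green", "green", "green"))
  pick2 <- select_mission_for_dimension(green, NULL, cat, "diet")
  expect_equal(pick2$behaviour_id, "D1")
  expect_error(select_mission_for_dimension(flags, NULL,
                                            mini_catalogue("X1", "other"),
                                            "diet"),
               "no missions")
})

test_that("selection agrees with the brute-force rule on exhaustive small cases", {
  flag_lv <- c("green", "yellow", "red")
  ids <- c("B1", "B2", "B3")
  cat <- mini_catalogue(ids)
  grid_cur <- expand.grid(f1 = flag_lv, f2 = flag_lv, f3 = flag_lv,
                          stringsAsFactors = FALSE)
  # exhaustive over current flags x 2 past weeks per behaviour
  grid_hist <- expand.grid(h1 = flag_lv, h2 = flag_lv,
                           stringsAsFactors = FALSE)
  set.seed(5)
  hist_idx <- replicate(40, grid_hist[sample(nrow(grid_hist), 3, TRUE), ],
                        simplify = FALSE)
  for (i in seq_len(nrow(grid_cur))) {
    cur <- unlist(grid_cur[i, ])
    for (hm in hist_idx[seq_len(5)]) {
      m <- as.matrix(hm)
      flags <- mini_flags(ids, cur)
      hist <- mini_history(ids, m)
      pick <- select_mission_for_dimension(flags, hist, cat, "diet")
      want <- ids[bf_select_behaviour(cur, split(m, row(m)))]
      expect_equal(pick$behaviour_id, want,
                   info = paste(paste(cur, collapse = ","), "|",
                                paste(t(m), collapse = ",")))
      # red-priority soundness
      if (any(cur == "red")) {
        expect_equal(unname(cur[ids == pick$behaviour_id]), "red")
      }
    }
  }
})

test_that("coaching plans carry exactly one mission per dimension for week T+1", {
  flags <- full_flags(c("red", "green", "yellow", "green", "yellow",
                        "red", "green"))
  plan <- generate_coaching_plan("c1", "2024-W10", flags)
  expect_s3_class(plan, "coaching_plan")
  expect_equal(nrow(plan), 3L)
  expect_setequal(plan$dimension,
                  c("physical_activity_sleep", "diet",
                    "education_empowerment"))
  expect_equal(unique(plan$plan_week), "2024-W11")
  # red behaviours win their dimensions
  expect_equal(plan$behaviour_id[plan$dimension == "physical_activity_sleep"],
               "P1")
  expect_equal(plan$behaviour_id[plan$dimension == "diet"], "D3")
  # determinism
  plan2 <- generate_coaching_plan("c1", "2024-W10", flags)
  expect_identical(tidy(plan), tidy(plan2))
  # all-green child gets three maintenance missions
  plan3 <- generate_coaching_plan("c1", "2024-W10", full_flags("green"))
  expect_equal(nrow(plan3), 3L)
  expect_true(all(plan3$flag == "green"))
  expect_error(generate_coaching_plan("c1", "2024-W10",
                                      flags[flags$dimension != "diet", ]),
               "missing: diet")
})

test_that("mission validation applies feedback, deadlines and educator precedence", {
  asg <- tibble::tibble(mission_id = c(1L, 2L, 3L), child_id = "c1",
                        week = "2024-W11")
  fb <- tibble::tibble(mission_id = c(1L, 2L), child_id = "c1",
                       week = "2024-W11", completed = c(TRUE, FALSE),
                       validated_by = c("family", "educator"))
  out <- validate_missions(asg, fb)
  expect_equal(out$status, c("completed", "not_completed", "pending"))
  expect_equal(out$validated_by, c("family", "educator", "none"))
  # past the deadline, pending becomes not_completed
  late <- validate_missions(asg, fb, as_of_week = "2024-W13")
  expect_equal(late$status[3], "not_completed")
  within <- validate_missions(asg, fb, as_of_week = "2024-W12")
  expect_equal(within$status[3], "pending")
  # conflicting reports: educator wins
  fb2 <- tibble::tibble(mission_id = 1L, child_id = "c1", week = "2024-W11",
                        completed = c(TRUE, FALSE),
                        validated_by = c("family", "educator"))
  expect_message(out2 <- validate_missions(asg[1, ], fb2), "educator")
  expect_equal(out2$status, "not_completed")
  # feedback for an unassigned mission is an error
  fb3 <- tibble::tibble(mission_id = 9L, child_id = "c1", week = "2024-W11",
                        completed = TRUE, validated_by = "family")
  expect_error(validate_missions(asg, fb3), "unassigned")
})

test_that("points and ability percentages are conserved", {
  cat <- tibble::tibble(mission_id = 1:3, dimension = "diet",
                        target_behaviour_id = "D1", description = "x",
                        mode = "individual", points = c(10L, 30L, 5L),
                        ability = c("dexterity", "intelligence", "discipline"))
  none <- validate_missions(tibble::tibble(mission_id = 3L, child_id = "c",
                                           week = "2024-W01"))
  ledger0 <- award_points(none, cat)
  expect_equal(unique(ledger0$total), 0)
  expect_equal(ledger0$pct, c(0, 0, 0))
  out <- tibble::tibble(mission_id = c(1L, 2L), child_id = "c",
                        week = "2024-W01", status = "completed",
                        validated_by = "family")
  ledger <- award_points(out, cat)
  expect_equal(unique(ledger$total), 40)
  expect_equal(ledger$pct[ledger$ability == "dexterity"], 25)
  expect_equal(ledger$pct[ledger$ability == "discipline"], 0)
  expect_equal(ledger$pct[ledger$ability == "intelligence"], 75)
  expect_equal(sum(ledger$pct), 100)
  one <- award_points(out[1, ] |> dplyr::mutate(mission_id = 3L), cat)
  expect_equal(unique(one$total), 5)
  expect_equal(one$pct[one$ability == "discipline"], 100)
})

test_that("motivation messages fire for stalled missions and risk verdicts only", {
  plan <- generate_coaching_plan("c1", "2024-W10", full_flags("yellow"))
  ok <- trigger_motivation(plan,
                           tibble::tibble(mission_id = plan$mission_id,
                                          progressing = TRUE))
  expect_equal(nrow(ok), 0L)
  stalled <- trigger_motivation(plan, tibble::tibble(
    mission_id = plan$mission_id[1], progressing = FALSE))
  expect_equal(nrow(stalled), 1L)
  expect_match(stalled$message, plan$description[1], fixed = TRUE)
  risk <- structure(list(variable = "steps",
                         verdict = "unhealthy_trend_confirmed_by_forecast"),
                    class = "risk_detection")
  msgs <- trigger_motivation(plan, NULL, list(risk))
  expect_equal(nrow(msgs), 1L)
  expect_equal(msgs$dimension, "physical_activity_sleep")
  # idempotent: same inputs, same message set
  expect_identical(msgs, trigger_motivation(plan, NULL, list(risk)))
})

test_that("the weekly agent report has exactly six unique items", {
  tpl <- build_agent_report()
  expect_equal(nrow(tpl), 6L)
  expect_equal(anyDuplicated(tpl$item_id), 0L)
  expect_identical(tpl, build_agent_report())
  bad <- default_agent_report_items()[1:5, ]
  expect_error(build_agent_report(bad), "exactly 6")
  expect_equal(nrow(build_agent_report(bad, strict = FALSE)), 5L)
})
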