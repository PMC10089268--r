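# The DSS proper: weekly behaviour assessment into green/yellow/red
# flags, prioritised mission selection with the red-history tie-break,
# coaching-plan generation, carer validation, points and motivation.

#' Default behaviour catalogue
#'
#' One row per monitored behaviour: its health dimension and the
#' variable whose stratification rule drives its flag. Row order is the
#' configured tie-break order within each dimension.
#'
#' @return tibble with `behaviour_id, label, dimension, variable_id`.
#' @export
default_behaviours <- function() {
  tibble::tribble(
    ~behaviour_id, ~label, ~dimension, ~variable_id,
    "P1", "Increase daily steps", "physical_activity_sleep", "steps",
    "P2", "Increase active minutes", "physical_activity_sleep", "active_minutes",
    "P3", "Increase sleep duration", "physical_activity_sleep", "sleep_minutes",
    "D1", "Increase fruit consumption", "diet", "fruit_per_week",
    "D2", "Increase vegetable consumption", "diet", "vegetables_per_week",
    "D3", "Reduce sweets consumption", "diet", "sweets_per_week",
    "E1", "Improve health knowledge", "education_empowerment", "education_score"
  )
}

#' Default stratification rules
#'
#' Green/yellow/red cut-offs per monitored variable. Cut-offs are
#' configuration, not science fixed in code: real deployments calibrate
#' them against a baseline evaluation of the cohort.
#'
#' @return tibble with `variable_id, direction, green_yellow, yellow_red,
#'   units`.
#' @export
default_stratification_rules <- function() {
  tibble::tribble(
    ~variable_id, ~direction, ~green_yellow, ~yellow_red, ~units,
    "steps", "lower_is_worse", 9000, 6000, "steps/day",
    "active_minutes", "lower_is_worse", 60, 30, "min/day",
    "sleep_minutes", "lower_is_worse", 540, 480, "min/day",
    "paqc_score", "lower_is_worse", 3.5, 2.5, "score",
    "fruit_per_week", "lower_is_worse", 14, 7, "portions/week",
    "vegetables_per_week", "lower_is_worse", 14, 7, "portions/week",
    "sweets_per_week", "higher_is_worse", 2, 5, "portions/week",
    "education_score", "lower_is_worse", 0.8, 0.5, "fraction"
  )
}

#' Default mission catalogue
#'
#' One individual and shared maintenance content per behaviour; points
#' and the developed ability (dexterity, discipline, intelligence) per
#' mission. The ability mapping is configuration with a default of
#' physical activity -> dexterity, diet -> discipline,
#' education -> intelligence.
#'
#' @return tibble with `mission_id, dimension, target_behaviour_id,
#'   description, mode, points, ability`.
#' @export
default_mission_catalogue <- function() {
  b <- default_behaviours()
  ability <- c(physical_activity_sleep = "dexterity", diet = "discipline",
               education_empowerment = "intelligence")
  tibble::tibble(
    mission_id = seq_len(nrow(b)),
    dimension = b$dimension,
    target_behaviour_id = b$behaviour_id,
    description = paste0("Weekly goal: ", tolower(b$label)),
    mode = rep(c("individual", "social"), length.out = nrow(b)),
    points = 10L,
    ability = unname(ability[b$dimension])
  )
}

validate_catalogue <- function(catalogue, behaviours = NULL) {
  req <- c("mission_id", "dimension", "target_behaviour_id", "mode",
           "points", "ability")
  missing <- setdiff(req, names(catalogue))
  if (length(missing) > 0) {
    abort(paste0("mission catalogue missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (any(catalogue$points < 0)) abort("mission points must be >= 0")
  bad <- setdiff(unique(catalogue$ability), ABILITIES)
  if (length(bad) > 0) abort(paste0("unknown ability: ", paste(bad, collapse = ", ")))
  if (!is.null(behaviours)) {
    b <- behaviours[match(catalogue$target_behaviour_id, behaviours$behaviour_id), ]
    off <- !is.na(b$dimension) & b$dimension != catalogue$dimension
    if (any(off)) abort("missions must target behaviours of their own dimension")
  }
  invisible(catalogue)
}

#' Weekly behaviour assessment into flags
#'
#' Resolves every behaviour's source variable from the week's summary
#' values and applies its stratification rule. Behaviours whose variable
#' is absent or NA are handled per the missing-data policy: "yellow"
#' (default; flagged yellow with a warning), "green", "red", or "error".
#'
#' @param values data frame with `variable_id, value` (one row per
#'   variable; weekly summaries), or a named numeric vector.
#' @param behaviours behaviour catalogue, see [default_behaviours()].
#' @param rules stratification rules, see
#'   [default_stratification_rules()].
#' @param missing_policy one of "yellow", "green", "red", "error".
#' @return tibble `behaviour_id, label, dimension, variable_id, value,
#'   flag` (flag is the ordered green/yellow/red factor).
#' @export
assess_weekly_flags <- function(values, behaviours = default_behaviours(),
                                rules = default_stratification_rules(),
                                missing_policy = c("yellow", "green", "red",
                                                   "error")) {
  missing_policy <- match.arg(missing_policy)
  if (is.numeric(values) && !is.null(names(values))) {
    values <- tibble::tibble(variable_id = names(values), value = unname(values))
  }
  if (!all(c("variable_id", "value") %in% names(values))) {
    abort("values needs columns variable_id and value")
  }
  norule <- setdiff(behaviours$variable_id, rules$variable_id)
  if (length(norule) > 0) {
    abort(paste0("no stratification rule for variable(s): ",
                 paste(norule, collapse = ", ")))
  }
  out <- behaviours |>
    dplyr::left_join(values, by = "variable_id") |>
    dplyr::left_join(rules, by = "variable_id") |>
    dplyr::rowwise() |>
    dplyr::mutate(flag = stratify_variable(.data$value, .data$direction,
                                           .data$green_yellow,
                                           .data$yellow_red)) |>
    dplyr::ungroup()
  if (any(is.na(out$flag))) {
    miss <- out$behaviour_id[is.na(out$flag)]
    if (missing_policy == "error") {
      abort(paste0("no data for behaviour(s): ", paste(miss, collapse = ", ")))
    }
    warn(paste0("missing data for behaviour(s) ", paste(miss, collapse = ", "),
                "; flagged ", missing_policy, " per policy"))
    out$flag[is.na(out$flag)] <- missing_policy
  }
  out |>
    dplyr::mutate(flag = as_flag(.data$flag)) |>
    dplyr::select("behaviour_id", "label", "dimension", "variable_id",
                  "value", "flag")
}

# length of the run of consecutive red flags ending at the most recent
# week, given past flags (oldest first) and the current flag
trailing_red_run <- function(past_flags, current_flag) {
  if (is.na(current_flag) || current_flag != "red") return(0L)
  run <- 1L
  for (f in rev(as.character(past_flags))) {
    if (!is.na(f) && f == "red") run <- run + 1L else break
  }
  run
}

#' Select the week's mission for one dimension
#'
#' Picks the behaviour needing most attention in the dimension: the most
#' severe current flag wins (red > yellow > green); among equal flags the
#' behaviour whose red flags persist through the longest run of
#' consecutive weeks ending at the current week wins; remaining ties fall
#' back to the configured behaviour order (row order of `flags`). The
#' returned mission is the lowest-numbered catalogue mission targeting
#' the chosen behaviour, so an all-green dimension still yields a
#' maintenance mission.
#'
#' @param flags tibble from [assess_weekly_flags()] (current week).
#' @param history tibble `behaviour_id, week, flag` of past weeks
#'   (strictly before the current week); may be empty.
#' @param catalogue mission catalogue, see [default_mission_catalogue()].
#' @param dimension the dimension to fill.
#' @return one-row tibble: the selected mission plus `behaviour_id` and
#'   `flag` of the behaviour it addresses and `red_run` used in the
#'   tie-break.
#' @export
select_mission_for_dimension <- function(flags, history, catalogue,
                                         dimension) {
  cand <- flags[flags$dimension == dimension, ]
  if (nrow(cand) == 0) abort(paste0("no behaviours for dimension ", dimension))
  cat_dim <- catalogue[catalogue$dimension == dimension, ]
  if (nrow(cat_dim) == 0) {
    abort(paste0("mission catalogue has no missions for dimension ", dimension))
  }
  if (is.null(history) || nrow(history) == 0) {
    history <- tibble::tibble(behaviour_id = character(), week = character(),
                              flag = character())
  }
  cand$red_run <- vapply(seq_len(nrow(cand)), function(i) {
    h <- history[history$behaviour_id == cand$behaviour_id[i], ]
    h <- h[order(h$week), ]
    trailing_red_run(h$flag, as.character(cand$flag[i]))
  }, integer(1))
  cand$.order <- seq_len(nrow(cand))
  pick <- cand[order(-flag_severity(cand$flag), -cand$red_run, cand$.order), ][1, ]
  missions <- cat_dim[cat_dim$target_behaviour_id == pick$behaviour_id, ]
  if (nrow(missions) == 0) {
    abort(paste0("no mission targets behaviour ", pick$behaviour_id))
  }
  mission <- missions[order(missions$mission_id), ][1, ]
  dplyr::bind_cols(
    mission,
    tibble::tibble(behaviour_id = pick$behaviour_id, flag = pick$flag,
                   red_run = pick$red_run)
  )
}

#' Generate a child's weekly coaching plan
#'
#' Exactly one mission per health dimension (physical activity & sleep,
#' diet, education & empowerment), each chosen by
#' [select_mission_for_dimension()]. The plan generated from week T data
#' applies to week T+1.
#'
#' @param child_id child identifier.
#' @param week ISO week ("YYYY-Www") of the data the plan is based on.
#' @param flags current-week flags from [assess_weekly_flags()].
#' @param history past flag history (`behaviour_id, week, flag`).
#' @param catalogue mission catalogue.
#' @return tibble of class `coaching_plan`: 3 rows with `child_id,
#'   plan_week`, the mission columns and the flag rationale.
#' @export
generate_coaching_plan <- function(child_id, week, flags,
                                   history = NULL,
                                   catalogue = default_mission_catalogue()) {
  validate_catalogue(catalogue)
  dims_present <- unique(flags$dimension)
  missing <- setdiff(DIMENSIONS, dims_present)
  if (length(missing) > 0) {
    abort(paste0("flags must cover all three dimensions; missing: ",
                 paste(missing, collapse = ", ")))
  }
  plan <- purrr::map_dfr(DIMENSIONS, function(d) {
    select_mission_for_dimension(flags, history, catalogue, d)
  })
  plan <- dplyr::bind_cols(
    tibble::tibble(child_id = child_id, plan_week = next_iso_week(week),
                   based_on_week = week),
    plan
  )
  class(plan) <- c("coaching_plan", class(plan))
  plan
}

#' Validate assigned missions against carer feedback
#'
#' Each assigned mission becomes `completed` or `not_completed` from the
#' feedback of family or educator; missions without feedback stay
#' `pending` until the validation deadline (end of the following week),
#' then default to `not_completed`. When family and educator disagree
#' the educator's report wins (logged).
#'
#' @param assignments tibble `mission_id, child_id, week` of assigned
#'   missions (week = the plan week).
#' @param feedback tibble `mission_id, child_id, week, completed
#'   (logical), validated_by ("family"/"educator")`; may be empty.
#' @param as_of_week ISO week the validation is run in; used for the
#'   deadline rule.
#' @return tibble `mission_id, child_id, week, status, validated_by`.
#' @export
validate_missions <- function(assignments, feedback = NULL,
                              as_of_week = NULL) {
  req <- c("mission_id", "child_id", "week")
  if (!all(req %in% names(assignments))) {
    abort("assignments needs mission_id, child_id, week")
  }
  if (is.null(feedback) || nrow(feedback) == 0) {
    feedback <- tibble::tibble(mission_id = integer(), child_id = character(),
                               week = character(), completed = logical(),
                               validated_by = character())
  }
  bad_auth <- setdiff(unique(feedback$validated_by), c("family", "educator"))
  if (length(bad_auth) > 0) {
    abort(paste0("unknown validator: ", paste(bad_auth, collapse = ", ")))
  }
  extra <- dplyr::anti_join(feedback, assignments,
                            by = c("mission_id", "child_id", "week"))
  if (nrow(extra) > 0) {
    abort(paste0("feedback for unassigned mission(s): ",
                 paste(unique(extra$mission_id), collapse = ", ")))
  }
  conflicts <- feedback |>
    dplyr::group_by(.data$mission_id, .data$child_id, .data$week) |>
    dplyr::filter(dplyr::n_distinct(.data$completed) > 1) |>
    dplyr::ungroup()
  if (nrow(conflicts) > 0) {
    inform(paste0("conflicting feedback for mission(s) ",
                  paste(unique(conflicts$mission_id), collapse = ", "),
                  "; educator report takes precedence"))
  }
  resolved <- feedback |>
    dplyr::mutate(.authority = ifelse(.data$validated_by == "educator", 2L, 1L)) |>
    dplyr::group_by(.data$mission_id, .data$child_id, .data$week) |>
    dplyr::slice_max(.data$.authority, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select(-".authority")
  out <- assignments |>
    dplyr::left_join(resolved, by = c("mission_id", "child_id", "week")) |>
    dplyr::mutate(
      status = dplyr::case_when(
        !is.na(.data$completed) & .data$completed ~ "completed",
        !is.na(.data$completed) ~ "not_completed",
        TRUE ~ "pending"
      ),
      validated_by = dplyr::coalesce(.data$validated_by, "none")
    )
  if (!is.null(as_of_week)) {
    deadline_passed <- vapply(out$week, function(w) {
      iso_week_monday(as_of_week) > iso_week_monday(next_iso_week(w))
    }, logical(1))
    out$status[out$status == "pending" & deadline_passed] <- "not_completed"
  }
  dplyr::select(out, "mission_id", "child_id", "week", "status",
                "validated_by")
}

#' Points and ability ledger from validated mission outcomes
#'
#' Total points over completed missions, plus per-ability points and the
#' percentage of the total each ability contributes (the dexterity /
#' discipline / intelligence progress shown to the child).
#'
#' @param outcomes tibble from [validate_missions()].
#' @param catalogue mission catalogue carrying `points` and `ability`.
#' @return tibble with one row per ability: `ability, points, pct`,
#'   plus a `total` column (repeated). Percentages sum to 100 when
#'   total > 0 and are all 0 otherwise.
#' @export
award_points <- function(outcomes, catalogue = default_mission_catalogue()) {
  done <- outcomes[outcomes$status == "completed", ]
  done <- dplyr::left_join(done,
                           dplyr::select(catalogue, "mission_id", "points",
                                         "ability"),
                           by = "mission_id")
  total <- sum(done$points %||% 0)
  per <- tibble::tibble(ability = ABILITIES) |>
    dplyr::left_join(
      dplyr::summarise(dplyr::group_by(done, .data$ability),
                       points = sum(.data$points), .groups = "drop"),
      by = "ability"
    ) |>
    dplyr::mutate(
      points = dplyr::coalesce(.data$points, 0L),
      pct = if (total > 0) 100 * .data$points / total else 0,
      total = total
    )
  per
}

#' Motivation messages for stalled missions and detected risks
#'
#' One message per assigned mission with no mid-week progress and one
#' per unhealthy trend verdict from the risk detector. Message templates
#' come from configuration; re-running with the same inputs yields the
#' identical message set (idempotent within a week).
#'
#' @param plan a [generate_coaching_plan()] result.
#' @param progress tibble `mission_id, progressing (logical)` of mid-week
#'   status; missions absent from it count as progressing.
#' @param risks list of `risk_detection` objects (or NULL).
#' @param templates named character templates with `{mission}`,
#'   `{variable}` placeholders.
#' @return tibble `type, mission_id, dimension, variable, message`.
#' @export
trigger_motivation <- function(plan, progress = NULL, risks = NULL,
                               templates = c(
                                 stalled = "Keep going! Mission '{mission}' is waiting for you this week.",
                                 risk = "Your {variable} trend needs attention - small daily wins count!"
                               )) {
  msgs <- tibble::tibble(type = character(), mission_id = integer(),
                         dimension = character(), variable = character(),
                         message = character())
  if (!is.null(progress) && nrow(progress) > 0) {
    stalled <- plan[plan$mission_id %in%
                      progress$mission_id[!progress$progressing], ]
    if (nrow(stalled) > 0) {
      msgs <- dplyr::bind_rows(msgs, tibble::tibble(
        type = "stalled", mission_id = stalled$mission_id,
        dimension = stalled$dimension, variable = NA_character_,
        message = gsub("{mission}", stalled$description,
                       templates[["stalled"]], fixed = TRUE)
      ))
    }
  }
  for (r in risks %||% list()) {
    if (r$verdict %in% c("unhealthy_trend_confirmed_by_forecast",
                         "unhealthy_trend_not_confirmed")) {
      dim <- if (r$variable %in% c("steps", "active_minutes", "sleep_minutes")) {
        "physical_activity_sleep"
      } else {
        NA_character_
      }
      msgs <- dplyr::bind_rows(msgs, tibble::tibble(
        type = "risk", mission_id = NA_integer_, dimension = dim,
        variable = r$variable,
        message = gsub("{variable}", gsub("_", " ", r$variable),
                       templates[["risk"]], fixed = TRUE)
      ))
    }
  }
  dplyr::distinct(msgs)
}

#' Weekly agent-report template
#'
#' The six-question weekly self-report the child submits in the app,
#' covering the previous week's food intake and physical activity.
#'
#' @param items data frame `item_id, prompt, dimension` defining the
#'   instrument; defaults to the shipped six items.
#' @param strict error unless exactly six items (default TRUE).
#' @return tibble template with one row per item and an empty `value`
#'   column.
#' @export
build_agent_report <- function(items = default_agent_report_items(),
                               strict = TRUE) {
  if (anyDuplicated(items$item_id)) abort("agent-report item ids must be unique")
  if (strict && nrow(items) != 6L) {
    abort(paste0("agent report must have exactly 6 items, got ", nrow(items)))
  }
  tibble::tibble(tibble::as_tibble(items), value = NA_character_)
}

#' Default agent-report items
#' @return tibble `item_id, prompt, dimension` (six items).
#' @export
default_agent_report_items <- function() {
  tibble::tribble(
    ~item_id, ~prompt, ~dimension,
    "ar1", "How many pieces of fruit did you eat on a usual day last week?", "diet",
    "ar2", "How many portions of vegetables did you eat on a usual day last week?", "diet",
    "ar3", "How often did you drink sugary drinks last week?", "diet",
    "ar4", "How many days were you active for at least 60 minutes last week?", "physical_activity_sleep",
    "ar5", "How did you usually get to school last week (walk, bike, vehicle)?", "physical_activity_sleep",
    "ar6", "How many evenings did you go to bed before 22:00 last week?", "physical_activity_sleep"
  )
}
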