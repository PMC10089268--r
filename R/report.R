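# Cohort-level reporting: status prevalences, flag distributions,
# mission completion and weekly variable means.

#' Cohort report
#'
#' Aggregates classified statuses, weekly flags, mission outcomes and
#' monitored-variable summaries into the prevalence-style report used to
#' describe a cohort: the five nutritional-status prevalences (summing to
#' 100%), the green/yellow/red distribution per week, the mission
#' completion rate (completed / assigned) and mean variable values by
#' week.
#'
#' @param statuses tibble with `child_id, status` (one row per child).
#' @param flags optional tibble `child_id, week, behaviour_id, flag`.
#' @param outcomes optional tibble from [validate_missions()].
#' @param weekly_values optional tibble `child_id, week, variable_id,
#'   value`.
#' @return list of class `cohort_report` with `status_prevalence`,
#'   `flag_distribution`, `completion_rate`, `variable_means`.
#' @export
cohort_report <- function(statuses, flags = NULL, outcomes = NULL,
                          weekly_values = NULL) {
  if (is.null(statuses) || nrow(statuses) == 0) abort("empty cohort")
  if (anyDuplicated(statuses$child_id)) {
    abort("statuses must have one row per child")
  }
  n <- nrow(statuses)
  status_prevalence <- tibble::tibble(status = STATUS_LEVELS) |>
    dplyr::left_join(
      dplyr::count(statuses, status = as.character(.data$status)),
      by = "status"
    ) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  prevalence_pct = 100 * .data$n / !!n)
  flag_distribution <- NULL
  if (!is.null(flags) && nrow(flags) > 0) {
    flag_distribution <- flags |>
      dplyr::count(.data$week, flag = as.character(.data$flag)) |>
      dplyr::group_by(.data$week) |>
      dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
      dplyr::ungroup()
  }
  completion_rate <- NULL
  if (!is.null(outcomes) && nrow(outcomes) > 0) {
    completion_rate <- 100 * mean(outcomes$status == "completed")
  }
  variable_means <- NULL
  if (!is.null(weekly_values) && nrow(weekly_values) > 0) {
    variable_means <- weekly_values |>
      dplyr::group_by(.data$week, .data$variable_id) |>
      dplyr::summarise(mean_value = mean(.data$value, na.rm = TRUE),
                       .groups = "drop")
  }
  structure(list(n_children = n, status_prevalence = status_prevalence,
                 flag_distribution = flag_distribution,
                 completion_rate = completion_rate,
                 variable_means = variable_means),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>", x$n_children, "children\n")
  p <- x$status_prevalence
  for (i in seq_len(nrow(p))) {
    cat(sprintf("  %-16s %5d  %5.1f%%\n", p$status[i], p$n[i],
                p$prevalence_pct[i]))
  }
  if (!is.null(x$completion_rate)) {
    cat(sprintf("  mission completion %.1f%%\n", x$completion_rate))
  }
  invisible(x)
}
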