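# broom-style tidiers and ggplot2 autoplot methods for the result types.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a risk detection: one row per fitted trend segment
#'
#' @param x a `risk_detection` object.
#' @param ... unused.
#' @return tibble with segment index, day span, dates, slope, intercept,
#'   SSE and slope class.
#' @export
tidy.risk_detection <- function(x, ...) {
  tibble::as_tibble(x$segments)
}

#' One-row summary of a risk detection
#'
#' @param x a `risk_detection` object.
#' @param ... unused.
#' @return tibble: variable, days analysed, number of segments, verdict,
#'   reference point and last-segment slope.
#' @export
glance.risk_detection <- function(x, ...) {
  tibble::tibble(
    variable = x$variable,
    n_days = nrow(x$data),
    n_segments = nrow(x$segments),
    verdict = x$verdict,
    reference_point = x$reference_point,
    final_slope = x$segments$slope[nrow(x$segments)]
  )
}

#' Plot a risk detection
#'
#' Daily values, the extracted trend, the fitted piecewise segments, the
#' forecast and the reference point (dashed vertical line).
#'
#' @param object a `risk_detection` object.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.risk_detection <- function(object, ...) {
  seg_lines <- purrr::pmap_dfr(
    object$segments[, c("start", "end", "slope", "intercept")],
    function(start, end, slope, intercept) {
      tibble::tibble(date = object$data$date[c(start, end)],
                     fit = intercept + slope * c(start, end),
                     segment = paste0(start, "-", end))
    })
  p <- ggplot2::ggplot(object$data, ggplot2::aes(x = .data$date)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value), alpha = 0.35,
                        size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$trend), colour = "grey40") +
    ggplot2::geom_line(data = seg_lines,
                       ggplot2::aes(y = .data$fit, group = .data$segment),
                       colour = "#d95f02", linewidth = 1) +
    ggplot2::labs(title = paste0(object$variable, ": ", object$verdict),
                  x = NULL, y = object$variable)
  if (!is.null(object$forecast)) {
    p <- p + ggplot2::geom_line(data = object$forecast,
                                ggplot2::aes(y = .data$value),
                                linetype = "dotted", colour = "#d95f02")
  }
  if (!is.na(object$reference_point)) {
    p <- p + ggplot2::geom_vline(xintercept = object$reference_point,
                                 linetype = "dashed", colour = "#7570b3")
  }
  p
}

#' Tidy a coaching plan
#' @param x a `coaching_plan`. @param ... unused.
#' @return plain tibble of the plan rows.
#' @export
tidy.coaching_plan <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "coaching_plan")
  tibble::as_tibble(out)
}

#' One-row summary of a coaching plan
#' @param x a `coaching_plan`. @param ... unused.
#' @return tibble: child, plan week, missions, red/yellow counts.
#' @export
glance.coaching_plan <- function(x, ...) {
  tibble::tibble(
    child_id = x$child_id[1],
    plan_week = x$plan_week[1],
    n_missions = nrow(x),
    n_red = sum(x$flag == "red"),
    n_yellow = sum(x$flag == "yellow")
  )
}

#' Tidy a cohort report (status prevalences)
#' @param x a `cohort_report`. @param ... unused.
#' @return the status-prevalence tibble.
#' @export
tidy.cohort_report <- function(x, ...) x$status_prevalence

#' One-row summary of a cohort report
#' @param x a `cohort_report`. @param ... unused.
#' @return tibble: cohort size, overweight/obesity prevalences, mission
#'   completion rate.
#' @export
glance.cohort_report <- function(x, ...) {
  p <- x$status_prevalence
  tibble::tibble(
    n_children = x$n_children,
    overweight_pct = p$prevalence_pct[p$status == "overweight"],
    obesity_pct = p$prevalence_pct[p$status == "obesity"],
    completion_rate = x$completion_rate %||% NA_real_
  )
}

#' Traffic-light tile plot of a flag history
#'
#' @param flags tibble `week, behaviour_id, flag` (optionally more
#'   columns; extra rows per child are faceted if `child_id` exists).
#' @return a ggplot with weeks on x, behaviours on y, flag colours.
#' @export
plot_flag_history <- function(flags) {
  p <- ggplot2::ggplot(flags,
                       ggplot2::aes(x = .data$week, y = .data$behaviour_id,
                                    fill = as_flag(.data$flag))) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.4) +
    ggplot2::scale_fill_manual(values = c(green = "#1b9e77",
                                          yellow = "#e6ab02",
                                          red = "#d95f02"),
                               name = "flag", drop = FALSE) +
    ggplot2::labs(x = "ISO week", y = NULL)
  if ("child_id" %in% names(flags) && length(unique(flags$child_id)) > 1) {
    p <- p + ggplot2::facet_wrap(~child_id)
  }
  p
}

#' Bar chart of cohort status prevalences
#' @param object a `cohort_report`. @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cohort_report <- function(object, ...) {
  p <- object$status_prevalence
  p$status <- factor(p$status, levels = STATUS_LEVELS)
  ggplot2::ggplot(p, ggplot2::aes(x = .data$status,
                                  y = .data$prevalence_pct)) +
    ggplot2::geom_col(fill = "#7570b3") +
    ggplot2::labs(x = NULL, y = "prevalence (%)")
}
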