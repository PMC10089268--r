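# Anthropometric classification, questionnaire scoring and the
# three-level (green/yellow/red) stratification feeding the flag scheme.

#' Body-mass index
#'
#' @param weight body weight in kg (> 0).
#' @param height standing height in m (> 0).
#' @return BMI in kg/m^2.
#' @examples
#' compute_bmi(50, 1.25) # 32
#' @export
compute_bmi <- function(weight, height) {
  check_number(weight, "weight", positive = TRUE)
  check_number(height, "height", positive = TRUE)
  weight / height^2
}

#' LMS z-score
#'
#' Standardises a measurement against an LMS growth reference:
#' z = ((x/M)^L - 1) / (L * S), with the limiting form z = ln(x/M) / S
#' when L = 0. Computed via `expm1(L * log(x/M))` so the general form is
#' numerically continuous with the log form as L -> 0.
#'
#' @param x measurement (same units as M), > 0.
#' @param l,m,s LMS parameters: skewness (Box-Cox power), median and
#'   coefficient of variation. `m > 0`, `s > 0`.
#' @return unitless z-score, strictly increasing in `x`.
#' @export
lms_zscore <- function(x, l, m, s) {
  check_number(x, "x", positive = TRUE)
  check_number(m, "M", positive = TRUE)
  check_number(s, "S", positive = TRUE)
  check_number(l, "L")
  r <- log(x / m)
  ifelse(l == 0, r / s, expm1(l * r) / (l * s))
}

#' Five-level nutritional status from a BMI-for-age z-score
#'
#' School-age cut-offs at z = -3, -2, +1, +2; boundaries belong to the
#' less severe side (z = -2 and z = +1 are both "normal").
#'
#' @param z finite BMI-for-age z-score.
#' @return ordered factor: severe_thinness < thinness < normal <
#'   overweight < obesity.
#' @export
classify_nutritional_status <- function(z) {
  if (!is.numeric(z) || any(!is.finite(z))) abort("z must be finite numeric")
  idx <- findInterval(z, c(-3, -2, 1, 2)) + 1L
  # findInterval closes intervals on the left; the convention here closes
  # every boundary on the LESS severe side, so z = +1 is still "normal"
  # and z = +2 still "overweight" (lower boundaries already comply).
  idx[z == 1] <- 3L
  idx[z == 2] <- 4L
  factor(STATUS_LEVELS[idx], levels = STATUS_LEVELS, ordered = TRUE)
}

#' Generic cut-off classifier
#'
#' Assigns the label of the half-open interval `[low, high)` containing
#' `value` (the last interval is unbounded above). Used for fat-mass and
#' abdominal-obesity categories with user-supplied reference cut-offs.
#'
#' @param value numeric vector.
#' @param cutoffs strictly increasing thresholds.
#' @param labels `length(cutoffs) + 1` labels, least to most extreme.
#' @return character vector of labels.
#' @examples
#' categorize_by_cutoffs(c(5, 10, 25), c(10, 20), c("low", "mid", "high"))
#' @export
categorize_by_cutoffs <- function(value, cutoffs, labels) {
  if (length(labels) != length(cutoffs) + 1L) {
    abort("need exactly length(cutoffs) + 1 labels")
  }
  if (is.unsorted(cutoffs, strictly = TRUE)) {
    abort("cutoffs must be strictly increasing")
  }
  check_number(value, "value")
  labels[findInterval(value, cutoffs) + 1L]
}

#' PAQ-C composite score
#'
#' Unweighted mean of the item scores of the Physical Activity
#' Questionnaire for Children (each item on a 1-5 scale).
#'
#' @param items integer item scores in 1..5.
#' @param n_items expected instrument length (default 9); NULL skips the
#'   length check.
#' @return composite score in `[1, 5]`.
#' @export
score_paqc <- function(items, n_items = 9L) {
  if (length(items) == 0) abort("no PAQ-C items supplied")
  if (!is.numeric(items) || any(!is.finite(items)) ||
      any(items != round(items)) || any(items < 1 | items > 5)) {
    abort("PAQ-C items must be integers in 1..5")
  }
  if (!is.null(n_items) && length(items) != n_items) {
    abort(paste0("expected ", n_items, " PAQ-C items, got ", length(items)))
  }
  mean(items)
}

#' Default FFQ category-to-frequency mapping
#'
#' Maps food-frequency questionnaire answer categories to consumptions
#' per week; ranged categories use the midpoint of their range.
#'
#' @return named numeric vector (category -> times per week).
#' @export
default_ffq_mapping <- function() {
  c("never" = 0, "<1/week" = 0.5, "1/week" = 1, "2-3/week" = 2.5,
    "4-6/week" = 5, "daily" = 7, ">1/day" = 10.5)
}

#' Weekly frequency of an FFQ answer category
#'
#' @param category character vector of answer categories.
#' @param mapping named numeric vector; defaults to [default_ffq_mapping()].
#' @return numeric weekly frequencies (>= 0).
#' @export
map_ffq_frequency <- function(category, mapping = default_ffq_mapping()) {
  unknown <- setdiff(unique(category), names(mapping))
  if (length(unknown) > 0) {
    abort(paste0("unknown FFQ categor", if (length(unknown) > 1) "ies: " else "y: ",
                 paste(unknown, collapse = ", ")))
  }
  unname(mapping[category])
}

#' Three-level risk stratification of one variable
#'
#' Every monitored variable carries its own green/yellow/red
#' stratification rule: a direction (whether high or low values are the
#' risky ones) and two cut-offs. Values exactly at a cut-off take the
#' less severe flag.
#'
#' @param value numeric vector.
#' @param direction "higher_is_worse" or "lower_is_worse".
#' @param green_yellow cut-off between green and yellow.
#' @param yellow_red cut-off between yellow and red. For
#'   "higher_is_worse" the cut-offs must satisfy
#'   `green_yellow <= yellow_red`, for "lower_is_worse" the reverse.
#' @return ordered flag factor (see [as_flag()]).
#' @examples
#' stratify_variable(7, "higher_is_worse", 2, 5) # red
#' @export
stratify_variable <- function(value, direction, green_yellow, yellow_red) {
  direction <- match.arg(direction, c("higher_is_worse", "lower_is_worse"))
  check_number(green_yellow, "green_yellow")
  check_number(yellow_red, "yellow_red")
  if (direction == "higher_is_worse" && green_yellow > yellow_red) {
    abort("higher_is_worse requires green_yellow <= yellow_red")
  }
  if (direction == "lower_is_worse" && green_yellow < yellow_red) {
    abort("lower_is_worse requires green_yellow >= yellow_red")
  }
  flag <- if (direction == "higher_is_worse") {
    ifelse(value <= green_yellow, "green",
           ifelse(value <= yellow_red, "yellow", "red"))
  } else {
    ifelse(value >= green_yellow, "green",
           ifelse(value >= yellow_red, "yellow", "red"))
  }
  flag[is.na(value)] <- NA
  as_flag(flag)
}

#' Weekly physical-activity target with dynamic percentage increases
#'
#' The coaching target grows from the child's individual baseline by a
#' fixed fraction per week until the population target level is reached:
#' `min(baseline * (1 + delta)^week, target)`.
#'
#' @param baseline individual baseline level (>= 0).
#' @param week_index weeks since baseline (integer >= 0).
#' @param delta fractional weekly increase (> 0), e.g. 0.10.
#' @param target_level level at which the progression caps.
#' @return the week's target; non-decreasing in `week_index`, never above
#'   `target_level`.
#' @examples
#' adjust_pa_target(5000, 1, 0.10, 10000) # 5500
#' @export
adjust_pa_target <- function(baseline, week_index, delta, target_level) {
  check_number(baseline, "baseline")
  if (any(baseline < 0)) abort("baseline must be >= 0")
  if (any(week_index < 0) || any(week_index != round(week_index))) {
    abort("week_index must be a non-negative integer")
  }
  check_number(delta, "delta", positive = TRUE)
  pmin(baseline * (1 + delta)^week_index, target_level)
}
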