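# LMS growth-reference table handling: reading, age interpolation and
# the anthropometrics -> BMI-for-age -> nutritional status pipeline.

#' Read an LMS reference table
#'
#' The table must have columns `sex, age_months, L, M, S` (header
#' required), one row per sex and month of age, `M > 0`, `S > 0`.
#' A synthetic BMI-for-age table for ages 96-167 months ships with the
#' package at `system.file("extdata", "lms_bmi_synthetic.csv",
#' package = "habitcoach")`; for real use supply a published reference.
#'
#' @param path CSV file path.
#' @return tibble with the five validated columns.
#' @export
read_lms_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("LMS table not found: ", path))
  lms <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("sex", "age_months", "L", "M", "S")
  missing <- setdiff(required, names(lms))
  if (length(missing) > 0) {
    abort(paste0("LMS table missing column(s): ", paste(missing, collapse = ", ")))
  }
  lms <- dplyr::select(lms, dplyr::all_of(required))
  bad_sex <- setdiff(unique(lms$sex), c("female", "male"))
  if (length(bad_sex) > 0) abort("LMS sex must be 'female' or 'male'")
  if (any(lms$M <= 0) || any(lms$S <= 0)) abort("LMS table requires M > 0 and S > 0")
  if (anyDuplicated(lms[, c("sex", "age_months")])) {
    abort("LMS table has duplicate (sex, age_months) rows")
  }
  dplyr::arrange(lms, .data$sex, .data$age_months)
}

#' Bundled synthetic LMS table
#'
#' Convenience loader for the synthetic BMI-for-age LMS fixture shipped
#' with the package (smooth plausible parameter curves, NOT a published
#' growth reference; adequate for demonstrations and for tests whose
#' oracles are closed-form in the table itself).
#'
#' @return tibble as from [read_lms_csv()].
#' @export
synthetic_lms_table <- function() {
  read_lms_csv(system.file("extdata", "lms_bmi_synthetic.csv",
                           package = "habitcoach"))
}

#' Interpolate LMS parameters at (possibly fractional) ages
#'
#' Linear interpolation in age, separately for L, M and S, within each
#' sex. Ages outside the table's range are an error.
#'
#' @param lms table as from [read_lms_csv()].
#' @param sex character vector, "female"/"male".
#' @param age_months numeric ages in months.
#' @return tibble with columns sex, age_months, L, M, S.
#' @export
lms_interpolate <- function(lms, sex, age_months) {
  if (length(sex) != length(age_months)) abort("sex and age_months lengths differ")
  out <- purrr::map2(sex, age_months, function(sx, age) {
    ref <- lms[lms$sex == sx, ]
    if (nrow(ref) == 0) abort(paste0("no LMS rows for sex ", sx))
    if (age < min(ref$age_months) || age > max(ref$age_months)) {
      abort(paste0("age ", round(age, 1), " months outside LMS table range [",
                   min(ref$age_months), ", ", max(ref$age_months), "]"))
    }
    c(L = stats::approx(ref$age_months, ref$L, age)$y,
      M = stats::approx(ref$age_months, ref$M, age)$y,
      S = stats::approx(ref$age_months, ref$S, age)$y)
  })
  out <- do.call(rbind, out)
  tibble::tibble(sex = sex, age_months = age_months,
                 L = unname(out[, "L"]), M = unname(out[, "M"]),
                 S = unname(out[, "S"]))
}

#' Age in months at a record date
#'
#' @param birth_date,date Date vectors.
#' @return numeric age in months (days / 30.4375).
#' @export
age_in_months <- function(birth_date, date) {
  birth_date <- as.Date(birth_date)
  date <- as.Date(date)
  if (any(date <= birth_date)) abort("record date must be after birth_date")
  as.numeric(date - birth_date) / 30.4375
}

#' BMI-for-age z-scores and nutritional status for a cohort
#'
#' Joins anthropometric records to child profiles, computes BMI, the
#' LMS z-score at each child's age on the record date, and the five-level
#' nutritional status. Records with |z| > `suspect_z` are flagged as
#' suspect (likely device or entry error) and kept, with a warning.
#'
#' @param anthropometrics data frame with `child_id, date, weight_kg,
#'   height_m` (dates ISO-8601).
#' @param profiles data frame with `child_id, sex, birth_date`.
#' @param lms LMS table as from [read_lms_csv()].
#' @param suspect_z absolute z beyond which a record is flagged (default 5).
#' @return tibble: input columns plus `age_months, bmi, z, status, suspect`.
#' @export
bmi_for_age <- function(anthropometrics, profiles, lms, suspect_z = 5) {
  required <- c("child_id", "date", "weight_kg", "height_m")
  missing <- setdiff(required, names(anthropometrics))
  if (length(missing) > 0) {
    abort(paste0("anthropometrics missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  out <- anthropometrics |>
    dplyr::inner_join(
      dplyr::select(profiles, "child_id", "sex", "birth_date"),
      by = "child_id"
    ) |>
    dplyr::mutate(
      date = as.Date(.data$date),
      age_months = age_in_months(.data$birth_date, .data$date),
      bmi = compute_bmi(.data$weight_kg, .data$height_m)
    )
  if (nrow(out) < nrow(anthropometrics)) {
    abort("anthropometric records reference child_ids absent from profiles")
  }
  par <- lms_interpolate(lms, out$sex, out$age_months)
  out <- out |>
    dplyr::mutate(
      z = lms_zscore(.data$bmi, par$L, par$M, par$S),
      status = classify_nutritional_status(.data$z),
      suspect = abs(.data$z) > suspect_z
    )
  if (any(out$suspect)) {
    warn(paste0(sum(out$suspect), " record(s) with |z| > ", suspect_z,
                " flagged as suspect (possible entry error)"))
  }
  tibble::as_tibble(out)
}

#' BMI (and weight) implied by a target z-score
#'
#' Inverts the LMS transform: the measurement whose z-score is `z` at the
#' given LMS parameters. Used by the simulator to generate anthropometry
#' with exact classification ground truth.
#'
#' @param z target z-score.
#' @param l,m,s LMS parameters.
#' @return measurement value (same units as `m`).
#' @export
lms_inverse <- function(z, l, m, s) {
  check_number(m, "M", positive = TRUE)
  check_number(s, "S", positive = TRUE)
  ifelse(l == 0, m * exp(s * z), m * (1 + l * s * z)^(1 / l))
}
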