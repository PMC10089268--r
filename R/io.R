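# Readers/writers for the flat-file interfaces: wearable CSV,
# anthropometrics CSV, weekly-values CSV, plans/outcomes JSON.

WEARABLE_VARIABLES <- c("steps", "active_minutes", "sleep_minutes", "calories")

#' Read a wearable CSV into long daily series
#'
#' Expects columns `child_id, date` and one or more of
#' `steps, active_minutes, sleep_minutes, calories`; empty cells are
#' missing days. Malformed rows (non-ISO dates, negative values,
#' duplicated child-days) abort with the offending rows named.
#'
#' @param path CSV file path.
#' @return long tibble `child_id, variable_id, date, value`, sorted.
#' @export
read_wearable_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("wearable file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(
    child_id = readr::col_character(), date = readr::col_character(),
    .default = readr::col_double()
  ))
  if (!all(c("child_id", "date") %in% names(raw))) {
    abort("wearable CSV must have child_id and date columns")
  }
  vars <- intersect(WEARABLE_VARIABLES, names(raw))
  if (length(vars) == 0) {
    abort(paste0("wearable CSV has none of the expected variable columns (",
                 paste(WEARABLE_VARIABLES, collapse = ", "), ")"))
  }
  parsed <- as.Date(raw$date, format = "%Y-%m-%d")
  bad <- which(is.na(parsed) & !is.na(raw$date))
  if (length(bad) > 0) {
    abort(paste0("non-ISO dates on data row(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  raw$date <- parsed
  dup <- duplicated(raw[, c("child_id", "date")])
  if (any(dup)) {
    d <- raw[dup, ][1, ]
    abort(paste0("duplicated (child_id, date): ", d$child_id, ", ",
                 format(d$date)))
  }
  long <- tidyr::pivot_longer(raw[, c("child_id", "date", vars)],
                              dplyr::all_of(vars),
                              names_to = "variable_id", values_to = "value")
  neg <- which(!is.na(long$value) & long$value < 0)
  if (length(neg) > 0) {
    abort(paste0("negative value(s) for ",
                 paste(unique(long$variable_id[neg]), collapse = ", ")))
  }
  dplyr::arrange(long, .data$child_id, .data$variable_id, .data$date)
}

#' Read an anthropometrics CSV
#'
#' Columns `child_id, date, weight_kg, height_m` required;
#' `waist_cm, hip_cm, fat_mass_pct` optional. Plausibility bounds are
#' configurable; offending rows abort.
#'
#' @param path CSV file path.
#' @param weight_range,height_range plausibility bounds (kg, m).
#' @return validated tibble.
#' @export
read_anthropometrics_csv <- function(path, weight_range = c(10, 150),
                                     height_range = c(0.9, 2.1)) {
  if (!file.exists(path)) abort(paste0("anthropometrics file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("child_id", "date", "weight_kg", "height_m")
  missing <- setdiff(req, names(raw))
  if (length(missing) > 0) {
    abort(paste0("anthropometrics CSV missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  raw$date <- as.Date(raw$date)
  if (any(is.na(raw$date))) abort("anthropometrics CSV has unparseable dates")
  out_w <- raw$weight_kg < weight_range[1] | raw$weight_kg > weight_range[2]
  out_h <- raw$height_m < height_range[1] | raw$height_m > height_range[2]
  if (any(out_w | out_h, na.rm = TRUE)) {
    abort(paste0("implausible weight/height on row(s): ",
                 paste(head(which(out_w | out_h), 5), collapse = ", ")))
  }
  if ("fat_mass_pct" %in% names(raw) &&
      any(raw$fat_mass_pct < 0 | raw$fat_mass_pct > 100, na.rm = TRUE)) {
    abort("fat_mass_pct must be within [0, 100]")
  }
  tibble::as_tibble(raw)
}

#' Read weekly behaviour values CSV
#'
#' Columns `child_id, week, variable_id, value`; weeks "YYYY-Www".
#'
#' @param path CSV file path.
#' @return validated tibble.
#' @export
read_weekly_values_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("weekly values file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("child_id", "week", "variable_id", "value")
  missing <- setdiff(req, names(raw))
  if (length(missing) > 0) {
    abort(paste0("weekly values CSV missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  iso_week_monday(unique(raw$week)) # validates the format
  tibble::as_tibble(raw)
}

#' Write a tibble to CSV atomically
#' @param x data frame. @param path destination.
#' @return the path, invisibly.
#' @export
write_csv_atomic <- function(x, path) {
  atomic_write(path, function(tmp) readr::write_csv(x, tmp))
}

#' Write an object to JSON atomically
#' @param x object (tibbles become arrays of records).
#' @param path destination.
#' @return the path, invisibly.
#' @export
write_json_atomic <- function(x, path) {
  atomic_write(path, function(tmp) {
    jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", Date = "ISO8601",
                         factor = "string", pretty = TRUE)
  })
}

#' Read coaching plans (or other records) from JSON
#' @param path JSON file of records.
#' @return tibble.
#' @export
read_records_json <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tibble::as_tibble(jsonlite::fromJSON(path))
}
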