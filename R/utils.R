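#' @importFrom rlang abort warn inform %||%
#' @importFrom stats lm coef rnorm runif rbinom setNames predict
#' @importFrom utils head tail
NULL

FLAG_LEVELS <- c("green", "yellow", "red")
STATUS_LEVELS <- c("severe_thinness", "thinness", "normal", "overweight", "obesity")
DIMENSIONS <- c("physical_activity_sleep", "diet", "education_empowerment")
ABILITIES <- c("dexterity", "discipline", "intelligence")

#' Risk-flag factor
#'
#' Converts a character vector to the ordered green < yellow < red flag
#' factor used throughout the engine (red is the most severe).
#'
#' @param x character vector of flag names.
#' @return ordered factor with levels green, yellow, red.
#' @export
as_flag <- function(x) {
  bad <- setdiff(unique(as.character(x[!is.na(x)])), FLAG_LEVELS)
  if (length(bad) > 0) {
    abort(paste0("unknown flag value(s): ", paste(bad, collapse = ", ")))
  }
  factor(as.character(x), levels = FLAG_LEVELS, ordered = TRUE)
}

flag_severity <- function(x) as.integer(as_flag(x))

# --- ISO-8601 week helpers (weeks are "YYYY-Www") ------------------------

#' ISO week identifier of a date
#'
#' @param date a Date vector.
#' @return character vector "YYYY-Www" (ISO-8601 week date year).
#' @export
iso_week <- function(date) {
  date <- as.Date(date)
  format(date, "%G-W%V")
}

#' Monday of an ISO week
#'
#' @param week character "YYYY-Www".
#' @return Date of the Monday starting that ISO week.
#' @export
iso_week_monday <- function(week) {
  m <- regmatches(week, regexec("^([0-9]{4})-W([0-9]{2})$", week))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    abort(paste0("malformed ISO week id: ", paste(week[bad], collapse = ", ")))
  }
  yr <- as.integer(vapply(m, `[`, "", 2L))
  wk <- as.integer(vapply(m, `[`, "", 3L))
  if (any(wk < 1L | wk > 53L)) abort("ISO week number must be in 1..53")
  jan4 <- as.Date(paste0(yr, "-01-04"))
  dow <- as.integer(format(jan4, "%u")) # 1 = Monday
  week1 <- jan4 - (dow - 1L)
  week1 + (wk - 1L) * 7L
}

#' Following ISO week
#'
#' Plans generated from week T data apply to week T+1; this computes T+1
#' with correct year rollover.
#'
#' @param week character "YYYY-Www".
#' @return character id of the next ISO week.
#' @export
next_iso_week <- function(week) {
  iso_week(iso_week_monday(week) + 7L)
}

# --- atomic writes -------------------------------------------------------

# Writes via a temp file in the same directory then renames, so a failed
# validation or interrupted run never leaves a partial output behind.
atomic_write <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = paste0(".tmp_", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) abort(paste0("could not write ", path))
  invisible(path)
}

check_number <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x)) abort(paste0(name, " must be numeric"))
  if (finite && any(!is.finite(x))) abort(paste0(name, " must be finite"))
  if (positive && any(x <= 0)) abort(paste0(name, " must be > 0"))
  invisible(x)
}
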