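# Engine configuration: assembled defaults, YAML/JSON loading and
# validation tying behaviours, rules, missions and policies together.

#' Default engine configuration
#'
#' @return list of class `engine_config` with behaviours, stratification
#'   rules, mission catalogue, FFQ mapping, detector configs, agent
#'   report items and policies.
#' @export
default_engine_config <- function() {
  structure(list(
    behaviours = default_behaviours(),
    rules = default_stratification_rules(),
    catalogue = default_mission_catalogue(),
    ffq_mapping = default_ffq_mapping(),
    detectors = default_detector_configs(),
    agent_report_items = default_agent_report_items(),
    policies = list(missing_data = "yellow",
                    validation_deadline_weeks = 1L),
    lms_path = system.file("extdata", "lms_bmi_synthetic.csv",
                           package = "habitcoach"),
    seed = 1L
  ), class = "engine_config")
}

#' Read an engine configuration from YAML or JSON
#'
#' Any top-level key absent from the file keeps its default. Tabular
#' sections (behaviours, rules, catalogue) are lists of records in the
#' file and validated against the same schema as the defaults.
#'
#' @param path .yaml/.yml or .json file.
#' @return validated `engine_config` list.
#' @export
read_engine_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  } else {
    abort("config must be .yaml/.yml or .json")
  }
  cfg <- default_engine_config()
  as_tbl <- function(x) {
    if (is.data.frame(x)) tibble::as_tibble(x) else dplyr::bind_rows(x)
  }
  if (!is.null(raw$behaviours)) cfg$behaviours <- as_tbl(raw$behaviours)
  if (!is.null(raw$rules)) cfg$rules <- as_tbl(raw$rules)
  if (!is.null(raw$catalogue)) cfg$catalogue <- as_tbl(raw$catalogue)
  if (!is.null(raw$ffq_mapping)) cfg$ffq_mapping <- unlist(raw$ffq_mapping)
  if (!is.null(raw$policies)) cfg$policies <- utils::modifyList(cfg$policies, raw$policies)
  if (!is.null(raw$lms_path)) cfg$lms_path <- raw$lms_path
  if (!is.null(raw$seed)) cfg$seed <- as.integer(raw$seed)
  if (!is.null(raw$detectors)) {
    for (v in names(raw$detectors)) {
      cfg$detectors[[v]] <- do.call(detector_config,
                                    c(list(variable = v), raw$detectors[[v]]))
    }
  }
  validate_engine_config(cfg)
}

#' Validate an engine configuration
#'
#' Checks the cross-references the engine relies on: every behaviour has
#' a stratification rule, every mission targets an existing behaviour of
#' its own dimension, rule cut-offs are ordered per direction, and the
#' LMS table (if a path is set) exists.
#'
#' @param cfg an `engine_config` list.
#' @return the config, invisibly; aborts on the first violation.
#' @export
validate_engine_config <- function(cfg) {
  norule <- setdiff(cfg$behaviours$variable_id, cfg$rules$variable_id)
  if (length(norule) > 0) {
    abort(paste0("behaviour variable(s) without a rule: ",
                 paste(norule, collapse = ", ")))
  }
  orphan <- setdiff(cfg$catalogue$target_behaviour_id,
                    cfg$behaviours$behaviour_id)
  if (length(orphan) > 0) {
    abort(paste0("mission(s) target unknown behaviour(s): ",
                 paste(orphan, collapse = ", ")))
  }
  validate_catalogue(cfg$catalogue, cfg$behaviours)
  for (i in seq_len(nrow(cfg$rules))) {
    r <- cfg$rules[i, ]
    ok <- if (r$direction == "higher_is_worse") {
      r$green_yellow <= r$yellow_red
    } else {
      r$green_yellow >= r$yellow_red
    }
    if (!ok) {
      abort(paste0("rule for ", r$variable_id,
                   " has cut-offs inconsistent with its direction"))
    }
  }
  if (!is.null(cfg$lms_path) && nzchar(cfg$lms_path) &&
      !file.exists(cfg$lms_path)) {
    abort(paste0("LMS table not found: ", cfg$lms_path))
  }
  invisible(cfg)
}
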