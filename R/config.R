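# Run configuration: schema-validated settings for the command-line
# pipeline, serializable as YAML or JSON.

config_schema <- function() {
  list(
    mode = list(default = "PFV", check = function(v)
      is.character(v) && length(v) == 1 && v %in% c("PF", "PFV")),
    speed = list(default = 1.8, check = function(v)
      is.numeric(v) && length(v) == 1 && v >= 1 && v <= 5),
    cycles = list(default = 20, check = function(v)
      is.numeric(v) && length(v) == 1 && v >= 2 && v == round(v)),
    seed = list(default = 1, check = function(v)
      is.numeric(v) && length(v) == 1 && v == round(v)),
    alpha = list(default = 0.5, check = function(v)
      is.numeric(v) && length(v) == 1 && v >= 0 && v <= 1),
    dt = list(default = 0.001, check = function(v)
      is.numeric(v) && length(v) == 1 && v > 0 && v <= 0.01),
    k_min = list(default = 5, check = function(v)
      is.numeric(v) && length(v) == 1 && v >= 0),
    k_max = list(default = 150, check = function(v)
      is.numeric(v) && length(v) == 1 && v > 0),
    zeta = list(default = 0.7, check = function(v)
      is.numeric(v) && length(v) == 1 && v >= 0),
    damping_mode = list(default = "critical", check = function(v)
      is.character(v) && length(v) == 1 && v %in% c("literal", "critical")),
    fes_rate = list(default = 40, check = function(v)
      is.numeric(v) && length(v) == 1 && v > 0),
    n_train = list(default = 2000, check = function(v)
      is.numeric(v) && length(v) == 1 && v > 0 && v == round(v)),
    max_epochs = list(default = 60, check = function(v)
      is.numeric(v) && length(v) == 1 && v >= 1 && v == round(v)),
    out_dir = list(default = ".", check = function(v)
      is.character(v) && length(v) == 1 && nzchar(v)),
    model_path = list(default = NULL, check = function(v)
      is.null(v) || (is.character(v) && length(v) == 1)),
    reference_table_path = list(default = NULL, check = function(v)
      is.null(v) || (is.character(v) && length(v) == 1)),
    envelope_TA_path = list(default = NULL, check = function(v)
      is.null(v) || (is.character(v) && length(v) == 1)),
    envelope_sol_path = list(default = NULL, check = function(v)
      is.null(v) || (is.character(v) && length(v) == 1))
  )
}

#' Validate a run configuration
#'
#' Fills defaults for missing keys, rejects unknown keys and checks each
#' value; all diagnostics name the offending key.
#'
#' @param values named list of configuration values.
#' @return validated configuration, class `run_config`.
#' @export
validate_config <- function(values) {
  schema <- config_schema()
  if (is.null(values)) values <- list()
  unknown <- setdiff(names(values), names(schema))
  if (length(unknown) > 0) {
    abort(paste0("unknown configuration key(s): ",
                 paste(unknown, collapse = ", ")),
          "hybridgait_schema_error")
  }
  cfg <- list()
  for (key in names(schema)) {
    v <- if (key %in% names(values)) values[[key]] else schema[[key]]$default
    if (!is.null(v) && !schema[[key]]$check(v)) {
      abort(paste0("invalid value for configuration key '", key, "'"),
            "hybridgait_schema_error")
    }
    cfg[key] <- list(v)
  }
  if (cfg$k_min > cfg$k_max) {
    abort("configuration keys 'k_min' and 'k_max' are inconsistent: k_min > k_max",
          "hybridgait_schema_error")
  }
  for (key in c("model_path", "reference_table_path", "envelope_TA_path",
                "envelope_sol_path")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      abort(paste0("configuration key '", key, "' references a missing file: ",
                   cfg[[key]]),
            "hybridgait_schema_error")
    }
  }
  structure(cfg, class = "run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' The format is chosen from the file extension (`.yaml`/`.yml` or
#' `.json`). Missing keys take their defaults; unknown keys and invalid
#' values are rejected with the key named.
#'
#' @param path path to the configuration file.
#' @return validated configuration, class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("configuration file not found: ", path),
          "hybridgait_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  values <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    abort("configuration file must be .yaml, .yml or .json",
          "hybridgait_io_error")
  }
  validate_config(values)
}

#' Save a run configuration
#'
#' Writes YAML or JSON depending on the file extension; a saved
#' configuration loads back equal.
#'
#' @param config a `run_config` (or plain named list, validated first).
#' @param path destination path (`.yaml`/`.yml`/`.json`).
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  vals <- unclass(config)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(vals, path)
  } else if (ext == "json") {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    abort("configuration file must be .yaml, .yml or .json",
          "hybridgait_io_error")
  }
  invisible(path)
}
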