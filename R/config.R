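## Run configuration.
##
## Analyses are driven by plain YAML (or JSON) configs validated before
## any stage runs: file paths, the unit system, and the stage
## parameters (MI k, expansion depth, SIS size, penalty grid, folds,
## seeds).  The analysis scripts under analysis/ and the exported
## functions are the package's interface; configs make a run
## self-describing.

.config_schema <- list(
  unit_system = function(v) is.character(v) && v %in% c("kJ", "kcal"),
  columns = function(v) is.list(v) &&
    all(vapply(v, is.character, logical(1))),
  mi_k = function(v) is.numeric(v) && v >= 1,
  depth = function(v) is.numeric(v) && v >= 1,
  sis_size = function(v) is.numeric(v) && v >= 1,
  max_support = function(v) is.numeric(v) && v >= 0 && v <= 8,
  penalty_grid = function(v) is.numeric(v) && all(v >= 0),
  folds = function(v) is.numeric(v) && v >= 2,
  seeds = function(v) is.numeric(v) && length(v) >= 1,
  paths = function(v) is.list(v) || is.character(v),
  output_dir = function(v) is.character(v)
)

#' Read and validate a run configuration
#'
#' Reads YAML (or JSON) and validates every recognized field against
#' the configuration schema; violations are reported with the field
#' path.  Unrecognized fields are kept untouched so callers can extend
#' configs.
#'
#' @param path YAML or JSON file path.
#' @return The validated configuration list (class `run_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop("config error: no such file: ", path, call. = FALSE)
  }
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_run_config(cfg)
}

#' Validate a run-configuration list
#' @param cfg named list.
#' @return `cfg` with class `run_config`; schema violations error with
#'   the offending field path.
#' @export
validate_run_config <- function(cfg) {
  if (!is.list(cfg)) stop("config error: top level must be a mapping",
                          call. = FALSE)
  for (field in intersect(names(cfg), names(.config_schema))) {
    if (!.config_schema[[field]](cfg[[field]])) {
      stop("config error at field '", field, "': invalid value",
           call. = FALSE)
    }
  }
  if (!is.null(cfg$paths)) {
    paths <- unlist(cfg$paths)
    missing_p <- paths[!file.exists(paths)]
    if (length(missing_p)) {
      stop("config error at field 'paths': no such file: ",
           paste(missing_p, collapse = ", "), call. = FALSE)
    }
  }
  class(cfg) <- c("run_config", "list")
  cfg
}
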