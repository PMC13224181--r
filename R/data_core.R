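## Domain tables: compound records and feature matrices.
##
## Compound tables are plain delimited text (comma separated, header
## row, "." decimal); a schema config maps file columns onto the
## canonical fields and declares the unit system.  Feature matrices are
## numeric matrices with row ids, an optional logS target, and a
## per-column provenance tag.

#' Construct a feature matrix
#'
#' @param X numeric matrix (rows = compounds, columns = named
#'   descriptors) or an object coercible to one.
#' @param row_ids compound ids (default from rownames).
#' @param target optional logS vector, one value per row.
#' @param provenance per-column tag, each one of `"thermodynamic"`,
#'   `"topological"`, `"derived"`.
#' @param unit_system unit system the thermodynamic columns are in.
#' @return An object of class `feature_matrix`: a list with elements
#'   `X`, `row_ids`, `target`, `provenance`, `unit_system`.
#' @export
feature_matrix <- function(X, row_ids = rownames(X), target = NULL,
                           provenance = rep("derived", ncol(X)),
                           unit_system = "kJ") {
  X <- as.matrix(X)
  if (is.null(colnames(X)) || anyDuplicated(colnames(X))) {
    stop("feature matrix columns must have unique names", call. = FALSE)
  }
  if (is.null(row_ids)) row_ids <- as.character(seq_len(nrow(X)))
  if (length(row_ids) != nrow(X)) {
    stop("row_ids length must match the number of rows", call. = FALSE)
  }
  if (!is.null(target) && length(target) != nrow(X)) {
    stop("target length must match the number of rows", call. = FALSE)
  }
  if (length(provenance) == 1L) provenance <- rep(provenance, ncol(X))
  if (length(provenance) != ncol(X)) {
    stop("provenance must have one tag per column", call. = FALSE)
  }
  bad <- setdiff(unique(provenance),
                 c("thermodynamic", "topological", "derived"))
  if (length(bad)) stop("invalid provenance tag(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  rownames(X) <- row_ids
  structure(list(X = X, row_ids = as.character(row_ids), target = target,
                 provenance = stats::setNames(provenance, colnames(X)),
                 unit_system = check_unit_system(unit_system)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d compounds x %d descriptors [%s]%s\n",
              nrow(x$X), ncol(x$X), x$unit_system,
              if (is.null(x$target)) "" else ", with logS target"))
  cat("  provenance:", paste(names(table(x$provenance)),
                             table(x$provenance), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$X)

## row subset preserving structure
fm_rows <- function(fm, idx) {
  feature_matrix(fm$X[idx, , drop = FALSE], row_ids = fm$row_ids[idx],
                 target = fm$target[idx], provenance = fm$provenance,
                 unit_system = fm$unit_system)
}

#' Bind thermodynamic columns and topological descriptors into one matrix
#'
#' @param compounds compound table carrying thermodynamic columns
#'   (`dG_solv`, `dH_sub`, ...) and `logS`.
#' @param topo a `feature_matrix` of topological descriptors for the
#'   same compounds (same order).
#' @param thermo_cols which compound-table columns to include.
#' @return A combined `feature_matrix` with mixed provenance.
#' @export
bind_thermo_features <- function(compounds, topo,
                                 thermo_cols = c("dG_solv", "dH_sub")) {
  stopifnot(inherits(topo, "feature_matrix"),
            all(thermo_cols %in% names(compounds)),
            nrow(compounds) == nrow(topo$X),
            all(compounds$id == topo$row_ids))
  Xt <- as.matrix(compounds[, thermo_cols, drop = FALSE])
  colnames(Xt) <- thermo_cols
  feature_matrix(cbind(Xt, topo$X), row_ids = topo$row_ids,
                 target = if ("logS" %in% names(compounds))
                   compounds$logS else topo$target,
                 provenance = c(rep("thermodynamic", length(thermo_cols)),
                                unname(topo$provenance)),
                 unit_system = topo$unit_system)
}

## ---- compound tables --------------------------------------------------

.thermo_fields <- c("dG_solv", "U_latt", "dH_sub", "dS_vib", "dS_trans",
                    "dS_rot", "dS_sub", "V_m", "T")

#' Read a compound table from delimited text
#'
#' Reads a comma-separated table with a header row and validates each
#' record: ids unique, solubility strictly positive, logS consistent
#' with log10(solubility) where both are present (logS is autocomputed
#' when only the solubility in mol/L is given), lattice energy and
#' sublimation enthalpy consistent with the -2RT relation where both
#' are present.  Energies given in kcal/mol are converted to kJ/mol on
#' entry; entropies are taken as J/(mol K).
#'
#' @param path file path of the delimited table.
#' @param config schema configuration: a list (or path to a YAML/JSON
#'   file parsed with [read_run_config()]) with optional entries
#'   `columns` (named list mapping canonical fields -- `id`, `name`,
#'   `smiles`, `solubility`, `logS`, `medium`, and the thermodynamic
#'   fields -- to file column names) and `unit_system` (`"kJ"` or
#'   `"kcal"`).  Defaults to identity mapping and kJ/mol.
#' @return A `data.frame` of validated compound records (class
#'   `compound_table`), in internal units, with attribute
#'   `"unit_system"` set to `"kJ"` after conversion.
#' @export
read_compound_table <- function(path, config = list()) {
  if (is.character(config)) config <- read_run_config(config)
  unit_in <- check_unit_system(config$unit_system %||% "kJ")
  raw <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  map <- config$columns %||% list()
  canonical <- c("id", "name", "smiles", "solubility", "logS", "medium",
                 .thermo_fields)
  df <- data.frame(row.names = seq_len(nrow(raw)))
  used <- character()
  for (field in canonical) {
    src <- map[[field]] %||% field
    if (src %in% names(raw)) {
      df[[field]] <- raw[[src]]
      used <- c(used, src)
    }
  }
  ## carry unmapped columns through untouched (extra measurement
  ## channels, annotations)
  for (extra in setdiff(names(raw), used)) df[[extra]] <- raw[[extra]]
  if (!"id" %in% names(df)) {
    stop("schema error: no 'id' column (after mapping) in ", path,
         call. = FALSE)
  }
  if (!"solubility" %in% names(df) && !"logS" %in% names(df)) {
    stop("schema error: need at least one of 'solubility' or 'logS'",
         call. = FALSE)
  }
  df$id <- as.character(df$id)
  validate_compound_table(df, unit_in = unit_in)
}

#' Validate (and unit-normalize) a compound table
#'
#' @param df data.frame of compound records.
#' @param unit_in unit system of the energy columns in `df`.
#' @return The validated table in kJ/mol internal units.
#' @export
validate_compound_table <- function(df, unit_in = "kJ") {
  check_unit_system(unit_in)
  if (anyDuplicated(df$id)) {
    stop("duplicate compound id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "),
         call. = FALSE)
  }
  if ("medium" %in% names(df)) {
    bad <- !df$medium %in% c("neat_solvent", "electrolyte", NA)
    if (any(bad)) {
      stop("invalid medium at row(s) ", paste(which(bad), collapse = ", "),
           " (must be neat_solvent or electrolyte)", call. = FALSE)
    }
  }
  for (col in c("dG_solv", "U_latt", "dH_sub")) {
    if (col %in% names(df)) df[[col]] <- energy_to_kj(df[[col]], unit_in)
  }
  if ("solubility" %in% names(df)) {
    bad <- which(!is.na(df$solubility) & df$solubility <= 0)
    if (length(bad)) {
      stop("non-positive solubility at row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (!"logS" %in% names(df)) df$logS <- NA_real_
    need <- is.na(df$logS) & !is.na(df$solubility)
    df$logS[need] <- log10(df$solubility[need])
    both <- !is.na(df$logS) & !is.na(df$solubility)
    incons <- which(both &
                      abs(df$logS - log10(df$solubility)) > 1e-9)
    if (length(incons)) {
      stop("logS inconsistent with log10(solubility) at row(s) ",
           paste(incons, collapse = ", "), call. = FALSE)
    }
  }
  if (all(c("U_latt", "dH_sub") %in% names(df))) {
    TT <- if ("T" %in% names(df)) df$T else ROOM_TEMPERATURE_K
    both <- !is.na(df$U_latt) & !is.na(df$dH_sub)
    incons <- which(both & abs(df$dH_sub -
                                 dH_sub_from_Ulatt(df$U_latt, TT)) > 1e-6)
    if (length(incons)) {
      stop("dH_sub inconsistent with -U_latt - 2RT at row(s) ",
           paste(incons, collapse = ", "), call. = FALSE)
    }
  }
  if ("V_m" %in% names(df)) {
    bad <- which(!is.na(df$V_m) & df$V_m <= 0)
    if (length(bad)) {
      stop("non-positive molar volume at row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  attr(df, "unit_system") <- "kJ"
  class(df) <- c("compound_table", "data.frame")
  df
}

#' Write a compound table as delimited text
#'
#' Numeric fields are written at full precision (15 significant
#' digits), so a write/read round trip reproduces them to 1e-12.
#'
#' @param df a compound table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_compound_table <- function(df, path) {
  out <- as.data.frame(df)
  for (col in names(out)) {
    if (is.numeric(out[[col]])) out[[col]] <- format(out[[col]],
                                                     digits = 15,
                                                     trim = TRUE)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- preprocessing ----------------------------------------------------

#' Preprocess a design matrix: drop non-numeric and zero-variance columns
#'
#' Non-numeric columns are dropped, then columns whose empirical
#' variance is exactly zero (or at most `var_eps`, when a tolerance for
#' near-constant columns is explicitly requested); columns containing
#' missing values fail loudly rather than being imputed -- with few
#' compounds, imputation distortions are large.  Row order is never
#' changed.  The drop report is attached as attribute `"preprocess_report"`.
#'
#' @param x a `feature_matrix`, matrix or data.frame (possibly with
#'   non-numeric columns).
#' @param var_eps variance threshold; the default 0 drops only exactly
#'   constant columns.
#' @return A `feature_matrix` containing only numeric, non-constant
#'   columns, with a data.frame report of dropped columns (`column`,
#'   `reason`) attached.
#' @export
preprocess_design_matrix <- function(x, var_eps = 0) {
  if (inherits(x, "feature_matrix")) {
    df <- as.data.frame(x$X)
    target <- x$target
    prov <- x$provenance
    ids <- x$row_ids
    units <- x$unit_system
  } else {
    df <- as.data.frame(x)
    target <- attr(x, "target")
    prov <- NULL
    ids <- rownames(df) %||% as.character(seq_len(nrow(df)))
    units <- "kJ"
  }
  dropped <- data.frame(column = character(), reason = character())
  keep <- character()
  for (col in names(df)) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      dropped <- rbind(dropped, data.frame(column = col,
                                           reason = "non-numeric"))
    } else if (anyNA(v)) {
      stop("column '", col, "' contains missing values; resolve or drop ",
           "explicitly before modeling (no silent imputation)",
           call. = FALSE)
    } else if (stats::var(v) <= var_eps) {
      dropped <- rbind(dropped, data.frame(column = col,
                                           reason = "zero-variance"))
    } else {
      keep <- c(keep, col)
    }
  }
  if (!length(keep)) {
    stop("no columns survive preprocessing (all non-numeric or constant)",
         call. = FALSE)
  }
  X <- as.matrix(df[, keep, drop = FALSE])
  out <- feature_matrix(
    X, row_ids = ids, target = target,
    provenance = if (is.null(prov)) rep("derived", length(keep))
                 else unname(prov[keep]),
    unit_system = units)
  attr(out, "preprocess_report") <- dropped
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
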