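#' @keywords internal
"_PACKAGE"

.ddmrd_targets <- c("p190", "p210", "control_ABL1")
.ddmrd_roles <- c("sample", "NTC", "healthy_donor", "plasmid_standard",
                  "ph_negative_control")
.well_columns <- c("well_id", "sample_id", "target", "role",
                   "replicate_group", "n_accepted", "k_positive")

#' Validate a droplet-well table
#'
#' Checks the invariants every droplet-well data frame must satisfy: the
#' required columns are present, `target` and `role` take known values,
#' droplet counts are non-negative integers and `k_positive <= n_accepted`.
#' Missing metadata columns (`sample_id`, `role`, `replicate_group`) are
#' filled with defaults.
#'
#' @param wells A data frame of wells.
#' @param permissive Logical; when `TRUE`, invariant violations are reported
#'   as warnings and offending rows dropped instead of raising errors.
#' @return The validated (possibly filtered) data frame, columns in canonical
#'   order.
#' @export
validate_wells <- function(wells, permissive = FALSE) {
  if (!is.data.frame(wells)) stop("'wells' must be a data frame", call. = FALSE)
  need <- c("well_id", "target", "n_accepted", "k_positive")
  missing_cols <- setdiff(need, names(wells))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(wells$sample_id)) wells$sample_id <- wells$well_id
  if (is.null(wells$role)) wells$role <- "sample"
  if (is.null(wells$replicate_group)) wells$replicate_group <- wells$sample_id

  complain <- function(rows, what) {
    msg <- sprintf("%s in row(s) %s (well %s)", what,
                   paste(rows, collapse = ", "),
                   paste(wells$well_id[rows], collapse = ", "))
    if (permissive) warning(msg, call. = FALSE) else stop(msg, call. = FALSE)
  }
  drop <- rep(FALSE, nrow(wells))
  bad <- which(!wells$target %in% .ddmrd_targets)
  if (length(bad)) { complain(bad, "unknown target"); drop[bad] <- TRUE }
  bad <- which(!wells$role %in% .ddmrd_roles)
  if (length(bad)) { complain(bad, "unknown role"); drop[bad] <- TRUE }
  bad <- which(is.na(wells$n_accepted) | is.na(wells$k_positive) |
                 wells$n_accepted < 0 | wells$k_positive < 0)
  if (length(bad)) { complain(bad, "negative or missing droplet count"); drop[bad] <- TRUE }
  bad <- which(!drop & wells$k_positive > wells$n_accepted)
  if (length(bad)) { complain(bad, "k_positive exceeds n_accepted"); drop[bad] <- TRUE }

  wells <- wells[!drop, , drop = FALSE]
  wells$n_accepted <- as.integer(wells$n_accepted)
  wells$k_positive <- as.integer(wells$k_positive)
  extra <- setdiff(names(wells), .well_columns)
  wells[, c(.well_columns, extra), drop = FALSE]
}

#' Read well-level droplet counts from CSV
#'
#' Reads a well table in the fixed dialect used throughout the package:
#' comma-separated, header row, UTF-8, `"."` decimal — one well per row with
#' columns `well_id`, `sample_id`, `target`, `role`, `replicate_group`,
#' `n_accepted`, `k_positive` (the first and the last three are mandatory).
#' Rows are validated against the droplet-well invariants; violations name
#' the offending rows and wells. Per-droplet amplitudes, when available, live
#' in a separate long-format file (see [read_amplitudes()]).
#'
#' @param path CSV file path.
#' @param layout Optional plate layout from [read_plate_layout()]; its
#'   metadata (sample, target, role, replicate group) is merged by `well_id`,
#'   overriding columns absent from the CSV.
#' @param permissive Passed to [validate_wells()].
#' @return A validated droplet-well data frame.
#' @export
read_wells <- function(path, layout = NULL, permissive = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!is.null(layout)) {
    lw <- layout$wells
    miss <- setdiff(df$well_id, lw$well_id)
    if (length(miss)) {
      stop("well(s) absent from plate layout: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    idx <- match(df$well_id, lw$well_id)
    for (col in c("sample_id", "target", "role", "replicate_group")) {
      if (is.null(df[[col]])) df[[col]] <- lw[[col]][idx]
    }
  }
  validate_wells(df, permissive = permissive)
}

#' Write well-level droplet counts to CSV
#'
#' @param wells Droplet-well data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_wells <- function(wells, path) {
  wells <- validate_wells(wells)
  utils::write.csv(wells[, .well_columns], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read per-droplet amplitudes
#'
#' Amplitudes are stored long-format (`well_id`, `amplitude`) in their own
#' CSV so that the common case — wells without amplitude exports — keeps the
#' well table small.
#'
#' @param path CSV with columns `well_id`, `amplitude`.
#' @return A named list of numeric amplitude vectors, one per well.
#' @export
read_amplitudes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("well_id", "amplitude") %in% names(df))) {
    stop("amplitude file needs columns well_id, amplitude", call. = FALSE)
  }
  split(df$amplitude, df$well_id)
}

#' Read a plate layout from YAML or JSON
#'
#' The layout maps `well_id` to sample, target, role and replicate group:
#' a top-level `run_id` plus a `wells` mapping of
#' `well_id: {sample_id, target, role, replicate_group}`.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A list of class `"plate_layout"` with `run_id` and a `wells` data
#'   frame.
#' @export
read_plate_layout <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$wells)) stop("layout has no 'wells' mapping", call. = FALSE)
  ids <- names(cfg$wells)
  if (anyDuplicated(ids)) {
    stop("duplicated well_id in layout: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  get <- function(w, f, default = NA_character_) {
    v <- w[[f]]; if (is.null(v)) default else as.character(v)
  }
  wells <- data.frame(
    well_id = ids,
    sample_id = vapply(cfg$wells, get, "", f = "sample_id"),
    target = vapply(cfg$wells, get, "", f = "target"),
    role = vapply(cfg$wells, get, "", f = "role", default = "sample"),
    replicate_group = vapply(cfg$wells, get, "", f = "replicate_group"),
    row.names = NULL
  )
  structure(list(run_id = if (is.null(cfg$run_id)) NA_character_ else cfg$run_id,
                 wells = wells),
            class = "plate_layout")
}

#' Write an MRD results table to CSV
#'
#' One row per sample/target with merged droplet counts, concentrations and
#' confidence bounds for target and control, the MRD ratio and class.
#' Numeric columns are serialised to 6 significant digits; column order is
#' fixed so files diff cleanly between runs.
#'
#' @param results An `"mrd_results"` data frame from [quantify_wells()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (!is.data.frame(results) || nrow(results) == 0) {
    stop("'results' must be a non-empty data frame", call. = FALSE)
  }
  out <- as.data.frame(results)
  num <- vapply(out, is.numeric, logical(1)) &
    !vapply(out, is.integer, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an MRD results table written by [write_results()]
#'
#' @param path CSV path.
#' @return An `"mrd_results"` data frame.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  res <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(res) <- c("mrd_results", "data.frame")
  res
}
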