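#' Patient cohort columns and vocabularies
#'
#' A cohort is an ordinary tibble with one row per reirradiation course.
#' The core columns are `id` (unique string), `time_months` (non-negative
#' survival time from the start of reirradiation), `event` (`TRUE` = death
#' observed, never missing), `kps` (Karnofsky performance status, a multiple
#' of 10 in 10..100, or `NA`), the logical prognostic factors `steroids`,
#' `liver_mets`, `pleural_effusion`, `bone_mets_only` (`TRUE` = no known
#' metastases outside bone), and `primary_site` (one of
#' `r paste(primary_site_levels(), collapse = ", ")`). Any further columns are
#' carried along as extra covariates (opioids, brain metastases, lab values,
#' and so on).
#'
#' @return `cohort_columns()` returns the core column names in canonical
#'   order; `primary_site_levels()` the allowed primary-site labels.
#' @export
cohort_columns <- function() {
  c("id", "time_months", "event", "kps", "steroids", "liver_mets",
    "pleural_effusion", "primary_site", "bone_mets_only")
}

#' @rdname cohort_columns
#' @export
primary_site_levels <- function() {
  c("prostate", "breast", "nsclc", "colorectal", "bladder", "kidney",
    "melanoma", "other")
}

kps_values <- function() seq(10L, 100L, by = 10L)

#' Validate a cohort tibble
#'
#' Checks the cohort invariants: unique ids, non-negative survival times,
#' a non-missing logical event indicator, and KPS values restricted to
#' multiples of 10 in 10..100 where present. Violations raise an error that
#' names the offending row and column.
#'
#' @param data A cohort data frame (see [cohort_columns()]).
#' @return The validated cohort, invisibly coerced to a tibble.
#' @export
validate_cohort <- function(data) {
  data <- tibble::as_tibble(data)
  for (col in c("id", "time_months", "event")) {
    if (!col %in% names(data)) {
      abort(sprintf("cohort is missing mandatory column '%s'", col),
            class = "reradscore_schema_error")
    }
  }
  if (anyDuplicated(data$id)) {
    dup <- data$id[duplicated(data$id)][1]
    abort(sprintf("duplicate patient id '%s'", dup),
          class = "reradscore_validation_error")
  }
  bad_time <- which(is.na(data$time_months) | data$time_months < 0)
  if (length(bad_time)) {
    abort(sprintf("negative or missing time_months at row %d", bad_time[1]),
          class = "reradscore_validation_error")
  }
  if (!is.logical(data$event) || anyNA(data$event)) {
    abort("column 'event' must be logical and never missing",
          class = "reradscore_validation_error")
  }
  if ("kps" %in% names(data)) {
    bad <- which(!is.na(data$kps) & !data$kps %in% kps_values())
    if (length(bad)) {
      abort(sprintf("row %d, column 'kps': value %s not in {10, 20, ..., 100}",
                    bad[1], data$kps[bad[1]]),
            class = "reradscore_validation_error")
    }
  }
  if ("primary_site" %in% names(data)) {
    bad <- which(!is.na(data$primary_site) &
                   !data$primary_site %in% primary_site_levels())
    if (length(bad)) {
      abort(sprintf(
        "row %d, column 'primary_site': unknown level '%s' (allowed: %s)",
        bad[1], data$primary_site[bad[1]],
        paste(primary_site_levels(), collapse = ", ")),
        class = "reradscore_validation_error")
    }
  }
  invisible(data)
}

parse_boolean_column <- function(x, col) {
  out <- rep(NA, length(x))
  low <- tolower(trimws(x))
  truey <- low %in% c("yes", "1", "true")
  falsy <- low %in% c("no", "0", "false")
  out[truey] <- TRUE
  out[falsy] <- FALSE
  bad <- which(!is.na(x) & !truey & !falsy)
  if (length(bad)) {
    abort(sprintf(
      "row %d, column '%s': cannot parse '%s' as yes/no/1/0/true/false",
      bad[1], col, x[bad[1]]), class = "reradscore_validation_error")
  }
  as.logical(out)
}

parse_numeric_column <- function(x, col) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) {
    abort(sprintf("row %d, column '%s': cannot parse '%s' as a number",
                  bad[1], col, x[bad[1]]),
          class = "reradscore_validation_error")
  }
  out
}

#' Read a patient cohort from CSV
#'
#' Reads a comma-separated file with a header row into a validated cohort
#' tibble. Empty cells and the sentinel string (default `"NA"`) become
#' missing values. Boolean columns accept yes/no, 1/0, and true/false in any
#' case. Parsing never silently coerces: any cell that cannot be interpreted
#' raises an error naming its row and column.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Optional named character vector mapping cohort field names
#'   to file column names, e.g. `c(time_months = "os_months")`. Unmapped
#'   fields are taken from identically named columns.
#' @param na Sentinel string treated as missing (the empty string always is).
#' @return A cohort tibble (see [cohort_columns()]); extra columns are
#'   type-converted (numbers, logicals) but otherwise kept verbatim.
#' @seealso [write_cohort()] for the inverse; the pair round-trips losslessly.
#' @export
read_cohort <- function(path, schema = NULL, na = "NA") {
  if (!file.exists(path)) {
    abort(sprintf("file '%s' does not exist", path), class = "reradscore_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE,
                         show_col_types = FALSE)
  if (!is.null(schema)) {
    for (field in names(schema)) {
      src <- schema[[field]]
      if (!src %in% names(raw)) {
        abort(sprintf("schema column '%s' (for field '%s') not found in file",
                      src, field), class = "reradscore_schema_error")
      }
      names(raw)[names(raw) == src] <- field
    }
  }
  for (col in c("time_months", "event")) {
    if (!col %in% names(raw)) {
      abort(sprintf("mandatory column '%s' missing from '%s'", col, path),
            class = "reradscore_schema_error")
    }
  }
  # sentinel handling: empty cells and the sentinel become NA everywhere
  raw <- dplyr::mutate(raw, dplyr::across(
    dplyr::everything(),
    function(x) ifelse(trimws(x) == "" | trimws(x) == na, NA_character_, x)
  ))
  n <- nrow(raw)
  out <- tibble::tibble(
    id = if ("id" %in% names(raw)) raw$id else sprintf("row%04d", seq_len(n)),
    time_months = parse_numeric_column(raw$time_months, "time_months"),
    event = parse_boolean_column(raw$event, "event")
  )
  if (anyNA(out$event)) {
    abort(sprintf("row %d, column 'event': event indicator may not be missing",
                  which(is.na(out$event))[1]),
          class = "reradscore_validation_error")
  }
  if ("kps" %in% names(raw)) {
    kps <- parse_numeric_column(raw$kps, "kps")
    out$kps <- as.integer(kps)
  }
  for (col in c("steroids", "liver_mets", "pleural_effusion", "bone_mets_only")) {
    if (col %in% names(raw)) out[[col]] <- parse_boolean_column(raw[[col]], col)
  }
  if ("primary_site" %in% names(raw)) out$primary_site <- raw$primary_site
  extra <- setdiff(names(raw), cohort_columns())
  for (col in extra) {
    out[[col]] <- type.convert(raw[[col]], as.is = TRUE, na.strings = character())
  }
  core <- intersect(cohort_columns(), names(out))
  out <- out[, c(core, setdiff(names(out), core)), drop = FALSE]
  validate_cohort(out)
  out
}

#' Write a patient cohort to CSV
#'
#' Writes one row per patient with a header row, the core columns first in
#' canonical order, and missing values rendered as the sentinel. The output
#' reads back with [read_cohort()] field-for-field identically.
#'
#' @param data A valid cohort tibble.
#' @param path Destination file path.
#' @param na Sentinel string written for missing values.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path, na = "NA") {
  validate_cohort(data)
  data <- tibble::as_tibble(data)
  core <- intersect(cohort_columns(), names(data))
  data <- data[, c(core, setdiff(names(data), core)), drop = FALSE]
  readr::write_csv(data, path, na = na, progress = FALSE)
  invisible(path)
}
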