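#' Read a study table from CSV
#'
#' Reads a UTF-8 CSV of per-study records in exactly one of two schemas
#' (column order is free, extra columns are rejected):
#' * g-level: `study_id, g, n1, n2`
#' * raw summaries: `study_id, mean1, sd1, n1, mean2, sd2, n2`
#'
#' Raw-summary rows are converted to g with [hedges_g()]; derived terms
#' (`m`, `ntilde`, `a`) are added; row order is preserved. Schema mismatches
#' report the missing and unexpected columns; non-numeric or invalid cells
#' report the offending row.
#'
#' @param path Path to the CSV file (header required).
#' @return A study tibble ready for [fit_meta()].
#' @export
read_study_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "metamixg_error_io")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  g_schema <- c("study_id", "g", "n1", "n2")
  raw_schema <- c("study_id", "mean1", "sd1", "n1", "mean2", "sd2", "n2")
  schema <- if (setequal(names(raw), g_schema)) {
    g_schema
  } else if (setequal(names(raw), raw_schema)) {
    raw_schema
  } else {
    best <- if (length(intersect(names(raw), raw_schema)) >
                length(intersect(names(raw), g_schema))) raw_schema else g_schema
    abort(paste0(
      "Unrecognized study-table schema.\n",
      "  missing: ", paste(setdiff(best, names(raw)), collapse = ", "), "\n",
      "  unexpected: ", paste(setdiff(names(raw), best), collapse = ", "), "\n",
      "Expected exactly (study_id, g, n1, n2) or ",
      "(study_id, mean1, sd1, n1, mean2, sd2, n2)."
    ), class = "metamixg_error_schema")
  }
  num_cols <- setdiff(schema, "study_id")
  parsed <- raw
  for (col in num_cols) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) & !is.na(raw[[col]]) | is.na(raw[[col]]))
    if (length(bad)) {
      abort(sprintf("Column `%s`: cannot parse value '%s' in data row %d.",
                    col, raw[[col]][bad[1]], bad[1]),
            class = "metamixg_error_parse")
    }
    parsed[[col]] <- vals
  }
  for (col in c("n1", "n2")) {
    bad <- which(parsed[[col]] != round(parsed[[col]]) | parsed[[col]] < 2)
    if (length(bad)) {
      abort(sprintf("Column `%s`: sizes must be integers >= 2 (data row %d).",
                    col, bad[1]),
            class = "metamixg_error_parse")
    }
    parsed[[col]] <- as.integer(parsed[[col]])
  }
  if (anyDuplicated(parsed$study_id)) {
    abort("Duplicate `study_id` values in study table.",
          class = "metamixg_error_input")
  }
  add_study_terms(parsed)
}

#' Write and re-read machine-readable fit reports
#'
#' `write_fit_json()` serializes one or more `meta_fit` objects (summary plus
#' per-study table) to JSON at full precision. `read_fit_json()` restores the
#' summaries and study tables as tibbles.
#'
#' @param fits A `meta_fit` object or list of them.
#' @param path Output path.
#' @return `write_fit_json()` returns `path` invisibly; `read_fit_json()` a
#'   list with tibbles `summary` and `studies`.
#' @export
write_fit_json <- function(fits, path) {
  if (inherits(fits, "meta_fit")) fits <- list(fits)
  payload <- list(
    summary = purrr::map_dfr(fits, glance),
    studies = purrr::map_dfr(fits, function(f) {
      dplyr::mutate(tidy(f), method = f$method, .before = 1)
    })
  )
  jsonlite::write_json(payload, path, dataframe = "rows", digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(summary = tibble::as_tibble(obj$summary),
       studies = tibble::as_tibble(obj$studies))
}
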