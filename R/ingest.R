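#' Column mapping for custom long-format uploads
#'
#' The custom upload schema has three required columns — patient identifier,
#' time point, and symptom/response — plus user-declared orderings of the
#' time labels and the response labels (ordering is an explicit user step,
#' never inferred from the data). An optional arm column extends the schema
#' for multi-arm extracts; when absent, all patients are placed in a single
#' arm labelled `"All"`.
#'
#' @param id_column,time_column,response_column Header names of the three
#'   required columns; must be distinct.
#' @param time_order Time labels in temporal order (unique).
#' @param response_order Response labels, least to most severe (unique).
#' @param arm_column Optional header name of a treatment-arm column.
#' @return An object of class `column_mapping`.
#' @export
column_mapping <- function(id_column, time_column, response_column,
                           time_order, response_order, arm_column = NULL) {
  named <- c(id_column, time_column, response_column, arm_column)
  if (anyDuplicated(named)) {
    stop("mapped column names must be distinct", call. = FALSE)
  }
  time_order <- as.character(time_order)
  response_order <- as.character(response_order)
  if (anyDuplicated(time_order) || anyDuplicated(response_order)) {
    stop("`time_order` and `response_order` must have unique entries",
         call. = FALSE)
  }
  structure(
    list(id_column = id_column, time_column = time_column,
         response_column = response_column, time_order = time_order,
         response_order = response_order, arm_column = arm_column),
    class = "column_mapping"
  )
}

#' Read a custom long-format AE/PRO table
#'
#' Parses a delimited file with one row per (patient, time point) holding
#' the response for a single symptom/term, per a [column_mapping()]. The
#' resulting table's scale levels equal `response_order` (with
#' `missing_label` as the missing level), its stage order equals
#' `time_order`, and its term is the response column's header name. Blank
#' response cells map to `missing_label` (that is the purpose of a
#' "No Response"-style category), rather than erroring.
#'
#' @param path File path of a delimited text file with a header row.
#' @param mapping A [column_mapping()].
#' @param missing_label Label for the missing/off-treatment category.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @param strict Error on duplicated (patient, time) keys? If `FALSE`,
#'   duplicates are resolved to the most severe response with a warning.
#' @return An [observation_table()].
#' @export
read_custom_table <- function(path, mapping, missing_label = "No Response",
                              delim = ",", strict = TRUE) {
  if (!inherits(mapping, "column_mapping")) {
    mapping <- do.call(column_mapping, mapping)  # validates before any I/O
  }
  if (missing_label %in% mapping$response_order) {
    stop("`missing_label` must not be among `response_order`", call. = FALSE)
  }
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE,
    show_col_types = FALSE)
  needed <- c(mapping$id_column, mapping$time_column, mapping$response_column,
              mapping$arm_column)
  absent <- setdiff(needed, names(raw))
  if (length(absent)) {
    stop("mapped column(s) missing from file header: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }

  time <- raw[[mapping$time_column]]
  bad_t <- which(!(time %in% mapping$time_order))
  if (length(bad_t)) {
    stop("time value '", time[bad_t[1]], "' at data row ", bad_t[1],
         " is not in the declared time_order", call. = FALSE)
  }
  resp <- raw[[mapping$response_column]]
  resp[is.na(resp) | resp == ""] <- missing_label
  known <- c(mapping$response_order, missing_label)
  bad_r <- which(!(resp %in% known))
  if (length(bad_r)) {
    stop("response value '", resp[bad_r[1]], "' at data row ", bad_r[1],
         " is not in the declared response_order", call. = FALSE)
  }

  arm <- if (is.null(mapping$arm_column)) {
    rep("All", nrow(raw))
  } else {
    raw[[mapping$arm_column]]
  }

  scale <- severity_scale(
    name = mapping$response_column,
    levels = mapping$response_order,
    missing_level = missing_label
  )
  table <- observation_table(
    tibble::tibble(
      patient_id = raw[[mapping$id_column]],
      arm = arm,
      term = mapping$response_column,
      timepoint = time,
      level = resp
    ),
    scale = scale, stage_order = mapping$time_order
  )
  findings <- validate_table(table)
  dups <- findings[findings$invariant == "duplicate_key", , drop = FALSE]
  if (nrow(dups)) {
    if (strict) {
      stop("duplicate (patient, time point) records: ",
           paste(utils::head(dups$key, 3L), collapse = "; "),
           if (nrow(dups) > 3L) " ...", call. = FALSE)
    }
    table <- resolve_duplicates(table, mode = "lenient")
  }
  table
}

#' Canonical mapping under which a table round-trips through CSV
#' @param table An [observation_table()] holding a single term.
#' @return A [column_mapping()] whose response column is the term name and
#'   which carries the table's stage and level orderings.
#' @export
canonical_mapping <- function(table) {
  stopifnot(inherits(table, "observation_table"))
  term <- unique(table$data$term)
  if (length(term) > 1L) {
    stop("the custom schema holds one term per file; table has ",
         length(term), call. = FALSE)
  }
  if (length(term) == 0L) term <- table$scale$name
  column_mapping(
    id_column = "patient_id", time_column = "timepoint",
    response_column = term, time_order = table$stage_order,
    response_order = table$scale$levels, arm_column = "arm"
  )
}

#' Write an observation table in the custom upload schema
#'
#' Emits UTF-8 CSV (RFC-4180 quoting) with columns patient id, arm, time
#' point, and one response column headed by the term name, so that
#' `read_custom_table(path, canonical_mapping(table), missing_label)`
#' reproduces the table exactly.
#'
#' @param table A single-term [observation_table()] that validates.
#' @param path Output file path.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_custom_table <- function(table, path, delim = ",") {
  assert_valid_table(table)
  mapping <- canonical_mapping(table)
  d <- table$data
  out <- tibble::tibble(
    patient_id = d$patient_id,
    arm = d$arm,
    timepoint = d$timepoint
  )
  out[[mapping$response_column]] <- d$level
  ord <- order(out$arm, out$patient_id,
               match(out$timepoint, table$stage_order))
  out <- out[ord, , drop = FALSE]
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}

#' Serialize a column mapping (plus missing label) to a JSON config file
#' @param mapping A [column_mapping()].
#' @param path Output path.
#' @param missing_label Missing/off-treatment label stored alongside.
#' @return `path`, invisibly.
#' @export
write_mapping <- function(mapping, path, missing_label = "No Response") {
  stopifnot(inherits(mapping, "column_mapping"))
  x <- unclass(mapping)
  x$missing_label <- missing_label
  x <- x[!vapply(x, is.null, logical(1))]
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a column mapping config written by [write_mapping()]
#' @param path Config file path.
#' @return A list with elements `mapping` (a [column_mapping()]) and
#'   `missing_label`.
#' @export
read_mapping <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(
    mapping = column_mapping(
      id_column = x$id_column, time_column = x$time_column,
      response_column = x$response_column, time_order = x$time_order,
      response_order = x$response_order,
      arm_column = x$arm_column
    ),
    missing_label = if (is.null(x$missing_label)) "No Response"
                    else x$missing_label
  )
}

#' Structural equality of observation tables
#'
#' Two tables are equivalent when they agree on stage order, scale levels
#' and missing level, and contain the same observation records (row order
#' ignored). Scale display names and grade-value mappings are configuration
#' rather than data and are not compared.
#'
#' @param a,b [observation_table()]s.
#' @return `TRUE` or `FALSE`.
#' @export
tables_equivalent <- function(a, b) {
  stopifnot(inherits(a, "observation_table"), inherits(b, "observation_table"))
  if (!identical(a$stage_order, b$stage_order)) return(FALSE)
  if (!identical(a$scale$levels, b$scale$levels)) return(FALSE)
  if (!identical(a$scale$missing_level, b$scale$missing_level)) return(FALSE)
  key <- function(t) {
    d <- t$data
    sort(paste(d$patient_id, d$arm, d$term, d$timepoint, d$level, sep = "\r"))
  }
  identical(key(a), key(b))
}
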