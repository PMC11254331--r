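#' Cohort query: arm, term, initial severity, and a stage window
#'
#' Mirrors the explorer inputs: a treatment arm, a symptom/AE term, the
#' cohort's severity level at the initial time point, and the initial and
#' final time points of interest. The window must span at least two stages.
#'
#' @param arm Treatment arm label.
#' @param term Symptom/AE term label.
#' @param initial_level Severity level required at `start_stage`.
#' @param start_stage,end_stage Stage labels; `start_stage` must precede
#'   `end_stage` in the table's stage order.
#' @return An object of class `cohort_query`.
#' @export
cohort_query <- function(arm, term, initial_level, start_stage, end_stage) {
  structure(
    list(arm = arm, term = term, initial_level = initial_level,
         start_stage = start_stage, end_stage = end_stage),
    class = "cohort_query"
  )
}

#' Select the patients matching a cohort query
#'
#' Returns exactly the patients in the query's arm whose state for the term
#' at the start stage equals the initial level, with stages clipped to
#' `[start_stage, end_stage]`. Zero matching patients is an empty matrix,
#' not an error; unknown labels are errors.
#'
#' @param table An [observation_table()].
#' @param query A [cohort_query()].
#' @return A [trajectory_matrix()] over the clipped window.
#' @export
select_cohort <- function(table, query) {
  stopifnot(inherits(table, "observation_table"),
            inherits(query, "cohort_query"))
  i0 <- match(query$start_stage, table$stage_order)
  i1 <- match(query$end_stage, table$stage_order)
  if (is.na(i0) || is.na(i1)) {
    stop("unknown stage label: ",
         paste(c(query$start_stage, query$end_stage)[is.na(c(i0, i1))],
               collapse = ", "), call. = FALSE)
  }
  if (i0 >= i1) {
    stop("the window must span at least two stages: start_stage must ",
         "precede end_stage", call. = FALSE)
  }
  if (!(query$initial_level %in% scale_states(table$scale))) {
    stop("unknown severity level: ", query$initial_level, call. = FALSE)
  }
  stages <- table$stage_order[i0:i1]
  traj <- pivot_trajectories(table, query$term, query$arm, stages)
  keep <- traj$states[, 1L] == query$initial_level
  trajectory_matrix(traj$states[keep, , drop = FALSE], stages, table$scale,
                    patient_ids = traj$patient_ids[keep])
}

#' Plain-language summary of the cohort's final states
#'
#' Tallies the last-stage states of a cohort and renders a statement of the
#' form "Of the initial N patients, k1 (p1%) were <state1>, ...". Percents
#' are whole numbers (nearest integer, halves away from zero) with the
#' initial cohort size as denominator — patients off treatment by the final
#' stage remain in the denominator — and are not force-balanced to 100.
#' Categories are listed in descending count order, ties broken most severe
#' first.
#'
#' @param trajectories A [trajectory_matrix()] with at least one patient.
#' @return An object of class `final_state_summary` with elements
#'   `cohort_size`, `counts`, `percents` (named integer vectors over the
#'   observed final states), and `statement`.
#' @export
final_state_summary <- function(trajectories) {
  stopifnot(inherits(trajectories, "trajectory_matrix"))
  n <- length(trajectories$patient_ids)
  if (n == 0L) {
    stop("at least one patient is required", call. = FALSE)
  }
  scale <- trajectories$scale
  final <- trajectories$states[, ncol(trajectories$states)]
  severity_rank <- c(rev(scale$levels), scale$missing_level)
  tab <- table(factor(final, levels = severity_rank))
  tab <- tab[tab > 0]
  ord <- order(-as.integer(tab), match(names(tab), severity_rank))
  counts <- stats::setNames(as.integer(tab)[ord], names(tab)[ord])
  percents <- stats::setNames(
    as.integer(round_half_up(100 * counts / n)), names(counts))
  describe <- function(state) {
    if (state == scale$missing_level) tolower(state)
    else if (state %in% as.character(0:5) || grepl("^[0-9]-[0-9]$", state)) {
      paste("at grade", state)
    } else paste0('"', state, '"')
  }
  parts <- sprintf("%d (%d%%) were %s", counts, percents,
                   vapply(names(counts), describe, character(1)))
  body <- if (length(parts) == 1L) parts else
    paste0(paste(parts[-length(parts)], collapse = ", "), " and ",
           parts[length(parts)])
  statement <- sprintf(
    "Of the initial %d patients, by the final time point (%s), %s.",
    n, trajectories$stages[length(trajectories$stages)], body)
  structure(
    list(cohort_size = n, counts = counts, percents = percents,
         statement = statement),
    class = "final_state_summary"
  )
}

#' @export
print.final_state_summary <- function(x, ...) {
  cat(x$statement, "\n")
  invisible(x)
}

#' Serialize a final-state summary to JSON
#' @param x A `final_state_summary`.
#' @param path Optional output file; if `NULL`, the JSON string is returned.
#' @return JSON string, or `path` invisibly when writing.
#' @export
final_state_summary_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "final_state_summary"))
  obj <- list(cohort_size = x$cohort_size, counts = as.list(x$counts),
              percents = as.list(x$percents), statement = x$statement)
  if (is.null(path)) {
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Distribution of each grade's occurrences across the stage window
#'
#' For each state, the row-normalised distribution over stages of the
#' patient-stage cells equal to that state: the denominator is the total
#' number of cells at that state across the window, so a patient at grade 3
#' in two cycles contributes two grade-3 cases. Percents are whole numbers
#' (halves away from zero); unrounded proportions sum exactly to 1 per
#' state. The missing/off-treatment category is excluded by default.
#'
#' @param trajectories A [trajectory_matrix()] with at least one patient.
#' @param include_missing Include the missing-level row? Default `FALSE`.
#' @return A tibble with columns `state`, `stage`, `count`, `prop`,
#'   `percent`, covering the states observed in the window.
#' @export
grade_duration <- function(trajectories, include_missing = FALSE) {
  stopifnot(inherits(trajectories, "trajectory_matrix"))
  if (length(trajectories$patient_ids) == 0L) {
    stop("at least one patient is required", call. = FALSE)
  }
  scale <- trajectories$scale
  states <- if (include_missing) scale_states(scale) else scale$levels
  st <- trajectories$states
  rows <- list()
  for (g in states) {
    counts <- vapply(seq_along(trajectories$stages), function(s) {
      sum(st[, s] == g)
    }, integer(1))
    tot <- sum(counts)
    if (tot == 0L) next
    rows[[length(rows) + 1L]] <- tibble::tibble(
      state = g, stage = trajectories$stages, count = counts,
      prop = counts / tot,
      percent = as.integer(round_half_up(100 * counts / tot))
    )
  }
  if (!length(rows)) {
    return(tibble::tibble(state = character(), stage = character(),
                          count = integer(), prop = numeric(),
                          percent = integer()))
  }
  dplyr::bind_rows(rows)
}

#' Serialize a grade-duration table to JSON (state -> stage -> percent)
#' @param gd A [grade_duration()] tibble.
#' @param path Optional output file; if `NULL`, the JSON string is returned.
#' @return JSON string, or `path` invisibly when writing.
#' @export
grade_duration_json <- function(gd, path = NULL) {
  states <- unique(gd$state)
  obj <- lapply(stats::setNames(states, states), function(g) {
    sub <- gd[gd$state == g, ]
    as.list(stats::setNames(sub$percent, sub$stage))
  })
  if (is.null(path)) {
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
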