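#' Canonical long-format store of tolerability observations
#'
#' One row per (patient, term, timepoint) holding that patient's severity
#' level for the given symptom/AE term at that stage. A table is governed by
#' a single [severity_scale()] and an explicit ordering of its timepoint
#' labels; stage labels are opaque ordered strings (the 6-month grid of a
#' typical phase III schedule is a preset, not an assumption).
#'
#' @param observations Data frame with character columns `patient_id`,
#'   `arm`, `term`, `timepoint`, `level`.
#' @param scale The governing [severity_scale()].
#' @param stage_order Character vector of timepoint labels in temporal order.
#' @return An object of class `observation_table` with elements `data`
#'   (a tibble), `scale`, and `stage_order`.
#' @export
observation_table <- function(observations, scale, stage_order) {
  stopifnot(inherits(scale, "severity_scale"))
  stage_order <- as.character(stage_order)
  if (length(stage_order) == 0L || anyDuplicated(stage_order)) {
    stop("`stage_order` must be non-empty and unique", call. = FALSE)
  }
  cols <- c("patient_id", "arm", "term", "timepoint", "level")
  if (!all(cols %in% names(observations))) {
    stop("observations must have columns ",
         paste(cols, collapse = ", "), call. = FALSE)
  }
  data <- tibble::as_tibble(observations)[cols]
  data[] <- lapply(data, as.character)
  structure(
    list(data = data, scale = scale, stage_order = stage_order),
    class = "observation_table"
  )
}

#' @export
print.observation_table <- function(x, ...) {
  cat("<observation_table> ", nrow(x$data), " observations | scale: ",
      x$scale$name, " | ", length(x$stage_order), " stages\n", sep = "")
  cat("  arms: ", paste(sort(unique(x$data$arm)), collapse = ", "), "\n",
      sep = "")
  cat("  terms: ", paste(sort(unique(x$data$term)), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Validate an observation table against its invariants
#'
#' Findings are data, not exceptions: each row names the violated invariant
#' and the offending record key. An empty result means all invariants hold.
#' Checked invariants: every level belongs to the scale (levels plus the
#' missing level), every timepoint belongs to `stage_order`, and there is at
#' most one observation per (patient, term, timepoint). With
#' `check_absorbing = TRUE` an observed missing-level record followed by a
#' later non-missing record for the same patient and term is flagged with
#' severity "warning" (whether off-treatment is absorbing is trial policy,
#' not a structural requirement).
#'
#' @param table An [observation_table()].
#' @param check_absorbing Also flag non-absorbing missing-level sequences?
#' @return A tibble with columns `invariant`, `key`, `message`, `severity`;
#'   zero rows iff the table is valid.
#' @seealso [assert_valid_table()] for the strict wrapper.
#' @export
validate_table <- function(table, check_absorbing = FALSE) {
  stopifnot(inherits(table, "observation_table"))
  d <- table$data
  states <- scale_states(table$scale)
  findings <- list()

  bad_lvl <- which(!(d$level %in% states))
  for (i in bad_lvl) {
    findings[[length(findings) + 1L]] <- tibble::tibble(
      invariant = "unknown_level",
      key = paste(d$patient_id[i], d$term[i], d$timepoint[i], sep = "/"),
      message = paste0("level '", d$level[i], "' is not on scale '",
                       table$scale$name, "'"),
      severity = "error"
    )
  }

  bad_tp <- which(!(d$timepoint %in% table$stage_order))
  for (i in bad_tp) {
    findings[[length(findings) + 1L]] <- tibble::tibble(
      invariant = "unknown_timepoint",
      key = paste(d$patient_id[i], d$term[i], d$timepoint[i], sep = "/"),
      message = paste0("timepoint '", d$timepoint[i],
                       "' is not in stage_order"),
      severity = "error"
    )
  }

  key <- paste(d$patient_id, d$term, d$timepoint, sep = "/")
  dup <- unique(key[duplicated(key)])
  for (k in dup) {
    findings[[length(findings) + 1L]] <- tibble::tibble(
      invariant = "duplicate_key",
      key = k,
      message = paste0(sum(key == k), " observations share key (patient_id",
                       ", term, timepoint) = (", k, ")"),
      severity = "error"
    )
  }

  if (isTRUE(check_absorbing) && nrow(d) > 0L) {
    pos <- match(d$timepoint, table$stage_order)
    miss <- d$level == table$scale$missing_level
    split_idx <- split(seq_len(nrow(d)), paste(d$patient_id, d$term, sep = "/"))
    for (k in names(split_idx)) {
      idx <- split_idx[[k]]
      m_pos <- pos[idx][miss[idx]]
      o_pos <- pos[idx][!miss[idx]]
      if (length(m_pos) && length(o_pos) && any(o_pos > min(m_pos))) {
        findings[[length(findings) + 1L]] <- tibble::tibble(
          invariant = "nonabsorbing_missing",
          key = k,
          message = paste0("'", table$scale$missing_level,
                           "' at an earlier stage is followed by an on-study",
                           " observation"),
          severity = "warning"
        )
      }
    }
  }

  if (length(findings) == 0L) {
    return(tibble::tibble(invariant = character(), key = character(),
                          message = character(), severity = character()))
  }
  dplyr::bind_rows(findings)
}

#' Strict validation wrapper: raise on any error-severity finding
#' @inheritParams validate_table
#' @return The table, invisibly, if valid.
#' @export
assert_valid_table <- function(table, check_absorbing = FALSE) {
  f <- validate_table(table, check_absorbing = check_absorbing)
  errs <- f[f$severity == "error", , drop = FALSE]
  if (nrow(errs) > 0L) {
    stop("invalid observation table: ",
         paste(utils::head(errs$message, 5L), collapse = "; "),
         if (nrow(errs) > 5L) paste0(" (+", nrow(errs) - 5L, " more)"),
         call. = FALSE)
  }
  invisible(table)
}

#' Resolve duplicate (patient, term, timepoint) records
#'
#' Trial extracts commonly contain repeated assessments. In `"strict"` mode
#' duplicates are an error; in `"lenient"` mode each duplicated key is
#' resolved to its most severe level (missing ranks below every severity
#' level) with a warning stating how many records were dropped.
#'
#' @param table An [observation_table()].
#' @param mode `"strict"` (default) or `"lenient"`.
#' @return A deduplicated `observation_table`.
#' @export
resolve_duplicates <- function(table, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "observation_table"))
  d <- table$data
  key <- paste(d$patient_id, d$term, d$timepoint, sep = "/")
  if (!anyDuplicated(key)) return(table)
  if (mode == "strict") {
    stop("duplicate (patient_id, term, timepoint) records present; ",
         "use mode = \"lenient\" to keep the most severe level",
         call. = FALSE)
  }
  sev <- match(d$level, c(table$scale$missing_level, table$scale$levels))
  ord <- order(key, -sev)
  keep <- ord[!duplicated(key[ord])]
  n_drop <- nrow(d) - length(keep)
  warning(n_drop, " duplicate record(s) resolved to the most severe level",
          call. = FALSE)
  observation_table(d[sort(keep), , drop = FALSE], table$scale,
                    table$stage_order)
}

#' Per-patient state sequences over an ordered stage window
#'
#' A rectangular matrix of level labels: one row per patient, one column per
#' stage. Every state is a scale level or the scale's missing level.
#'
#' @param states Character matrix of states (patients x stages).
#' @param stages Character vector of stage labels (column order).
#' @param scale The governing [severity_scale()].
#' @param patient_ids Row labels; defaults to existing rownames.
#' @return An object of class `trajectory_matrix`.
#' @export
trajectory_matrix <- function(states, stages, scale,
                              patient_ids = rownames(states)) {
  stopifnot(inherits(scale, "severity_scale"))
  states <- as.matrix(states)
  stages <- as.character(stages)
  if (ncol(states) != length(stages)) {
    stop("`states` must have one column per stage", call. = FALSE)
  }
  if (nrow(states) > 0L) {
    bad <- setdiff(unique(as.vector(states)), scale_states(scale))
    if (length(bad)) {
      stop("states not on the scale: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  if (is.null(patient_ids)) patient_ids <- as.character(seq_len(nrow(states)))
  stopifnot(length(patient_ids) == nrow(states))
  dimnames(states) <- list(patient_ids, stages)
  structure(
    list(patient_ids = as.character(patient_ids), stages = stages,
         states = states, scale = scale),
    class = "trajectory_matrix"
  )
}

#' @export
print.trajectory_matrix <- function(x, ...) {
  cat("<trajectory_matrix> ", length(x$patient_ids), " patients x ",
      length(x$stages), " stages | scale: ", x$scale$name, "\n", sep = "")
  if (length(x$patient_ids)) {
    print(utils::head(x$states, 6L))
    if (length(x$patient_ids) > 6L) cat("  ...\n")
  }
  invisible(x)
}

#' Pivot long observations into per-patient trajectories
#'
#' Selects the records of one term in one arm over a contiguous stage window
#' and lays them out as a rectangular patient-by-stage state matrix. A
#' patient contributes a row iff they have at least one observation for the
#' term within the window; any absent (patient, stage) cell is filled with
#' the scale's missing level ("Off Treatment" for AE scales, "No Response"
#' for PRO scales).
#'
#' @param table An [observation_table()].
#' @param term Symptom/AE term label.
#' @param arm Treatment arm label.
#' @param stages Contiguous sublist of `table$stage_order`; defaults to the
#'   full stage order.
#' @return A [trajectory_matrix()] with rows sorted by patient id.
#' @export
pivot_trajectories <- function(table, term, arm,
                               stages = table$stage_order) {
  stopifnot(inherits(table, "observation_table"))
  stages <- as.character(stages)
  if (length(stages) == 0L) {
    stop("`stages` must be a non-empty stage window", call. = FALSE)
  }
  pos <- match(stages, table$stage_order)
  if (anyNA(pos)) {
    stop("unknown stage label(s): ",
         paste(stages[is.na(pos)], collapse = ", "), call. = FALSE)
  }
  if (length(pos) > 1L && any(diff(pos) != 1L)) {
    stop("`stages` must be a contiguous, ordered sublist of stage_order",
         call. = FALSE)
  }
  d <- table$data
  if (!any(d$term == term)) {
    stop("no matching records: term '", term, "' does not occur in the table",
         call. = FALSE)
  }
  if (!any(d$arm == arm)) {
    stop("no matching records: arm '", arm, "' does not occur in the table",
         call. = FALSE)
  }
  d <- d[d$term == term & d$arm == arm & d$timepoint %in% stages, ,
         drop = FALSE]
  patients <- sort(unique(d$patient_id))
  m <- matrix(table$scale$missing_level, nrow = length(patients),
              ncol = length(stages), dimnames = list(patients, stages))
  if (nrow(d) > 0L) {
    m[cbind(match(d$patient_id, patients), match(d$timepoint, stages))] <-
      d$level
  }
  trajectory_matrix(m, stages, table$scale, patient_ids = patients)
}
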