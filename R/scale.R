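#' Ordered severity scales
#'
#' A severity scale is an ordered categorical scale used to grade adverse
#' events or patient-reported symptom bother. Levels run from least to most
#' severe, and a designated `missing_level` (e.g. "Off Treatment" for CTCAE
#' data, "No Response" for PRO data) represents absent or off-treatment
#' observations. It is appended as an extra terminal display category and is
#' never itself a severity level.
#'
#' Scales that support the Toxicity Index additionally carry `grade_values`,
#' a mapping from each level to a numeric grade in `[0, 5]`, non-decreasing
#' along the level order.
#'
#' @param name Short label for the scale (e.g. "CTCAE").
#' @param levels Character vector of level labels, least to most severe.
#' @param missing_level Label for absent/off-treatment observations.
#' @param grade_values Optional named numeric vector mapping every level to a
#'   finite grade `>= 0`, non-decreasing along `levels`.
#' @return An object of class `severity_scale`.
#' @examples
#' severity_scale("CTCAE", as.character(0:5), "Off Treatment",
#'                grade_values = stats::setNames(0:5, as.character(0:5)))
#' @export
severity_scale <- function(name, levels, missing_level, grade_values = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  levels <- as.character(levels)
  if (length(levels) == 0L) {
    stop("`levels` must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(levels)) {
    stop("`levels` must be unique", call. = FALSE)
  }
  stopifnot(is.character(missing_level), length(missing_level) == 1L)
  if (missing_level %in% levels) {
    stop("`missing_level` must not be among `levels`", call. = FALSE)
  }
  if (!is.null(grade_values)) {
    if (is.null(names(grade_values)) || !setequal(names(grade_values), levels)) {
      stop("`grade_values` must name every level exactly once", call. = FALSE)
    }
    grade_values <- grade_values[levels]
    if (!all(is.finite(grade_values)) || any(grade_values < 0)) {
      stop("`grade_values` must be finite and >= 0", call. = FALSE)
    }
    if (is.unsorted(grade_values)) {
      stop("`grade_values` must be non-decreasing along the level order",
           call. = FALSE)
    }
  }
  structure(
    list(name = name, levels = levels, missing_level = missing_level,
         grade_values = grade_values),
    class = "severity_scale"
  )
}

#' All states of a scale: its levels plus the missing/off-treatment category
#' @param scale A [severity_scale()].
#' @return Character vector, levels first then `missing_level`.
#' @export
scale_states <- function(scale) {
  stopifnot(inherits(scale, "severity_scale"))
  c(scale$levels, scale$missing_level)
}

#' @export
print.severity_scale <- function(x, ...) {
  cat("<severity_scale> ", x$name, "\n", sep = "")
  cat("  levels (least -> most severe): ", paste(x$levels, collapse = " < "),
      "\n", sep = "")
  cat("  missing level: ", x$missing_level, "\n", sep = "")
  if (!is.null(x$grade_values)) {
    cat("  grades: ", paste(x$grade_values, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' CTCAE adverse-event scale with raw grades 0-5
#'
#' Raw grades are stored so the Toxicity Index can use them; the common
#' "0-1" display bin is applied at flow/summary time via
#' [collapse_levels()] with [ctcae_display_bins()].
#'
#' @return A `severity_scale` with levels "0".."5", grades 0..5, and
#'   missing level "Off Treatment".
#' @export
ctcae_scale <- function() {
  severity_scale(
    name = "CTCAE",
    levels = as.character(0:5),
    missing_level = "Off Treatment",
    grade_values = stats::setNames(as.numeric(0:5), as.character(0:5))
  )
}

#' Display binning that merges CTCAE grades 0 and 1 into "0-1"
#' @return Named list mapping display bins to raw levels, for
#'   [collapse_levels()].
#' @export
ctcae_display_bins <- function() {
  list(`0-1` = c("0", "1"))
}

#' BCPT symptom-checklist bother scale
#'
#' Five ordinal bother levels with "No Response" as the missing category.
#' No grade values are attached by default; pass `grades = TRUE` for a
#' 0-4 mapping if a Toxicity Index over PRO levels is wanted.
#'
#' @param grades Attach a 0-4 grade mapping? Default `FALSE`.
#' @return A `severity_scale`.
#' @export
bcpt_scale <- function(grades = FALSE) {
  lv <- c("Not at all", "Slightly", "Moderately", "Quite a bit", "Extremely")
  gv <- if (isTRUE(grades)) stats::setNames(as.numeric(0:4), lv) else NULL
  severity_scale("BCPT", lv, "No Response", grade_values = gv)
}

#' Collapse scale levels into display bins
#'
#' Rewrites the states of a trajectory matrix through a binning such as
#' [ctcae_display_bins()], producing a new matrix governed by the coarser
#' display scale. Grade values do not survive binning (the Toxicity Index is
#' computed on raw grades, before display binning).
#'
#' @param trajectories A [trajectory_matrix()].
#' @param bins Named list: each element is a character vector of consecutive
#'   raw levels to merge, named by the display label.
#' @return A new `trajectory_matrix` on the binned scale.
#' @export
collapse_levels <- function(trajectories, bins = ctcae_display_bins()) {
  stopifnot(inherits(trajectories, "trajectory_matrix"))
  scale <- trajectories$scale
  mapping <- stats::setNames(scale$levels, scale$levels)
  new_levels <- scale$levels
  for (lab in names(bins)) {
    members <- bins[[lab]]
    if (!all(members %in% scale$levels)) {
      stop("bin '", lab, "' refers to levels not on the scale", call. = FALSE)
    }
    idx <- match(members, new_levels)
    idx <- idx[!is.na(idx)]
    if (any(diff(sort(idx)) != 1L)) {
      stop("bin '", lab, "' must merge consecutive levels", call. = FALSE)
    }
    new_levels[sort(idx)[1]] <- lab
    new_levels <- new_levels[-sort(idx)[-1]]
    mapping[members] <- lab
  }
  new_scale <- severity_scale(scale$name, new_levels, scale$missing_level)
  states <- trajectories$states
  non_missing <- states != scale$missing_level
  states[non_missing] <- mapping[states[non_missing]]
  trajectory_matrix(states, trajectories$stages, new_scale,
                    patient_ids = trajectories$patient_ids)
}
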