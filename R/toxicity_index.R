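#' Toxicity Index of a grade profile
#'
#' The Toxicity Index (TI) condenses a patient's multiset of per-cycle
#' toxicity grades into a single order-preserving severity score. With the
#' grades sorted in descending order \eqn{w_{(1)} \ge w_{(2)} \ge \dots \ge
#' w_{(n)}},
#' \deqn{TI = \sum_{i=1}^{n} w_{(i)} \prod_{j<i} (1 + w_{(j)})^{-1},}
#' so the leading term is the maximum grade and every further grade adds a
#' strictly smaller correction. Consequences: the TI of a non-empty profile
#' with maximum grade \eqn{m > 0} lies in \eqn{[m, m+1)}; profiles with a
#' higher maximum grade always outrank profiles with a lower one; for CTCAE
#' grades in `[0, 5]` the TI lies in `[0, 6)`. The value is invariant to the
#' input order and unchanged by appending zeros.
#'
#' @param grades Numeric vector of grades, each finite and in `[0, 5]`.
#'   One grade per assessed cycle of the selected term within the selected
#'   window; missing/off-treatment cycles contribute no grade. May be empty.
#' @return A single number: 0 for empty or all-zero profiles, otherwise a
#'   value in `[max(grades), max(grades) + 1)`.
#' @examples
#' toxicity_index(c(3, 2))    # 3 + 2/(1+3) = 3.5
#' toxicity_index(c(3, 3, 2)) # 3 + 3/4 + 2/16 = 3.875
#' @export
toxicity_index <- function(grades) {
  grades <- as.numeric(grades)
  if (length(grades) == 0L) return(0)
  if (!all(is.finite(grades)) || any(grades < 0) || any(grades > 5)) {
    stop("grades must be finite and in [0, 5]", call. = FALSE)
  }
  w <- sort(grades, decreasing = TRUE)
  denom <- c(1, cumprod(1 + w)[-length(w)])
  sum(w / denom)
}

#' Per-patient grade profiles of a trajectory cohort
#'
#' Maps each patient's non-missing states through the scale's grade values.
#' Missing/off-treatment cycles are skipped, not imputed as grade 0.
#'
#' @param trajectories A [trajectory_matrix()].
#' @param scale A [severity_scale()] with `grade_values`; defaults to the
#'   matrix's own scale.
#' @return Named list of numeric grade vectors, one per patient.
#' @export
grade_profiles <- function(trajectories, scale = trajectories$scale) {
  stopifnot(inherits(trajectories, "trajectory_matrix"))
  if (is.null(scale$grade_values)) {
    stop("scale '", scale$name, "' has no grade_values; the Toxicity Index ",
         "needs a numeric grade per level", call. = FALSE)
  }
  lapply(stats::setNames(trajectories$patient_ids, trajectories$patient_ids),
         function(p) {
    s <- trajectories$states[p, ]
    s <- s[s != scale$missing_level]
    unname(scale$grade_values[s])
  })
}

#' Toxicity Index distribution over a cohort
#'
#' Computes one TI value per patient from that patient's non-missing states
#' (mapped through the scale's grade values), then summarises the
#' distribution: mean, sample standard deviation (n-1 denominator; reported
#' as `NA` for a single patient, never 0), median, quartiles, and a
#' fixed-bin histogram over the TI range `[0, 6)`.
#'
#' @param trajectories A non-empty [trajectory_matrix()].
#' @param scale A [severity_scale()] with `grade_values`; defaults to the
#'   matrix's own scale.
#' @param bin_width Histogram bin width over `[0, 6)`; default 0.5.
#' @param quantile_type Quartile convention passed to [stats::quantile()];
#'   default 7 (linear interpolation between order statistics).
#' @return An object of class `ti_summary` with elements `values`, `mean`,
#'   `sd`, `median`, `q1`, `q3`, `bin_edges`, `bin_counts`.
#' @export
cohort_ti_summary <- function(trajectories, scale = trajectories$scale,
                              bin_width = 0.5, quantile_type = 7) {
  stopifnot(inherits(trajectories, "trajectory_matrix"))
  if (length(trajectories$patient_ids) == 0L) {
    stop("trajectories must contain at least one patient", call. = FALSE)
  }
  profiles <- grade_profiles(trajectories, scale)
  values <- vapply(profiles, toxicity_index, numeric(1))
  qs <- stats::quantile(values, probs = c(0.25, 0.5, 0.75),
                        type = quantile_type, names = FALSE)
  edges <- seq(0, 6, by = bin_width)
  counts <- as.integer(
    table(cut(values, breaks = edges, include.lowest = TRUE, right = FALSE))
  )
  structure(
    list(values = unname(values), patient_ids = names(values),
         mean = mean(values),
         sd = if (length(values) > 1L) stats::sd(values) else NA_real_,
         median = qs[2], q1 = qs[1], q3 = qs[3],
         bin_edges = edges, bin_counts = counts),
    class = "ti_summary"
  )
}

#' @export
print.ti_summary <- function(x, ...) {
  cat("<ti_summary> n = ", length(x$values), "\n", sep = "")
  cat(sprintf("  mean (SD): %.2f (%s)\n", x$mean,
              if (is.na(x$sd)) "NA" else sprintf("%.2f", x$sd)))
  cat(sprintf("  median [IQR]: %.2f [%.2f-%.2f]\n", x$median, x$q1, x$q3))
  invisible(x)
}

#' Serialize a TI summary to JSON
#' @param x A `ti_summary`.
#' @param path Optional output file; if `NULL`, the JSON string is returned.
#' @return JSON string, or `path` invisibly when writing.
#' @export
ti_summary_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "ti_summary"))
  obj <- list(values = x$values, mean = x$mean, sd = x$sd,
              median = x$median, q1 = x$q1, q3 = x$q3,
              bin_edges = x$bin_edges, bin_counts = x$bin_counts)
  if (is.null(path)) {
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null"))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
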