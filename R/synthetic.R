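#' First-order Markov specification of a synthetic tolerability trial
#'
#' Defines the generative model for synthetic trial extracts: per-arm
#' initial state distributions and per-arm stochastic transition matrices
#' over the scale's states (levels plus the missing/off-treatment level),
#' stepped over an ordered stage grid. With `dropout_absorbing = TRUE`
#' (default), once a patient reaches the missing level they remain there —
#' the missing-level row of every transition matrix must be the unit vector
#' on the missing level.
#'
#' @param scale A [severity_scale()].
#' @param arms Character vector of arm labels.
#' @param initial_dist Named list (one element per arm) of probability
#'   vectors over `scale_states(scale)`; a single vector is recycled to all
#'   arms. Each must be non-negative and sum to 1 within 1e-9.
#' @param transition Named list (one per arm) of row-stochastic matrices
#'   over `scale_states(scale)`; a single matrix is recycled.
#' @param stages Ordered stage labels (at least 2).
#' @param dropout_absorbing Enforce absorbing dropout? Default `TRUE`.
#' @return An object of class `markov_spec`.
#' @export
markov_spec <- function(scale, arms, initial_dist, transition, stages,
                        dropout_absorbing = TRUE) {
  stopifnot(inherits(scale, "severity_scale"))
  arms <- as.character(arms)
  if (length(arms) == 0L || anyDuplicated(arms)) {
    stop("`arms` must be non-empty and unique", call. = FALSE)
  }
  stages <- as.character(stages)
  if (length(stages) < 2L || anyDuplicated(stages)) {
    stop("`stages` must hold at least two unique labels", call. = FALSE)
  }
  states <- scale_states(scale)
  K <- length(states)

  normalize_per_arm <- function(x, what) {
    if (!is.list(x)) x <- stats::setNames(rep(list(x), length(arms)), arms)
    if (!setequal(names(x), arms)) {
      stop("`", what, "` must be named by arm", call. = FALSE)
    }
    x[arms]
  }
  initial_dist <- normalize_per_arm(initial_dist, "initial_dist")
  transition <- normalize_per_arm(transition, "transition")

  check_prob <- function(p, what) {
    if (length(p) != K) {
      stop(what, " must have one entry per state (", K, ")", call. = FALSE)
    }
    if (!is.null(names(p)) && !identical(names(p), states)) p <- p[states]
    if (any(!is.finite(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop(what, " must be a probability vector summing to 1", call. = FALSE)
    }
    stats::setNames(as.numeric(p), states)
  }
  for (a in arms) {
    initial_dist[[a]] <- check_prob(initial_dist[[a]],
                                    paste0("initial_dist[", a, "]"))
    m <- as.matrix(transition[[a]])
    if (!all(dim(m) == K)) {
      stop("transition[", a, "] must be ", K, "x", K, call. = FALSE)
    }
    if (!is.null(rownames(m))) m <- m[states, states]
    for (k in seq_len(K)) {
      m[k, ] <- check_prob(m[k, ], paste0("transition[", a, "] row ",
                                          states[k]))
    }
    dimnames(m) <- list(states, states)
    if (isTRUE(dropout_absorbing)) {
      miss <- scale$missing_level
      unit <- stats::setNames(as.numeric(states == miss), states)
      if (!isTRUE(all.equal(unname(m[miss, ]), unname(unit),
                            tolerance = 1e-12))) {
        stop("dropout_absorbing = TRUE requires the '", miss,
             "' row to be the unit vector on itself", call. = FALSE)
      }
    }
    transition[[a]] <- m
  }
  structure(
    list(scale = scale, arms = arms, initial_dist = initial_dist,
         transition = transition, stages = stages,
         dropout_absorbing = isTRUE(dropout_absorbing)),
    class = "markov_spec"
  )
}

# Ordinal transition kernel: from each severity level, probability mass is
# split between staying, moving one level down (improvement), one level up
# (worsening), and dropping out to the missing level; boundary mass folds
# into staying. The top level (e.g. CTCAE grade 5, death) routes entirely
# off treatment, and the missing level is absorbing.
ordinal_kernel <- function(scale, stay, improve, worsen, dropout,
                           top_exits = TRUE) {
  states <- scale_states(scale)
  K <- length(states)
  n_lv <- length(scale$levels)
  m <- matrix(0, K, K, dimnames = list(states, states))
  for (i in seq_len(n_lv)) {
    if (top_exits && i == n_lv && n_lv > 1L) {
      m[i, K] <- 1
      next
    }
    p_stay <- stay
    p_down <- if (i > 1L) improve else 0
    p_up <- if (i < n_lv) worsen else 0
    p_stay <- p_stay + (improve - p_down) + (worsen - p_up)
    m[i, i] <- p_stay
    if (i > 1L) m[i, i - 1L] <- p_down
    if (i < n_lv) m[i, i + 1L] <- p_up
    m[i, K] <- dropout
    m[i, ] <- m[i, ] / sum(m[i, ])
  }
  m[K, K] <- 1
  m
}

#' CTCAE-like two-arm preset on a 6-to-60-month grid
#'
#' Two arms assessed every 6 months for 10 cycles on raw CTCAE grades 0-5
#' with absorbing "Off Treatment". Symptoms are mostly low grade at the
#' first cycle, tend to improve by one grade per cycle more often than they
#' worsen, and carry a roughly 6 percent per-cycle dropout hazard; grade 5
#' exits the study.
#'
#' @return A [markov_spec()].
#' @export
preset_b35 <- function() {
  scale <- ctcae_scale()
  stages <- paste(seq(6L, 60L, by = 6L), "mo")
  arms <- c("Anastrozole", "Tamoxifen")
  init <- list(
    Anastrozole = c(`0` = 0.42, `1` = 0.30, `2` = 0.17, `3` = 0.08,
                    `4` = 0.02, `5` = 0.01, `Off Treatment` = 0),
    Tamoxifen = c(`0` = 0.50, `1` = 0.29, `2` = 0.13, `3` = 0.06,
                  `4` = 0.015, `5` = 0.005, `Off Treatment` = 0)
  )
  trans <- list(
    Anastrozole = ordinal_kernel(scale, stay = 0.55, improve = 0.24,
                                 worsen = 0.15, dropout = 0.06),
    Tamoxifen = ordinal_kernel(scale, stay = 0.55, improve = 0.27,
                               worsen = 0.12, dropout = 0.06)
  )
  markov_spec(scale, arms, init, trans, stages)
}

#' BCPT-like three-arm PRO preset from baseline to 24 months
#'
#' Three chemotherapy arms with symptom bother reported at baseline, day 1
#' of cycle 4, and 6-month intervals to 24 months, on the five-level bother
#' scale with absorbing "No Response". Bother rises during treatment and
#' settles afterwards; a 5 percent per-interval non-response hazard applies.
#'
#' @return A [markov_spec()].
#' @export
preset_b30 <- function() {
  scale <- bcpt_scale(grades = TRUE)
  stages <- c("Baseline", "Cycle 4 Day 1", "6-month follow-up",
              "12-month follow-up", "18-month follow-up",
              "24-month follow-up")
  arms <- c("Sequential ACT", "AT", "Concurrent ACT")
  base_init <- c("Not at all" = 0.55, "Slightly" = 0.25, "Moderately" = 0.12,
                 "Quite a bit" = 0.06, "Extremely" = 0.02, "No Response" = 0)
  trans <- list(
    `Sequential ACT` = ordinal_kernel(scale, stay = 0.50, improve = 0.22,
                                      worsen = 0.23, dropout = 0.05,
                                      top_exits = FALSE),
    AT = ordinal_kernel(scale, stay = 0.50, improve = 0.25, worsen = 0.20,
                        dropout = 0.05, top_exits = FALSE),
    `Concurrent ACT` = ordinal_kernel(scale, stay = 0.48, improve = 0.21,
                                      worsen = 0.26, dropout = 0.05,
                                      top_exits = FALSE)
  )
  markov_spec(scale, arms, base_init, trans, stages)
}

#' Simulate a synthetic trial extract
#'
#' Draws `n_per_arm` patients per arm; each patient's state sequence is a
#' first-order Markov chain started from the arm's initial distribution and
#' stepped through the arm's transition matrix across the stage grid.
#' Stages where the state is the missing level produce no stored
#' observation (exercising the downstream fill rule). Identical
#' `(spec, n_per_arm, term, seed)` give identical tables; the caller's RNG
#' stream is left untouched.
#'
#' @param spec A [markov_spec()].
#' @param n_per_arm Patients per arm (>= 1).
#' @param term Symptom/AE term label recorded on every observation.
#' @param seed Integer seed.
#' @return An [observation_table()].
#' @export
simulate_trial <- function(spec, n_per_arm, term = "Synthetic term",
                           seed = 1L) {
  stopifnot(inherits(spec, "markov_spec"))
  n_per_arm <- as.integer(n_per_arm)
  if (is.na(n_per_arm) || n_per_arm < 1L) {
    stop("`n_per_arm` must be a positive integer", call. = FALSE)
  }
  states <- scale_states(spec$scale)
  K <- length(states)
  S <- length(spec$stages)
  with_seed(seed, {
    pieces <- vector("list", length(spec$arms))
    for (ai in seq_along(spec$arms)) {
      arm <- spec$arms[ai]
      ids <- sprintf("A%d-%04d", ai, seq_len(n_per_arm))
      path <- matrix(0L, n_per_arm, S)
      path[, 1L] <- sample.int(K, n_per_arm, replace = TRUE,
                               prob = spec$initial_dist[[arm]])
      tr <- spec$transition[[arm]]
      for (s in seq_len(S - 1L)) {
        cur <- path[, s]
        nxt <- integer(n_per_arm)
        for (k in sort(unique(cur))) {
          idx <- which(cur == k)
          nxt[idx] <- sample.int(K, length(idx), replace = TRUE,
                                 prob = tr[k, ])
        }
        path[, s + 1L] <- nxt
      }
      # missing-level cells produce no stored observation
      keep <- which(states[path] != spec$scale$missing_level)
      keep <- arrayInd(keep, dim(path))
      pieces[[ai]] <- tibble::tibble(
        patient_id = ids[keep[, 1L]],
        arm = arm,
        term = term,
        timepoint = spec$stages[keep[, 2L]],
        level = states[path[keep]]
      )
    }
    d <- dplyr::bind_rows(pieces)
    d <- d[order(d$arm, d$patient_id, match(d$timepoint, spec$stages)), ]
    observation_table(d, spec$scale, spec$stages)
  })
}

#' Estimate the transition matrix from observed trajectories
#'
#' Row-normalised consecutive-stage transition counts for one term and arm,
#' including the missing-level fill, over the table's full stage order.
#' Rows for source states never observed are `NA` and flagged in the
#' `"unobserved"` attribute rather than fabricated.
#'
#' @param table An [observation_table()] with >= 2 stages.
#' @param term Term label.
#' @param arm Arm label.
#' @return A row-stochastic matrix over `scale_states(table$scale)` with
#'   attributes `"unobserved"` (source states never visited),
#'   `"row_counts"` (observed transitions per source state, the support
#'   behind each estimated row), and `"n_transitions"`.
#' @export
estimate_transitions <- function(table, term, arm) {
  stopifnot(inherits(table, "observation_table"))
  if (length(table$stage_order) < 2L) {
    stop("at least two stages of data are required", call. = FALSE)
  }
  traj <- pivot_trajectories(table, term, arm)
  states <- scale_states(table$scale)
  st <- traj$states
  counts <- matrix(0L, length(states), length(states),
                   dimnames = list(states, states))
  for (s in seq_len(ncol(st) - 1L)) {
    tab <- table(factor(st[, s], levels = states),
                 factor(st[, s + 1L], levels = states))
    counts <- counts + matrix(as.integer(tab), nrow = length(states))
  }
  dimnames(counts) <- list(states, states)
  rs <- rowSums(counts)
  est <- counts / ifelse(rs == 0, NA_real_, rs)
  attr(est, "unobserved") <- states[rs == 0]
  attr(est, "row_counts") <- rs
  attr(est, "n_transitions") <- sum(counts)
  est
}

#' Serialize a Markov spec to a JSON config file
#' @param spec A [markov_spec()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_markov_spec <- function(spec, path) {
  stopifnot(inherits(spec, "markov_spec"))
  obj <- list(
    scale = list(name = spec$scale$name, levels = spec$scale$levels,
                 missing_level = spec$scale$missing_level,
                 grade_values = if (is.null(spec$scale$grade_values)) NULL
                                else as.list(spec$scale$grade_values)),
    arms = spec$arms,
    initial_dist = lapply(spec$initial_dist, as.list),
    transition = lapply(spec$transition, function(m) {
      stats::setNames(lapply(seq_len(nrow(m)), function(i) unname(m[i, ])),
                      rownames(m))
    }),
    stages = spec$stages,
    dropout_absorbing = spec$dropout_absorbing
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a Markov spec config written by [write_markov_spec()]
#' @param path Config file path.
#' @return A [markov_spec()].
#' @export
read_markov_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  gv <- x$scale$grade_values
  if (!is.null(gv)) gv <- unlist(gv)
  scale <- severity_scale(x$scale$name, x$scale$levels,
                          x$scale$missing_level, grade_values = gv)
  states <- scale_states(scale)
  trans <- lapply(x$transition, function(rows) {
    m <- do.call(rbind, rows[states])
    dimnames(m) <- list(states, states)
    m
  })
  init <- lapply(x$initial_dist, function(p) unlist(p)[states])
  markov_spec(scale, x$arms, init, trans, x$stages,
              dropout_absorbing = isTRUE(x$dropout_absorbing))
}
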