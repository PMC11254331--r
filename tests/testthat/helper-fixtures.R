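# Fixtures and independent oracles, built in code at test time.

# Small CTCAE display-style scale used by hand-built fixtures.
disp_scale <- function() {
  severity_scale("CTCAE display", c("0-1", "2", "3", "4", "5"),
                 "Off Treatment")
}

# Hand-built table: 3 patients, 3 stages, one term, one arm.
small_table <- function() {
  obs <- tibble::tibble(
    patient_id = c("P1", "P1", "P2", "P2", "P2", "P3"),
    arm = "A",
    term = c(rep("arthralgia", 5), "headache"),
    timepoint = c("6 mo", "12 mo", "6 mo", "12 mo", "18 mo", "6 mo"),
    level = c("2", "2", "3", "2", "0-1", "2")
  )
  observation_table(obs, disp_scale(), c("6 mo", "12 mo", "18 mo"))
}

# Independent Toxicity Index oracle: the recursive form
# TI(w1..wn) = w1 + TI(w2..wn) / (1 + w1) on descending-sorted grades.
ti_oracle <- function(grades) {
  w <- sort(as.numeric(grades), decreasing = TRUE)
  rec <- function(v) {
    if (length(v) == 0L) return(0)
    v[1] + rec(v[-1]) / (1 + v[1])
  }
  rec(w)
}

# Brute-force Sankey tally oracle: a plain dictionary over every
# (patient, consecutive-stage) pair, independent of build_flow_graph.
oracle_flow <- function(states_mat, states) {
  S <- ncol(states_mat)
  nodes <- matrix(0L, S, length(states),
                  dimnames = list(colnames(states_mat), states))
  links <- list()
  for (s in seq_len(S - 1L)) {
    links[[s]] <- matrix(0L, length(states), length(states),
                         dimnames = list(states, states))
  }
  for (p in seq_len(nrow(states_mat))) {
    for (s in seq_len(S)) {
      a <- states_mat[p, s]
      nodes[s, a] <- nodes[s, a] + 1L
      if (s < S) {
        b <- states_mat[p, s + 1L]
        links[[s]][a, b] <- links[[s]][a, b] + 1L
      }
    }
  }
  list(nodes = nodes, links = links)
}

# Random trajectory matrix on a given scale.
rand_traj <- function(n_patients, n_stages, scale = disp_scale()) {
  states <- scale_states(scale)
  m <- matrix(sample(states, n_patients * n_stages, replace = TRUE),
              nrow = n_patients,
              dimnames = list(sprintf("P%02d", seq_len(n_patients)),
                              paste0("s", seq_len(n_stages))))
  trajectory_matrix(m, colnames(m), scale)
}

# Conservation identities of a flow graph, checked directly.
expect_flow_conserved <- function(graph) {
  expect_true(all(rowSums(graph$node_counts) == graph$total))
  S <- length(graph$stages)
  for (s in seq_len(S - 1L)) {
    expect_equal(unname(rowSums(graph$link_counts[[s]])),
                 unname(graph$node_counts[s, ]))
    expect_equal(unname(colSums(graph$link_counts[[s]])),
                 unname(graph$node_counts[s + 1L, ]))
  }
}

# Trajectory matrix built directly from a patient x stage character matrix.
traj_from <- function(rows, stages, scale = disp_scale()) {
  m <- do.call(rbind, rows)
  rownames(m) <- sprintf("P%d", seq_along(rows))
  trajectory_matrix(m, stages, scale)
}
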