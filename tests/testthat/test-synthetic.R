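two_state_spec <- function(p_stay = 0.7, dropout = 0) {
  sc <- severity_scale("binary", c("low", "high"), "Missing")
  states <- scale_states(sc)
  m <- matrix(c(p_stay, 1 - p_stay - dropout, dropout,
                1 - p_stay - dropout, p_stay, dropout,
                0, 0, 1),
              nrow = 3, byrow = TRUE, dimnames = list(states, states))
  markov_spec(sc, arms = "X",
              initial_dist = c(low = 0.5, high = 0.5, Missing = 0),
              transition = m, stages = paste0("s", 1:6))
}

test_that("spec validation rejects malformed probability inputs", {
  sc <- severity_scale("binary", c("low", "high"), "Missing")
  states <- scale_states(sc)
  ok <- diag(3)
  dimnames(ok) <- list(states, states)
  expect_error(
    markov_spec(sc, "X", c(low = 0.5, high = 0.6, Missing = 0), ok,
                paste0("s", 1:3)),
    "summing to 1")
  bad <- ok
  bad["Missing", ] <- c(0.5, 0.5, 0)
  expect_error(
    markov_spec(sc, "X", c(low = 1, high = 0, Missing = 0), bad,
                paste0("s", 1:3)),
    "unit vector")
  # and accepted when dropout is declared non-absorbing
  expect_s3_class(
    markov_spec(sc, "X", c(low = 1, high = 0, Missing = 0), bad,
                paste0("s", 1:3), dropout_absorbing = FALSE),
    "markov_spec")
  expect_error(markov_spec(sc, "X", c(low = 1, high = 0, Missing = 0), ok,
                           stages = "s1"),
               "two unique labels")
})

test_that("an identity transition matrix freezes every patient's state", {
  sc <- severity_scale("binary", c("low", "high"), "Missing")
  states <- scale_states(sc)
  ident <- diag(3)
  dimnames(ident) <- list(states, states)
  spec <- markov_spec(sc, "X", c(low = 0.4, high = 0.6, Missing = 0),
                      ident, paste0("s", 1:5))
  tab <- simulate_trial(spec, 40, term = "T", seed = 9)
  traj <- pivot_trajectories(tab, "T", "X")
  expect_true(all(traj$states == traj$states[, 1]))
})

test_that("identical seeds give byte-identical serialized tables", {
  a <- simulate_trial(preset_b35(), 30, term = "T", seed = 123)
  b <- simulate_trial(preset_b35(), 30, term = "T", seed = 123)
  fa <- withr::local_tempfile(fileext = ".csv")
  fb <- withr::local_tempfile(fileext = ".csv")
  write_custom_table(a, fa)
  write_custom_table(b, fb)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))
  c <- simulate_trial(preset_b35(), 30, term = "T", seed = 124)
  expect_false(tables_equivalent(a, c))
})

test_that("simulation leaves the caller's RNG stream untouched", {
  set.seed(555)
  before <- .Random.seed
  invisible(simulate_trial(preset_b30(), 10, term = "T", seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("empirical stay frequency matches the chain at large n", {
  spec <- two_state_spec(p_stay = 0.7)
  tab <- simulate_trial(spec, 5000, term = "T", seed = 17)
  traj <- pivot_trajectories(tab, "T", "X")
  st <- traj$states
  same <- st[, -ncol(st)] == st[, -1]
  stay_freq <- mean(same)
  # binomial SE ~ 0.006 at 25,000 transitions
  expect_lt(abs(stay_freq - 0.7), 0.02)
})

test_that("estimated transition rows are honest about observation", {
  sc <- severity_scale("binary", c("low", "high"), "Missing")
  obs <- tibble::tibble(patient_id = "P1", arm = "X", term = "T",
                        timepoint = paste0("s", 1:4), level = "low")
  tab <- observation_table(obs, sc, paste0("s", 1:4))
  est <- estimate_transitions(tab, "T", "X")
  expect_identical(unname(est["low", ]), c(1, 0, 0))
  expect_true(all(is.na(est["high", ])))
  expect_setequal(attr(est, "unobserved"), c("high", "Missing"))
})

test_that("transition estimates recover the generating chain", {
  # a row estimated from k observed transitions has binomial standard error
  # up to 0.5/sqrt(k); +/- 0.03 with a 3-sigma margin needs SE <= 0.01,
  # i.e. k >= 2500, so the check covers the rows with that much support
  spec <- preset_b35()
  tab <- simulate_trial(spec, 5000, term = "T", seed = 29)
  for (arm in spec$arms) {
    est <- estimate_transitions(tab, "T", arm)
    truth <- spec$transition[[arm]]
    supported <- names(which(attr(est, "row_counts") >= 2500))
    expect_gte(length(supported), 4L)
    err <- max(abs(est[supported, ] - truth[supported, ]))
    expect_lt(err, 0.03)
  }
})

test_that("recovery error shrinks as the cohort grows", {
  spec <- two_state_spec(p_stay = 0.65, dropout = 0.05)
  err_at <- function(n, seed) {
    tab <- simulate_trial(spec, n, term = "T", seed = seed)
    est <- estimate_transitions(tab, "T", "X")
    rows <- setdiff(rownames(est), attr(est, "unobserved"))
    max(abs(est[rows, ] - spec$transition$X[rows, ]))
  }
  # error should roughly halve when n quadruples; averaged over seeds to
  # stay clear of sampling noise
  small <- mean(vapply(1:4, function(s) err_at(150, s), numeric(1)))
  large <- mean(vapply(1:4, function(s) err_at(2400, s + 100), numeric(1)))
  expect_lt(large, small)
})

test_that("simulated tables always pass validation", {
  for (seed in 1:6) {
    spec <- if (seed %% 2L) preset_b35() else preset_b30()
    tab <- simulate_trial(spec, 12, term = "T", seed = seed)
    expect_identical(nrow(validate_table(tab, check_absorbing = TRUE)), 0L)
  }
})

test_that("markov specs round-trip through their JSON config", {
  spec <- preset_b30()
  path <- withr::local_tempfile(fileext = ".json")
  write_markov_spec(spec, path)
  back <- read_markov_spec(path)
  expect_identical(back$arms, spec$arms)
  expect_identical(back$stages, spec$stages)
  expect_equal(back$initial_dist, spec$initial_dist)
  expect_equal(back$transition, spec$transition)
  a <- simulate_trial(spec, 8, term = "T", seed = 2)
  b <- simulate_trial(back, 8, term = "T", seed = 2)
  expect_true(tables_equivalent(a, b))
})
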