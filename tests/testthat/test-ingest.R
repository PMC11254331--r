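write_fixture_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

basic_mapping <- function() {
  column_mapping(
    id_column = "patient_id", time_column = "crs", response_column = "numb",
    time_order = c("Baseline", "Cycle 4", "6 mo FU"),
    response_order = c("Not at all", "A little bit", "Quite a bit"))
}

test_that("a 2-patient x 3-timepoint file yields 6 observations", {
  path <- write_fixture_csv(c(
    "patient_id,crs,numb",
    "P1,Baseline,Not at all",
    "P1,Cycle 4,Quite a bit",
    "P1,6 mo FU,A little bit",
    "P2,Baseline,A little bit",
    "P2,Cycle 4,Not at all",
    "P2,6 mo FU,Not at all"))
  tab <- read_custom_table(path, basic_mapping(), missing_label = "No Response")
  expect_identical(nrow(tab$data), 6L)
  expect_length(tab$stage_order, 3L)
  expect_identical(tab$scale$levels,
                   c("Not at all", "A little bit", "Quite a bit"))
  expect_identical(unique(tab$data$term), "numb")
  expect_identical(unique(tab$data$arm), "All")
  expect_identical(nrow(validate_table(tab)), 0L)
})

test_that("unknown response and time labels error with the row number", {
  path <- write_fixture_csv(c(
    "patient_id,crs,numb",
    "P1,Baseline,Not at all",
    "P1,Cycle 4,Maybe"))
  expect_error(read_custom_table(path, basic_mapping()),
               "'Maybe' at data row 2")
  path2 <- write_fixture_csv(c(
    "patient_id,crs,numb",
    "P1,Never,Not at all"))
  expect_error(read_custom_table(path2, basic_mapping()),
               "'Never' at data row 1")
})

test_that("mapping invariants are checked before any I/O", {
  expect_error(
    column_mapping("patient_id", "patient_id", "numb",
                   time_order = "Baseline", response_order = "Not at all"),
    "distinct")
  expect_error(
    read_custom_table("does/not/exist.csv",
                      list(id_column = "a", time_column = "a",
                           response_column = "b", time_order = "t",
                           response_order = "r")),
    "distinct")
  expect_error(
    column_mapping("id", "crs", "numb", time_order = c("a", "a"),
                   response_order = "r"),
    "unique")
})

test_that("a missing mapped column is a schema error naming the column", {
  path <- write_fixture_csv(c("patient_id,crs,other", "P1,Baseline,x"))
  expect_error(read_custom_table(path, basic_mapping()),
               "missing from file header: numb")
})

test_that("blank response cells map to the missing label", {
  path <- write_fixture_csv(c(
    "patient_id,crs,numb",
    "P1,Baseline,Not at all",
    "P1,Cycle 4,",
    "P2,Baseline,"))
  tab <- read_custom_table(path, basic_mapping(), missing_label = "No Response")
  expect_identical(tab$data$level[2], "No Response")
  expect_identical(sum(tab$data$level == "No Response"), 2L)
})

test_that("duplicate (id, time) rows are a strict-mode error", {
  path <- write_fixture_csv(c(
    "patient_id,crs,numb",
    "P1,Baseline,Not at all",
    "P1,Baseline,Quite a bit"))
  expect_error(read_custom_table(path, basic_mapping()), "duplicate")
  expect_warning(
    tab <- read_custom_table(path, basic_mapping(), strict = FALSE),
    "most severe")
  expect_identical(tab$data$level, "Quite a bit")
})

test_that("an empty table writes a header-only file", {
  sc <- disp_scale()
  tab <- observation_table(
    tibble::tibble(patient_id = character(), arm = character(),
                   term = character(), timepoint = character(),
                   level = character()),
    sc, c("6 mo", "12 mo"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_custom_table(tab, path)
  expect_length(readLines(path), 1L)
})

test_that("adversarial labels with quoted commas round-trip stably", {
  sc <- severity_scale("bother", c('Not, at all', 'A "bit"', "Quite,a,bit"),
                       "No, Response")
  obs <- tibble::tibble(
    patient_id = c("P,1", "P,1", 'P"2"'),
    arm = "Arm, A",
    term = "numb, tingle",
    timepoint = c("t,1", "t,2", "t,1"),
    level = c('Not, at all', "No, Response", 'A "bit"'))
  tab <- observation_table(obs, sc, c("t,1", "t,2"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_custom_table(tab, path)
  back <- read_custom_table(path, canonical_mapping(tab),
                            missing_label = "No, Response")
  expect_true(tables_equivalent(tab, back))
})

test_that("reading is insensitive to input row order", {
  tab <- simulate_trial(preset_b30(), 15, term = "Numbness", seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_custom_table(tab, path)
  lines <- readLines(path)
  shuffled <- withr::local_tempfile(fileext = ".csv")
  set.seed(99)
  writeLines(c(lines[1], sample(lines[-1])), shuffled)
  mp <- canonical_mapping(tab)
  a <- read_custom_table(path, mp, missing_label = "No Response")
  b <- read_custom_table(shuffled, mp, missing_label = "No Response")
  expect_true(tables_equivalent(a, b))
})

test_that("synthetic tables round-trip through CSV across seeds", {
  for (seed in 1:8) {
    spec <- if (seed %% 2L) preset_b35() else preset_b30()
    miss <- spec$scale$missing_level
    tab <- simulate_trial(spec, 10, term = "Term X", seed = seed)
    path <- withr::local_tempfile(fileext = ".csv")
    write_custom_table(tab, path)
    back <- read_custom_table(path, canonical_mapping(tab),
                              missing_label = miss)
    expect_true(tables_equivalent(tab, back))
  }
})

test_that("tab-delimited files are supported via the delim flag", {
  tab <- simulate_trial(preset_b35(), 8, term = "T", seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_custom_table(tab, path, delim = "\t")
  back <- read_custom_table(path, canonical_mapping(tab),
                            missing_label = "Off Treatment", delim = "\t")
  expect_true(tables_equivalent(tab, back))
})

test_that("mapping configs round-trip through their JSON file", {
  mp <- basic_mapping()
  path <- withr::local_tempfile(fileext = ".json")
  write_mapping(mp, path, missing_label = "No Response")
  back <- read_mapping(path)
  expect_identical(back$missing_label, "No Response")
  expect_identical(back$mapping$time_order, mp$time_order)
  expect_identical(back$mapping$response_order, mp$response_order)
  expect_identical(back$mapping$id_column, mp$id_column)
})
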