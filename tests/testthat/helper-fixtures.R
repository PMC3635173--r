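# Shared fixtures, built once per test run and memoized. Coefficient tables
# are Monte Carlo products, so they are generated at moderate statistics and
# reused across test files.

.fixture_env <- new.env(parent = emptyenv())

all_phantom_ids <- function() {
  as.vector(outer(c("newborn", "1y", "5y", "10y", "15y", "adult"),
                  c("male", "female"), paste, sep = "_"))
}

fixture_tables <- function() {
  if (is.null(.fixture_env$tables)) {
    .fixture_env$tables <- default_coefficient_tables(
      all_phantom_ids(), kvp = c(80, 100, 120, 140), z_step_mm = 60,
      n_photons = 1200, seed = 42)
  }
  .fixture_env$tables
}

fixture_cohort <- function(n = 120, seed = 7, ...) {
  key <- paste0("cohort_", n, "_", seed, "_",
                paste(unlist(list(...)), collapse = "_"))
  if (is.null(.fixture_env[[key]])) {
    cfg <- synth_config(n_patients = n, master_seed = seed, ...)
    .fixture_env[[key]] <- generate_cohort(cfg, fixture_tables())
  }
  .fixture_env[[key]]
}

# minimal single-series cohort for sharing-structure checks: `n` patients,
# one identical head series each, all in one protocol group, mAs missing
fixture_shared_cohort <- function(n = 3) {
  patients <- tibble::tibble(patient_id = sprintf("S%02d", seq_len(n)),
                             sex = "male")
  series <- tibble::tibble(
    patient_id = patients$patient_id,
    exam_id = paste0(patients$patient_id, "_E1"),
    series_id = paste0(patients$patient_id, "_E1_S1"),
    region = "head", scenario = "pre_pacs", group_key = "G1",
    phantom_id = "5y_male", scanner_class = "single_slice",
    kvp = 120, exposure_mas = NA_real_, pitch = 1,
    collimation_mm = 10, scan_length_mm = 160,
    reported_ctdiw_mgy = 20)
  dose_cohort(patients, series, fixture_tables()["5y_male"])
}

expect_no_extrapolation_error <- function(expr) {
  expect_error(expr, NA)
}
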