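test_that("cohort generation is deterministic and era-consistent", {
  co1 <- fixture_cohort(n = 60, seed = 19)
  cfg <- synth_config(n_patients = 60, master_seed = 19)
  co2 <- generate_cohort(cfg, fixture_tables())
  expect_identical(co1$series$exposure_mas, co2$series$exposure_mas)
  expect_identical(co1$outcomes$cases, co2$outcomes$cases)
  expect_identical(co1$truth$doses$dose_mgy, co2$truth$doses$dose_mgy)
  # exam dates partition into eras at the hospital transition date
  m <- merge(co1$exams, data.frame(hospital_id = names(co1$transitions),
                                   transition = as.Date(co1$transitions)))
  expect_true(all((m$exam_date < m$transition) == (m$scenario == "pre_pacs")))
  # ages within the paediatric range
  expect_true(all(co1$exams$age_at_exam >= 0 & co1$exams$age_at_exam < 20))
})

test_that("a transition before the span start makes every exam post-PACS", {
  cfg <- synth_config(n_patients = 25, master_seed = 5,
                      transition_dates = as.Date("1984-01-01"))
  co <- generate_cohort(cfg, fixture_tables())
  expect_true(all(co$exams$scenario == "post_pacs"))
})

test_that("under a null slope, outcomes are independent of dose", {
  co <- fixture_cohort(n = 200, seed = 23)
  out0 <- simulate_outcomes(co, beta = 0, seed = 101)
  # permutation oracle on the dose-case correlation
  obs <- cor(out0$cases, out0$true_dose_gy)
  perm <- ctdosim:::with_seed(55, {
    replicate(400, cor(sample(out0$cases), out0$true_dose_gy))
  })
  p <- mean(abs(perm) >= abs(obs))
  expect_gt(p, 0.01)
  # and a strongly positive slope induces association
  out2 <- simulate_outcomes(co, beta = 50, seed = 102)
  expect_gt(cor(out2$cases, out2$true_dose_gy), obs)
})

test_that("ground-truth doses are reproduced by the reconstruction engine", {
  co <- fixture_cohort(n = 40, seed = 31)
  again <- reconstruct_doses(co)
  expect_equal(again$dose_mgy, co$truth$doses$dose_mgy, tolerance = 1e-12)
})

test_that("series doses agree between the batch kernel and the per-series engine", {
  # dual route: the realization fast path vs compute_series_dose
  co <- fixture_cohort(n = 25, seed = 37)
  truth <- co$truth$doses
  phs <- lapply(setNames(nm = unique(co$series$phantom_id)), function(id) {
    p <- strsplit(id, "_")[[1]]
    build_reference_phantom(p[1], p[2])
  })
  per_series <- lapply(seq_len(nrow(co$series)), function(i) {
    s <- as.list(co$series[i, ])
    s$nctdiw_factor <- 1
    compute_series_dose(s, phs[[s$phantom_id]], co$tables[[s$phantom_id]]) %>%
      dplyr::select(organ, dose_mgy) %>%
      dplyr::mutate(patient_id = s$patient_id)
  })
  manual <- dplyr::bind_rows(per_series) %>%
    dplyr::group_by(patient_id, organ) %>%
    dplyr::summarise(dose_mgy = sum(dose_mgy), .groups = "drop")
  cmp <- dplyr::left_join(truth, manual, by = c("patient_id", "organ"),
                          suffix = c("_kernel", "_engine")) %>%
    dplyr::mutate(dose_mgy_engine = ifelse(is.na(dose_mgy_engine), 0,
                                           dose_mgy_engine))
  expect_equal(cmp$dose_mgy_engine, cmp$dose_mgy_kernel, tolerance = 1e-10)
})

test_that("scenario masking removes presence, never alters retained values", {
  co <- fixture_cohort(n = 80, seed = 41)
  m <- mask_for_scenario(co)
  pre <- m$series$scenario == "pre_pacs"
  for (f in c("kvp", "exposure_mas", "pitch", "scan_length_mm",
              "reported_ctdiw_mgy")) {
    expect_true(all(is.na(m$series[[f]][pre])), label = paste("pre", f))
  }
  # retained post-PACS values are bit-identical to the truth
  post <- !pre
  for (f in c("kvp", "exposure_mas", "pitch")) {
    kept <- post & !is.na(m$series[[f]])
    expect_identical(m$series[[f]][kept], co$series[[f]][kept])
  }
  # dropout 0: post-PACS untouched; dropout 1: field gone everywhere
  cfg0 <- co$config; cfg0$dropout <- c(pitch = 0)
  m0 <- mask_for_scenario(co, cfg0)
  expect_identical(m0$series$pitch[post], co$series$pitch[post])
  cfg1 <- co$config; cfg1$dropout <- c(pitch = 1)
  m1 <- mask_for_scenario(co, cfg1)
  expect_true(all(is.na(m1$series$pitch[post])))
})

test_that("DICOM fixtures round-trip field-identically through intake", {
  co <- fixture_cohort(n = 50, seed = 43)
  m <- mask_for_scenario(co)
  post <- m$series %>% dplyr::filter(scenario == "post_pacs")
  take_exams <- unique(post$exam_id)[1:5]
  dir <- tempfile("dicomrt")
  sel <- post %>% dplyr::filter(exam_id %in% take_exams)
  manifest <- write_dicom_fixtures(
    structure(list(series = dplyr::mutate(sel, scenario = "post_pacs"),
                   patients = co$patients), class = "synth_cohort"),
    dir)
  expect_equal(nrow(manifest), nrow(sel))
  uid_map <- manifest %>% dplyr::select(series_id, series_uid)
  for (ex in take_exams) {
    rec <- extract_series_metadata(file.path(dir, ex))
    orig <- sel %>% dplyr::filter(exam_id == ex) %>%
      dplyr::left_join(uid_map, by = "series_id")
    got <- rec$series[match(orig$series_uid, rec$series$series_uid), ]
    expect_equal(nrow(got), nrow(orig))
    expect_equal(rec$exam$n_scans, nrow(orig))
    for (f in c("kvp", "exposure_mas", "pitch", "collimation_mm")) {
      expect_identical(got[[f]], orig[[f]], label = paste(ex, f))
    }
    # reported CTDIw reconstructed bit-identically from CTDIvol x pitch
    expect_identical(got$reported_ctdiw_mgy, orig$reported_ctdiw_mgy)
    # scan range spans the recorded length
    len <- got$scan_end_mm - got$scan_start_mm
    expect_equal(len, orig$scan_length_mm, tolerance = 1e-9)
  }
  unlink(dir, recursive = TRUE)
})

test_that("absent optional fields are omitted from the files, not zero-filled", {
  series <- tibble::tibble(
    patient_id = "PX", exam_id = "PX_E1", series_id = "PX_E1_S1",
    scenario = "post_pacs", region = "head", scanner_model = NA_character_,
    exam_date = as.Date("2005-05-05"),
    kvp = 120, exposure_mas = NA_real_, pitch = NA_real_,
    collimation_mm = 10, scan_length_mm = 150,
    ctdi_vol_mgy = NA_real_, reported_ctdiw_mgy = NA_real_)
  dir <- tempfile("sparse")
  write_dicom_fixtures(series, dir)
  files <- list.files(file.path(dir, "PX_E1"), full.names = TRUE)
  h <- read_dicom(files[1])
  expect_false(any(c("Exposure", "SpiralPitchFactor", "CTDIvol",
                     "ManufacturerModelName") %in% names(h)))
  expect_equal(h$KVP, 120)
  unlink(dir, recursive = TRUE)
})
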