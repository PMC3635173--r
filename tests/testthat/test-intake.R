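# helper: write a small exam of hand-built DICOM series to a fresh directory
write_test_exam <- function(series_list, dir = tempfile("exam")) {
  dir.create(dir)
  for (s in seq_along(series_list)) {
    el <- series_list[[s]]
    n <- el$n_slices %||% 3
    locs <- el$locs %||% seq(50, 50 + (n - 1) * 10, by = 10)
    for (k in seq_len(n)) {
      base <- el$elements
      base$SeriesInstanceUID <- el$uid
      base$SliceLocation <- locs[k]
      base$InstanceNumber <- k
      write_dicom(file.path(dir, paste0("s", s, "_", k, ".dcm")), base)
    }
  }
  dir
}

`%||%` <- function(a, b) if (is.null(a)) b else a

std_elements <- function(...) {
  utils::modifyList(list(
    Modality = "CT", Manufacturer = "SynthetiScan",
    ManufacturerModelName = "MX", PatientID = "P1", PatientSex = "M",
    StudyDate = "20040115", KVP = 120, Exposure = 120L,
    ExposureTime = 1000L, XRayTubeCurrent = 120L,
    SpiralPitchFactor = 1.0, TotalCollimationWidth = 10),
    list(...))
}

test_that("series are grouped and counted from the file set", {
  dir <- write_test_exam(list(
    list(uid = "1.1", elements = std_elements()),
    list(uid = "1.2", elements = std_elements(KVP = 100))
  ))
  rec <- extract_series_metadata(dir)
  expect_equal(rec$exam$n_scans, 2L)
  expect_equal(nrow(rec$series), 2L)
  expect_setequal(rec$series$kvp, c(120, 100))
  expect_equal(rec$exam$exam_date, as.Date("2004-01-15"))
  # scan range from min/max slice positions
  expect_equal(rec$series$scan_start_mm, c(50, 50))
  expect_equal(rec$series$scan_end_mm, c(70, 70))
  unlink(dir, recursive = TRUE)
})

test_that("missing attributes are reported, never defaulted", {
  el <- std_elements()
  el$SpiralPitchFactor <- NULL
  dir <- write_test_exam(list(list(uid = "2.1", elements = el)))
  rec <- extract_series_metadata(dir)
  expect_true(is.na(rec$series$pitch))
  expect_true("pitch" %in% rec$report$missing$field)
  unlink(dir, recursive = TRUE)

  # property: removing k fields reports exactly those k (of the checked set)
  drop_sets <- list(c("KVP"), c("KVP", "Manufacturer"),
                    c("Exposure", "XRayTubeCurrent", "ExposureTime",
                      "SpiralPitchFactor"))
  field_of <- c(KVP = "kvp", Manufacturer = "manufacturer",
                Exposure = "exposure_mas", SpiralPitchFactor = "pitch")
  for (ds in drop_sets) {
    el <- std_elements()
    for (f in ds) el[[f]] <- NULL
    dir <- write_test_exam(list(list(uid = "3.1", elements = el)))
    rec <- extract_series_metadata(dir)
    expected <- unname(field_of[intersect(ds, names(field_of))])
    # dropping all mAs sources removes the exposure field too
    if (all(c("Exposure", "XRayTubeCurrent") %in% ds)) {
      expected <- c(expected, "exposure_mas")
    }
    expect_setequal(intersect(rec$report$missing$field,
                              c("kvp", "manufacturer", "exposure_mas", "pitch")),
                    unique(expected))
    unlink(dir, recursive = TRUE)
  }
})

test_that("exposure precedence and disagreement flagging work", {
  # exposure attribute wins; >10% disagreement with mA x time is flagged
  el <- std_elements(Exposure = 200L, XRayTubeCurrent = 120L,
                     ExposureTime = 1000L)
  dir <- write_test_exam(list(list(uid = "4.1", elements = el)))
  rec <- extract_series_metadata(dir)
  expect_equal(rec$series$exposure_mas, 200)
  expect_equal(nrow(rec$report$flags), 1L)
  unlink(dir, recursive = TRUE)
  # absent exposure attribute falls back to current x rotation time
  el <- std_elements(); el$Exposure <- NULL
  dir <- write_test_exam(list(list(uid = "4.2", elements = el)))
  rec <- extract_series_metadata(dir)
  expect_equal(rec$series$exposure_mas, 120)
  unlink(dir, recursive = TRUE)
})

test_that("mixed patients in one set raise a consistency error", {
  dir <- write_test_exam(list(
    list(uid = "5.1", elements = std_elements(PatientID = "A")),
    list(uid = "5.2", elements = std_elements(PatientID = "B"))
  ))
  expect_error(extract_series_metadata(dir),
               class = "ctdosim_consistency_error")
  unlink(dir, recursive = TRUE)
})

test_that("body region classification follows the rule cascade", {
  feat <- function(bone, air) tibble::tibble(area_mm2 = 1000,
                                             bone_frac = bone, air_frac = air)
  expect_equal(classify_body_region(feat(0.3, 0.01))$region, "head")
  expect_equal(classify_body_region(feat(0.0, 0.30))$region, "chest")
  expect_equal(classify_body_region(feat(0.01, 0.02))$region, "abdomen")
  expect_error(classify_body_region(feat(1, 1)[0, ]),
               class = "ctdosim_validation_error")
  # mixed 60/40 chest/abdomen slices: majority label, confidence 0.6
  mixed <- dplyr::bind_rows(
    tibble::tibble(area_mm2 = 1, bone_frac = 0, air_frac = rep(0.3, 6)),
    tibble::tibble(area_mm2 = 1, bone_frac = 0, air_frac = rep(0.02, 4)))
  cls <- classify_body_region(mixed)
  expect_equal(cls$region, "chest")
  expect_equal(cls$confidence, 0.6)
})

test_that("synthetic image stacks classify correctly by construction", {
  for (region in c("head", "chest", "abdomen")) {
    scans <- generate_axial_images(region, n_scans = 10, seed = 99)
    labs <- vapply(scans, function(sc) {
      feats <- dplyr::bind_rows(lapply(sc$images, slice_features))
      classify_body_region(feats)$region
    }, character(1))
    expect_equal(labs, rep(region, 10))
  }
  # zero noise puts features exactly at their configured geometry
  s0 <- generate_axial_images("head", 1, seed = 1, noise_sd = 0)
  f0 <- slice_features(s0[[1]]$images[[1]])
  expect_gt(f0$bone_frac, 0.2)
  expect_equal(f0$air_frac, 0)
  # determinism
  s1 <- generate_axial_images("chest", 2, seed = 5)
  s2 <- generate_axial_images("chest", 2, seed = 5)
  expect_identical(s1, s2)
})

test_that("group assignment partitions exams with stated conventions", {
  protocols <- tibble::tibble(
    hospital_id = "H1",
    period_from = as.Date(c("1990-01-01", "1995-01-01")),
    period_to = as.Date(c("1994-12-31", "1999-12-31")),
    scanner_model = c("S1", "S2"),
    exam_type = "head", age_group = "5-9",
    kvp = c(120, 120), mas = c(200, 150), pitch = 1,
    scan_length_mm = 150, weight = 1)
  exams <- tibble::tibble(
    hospital_id = c("H1", "H1", "H2"),
    exam_date = as.Date(c("1992-06-01", "1994-12-31", "1992-06-01")),
    exam_type = "head", age_at_exam = 7)
  out <- assign_group(exams, protocols)
  expect_match(out$group_key[1], "^H1\\|1990-01-01")
  # boundary date resolves to the earlier period
  expect_match(out$group_key[2], "^H1\\|1990-01-01")
  expect_equal(out$group_key[3], "unmatched")
  # partition property: every exam gets exactly one key
  expect_equal(length(out$group_key), nrow(exams))
  expect_true(all(nzchar(out$group_key)))
  expect_error(assign_group(dplyr::mutate(exams, exam_date = as.Date(NA)),
                            protocols),
               class = "ctdosim_validation_error")
})

test_that("protocol lookup normalizes weights and handles unmatched keys", {
  protocols <- tibble::tibble(
    hospital_id = "H1", period_from = as.Date("1990-01-01"),
    period_to = as.Date("1994-12-31"), scanner_model = "S1",
    exam_type = "chest", age_group = "1-4",
    kvp = c(120, 100), mas = c(100, 50), pitch = 1, scan_length_mm = 200,
    weight = c(2, 1))
  exams <- tibble::tibble(hospital_id = "H1",
                          exam_date = as.Date("1991-01-01"),
                          exam_type = "chest", age_at_exam = 2)
  key <- assign_group(exams, protocols)$group_key
  rows <- lookup_protocol(key, protocols)
  expect_equal(nrow(rows), 2L)
  expect_equal(rows$weight, c(2 / 3, 1 / 3))
  expect_equal(nrow(lookup_protocol("unmatched", protocols)), 0L)
  one <- lookup_protocol(key, protocols[1, ] %>% dplyr::mutate(weight = NULL))
  expect_equal(one$weight, 1)
})

test_that("the five-item minimum data set is validated with the exam-type proxy", {
  patient <- list(sex = "male", birth_date = as.Date("1990-01-01"),
                  hospital_id = "H1")
  exam <- list(exam_date = as.Date("1999-01-01"), scanner_model = "S1",
               body_region = "head", n_scans = 1)
  expect_length(validate_minimum_dataset(patient, exam), 0)
  # missing body region with no proxy
  e2 <- exam; e2$body_region <- NULL
  expect_equal(validate_minimum_dataset(patient, e2), "body area scanned")
  # exam type acts as proxy for the body area
  e3 <- e2; e3$exam_type <- "head CT"
  expect_length(validate_minimum_dataset(patient, e3), 0)
  # several items missing at once
  e4 <- list(n_scans = 2)
  p4 <- list(sex = "female")
  out <- validate_minimum_dataset(p4, e4)
  expect_setequal(out, c("patient sex, age and radiology department",
                         "year of scan and scanner type or generation",
                         "body area scanned", "date of scan"))
})
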