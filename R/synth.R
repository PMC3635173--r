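#' Synthetic study configuration
#'
#' Defaults describe a plausible multi-hospital paediatric CT cohort spanning
#' the pre- and post-PACS eras: exams over 1985-2010 with per-hospital PACS
#' transitions in the late 1990s, head/chest/abdomen exams on patients aged
#' 0-19, protocol parameters per hospital x era x exam type x age group, and
#' outcomes generated under a known excess relative risk (default 2 per Gy to
#' red bone marrow) on a Poisson baseline.
#'
#' @param n_patients cohort size.
#' @param n_hospitals number of hospitals.
#' @param span calendar span of exam dates (`Date` length 2).
#' @param exam_rate mean number of additional exams per patient (Poisson).
#' @param p_exam_type sampling probabilities for head/chest/abdomen.
#' @param true_err_per_gy true excess relative risk per Gy.
#' @param risk_organ organ driving the outcome model.
#' @param baseline_rate baseline case rate per person-year.
#' @param pyr_range uniform band for person-years at risk.
#' @param dropout named per-field dropout probabilities applied to post-PACS
#'   series (fields of the series table).
#' @param collimation_mm beam collimation used by all synthetic scanners.
#' @param p_second_series probability that an exam has a second series.
#' @param transition_dates optional explicit per-hospital PACS transition
#'   dates (recycled); default draws them inside the middle of the span.
#' @param master_seed master seed; every downstream draw derives from it.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_patients = 500, n_hospitals = 3,
                         span = as.Date(c("1985-01-01", "2010-12-31")),
                         exam_rate = 0.6,
                         p_exam_type = c(head = 0.5, chest = 0.2, abdomen = 0.3),
                         true_err_per_gy = 2, risk_organ = "red_bone_marrow",
                         baseline_rate = 0.02, pyr_range = c(5, 15),
                         dropout = c(pitch = 0.10, exposure_mas = 0.05,
                                     kvp = 0.02, reported_ctdiw_mgy = 0.40),
                         collimation_mm = 10, p_second_series = 0.2,
                         transition_dates = NULL,
                         master_seed = 20100101) {
  stopifnot(length(span) == 2, span[1] < span[2])
  if (any(dropout < 0 | dropout > 1)) stop_validation("dropout must be in [0,1]")
  structure(as.list(environment()), class = "synth_config")
}

# per-hospital PACS transition dates, inside the calendar span unless
# overridden
.pacs_transitions <- function(config) {
  if (!is.null(config$transition_dates)) {
    return(rep(as.Date(config$transition_dates),
               length.out = config$n_hospitals))
  }
  with_seed(derive_seed(config$master_seed, "pacs"), {
    days <- as.integer(config$span[2] - config$span[1])
    lo <- config$span[1] + round(0.35 * days)
    hi <- config$span[1] + round(0.65 * days)
    as.Date(sort(sample(seq(lo, hi, by = "day"), config$n_hospitals)),
            origin = "1970-01-01")
  })
}

# true protocol tables: one or two joint parameter rows per hospital x era x
# exam type x age group
.true_protocols <- function(config) {
  transitions <- .pacs_transitions(config)
  age_groups <- c("<1", "1-4", "5-9", "10-14", "15-19")
  age_factor <- c(0.45, 0.6, 0.75, 0.9, 1.0)
  base_mas <- c(head = 180, chest = 90, abdomen = 120)
  base_len <- c(head = 160, chest = 250, abdomen = 280)
  rows <- list()
  for (h in seq_len(config$n_hospitals)) {
    for (era in c("pre_pacs", "post_pacs")) {
      from <- if (era == "pre_pacs") config$span[1] else transitions[h]
      to <- if (era == "pre_pacs") transitions[h] - 1 else config$span[2]
      for (et in BODY_REGIONS) {
        for (ia in seq_along(age_groups)) {
          seed <- derive_seed(config$master_seed, "protocol", h, era, et, ia)
          row <- with_seed(seed, {
            kvp <- if (era == "pre_pacs") sample(c(100, 120, 140), 1)
                   else sample(c(80, 100, 120), 1)
            mas <- unname(round(base_mas[et] * age_factor[ia] *
                                  runif(1, 0.85, 1.15)))
            pitch <- if (era == "pre_pacs") 1.0 else sample(c(0.9, 1.2, 1.5), 1)
            len <- unname(round(base_len[et] * (0.5 + 0.5 * age_factor[ia]) *
                                  runif(1, 0.9, 1.1)))
            tibble(kvp = kvp, mas = mas, pitch = pitch, scan_length_mm = len,
                   weight = 1)
          })
          rows[[length(rows) + 1]] <- row %>%
            mutate(hospital_id = paste0("H", h), period_from = from,
                   period_to = to,
                   scanner_model = paste0("H", h, "_",
                                          if (era == "pre_pacs") "SS" else "MS"),
                   exam_type = et, age_group = age_groups[ia], era = era)
        }
      }
    }
  }
  bind_rows(rows)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws patients, examinations and per-series technical parameters from the
#' configured protocol tables, computes every patient's true organ doses with
#' the same deterministic dose engine used for reconstruction (so perfect
#' information recovers them exactly), and generates outcomes from a Poisson
#' model with rate `baseline * (1 + beta * D)`.
#'
#' @param config a [synth_config()].
#' @param tables named list of `coefficient_table`s covering every phantom
#'   used (see [default_coefficient_tables()]).
#' @return list of class `synth_cohort`: `patients`, `exams`, `series`,
#'   `protocols`, `outcomes`, `truth` (per-exam true parameters and
#'   per-patient true organ doses), `transitions`, `config`.
#' @export
generate_cohort <- function(config, tables) {
  stopifnot(inherits(config, "synth_config"))
  protocols <- .true_protocols(config)
  transitions <- .pacs_transitions(config)
  names(transitions) <- paste0("H", seq_len(config$n_hospitals))

  patients <- with_seed(derive_seed(config$master_seed, "patients"), {
    n <- config$n_patients
    tibble(
      patient_id = sprintf("P%05d", seq_len(n)),
      sex = sample(c("male", "female"), n, replace = TRUE),
      hospital_id = sample(names(transitions), n, replace = TRUE)
    )
  })

  exams <- with_seed(derive_seed(config$master_seed, "exams"), {
    purrr::map_dfr(seq_len(nrow(patients)), function(i) {
      n_exams <- 1L + rpois(1, config$exam_rate)
      first_date <- config$span[1] +
        round(runif(1) * as.integer(config$span[2] - config$span[1] - 1100))
      age1 <- runif(1, 0, 17)
      dates <- sort(first_date + c(0, round(runif(n_exams - 1, 30, 1000))))
      ages <- pmin(age1 + as.numeric(dates - first_date) / 365.25, 19.99)
      tibble(
        patient_id = patients$patient_id[i],
        exam_id = paste0(patients$patient_id[i], "_E", seq_len(n_exams)),
        hospital_id = patients$hospital_id[i],
        exam_date = dates,
        age_at_exam = ages,
        exam_type = sample(names(config$p_exam_type), n_exams, replace = TRUE,
                           prob = config$p_exam_type)
      )
    })
  })
  exams <- exams %>%
    mutate(scenario = if_else(.data$exam_date < transitions[.data$hospital_id],
                              "pre_pacs", "post_pacs"),
           birth_offset_years = .data$age_at_exam)
  patients <- patients %>%
    left_join(exams %>% group_by(.data$patient_id) %>%
                summarise(birth_date = first(.data$exam_date) -
                            round(first(.data$age_at_exam) * 365.25),
                          age_first_exam = first(.data$age_at_exam),
                          sex_band = NA, .groups = "drop") %>%
                select("patient_id", "birth_date", "age_first_exam"),
              by = "patient_id")

  # per-exam phantom selection and series-level true parameters
  exams <- exams %>%
    mutate(age_group = age_group_of(.data$age_at_exam),
           phantom_id = paste0(
             select_phantom(.data$age_at_exam,
                            patients$sex[match(.data$patient_id,
                                               patients$patient_id)]),
             "_", patients$sex[match(.data$patient_id, patients$patient_id)]))
  exams <- assign_group(
    exams %>% mutate(scanner_model = NA_character_), protocols)

  series <- with_seed(derive_seed(config$master_seed, "series"), {
    purrr::map_dfr(seq_len(nrow(exams)), function(i) {
      e <- exams[i, ]
      proto <- lookup_protocol(e$group_key, protocols)
      stopifnot(nrow(proto) >= 1)
      row <- proto[sample.int(nrow(proto), 1, prob = proto$weight), ]
      n_series <- 1L + stats::rbinom(1, 1, config$p_second_series)
      cls <- if (e$scenario == "pre_pacs") "single_slice" else "multi_slice"
      mas <- as.integer(round(row$mas * runif(n_series, 0.9, 1.1)))
      spec <- if (e$exam_type == "head") "head" else "body"
      ctdivol <- if (e$scenario == "post_pacs") {
        nctdiw_lookup(row$kvp, spec, cls) * runif(n_series, 0.92, 1.08) *
          mas / 100 / row$pitch
      } else {
        rep(NA_real_, n_series)
      }
      tibble(
        patient_id = e$patient_id, exam_id = e$exam_id,
        series_id = paste0(e$exam_id, "_S", seq_len(n_series)),
        hospital_id = e$hospital_id, exam_date = e$exam_date,
        scenario = e$scenario, group_key = e$group_key,
        region = e$exam_type, phantom_id = e$phantom_id,
        scanner_class = cls, scanner_model = row$scanner_model,
        kvp = row$kvp, exposure_mas = as.double(mas), pitch = row$pitch,
        collimation_mm = config$collimation_mm,
        scan_length_mm = row$scan_length_mm,
        ctdi_vol_mgy = ctdivol,
        reported_ctdiw_mgy = ctdivol * row$pitch
      )
    })
  })

  cohort <- dose_cohort(patients, series, tables)
  truth_doses <- reconstruct_doses(cohort)

  outcomes <- with_seed(derive_seed(config$master_seed, "outcomes"), {
    d_gy <- truth_doses %>%
      filter(.data$organ == config$risk_organ) %>%
      mutate(dose_gy = mgy_to_gy(.data$dose_mgy))
    df <- patients %>%
      left_join(select(d_gy, "patient_id", "dose_gy"), by = "patient_id") %>%
      mutate(dose_gy = if_else(is.na(.data$dose_gy), 0, .data$dose_gy),
             pyr = runif(n(), config$pyr_range[1], config$pyr_range[2]),
             age_band = age_group_of(.data$age_first_exam),
             rate = config$baseline_rate *
               (1 + config$true_err_per_gy * .data$dose_gy),
             cases = rpois(n(), .data$rate * .data$pyr))
    select(df, "patient_id", "sex", "age_band", "pyr", "cases",
           true_dose_gy = "dose_gy")
  })

  structure(list(
    patients = patients, exams = exams, series = series,
    protocols = protocols, outcomes = outcomes,
    truth = list(series_parameters = series, doses = truth_doses),
    transitions = transitions, config = config, tables = tables
  ), class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat("<synth_cohort>", nrow(x$patients), "patients,", nrow(x$exams),
      "exams,", nrow(x$series), "series\n")
  cat("  eras:", paste(names(table(x$exams$scenario)),
                       table(x$exams$scenario), collapse = ", "), "\n")
  invisible(x)
}

#' Deterministic cohort dose reconstruction
#'
#' Runs the dose engine for every series of a fully parameterized cohort and
#' returns cumulative per-patient organ doses. Any missing technical
#' parameter is an error here -- uncertain cohorts go through
#' [generate_realizations()] instead.
#'
#' @param cohort a [dose_cohort()] or `synth_cohort`.
#' @return tibble `patient_id`, `organ`, `dose_mgy`.
#' @export
reconstruct_doses <- function(cohort) {
  if (inherits(cohort, "synth_cohort")) {
    cohort <- dose_cohort(cohort$patients, cohort$series, cohort$tables)
  }
  stopifnot(inherits(cohort, "dose_cohort"))
  rs <- generate_realizations(cohort, list(), V = 1, master_seed = 0)
  as_tibble(rs) %>%
    select("patient_id", "organ", "dose_mgy")
}

#' Apply scenario-dependent masking
#'
#' Emulates what each data-availability scenario can actually see: pre-PACS
#' examinations keep only the limited roster fields (department, date, body
#' part, number of scans, sex, age) -- every per-series technical parameter is
#' removed; post-PACS examinations keep technical parameters subject to the
#' configured per-field dropout. Masking changes field presence only, never a
#' retained value.
#'
#' @param cohort a `synth_cohort`.
#' @param config defaults to the cohort's config.
#' @return the cohort with a masked `series` table (original kept in
#'   `truth`).
#' @export
mask_for_scenario <- function(cohort, config = cohort$config) {
  stopifnot(inherits(cohort, "synth_cohort"))
  s <- cohort$series
  pre <- s$scenario == "pre_pacs"
  for (f in c("kvp", "exposure_mas", "pitch", "scan_length_mm",
              "ctdi_vol_mgy", "reported_ctdiw_mgy")) {
    s[[f]][pre] <- NA_real_
  }
  s$scanner_model[pre] <- NA_character_
  drop <- config$dropout
  s <- with_seed(derive_seed(config$master_seed, "mask"), {
    for (f in names(drop)) {
      hit <- !pre & runif(nrow(s)) < drop[[f]]
      s[[f]][hit] <- NA_real_
      if (f == "reported_ctdiw_mgy") s$ctdi_vol_mgy[hit] <- NA_real_
    }
    s
  })
  # the weighted index is only derivable from the headers when both the
  # volume index and the pitch survive
  s$reported_ctdiw_mgy[is.na(s$pitch) | is.na(s$ctdi_vol_mgy)] <- NA_real_
  cohort$series <- s
  cohort
}

#' Resample outcomes for an existing cohort under a chosen slope
#'
#' Draws a fresh outcome table for the cohort's fixed true doses under an
#' excess relative risk of `beta` per Gy -- the repeated-outcome experiment
#' used for type-I error and recovery checks (the dose design stays fixed,
#' only the Poisson outcomes vary).
#'
#' @param cohort a `synth_cohort`.
#' @param beta excess relative risk per Gy.
#' @param seed integer seed.
#' @return outcomes tibble (same shape as `cohort$outcomes`).
#' @export
simulate_outcomes <- function(cohort, beta, seed) {
  stopifnot(inherits(cohort, "synth_cohort"))
  config <- cohort$config
  with_seed(seed, {
    cohort$outcomes %>%
      mutate(pyr = runif(n(), config$pyr_range[1], config$pyr_range[2]),
             cases = rpois(n(), config$baseline_rate *
                             (1 + beta * .data$true_dose_gy) * .data$pyr))
  })
}

#' Write DICOM fixtures for the post-PACS series
#'
#' Emits valid single-frame DICOM Part 10 CT files (one file per slice, one
#' series per series record) with the technical parameters written to the
#' standard CT attributes. Absent parameters are omitted from the headers,
#' never zero-filled, so the intake round trip is field-identical.
#'
#' @param cohort a `synth_cohort` (post-PACS series are selected
#'   automatically) or a series tibble.
#' @param dir output directory (one subdirectory per exam).
#' @param max_slices cap on slices per series.
#' @return manifest tibble: one row per written series.
#' @export
write_dicom_fixtures <- function(cohort, dir, max_slices = 12) {
  series <- if (inherits(cohort, "synth_cohort")) {
    cohort$series %>% filter(.data$scenario == "post_pacs")
  } else {
    as_tibble(cohort)
  }
  if (nrow(series) == 0) stop_validation("no post-PACS series to write")
  patients <- if (inherits(cohort, "synth_cohort")) cohort$patients else NULL
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- purrr::map_dfr(seq_len(nrow(series)), function(i) {
    s <- series[i, ]
    exam_dir <- file.path(dir, s$exam_id)
    dir.create(exam_dir, showWarnings = FALSE)
    suid <- paste(DICOM_UID_ROOT, "2", i, gsub("[^0-9]", "", s$series_id),
                  sep = ".")
    study_uid <- paste(DICOM_UID_ROOT, "3", gsub("[^0-9]", "", s$exam_id),
                      sep = ".")
    n_slices <- if (!is.na(s$scan_length_mm)) {
      max(2L, min(max_slices, ceiling(s$scan_length_mm / 30)))
    } else 2L
    locs <- if (!is.na(s$scan_length_mm)) {
      seq(100, 100 + s$scan_length_mm, length.out = n_slices)
    } else rep(NA_real_, n_slices)
    pt <- if (!is.null(patients)) {
      patients[patients$patient_id == s$patient_id, ]
    } else NULL
    files <- vapply(seq_len(n_slices), function(k) {
      f <- file.path(exam_dir, paste0(s$series_id, "_", k, ".dcm"))
      write_dicom(f, list(
        SOPInstanceUID = paste(suid, k, sep = "."),
        Modality = "CT",
        StudyDate = format(s$exam_date, "%Y%m%d"),
        Manufacturer = "SynthetiScan",
        ManufacturerModelName = s$scanner_model %||% NA,
        PatientID = s$patient_id,
        PatientSex = if (!is.null(pt) && nrow(pt)) {
          c(male = "M", female = "F")[pt$sex]
        } else NA,
        PatientBirthDate = if (!is.null(pt) && nrow(pt) &&
                               !is.na(pt$birth_date %||% NA)) {
          format(pt$birth_date, "%Y%m%d")
        } else NA,
        SliceThickness = s$collimation_mm,
        KVP = s$kvp,
        ExposureTime = if (!is.na(s$exposure_mas)) 1000 else NA,
        XRayTubeCurrent = if (!is.na(s$exposure_mas)) {
          as.integer(round(s$exposure_mas))
        } else NA,
        Exposure = if (!is.na(s$exposure_mas)) {
          as.integer(round(s$exposure_mas))
        } else NA,
        TotalCollimationWidth = s$collimation_mm,
        SpiralPitchFactor = s$pitch,
        CTDIvol = s$ctdi_vol_mgy,
        StudyInstanceUID = study_uid,
        SeriesInstanceUID = suid,
        SeriesNumber = as.integer(sub(".*_S", "", s$series_id)),
        InstanceNumber = k,
        SliceLocation = locs[k]
      ))
      f
    }, character(1))
    tibble(series_id = s$series_id, exam_id = s$exam_id,
           patient_id = s$patient_id, series_uid = suid,
           n_files = n_slices, dir = exam_dir,
           first_file = files[1])
  })
  manifest
}

#' Generate labelled synthetic axial image stacks
#'
#' Geometric phantasms with the segmentation signatures of the three scanned
#' regions: heads are elliptical bodies with a high-intensity peripheral
#' ring (skull), chests carry two internal low-intensity ellipses (lungs),
#' abdomens have neither. Sizes and noise are jittered per scan; ground-truth
#' labels ride along.
#'
#' @param region "head", "chest" or "abdomen".
#' @param n_scans number of scans.
#' @param seed integer seed.
#' @param n_slices slices per scan.
#' @param size image side, pixels.
#' @param noise_sd Gaussian intensity noise (0 gives exact configured means).
#' @return list of scans; each scan is `list(region, images)` with `images` a
#'   list of `size x size` matrices.
#' @export
generate_axial_images <- function(region, n_scans, seed = 1, n_slices = 6,
                                  size = 64, noise_sd = 0.02) {
  assert_choice(region, BODY_REGIONS, "region")
  with_seed(seed, {
    lapply(seq_len(n_scans), function(i) {
      jit <- runif(1, 0.9, 1.1)
      a <- 0.40 * size * jit
      b <- 0.32 * size * jit
      xs <- matrix(seq_len(size), size, size)
      ys <- t(xs)
      cx <- size / 2; cy <- size / 2
      r2 <- ((xs - cx) / a)^2 + ((ys - cy) / b)^2
      images <- lapply(seq_len(n_slices), function(k) {
        img <- matrix(0, size, size)
        img[r2 <= 1] <- 0.45
        if (region == "head") {
          img[r2 <= 1 & r2 >= 0.64] <- 0.9
        } else if (region == "chest") {
          l2 <- ((xs - (cx - 0.45 * a)) / (0.33 * a))^2 +
            ((ys - cy) / (0.55 * b))^2
          rgt <- ((xs - (cx + 0.45 * a)) / (0.33 * a))^2 +
            ((ys - cy) / (0.55 * b))^2
          img[(l2 <= 1 | rgt <= 1) & r2 <= 1] <- 0.02
        }
        if (noise_sd > 0) {
          img <- img + matrix(rnorm(size^2, 0, noise_sd), size, size)
        }
        img
      })
      list(region = region, images = images)
    })
  })
}
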