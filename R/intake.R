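#' Extract per-series CT metadata from a DICOM file set
#'
#' Builds an examination record from a directory (or explicit file list) of
#' single-frame DICOM CT files: series are grouped by SeriesInstanceUID,
#' technical fields are mapped from the standard CT attributes, and the scan
#' range is taken from the min/max slice locations. Attributes absent from
#' the headers are recorded as missing in the validation report -- they are
#' never defaulted. When both the exposure attribute and tube current x
#' rotation time are present, the exposure attribute wins; a discrepancy of
#' more than 10% between the two is flagged.
#'
#' @param path directory containing DICOM files, or a character vector of
#'   file paths.
#' @return list of class `examination_record`: `patient` (1-row tibble),
#'   `exam` (1-row tibble: exam date, scenario flag, number of scans),
#'   `series` (one row per series) and `report` (validation report:
#'   `missing` tibble of absent fields, `flags` tibble of consistency
#'   warnings).
#' @export
extract_series_metadata <- function(path) {
  files <- if (length(path) == 1 && dir.exists(path)) {
    list.files(path, full.names = TRUE, recursive = TRUE)
  } else {
    path
  }
  if (length(files) == 0) stop_format("no files to read")
  headers <- lapply(files, read_dicom)

  pid <- unique(vapply(headers, function(h) h$PatientID %||% NA_character_,
                       character(1)))
  if (length(pid[!is.na(pid)]) > 1) {
    stop_consistency(paste0("mixed patients in one file set: ",
                            paste(stats::na.omit(pid), collapse = ", ")))
  }
  h1 <- headers[[1]]
  patient <- tibble(
    patient_id = h1$PatientID %||% NA_character_,
    sex = c(M = "male", F = "female", O = "other")[h1$PatientSex %||% NA_character_],
    birth_date = .dicom_date(h1$PatientBirthDate)
  )

  suid <- vapply(headers, function(h) h$SeriesInstanceUID %||% NA_character_,
                 character(1))
  series_ids <- unique(suid)
  get1 <- function(hs, kw) {
    v <- unlist(lapply(hs, function(h) h[[kw]]))
    if (is.null(v) || !length(v)) NA else v[1]
  }
  series <- purrr::map_dfr(seq_along(series_ids), function(k) {
    hs <- headers[suid == series_ids[k]]
    locs <- unlist(lapply(hs, function(h) h$SliceLocation))
    cur <- get1(hs, "XRayTubeCurrent")
    rot <- get1(hs, "ExposureTime")
    expo <- get1(hs, "Exposure")
    pitch <- get1(hs, "SpiralPitchFactor")
    ctdivol <- get1(hs, "CTDIvol")
    tibble(
      series_uid = series_ids[k],
      series_number = k,
      manufacturer = as.character(get1(hs, "Manufacturer")),
      model = as.character(get1(hs, "ManufacturerModelName")),
      kvp = as.double(get1(hs, "KVP")),
      tube_current_ma = as.double(cur),
      rotation_time_s = as.double(rot) / 1000,
      exposure_mas = as.double(expo),
      pitch = as.double(pitch),
      collimation_mm = as.double(get1(hs, "TotalCollimationWidth")),
      scan_start_mm = if (length(locs)) min(locs) else NA_real_,
      scan_end_mm = if (length(locs)) max(locs) else NA_real_,
      ctdi_vol_mgy = as.double(ctdivol),
      reported_ctdiw_mgy = as.double(ctdivol) * as.double(pitch),
      n_slices = length(hs)
    )
  })
  # exposure fallback: current x rotation time when the attribute is absent
  series <- series %>%
    mutate(mas_from_current = .data$tube_current_ma * .data$rotation_time_s,
           exposure_mas = if_else(is.na(.data$exposure_mas),
                                  .data$mas_from_current, .data$exposure_mas))

  check_fields <- c("manufacturer", "model", "kvp", "exposure_mas", "pitch",
                    "collimation_mm", "scan_start_mm", "scan_end_mm")
  missing <- purrr::map_dfr(seq_len(nrow(series)), function(i) {
    absent <- check_fields[vapply(check_fields, function(f) {
      is.na(series[[f]][i])
    }, logical(1))]
    if (length(absent)) tibble(series_uid = series$series_uid[i], field = absent)
    else tibble(series_uid = character(), field = character())
  })
  flags <- series %>%
    filter(!is.na(.data$exposure_mas), !is.na(.data$mas_from_current),
           .data$mas_from_current > 0,
           abs(.data$exposure_mas - .data$mas_from_current) /
             .data$mas_from_current > 0.10) %>%
    mutate(flag = "exposure attribute and mA x rotation time disagree > 10%") %>%
    select("series_uid", "flag")

  exam <- tibble(
    patient_id = patient$patient_id,
    exam_date = .dicom_date(h1$StudyDate),
    scenario = "post_pacs",
    n_scans = nrow(series)
  )
  structure(list(patient = patient, exam = exam,
                 series = select(series, -"mas_from_current"),
                 report = list(missing = missing, flags = flags)),
            class = "examination_record")
}

.dicom_date <- function(x) {
  if (is.null(x) || is.na(x) || !nzchar(x)) return(as.Date(NA))
  as.Date(x, format = "%Y%m%d")
}

#' @export
print.examination_record <- function(x, ...) {
  cat("<examination_record>", x$patient$patient_id, "on",
      format(x$exam$exam_date), "-", x$exam$n_scans, "series\n")
  if (nrow(x$report$missing)) {
    cat("  missing fields:", nrow(x$report$missing), "\n")
  }
  invisible(x)
}

#' Compute segmentation features of an axial slice
#'
#' Threshold segmentation of a single axial image (numeric matrix, arbitrary
#' normalized intensity): the body mask is everything at or above
#' `body_threshold`; the interior is the row-wise span of the body mask
#' (bodies are convex here); bone is the high-intensity fraction of body
#' pixels and air cavities the low-intensity fraction of interior pixels.
#'
#' @param img numeric matrix.
#' @param body_threshold,bone_threshold,air_threshold segmentation thresholds
#'   on normalized intensity.
#' @param pixel_mm pixel size, mm.
#' @return 1-row tibble: `area_mm2`, `bone_frac`, `air_frac`.
#' @export
slice_features <- function(img, body_threshold = 0.2, bone_threshold = 0.7,
                           air_threshold = 0.1, pixel_mm = 1) {
  stopifnot(is.matrix(img))
  body <- img >= body_threshold
  interior <- matrix(FALSE, nrow(img), ncol(img))
  for (r in seq_len(nrow(img))) {
    w <- which(body[r, ])
    if (length(w) >= 2) interior[r, w[1]:w[length(w)]] <- TRUE
  }
  nb <- sum(body)
  ni <- sum(interior)
  tibble(
    area_mm2 = ni * pixel_mm^2,
    bone_frac = if (nb > 0) sum(body & img >= bone_threshold) / nb else 0,
    air_frac = if (ni > 0) sum(interior & img < air_threshold) / ni else 0
  )
}

#' Classify the scanned body region from slice features
#'
#' Deterministic rule cascade on per-scan median features: high bone fraction
#' with no internal air is a head; large internal air fraction is a chest;
#' anything else is an abdomen. Confidence is the fraction of individual
#' slices whose own classification agrees with the scan-level label.
#'
#' @param features tibble with one row per slice (`bone_frac`, `air_frac`;
#'   see [slice_features()]).
#' @param theta_bone,theta_air,theta_lung rule thresholds (defaults 0.05,
#'   0.05, 0.15).
#' @return list: `region` ("head"/"chest"/"abdomen") and `confidence` in
#'   (0, 1].
#' @export
classify_body_region <- function(features, theta_bone = 0.05,
                                 theta_air = 0.05, theta_lung = 0.15) {
  features <- as_tibble(features)
  if (nrow(features) == 0) stop_validation("empty feature sequence")
  rule <- function(bone, air) {
    if_else(bone > theta_bone & air < theta_air, "head",
            if_else(air > theta_lung, "chest", "abdomen"))
  }
  region <- rule(median(features$bone_frac), median(features$air_frac))
  per_slice <- rule(features$bone_frac, features$air_frac)
  list(region = region, confidence = mean(per_slice == region))
}

#' Default age grouping
#'
#' Age bands mirroring the phantom age series: `<1`, `1-4`, `5-9`, `10-14`,
#' `15-19` years.
#'
#' @param age ages in years (vectorized).
#' @param breaks lower bounds of the bands.
#' @return character vector of band labels.
#' @export
age_group_of <- function(age, breaks = c(0, 1, 5, 10, 15)) {
  labels <- paste0(breaks, "-", c(breaks[-1] - 1, 19))
  labels[1] <- paste0("<", breaks[2])
  labels[findInterval(age, breaks)]
}

#' Assign examinations to protocol groups
#'
#' Groups patients by hospital, protocol period, scanner model where known,
#' examination type and age group -- the strata over which historical
#' protocols are documented. A date on the boundary of two abutting periods
#' resolves to the earlier period. Every exam maps to exactly one group;
#' exams with no matching protocol stratum get the explicit key
#' `"unmatched"`.
#'
#' @param exams tibble with `hospital_id`, `exam_date`, `exam_type`,
#'   `age_at_exam` and optionally `scanner_model`.
#' @param protocols protocol table: `hospital_id`, `period_from`, `period_to`,
#'   `scanner_model`, `exam_type`, `age_group` plus parameter columns.
#' @return `exams` with a `group_key` column appended.
#' @export
assign_group <- function(exams, protocols) {
  exams <- as_tibble(exams)
  if (any(is.na(exams$exam_date))) stop_validation("exam dates must be present")
  has_scanner <- "scanner_model" %in% names(exams)
  keys <- vapply(seq_len(nrow(exams)), function(i) {
    e <- exams[i, ]
    cand <- protocols %>%
      filter(.data$hospital_id == e$hospital_id,
             .data$exam_type == e$exam_type,
             .data$age_group == age_group_of(e$age_at_exam),
             .data$period_from <= e$exam_date,
             e$exam_date <= .data$period_to)
    if (nrow(cand) == 0) return("unmatched")
    # earlier period wins when periods overlap on a boundary
    first_from <- min(cand$period_from)
    cand <- cand %>% filter(.data$period_from == first_from)
    scanner <- if (has_scanner && !is.na(e$scanner_model) &&
                   e$scanner_model %in% cand$scanner_model) {
      e$scanner_model
    } else {
      sort(unique(cand$scanner_model))[1]  # deterministic period default
    }
    paste(e$hospital_id, format(first_from),
          format(min(cand$period_to[cand$scanner_model == scanner])),
          scanner, e$exam_type, age_group_of(e$age_at_exam), sep = "|")
  }, character(1))
  exams$group_key <- keys
  exams
}

#' Look up the joint protocol parameter rows for a group
#'
#' @param group_key a key produced by [assign_group()].
#' @param protocols the protocol table (see [assign_group()]); optional
#'   `weight` column carries row frequencies.
#' @return tibble of joint parameter rows with normalized `weight`; empty for
#'   the `"unmatched"` key.
#' @export
lookup_protocol <- function(group_key, protocols) {
  empty <- protocols[0, ]
  if (identical(group_key, "unmatched")) return(empty)
  p <- strsplit(group_key, "|", fixed = TRUE)[[1]]
  if (length(p) != 6) stop_validation("malformed group key")
  rows <- protocols %>%
    filter(.data$hospital_id == p[1],
           format(.data$period_from) == p[2],
           .data$scanner_model == p[4],
           .data$exam_type == p[5],
           .data$age_group == p[6])
  if (nrow(rows) == 0) return(empty)
  if (!"weight" %in% names(rows)) rows$weight <- 1
  rows$weight[is.na(rows$weight)] <- 1
  rows$weight <- rows$weight / sum(rows$weight)
  rows
}

#' Validate the minimum dosimetry data set
#'
#' Checks the five-item minimum data set needed for even a crude dose
#' estimate: (1) patient sex, age and radiology department; (2) year of scan
#' and scanner type or generation; (3) body area scanned -- satisfiable by
#' proxy from the examination type; (4) date of scan; (5) number of scans.
#'
#' @param patient list/1-row data frame: `sex`, `birth_date` (or
#'   `age_at_exam`), `hospital_id`.
#' @param exam list/1-row data frame: `exam_date`, `scanner_model` or
#'   `scanner_class`, `body_region` or `exam_type`, `n_scans`.
#' @return character vector of unmet item labels (empty when complete).
#' @export
validate_minimum_dataset <- function(patient, exam) {
  patient <- as.list(patient)
  exam <- as.list(exam)
  has <- function(x) !is.null(x) && length(x) == 1 && !is.na(x)
  missing <- character()
  if (!(has(patient$sex) &&
        (has(patient$birth_date) || has(exam$age_at_exam) ||
         has(patient$age_at_exam)) &&
        has(patient$hospital_id))) {
    missing <- c(missing, "patient sex, age and radiology department")
  }
  if (!((has(exam$exam_date) || has(exam$year)) &&
        (has(exam$scanner_model) || has(exam$scanner_class)))) {
    missing <- c(missing, "year of scan and scanner type or generation")
  }
  if (!(has(exam$body_region) || has(exam$exam_type))) {
    missing <- c(missing, "body area scanned")
  }
  if (!has(exam$exam_date)) {
    missing <- c(missing, "date of scan")
  }
  if (!has(exam$n_scans)) {
    missing <- c(missing, "number of scans")
  }
  missing
}

#' Write an intake validation report as JSON
#'
#' @param record an `examination_record`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(record, path) {
  stopifnot(inherits(record, "examination_record"))
  jsonlite::write_json(record$report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
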