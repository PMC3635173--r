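#' CT dose index algebra
#'
#' `ctdi_vol()` divides the weighted CT dose index by the pitch;
#' `dlp()` is the dose-length product CTDIvol x scan length.
#'
#' @param ctdiw_mgy weighted CT dose index, mGy.
#' @param pitch table advance per rotation over collimation; must be > 0.
#' @return CTDIvol in mGy.
#' @export
ctdi_vol <- function(ctdiw_mgy, pitch) {
  if (any(!is.finite(pitch)) || any(pitch <= 0)) {
    stop_validation("pitch must be > 0")
  }
  ctdiw_mgy / pitch
}

#' @rdname ctdi_vol
#' @param ctdivol_mgy volume CT dose index, mGy.
#' @param scan_length_mm scan length, mm (>= 0).
#' @return DLP in mGy.cm.
#' @export
dlp <- function(ctdivol_mgy, scan_length_mm) {
  if (any(!is.finite(scan_length_mm)) || any(scan_length_mm < 0)) {
    stop_validation("scan length must be >= 0")
  }
  ctdivol_mgy * scan_length_mm / 10
}

#' Map a recorded scan range onto the phantom axis
#'
#' Affine placement of a series on the phantom: with no usable positions the
#' scan covers the body-region landmark exactly; with absolute table
#' positions plus a localizer reference the recorded length is preserved,
#' centred on the landmark. Orientation is normalized so `z0 < z1`, and the
#' interval is clipped to the phantom extent.
#'
#' @param phantom a `stylized_phantom`.
#' @param region body region label ("head", "chest", "abdomen").
#' @param scan_start_mm,scan_end_mm recorded table positions (optional).
#' @param scan_length_mm recorded scan length (optional alternative to the
#'   positions, e.g. from a protocol entry).
#' @param has_localizer whether the positions are referenced to a localizer
#'   (absolute positions without one are ignored).
#' @return numeric `c(z0, z1)` in phantom mm.
#' @export
map_scan_range <- function(phantom, region, scan_start_mm = NA,
                           scan_end_mm = NA, scan_length_mm = NA,
                           has_localizer = TRUE) {
  if (is.na(region)) {
    if (is.na(scan_start_mm) || is.na(scan_end_mm)) {
      stop_reconstruction("no body region and no scan positions: cannot map scan range")
    }
    stop_reconstruction("scan positions without a body region are not mappable")
  }
  lm <- locate_region(phantom, region)
  H <- phantom$height_cm * 10
  if ((is.na(scan_start_mm) || is.na(scan_end_mm) || !isTRUE(has_localizer)) &&
      is.na(scan_length_mm)) {
    return(lm)
  }
  len <- if (!is.na(scan_length_mm)) scan_length_mm
         else abs(scan_end_mm - scan_start_mm)
  mid <- mean(lm)
  z0 <- max(0, mid - len / 2)
  z1 <- min(H, mid + len / 2)
  c(z0, z1)
}

# rotation positions + weights across an interval: contiguous axial rotations
# stepped by collimation x pitch, partial last rotation weighted by fractional
# coverage
rotation_positions <- function(z0, z1, collimation_mm, pitch) {
  step <- collimation_mm * pitch
  len <- z1 - z0
  n_full <- floor(len / step + 1e-9)
  z <- z0 + (seq_len(n_full) - 0.5) * step
  w <- rep(1, n_full)
  frac <- (len - n_full * step) / step
  if (frac > 1e-9) {
    z <- c(z, z0 + (n_full + frac / 2) * step)
    w <- c(w, frac)
  }
  list(z = z, w = w, step = step)
}

# bilinear coefficient lookup: linear in z (clamped at grid ends), linear in
# log-kVp between grid points, hard error outside the kVp grid.
# returns matrix [length(z) x n_organ]
coeff_lookup <- function(table, z, kvp) {
  kg <- table$kvp
  if (kvp < min(kg) - 1e-9 || kvp > max(kg) + 1e-9) {
    stop_reconstruction(paste0("kVp ", kvp, " outside coefficient grid [",
                               min(kg), ", ", max(kg), "]; no extrapolation"))
  }
  lk <- log(kg)
  ik <- findInterval(log(kvp), lk, rightmost.closed = TRUE)
  ik <- max(1L, min(ik, length(kg) - 1L))
  wk <- if (length(kg) == 1) 0 else (log(kvp) - lk[ik]) / (lk[ik + 1] - lk[ik])
  wk <- max(0, min(1, wk))
  zg <- table$z
  zi <- pmin(pmax(z, zg[1]), zg[length(zg)])
  iz <- pmin(pmax(findInterval(zi, zg), 1L), length(zg) - 1L)
  if (length(zg) == 1) {
    iz <- rep(1L, length(zi)); wz <- rep(0, length(zi))
  } else {
    wz <- (zi - zg[iz]) / (zg[iz + 1] - zg[iz])
    wz <- pmin(pmax(wz, 0), 1)
  }
  norg <- length(table$organs)
  out <- matrix(0, length(z), norg, dimnames = list(NULL, table$organs))
  ik2 <- min(ik + 1L, length(kg))
  for (io in seq_len(norg)) {
    c00 <- table$coeff[iz, ik, io]
    c10 <- table$coeff[pmin(iz + 1L, length(zg)), ik, io]
    c01 <- table$coeff[iz, ik2, io]
    c11 <- table$coeff[pmin(iz + 1L, length(zg)), ik2, io]
    out[, io] <- (1 - wk) * ((1 - wz) * c00 + wz * c10) +
      wk * ((1 - wz) * c01 + wz * c11)
  }
  out
}

nctdiw_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- as_tibble(read.csv(extdata_path("nctdiw.csv"),
                                   stringsAsFactors = FALSE))
    }
    cache
  }
})

#' Normalized CTDIw lookup for a scanner class
#'
#' Bundled fallback values of CTDIw per 100 mAs by scanner class
#' (single-slice vs multi-slice era), dosimetry phantom (head/body) and tube
#' voltage; log-kVp interpolated. Used only when neither a reported CTDIw nor
#' a calibrated scanner entry is available.
#'
#' @param kvp tube voltage.
#' @param ctdi_spec "head" or "body".
#' @param scanner_class "single_slice" or "multi_slice".
#' @return CTDIw in mGy per 100 mAs.
#' @export
nctdiw_lookup <- function(kvp, ctdi_spec = "body", scanner_class = "multi_slice") {
  tab <- nctdiw_cached() %>%
    filter(.data$scanner_class == .env$scanner_class,
           .data$ctdi_spec == .env$ctdi_spec)
  if (nrow(tab) == 0) stop_validation("unknown scanner class / CTDI spec")
  if (kvp < min(tab$kvp) || kvp > max(tab$kvp)) {
    stop_reconstruction("kVp outside the normalized-CTDIw table")
  }
  exp(approx(log(tab$kvp), log(tab$nctdiw_mgy_per_100mas), xout = log(kvp))$y)
}

#' Compute per-organ dose for one series
#'
#' Places contiguous axial rotations (step = collimation x pitch, fractional
#' last rotation weighted) across the mapped scan interval and accumulates
#' coefficient x CTDIw-per-rotation for every organ. CTDIw per rotation is
#' the reported CTDIw scaled to the rotation mAs (reported values are per
#' 100 mAs) when available, otherwise the bundled normalized-CTDIw lookup for
#' the scanner class. A modulation profile, when present, scales each
#' rotation's mAs (linearly re-sampled to the rotation count). The result is
#' exactly linear in total mAs.
#'
#' @param series 1-row data frame / list with `kvp`, `exposure_mas`, `pitch`,
#'   `collimation_mm`, optional `reported_ctdiw_mgy`, `scan_start_mm`,
#'   `scan_end_mm`, `region`, optional `modulation` (numeric vector of
#'   per-rotation relative mA), optional `scanner_class`.
#' @param phantom a `stylized_phantom`.
#' @param coeff_table a `coefficient_table` for that phantom.
#' @return tibble `organ`, `dose_mgy`, plus `ctdi_vol_mgy`, `dlp_mgy_cm` and
#'   the CTDIw source tier as attributes-free columns (`ctdiw_source`).
#' @export
compute_series_dose <- function(series, phantom, coeff_table) {
  s <- as.list(series)
  for (f in c("kvp", "exposure_mas", "pitch", "collimation_mm")) {
    if (is.null(s[[f]]) || is.na(s[[f]])) {
      stop_reconstruction(paste0("missing parameter: ", f))
    }
  }
  if (s$pitch <= 0) stop_validation("pitch must be > 0")
  zint <- map_scan_range(phantom, s$region %||% NA,
                         s$scan_start_mm %||% NA, s$scan_end_mm %||% NA,
                         scan_length_mm = s$scan_length_mm %||% NA,
                         has_localizer = s$has_localizer %||% TRUE)
  rot <- rotation_positions(zint[1], zint[2], s$collimation_mm, s$pitch)
  cf <- coeff_lookup(coeff_table, rot$z, s$kvp)
  # per-rotation mAs, optionally modulated
  mas <- rep(s$exposure_mas, length(rot$z))
  if (!is.null(s$modulation) && length(s$modulation) > 0 &&
      !all(is.na(s$modulation))) {
    prof <- s$modulation
    if (length(prof) != length(rot$z)) {
      prof <- approx(seq(0, 1, length.out = length(prof)), prof,
                     xout = seq(0, 1, length.out = length(rot$z)))$y
    }
    mas <- mas * prof
  }
  # CTDIw per 100 mAs, by source tier
  reported <- s$reported_ctdiw_mgy %||% NA
  if (!is.na(reported)) {
    ctdiw100 <- rep(reported, length(rot$z))
    tier <- "reported"
  } else {
    spec_z <- if_else(rot$z <= locate_region(phantom, "head")[2], "head", "body")
    cls <- s$scanner_class %||% "multi_slice"
    ctdiw100 <- vapply(unique(spec_z), function(sp) {
      nctdiw_lookup(s$kvp, sp, cls)
    }, numeric(1))[spec_z]
    ctdiw100 <- ctdiw100 * (s$nctdiw_factor %||% 1)
    tier <- "era_lookup"
  }
  dose <- colSums(cf * (rot$w * mas / 100 * ctdiw100))
  mean_ctdiw <- weighted.mean(ctdiw100, rot$w)
  cv <- ctdi_vol(mean_ctdiw * s$exposure_mas / 100, s$pitch)
  tibble(organ = names(dose), dose_mgy = unname(dose),
         ctdi_vol_mgy = cv, dlp_mgy_cm = dlp(cv, zint[2] - zint[1]),
         ctdiw_source = tier)
}

#' Sum series doses into an examination dose
#'
#' @param series_doses list of per-series results from
#'   [compute_series_dose()].
#' @return tibble `organ`, `dose_mgy`, `n_series`.
#' @export
compute_exam_dose <- function(series_doses) {
  bind_rows(series_doses) %>%
    group_by(.data$organ) %>%
    summarise(dose_mgy = sum(.data$dose_mgy), .groups = "drop") %>%
    mutate(n_series = length(series_doses))
}

#' Accumulate per-patient cumulative organ dose
#'
#' Organ-wise sum of examination dose results for one patient. An empty list
#' yields all-zero doses; exam order does not matter.
#'
#' @param exam_results list of tibbles (`organ`, `dose_mgy`), one per exam,
#'   each optionally carrying a `patient_id` column (must agree).
#' @param organs organ set for the all-zero case.
#' @return tibble `organ`, `dose_mgy`, `n_exams`.
#' @export
accumulate_patient_dose <- function(exam_results, organs = ORGANS) {
  if (length(exam_results) == 0) {
    return(tibble(organ = sort(organs), dose_mgy = 0, n_exams = 0L))
  }
  all <- bind_rows(exam_results)
  if ("patient_id" %in% names(all) &&
      length(unique(all$patient_id)) > 1) {
    stop_consistency("exam results from multiple patients cannot be accumulated")
  }
  all %>%
    group_by(.data$organ) %>%
    summarise(dose_mgy = sum(.data$dose_mgy), .groups = "drop") %>%
    mutate(n_exams = length(exam_results)) %>%
    arrange(.data$organ)
}
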