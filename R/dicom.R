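# Minimal DICOM Part 10 support: explicit-VR little-endian read/write of the
# CT header attributes this pipeline needs. Only single-frame (one file per
# slice) objects are handled; values are scalar per element. Absent attributes
# are simply not written -- never zero-filled.

DICOM_TX_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
DICOM_SOP_CT <- "1.2.840.10008.5.1.4.1.1.2"
DICOM_IMPL_UID <- "1.2.826.0.1.3680043.10.1101.1"
DICOM_UID_ROOT <- "1.2.826.0.1.3680043.10.1101"

# keyword -> group, element, VR
dicom_dictionary <- function() {
  tibble::tribble(
    ~keyword, ~group, ~element, ~vr,
    "SOPClassUID",            0x0008, 0x0016, "UI",
    "SOPInstanceUID",         0x0008, 0x0018, "UI",
    "StudyDate",              0x0008, 0x0020, "DA",
    "Modality",               0x0008, 0x0060, "CS",
    "Manufacturer",           0x0008, 0x0070, "LO",
    "ManufacturerModelName",  0x0008, 0x1090, "LO",
    "PatientName",            0x0010, 0x0010, "PN",
    "PatientID",              0x0010, 0x0020, "LO",
    "PatientBirthDate",       0x0010, 0x0030, "DA",
    "PatientSex",             0x0010, 0x0040, "CS",
    "SliceThickness",         0x0018, 0x0050, "DS",
    "KVP",                    0x0018, 0x0060, "DS",
    "ExposureTime",           0x0018, 0x1150, "IS",
    "XRayTubeCurrent",        0x0018, 0x1151, "IS",
    "Exposure",               0x0018, 0x1152, "IS",
    "TotalCollimationWidth",  0x0018, 0x9307, "FD",
    "SpiralPitchFactor",      0x0018, 0x9311, "FD",
    "CTDIvol",                0x0018, 0x9345, "FD",
    "StudyInstanceUID",       0x0020, 0x000D, "UI",
    "SeriesInstanceUID",      0x0020, 0x000E, "UI",
    "SeriesNumber",           0x0020, 0x0011, "IS",
    "InstanceNumber",         0x0020, 0x0013, "IS",
    "SliceLocation",          0x0020, 0x1041, "DS"
  )
}

.int_le <- function(x, size) {
  # raw little-endian encoding of a non-negative integer
  writeBin(as.integer(x), raw(), size = size, endian = "little")
}

.pad_even <- function(raw_val, pad) {
  if (length(raw_val) %% 2 == 1L) c(raw_val, pad) else raw_val
}

.encode_value <- function(value, vr) {
  switch(vr,
    OB = .pad_even(as.raw(value), as.raw(0L)),
    UI = .pad_even(charToRaw(as.character(value)), as.raw(0L)),
    FD = writeBin(as.double(value), raw(), size = 8, endian = "little"),
    UL = .int_le(value, 4),
    DS = .pad_even(charToRaw(format(as.double(value), digits = 10,
                                    scientific = FALSE, trim = TRUE)),
                   charToRaw(" ")),
    IS = .pad_even(charToRaw(format(as.integer(round(value)))), charToRaw(" ")),
    # CS, LO, PN, DA and other string VRs
    .pad_even(charToRaw(as.character(value)), charToRaw(" "))
  )
}

.encode_element <- function(group, element, vr, value) {
  val <- .encode_value(value, vr)
  hdr <- c(.int_le(group, 2), .int_le(element, 2), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(hdr, as.raw(c(0, 0)), .int_le(length(val), 4), val)
  } else {
    if (length(val) > 65534) stop_format("element value too long")
    c(hdr, .int_le(length(val), 2), val)
  }
}

#' Write a DICOM Part 10 file
#'
#' Writes a single-frame CT header as explicit-VR little-endian DICOM Part 10
#' (128-byte preamble, "DICM", file meta group, dataset). Only attributes
#' present in `elements` are written; `NULL`/`NA` entries are dropped, so an
#' absent acquisition parameter stays absent in the file.
#'
#' @param path output file.
#' @param elements named list keyed by DICOM keyword (see
#'   `ctdosim:::dicom_dictionary()` for the supported set).
#' @return `path`, invisibly.
#' @export
write_dicom <- function(path, elements) {
  dict <- dicom_dictionary()
  elements <- elements[!vapply(elements, function(v) {
    is.null(v) || (length(v) == 1 && is.na(v))
  }, logical(1))]
  unknown <- setdiff(names(elements), dict$keyword)
  if (length(unknown)) {
    stop_format(paste0("unsupported DICOM keyword(s): ",
                       paste(unknown, collapse = ", ")))
  }
  if (is.null(elements$SOPClassUID)) elements$SOPClassUID <- DICOM_SOP_CT
  if (is.null(elements$SOPInstanceUID)) {
    elements$SOPInstanceUID <- dicom_uid()
  }
  rows <- dict[match(names(elements), dict$keyword), ]
  ord <- order(rows$group, rows$element)
  body <- unlist(lapply(ord, function(i) {
    .encode_element(rows$group[i], rows$element[i], rows$vr[i],
                    elements[[names(elements)[i]]])
  }))
  meta_elems <- c(
    .encode_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    .encode_element(0x0002, 0x0002, "UI", elements$SOPClassUID),
    .encode_element(0x0002, 0x0003, "UI", elements$SOPInstanceUID),
    .encode_element(0x0002, 0x0010, "UI", DICOM_TX_EXPLICIT_LE),
    .encode_element(0x0002, 0x0012, "UI", DICOM_IMPL_UID)
  )
  meta <- c(.encode_element(0x0002, 0x0000, "UL", length(meta_elems)),
            meta_elems)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

# monotone unique UID generator (process-local counter)
dicom_uid <- local({
  counter <- 0L
  function() {
    counter <<- counter + 1L
    paste(DICOM_UID_ROOT, Sys.getpid(), counter,
          format(as.integer(Sys.time())), sep = ".")
  }
})

.decode_value <- function(val, vr) {
  switch(vr,
    FD = readBin(val, "double", n = length(val) / 8, size = 8,
                 endian = "little"),
    UL = readBin(val, "integer", n = length(val) / 4, size = 4,
                 endian = "little"),
    DS = as.double(trimws(rawToChar(val))),
    IS = as.integer(trimws(rawToChar(val))),
    OB = val,
    {
      s <- rawToChar(val[val != as.raw(0)])
      trimws(s)
    }
  )
}

#' Read a DICOM Part 10 file
#'
#' Parses an explicit-VR little-endian DICOM Part 10 file and returns the
#' recognized CT attributes as a named list (DICOM keywords). Unrecognized
#' elements are skipped; attributes not present in the file are simply absent
#' from the result -- they are never defaulted.
#'
#' @param path file to read.
#' @return named list of attribute values.
#' @export
read_dicom <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 140 ||
      rawToChar(bytes[129:132]) != "DICM") {
    stop_format(paste0("not a DICOM Part 10 file: ", path))
  }
  dict <- dicom_dictionary()
  key <- paste(dict$group, dict$element)
  out <- list()
  i <- 133L
  n <- length(bytes)
  transfer_checked <- FALSE
  u16 <- function(at) {
    as.integer(bytes[at]) + 256L * as.integer(bytes[at + 1L])
  }
  u32 <- function(at) {
    as.integer(bytes[at]) + 256 * as.integer(bytes[at + 1L]) +
      65536 * as.integer(bytes[at + 2L]) + 16777216 * as.integer(bytes[at + 3L])
  }
  while (i + 7L <= n) {
    group <- u16(i); element <- u16(i + 2L)
    vr <- rawToChar(bytes[(i + 4L):(i + 5L)])
    if (!grepl("^[A-Z]{2}$", vr)) {
      stop_format("implicit-VR or corrupt DICOM stream not supported")
    }
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- u32(i + 8L)
      vstart <- i + 12L
    } else {
      len <- u16(i + 6L)
      vstart <- i + 8L
    }
    if (len < 0 || vstart + len - 1L > n) stop_format("truncated DICOM element")
    val <- if (len > 0) bytes[vstart:(vstart + len - 1L)] else raw(0)
    if (group == 0x0002 && element == 0x0010) {
      tx <- .decode_value(val, "UI")
      if (tx != DICOM_TX_EXPLICIT_LE) {
        stop_format(paste0("unsupported transfer syntax: ", tx))
      }
      transfer_checked <- TRUE
    }
    hit <- match(paste(group, element), key)
    if (!is.na(hit)) out[[dict$keyword[hit]]] <- .decode_value(val, dict$vr[hit])
    i <- vstart + len
  }
  if (!transfer_checked) stop_format("missing transfer syntax UID")
  out
}
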