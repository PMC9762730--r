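# Minimal single-frame DICOM part-10 reader and writer, explicit VR little
# endian only (transfer syntax 1.2.840.10008.1.2.1). No DICOM toolkit exists
# in the pre-installed stack; this subset covers what CT slice ingestion and
# the phantom generator need: uncompressed 16-bit grayscale pixel data plus
# the identification, geometry and rescale attributes. Sequences, implicit
# VR and compressed transfer syntaxes are rejected with "format error".

.dcm_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# tag -> canonical metadata name used by anonymization policies
.dcm_tag_names <- c(
  "00080060" = "modality",
  "0008103E" = "series_description",
  "00080080" = "institution_name",
  "00081070" = "operators_name",
  "00100010" = "patient_name",
  "00100020" = "patient_id",
  "00100030" = "patient_birth_date",
  "00101040" = "patient_address",
  "00102154" = "patient_phone",
  "0020000D" = "study_uid",
  "0020000E" = "series_uid",
  "00200013" = "instance_number",
  "00200032" = "image_position",
  "00201041" = "slice_location"
)

.dcm_tag_key <- function(group, elem) sprintf("%04X%04X", group, elem)

.dcm_element_raw <- function(group, elem, vr, value) {
  if (is.character(value)) {
    b <- charToRaw(paste(value, collapse = "\\"))
    pad <- if (vr == "UI") as.raw(0) else charToRaw(" ")
    if (length(b) %% 2L == 1L) b <- c(b, pad)
  } else if (is.raw(value)) {
    b <- value
    if (length(b) %% 2L == 1L) b <- c(b, as.raw(0))
  } else if (vr %in% c("US", "UL")) {
    size <- if (vr == "US") 2L else 4L
    con <- rawConnection(raw(0), "wb")
    writeBin(as.integer(value), con, size = size, endian = "little")
    b <- rawConnectionValue(con); close(con)
  } else if (vr == "OW") {
    con <- rawConnection(raw(0), "wb")
    writeBin(as.integer(value), con, size = 2L, endian = "little")
    b <- rawConnectionValue(con); close(con)
  } else {
    stop("unsupported DICOM value type")
  }
  con <- rawConnection(raw(0), "wb")
  writeBin(as.integer(c(group, elem)), con, size = 2L, endian = "little")
  writeBin(charToRaw(vr), con)
  if (vr %in% .dcm_long_vrs) {
    writeBin(raw(2), con)
    writeBin(length(b), con, size = 4L, endian = "little")
  } else {
    writeBin(length(b), con, size = 2L, endian = "little")
  }
  out <- c(rawConnectionValue(con), b)
  close(con)
  out
}

#' Write a single-frame CT DICOM file
#'
#' Explicit-VR little-endian part-10 writer used by the phantom generator and
#' the test fixtures. Pixel values are stored as signed 16-bit integers; the
#' Hounsfield value of a voxel is `stored * rescale_slope + rescale_intercept`.
#'
#' @param path Output file path.
#' @param pixels Integer matrix (rows x cols) of stored values.
#' @param meta Named list of header strings; recognised names are the
#'   canonical ones (`patient_name`, `patient_id`, `patient_birth_date`,
#'   `patient_address`, `patient_phone`, `institution_name`,
#'   `operators_name`, `series_uid`, `study_uid`).
#' @param instance_number 1-based acquisition counter.
#' @param slice_position Through-plane (z) position in mm.
#' @param rescale_slope,rescale_intercept DICOM rescale mapping.
#' @return `path`, invisibly.
#' @keywords internal
write_dicom_slice <- function(path, pixels, meta = list(),
                              instance_number = 1L, slice_position = 0,
                              rescale_slope = 1, rescale_intercept = 0) {
  stopifnot(is.matrix(pixels))
  g <- function(name, default) if (!is.null(meta[[name]])) meta[[name]] else default
  sop_uid <- paste0("1.2.826.0.1.3680043.9999.", abs(instance_number),
                    ".", sum(as.double(pixels[1, ])) %% 997)

  body <- c(
    .dcm_element_raw(0x0008L, 0x0060L, "CS", "CT"),
    .dcm_element_raw(0x0008L, 0x0080L, "LO", g("institution_name", "SYNTHETIC")),
    .dcm_element_raw(0x0008L, 0x103EL, "LO", g("series_description", "SER")),
    .dcm_element_raw(0x0008L, 0x1070L, "PN", g("operators_name", "SYNTH^OP")),
    .dcm_element_raw(0x0010L, 0x0010L, "PN", g("patient_name", "PHANTOM^SYNTH")),
    .dcm_element_raw(0x0010L, 0x0020L, "LO", g("patient_id", "P000")),
    .dcm_element_raw(0x0010L, 0x0030L, "DA", g("patient_birth_date", "19700101")),
    .dcm_element_raw(0x0010L, 0x1040L, "LO", g("patient_address", "1 Synthetic Way")),
    .dcm_element_raw(0x0010L, 0x2154L, "SH", g("patient_phone", "000-0000")),
    .dcm_element_raw(0x0020L, 0x000DL, "UI", g("study_uid", "1.2.826.0.1.3680043.9999.1")),
    .dcm_element_raw(0x0020L, 0x000EL, "UI", g("series_uid", "1.2.826.0.1.3680043.9999.2")),
    .dcm_element_raw(0x0020L, 0x0013L, "IS", as.character(instance_number)),
    .dcm_element_raw(0x0020L, 0x0032L, "DS",
                     paste(c("0", "0", format(slice_position)), collapse = "\\")),
    .dcm_element_raw(0x0020L, 0x1041L, "DS", format(slice_position)),
    .dcm_element_raw(0x0028L, 0x0002L, "US", 1L),
    .dcm_element_raw(0x0028L, 0x0010L, "US", nrow(pixels)),
    .dcm_element_raw(0x0028L, 0x0011L, "US", ncol(pixels)),
    .dcm_element_raw(0x0028L, 0x0100L, "US", 16L),
    .dcm_element_raw(0x0028L, 0x0101L, "US", 16L),
    .dcm_element_raw(0x0028L, 0x0102L, "US", 15L),
    .dcm_element_raw(0x0028L, 0x0103L, "US", 1L),
    .dcm_element_raw(0x0028L, 0x1052L, "DS", format(rescale_intercept)),
    .dcm_element_raw(0x0028L, 0x1053L, "DS", format(rescale_slope)),
    # row-major scan order: row 1 first
    .dcm_element_raw(0x7FE0L, 0x0010L, "OW", as.integer(t(pixels)))
  )

  meta_elems <- c(
    .dcm_element_raw(0x0002L, 0x0001L, "OB", as.raw(c(0, 1))),
    .dcm_element_raw(0x0002L, 0x0002L, "UI", "1.2.840.10008.5.1.4.1.1.2"),
    .dcm_element_raw(0x0002L, 0x0003L, "UI", sop_uid),
    .dcm_element_raw(0x0002L, 0x0010L, "UI", "1.2.840.10008.1.2.1")
  )
  meta_grp <- c(.dcm_element_raw(0x0002L, 0x0000L, "UL", length(meta_elems)),
                meta_elems)

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta_grp, body), con)
  invisible(path)
}

#' Read a single-frame DICOM file
#'
#' @param path Path to a part-10 explicit-VR little-endian file.
#' @return A list with `pixels` (integer matrix of stored values, rows x
#'   cols), `meta` (canonical named fields), `rescale_slope`,
#'   `rescale_intercept`, `instance_number`, `slice_position`, `series_uid`.
#' @keywords internal
read_dicom_slice <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  if (length(bytes) < 140L || rawToChar(bytes[129:132]) != "DICM")
    stop("format error: not a part-10 DICOM file")

  pos <- 133L  # next unread byte (1-based)
  n <- length(bytes)
  u16 <- function(off) readBin(bytes[off:(off + 1L)], "integer", size = 2L,
                               signed = FALSE, endian = "little")
  u32 <- function(off) readBin(bytes[off:(off + 3L)], "integer", size = 4L,
                               endian = "little")
  elements <- list()
  while (pos + 7L <= n) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("format error: implicit VR or corrupt element")
    if (vr %in% .dcm_long_vrs) {
      len <- u32(pos + 8L); pos <- pos + 12L
    } else {
      len <- u16(pos + 6L); pos <- pos + 8L
    }
    if (vr == "SQ") stop("format error: sequences unsupported")
    if (len < 0L || pos + len - 1L > n)
      stop("format error: element overruns file")
    val_raw <- if (len > 0L) bytes[pos:(pos + len - 1L)] else raw(0)
    pos <- pos + len
    key <- .dcm_tag_key(group, elem)
    elements[[key]] <- list(vr = vr, raw = val_raw)
  }

  getel <- function(key) elements[[key]]
  as_str <- function(key) {
    el <- getel(key)
    if (is.null(el)) return(NULL)
    trimws(rawToChar(el$raw))
  }
  as_num <- function(key) {
    s <- as_str(key)
    if (is.null(s) || !nzchar(s)) return(NULL)
    as.numeric(strsplit(s, "\\\\", fixed = FALSE)[[1L]])
  }
  as_us <- function(key) {
    el <- getel(key)
    if (is.null(el)) return(NULL)
    readBin(el$raw, "integer", size = 2L, signed = FALSE, endian = "little")
  }

  rows <- as_us("00280010"); cols <- as_us("00280011")
  bits <- as_us("00280100")
  if (is.null(rows) || is.null(cols) || is.null(bits) || bits != 16L)
    stop("format error: missing or unsupported pixel description")
  signed <- identical(as_us("00280103"), 1L)
  px <- getel("7FE00010")
  if (is.null(px)) stop("format error: no pixel data")
  vals <- readBin(px$raw, "integer", n = rows * cols, size = 2L,
                  signed = signed, endian = "little")
  pixels <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)

  meta <- list()
  for (key in names(.dcm_tag_names)) {
    v <- as_str(key)
    if (!is.null(v)) meta[[.dcm_tag_names[[key]]]] <- v
  }
  ipp <- as_num("00200032")
  loc <- as_num("00201041")
  list(
    pixels = pixels,
    meta = meta,
    rescale_slope = if (is.null(as_num("00281053"))) 1 else as_num("00281053"),
    rescale_intercept = if (is.null(as_num("00281052"))) 0 else as_num("00281052"),
    instance_number = if (is.null(as_num("00200013"))) NA_real_ else as_num("00200013"),
    slice_position = if (!is.null(ipp) && length(ipp) >= 3L) ipp[3L]
                     else if (!is.null(loc)) loc else NA_real_,
    series_uid = meta$series_uid
  )
}
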