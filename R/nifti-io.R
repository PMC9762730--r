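# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# The pre-installed R stack carries no NIfTI package, so the subset of the
# format this package needs is implemented here: one 3-D (or 4-D, first
# volume) image per file, little- or big-endian headers, integer and float
# datatypes, scl_slope/scl_inter scaling, and the sform/qform rows needed to
# decide through-plane direction. Everything else (extensions, multi-file
# .hdr/.img pairs, shear/oblique handling) is out of scope.

.nii_datatypes <- list(
  `2`   = list(what = "integer", size = 1, signed = FALSE),
  `4`   = list(what = "integer", size = 2, signed = TRUE),
  `8`   = list(what = "integer", size = 4, signed = TRUE),
  `16`  = list(what = "double",  size = 4, signed = TRUE),
  `64`  = list(what = "double",  size = 8, signed = TRUE),
  `512` = list(what = "integer", size = 2, signed = FALSE)
)

.nii_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a NIfTI-1 volume
#'
#' Low-level reader returning the raw image array plus the header fields the
#' ingestion layer needs. Most users want [load_nifti_volume()] instead.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with `img` (array, storage order x,y,z), `dim`, `pixdim`,
#'   `descrip`, `srow` (3x4 matrix or `NULL`), `qfac`, `sform_code`,
#'   `qform_code`.
#' @keywords internal
read_nifti <- function(path) {
  con <- .nii_open(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- readBin(con, "raw", 352L)
  if (length(hdr) < 348L) stop("format error: truncated NIfTI header")

  ri16 <- function(off, n = 1L, endian) readBin(hdr[(off + 1L):(off + 2L * n)],
    "integer", n = n, size = 2L, endian = endian)
  ri32 <- function(off, n = 1L, endian) readBin(hdr[(off + 1L):(off + 4L * n)],
    "integer", n = n, size = 4L, endian = endian)
  rf32 <- function(off, n = 1L, endian) readBin(hdr[(off + 1L):(off + 4L * n)],
    "double", n = n, size = 4L, endian = endian)

  endian <- "little"
  if (ri32(0L, 1L, endian) != 348L) {
    endian <- "big"
    if (ri32(0L, 1L, endian) != 348L) stop("format error: not a NIfTI-1 file")
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("format error: bad NIfTI magic")

  dims <- ri16(40L, 8L, endian)
  ndim <- dims[1L]
  if (ndim < 3L || any(dims[2:4] < 1L) || dims[4L] < 2L)
    stop("not a volume: fewer than 3 spatial dimensions")
  datatype <- ri16(70L, 1L, endian)
  dt <- .nii_datatypes[[as.character(datatype)]]
  if (is.null(dt)) stop(sprintf("format error: unsupported datatype %d", datatype))

  pixdim <- rf32(76L, 8L, endian)
  vox_offset <- rf32(108L, 1L, endian)
  scl_slope <- rf32(112L, 1L, endian)
  scl_inter <- rf32(116L, 1L, endian)
  descrip_raw <- hdr[149:228]
  nul <- which(descrip_raw == as.raw(0))
  descrip <- rawToChar(descrip_raw[seq_len(if (length(nul)) nul[1L] - 1L else 80L)])
  qform_code <- ri16(252L, 1L, endian)
  sform_code <- ri16(254L, 1L, endian)
  srow <- rbind(rf32(280L, 4L, endian), rf32(296L, 4L, endian), rf32(312L, 4L, endian))

  nxyz <- as.integer(dims[2:4])
  nvox <- prod(nxyz)
  # position connection at vox_offset (we already consumed 352 bytes)
  skip <- as.integer(round(vox_offset)) - 352L
  if (skip < 0L) stop("format error: vox_offset below header size")
  if (skip > 0L) readBin(con, "raw", skip)
  vals <- readBin(con, dt$what, n = nvox, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(vals) < nvox) stop("format error: truncated NIfTI data")
  img <- array(as.double(vals), dim = nxyz)
  if (!is.na(scl_slope) && scl_slope != 0)
    img <- img * scl_slope + scl_inter

  list(img = img, dim = nxyz, pixdim = pixdim[2:4], descrip = descrip,
       srow = if (sform_code > 0L) srow else NULL,
       qfac = if (pixdim[1L] == 0) 1 else pixdim[1L],
       sform_code = sform_code, qform_code = qform_code)
}

#' Write a NIfTI-1 volume
#'
#' Writes a 3-D array (storage order x,y,z) as float32 with an axis-aligned
#' sform. `axial_sign` < 0 stores the volume with a negative through-plane
#' direction, i.e. stored slice order runs superior-to-inferior.
#'
#' @param img 3-D numeric array in x,y,z storage order.
#' @param path Output path; `.gz` suffix triggers gzip compression.
#' @param pixdim Voxel sizes in mm, length 3.
#' @param descrip Free-text header field (max 79 bytes; used by the phantom
#'   generator to plant header metadata).
#' @param axial_sign +1 or -1, sign of the z row of the sform.
#' @return `path`, invisibly.
#' @keywords internal
write_nifti <- function(img, path, pixdim = c(1, 1, 1), descrip = "",
                        axial_sign = 1) {
  stopifnot(length(dim(img)) == 3L)
  con <- .nii_open(path, "wb")
  on.exit(close(con), add = TRUE)
  wi16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  wi32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf32 <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  wpad <- function(n) writeBin(raw(n), con)
  wchr <- function(s, n) {
    b <- charToRaw(s)
    if (length(b) > n) b <- b[seq_len(n)]
    writeBin(c(b, raw(n - length(b))), con)
  }

  d <- dim(img)
  wi32(348L)                       # sizeof_hdr
  wpad(36L)                        # data_type..dim_info
  wi16(c(3L, d, 1L, 1L, 1L, 1L))   # dim[8]
  wf32(c(0, 0, 0))                 # intent_p1..p3
  wi16(0L)                         # intent_code
  wi16(16L)                        # datatype: float32
  wi16(32L)                        # bitpix
  wi16(0L)                         # slice_start
  wf32(c(1, pixdim, 1, 1, 1, 1))   # pixdim[8], qfac = 1
  wf32(352)                        # vox_offset
  wf32(1); wf32(0)                 # scl_slope, scl_inter
  wi16(0L); wpad(2L)               # slice_end, slice_code + xyzt_units
  wf32(c(0, 0, 0, 0))              # cal_max..toffset
  wi32(c(0L, 0L))                  # glmax, glmin
  wchr(descrip, 80L)
  wpad(24L)                        # aux_file
  wi16(0L)                         # qform_code
  wi16(1L)                         # sform_code
  wf32(c(0, 0, 0)); wf32(c(0, 0, 0))   # quatern, qoffset
  wf32(c(pixdim[1L], 0, 0, 0))
  wf32(c(0, pixdim[2L], 0, 0))
  zoff <- if (axial_sign < 0) pixdim[3L] * (d[3L] - 1L) else 0
  wf32(c(0, 0, sign(axial_sign) * pixdim[3L], zoff))
  wpad(16L)                        # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  wpad(4L)                         # extender
  writeBin(as.double(img), con, size = 4L, endian = "little")
  invisible(path)
}
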