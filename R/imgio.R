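#' Default anonymization policy
#'
#' A deny-list of direct identifiers stripped from every ingested volume's
#' metadata. Fields that a format requires but that carry private content are
#' replaced by `replacement_token` when files are (re)written. Full
#' profile-based de-identification is out of scope.
#'
#' @param fields_to_remove Character vector of canonical header-field names.
#' @param replacement_token Replacement string for mandatory-but-private
#'   fields.
#' @return An object of class `anonymization_policy`.
#' @export
#' @examples
#' default_anonymization_policy()
default_anonymization_policy <- function(
    fields_to_remove = c("patient_name", "patient_birth_date",
                         "patient_address", "patient_phone",
                         "operators_name", "institution_name"),
    replacement_token = "ANON") {
  stopifnot(length(fields_to_remove) >= 1L, is.character(fields_to_remove))
  structure(list(fields_to_remove = fields_to_remove,
                 replacement_token = replacement_token),
            class = "anonymization_policy")
}

.apply_policy <- function(meta, policy) {
  meta[setdiff(names(meta), policy$fields_to_remove)]
}

.new_volume_record <- function(patient_id, series_id, voxels, slice_order,
                               metadata, source = "") {
  stopifnot(length(dim(voxels)) == 3L, dim(voxels)[1L] >= 1L)
  structure(list(patient_id = patient_id, series_id = series_id,
                 voxels = voxels, slice_order = as.integer(slice_order),
                 metadata = metadata, source = source),
            class = "volume_record")
}

#' @export
print.volume_record <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<volume_record> patient=%s series=%s  %d slices of %dx%d\n",
              x$patient_id, x$series_id, d[1L], d[2L], d[3L]))
  invisible(x)
}

#' Load a DICOM series directory as one volume
#'
#' Reads every single-frame DICOM file of one series, applies the stored
#' rescale slope/intercept (so voxels are in Hounsfield units for CT), sorts
#' slices by through-plane position (instance number as fallback), and strips
#' every metadata field named in the anonymization policy.
#'
#' @param dir_path Directory holding the files of exactly one series.
#' @param policy An [default_anonymization_policy()] object.
#' @return A `volume_record`: `voxels` is a slices x rows x cols array in
#'   sorted slice order, `slice_order` the 0-based permutation mapping sorted
#'   position to stored file order, `metadata` the retained header fields.
#' @export
load_dicom_series <- function(dir_path, policy = default_anonymization_policy()) {
  files <- sort(list.files(dir_path, pattern = "\\.dcm$", full.names = TRUE))
  if (length(files) == 0L)
    files <- sort(list.files(dir_path, full.names = TRUE))
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("no input: empty directory ", dir_path)

  slices <- lapply(files, read_dicom_slice)
  uids <- vapply(slices, function(s) s$series_uid %||% "", "")
  if (length(unique(uids)) > 1L)
    stop("inconsistent series: multiple series identities in ", dir_path)
  dims <- vapply(slices, function(s) dim(s$pixels), integer(2L))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent geometry: in-plane dimensions differ in ", dir_path)

  pos <- vapply(slices, function(s) s$slice_position, 0)
  inst <- vapply(slices, function(s) s$instance_number, 0)
  if (anyNA(pos)) pos <- inst
  ord <- order(pos, inst)

  nr <- dims[1, 1]; nc <- dims[2, 1]
  vox <- array(0, dim = c(length(slices), nr, nc))
  for (i in seq_along(ord)) {
    s <- slices[[ord[i]]]
    vox[i, , ] <- s$pixels * s$rescale_slope + s$rescale_intercept
  }
  meta <- .apply_policy(slices[[ord[1L]]]$meta, policy)
  pid <- slices[[1L]]$meta$patient_id %||% basename(dir_path)
  sid <- slices[[1L]]$meta$series_description %||% slices[[1L]]$series_uid %||%
    basename(dir_path)
  .new_volume_record(pid, sid, vox, ord - 1L, meta, source = dir_path)
}

#' Load a NIfTI volume
#'
#' The axial (through-plane) axis is taken from the stored orientation: the
#' voxel axis with the largest z-component of the sform. A negative
#' through-plane direction reverses the slice order so returned slices always
#' run inferior-to-superior. 4-D inputs use volume 0.
#'
#' @inheritParams load_dicom_series
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A `volume_record` (see [load_dicom_series()]).
#' @export
load_nifti_volume <- function(path, policy = default_anonymization_policy()) {
  nii <- tryCatch(read_nifti(path), error = function(e) {
    if (grepl("not a volume", conditionMessage(e))) stop(e)
    stop("format error: ", conditionMessage(e), call. = FALSE)
  })
  img <- nii$img
  ax <- 3L
  ascending <- TRUE
  if (!is.null(nii$srow)) {
    ax <- which.max(abs(nii$srow[3L, 1:3]))
    ascending <- nii$srow[3L, ax] >= 0
  } else if (nii$qform_code > 0L) {
    ascending <- nii$qfac >= 0
  }
  if (ax != 3L) img <- aperm(img, order(replace(c(1L, 2L, 3L), ax, 4L)))
  nz <- dim(img)[3L]
  stored <- seq_len(nz)
  ord <- if (ascending) stored else rev(stored)

  # voxels: slices x rows x cols, slice s = transposed in-plane matrix
  vox <- aperm(img[, , ord, drop = FALSE], c(3L, 2L, 1L))

  meta <- list()
  if (nzchar(nii$descrip)) {
    for (kv in strsplit(strsplit(nii$descrip, ";", fixed = TRUE)[[1L]], "=", fixed = TRUE)) {
      if (length(kv) == 2L) meta[[trimws(kv[1L])]] <- trimws(kv[2L])
    }
    if (length(meta) == 0L) meta$descrip <- nii$descrip
  }
  meta <- .apply_policy(meta, policy)
  base <- sub("\\.nii(\\.gz)?$", "", basename(path))
  pid <- meta$patient_id %||% base
  sid <- meta$series_id %||% base
  .new_volume_record(pid, sid, vox, ord - 1L, meta, source = path)
}

#' Split a volume into windowed axial slices
#'
#' Applies a linear CT display window: intensities in
#' `[center - width/2, center + width/2]` map to `[0, 1]`, values outside are
#' clipped. The default soft-tissue window (center 40 HU, width 400 HU) is
#' the standard abdominal viewing window.
#'
#' @param volume A `volume_record`.
#' @param window_center,window_width Window parameters in the volume's
#'   intensity units (HU for CT). `window_width` must be positive.
#' @return A list of `slice_image` objects in anatomical order; each has
#'   `pixels` in `[0, 1]` and a 0-based `slice_index`.
#' @export
split_axial <- function(volume, window_center = 40, window_width = 400) {
  stopifnot(inherits(volume, "volume_record"))
  if (!is.numeric(window_width) || window_width <= 0)
    stop("invalid window: window_width must be > 0")
  lo <- window_center - window_width / 2
  dims <- dim(volume$voxels)
  lapply(seq_len(dims[1L]), function(s) {
    p <- matrix(volume$voxels[s, , ], dims[2L], dims[3L])
    p <- (p - lo) / window_width
    p[p < 0] <- 0; p[p > 1] <- 1
    new_slice_image(volume$patient_id, volume$series_id, s - 1L, p,
                    source_path = volume$source)
  })
}

#' Construct a slice image
#'
#' @param patient_id,series_id Opaque identifying tokens.
#' @param slice_index 0-based position in anatomical order.
#' @param pixels Numeric matrix with values in `[0, 1]`.
#' @param source_path Provenance string.
#' @return A `slice_image` object.
#' @export
new_slice_image <- function(patient_id, series_id, slice_index, pixels,
                            source_path = "") {
  stopifnot(is.matrix(pixels), slice_index >= 0L)
  structure(list(patient_id = as.character(patient_id),
                 series_id = as.character(series_id),
                 slice_index = as.integer(slice_index),
                 pixels = pixels, source_path = source_path),
            class = "slice_image")
}

#' @export
print.slice_image <- function(x, ...) {
  cat(sprintf("<slice_image> %s/%s #%d  %dx%d px in [%.3f, %.3f]\n",
              x$patient_id, x$series_id, x$slice_index,
              nrow(x$pixels), ncol(x$pixels), min(x$pixels), max(x$pixels)))
  invisible(x)
}

.slice_filename <- function(slice) {
  sprintf("%s_%s_%04d.png", slice$patient_id, slice$series_id,
          slice$slice_index)
}

#' Write a slice as an 8-bit grayscale PNG
#'
#' Bytes are `round(pixel * 255)` with round-half-up, so a read-back
#' reproduces the quantized values exactly. Filenames follow
#' `{patient}_{series}_{index:04d}.png`. No metadata is embedded.
#'
#' @param slice A `slice_image` with pixels in `[0, 1]`.
#' @param out_dir Existing or creatable output directory.
#' @return The written file path.
#' @export
write_png <- function(slice, out_dir) {
  stopifnot(inherits(slice, "slice_image"))
  if (any(slice$pixels < 0 | slice$pixels > 1))
    stop("pixels outside [0,1]; window the slice first")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("I/O error: cannot create ", out_dir)
  path <- file.path(out_dir, .slice_filename(slice))
  q <- floor(slice$pixels * 255 + 0.5)  # round half up
  ok <- tryCatch({png::writePNG(q / 255, path); TRUE},
                 error = function(e) FALSE)
  if (!ok) stop("I/O error: cannot write ", path)
  path
}

#' Read back an 8-bit grayscale PNG as a matrix in `[0, 1]`
#'
#' @param path PNG file path.
#' @return Numeric matrix of `byte / 255` values.
#' @export
read_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}

`%||%` <- function(a, b) if (is.null(a)) b else a
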