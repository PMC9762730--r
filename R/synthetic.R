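# Synthetic phantom cohorts. Each patient is an axial CT-like stack in
# Hounsfield units: a smooth low-frequency "anatomy" background plus iid
# Gaussian noise; a contiguous run of slices additionally carries a bright
# elliptical lesion with a Gaussian-feathered edge. Lesion contrast is
# `separation * noise_sd`, so `separation` is the class separability in
# noise-sd units. Patients alternate between two classes that differ only in
# the lesion's internal speckle variance (a learnable texture signal for the
# downstream demo). Per-slice ground-truth relevance makes every pipeline
# stage testable without external data.

#' Phantom cohort specification
#'
#' Defaults describe the stated desk-scale world: 20 patients, 40 axial
#' slices of 64x64 voxels each, a 10-slice tumor run, background noise sd
#' 20 HU (typical soft-tissue CT noise), lesion contrast
#' `separation * noise_sd`.
#'
#' @param n_patients Number of patients (volumes).
#' @param n_slices Axial slices per volume.
#' @param image_size In-plane size in voxels (square).
#' @param tumor_run Integer pair `(start, end)`, inclusive 0-based slice
#'   interval containing the lesion.
#' @param separation Lesion contrast in units of `noise_sd`; 0 means
#'   tumor-level slices are statistically identical to background.
#' @param noise_sd Gaussian voxel noise sd, HU.
#' @param background_amplitude Amplitude range of the low-frequency cosine
#'   anatomy texture, HU.
#' @param base_hu Mean background intensity, HU (soft tissue ~ 40).
#' @param class_speckle Named internal-texture sd multipliers for the two
#'   patient classes.
#' @param seed Integer; the whole cohort is a deterministic function of it.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(n_patients = 20L, n_slices = 40L, image_size = 64L,
                         tumor_run = c(15L, 24L), separation = 3,
                         noise_sd = 20, background_amplitude = c(10, 25),
                         base_hu = 40,
                         class_speckle = c(Class1 = 0.9, Class2 = 0.3),
                         seed = 0L) {
  tumor_run <- as.integer(tumor_run)
  if (length(tumor_run) != 2L || tumor_run[1L] < 0L ||
      tumor_run[1L] > tumor_run[2L] || tumor_run[2L] >= n_slices)
    stop("bad tumor_run: need 0 <= start <= end < n_slices")
  stopifnot(separation >= 0, noise_sd > 0, n_patients >= 1L, image_size >= 16L)
  structure(list(n_patients = as.integer(n_patients),
                 n_slices = as.integer(n_slices),
                 image_size = as.integer(image_size),
                 tumor_run = tumor_run, separation = separation,
                 noise_sd = noise_sd,
                 background_amplitude = background_amplitude,
                 base_hu = base_hu, class_speckle = class_speckle,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

.phantom_patient_ids <- function(spec) sprintf("P%03d", seq_len(spec$n_patients))

.phantom_classes <- function(spec) {
  ifelse(seq_len(spec$n_patients) %% 2L == 1L, "Class1", "Class2")
}

# one volume as slices x rows x cols array of HU, deterministic given the
# RNG state at entry
.phantom_volume <- function(spec, class_label) {
  m <- spec$image_size; S <- spec$n_slices
  u <- (seq_len(m) - 0.5) / m

  # One low-frequency in-plane texture per volume, constant along z: slices
  # must differ only by noise (and, inside the tumor run, by the lesion), so
  # that `separation` is the sole slice-relevance signal and s = 0 is a true
  # null. Through-plane anatomy drift is deliberately not modelled.
  bg <- matrix(0, m, m)
  for (j in 1:4) {
    amp <- stats::runif(1, spec$background_amplitude[1L],
                        spec$background_amplitude[2L])
    fx <- stats::runif(1, 0.5, 2.5); fy <- stats::runif(1, 0.5, 2.5)
    ph <- stats::runif(1, 0, 2 * pi)
    bg <- bg + amp * cos(2 * pi * outer(u * fy, u * fx, "+") + ph)
  }
  vol <- array(stats::rnorm(S * m * m, 0, spec$noise_sd), dim = c(S, m, m))
  vol <- vol + rep(spec$base_hu + bg, each = S)

  cx <- stats::runif(1, 0.4, 0.6); cy <- stats::runif(1, 0.4, 0.6)
  rx <- stats::runif(1, 0.12, 0.22); ry <- stats::runif(1, 0.12, 0.22)
  d <- sqrt(outer(((u - cy) / ry)^2, ((u - cx) / rx)^2, "+"))
  feather <- 1 / (1 + exp((d - 1) / 0.08))
  # Lesion contrast and internal speckle both scale with `separation`: at
  # s = 0 nothing is added, so tumor-run slices are exactly exchangeable
  # with background slices (a true null for the filterability tests).
  amp <- spec$separation * spec$noise_sd
  tau <- spec$class_speckle[[class_label]]
  run <- spec$tumor_run
  for (s in (run[1L]:run[2L]) + 1L) {
    speckle <- matrix(stats::rnorm(m * m), m, m) * (tau * amp)
    vol[s, , ] <- vol[s, , ] + feather * (amp + speckle)
  }
  vol
}

#' Generate a phantom cohort
#'
#' Writes one file (NIfTI) or one directory (DICOM series) per patient under
#' `out_dir`, plus returns the ground-truth table. Headers deliberately
#' contain planted private fields (patient name, birth date, institution,
#' operator, address, phone) so anonymization is exercised end to end. The
#' output is byte-identical for a fixed spec (including seed).
#'
#' @param spec A [phantom_spec()].
#' @param out_dir Output directory, created if needed. `NULL` keeps the
#'   cohort in memory only (`volumes` field), which the property tests use
#'   for speed.
#' @param format `"nifti"` (default, one `.nii` per patient) or `"dicom"`
#'   (one directory of single-frame files per patient).
#' @return A list with `truth` (data frame: `patient_id`, `series_id`,
#'   `slice_index`, `relevant`, `class_label`), `files` (written paths, or
#'   `NULL`), `volumes` (in-memory `volume_record`s when `out_dir` is
#'   `NULL`), and `spec`.
#' @export
generate_cohort <- function(spec, out_dir = NULL,
                            format = c("nifti", "dicom")) {
  format <- match.arg(format)
  stopifnot(inherits(spec, "phantom_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  ids <- .phantom_patient_ids(spec)
  classes <- .phantom_classes(spec)
  write <- !is.null(out_dir)
  if (write) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  files <- character(0)
  volumes <- list()
  truth <- vector("list", spec$n_patients)
  run <- spec$tumor_run
  for (i in seq_len(spec$n_patients)) {
    vol <- .phantom_volume(spec, classes[i])
    sid <- sprintf("S%03d", i)
    truth[[i]] <- data.frame(
      patient_id = ids[i], series_id = sid,
      slice_index = seq_len(spec$n_slices) - 1L,
      relevant = seq_len(spec$n_slices) - 1L >= run[1L] &
                 seq_len(spec$n_slices) - 1L <= run[2L],
      class_label = classes[i], stringsAsFactors = FALSE)

    if (!write) {
      volumes[[i]] <- .new_volume_record(
        ids[i], sid, vol, seq_len(spec$n_slices) - 1L,
        metadata = list(class_hint = classes[i]), source = "<memory>")
      next
    }
    if (format == "nifti") {
      path <- file.path(out_dir, paste0(ids[i], ".nii"))
      # descrip is capped at 79 bytes; keep the planted fields short
      descrip <- sprintf(
        "patient_id=%s;series_id=%s;patient_name=PHANTOM^%s;institution_name=SYN",
        ids[i], sid, ids[i])
      # storage order x,y,z: invert the slices x rows x cols convention
      img <- aperm(vol, c(3L, 2L, 1L))
      write_nifti(img, path, descrip = descrip)
      files <- c(files, path)
    } else {
      sdir <- file.path(out_dir, ids[i])
      dir.create(sdir, showWarnings = FALSE)
      uid <- paste0("1.2.826.0.1.3680043.8888.", i)
      for (s in seq_len(spec$n_slices)) {
        stored <- matrix(as.integer(round(vol[s, , ])), spec$image_size,
                         spec$image_size)
        path <- file.path(sdir, sprintf("slice_%04d.dcm", s))
        write_dicom_slice(path, stored,
          meta = list(patient_id = ids[i], series_uid = uid,
                      series_description = sid,
                      patient_name = paste0("PHANTOM^", ids[i]),
                      institution_name = "SYNTH_HOSPITAL"),
          instance_number = s, slice_position = (s - 1L) * 5,
          rescale_slope = 1, rescale_intercept = 0)
        files <- c(files, path)
      }
    }
  }
  list(truth = do.call(rbind, truth), files = if (write) files else NULL,
       volumes = if (!write) volumes else NULL, spec = spec,
       dir = if (write) out_dir else NULL)
}

#' Patient-level train/test split
#'
#' Splits at the patient level (never slice level) so no patient leaks
#' between sides; the split is a deterministic function of the spec's seed.
#' The default fraction emulates a 300/360 train share.
#'
#' @param spec A [phantom_spec()].
#' @param train_fraction Fraction of patients assigned to training,
#'   strictly between 0 and 1; both sides must be non-empty.
#' @return List with character vectors `train` and `test` of patient ids.
#' @export
generate_labeled_split <- function(spec, train_fraction = 300 / 360) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    stop("degenerate split: train_fraction must be in (0, 1)")
  ids <- .phantom_patient_ids(spec)
  n_train <- round(spec$n_patients * train_fraction)
  if (n_train < 1L || n_train >= spec$n_patients)
    stop("degenerate split: a side would be empty")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed + 1000003L)
  train <- sort(sample(ids, n_train))
  list(train = train, test = sort(setdiff(ids, train)))
}
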