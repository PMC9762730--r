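test_that("DICOM series loads sorted by through-plane position", {
  d <- write_scrambled_series(file.path(tempdir(), "scram"))
  v <- load_dicom_series(d)
  # positions written 30, 10, 20 -> sorted order is files 2, 3, 1
  expect_identical(v$slice_order, c(1L, 2L, 0L))
  # first voxel of each sorted slice encodes its position (pos*10 + 1)
  expect_equal(v$voxels[, 1, 1], c(101, 201, 301))
  expect_identical(v$patient_id, "PX")
  expect_identical(v$series_id, "SFIX")
  unlink(d, recursive = TRUE)
})

test_that("anonymization strips every policy field", {
  d <- write_scrambled_series(file.path(tempdir(), "anon"))
  pol <- default_anonymization_policy()
  v <- load_dicom_series(d, pol)
  expect_length(intersect(names(v$metadata), pol$fields_to_remove), 0)
  # a custom policy removes what it names, and only that
  pol2 <- default_anonymization_policy(fields_to_remove = "modality")
  v2 <- load_dicom_series(d, pol2)
  expect_false("modality" %in% names(v2$metadata))
  expect_true("patient_name" %in% names(v2$metadata))
  unlink(d, recursive = TRUE)
})

test_that("DICOM rescale slope/intercept is applied", {
  d <- file.path(tempdir(), "resc")
  dir.create(d, showWarnings = FALSE)
  px <- matrix(512L, 4, 4)
  write_dicom_slice(file.path(d, "a.dcm"), px,
                    rescale_slope = 2, rescale_intercept = -1024)
  v <- load_dicom_series(d)
  expect_equal(unique(as.vector(v$voxels)), 2 * 512 - 1024)  # = 0
  unlink(d, recursive = TRUE)
})

test_that("DICOM ingestion errors are specific", {
  empty <- file.path(tempdir(), "emptyser")
  dir.create(empty, showWarnings = FALSE)
  expect_error(load_dicom_series(empty), "no input")

  mixed <- file.path(tempdir(), "mixed")
  dir.create(mixed, showWarnings = FALSE)
  write_dicom_slice(file.path(mixed, "a.dcm"), matrix(1L, 4, 4),
                    meta = list(series_uid = "1.1"))
  write_dicom_slice(file.path(mixed, "b.dcm"), matrix(1L, 4, 4),
                    meta = list(series_uid = "1.2"))
  expect_error(load_dicom_series(mixed), "inconsistent series")

  geo <- file.path(tempdir(), "geo")
  dir.create(geo, showWarnings = FALSE)
  write_dicom_slice(file.path(geo, "a.dcm"), matrix(1L, 4, 4))
  write_dicom_slice(file.path(geo, "b.dcm"), matrix(1L, 6, 4))
  expect_error(load_dicom_series(geo), "inconsistent geometry")
  unlink(c(empty, mixed, geo), recursive = TRUE)
})

test_that("NIfTI volumes load with shape, determinism and axial flip", {
  path <- tempfile(fileext = ".nii")
  img <- array(seq_len(4 * 4 * 5), dim = c(4, 4, 5))
  write_nifti(img, path)
  v <- load_nifti_volume(path)
  expect_identical(dim(v$voxels), c(5L, 4L, 4L))
  expect_identical(v$slice_order, 0:4)
  v2 <- load_nifti_volume(path)
  expect_identical(v$voxels, v2$voxels)

  # negative z row in the sform: stored order must be reversed on load.
  # Oracle: the affine maps storage index k to z = -k + const, so the
  # anatomically first (lowest-z) slice is the last stored one.
  flip <- tempfile(fileext = ".nii")
  write_nifti(img, flip, axial_sign = -1)
  vf <- load_nifti_volume(flip)
  expect_identical(vf$slice_order, 4:0)
  expect_identical(vf$voxels[1, , ], v$voxels[5, , ])
  expect_identical(vf$voxels[5, , ], v$voxels[1, , ])

  # gz round trip
  gz <- tempfile(fileext = ".nii.gz")
  write_nifti(img, gz)
  expect_identical(load_nifti_volume(gz)$voxels, v$voxels)
  unlink(c(path, flip, gz))
})

test_that("NIfTI loader agrees with an independent reader (nibabel)", {
  path <- tempfile(fileext = ".nii")
  set.seed(7)
  img <- array(round(rnorm(6 * 5 * 4), 3), dim = c(6, 5, 4))
  write_nifti(img, path)
  out <- suppressWarnings(system2("python", c("-c", shQuote(paste0(
    "import nibabel, numpy as np;",
    "d = np.asanyarray(nibabel.load('", path, "').dataobj);",
    "print(d.shape); print(float(d.sum()), float(d[2,3,1]))"
  ))), stdout = TRUE, stderr = TRUE))
  expect_true(length(out) >= 2L && grepl("^\\(6, 5, 4\\)", out[1L]))
  nums <- as.numeric(strsplit(out[2L], " ")[[1L]])
  expect_equal(nums[1L], sum(img), tolerance = 1e-5)
  expect_equal(nums[2L], img[3, 4, 2], tolerance = 1e-5)
  unlink(path)
})

test_that("NIfTI error cases", {
  bad <- tempfile(fileext = ".nii")
  writeBin(as.raw(1:100), bad)
  expect_error(load_nifti_volume(bad), "format error")
  unlink(bad)
  suppressWarnings(  # file() warns before the reader errors
    expect_error(load_nifti_volume(tempfile(fileext = ".nii")), "format error"))
})

test_that("split_axial windows linearly with clipping", {
  vox <- array(40, dim = c(3, 4, 4))
  vol <- rknet:::.new_volume_record("P", "S", vox, 0:2, list())
  sl <- split_axial(vol, 40, 400)
  expect_length(sl, 3L)
  expect_true(all(vapply(sl, function(s) all(s$pixels == 0.5), TRUE)))
  expect_identical(vapply(sl, `[[`, 0L, "slice_index"), 0:2)

  vox2 <- array(rep(c(-160, -500, 240, 999, 140), each = 1), dim = c(5, 1, 1))
  vol2 <- rknet:::.new_volume_record("P", "S", vox2, 0:4, list())
  px <- vapply(split_axial(vol2, 40, 400), function(s) s$pixels[1, 1], 0)
  expect_equal(px, c(0, 0, 1, 1, 0.75))  # (140 - (-160)) / 400 = 0.75

  expect_error(split_axial(vol, 40, 0), "invalid window")
  expect_error(split_axial(vol, 40, -10), "invalid window")
})

test_that("write_png quantizes round-half-up and round-trips exactly", {
  s <- make_slice(matrix(c(0, 0.5, 1, 0.2), 2, 2))
  d <- file.path(tempdir(), "pngs")
  path <- write_png(s, d)
  expect_identical(basename(path), "P1_S1_0000.png")
  back <- read_png(path)
  expect_equal(back * 255, matrix(c(0, 128, 255, 51), 2, 2))

  set.seed(3)
  s2 <- make_slice(matrix(runif(64), 8, 8), index = 12L)
  p2 <- write_png(s2, d)
  expect_identical(basename(p2), "P1_S1_0012.png")
  expect_identical(read_png(p2), read_png(write_png(s2, d)))
  expect_true(max(abs(read_png(p2) - s2$pixels)) <= 1 / 255 + 1e-12)
  unlink(d, recursive = TRUE)
})

test_that("window + PNG round trip stays within one gray level", {
  set.seed(11)
  vox <- array(rnorm(4 * 8 * 8, 40, 150), dim = c(4, 8, 8))
  vol <- rknet:::.new_volume_record("P7", "S7", vox, 0:3, list())
  d <- file.path(tempdir(), "rt")
  for (s in split_axial(vol)) {
    back <- read_png(write_png(s, d))
    expect_lt(max(abs(back - s$pixels)), 1 / 255)
  }
  expect_length(list.files(d), 4L)  # slice-count conservation
  unlink(d, recursive = TRUE)
})
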