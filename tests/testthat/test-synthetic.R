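test_that("phantom cohorts are deterministic and carry exact truth", {
  spec <- phantom_spec(n_patients = 2, n_slices = 12, tumor_run = c(4, 7),
                       seed = 3)
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  c1 <- generate_cohort(spec, d1)
  c2 <- generate_cohort(spec, d2)
  for (i in seq_along(c1$files)) {
    expect_identical(readBin(c1$files[i], "raw", file.size(c1$files[i])),
                     readBin(c2$files[i], "raw", file.size(c2$files[i])))
  }
  # relevance is true exactly on the tumor run
  tt <- c1$truth[c1$truth$patient_id == "P001", ]
  expect_identical(which(tt$relevant) - 1L, 4:7)
  expect_identical(unique(c1$truth$class_label[c1$truth$patient_id == "P001"]),
                   "Class1")
  expect_identical(unique(c1$truth$class_label[c1$truth$patient_id == "P002"]),
                   "Class2")
  expect_error(phantom_spec(n_slices = 10, tumor_run = c(8, 12)),
               "bad tumor_run")
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("dicom-format cohorts round-trip through the series loader", {
  spec <- phantom_spec(n_patients = 1, n_slices = 4, tumor_run = c(1, 2),
                       image_size = 16, seed = 5)
  d <- file.path(tempdir(), "dcoh")
  co <- generate_cohort(spec, d, format = "dicom")
  v <- load_dicom_series(file.path(d, "P001"))
  expect_identical(dim(v$voxels), c(4L, 16L, 16L))
  expect_identical(v$patient_id, "P001")
  expect_identical(v$series_id, "S001")
  # planted private fields are stripped by the default policy
  expect_false(any(c("patient_name", "institution_name") %in%
                   names(v$metadata)))
  unlink(d, recursive = TRUE)
})

test_that("at separation 0 tumor slices are exchangeable with background", {
  # identical RNG stream, amplitude and speckle both scale to 0
  spec0 <- phantom_spec(n_patients = 1, separation = 0, seed = 2)
  co <- generate_cohort(spec0)
  v <- co$volumes[[1]]
  tt <- co$truth[co$truth$patient_id == v$patient_id, ]
  in_run <- apply(v$voxels[tt$relevant, , ], 1, mean)
  out_run <- apply(v$voxels[!tt$relevant, , ], 1, mean)
  # same distribution: slice means differ only by noise-of-noise
  expect_lt(abs(mean(in_run) - mean(out_run)), 1)
})

test_that("patient-level splits partition without leakage", {
  spec <- phantom_spec(n_patients = 360, seed = 1)
  sp <- generate_labeled_split(spec, 300 / 360)
  expect_length(sp$train, 300L)
  expect_length(sp$test, 60L)
  expect_length(intersect(sp$train, sp$test), 0L)

  spec10 <- phantom_spec(n_patients = 10, seed = 4)
  for (seed in 0:5) {
    spec10$seed <- seed
    sp2 <- generate_labeled_split(spec10, 0.5)
    expect_length(sp2$train, 5L)
    expect_length(intersect(sp2$train, sp2$test), 0L)
    expect_setequal(c(sp2$train, sp2$test), sprintf("P%03d", 1:10))
  }
  expect_error(generate_labeled_split(spec10, 0), "degenerate split")
  expect_error(generate_labeled_split(spec10, 0.01), "degenerate split")
})

test_that("filter recovery increases with separation (scaled sweep)", {
  # scaled down from the acceptance version (20 seeds, 20 patients) to keep
  # the default suite fast; full-scale sweep runs in test-acceptance.R
  seeds <- 0:4
  rec <- sapply(c(0, 1, 3), function(s)
    mean(sapply(seeds, function(sd)
      phantom_filter_stats(s, sd, n_patients = 6L)$recovery)))
  expect_gte(rec[2], rec[1] - 0.05)  # non-decreasing up to sampling error
  expect_gte(rec[3], rec[2] - 0.05)
  expect_gt(rec[3], rec[1])          # strict between s=0 and s=3
  expect_gt(rec[3], 0.9)
})
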