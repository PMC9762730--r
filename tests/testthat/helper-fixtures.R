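# Shared fixtures, all built in code at test time.

make_slice <- function(pixels, patient = "P1", series = "S1", index = 0L) {
  new_slice_image(patient, series, index, pixels)
}

const_slice <- function(value, n = 16L, ...) {
  make_slice(matrix(value, n, n), ...)
}

# Three-slice DICOM series with through-plane positions 30, 10, 20 (written
# in that order) so position sorting is observable.
write_scrambled_series <- function(dir, positions = c(30, 10, 20),
                                   series_uid = "1.2.826.0.1.3680043.1.1",
                                   patient_id = "PX", size = 8L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(positions)) {
    px <- matrix(as.integer(positions[i] * 10 + seq_len(size * size)),
                 size, size)
    write_dicom_slice(
      file.path(dir, sprintf("f%d.dcm", i)), px,
      meta = list(patient_id = patient_id, series_uid = series_uid,
                  series_description = "SFIX",
                  patient_name = "DOE^JANE"),
      instance_number = i, slice_position = positions[i])
  }
  dir
}

# Per-series filtering statistics on an in-memory phantom cohort; used by
# the synthetic-module property tests and the acceptance criteria. Exemplars
# are 3 evenly spaced truth tumor slices per series.
phantom_filter_stats <- function(separation, seed, n_patients = 20L, ...) {
  spec <- phantom_spec(n_patients = n_patients, separation = separation,
                       seed = seed, ...)
  co <- generate_cohort(spec)
  rec <- recn <- fpr <- agree_fg <- numeric(0)
  for (v in co$volumes) {
    sl <- split_axial(v)
    fm <- extract_features(sl)
    m <- kmeans_fit(fm, k = 2L, seed = seed)
    tt <- co$truth[co$truth$patient_id == v$patient_id, ]
    run <- which(tt$relevant)
    exi <- run[unique(round(seq(1L, length(run), length.out = 3L)))]
    relmap <- map_clusters_to_relevance(m, fm, "exemplar",
                                        exemplars = tt[exi, ])
    pr <- unname(relmap[as.character(m$assignments)]) == "relevant"
    rec <- c(rec, mean(pr[tt$relevant]))
    recn <- c(recn, mean(pr[setdiff(run, exi)]))
    fpr <- c(fpr, mean(pr[!tt$relevant]))
    fg <- map_clusters_to_relevance(m, fm, "foreground-mass")
    pr_fg <- unname(fg[as.character(m$assignments)]) == "relevant"
    agree_fg <- c(agree_fg, mean(pr_fg[tt$relevant]) > 0.5 &&
                            mean(pr_fg[!tt$relevant]) < 0.5)
  }
  list(recovery = mean(rec), recovery_nonexemplar = mean(recn),
       fpr = mean(fpr), fg_mapping_agreement = mean(agree_fg))
}

# Exemplar table (3 evenly spaced truth tumor slices per series) for
# disk-based pipeline runs.
cohort_exemplars <- function(truth) {
  rel <- truth[truth$relevant, ]
  do.call(rbind, lapply(split(rel, rel$patient_id), function(d) {
    d[unique(round(seq(1L, nrow(d), length.out = 3L))), ]
  }))
}
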