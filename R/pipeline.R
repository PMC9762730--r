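# End-to-end orchestration: discover series under an input root, ingest,
# window/split, embed, cluster (per series by default), map clusters to
# relevance, write sorted PNGs and the CSV + JSON manifests. Series that
# fail ingestion are logged and skipped; the run fails only if nothing
# ingests.

.with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

#' Pipeline configuration
#'
#' One declarative object covering every stage. Defaults: soft-tissue window
#' (40/400 HU), reference extractor with z-scoring, k-means with k = 2,
#' k-means++ seeding and 10 restarts, per-series clustering scope,
#' foreground-mass relevance rule, seed 0.
#'
#' @param window_center,window_width CT display window, HU.
#' @param extractor An [extractor_config()].
#' @param normalize Z-score feature columns before clustering.
#' @param k,init_method,n_restarts,max_iter,tol K-means controls.
#' @param scope `"per-series"` (slice relevance is a within-volume notion)
#'   or `"pooled"` (one model across the cohort).
#' @param rule Relevance rule, see [map_clusters_to_relevance()].
#' @param exemplars Data frame of known-relevant slice keys (exemplar rule).
#' @param min_centroid_separation Runs whose between-centroid distance falls
#'   below this floor (in normalized feature units) are flagged in the
#'   manifest: the series may contain no tumor at all.
#' @param seed Top-level seed propagated to all stochastic components.
#' @return An `rknet_config` list.
#' @export
rknet_config <- function(window_center = 40, window_width = 400,
                         extractor = extractor_config("reference"),
                         normalize = TRUE, k = 2L,
                         init_method = "kmeans++", n_restarts = 10L,
                         max_iter = 300L, tol = 1e-6,
                         scope = c("per-series", "pooled"),
                         rule = c("foreground-mass", "exemplar",
                                  "majority-size"),
                         exemplars = NULL,
                         min_centroid_separation = 0.5, seed = 0L) {
  structure(list(window_center = window_center, window_width = window_width,
                 extractor = extractor, normalize = normalize, k = as.integer(k),
                 init_method = init_method, n_restarts = as.integer(n_restarts),
                 max_iter = as.integer(max_iter), tol = tol,
                 scope = match.arg(scope), rule = match.arg(rule),
                 exemplars = exemplars,
                 min_centroid_separation = min_centroid_separation,
                 seed = as.integer(seed)),
            class = "rknet_config")
}

.discover_series <- function(input_root) {
  niis <- list.files(input_root, pattern = "\\.nii(\\.gz)?$",
                     full.names = TRUE)
  dirs <- list.dirs(input_root, recursive = FALSE)
  dirs <- dirs[vapply(dirs, function(d) length(list.files(d)) > 0L, TRUE)]
  c(as.list(niis), as.list(dirs))
}

.ingest_one <- function(src, policy) {
  if (dir.exists(src)) load_dicom_series(src, policy)
  else load_nifti_volume(src, policy)
}

.cluster_and_map <- function(fm, slices, config) {
  model <- kmeans_fit(fm, k = config$k, init_method = config$init_method,
                      seed = config$seed, max_iter = config$max_iter,
                      tol = config$tol, n_restarts = config$n_restarts)
  scores <- vapply(slices, slice_foreground_score, 0)
  relmap <- map_clusters_to_relevance(model, fm, rule = config$rule,
                                      exemplars = config$exemplars,
                                      scores = if (config$rule == "foreground-mass")
                                        scores else NULL)
  flagged <- FALSE
  if (model$k == 2L) {
    sep <- sqrt(sum((model$centroids[1L, ] - model$centroids[2L, ])^2))
    flagged <- sep < config$min_centroid_separation
  }
  list(model = model, relmap = relmap, flagged = flagged)
}

#' Run the full slice-filtering pipeline
#'
#' For each ingestible series under `input_root`: anonymize, window, split
#' axially, extract features, fit k-means (per series or pooled), map the
#' two clusters to relevant/irrelevant, write every slice as PNG under
#' `output_root/{relevance}/{patient}/`, and write `manifest.csv` plus
#' `run_manifest.json` at `output_root`. Re-running with the same inputs,
#' config and seed reproduces the CSV body byte for byte.
#'
#' @param input_root Directory with NIfTI files and/or DICOM series
#'   subdirectories.
#' @param output_root Output directory (created).
#' @param config An [rknet_config()].
#' @param policy An [default_anonymization_policy()].
#' @return A `slice_manifest`: `records` data frame (one row per slice:
#'   patient_id, series_id, slice_index, cluster, relevance,
#'   distance_to_centroid, source_path, output_path, flag_low_separation),
#'   `counts`, `run_id`, `config_snapshot`, `errors`.
#' @export
run_rknet <- function(input_root, output_root, config = rknet_config(),
                      policy = default_anonymization_policy()) {
  sources <- .discover_series(input_root)
  if (length(sources) == 0L) stop("empty run: no ingestible series under ", input_root)
  dir.create(output_root, recursive = TRUE, showWarnings = FALSE)

  errors <- list()
  per_series <- list()
  for (src in sources) {
    res <- tryCatch({
      vol <- .ingest_one(src, policy)
      slices <- split_axial(vol, config$window_center, config$window_width)
      fm <- extract_features(slices, config$extractor, config$normalize)
      list(vol = vol, slices = slices, fm = fm)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[basename(src)]] <- conditionMessage(res)
      message(sprintf("[rknet] skipping %s: %s", basename(src),
                      conditionMessage(res)))
    } else {
      per_series[[basename(src)]] <- res
    }
  }
  if (length(per_series) == 0L) stop("empty run: no series ingested successfully")

  records <- list()
  if (config$scope == "per-series") {
    for (nm in names(per_series)) {
      ps <- per_series[[nm]]
      cm <- .cluster_and_map(ps$fm, ps$slices, config)
      records[[nm]] <- .series_records(ps, cm, output_root)
    }
  } else {
    slices <- do.call(c, lapply(per_series, `[[`, "slices"))
    fm <- extract_features(slices, config$extractor, config$normalize)
    cm <- .cluster_and_map(fm, slices, config)
    records[["pooled"]] <- .series_records(
      list(slices = slices, fm = fm), cm, output_root)
  }
  rec <- do.call(rbind, records)
  rec <- rec[order(rec$patient_id, rec$series_id, rec$slice_index), ]
  rownames(rec) <- NULL

  counts <- table(factor(rec$relevance, levels = c("relevant", "irrelevant")))
  manifest <- structure(list(
    records = rec,
    counts = as.list(counts),
    run_id = sprintf("rknet-%08x", config$seed),
    config_snapshot = config,
    errors = errors), class = "slice_manifest")

  write_manifest_csv(manifest, file.path(output_root, "manifest.csv"))
  jsonlite::write_json(list(
    run_id = manifest$run_id, seed = config$seed,
    scope = config$scope, rule = config$rule,
    window = c(config$window_center, config$window_width),
    extractor = config$extractor$name,
    n_slices = nrow(rec), counts = manifest$counts,
    errors = errors), file.path(output_root, "run_manifest.json"),
    auto_unbox = TRUE, pretty = TRUE)
  manifest
}

.series_records <- function(ps, cm, output_root) {
  slices <- ps$slices
  fm <- ps$fm
  model <- cm$model
  a <- model$assignments
  d2 <- .sqdist(fm$values, model$centroids)
  dist <- sqrt(d2[cbind(seq_along(a), a + 1L)])
  out <- vector("list", length(slices))
  for (i in seq_along(slices)) {
    sl <- slices[[i]]
    relevance <- unname(cm$relmap[as.character(a[i])])
    dir_out <- file.path(output_root, relevance, sl$patient_id)
    path <- write_png(sl, dir_out)
    out[[i]] <- data.frame(
      patient_id = sl$patient_id, series_id = sl$series_id,
      slice_index = sl$slice_index, cluster = a[i],
      relevance = relevance,
      distance_to_centroid = round(dist[i], 6),
      source_path = sl$source_path, output_path = path,
      flag_low_separation = cm$flagged, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write the classification manifest as CSV
#'
#' RFC-4180 CSV, UTF-8, fixed header
#' `patient_id,series_id,slice_index,cluster,relevance,distance_to_centroid,source_path,output_path,flag_low_separation`,
#' rows sorted by (patient, series, slice_index).
#'
#' @param manifest A `slice_manifest` (or data frame of records).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_manifest_csv <- function(manifest, path) {
  rec <- if (inherits(manifest, "slice_manifest")) manifest$records else manifest
  cols <- c("patient_id", "series_id", "slice_index", "cluster", "relevance",
            "distance_to_centroid", "source_path", "output_path",
            "flag_low_separation")
  rec <- rec[cols]
  rec <- rec[order(rec$patient_id, rec$series_id, rec$slice_index), ]
  ok <- tryCatch({
    utils::write.csv(rec, path, row.names = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("write error: cannot write ", path)
  invisible(path)
}

#' Read a manifest CSV back
#' @param path CSV path written by [write_manifest_csv()].
#' @return Data frame of records.
#' @export
read_manifest_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @export
print.slice_manifest <- function(x, ...) {
  cat(sprintf("<slice_manifest> %s  %d slices: %d relevant, %d irrelevant\n",
              x$run_id, nrow(x$records), x$counts$relevant,
              x$counts$irrelevant))
  if (length(x$errors))
    cat("  skipped series:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}
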