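# Slice embeddings. The clustering stage is agnostic to where the embedding
# comes from; extractors are pluggable. Two are provided:
#   * "reference" — a deterministic, dependency-free 64-dimensional
#     hand-crafted descriptor (frozen layout below) so the whole pipeline is
#     testable offline;
#   * "cnn-adapter" — a contract for a frozen pre-trained network embedding
#     registered by the user (image in -> fixed-length finite vector,
#     deterministic in inference mode). No network is bundled.

.adapter_registry <- new.env(parent = emptyenv())

#' Extractor configuration
#'
#' @param name `"reference"` or `"cnn-adapter"`.
#' @param input_size Integer pair; the slice is resampled to this size before
#'   extraction (bilinear). Both dimensions must be >= 8. The reference
#'   extractor uses 64x64 by default for speed; 224x224 matches common
#'   pre-trained embeddings.
#' @param adapter_options Named list passed through to a registered adapter.
#' @return An `extractor_config` object.
#' @export
extractor_config <- function(name = c("reference", "cnn-adapter"),
                             input_size = NULL, adapter_options = list()) {
  name <- match.arg(name)
  if (is.null(input_size))
    input_size <- if (name == "reference") c(64L, 64L) else c(224L, 224L)
  stopifnot(length(input_size) == 2L, all(input_size >= 8L))
  structure(list(name = name, input_size = as.integer(input_size),
                 adapter_options = adapter_options),
            class = "extractor_config")
}

#' Register a CNN embedding adapter
#'
#' The adapter is a function `f(pixels, options)` taking a numeric matrix in
#' `[0, 1]` (replicate to multiple channels inside the adapter if the model
#' expects them) and returning a fixed-length finite numeric vector,
#' deterministically. Pass `NULL` to unregister.
#'
#' @param fn Adapter function or `NULL`.
#' @param name Registry key (default `"default"`).
#' @return Invisibly, the previous adapter (or `NULL`).
#' @export
register_cnn_adapter <- function(fn, name = "default") {
  old <- .adapter_registry[[name]]
  if (is.null(fn)) {
    if (!is.null(old)) rm(list = name, envir = .adapter_registry)
  } else {
    stopifnot(is.function(fn))
    assign(name, fn, envir = .adapter_registry)
  }
  invisible(old)
}

.resample_bilinear <- function(m, nr, nc) {
  if (nrow(m) == nr && ncol(m) == nc) return(m)
  yi <- pmin(pmax((seq_len(nr) - 0.5) * nrow(m) / nr + 0.5, 1), nrow(m))
  xi <- pmin(pmax((seq_len(nc) - 0.5) * ncol(m) / nc + 0.5, 1), ncol(m))
  y0 <- pmin(floor(yi), nrow(m) - 1L); x0 <- pmin(floor(xi), ncol(m) - 1L)
  wy <- matrix(yi - y0, nr, nc)
  wx <- matrix(xi - x0, nr, nc, byrow = TRUE)
  a <- m[y0, x0, drop = FALSE]; b <- m[y0, x0 + 1L, drop = FALSE]
  cc <- m[y0 + 1L, x0, drop = FALSE]; d <- m[y0 + 1L, x0 + 1L, drop = FALSE]
  (1 - wy) * ((1 - wx) * a + wx * b) + wy * ((1 - wx) * cc + wx * d)
}

.conv_valid <- function(m, k) {
  nr <- nrow(m) - nrow(k) + 1L
  nc <- ncol(m) - ncol(k) + 1L
  out <- matrix(0, nr, nc)
  for (i in seq_len(nrow(k))) for (j in seq_len(ncol(k))) {
    if (k[i, j] != 0)
      out <- out + k[i, j] * m[i:(i + nr - 1L), j:(j + nc - 1L)]
  }
  out
}

.pool2 <- function(m) {
  nr <- nrow(m) %/% 2L * 2L; nc <- ncol(m) %/% 2L * 2L
  m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
  (m[seq(1L, nr, 2L), seq(1L, nc, 2L)] + m[seq(2L, nr, 2L), seq(1L, nc, 2L)] +
   m[seq(1L, nr, 2L), seq(2L, nc, 2L)] + m[seq(2L, nr, 2L), seq(2L, nc, 2L)]) / 4
}

.block_stats <- function(m, nb) {
  # nb x nb block means and population variances via indicator matrices
  br <- matrix(0, nrow(m), nb); bc <- matrix(0, ncol(m), nb)
  ir <- ceiling(seq_len(nrow(m)) / (nrow(m) / nb))
  ic <- ceiling(seq_len(ncol(m)) / (ncol(m) / nb))
  br[cbind(seq_len(nrow(m)), ir)] <- 1
  bc[cbind(seq_len(ncol(m)), ic)] <- 1
  cnt <- crossprod(br, matrix(1, nrow(m), ncol(m)) %*% bc)
  mu <- crossprod(br, m %*% bc) / cnt
  m2 <- crossprod(br, (m * m) %*% bc) / cnt
  list(mean = mu, var = pmax(m2 - mu * mu, 0))
}

.edge_kernels <- list(
  h  = matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3, byrow = TRUE) / 4,
  v  = matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE) / 4,
  d1 = matrix(c(-2, -1, 0, -1, 0, 1, 0, 1, 2), 3, 3, byrow = TRUE) / 4,
  d2 = matrix(c(0, -1, -2, 1, 0, -1, 2, 1, 0), 3, 3, byrow = TRUE) / 4
)

#' Reference slice descriptor (d = 64)
#'
#' Deterministic hand-crafted embedding standing in for a frozen CNN. The
#' slice is bilinearly resampled to `cfg$input_size`; the 64 coordinates are,
#' in frozen order:
#' \describe{
#'   \item{1-16}{16-bin intensity histogram density on `[0, 1]` (sums to 1).}
#'   \item{17-32}{4x4 block means, row-major.}
#'   \item{33-48}{4x4 block population variances, row-major.}
#'   \item{49-56}{mean absolute response of 4 oriented 3x3 edge kernels
#'     (horizontal, vertical, two diagonals) at full scale then on the
#'     2x2-mean-pooled image.}
#'   \item{57-60}{2x2 quadrant population variances.}
#'   \item{61}{global population variance.}
#'   \item{62}{global mean.}
#'   \item{63}{global mean absolute finite-difference gradient.}
#'   \item{64}{foreground fraction: share of pixels above 0.5.}
#' }
#'
#' @param slice A `slice_image` with pixels in `[0, 1]`.
#' @param cfg An [extractor_config()].
#' @return Numeric vector of length 64.
#' @export
extract_reference <- function(slice, cfg = extractor_config("reference")) {
  p <- slice$pixels
  if (!all(is.finite(p))) stop("invalid input: non-finite pixels in slice ",
                               slice$patient_id, "/", slice$slice_index)
  m <- .resample_bilinear(p, cfg$input_size[1L], cfg$input_size[2L])
  n <- length(m)

  bins <- pmin(floor(m * 16) + 1L, 16L)
  hist16 <- tabulate(bins, 16L) / n

  b4 <- .block_stats(m, 4L)
  b2 <- .block_stats(m, 2L)

  edges <- numeric(8L)
  mp <- .pool2(m)
  for (i in seq_along(.edge_kernels)) {
    edges[i] <- mean(abs(.conv_valid(m, .edge_kernels[[i]])))
    edges[i + 4L] <- mean(abs(.conv_valid(mp, .edge_kernels[[i]])))
  }

  gmu <- mean(m)
  gvar <- mean(m * m) - gmu * gmu
  grad <- (sum(abs(diff(m))) + sum(abs(t(diff(t(m)))))) /
    (2L * n - nrow(m) - ncol(m))
  fg <- mean(m > 0.5)

  c(hist16, as.vector(t(b4$mean)), as.vector(t(b4$var)), edges,
    as.vector(t(b2$var)), gvar, gmu, grad, fg)
}

#' CNN adapter embedding
#'
#' Delegates to a registered adapter (see [register_cnn_adapter()]) standing
#' for the penultimate layer of a frozen pre-trained network. The returned
#' vector must be finite; otherwise the adapter is treated as unavailable.
#'
#' @inheritParams extract_reference
#' @return Numeric embedding vector.
#' @export
extract_cnn <- function(slice, cfg = extractor_config("cnn-adapter")) {
  fn <- .adapter_registry[["default"]]
  if (is.null(fn))
    stop("adapter unavailable: no CNN adapter registered")
  m <- .resample_bilinear(slice$pixels, cfg$input_size[1L], cfg$input_size[2L])
  v <- fn(m, cfg$adapter_options)
  if (!is.numeric(v) || length(v) < 1L || !all(is.finite(v)))
    stop(sprintf("adapter unavailable: non-finite embedding for %s/%s #%d",
                 slice$patient_id, slice$series_id, slice$slice_index))
  as.double(v)
}

#' Assemble feature rows into a (optionally z-scored) matrix
#'
#' @param rows List of equal-length numeric vectors, or a numeric matrix.
#' @param row_keys Data frame with columns `patient_id`, `series_id`,
#'   `slice_index`, one row per feature row; keys must be unique.
#' @param do_normalize Column z-scoring (population sd, so two points map to
#'   -1/+1); constant columns are set
#'   to 0. K-means is scale-sensitive, so this is on by default.
#' @param extractor_name Provenance label.
#' @return A `feature_matrix`: `values` (n x d), `row_keys`,
#'   `extractor_name`, `normalized`; when normalized, the raw matrix is kept
#'   in `raw_values` (the relevance-mapping rule reads raw coordinates).
#' @export
assemble_and_normalize <- function(rows, row_keys, do_normalize = TRUE,
                                   extractor_name = "reference") {
  if (is.list(rows)) {
    lens <- lengths(rows)
    if (length(unique(lens)) > 1L)
      stop("dimension mismatch: ragged feature rows")
    values <- do.call(rbind, rows)
  } else {
    values <- as.matrix(rows)
  }
  stopifnot(is.data.frame(row_keys),
            all(c("patient_id", "series_id", "slice_index") %in% names(row_keys)))
  if (nrow(values) != nrow(row_keys))
    stop("dimension mismatch: rows vs row_keys")
  key <- paste(row_keys$patient_id, row_keys$series_id, row_keys$slice_index)
  if (anyDuplicated(key)) stop("duplicate slice: row keys must be unique")
  if (!all(is.finite(values))) stop("invalid input: non-finite features")

  raw <- values
  if (do_normalize) values <- .zscore_cols(values)
  structure(list(values = values, row_keys = row_keys,
                 extractor_name = extractor_name, normalized = do_normalize,
                 raw_values = if (do_normalize) raw else NULL),
            class = "feature_matrix")
}

.zscore_cols <- function(m) {
  # population sd, so two points map to exactly -1 and +1
  mu <- colMeans(m)
  centered <- sweep(m, 2L, mu)
  s <- sqrt(colMeans(centered * centered))
  out <- sweep(centered, 2L, ifelse(s > 1e-12, s, 1), "/")
  out[, s <= 1e-12] <- 0
  out
}

#' Extract features for a list of slices
#'
#' @param slices List of `slice_image` objects.
#' @param cfg An [extractor_config()]. With `name = "cnn-adapter"` and no
#'   registered adapter, falls back to the reference extractor with a
#'   warning.
#' @param do_normalize See [assemble_and_normalize()].
#' @return A `feature_matrix`.
#' @export
extract_features <- function(slices, cfg = extractor_config("reference"),
                             do_normalize = TRUE) {
  name <- cfg$name
  if (name == "cnn-adapter" && is.null(.adapter_registry[["default"]])) {
    warning("adapter unavailable; falling back to reference extractor")
    name <- "reference"
    cfg <- extractor_config("reference")
  }
  f <- if (name == "reference") extract_reference else extract_cnn
  rows <- lapply(slices, f, cfg = cfg)
  keys <- data.frame(
    patient_id = vapply(slices, `[[`, "", "patient_id"),
    series_id = vapply(slices, `[[`, "", "series_id"),
    slice_index = vapply(slices, `[[`, 0L, "slice_index"),
    stringsAsFactors = FALSE)
  assemble_and_normalize(rows, keys, do_normalize, extractor_name = name)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d slices x %d features (%s%s)\n",
              nrow(x$values), ncol(x$values), x$extractor_name,
              if (x$normalized) ", z-scored" else ""))
  invisible(x)
}
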