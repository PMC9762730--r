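test_that("reference extractor has the frozen layout on a constant image", {
  f <- extract_reference(const_slice(0, 64))
  expect_length(f, 64L)
  expect_equal(f[1], 1)                  # all mass in histogram bin 1
  expect_equal(f[2:16], rep(0, 15))
  expect_equal(f[17:32], rep(0, 16))     # block means
  expect_equal(f[33:48], rep(0, 16))     # block variances
  expect_equal(f[49:56], rep(0, 8))      # edge responses
  expect_equal(f[57:64], rep(0, 8))      # pooled/global stats
})

test_that("reference extractor is deterministic and resamples any size", {
  set.seed(5)
  s <- make_slice(matrix(runif(30 * 50), 30, 50))
  expect_identical(extract_reference(s), extract_reference(s))
  f <- extract_reference(s, extractor_config("reference", c(32L, 32L)))
  expect_length(f, 64L)
  expect_true(all(is.finite(f)))
  expect_error(extract_reference(make_slice(matrix(NaN, 8, 8))),
               "invalid input")
})

test_that("variance features separate flat from bimodal slices", {
  flat <- extract_reference(const_slice(0.5, 64))
  half <- matrix(0, 64, 64); half[, 33:64] <- 1
  bim <- extract_reference(make_slice(half))
  # oracle: population variance of the half-half image is 0.25, of the flat
  # image 0; pooled variance cells (57:61) can only grow
  expect_equal(bim[61], 0.25, tolerance = 1e-12)
  expect_equal(flat[61], 0)
  expect_gt(sum(bim[57:61]), sum(flat[57:61]))
  expect_gt(sum(bim[49:56]), sum(flat[49:56]))  # boundary has edge energy
})

test_that("cnn adapter contract: delegation, determinism, finiteness gate", {
  on.exit(register_cnn_adapter(NULL), add = TRUE)
  expect_error(extract_cnn(const_slice(0.5, 16)), "adapter unavailable")

  register_cnn_adapter(function(m, opts) rowSums(m))
  cfg <- extractor_config("cnn-adapter", input_size = c(16L, 16L))
  s <- const_slice(0.25, 16)
  expect_equal(extract_cnn(s, cfg), rep(0.25 * 16, 16))  # hand computation
  set.seed(8)
  s2 <- make_slice(matrix(runif(256), 16, 16), index = 1L)
  expect_identical(extract_cnn(s2, cfg), extract_cnn(s2, cfg))

  register_cnn_adapter(function(m, opts) c(1, NaN))
  expect_error(extract_cnn(s, cfg), "adapter unavailable")

  register_cnn_adapter(NULL)
  expect_warning(fm <- extract_features(list(s, s2),
                                        extractor_config("cnn-adapter")),
                 "falling back")
  expect_identical(fm$extractor_name, "reference")
})

test_that("assemble_and_normalize z-scores columns and validates input", {
  keys <- function(n) data.frame(patient_id = "P", series_id = "S",
                                 slice_index = seq_len(n) - 1L)
  fm <- assemble_and_normalize(list(0, 2), keys(2))
  expect_equal(as.vector(fm$values), c(-1, 1))

  m <- matrix(c(1, 2, 3, 10, 20, 30, 5, 5, 5), 3)
  fm2 <- assemble_and_normalize(m, keys(3))
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  expect_equal(colMeans(fm2$values), rep(0, 3), tolerance = 1e-12)
  expect_equal(apply(fm2$values[, 1:2], 2, pop_sd), c(1, 1), tolerance = 1e-12)
  expect_equal(fm2$values[, 3], rep(0, 3))   # constant column rule
  expect_identical(fm2$raw_values, m)

  expect_error(assemble_and_normalize(list(c(1, 2), 3), keys(2)),
               "dimension mismatch")
  k <- keys(2); k$slice_index <- c(0L, 0L)
  expect_error(assemble_and_normalize(list(1, 2), k), "duplicate slice")
})

test_that("normalization is idempotent", {
  set.seed(21)
  keys <- data.frame(patient_id = "P", series_id = "S", slice_index = 0:19)
  m <- matrix(rnorm(20 * 6, sd = c(1, 10, 100)), 20, 6)
  fm1 <- assemble_and_normalize(m, keys)
  fm2 <- assemble_and_normalize(fm1$values, keys)
  expect_lt(max(abs(fm1$values - fm2$values)), 1e-8)
})

test_that("phantom classes separate in feature space at s >= 2", {
  spec <- phantom_spec(n_patients = 2, separation = 2, seed = 4)
  co <- generate_cohort(spec)
  v <- co$volumes[[1]]
  fm <- extract_features(split_axial(v), do_normalize = TRUE)
  tt <- co$truth[co$truth$patient_id == v$patient_id, ]
  X <- fm$values
  dmat <- as.matrix(dist(X))
  rel <- tt$relevant
  between <- mean(dmat[rel, !rel])
  within <- mean(c(dmat[rel, rel][upper.tri(dmat[rel, rel])],
                   dmat[!rel, !rel][upper.tri(dmat[!rel, !rel])]))
  expect_gt(between, within)
})
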