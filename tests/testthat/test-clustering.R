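test_that("kmeans_fit solves canonical instances", {
  # two points, k = 2: each its own centroid, E = 0
  m <- kmeans_fit(rbind(c(0, 0), c(10, 10)), k = 2, seed = 1)
  expect_equal(m$objective, 0)
  expect_setequal(m$assignments, 0:1)

  # identical rows, k = 1: centroid is the row, E = 0
  m1 <- kmeans_fit(matrix(3, 7, 2), k = 1, seed = 1)
  expect_equal(m1$objective, 0)
  expect_equal(as.vector(m1$centroids), c(3, 3))

  # 1-D {0,1,9,10}: optimum {0,1}/{9,10}, centroids 0.5/9.5, E = 1
  m2 <- kmeans_fit(matrix(c(0, 1, 9, 10)), k = 2, seed = 1)
  expect_equal(m2$objective, 1)
  expect_setequal(as.vector(m2$centroids), c(0.5, 9.5))
  expect_identical(m2$assignments[1], m2$assignments[2])
  expect_identical(m2$assignments[3], m2$assignments[4])

  expect_error(kmeans_fit(matrix(1), k = 2), "too few samples")
  expect_error(kmeans_fit(matrix(c(1, NA, 3, 4), 2), k = 2), "invalid input")
})

test_that("compute_objective evaluates the squared-distance sum", {
  expect_equal(compute_objective(matrix(c(1, 2), 1), matrix(c(1, 2), 1), 0L), 0)
  expect_equal(compute_objective(matrix(c(3, 4), 1), matrix(c(0, 0), 1), 0L), 25)
  X <- matrix(c(0, 1, 9, 10))
  expect_equal(compute_objective(X, matrix(c(0.5, 9.5)), c(0L, 0L, 1L, 1L)), 1)
  expect_error(compute_objective(X, matrix(c(0.5, 9.5)), c(0L, 0L, 1L, 2L)),
               "invalid assignment")
})

test_that("update_centroids averages assigned rows", {
  expect_equal(update_centroids(rbind(c(0, 0), c(2, 2)), c(0L, 0L), 1L),
               matrix(c(1, 1), 1))
  expect_equal(update_centroids(rbind(c(5, 7)), 0L, 1L), matrix(c(5, 7), 1))
  expect_equal(as.vector(update_centroids(matrix(c(1, 3, 7)), c(0L, 0L, 1L), 2L)),
               c(2, 7))
})

test_that("exhaustive oracle enumerates the global optimum", {
  expect_equal(exhaustive_kmeans(rbind(c(0, 0), c(5, 5)), 2)$objective, 0)
  o <- exhaustive_kmeans(matrix(c(0, 1, 9, 10)), 2)
  expect_equal(o$objective, 1)
  expect_identical(o$assignments, c(0L, 0L, 1L, 1L))
  # duplicating every row doubles E but keeps the same partition structure
  X <- matrix(c(0, 1.5, 9, 10.25))
  E1 <- exhaustive_kmeans(X, 2)$objective
  E2 <- exhaustive_kmeans(rbind(X, X), 2)$objective
  expect_equal(E2, 2 * E1)
  expect_error(exhaustive_kmeans(matrix(rnorm(11)), 2), "oracle cap exceeded")
})

test_that("kmeans matches the oracle on random small instances", {
  # scaled-down nightly version of the acceptance sweep (full 200 draws in
  # test-acceptance.R)
  set.seed(42)
  for (i in 1:30) {
    n <- sample(2:8, 1); d <- sample(1:3, 1)
    X <- matrix(round(rnorm(n * d), 2), n, d)
    fit <- kmeans_fit(X, k = 2, seed = i, n_restarts = 10)
    expect_lt(abs(fit$objective - exhaustive_kmeans(X, 2)$objective), 1e-9)
  }
})

test_that("fits satisfy the objective and centroid contracts", {
  set.seed(9)
  for (i in 1:15) {
    n <- sample(5:40, 1); d <- sample(1:4, 1); k <- sample(1:3, 1)
    X <- matrix(rnorm(n * d), n, d)
    m <- kmeans_fit(X, k = k, seed = i)
    expect_true(all(diff(m$trace) <= 1e-12))                 # non-increasing
    expect_true(all(m$assignments %in% 0:(k - 1)))
    expect_true(all(tabulate(m$assignments + 1L, k) > 0L))   # non-empty
    # centroid-update fixed point at convergence
    means <- update_centroids(X, m$assignments, k)
    expect_lt(max(abs(means - m$centroids)), 1e-8)
    # objective equals direct recomputation
    E <- sum(vapply(seq_len(n), function(j)
      sum((X[j, ] - m$centroids[m$assignments[j] + 1L, ])^2), 0))
    expect_lt(abs(E - m$objective), 1e-8)
  }
})

test_that("kmeans is seed-deterministic, permutation and scale invariant", {
  set.seed(77)
  X <- matrix(rnorm(16), 8, 2)
  expect_identical(kmeans_fit(X, seed = 5), kmeans_fit(X, seed = 5))

  perm <- sample(nrow(X))
  m <- kmeans_fit(X, seed = 5)
  mp <- kmeans_fit(X[perm, ], seed = 6)
  expect_equal(m$objective, mp$objective, tolerance = 1e-12)
  # partitions agree up to cluster relabeling
  a <- m$assignments[perm]; b <- mp$assignments
  expect_true(all(a == b) || all(a == 1L - b))

  for (c_ in c(0.5, 3)) {
    ms <- kmeans_fit(X * c_, seed = 5)
    expect_equal(ms$objective, c_^2 * m$objective, tolerance = 1e-9)
  }
})

test_that("empty-cluster repair keeps k clusters on degenerate data", {
  X <- matrix(1, 6, 2)  # all points identical
  m <- kmeans_fit(X, k = 2, seed = 0)
  expect_equal(m$objective, 0)
  expect_true(all(tabulate(m$assignments + 1L, 2L) > 0L))
})

test_that("relevance mapping rules behave as documented", {
  set.seed(13)
  keys <- data.frame(patient_id = "P", series_id = "S", slice_index = 0:9)
  raw <- matrix(rnorm(10 * 64), 10, 64)
  raw[1:4, c(61, 63, 64)] <- raw[1:4, c(61, 63, 64)] + 5  # high foreground
  fm <- assemble_and_normalize(raw, keys, do_normalize = TRUE)
  model <- structure(list(k = 2L, assignments = rep(c(0L, 1L), c(4L, 6L)),
                          centroids = matrix(0, 2, 64)),
                     class = "cluster_model")

  fg <- map_clusters_to_relevance(model, fm, "foreground-mass")
  expect_identical(unname(fg["0"]), "relevant")

  ex3 <- keys[1:3, ]  # all in cluster 0
  em <- map_clusters_to_relevance(model, fm, "exemplar", exemplars = ex3)
  expect_identical(unname(em["0"]), "relevant")
  expect_error(map_clusters_to_relevance(model, fm, "exemplar"),
               "no exemplars")
  # 1 exemplar in cluster 0, 1 in cluster 1: tie
  expect_error(map_clusters_to_relevance(model, fm, "exemplar",
                                         exemplars = keys[c(1, 6), ]),
               "ambiguous mapping")
  expect_warning(ms <- map_clusters_to_relevance(model, fm, "majority-size"),
                 "discouraged")
  expect_identical(unname(ms["1"]), "relevant")  # larger cluster
})
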