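# From-scratch K-means (Lloyd iterations), k = 2 by default, used to
# separate tumor-level slices from irrelevant ones. The objective is the
# within-cluster sum of squared Euclidean distances
#     E = sum_i sum_{x in C_i} ||x - mu_i||_2^2,
# minimized by alternating nearest-centroid assignment with the centroid
# update mu_i = mean of C_i. Smaller E means higher within-cluster
# similarity. All tie-break, initialization, convergence and empty-cluster
# policies are explicit so runs are reproducible bit-for-bit.

.as_matrix <- function(X) {
  if (inherits(X, "feature_matrix")) X$values else as.matrix(X)
}

# n x k matrix of squared Euclidean distances
.sqdist <- function(X, C) {
  d2 <- outer(rowSums(X * X), rowSums(C * C), "+") - 2 * X %*% t(C)
  d2[d2 < 0] <- 0
  d2
}

#' Within-cluster sum of squared distances
#'
#' Direct evaluation of the clustering objective
#' `E = sum_i sum_{x in C_i} ||x - mu_i||^2`.
#'
#' @param X Numeric matrix or `feature_matrix` (n rows).
#' @param centroids k x d matrix of mean vectors.
#' @param assignments Length-n vector of 0-based cluster labels.
#' @return The scalar objective E.
#' @export
compute_objective <- function(X, centroids, assignments) {
  X <- .as_matrix(X)
  centroids <- as.matrix(centroids)
  a <- as.integer(assignments)
  if (length(a) != nrow(X)) stop("invalid assignment: wrong length")
  if (any(a < 0L | a >= nrow(centroids)))
    stop("invalid assignment: label out of range")
  diffs <- X - centroids[a + 1L, , drop = FALSE]
  sum(diffs * diffs)
}

#' Centroid update step
#'
#' Sets each centroid to the arithmetic mean of its assigned rows. Empty
#' clusters keep their previous centroid here; [kmeans_fit()] repairs them by
#' reseeding at the point farthest from its current centroid.
#'
#' @inheritParams compute_objective
#' @param k Number of clusters.
#' @param previous Optional k x d matrix used for clusters with no members.
#' @return k x d matrix of centroids.
#' @export
update_centroids <- function(X, assignments, k, previous = NULL) {
  X <- .as_matrix(X)
  a <- as.integer(assignments)
  if (any(a < 0L | a >= k)) stop("invalid assignment: label out of range")
  C <- matrix(NA_real_, k, ncol(X))
  counts <- tabulate(a + 1L, k)
  sums <- rowsum(X, a, reorder = TRUE)
  present <- sort(unique(a))
  C[present + 1L, ] <- sums / counts[present + 1L]
  if (any(counts == 0L)) {
    if (is.null(previous)) stop("empty cluster with no previous centroids")
    C[counts == 0L, ] <- previous[counts == 0L, , drop = FALSE]
  }
  C
}

.kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- .sqdist(X, X[centers[1L], , drop = FALSE])[, 1L]
    for (j in 2L:k) {
      if (sum(d2) <= 0) {
        centers[j] <- sample.int(n, 1L)
      } else {
        centers[j] <- sample.int(n, 1L, prob = d2 / sum(d2))
      }
      d2 <- pmin(d2, .sqdist(X, X[centers[j], , drop = FALSE])[, 1L])
    }
  }
  X[centers, , drop = FALSE]
}

.lloyd_once <- function(X, k, init, max_iter, tol) {
  n <- nrow(X)
  C <- if (init == "kmeans++") .kmeanspp_init(X, k)
       else X[sample.int(n, k), , drop = FALSE]
  labels <- rep(-1L, n)
  trace <- numeric(0)
  converged <- FALSE
  prev_E <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    d2 <- .sqdist(X, C)
    new_labels <- max.col(-d2, ties.method = "first") - 1L  # lowest index wins
    # empty-cluster repair: reseed at the point farthest from its centroid
    counts <- tabulate(new_labels + 1L, k)
    while (any(counts == 0L)) {
      j <- which(counts == 0L)[1L]
      cur <- d2[cbind(seq_len(n), new_labels + 1L)]
      cur[counts[new_labels + 1L] == 1L] <- -Inf  # keep donors non-empty
      far <- which.max(cur)
      C[j, ] <- X[far, ]
      d2[, j] <- .sqdist(X, C[j, , drop = FALSE])[, 1L]
      new_labels <- max.col(-d2, ties.method = "first") - 1L
      new_labels[far] <- j - 1L
      counts <- tabulate(new_labels + 1L, k)
    }
    E <- sum(d2[cbind(seq_len(n), new_labels + 1L)])
    trace <- c(trace, E)
    fixed <- identical(new_labels, labels)
    labels <- new_labels
    C <- update_centroids(X, labels, k, previous = C)
    if (fixed || abs(prev_E - E) <= tol) {
      converged <- TRUE
      break
    }
    prev_E <- E
  }
  # Hartigan-style polish: Lloyd fixed points are not always optimal (a
  # single point can sit nearer its own centroid yet still pay more than a
  # transfer would cost once both means shift). First-improvement
  # single-point relocations, in row order, until no move lowers E.
  if (k > 1L) {
    sizes <- tabulate(labels + 1L, k)
    improved <- TRUE
    guard <- 0L
    while (improved && guard < 100L) {
      improved <- FALSE
      guard <- guard + 1L
      for (j in seq_len(n)) {
        from <- labels[j] + 1L
        if (sizes[from] == 1L) next
        x <- X[j, ]
        loss_out <- sizes[from] / (sizes[from] - 1L) * sum((x - C[from, ])^2)
        for (to in seq_len(k)) {
          if (to == from) next
          gain_in <- sizes[to] / (sizes[to] + 1L) * sum((x - C[to, ])^2)
          if (gain_in < loss_out - 1e-12) {
            C[from, ] <- (C[from, ] * sizes[from] - x) / (sizes[from] - 1L)
            C[to, ] <- (C[to, ] * sizes[to] + x) / (sizes[to] + 1L)
            sizes[from] <- sizes[from] - 1L
            sizes[to] <- sizes[to] + 1L
            labels[j] <- to - 1L
            improved <- TRUE
            break
          }
        }
      }
    }
    C <- update_centroids(X, labels, k)
  }
  E_final <- compute_objective(X, C, labels)
  trace <- c(trace, E_final)
  list(centroids = C, assignments = labels, objective = E_final,
       trace = trace, n_iter = iter, converged = converged)
}

#' Fit K-means by Lloyd iterations
#'
#' Runs `n_restarts` seeded initializations and keeps the run with the
#' smallest final objective E. The default `"mixed"` schedule alternates
#' k-means++ seeding (odd restarts) with plain random-row seeding (even
#' restarts): k-means++ restarts concentrate on spread-out centers and can
#' all fall into the same basin on small adversarial instances, so the
#' random restarts buy basin diversity (pure k-means++ misses the global
#' optimum on a small fraction of tiny instances even with 10 restarts).
#' Convergence is declared on an assignment fixed point or `|dE| <= tol`,
#' up to `max_iter` iterations. Deterministic for a fixed
#' `(X, k, init_method, seed)`; the caller's RNG state is left untouched.
#'
#' @param X Numeric matrix or `feature_matrix`, n >= k rows, finite entries.
#' @param k Number of clusters (default 2: tumor-level vs irrelevant).
#' @param init_method `"mixed"` (default), `"kmeans++"`, or `"random"`
#'   (random distinct rows).
#' @param seed Integer seed.
#' @param max_iter Iteration cap per restart.
#' @param tol Absolute objective-change tolerance.
#' @param n_restarts Number of independent initializations.
#' @return A `cluster_model` with `centroids`, 0-based `assignments`,
#'   `objective`, non-increasing `trace`, `seed`, `n_iter`, `converged`.
#' @export
#' @examples
#' m <- kmeans_fit(matrix(c(0, 1, 9, 10)), k = 2, seed = 1)
#' m$objective  # 1.0
kmeans_fit <- function(X, k = 2L,
                       init_method = c("mixed", "kmeans++", "random"),
                       seed = 0L, max_iter = 300L, tol = 1e-6,
                       n_restarts = 10L) {
  init_method <- match.arg(init_method)
  X <- .as_matrix(X)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("invalid input: non-finite feature values")
  n <- nrow(X)
  if (n < k) stop("too few samples: n < k")
  stopifnot(k >= 1L, max_iter >= 1L, tol >= 0)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))

  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- if (init_method != "mixed") init_method
            else if (r %% 2L == 1L) "kmeans++" else "random"
    run <- .lloyd_once(X, k, init, max_iter, tol)
    if (is.null(best) || run$objective < best$objective) best <- run
  }
  structure(c(best, list(k = as.integer(k), seed = as.integer(seed),
                         init_method = init_method)),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k=%d  n=%d  E=%.6g  iter=%d%s\n",
              x$k, length(x$assignments), x$objective, x$n_iter,
              if (x$converged) " (converged)" else ""))
  cat("  cluster sizes:", tabulate(x$assignments + 1L, x$k), "\n")
  invisible(x)
}

#' Globally optimal K-means by exhaustive enumeration
#'
#' Brute-force oracle for tests: enumerates every partition into non-empty
#' clusters (k = 1 or 2 only) and returns the partition minimizing E, with
#' ties broken by the lexicographically smallest assignment vector. Capped at
#' n <= 10 for k = 2.
#'
#' @inheritParams kmeans_fit
#' @return A `cluster_model` (with `trace` of length 1).
#' @export
exhaustive_kmeans <- function(X, k = 2L) {
  X <- .as_matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (n < k) stop("too few samples: n < k")
  if (k == 1L) {
    C <- matrix(colMeans(X), 1L)
    a <- rep(0L, n)
    E <- compute_objective(X, C, a)
  } else if (k == 2L) {
    if (n > 10L) stop("oracle cap exceeded: n > 10 for k = 2")
    best_E <- Inf; a <- NULL; C <- NULL
    for (mask in seq_len(2L^(n - 1L) - 1L)) {
      labels <- c(0L, as.integer(intToBits(mask))[seq_len(n - 1L)])
      cand_C <- update_centroids(X, labels, 2L)
      E <- compute_objective(X, cand_C, labels)
      if (E < best_E - 1e-15 ||
          (abs(E - best_E) <= 1e-15 && !is.null(a) &&
           .lex_less(labels, a))) {
        best_E <- E; a <- labels; C <- cand_C
      }
    }
    E <- best_E
  } else {
    stop("oracle supports k <= 2 only")
  }
  structure(list(centroids = C, assignments = a, objective = E, trace = E,
                 n_iter = 1L, converged = TRUE, k = as.integer(k),
                 seed = NA_integer_, init_method = "exhaustive"),
            class = "cluster_model")
}

.lex_less <- function(a, b) {
  d <- which(a != b)
  length(d) > 0L && a[d[1L]] < b[d[1L]]
}

#' Foreground score of a slice
#'
#' Extractor-agnostic summary used by the `"foreground-mass"` relevance rule:
#' global intensity variance + mean absolute gradient + foreground fraction
#' of the windowed slice. Lesion-bearing slices score higher because the
#' bright blob adds mass above the window midpoint and edge energy at its
#' rim.
#'
#' @param slice A `slice_image`.
#' @return Scalar score.
#' @export
slice_foreground_score <- function(slice) {
  m <- slice$pixels
  n <- length(m)
  gvar <- mean(m * m) - mean(m)^2
  grad <- (sum(abs(diff(m))) + sum(abs(t(diff(t(m)))))) /
    (2L * n - nrow(m) - ncol(m))
  gvar + grad + mean(m > 0.5)
}

#' Map the two clusters to relevance classes
#'
#' The clustering itself is symmetric; deciding which cluster holds the
#' tumor-level slices needs a rule. Three are provided:
#' \describe{
#'   \item{foreground-mass}{default: the cluster whose members have the
#'     higher mean [slice_foreground_score()] (for reference features the
#'     scores are read from the raw coordinates 61, 63 and 64) is relevant.}
#'   \item{exemplar}{the cluster containing the majority of user-supplied
#'     known-relevant slice keys is relevant.}
#'   \item{majority-size}{the larger cluster is relevant; discouraged (a
#'     volume usually holds more irrelevant than tumor-level slices) and
#'     warned about.}
#' }
#'
#' @param model A `cluster_model` with k = 2.
#' @param X The `feature_matrix` the model was fitted on.
#' @param rule One of `"foreground-mass"`, `"exemplar"`, `"majority-size"`.
#' @param exemplars Data frame of known-relevant slice keys (`patient_id`,
#'   `series_id`, `slice_index`) for the exemplar rule.
#' @param scores Optional per-row foreground scores overriding the ones
#'   derived from `X` (needed for non-reference extractors).
#' @return Named character vector mapping cluster label (`"0"`, `"1"`) to
#'   `"relevant"`/`"irrelevant"`, with the rule in `attr(, "rule")`.
#' @export
map_clusters_to_relevance <- function(model, X,
                                      rule = c("foreground-mass", "exemplar",
                                               "majority-size"),
                                      exemplars = NULL, scores = NULL) {
  rule <- match.arg(rule)
  stopifnot(inherits(model, "cluster_model"), model$k == 2L)
  a <- model$assignments

  relevant <- switch(rule,
    "foreground-mass" = {
      if (is.null(scores)) {
        if (!inherits(X, "feature_matrix") || X$extractor_name != "reference")
          stop("foreground-mass needs reference features or explicit scores")
        raw <- if (X$normalized) X$raw_values else X$values
        scores <- raw[, 61L] + raw[, 63L] + raw[, 64L]
      }
      m0 <- mean(scores[a == 0L]); m1 <- mean(scores[a == 1L])
      if (m0 >= m1) 0L else 1L
    },
    "exemplar" = {
      if (is.null(exemplars) || nrow(exemplars) == 0L)
        stop("no exemplars: exemplar rule requires known-relevant keys")
      if (!inherits(X, "feature_matrix"))
        stop("exemplar rule needs a feature_matrix with row keys")
      rk <- X$row_keys
      key <- paste(rk$patient_id, rk$series_id, rk$slice_index)
      ek <- paste(exemplars$patient_id, exemplars$series_id,
                  exemplars$slice_index)
      hit <- match(ek, key)
      hit <- hit[!is.na(hit)]
      if (length(hit) == 0L)
        stop("no exemplars: none of the supplied keys are in the matrix")
      n1 <- sum(a[hit] == 1L); n0 <- length(hit) - n1
      if (n0 == n1) stop("ambiguous mapping: exemplar counts tied")
      if (n0 > n1) 0L else 1L
    },
    "majority-size" = {
      warning("majority-size rule is discouraged; prefer foreground-mass or exemplar")
      if (sum(a == 0L) >= sum(a == 1L)) 0L else 1L
    })

  out <- c("irrelevant", "irrelevant")
  out[relevant + 1L] <- "relevant"
  names(out) <- c("0", "1")
  attr(out, "rule") <- rule
  out
}
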