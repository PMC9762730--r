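# Desk-scale stand-in for the downstream diagnostic model: a multinomial
# logistic (softmax) classifier trained with mini-batch stochastic gradient
# descent and cross-entropy loss. The defaults copy the clinical model's
# hyperparameters (learning rate 0.1, batch size 32, cross-entropy); the
# deep backbone is deliberately replaced by a linear model because the
# question under test is the effect of data refinement, not model capacity.

#' Training configuration for the linear SGD classifier
#'
#' @param learning_rate SGD step size (> 0); default 0.1.
#' @param batch_size Mini-batch size (>= 1); default 32.
#' @param n_steps Number of SGD steps; default 300.
#' @param seed Integer seed controlling shuffling.
#' @param shuffle Reshuffle sample order every epoch.
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 0.1, batch_size = 32L,
                         n_steps = 300L, seed = 0L, shuffle = TRUE) {
  if (!is.numeric(learning_rate) || learning_rate <= 0)
    stop("learning_rate must be > 0")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 n_steps = as.integer(n_steps), seed = as.integer(seed),
                 shuffle = isTRUE(shuffle), loss = "cross-entropy"),
            class = "train_config")
}

.softmax <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Train a multinomial logistic model with mini-batch SGD
#'
#' Softmax cross-entropy loss, zero-initialized weights, per-epoch seeded
#' shuffling; fully deterministic per `(features, labels, cfg)`. Features
#' are standardized internally (training statistics kept in the model for
#' prediction).
#'
#' @param features Numeric matrix (n x d), finite.
#' @param labels Vector coercible to factor; at least 2 classes must be
#'   present.
#' @param cfg A [train_config()].
#' @return List with `model` (weights d+1 x C, classes, centering/scaling)
#'   and `trace` (data frame: step, loss, accuracy on the step's batch).
#' @export
train_linear_sgd <- function(features, labels, cfg = train_config()) {
  X <- as.matrix(features)
  if (!all(is.finite(X))) stop("invalid input: non-finite features")
  y <- factor(labels)
  if (nlevels(y) < 2L) stop("degenerate labels: need >= 2 classes")
  if (nrow(X) != length(y)) stop("length mismatch: features vs labels")

  mu <- colMeans(X)
  s <- apply(X, 2L, stats::sd)
  s[s <= 1e-12] <- 1
  Xs <- cbind(1, sweep(sweep(X, 2L, mu), 2L, s, "/"))
  n <- nrow(Xs); C <- nlevels(y)
  Y <- matrix(0, n, C); Y[cbind(seq_len(n), as.integer(y))] <- 1
  W <- matrix(0, ncol(Xs), C)

  trace <- data.frame(step = seq_len(cfg$n_steps), loss = NA_real_,
                      accuracy = NA_real_)
  .with_seed(cfg$seed, {
    ord <- if (cfg$shuffle) sample.int(n) else seq_len(n)
    pos <- 1L
    for (step in seq_len(cfg$n_steps)) {
      if (pos > n) {
        ord <- if (cfg$shuffle) sample.int(n) else seq_len(n)
        pos <- 1L
      }
      idx <- ord[pos:min(pos + cfg$batch_size - 1L, n)]
      pos <- pos + cfg$batch_size
      Xb <- Xs[idx, , drop = FALSE]; Yb <- Y[idx, , drop = FALSE]
      P <- .softmax(Xb %*% W)
      eps <- 1e-12
      trace$loss[step] <- -mean(log(pmax(P[Yb == 1], eps)))
      trace$accuracy[step] <- mean(max.col(P) == max.col(Yb))
      G <- crossprod(Xb, P - Yb) / nrow(Xb)
      W <- W - cfg$learning_rate * G
    }
  })
  list(model = list(weights = W, classes = levels(y), center = mu, scale = s),
       trace = trace)
}

#' Predict class labels from a trained linear model
#'
#' @param model The `model` element returned by [train_linear_sgd()].
#' @param features Numeric matrix with the training dimensionality.
#' @return Character vector of predicted class labels.
#' @export
predict_linear <- function(model, features) {
  X <- as.matrix(features)
  Xs <- cbind(1, sweep(sweep(X, 2L, model$center), 2L, model$scale, "/"))
  model$classes[max.col(.softmax(Xs %*% model$weights), ties.method = "first")]
}

#' Compare filtered vs unfiltered training arms on a phantom cohort
#'
#' Trains the identical classifier (same config and seed) on three training
#' sets derived from one synthetic cohort and evaluates each on the same
#' held-out patients:
#' \describe{
#'   \item{unfiltered}{every slice; off-tumor slices inherit the patient's
#'     class label and act as label noise.}
#'   \item{oracle-screened}{only ground-truth tumor-level slices (the
#'     manual-screening ideal).}
#'   \item{rknet-filtered}{only slices the clustering pipeline marked
#'     relevant (exemplar mapping with 3 planted tumor slices per series).}
#' }
#' Slice labels inherit the patient class. Test metrics are computed on the
#' truth tumor-level slices of test patients, both per slice and per patient
#' (majority vote).
#'
#' @param spec A [phantom_spec()]; the cohort is generated in memory.
#' @param arms Subset of `c("unfiltered", "oracle-screened",
#'   "rknet-filtered")`.
#' @param cfg A [train_config()].
#' @param train_fraction Patient-level train share.
#' @param positive_label Class treated as positive in metrics.
#' @return Named list per arm: `trace`, `final_loss` (mean loss over the
#'   last 20 steps), `n_train`, `metrics` (slice-level `metrics_report`),
#'   `patient_metrics` (majority-vote), or an `error` string for skipped
#'   arms.
#' @export
compare_filtering_arms <- function(spec,
                                   arms = c("unfiltered", "oracle-screened",
                                            "rknet-filtered"),
                                   cfg = train_config(),
                                   train_fraction = 0.75,
                                   positive_label = "Class1") {
  arms <- match.arg(arms, several.ok = TRUE)
  cohort <- generate_cohort(spec, out_dir = NULL)
  truth <- cohort$truth

  slices <- list(); feats <- list()
  for (v in cohort$volumes) {
    sl <- split_axial(v)
    slices <- c(slices, sl)
  }
  fm_raw <- extract_features(slices, do_normalize = FALSE)
  key <- paste(fm_raw$row_keys$patient_id, fm_raw$row_keys$series_id,
               fm_raw$row_keys$slice_index)
  tkey <- paste(truth$patient_id, truth$series_id, truth$slice_index)
  truth <- truth[match(key, tkey), ]

  split <- generate_labeled_split(spec, train_fraction)
  is_train <- truth$patient_id %in% split$train
  y <- truth$class_label

  # per-series clustering for the pipeline-filtered arm
  pipeline_relevant <- rep(NA, nrow(truth))
  if ("rknet-filtered" %in% arms) {
    for (pid in unique(truth$patient_id)) {
      sel <- which(truth$patient_id == pid)
      fm <- assemble_and_normalize(fm_raw$values[sel, , drop = FALSE],
                                   fm_raw$row_keys[sel, ], do_normalize = TRUE)
      model <- kmeans_fit(fm, k = 2L, seed = cfg$seed)
      run_idx <- which(truth$relevant[sel])
      ex_rows <- sel[run_idx[unique(round(seq(1L, length(run_idx), length.out = 3L)))]]
      relmap <- map_clusters_to_relevance(model, fm, rule = "exemplar",
                                          exemplars = truth[ex_rows, ])
      pipeline_relevant[sel] <-
        unname(relmap[as.character(model$assignments)]) == "relevant"
    }
  }

  test_idx <- which(!is_train & truth$relevant)
  arm_rows <- list(
    "unfiltered" = which(is_train),
    "oracle-screened" = which(is_train & truth$relevant),
    "rknet-filtered" = which(is_train & pipeline_relevant %in% TRUE))

  out <- list()
  for (arm in arms) {
    rows <- arm_rows[[arm]]
    if (length(rows) == 0L || length(unique(y[rows])) < 2L) {
      out[[arm]] <- list(error = "empty arm")
      next
    }
    fit <- train_linear_sgd(fm_raw$values[rows, , drop = FALSE], y[rows], cfg)
    pred <- predict_linear(fit$model, fm_raw$values[test_idx, , drop = FALSE])
    cc <- confusion_counts(pred, y[test_idx], positive_label)
    # patient-level majority vote over tumor-level test slices
    agg <- tapply(pred == positive_label, truth$patient_id[test_idx], mean)
    ptruth <- tapply(y[test_idx] == positive_label, truth$patient_id[test_idx],
                     function(v) v[1L])
    ppred <- ifelse(agg > 0.5, positive_label, "other")
    ptruth_lab <- ifelse(ptruth, positive_label, "other")
    pcc <- confusion_counts(ppred, ptruth_lab, positive_label)
    last <- utils::tail(fit$trace$loss, 20L)
    out[[arm]] <- list(trace = fit$trace, final_loss = mean(last),
                       n_train = length(rows),
                       metrics = compute_metrics(cc),
                       patient_metrics = compute_metrics(pcc))
  }
  out
}
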