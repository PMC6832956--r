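#' Fit a principal component model to spectra
#'
#' Mean-centered PCA; components are ordered by decreasing explained
#' variance. Nine components are retained by default, the number that in
#' practice carries more than 95% of cumulative spectral variance for
#' preprocessed pollen spectra.
#'
#' @param X samples x channels matrix.
#' @param n_components components to retain;
#'   `<= min(n_samples - 1, n_channels)`.
#' @return list of class `pca_model`: `mean`, `loadings`
#'   (channels x n_components, orthonormal), `explained_variance` (all
#'   components), `explained_variance_ratio`, `cumulative_variance`
#'   (through the retained components), `n_components`.
#' @export
pca_fit <- function(X, n_components = 9) {
  X <- as.matrix(X)
  max_comp <- min(nrow(X) - 1, ncol(X))
  if (n_components > max_comp) {
    stop(sprintf("n_components (%d) exceeds min(n_samples - 1, n_channels) = %d",
                 n_components, max_comp), call. = FALSE)
  }
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2
  ratio <- ev / sum(ev)
  structure(list(mean = pr$center,
                 loadings = pr$rotation[, seq_len(n_components),
                                        drop = FALSE],
                 explained_variance = ev,
                 explained_variance_ratio = ratio,
                 cumulative_variance = cumsum(ratio)[n_components],
                 n_components = n_components),
            class = "pca_model")
}

#' Project spectra onto a fitted PCA basis
#'
#' @param X samples x channels matrix on the model's channel grid.
#' @param model a [pca_fit()] result.
#' @return samples x n_components score matrix.
#' @export
pca_transform <- function(X, model) {
  X <- as.matrix(X)
  sweep(X, 2, model$mean) %*% model$loadings
}

#' Training configuration for the PCA-SVM stage
#'
#' @param n_train_scores training samples drawn per class (without
#'   replacement); the screening protocol trains on 100 score sets per
#'   class.
#' @param n_folds stratified cross-validation folds (default 10).
#' @param seed integer seed for the training draw and fold assignment.
#' @param strict if `TRUE`, a class smaller than `n_train_scores` is an
#'   error; otherwise all its samples are used with a warning.
#' @return list of class `train_config`.
#' @export
train_config <- function(n_train_scores = 100, n_folds = 10, seed = 1L,
                         strict = FALSE) {
  stopifnot(n_folds >= 2, n_train_scores >= n_folds)
  structure(list(n_train_scores = as.integer(n_train_scores),
                 n_folds = as.integer(n_folds), seed = as.integer(seed),
                 strict = strict),
            class = "train_config")
}

# Median-heuristic Gaussian kernel scale for one binary problem:
# gamma = 1 / (2 * median(pairwise distance)^2).
median_gamma <- function(X) {
  n <- nrow(X)
  if (n > 200) X <- X[seq(1, n, length.out = 200), , drop = FALSE]
  m <- stats::median(stats::dist(X))
  if (!is.finite(m) || m <= 0) m <- 1
  1 / (2 * m^2)
}

# Train the k(k-1)/2 one-vs-one Gaussian-kernel binary learners over the
# ECOC code matrix. `kernel_scale` is gamma; NULL = per-learner median
# heuristic.
fit_ecoc <- function(scores, labels, kernel_scale = NULL) {
  scores <- as.matrix(scores)
  labels <- factor(labels)
  classes <- levels(labels)
  k <- length(classes)
  if (k < 2) stop("need at least 2 classes", call. = FALSE)
  pairs <- utils::combn(k, 2)
  n_learners <- ncol(pairs)
  code <- matrix(0L, k, n_learners,
                 dimnames = list(classes, NULL))
  learners <- vector("list", n_learners)
  gammas <- numeric(n_learners)
  for (l in seq_len(n_learners)) {
    i <- pairs[1, l]; j <- pairs[2, l]
    code[i, l] <- 1L
    code[j, l] <- -1L
    sel <- labels %in% classes[c(i, j)]
    Xl <- scores[sel, , drop = FALSE]
    yl <- droplevels(labels[sel])
    gammas[l] <- if (is.null(kernel_scale)) median_gamma(Xl) else {
      kernel_scale
    }
    learners[[l]] <- e1071::svm(Xl, yl, kernel = "radial",
                                gamma = gammas[l], scale = FALSE)
  }
  structure(list(learners = learners, pairs = pairs, code = code,
                 classes = classes, gamma = gammas),
            class = "ecoc_svm")
}

# ECOC decoding: each one-vs-one learner votes; the predicted class
# minimizes the Hamming distance to its code row over the non-zero
# entries (equivalently, maximizes votes). Ties break to the first
# (lowest-order) class label.
predict_ecoc <- function(model, scores) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  k <- length(model$classes)
  votes <- matrix(0L, n, k, dimnames = list(NULL, model$classes))
  for (l in seq_along(model$learners)) {
    pred <- as.character(stats::predict(model$learners[[l]], scores))
    for (cls in model$classes[model$pairs[, l]]) {
      votes[pred == cls, cls] <- votes[pred == cls, cls] + 1L
    }
  }
  factor(model$classes[apply(votes, 1, which.max)],
         levels = model$classes)
}

#' Train the one-vs-one ECOC SVM on PCA scores
#'
#' Draws `config$n_train_scores` samples per class without replacement
#' (seeded) as the training set, reserves the remainder as the test set,
#' and trains `k(k-1)/2` one-vs-one Gaussian-kernel binary learners over
#' the error-correcting output code matrix.
#'
#' @param scores samples x components score matrix.
#' @param labels class label per row.
#' @param kernel_scale Gaussian kernel gamma; `NULL` for the per-learner
#'   median heuristic.
#' @param config a [train_config()].
#' @return list of class `svm_model`: the fitted `ecoc` learners plus
#'   `train_idx`, `test_idx`, `classes`, `config`.
#' @export
train_svm <- function(scores, labels, kernel_scale = NULL,
                      config = train_config()) {
  scores <- as.matrix(scores)
  labels <- factor(labels)
  classes <- levels(labels)
  if (length(classes) < 2) stop("need at least 2 classes", call. = FALSE)
  sizes <- table(labels)
  if (any(sizes < config$n_folds)) {
    stop("every class needs at least n_folds training samples",
         call. = FALSE)
  }
  train_idx <- with_seed(config$seed, {
    unlist(lapply(classes, function(cls) {
      idx <- which(labels == cls)
      if (length(idx) < config$n_train_scores) {
        if (config$strict) {
          stop(sprintf("class '%s' has %d < %d samples (strict mode)",
                       cls, length(idx), config$n_train_scores),
               call. = FALSE)
        }
        warning(sprintf("class '%s': using all %d samples for training",
                        cls, length(idx)), call. = FALSE)
        idx
      } else {
        sample(idx, config$n_train_scores)
      }
    }))
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(nrow(scores)), train_idx)
  ecoc <- fit_ecoc(scores[train_idx, , drop = FALSE],
                   droplevels(labels[train_idx]), kernel_scale)
  structure(list(ecoc = ecoc, classes = classes,
                 train_idx = train_idx, test_idx = test_idx,
                 kernel_scale = kernel_scale, config = config),
            class = "svm_model")
}

#' @export
predict.svm_model <- function(object, newdata, ...) {
  predict_ecoc(object$ecoc, newdata)
}

# Stratified fold assignment: per class, shuffle then deal out cyclically,
# so fold sizes differ by at most 1 per class.
stratified_folds <- function(labels, n_folds, seed) {
  labels <- factor(labels)
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cls in levels(labels)) {
      idx <- sample(which(labels == cls))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

#' Stratified k-fold cross-validation of the ECOC SVM
#'
#' Partitions the samples into `config$n_folds` label-stratified folds,
#' holds each fold out once, trains the one-vs-one ECOC SVM on the rest,
#' and returns the mean held-out misclassification rate over folds.
#'
#' @inheritParams train_svm
#' @return mean misclassification rate, with per-fold rates and the fold
#'   assignment as attributes.
#' @export
cross_validate <- function(scores, labels, kernel_scale = NULL,
                           config = train_config()) {
  scores <- as.matrix(scores)
  labels <- factor(labels)
  if (nrow(scores) < config$n_folds) {
    stop("fewer samples than folds", call. = FALSE)
  }
  fold <- stratified_folds(labels, config$n_folds, config$seed)
  rates <- vapply(seq_len(config$n_folds), function(f) {
    hold <- fold == f
    model <- fit_ecoc(scores[!hold, , drop = FALSE],
                      droplevels(labels[!hold]), kernel_scale)
    pred <- predict_ecoc(model, scores[hold, , drop = FALSE])
    mean(as.character(pred) != as.character(labels[hold]))
  }, numeric(1))
  out <- mean(rates)
  attr(out, "per_fold") <- rates
  attr(out, "fold") <- fold
  out
}

#' Score a trained model on held-out data
#'
#' @param model a [train_svm()] result.
#' @param test_scores samples x components matrix, disjoint from the
#'   training set.
#' @param test_labels true labels; every label must be known to the model.
#' @return a [confusion_matrix()].
#' @export
predict_and_score <- function(model, test_scores, test_labels) {
  test_labels <- as.character(test_labels)
  unseen <- setdiff(unique(test_labels), model$classes)
  if (length(unseen) > 0) {
    stop("unseen label(s) in test set: ",
         paste(unseen, collapse = ", "), call. = FALSE)
  }
  pred <- predict_ecoc(model$ecoc, test_scores)
  confusion_matrix(test_labels, as.character(pred),
                   classes = model$classes)
}
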