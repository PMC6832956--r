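#' Per-habit taxonomy configuration
#'
#' @param n_components retained principal components (default 9).
#' @param regions a [region_config()]; the classifier works on the
#'   concatenated fingerprint and high-wavenumber windows.
#' @param train a [train_config()].
#' @param kernel_scale Gaussian kernel gamma, `NULL` for the median
#'   heuristic.
#' @param tsne_perplexity,tsne_iter embedding parameters.
#' @param class_column manifest column holding the class label
#'   (default `"genus"`).
#' @return list of class `taxonomy_config`.
#' @export
taxonomy_config <- function(n_components = 9, regions = region_config(),
                            train = train_config(), kernel_scale = NULL,
                            tsne_perplexity = 30, tsne_iter = 500,
                            class_column = "genus") {
  structure(list(n_components = n_components, regions = regions,
                 train = train, kernel_scale = kernel_scale,
                 tsne_perplexity = tsne_perplexity,
                 tsne_iter = tsne_iter, class_column = class_column),
            class = "taxonomy_config")
}

# Feature matrix for classification: concatenated fingerprint +
# high-wavenumber windows, samples in rows.
taxonomy_features <- function(dataset, regions) {
  idx <- c(crop_region(dataset$wavenumber, regions$fingerprint),
           crop_region(dataset$wavenumber, regions$high_wavenumber))
  t(dataset$intensities[idx, , drop = FALSE])
}

#' Run the per-habit PCA-SVM taxonomy pipeline
#'
#' For one growth-habit group: crop the preprocessed spectra to the
#' concatenated fingerprint + high-wavenumber regions, fit PCA and retain
#' `n_components` score dimensions, draw the seeded per-class training
#' set, run stratified cross-validation on the training scores, score the
#' held-out test set, and embed the training scores with t-SNE.
#'
#' @param dataset preprocessed `spectral_dataset`.
#' @param habit growth habit to analyse (`"grass"`, `"herb"`, `"shrub"`
#'   or `"tree"`).
#' @param config a [taxonomy_config()].
#' @return list of class `taxonomy_result`: `pca`, `svm`,
#'   `cv_misclassification`, `confusion`, `embedding`,
#'   `cumulative_variance`, `habit`, `classes`, `n_train`, `n_test`.
#' @export
run_taxonomy <- function(dataset, habit, config = taxonomy_config()) {
  sel <- dataset$manifest$growth_habit == habit
  if (!any(sel)) stop("habit '", habit, "' absent from dataset",
                      call. = FALSE)
  ds <- subset_spectra(dataset, sel)
  labels <- ds$manifest[[config$class_column]]
  if (length(unique(labels)) < 2) {
    stop("degenerate classification: habit '", habit,
         "' has a single class", call. = FALSE)
  }
  X <- taxonomy_features(ds, config$regions)
  pca <- pca_fit(X, config$n_components)
  scores <- pca_transform(X, pca)
  svm <- train_svm(scores, labels, config$kernel_scale, config$train)
  train_scores <- scores[svm$train_idx, , drop = FALSE]
  train_labels <- labels[svm$train_idx]
  cv <- cross_validate(train_scores, train_labels, config$kernel_scale,
                       config$train)
  if (length(svm$test_idx) == 0) {
    stop("no held-out test samples; reduce n_train_scores", call. = FALSE)
  }
  confusion <- predict_and_score(svm, scores[svm$test_idx, , drop = FALSE],
                                 labels[svm$test_idx])
  perplexity <- min(config$tsne_perplexity,
                    floor((length(svm$train_idx) - 1) / 3))
  embedding <- tsne_embed(train_scores, train_labels,
                          perplexity = max(perplexity, 2),
                          seed = config$train$seed,
                          n_iter = config$tsne_iter)
  structure(list(pca = pca, svm = svm,
                 cv_misclassification = as.numeric(cv),
                 cv_per_fold = attr(cv, "per_fold"),
                 confusion = confusion, embedding = embedding,
                 cumulative_variance = pca$cumulative_variance,
                 habit = habit, classes = svm$classes,
                 n_train = length(svm$train_idx),
                 n_test = length(svm$test_idx)),
            class = "taxonomy_result")
}

#' @export
print.taxonomy_result <- function(x, ...) {
  cat(sprintf(
    "<taxonomy_result> habit '%s': %d classes, train %d / test %d\n",
    x$habit, length(x$classes), x$n_train, x$n_test))
  cat(sprintf("  cumulative variance (%d PCs): %.2f%%\n",
              x$pca$n_components, 100 * x$cumulative_variance))
  cat(sprintf("  CV misclassification: %.2f%%  test accuracy: %.2f%%\n",
              100 * x$cv_misclassification, 100 * x$confusion$accuracy))
  invisible(x)
}

#' Class mean spectra of a dataset
#'
#' @param dataset a `spectral_dataset`.
#' @param by manifest column to average over (default `"species"`).
#' @return matrix with one row per class (rownames = class labels).
#' @export
class_mean_spectra <- function(dataset, by = "species") {
  groups <- dataset$manifest[[by]]
  classes <- unique(groups)
  means <- t(vapply(classes, function(cls) {
    rowMeans(dataset$intensities[, groups == cls, drop = FALSE])
  }, numeric(nrow(dataset$intensities))))
  rownames(means) <- classes
  means
}

#' Growth-habit screening by hierarchical clustering
#'
#' The unsupervised arm of the pipeline: average per-species spectra over
#' the fingerprint region, cluster them with average-linkage HCA under
#' the Minkowski (p = 5) distance, cut the tree into four groups, and map
#' each cluster to its majority growth habit.
#'
#' @param dataset preprocessed `spectral_dataset`.
#' @param config an [hca_config()].
#' @return list: `hca` (an [hca()] result), `cut` (a [cut_and_map()]
#'   result), `habits` (true habit per clustered species).
#' @export
screen_growth_habit <- function(dataset, config = hca_config()) {
  means <- class_mean_spectra(dataset, by = "species")
  idx <- crop_region(dataset$wavenumber, config$region)
  means <- means[, idx, drop = FALSE]
  res <- hca(means, labels = rownames(means), config = config)
  species_habit <- dataset$manifest$growth_habit[
    match(rownames(means), dataset$manifest$species)]
  cut <- cut_and_map(res, config$n_clusters, species_habit)
  list(hca = res, cut = cut,
       habits = stats::setNames(species_habit, rownames(means)))
}
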