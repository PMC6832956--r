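#' Minkowski distance
#'
#' `(sum(|x_i - y_i|^p))^(1/p)`; `p = 2` is Euclidean. The clustering
#' stage of the pipeline uses `p = 5`, which emphasizes the largest
#' channel-wise differences between mean spectra.
#'
#' @param x,y numeric vectors of equal length.
#' @param p exponent, >= 1.
#' @return scalar distance.
#' @export
minkowski_distance <- function(x, y, p = 5) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (p < 1) stop("p must be >= 1", call. = FALSE)
  sum(abs(x - y)^p)^(1 / p)
}

#' Hierarchical clustering configuration
#'
#' @param p Minkowski exponent (default 5).
#' @param linkage agglomeration method (default `"average"`).
#' @param n_clusters flat clusters for the growth-habit cut (default 4).
#' @param region spectral window used for clustering (default the
#'   fingerprint region).
#' @return list of class `hca_config`.
#' @export
hca_config <- function(p = 5, linkage = "average", n_clusters = 4,
                       region = c(758, 1800)) {
  stopifnot(p >= 1, n_clusters >= 1)
  structure(list(p = p, linkage = linkage,
                 n_clusters = as.integer(n_clusters), region = region),
            class = "hca_config")
}

#' Hierarchical cluster analysis of class mean spectra
#'
#' Average-linkage agglomeration over the pairwise Minkowski (exponent
#' `config$p`) distance matrix, with the cophenetic distance matrix and
#' the cophenetic correlation coefficient (Pearson correlation between
#' original and cophenetic distances over all pairs) as a dendrogram
#' fidelity measure.
#'
#' @param spectra numeric matrix, one row per item (class mean spectrum),
#'   already cropped to the clustering region.
#' @param labels item labels (defaults to rownames).
#' @param config an [hca_config()].
#' @return list of class `hca_result`: `hclust`, `distance`,
#'   `cophenetic`, `cophenetic_coefficient`, `labels`, `config`.
#' @export
hca <- function(spectra, labels = rownames(spectra),
                config = hca_config()) {
  spectra <- as.matrix(spectra)
  if (nrow(spectra) < 2) stop("need at least 2 items", call. = FALSE)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(spectra)))
  rownames(spectra) <- labels
  d <- stats::dist(spectra, method = "minkowski", p = config$p)
  hc <- stats::hclust(d, method = config$linkage)
  coph <- stats::cophenetic(hc)
  cc <- if (length(d) < 2 || stats::sd(d) == 0 || stats::sd(coph) == 0) {
    1   # a degenerate or perfectly ultrametric configuration
  } else {
    stats::cor(d, coph)
  }
  structure(list(hclust = hc, distance = d, cophenetic = coph,
                 cophenetic_coefficient = cc, labels = labels,
                 config = config),
            class = "hca_result")
}

#' Cut a dendrogram and map clusters to majority groups
#'
#' Cuts the tree into exactly `n_clusters` flat clusters, assigns each
#' cluster the majority true group among its members (ties resolve to the
#' lexicographically first group), and scores the mapping against the true
#' groups with a confusion matrix.
#'
#' @param hca_result an [hca()] result (or a plain `hclust`).
#' @param n_clusters number of flat clusters.
#' @param true_groups true group label per clustered item.
#' @return list with `cluster` (integer cluster id per item), `mapping`
#'   (cluster id -> group), `predicted` (mapped group per item), and
#'   `confusion` (a [confusion_matrix()]).
#' @export
cut_and_map <- function(hca_result, n_clusters, true_groups) {
  hc <- if (inherits(hca_result, "hca_result")) hca_result$hclust
        else hca_result
  true_groups <- as.character(true_groups)
  cl <- stats::cutree(hc, k = n_clusters)
  mapping <- vapply(sort(unique(cl)), function(k) {
    members <- true_groups[cl == k]
    counts <- table(members)
    names(counts)[counts == max(counts)][1]   # lexicographic tie-break
  }, character(1))
  names(mapping) <- as.character(sort(unique(cl)))
  predicted <- unname(mapping[as.character(cl)])
  list(cluster = cl, mapping = mapping, predicted = predicted,
       confusion = confusion_matrix(true_groups, predicted))
}
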