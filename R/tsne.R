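# Conditional input affinities P_{j|i} with per-point precision chosen by
# binary search so each row's perplexity matches the target.
tsne_affinities <- function(D2, perplexity, tol = 1e-5, max_iter = 50) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  log_u <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    beta_min <- -Inf
    beta_max <- Inf
    di <- D2[i, -i]
    for (iter in seq_len(max_iter)) {
      p <- exp(-di * beta)
      sum_p <- sum(p)
      if (sum_p == 0) {
        h <- 0
        p[] <- 0
      } else {
        h <- log(sum_p) + beta * sum(di * p) / sum_p
        p <- p / sum_p
      }
      diff <- h - log_u
      if (abs(diff) < tol) break
      if (diff > 0) {
        beta_min <- beta
        beta <- if (is.finite(beta_max)) (beta + beta_max) / 2 else beta * 2
      } else {
        beta_max <- beta
        beta <- if (is.finite(beta_min)) (beta + beta_min) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P
}

#' t-SNE embedding of PCA scores with class medians
#'
#' t-distributed stochastic neighbor embedding to two dimensions, used to
#' visualize the per-habit training score sets. This implementation
#' evaluates the exact O(n^2) gradient (the limit of the Barnes-Hut
#' approximation as its accuracy parameter goes to zero), with standard
#' early exaggeration and momentum scheduling; the score sets embedded by
#' the pipeline are small enough that the exact gradient is cheap. The
#' embedding is deterministic for a fixed seed and is used for
#' visualization only — it never feeds classification.
#'
#' @param X samples x components matrix (>= 3 rows).
#' @param labels optional class label per row; enables per-class medians.
#' @param perplexity effective neighbourhood size; must be `< nrow(X)`.
#' @param seed integer seed for the random initialization.
#' @param n_iter gradient iterations.
#' @return list of class `tsne_embedding`: `coords` (n x 2), `medians`
#'   (data.frame `class`, `x`, `y`, component-wise per class; `NULL`
#'   without labels), `perplexity`, `seed`.
#' @export
tsne_embed <- function(X, labels = NULL, perplexity = 30, seed = 1L,
                       n_iter = 500) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  if (perplexity >= n) {
    stop("perplexity must be smaller than the number of points",
         call. = FALSE)
  }
  D2 <- as.matrix(stats::dist(X))^2
  P <- tsne_affinities(D2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  exaggeration <- 12
  stop_exag <- 100
  eta <- max(n / 12, 50)
  Y <- with_seed(seed, matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2))
  gains <- matrix(1, n, 2)
  update <- matrix(0, n, 2)
  for (iter in seq_len(n_iter)) {
    momentum <- if (iter <= 250) 0.5 else 0.8
    Pe <- if (iter <= stop_exag) P * exaggeration else P
    sum_y <- rowSums(Y^2)
    num <- 1 / (1 + outer(sum_y, sum_y, `+`) - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(W)) %*% Y - W %*% Y)
    same_sign <- sign(grad) == sign(update)
    gains <- ifelse(same_sign, gains * 0.8, gains + 0.2)
    gains[gains < 0.01] <- 0.01
    update <- momentum * update - eta * gains * grad
    Y <- Y + update
    Y <- sweep(Y, 2, colMeans(Y))
  }
  medians <- NULL
  if (!is.null(labels)) {
    labels <- as.character(labels)
    medians <- do.call(rbind, lapply(sort(unique(labels)), function(cls) {
      sel <- labels == cls
      data.frame(class = cls,
                 x = stats::median(Y[sel, 1]),
                 y = stats::median(Y[sel, 2]))
    }))
  }
  structure(list(coords = Y, medians = medians, perplexity = perplexity,
                 seed = as.integer(seed)),
            class = "tsne_embedding")
}
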