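# Independent brute-force oracles used to validate the implementation.
# These deliberately share no code with the package internals.

# Exhaustive Otsu search: try all 255 cuts, score each with the plain
# between-class variance formula, return the lowest maximizer.
oracle_otsu <- function(gray8) {
  v <- as.integer(gray8)
  best_t <- NA_integer_
  best_s <- -Inf
  n <- length(v)
  for (t in 0:254) {
    lo <- v[v <= t]
    hi <- v[v > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / n
    w1 <- length(hi) / n
    s <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (s > best_s + 1e-12) {
      best_s <- s
      best_t <- t
    }
  }
  best_t
}

# Queue-based flood-fill labeling, 8-connectivity.
oracle_label <- function(binary) {
  binary <- binary != 0
  nr <- nrow(binary); nc <- ncol(binary)
  labels <- matrix(0L, nr, nc)
  current <- 0L
  for (start in which(binary)) {
    if (labels[start] != 0L) next
    current <- current + 1L
    queue <- start
    labels[start] <- current
    while (length(queue) > 0) {
      p <- queue[1]; queue <- queue[-1]
      r <- (p - 1L) %% nr + 1L
      c <- (p - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
          q <- (cc - 1L) * nr + rr
          if (binary[q] && labels[q] == 0L) {
            labels[q] <- current
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  labels
}

# 3x3 dilation as an explicit logical-or of shifted copies.
oracle_dilate3x3 <- function(binary) {
  binary <- binary != 0
  nr <- nrow(binary); nc <- ncol(binary)
  out <- matrix(FALSE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- out[rs, cs] | binary[rs - dr, cs - dc]
  }
  out
}

# Naive O(n^3) average-linkage agglomeration over a distance matrix.
# Returns merge heights (in merge order) and the cophenetic matrix.
oracle_average_linkage <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1)
  coph <- matrix(0, n, n)
  for (step in seq_len(n - 1)) {
    m <- length(clusters)
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      d <- mean(D[clusters[[i]], clusters[[j]]])
      if (d < best_d) {
        best_d <- d
        best <- c(i, j)
      }
    }
    heights[step] <- best_d
    for (a in clusters[[best[1]]]) for (b in clusters[[best[2]]]) {
      coph[a, b] <- coph[b, a] <- best_d
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, cophenetic = coph)
}

# Mean silhouette width for a labelled 2-D embedding (hand-rolled).
oracle_silhouette <- function(coords, labels) {
  D <- as.matrix(dist(coords))
  labels <- as.character(labels)
  n <- nrow(coords)
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- labels == labels[i]
    a <- mean(D[i, same & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(D[i, labels == cl])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Small noise-free single-peak design shared across tests.
quiet_design <- function(...) {
  spectrum_design(scatter_sd = 0, noise_sd = 0, spike_rate = 0, ...)
}
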