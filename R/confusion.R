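#' Confusion matrix with per-class sensitivity and PPV
#'
#' Rows are the target (actual) class, columns the output (predicted)
#' class. Sensitivity of class i is `M[i,i] / rowSums(M)[i]` (recall);
#' positive predictive value of class j is `M[j,j] / colSums(M)[j]`
#' (precision); overall accuracy is `trace(M) / sum(M)`.
#'
#' @param actual,predicted label vectors of equal length.
#' @param classes class ordering; defaults to the sorted union of labels.
#' @return list of class `confusion_matrix`: `counts`, `sensitivity`,
#'   `ppv`, `accuracy`, `classes`.
#' @export
confusion_matrix <- function(actual, predicted,
                             classes = sort(unique(c(as.character(actual),
                                                     as.character(predicted))))) {
  actual <- factor(as.character(actual), levels = classes)
  predicted <- factor(as.character(predicted), levels = classes)
  if (length(actual) != length(predicted)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  counts <- table(actual = actual, predicted = predicted)
  counts <- matrix(as.numeric(counts), nrow = length(classes),
                   dimnames = list(actual = classes, predicted = classes))
  rs <- rowSums(counts)
  cs <- colSums(counts)
  sens <- ifelse(rs > 0, diag(counts) / rs, NA_real_)
  ppv <- ifelse(cs > 0, diag(counts) / cs, NA_real_)
  structure(list(counts = counts,
                 sensitivity = stats::setNames(sens, classes),
                 ppv = stats::setNames(ppv, classes),
                 accuracy = sum(diag(counts)) / sum(counts),
                 classes = classes),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> %d classes, n = %d, accuracy = %.1f%%\n",
              length(x$classes), sum(x$counts), 100 * x$accuracy))
  print(x$counts)
  cat("sensitivity (%):",
      paste(sprintf("%s %.1f", x$classes, 100 * x$sensitivity),
            collapse = ", "), "\n")
  cat("PPV (%):",
      paste(sprintf("%s %.1f", x$classes, 100 * x$ppv),
            collapse = ", "), "\n")
  invisible(x)
}
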