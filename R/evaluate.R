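#' Confusion matrix (rows = actual, columns = predicted)
#'
#' @param actual,predicted Equal-length integer label vectors with values
#'   in `0..n_classes-1`.
#' @param n_classes Number of classes.
#' @return Integer `n_classes` x `n_classes` matrix; entry `[a, p]` counts
#'   samples with actual label `a` predicted as `p`. Dimnames carry the
#'   label values.
#' @examples
#' confusion_matrix(c(0, 0, 1), c(1, 0, 1), 2)
#' @export
confusion_matrix <- function(actual, predicted, n_classes) {
  actual <- as.integer(actual)
  predicted <- as.integer(predicted)
  n_classes <- as.integer(n_classes)
  if (length(actual) != length(predicted)) {
    stop("`actual` and `predicted` must have equal length", call. = FALSE)
  }
  rng <- range(c(actual, predicted))
  if (rng[1] < 0L || rng[2] >= n_classes) {
    stop("labels must lie in 0..", n_classes - 1L, call. = FALSE)
  }
  m <- table(factor(actual, levels = 0:(n_classes - 1L)),
             factor(predicted, levels = 0:(n_classes - 1L)))
  m <- matrix(as.integer(m), n_classes, n_classes,
              dimnames = list(actual = 0:(n_classes - 1L),
                              predicted = 0:(n_classes - 1L)))
  m
}

#' Per-class and averaged classification metrics from a confusion matrix
#'
#' For each class (one-vs-rest): precision = TP / (TP + FP),
#' recall = TP / (TP + FN), F1 = harmonic mean of the two, and a
#' percentage accuracy. Averages are unweighted (macro) means. The overall
#' accuracy is the correct fraction over all samples,
#' `trace(confusion) / sum(confusion) * 100`.
#'
#' Two readings of a class-wise "accuracy" column are supported:
#' `"one_vs_rest"` (default) scores each class as a binary problem over
#' all samples (class k vs. not-k), so per-class accuracy can exceed every
#' per-class recall; `"recall"` reports recall x 100 instead.
#' A class never predicted (TP + FP = 0) gets precision 0 with a warning
#' rather than NaN.
#'
#' @param confusion Square nonnegative integer matrix, rows = actual.
#' @param class_accuracy Which per-class accuracy definition to report.
#' @return An `eval_report`: list with `confusion`, `per_class` (data
#'   frame: class, accuracy, precision, recall, f1), `averages`,
#'   `overall_accuracy` (percent), and `n_classes`.
#' @examples
#' metrics_from_confusion(matrix(c(40, 20, 10, 30), 2))
#' @export
metrics_from_confusion <- function(confusion,
                                   class_accuracy = c("one_vs_rest",
                                                      "recall")) {
  class_accuracy <- match.arg(class_accuracy)
  confusion <- as.matrix(confusion)
  K <- nrow(confusion)
  stopifnot(K == ncol(confusion), all(confusion >= 0))
  total <- sum(confusion)
  if (total < 1) stop("confusion matrix has no samples", call. = FALSE)

  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  tn <- total - tp - fp - fn

  precision <- numeric(K)
  for (k in seq_len(K)) {
    if (tp[k] + fp[k] == 0) {
      warning("class ", k - 1L, " is never predicted; precision set to 0",
              call. = FALSE)
      precision[k] <- 0
    } else {
      precision[k] <- tp[k] / (tp[k] + fp[k])
    }
  }
  recall <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  f1 <- ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall))
  acc <- if (class_accuracy == "one_vs_rest") {
    (tp + tn) / total * 100
  } else {
    recall * 100
  }

  per_class <- data.frame(class = seq_len(K) - 1L, accuracy = acc,
                          precision = precision, recall = recall, f1 = f1)
  averages <- c(accuracy = mean(acc), precision = mean(precision),
                recall = mean(recall), f1 = mean(f1))
  structure(list(confusion = confusion, per_class = per_class,
                 averages = averages,
                 overall_accuracy = sum(tp) / total * 100,
                 n_classes = K),
            class = "eval_report")
}

#' Evaluate a fitted model on a labeled image stack
#'
#' Convenience wrapper: predict, tabulate the confusion matrix on the
#' 0-based class codes, and compute the metric report.
#'
#' @param model A fitted [gaf_cnn()].
#' @param stack A `gaf_stack` with labels.
#' @param ... Passed to [metrics_from_confusion()].
#' @return An `eval_report`.
#' @export
evaluate_model <- function(model, stack, ...) {
  pred <- predict(model, stack)
  labs <- model$classes
  cm <- confusion_matrix(match(stack$labels, labs) - 1L,
                         match(pred, labs) - 1L, length(labs))
  dimnames(cm) <- list(actual = labs, predicted = labs)
  metrics_from_confusion(cm, ...)
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  cat("Classification report (", x$n_classes, " classes, ",
      sum(x$confusion), " samples)\n", sep = "")
  cat(sprintf("Overall accuracy: %.2f%%\n\n", x$overall_accuracy))
  pc <- x$per_class
  pc$accuracy <- sprintf("%.2f%%", pc$accuracy)
  pc[-(1:2)] <- lapply(pc[-(1:2)], function(v) round(v, 2))
  print(pc, row.names = FALSE)
  av <- x$averages
  cat(sprintf("Average:  %.2f%%  %0.2f  %0.2f  %0.2f\n",
              av["accuracy"], av["precision"], av["recall"], av["f1"]))
  invisible(x)
}

#' Render the per-class report as a table with an Average row
#'
#' Mirrors the standard stress-study report layout: one row per class
#' (named), columns Accuracy / Precision / Recall / F1 Score, and a final
#' Average row of unweighted column means.
#'
#' @param report An `eval_report`.
#' @param class_names Character vector of class display names, one per
#'   class (e.g. `c("Meditation", "Baseline", "Stress", "Amusement")`).
#' @param path Optional CSV path; when given the table is also written.
#' @return A data frame with `n_classes + 1` rows.
#' @export
report_tables <- function(report, class_names, path = NULL) {
  stopifnot(inherits(report, "eval_report"))
  if (length(class_names) != report$n_classes) {
    stop("`class_names` must name each of the ", report$n_classes,
         " classes", call. = FALSE)
  }
  pc <- report$per_class
  # the Average row is the mean of the class rows as displayed
  avg_of <- function(v) round(mean(round(v, 2)), 2)
  out <- data.frame(
    stress_level = c(class_names, "Average"),
    accuracy = c(round(pc$accuracy, 2), avg_of(pc$accuracy)),
    precision = c(round(pc$precision, 2), avg_of(pc$precision)),
    recall = c(round(pc$recall, 2), avg_of(pc$recall)),
    f1_score = c(round(pc$f1, 2), avg_of(pc$f1)),
    row.names = NULL
  )
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' Confusion-matrix heatmap
#'
#' Renders counts or row-normalized percentages (percentage of each actual
#' class falling in each predicted cell) as a PNG heatmap.
#'
#' @param confusion Square matrix (or an `eval_report`).
#' @param path Output PNG path.
#' @param percent Show row percentages (default) instead of raw counts.
#' @param class_names Optional axis labels.
#' @return `path`, invisibly.
#' @export
plot_confusion <- function(confusion, path, percent = TRUE,
                           class_names = NULL) {
  if (inherits(confusion, "eval_report")) confusion <- confusion$confusion
  m <- as.matrix(confusion)
  K <- nrow(m)
  disp <- if (percent) m / pmax(rowSums(m), 1) * 100 else m
  if (is.null(class_names)) class_names <- as.character(0:(K - 1L))
  grDevices::png(path, width = 480, height = 480)
  on.exit(grDevices::dev.off())
  graphics::image(seq_len(K), seq_len(K),
                  t(disp[K:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "Blues 3", rev = TRUE),
                  axes = FALSE, xlab = "Predicted", ylab = "Actual")
  graphics::axis(1, at = seq_len(K), labels = class_names)
  graphics::axis(2, at = seq_len(K), labels = rev(class_names))
  for (a in seq_len(K)) {
    for (p in seq_len(K)) {
      lab <- if (percent) sprintf("%.1f%%", disp[a, p]) else disp[a, p]
      graphics::text(p, K - a + 1L, lab)
    }
  }
  invisible(path)
}
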