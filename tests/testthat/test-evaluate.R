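test_that("confusion_matrix counts actual x predicted", {
  expect_equal(unname(confusion_matrix(c(0, 1), c(0, 1), 2)),
               diag(2) * 1L, ignore_attr = TRUE)
  expect_equal(unname(confusion_matrix(c(0, 0, 1), c(1, 0, 1), 2)),
               matrix(c(1L, 0L, 1L, 1L), 2), ignore_attr = TRUE)
  perfect <- confusion_matrix(rep(0:2, 5), rep(0:2, 5), 3)
  expect_true(all(perfect[upper.tri(perfect) | lower.tri(perfect)] == 0L))
  expect_error(confusion_matrix(c(0, 4), c(0, 1), 3), "labels")
  expect_error(confusion_matrix(c(0, 1), c(0), 2), "equal length")
})

test_that("metrics reproduce the hand-worked confusion example", {
  rep <- metrics_from_confusion(matrix(c(40, 20, 10, 30), 2))
  # class 0: precision 40/60, recall 40/50, F1 harmonic mean
  expect_equal(rep$per_class$precision[1], 40 / 60, tolerance = 1e-12)
  expect_equal(rep$per_class$recall[1], 0.8, tolerance = 1e-12)
  expect_equal(rep$per_class$f1[1],
               2 / (1 / (40 / 60) + 1 / 0.8), tolerance = 1e-12)
  expect_equal(rep$overall_accuracy, 70)
})

test_that("a perfect classifier scores 1.0 everywhere", {
  rep <- metrics_from_confusion(diag(c(50, 50)))
  expect_equal(rep$per_class$precision, c(1, 1))
  expect_equal(rep$per_class$recall, c(1, 1))
  expect_equal(rep$per_class$f1, c(1, 1))
  expect_equal(rep$overall_accuracy, 100)
  expect_equal(unname(rep$averages["accuracy"]), 100)
})

test_that("F1 equals precision and recall at their fixed point", {
  # symmetric confusion: precision == recall per class
  rep <- metrics_from_confusion(matrix(c(30, 10, 10, 30), 2))
  for (k in 1:2) {
    expect_equal(rep$per_class$precision[k], rep$per_class$recall[k])
    expect_equal(rep$per_class$f1[k], rep$per_class$precision[k],
                 tolerance = 1e-12)
  }
})

test_that("metrics agree with a brute-force recount on random labelings", {
  set.seed(77)
  for (i in 1:100) {
    K <- sample(2:5, 1)
    n <- sample(20:80, 1)
    actual <- sample(0:(K - 1), n, replace = TRUE)
    predicted <- sample(0:(K - 1), n, replace = TRUE)
    cm <- confusion_matrix(actual, predicted, K)
    rep <- suppressWarnings(metrics_from_confusion(cm))
    oracle <- brute_force_metrics(actual, predicted, K)
    expect_equal(rep$per_class$accuracy, unname(oracle[, "accuracy"]),
                 tolerance = 1e-12)
    expect_equal(rep$per_class$precision, unname(oracle[, "precision"]),
                 tolerance = 1e-12)
    expect_equal(rep$per_class$recall, unname(oracle[, "recall"]),
                 tolerance = 1e-12)
    expect_equal(rep$per_class$f1, unname(oracle[, "f1"]),
                 tolerance = 1e-12)
    expect_equal(rep$overall_accuracy, mean(actual == predicted) * 100,
                 tolerance = 1e-12)
    # macro F1 is bracketed by the per-class extremes
    expect_lte(rep$averages["f1"], max(rep$per_class$f1))
    expect_gte(rep$averages["f1"], min(rep$per_class$f1))
  }
})

test_that("a never-predicted class gets precision 0 with a warning", {
  cm <- matrix(c(5, 5, 0, 0), 2)   # nothing predicted as class 1
  expect_warning(rep <- metrics_from_confusion(cm), "never predicted")
  expect_equal(rep$per_class$precision[2], 0)
})

test_that("the recall reading of class-wise accuracy is available", {
  cm <- matrix(c(40, 20, 10, 30), 2)
  rep <- metrics_from_confusion(cm, class_accuracy = "recall")
  expect_equal(rep$per_class$accuracy, rep$per_class$recall * 100)
})

test_that("report tables append an Average row of column means", {
  cm <- matrix(c(40, 5, 3, 2,
                 4, 42, 2, 2,
                 3, 2, 44, 1,
                 2, 1, 2, 45), 4, byrow = TRUE)
  rep <- metrics_from_confusion(cm)
  tab <- report_tables(rep, c("Meditation", "Baseline", "Stress",
                              "Amusement"))
  expect_equal(nrow(tab), 5L)
  expect_equal(tab$stress_level[5], "Average")
  for (col in c("accuracy", "precision", "recall", "f1_score")) {
    expect_equal(tab[[col]][5], round(mean(head(tab[[col]], 4)), 2),
                 tolerance = 0.011)
  }
  tab3 <- report_tables(metrics_from_confusion(diag(c(5, 5, 5))),
                        c("No Stress", "Time Pressure", "Interruption"))
  expect_equal(nrow(tab3), 4L)
  expect_error(report_tables(rep, c("a", "b")), "name")
})

test_that("confusion heatmaps are written to disk", {
  cm <- matrix(c(9, 1, 2, 8), 2)
  path <- withr::local_tempfile(fileext = ".png")
  plot_confusion(cm, path)
  expect_true(file.exists(path) && file.size(path) > 0)
})
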