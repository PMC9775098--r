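test_that("stratified splitting preserves class counts and is seeded", {
  stack <- small_stack(n = 100, K = 4, seed = 1)
  sp <- split_train_test(stack, test_fraction = 0.4, seed = 9)
  expect_length(sp$train$labels, 240L)
  expect_length(sp$test$labels, 160L)
  expect_equal(unname(table(sp$train$labels)), rep(60L, 4),
               ignore_attr = TRUE)
  expect_equal(unname(table(sp$test$labels)), rep(40L, 4),
               ignore_attr = TRUE)
  # one-hot labels accompany both halves
  expect_equal(dim(sp$train$onehot), c(240L, 4L))
  expect_true(all(rowSums(sp$train$onehot) == 1))
  sp2 <- split_train_test(stack, test_fraction = 0.4, seed = 9)
  expect_identical(sp$test$labels, sp2$test$labels)
  expect_identical(sp$test$images, sp2$test$images)
})

test_that("a 0.5 split of 10 samples gives 5/5 and tiny classes error", {
  set.seed(2)
  stack <- structure(list(images = array(rnorm(10 * 64), c(10, 8, 8)),
                          labels = rep(c(0L, 1L), c(6L, 4L)), side = 8L,
                          method = "summation"),
                     class = "gaf_stack")
  sp <- split_train_test(stack, test_fraction = 0.5, seed = 1)
  expect_length(sp$train$labels, 5L)
  expect_length(sp$test$labels, 5L)

  one <- structure(list(images = array(0, c(3, 8, 8)),
                        labels = c(0L, 0L, 1L), side = 8L,
                        method = "summation"),
                   class = "gaf_stack")
  expect_error(split_train_test(one), "at least 2")
})

test_that("temporal splitting holds out the trailing rows of each class", {
  stack <- small_stack(n = 10, K = 2, seed = 3)
  sp <- split_train_test(stack, test_fraction = 0.4, temporal = TRUE)
  # per class, test images are the last 4 of the 10
  for (k in 0:1) {
    idx <- which(stack$labels == k)
    test_imgs <- sp$test$images[sp$test$labels == k, , , drop = FALSE]
    expect_equal(test_imgs, stack$images[tail(idx, 4), , , drop = FALSE])
  }
})

test_that("backpropagated gradients match finite differences", {
  set.seed(101)
  B <- 4L
  X <- matrix(rnorm(B * 64), B, 64)
  Y <- diag(3)[sample(1:3, B, replace = TRUE), ]
  net <- gafstress:::.nn_init(8L, 3L)
  net$plans <- new.env(parent = emptyenv())
  loss_at <- function(net) {
    fw <- gafstress:::.nn_forward(net, X, training = TRUE)
    gafstress:::.nn_loss(fw$probs, Y)
  }
  fw <- gafstress:::.nn_forward(net, X, training = TRUE)
  grads <- gafstress:::.nn_backward(net, fw$cache, fw$probs, Y)
  h <- 1e-6
  for (nm in c("W1", "b1", "g1", "be1", "W2", "g2", "W3", "be3", "W4",
               "b4", "W5", "b5")) {
    p <- net$params[[nm]]
    picks <- sample(length(p), min(4L, length(p)))
    for (i in picks) {
      np <- net
      np$params[[nm]][i] <- p[i] + h
      up <- loss_at(np)
      np$params[[nm]][i] <- p[i] - h
      dn <- loss_at(np)
      num <- (up - dn) / (2 * h)
      ana <- grads[[nm]][i]
      expect_equal(ana, num, tolerance = 1e-4,
                   label = sprintf("d%s[%d] analytic", nm, i))
    }
  }
})

test_that("training bookkeeping: one epoch gives one history row", {
  stack <- small_stack(n = 8, K = 2, seed = 4)
  fit <- gaf_cnn(stack, epochs = 1, seed = 1)
  expect_equal(nrow(fit$history), 1L)
  expect_true(is.finite(fit$history$loss))
  fit3 <- gaf_cnn(stack, epochs = 3, seed = 1)
  expect_equal(fit3$history$epoch, 1:3)
})

test_that("training is reproducible under a fixed seed", {
  stack <- small_stack(n = 12, K = 2, seed = 6)
  f1 <- gaf_cnn(stack, epochs = 2, seed = 7)
  f2 <- gaf_cnn(stack, epochs = 2, seed = 7)
  expect_identical(f1$history, f2$history)
  expect_identical(coef(f1), coef(f2))
})

test_that("predictions are normalized probabilities with consistent argmax", {
  stack <- small_stack(n = 15, K = 3, seed = 5)
  fit <- gaf_cnn(stack, epochs = 2, seed = 2)
  probs <- predict(fit, stack, type = "prob")
  expect_equal(rowSums(probs), rep(1, nrow(probs)), tolerance = 1e-6)
  cls <- predict(fit, stack)
  expect_equal(cls, fit$classes[max.col(probs, ties.method = "first")])
  # duplicated inputs predict identically
  dup <- stack$images[c(1, 1, 2, 2), , ]
  p <- predict(fit, dup, type = "prob")
  expect_identical(p[1, ], p[2, ])
  expect_identical(p[3, ], p[4, ])
  # shape mismatch is caught
  expect_error(predict(fit, array(0, c(2, 9, 9))), "8x8")
})

test_that("training loss decreases on separable data across seeds", {
  drops <- 0L
  total <- 0L
  for (seed in 1:5) {
    stack <- small_stack(n = 100, K = 4, seed = seed)
    fit <- gaf_cnn(stack, epochs = 8, seed = seed)
    d <- diff(fit$history$loss)
    drops <- drops + sum(d <= 1e-6)
    total <- total + length(d)
  }
  expect_gte(drops / total, 0.9)
})

test_that("models survive a checkpoint round-trip", {
  stack <- small_stack(n = 10, K = 2, seed = 8)
  fit <- gaf_cnn(stack, epochs = 1, seed = 3)
  path <- withr::local_tempfile(fileext = ".rds")
  save_gaf_cnn(fit, path)
  back <- load_gaf_cnn(path)
  expect_identical(predict(fit, stack, type = "prob"),
                   predict(back, stack, type = "prob"))
})
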