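#' Stratified train/test split of a labeled image stack
#'
#' Randomly assigns `test_fraction` of each class to the test set (the 3:2
#' train:test ratio of the standard pipeline corresponds to
#' `test_fraction = 0.4`). One-hot label matrices are attached to both
#' halves. A temporal split (first rows train, last rows test, per class)
#' is available because random splitting of contiguous sensor streams lets
#' adjacent, nearly identical samples straddle the split and can inflate
#' accuracy on real recordings.
#'
#' @param stack A `gaf_stack` from [encode_dataset()].
#' @param test_fraction Fraction of each class held out, in (0, 1);
#'   default 0.4.
#' @param seed Integer seed for the random assignment.
#' @param temporal If `TRUE`, split each class block by time instead of at
#'   random.
#' @return List with elements `train` and `test`, each a `gaf_stack` with
#'   an additional `onehot` matrix.
#' @export
split_train_test <- function(stack, test_fraction = 0.4, seed = 1L,
                             temporal = FALSE) {
  stopifnot(inherits(stack, "gaf_stack"),
            test_fraction > 0, test_fraction < 1)
  labs <- sort(unique(stack$labels))
  counts <- table(factor(stack$labels, levels = labs))
  if (any(counts < 2L)) {
    stop("every class needs at least 2 samples to split; class(es) ",
         paste(names(counts)[counts < 2L], collapse = ", "),
         " are too small", call. = FALSE)
  }
  set.seed(seed)
  test_idx <- integer(0)
  for (l in labs) {
    idx <- which(stack$labels == l)
    n_test <- round(length(idx) * test_fraction)
    n_test <- max(1L, min(length(idx) - 1L, n_test))
    picked <- if (temporal) {
      idx[seq.int(length(idx) - n_test + 1L, length(idx))]
    } else {
      sort(sample(idx, n_test))
    }
    test_idx <- c(test_idx, picked)
  }
  take <- function(idx) {
    structure(list(images = stack$images[idx, , , drop = FALSE],
                   labels = stack$labels[idx],
                   side = stack$side, method = stack$method,
                   onehot = .onehot(stack$labels[idx], labs)),
              class = "gaf_stack")
  }
  list(train = take(setdiff(seq_along(stack$labels), test_idx)),
       test = take(test_idx))
}

.onehot <- function(labels, levels) {
  Y <- matrix(0, length(labels), length(levels))
  Y[cbind(seq_along(labels), match(labels, levels))] <- 1
  colnames(Y) <- levels
  Y
}

.flatten_images <- function(images) {
  n <- dim(images)[1]
  s <- dim(images)[2]
  X <- matrix(0, n, s * s)
  for (i in seq_len(n)) X[i, ] <- as.vector(images[i, , ])
  X
}

#' Fit the small GAF-image convolutional network
#'
#' Trains the fixed architecture of [build_architecture()] -- three 3x3
#' valid convolutions with 64 filters and ReLU, each followed by batch
#' normalization, then 2x2 max pooling, a linear 6-unit dense layer and a
#' softmax output -- by minimizing categorical cross-entropy with Adam.
#' Labels are one-hot encoded internally. Training is mini-batch gradient
#' descent with per-epoch reshuffling; the per-epoch history records the
#' running training loss and accuracy exactly as accumulated over the
#' epoch's batches (i.e. before-update forward passes).
#'
#' @param x A `gaf_stack` from [encode_dataset()], or an n x side x side
#'   numeric array of images.
#' @param y Integer label vector (ignored when `x` is a `gaf_stack`, which
#'   carries its own labels).
#' @param epochs Training epochs (full-scale wearable runs use about 100;
#'   strongly separated synthetic data converges in far fewer).
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size.
#' @param seed Integer seed governing weight initialization and shuffling.
#' @param validation Optional list with elements `x` (stack or array) and
#'   `y`; evaluated in inference mode after every epoch.
#' @param verbose Print a line every `verbose` epochs (0 = silent).
#' @return An object of class `gaf_cnn`: the fitted weights, batch-norm
#'   statistics, training history (`data.frame` epoch/loss/accuracy, plus
#'   validation columns when supplied), the class levels and the
#'   architecture table.
#' @seealso [predict.gaf_cnn()], [build_architecture()], [run_pipeline()]
#' @examples
#' \donttest{
#' cm <- generate_synthetic(synthetic_config(points_per_class = 120,
#'                                           seed = 5))
#' gs <- preprocess_channels(cm, window_size = 120)
#' stack <- encode_dataset(gs)
#' sp <- split_train_test(stack, 0.4, seed = 5)
#' fit <- gaf_cnn(sp$train, epochs = 3, seed = 5)
#' mean(predict(fit, sp$test) == sp$test$labels)
#' }
#' @export
gaf_cnn <- function(x, y = NULL, epochs = 30L, batch_size = 32L,
                    learning_rate = 1e-3, seed = 1L, validation = NULL,
                    verbose = 0L) {
  if (inherits(x, "gaf_stack")) {
    images <- x$images
    y <- x$labels
  } else {
    images <- x
    if (is.null(y)) stop("`y` is required when `x` is a plain array",
                         call. = FALSE)
  }
  stopifnot(length(dim(images)) == 3L, dim(images)[2] == dim(images)[3])
  side <- dim(images)[2]
  classes <- sort(unique(as.integer(y)))
  K <- length(classes)
  arch <- build_architecture(side, K)
  X <- .flatten_images(images)
  Y <- .onehot(as.integer(y), classes)
  n <- nrow(X)

  set.seed(seed)
  net <- .nn_init(side, K)
  net$plans <- new.env(parent = emptyenv())
  adam <- .adam_init(net$params)

  val <- NULL
  if (!is.null(validation)) {
    vx <- validation$x
    vy <- if (inherits(vx, "gaf_stack")) vx$labels else validation$y
    vimg <- if (inherits(vx, "gaf_stack")) vx$images else vx
    val <- list(X = .flatten_images(vimg), y = as.integer(vy))
  }

  history <- data.frame(epoch = seq_len(epochs), loss = NA_real_,
                        accuracy = NA_real_)
  if (!is.null(val)) history$val_loss <- history$val_accuracy <- NA_real_

  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    tot_loss <- 0
    tot_correct <- 0
    for (start in seq.int(1L, n, by = batch_size)) {
      idx <- ord[seq.int(start, min(start + batch_size - 1L, n))]
      Xb <- X[idx, , drop = FALSE]
      Yb <- Y[idx, , drop = FALSE]
      fw <- .nn_forward(net, Xb, training = TRUE)
      tot_loss <- tot_loss + .nn_loss(fw$probs, Yb) * length(idx)
      tot_correct <- tot_correct +
        sum(max.col(fw$probs) == max.col(Yb))
      grads <- .nn_backward(net, fw$cache, fw$probs, Yb)
      step <- .adam_step(net$params, grads, adam, lr = learning_rate)
      net$params <- step$params
      adam <- step$adam
      net$bn <- fw$cache$bn_new
    }
    history$loss[ep] <- tot_loss / n
    history$accuracy[ep] <- tot_correct / n
    if (!is.null(val)) {
      pv <- .nn_predict_probs(net, val$X)
      history$val_loss[ep] <- .nn_loss(pv, .onehot(val$y, classes))
      history$val_accuracy[ep] <- mean(classes[max.col(pv)] == val$y)
    }
    if (verbose > 0L && (ep %% verbose == 0L || ep == epochs)) {
      message(sprintf("epoch %3d/%d  loss %.4f  acc %.4f", ep, epochs,
                      history$loss[ep], history$accuracy[ep]))
    }
  }

  structure(list(net = net, classes = classes, side = side,
                 history = history, architecture = arch,
                 epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, seed = seed,
                 call = match.call()),
            class = "gaf_cnn")
}

# inference-mode forward in bounded batches
.nn_predict_probs <- function(net, X, batch = 512L) {
  n <- nrow(X)
  out <- matrix(0, n, net$n_classes)
  for (start in seq.int(1L, n, by = batch)) {
    idx <- seq.int(start, min(start + batch - 1L, n))
    out[idx, ] <- .nn_forward(net, X[idx, , drop = FALSE],
                              training = FALSE)$probs
  }
  out
}

#' Predict classes or probabilities from a fitted GAF network
#'
#' @param object A fitted [gaf_cnn()] model.
#' @param newdata A `gaf_stack`, an n x side x side array, or a single
#'   side x side matrix.
#' @param type `"class"` (default) for hard labels on the original label
#'   scale, `"prob"` for the softmax class-probability matrix.
#' @param ... Unused.
#' @return Integer label vector or probability matrix (rows sum to 1,
#'   columns named by class).
#' @export
predict.gaf_cnn <- function(object, newdata, type = c("class", "prob"),
                            ...) {
  type <- match.arg(type)
  images <- if (inherits(newdata, "gaf_stack")) newdata$images else newdata
  if (is.matrix(images)) {
    images <- array(images, dim = c(1L, nrow(images), ncol(images)))
  }
  if (length(dim(images)) != 3L || dim(images)[2] != object$side ||
      dim(images)[3] != object$side) {
    stop("`newdata` images must be ", object$side, "x", object$side,
         " to match the fitted model", call. = FALSE)
  }
  probs <- .nn_predict_probs(object$net, .flatten_images(images))
  colnames(probs) <- object$classes
  if (type == "prob") return(probs)
  object$classes[max.col(probs, ties.method = "first")]
}

#' @export
print.gaf_cnn <- function(x, ...) {
  cat("GAF-image convolutional network\n")
  cat("  input: ", x$side, "x", x$side, "x1, classes: ",
      paste(x$classes, collapse = " "), "\n", sep = "")
  cat("  trained ", x$epochs, " epochs (batch ", x$batch_size,
      ", lr ", format(x$learning_rate), ", seed ", x$seed, ")\n", sep = "")
  last <- x$history[nrow(x$history), ]
  cat(sprintf("  final training loss %.4f, accuracy %.4f\n",
              last$loss, last$accuracy))
  if (!is.null(x$history$val_accuracy)) {
    cat(sprintf("  final validation accuracy %.4f\n", last$val_accuracy))
  }
  invisible(x)
}

#' @export
summary.gaf_cnn <- function(object, ...) {
  print(object)
  cat("\n")
  print(object$architecture)
  invisible(object)
}

#' Plot training curves of a fitted GAF network
#'
#' Loss versus epoch and accuracy versus epoch, side by side.
#'
#' @param x A fitted [gaf_cnn()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.gaf_cnn <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch",
                 ylab = "loss", main = "Training loss", ...)
  if (!is.null(h$val_loss)) graphics::lines(h$epoch, h$val_loss, lty = 2)
  graphics::plot(h$epoch, h$accuracy, type = "l", xlab = "epoch",
                 ylab = "accuracy", ylim = c(0, 1),
                 main = "Training accuracy", ...)
  if (!is.null(h$val_accuracy)) {
    graphics::lines(h$epoch, h$val_accuracy, lty = 2)
  }
  invisible(x)
}

#' Extract fitted weights
#'
#' @param object A fitted [gaf_cnn()].
#' @param ... Unused.
#' @return Named list of weight matrices/vectors (convolution kernels as
#'   im2col matrices, batch-norm scale/shift, dense weights).
#' @export
coef.gaf_cnn <- function(object, ...) object$net$params

#' Save / load a fitted model
#'
#' Thin wrappers around R's native serialization, the package's checkpoint
#' format.
#'
#' @param object A fitted [gaf_cnn()].
#' @param path File path.
#' @return `save_gaf_cnn` returns `path` invisibly; `load_gaf_cnn` the
#'   restored model.
#' @export
save_gaf_cnn <- function(object, path) {
  stopifnot(inherits(object, "gaf_cnn"))
  # index plans are a per-session cache; rebuilt lazily after load
  object$net$plans <- NULL
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_gaf_cnn
#' @export
load_gaf_cnn <- function(path) {
  object <- readRDS(path)
  stopifnot(inherits(object, "gaf_cnn"))
  object$net$plans <- new.env(parent = emptyenv())
  object
}
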