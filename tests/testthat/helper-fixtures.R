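# Shared fixture builders; everything is generated in code at test time.

# small encoded stack: K classes x n rows/class of 8-channel synthetic data
small_stack <- function(n = 60, K = 4, seed = 42, sep = 3, noise = 0.3) {
  cm <- generate_synthetic(synthetic_config(
    n_classes = K, n_channels = 8, points_per_class = n,
    noise_sd = noise, class_separation = sep, seed = seed))
  encode_dataset(preprocess_channels(cm, window_size = n))
}

# miniature per-subject chest record in the loader's expected structure
write_chest_record <- function(path, n = 20, labels = rep(0:3, each = 5),
                               seed = 1) {
  set.seed(seed)
  rec <- list(
    chest = list(
      ACC = matrix(rnorm(n * 3), n, 3),
      ECG = rnorm(n), EMG = rnorm(n), EDA = rnorm(n),
      TEMP = rnorm(n), RESP = rnorm(n)
    ),
    label = as.integer(labels)
  )
  saveRDS(rec, path)
  rec
}

# brute-force metric recount straight from label vectors, used as the
# independent oracle for metrics_from_confusion
brute_force_metrics <- function(actual, predicted, K) {
  per <- lapply(0:(K - 1), function(k) {
    tp <- sum(actual == k & predicted == k)
    fp <- sum(actual != k & predicted == k)
    fn <- sum(actual == k & predicted != k)
    tn <- sum(actual != k & predicted != k)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    c(accuracy = (tp + tn) / length(actual) * 100,
      precision = prec, recall = rec, f1 = f1)
  })
  do.call(rbind, per)
}
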