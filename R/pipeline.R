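#' Pipeline configuration
#'
#' One object describing a full run: data source, preprocessing window,
#' image side, training settings, seed and output directory. A single seed
#' fans out deterministically to the synthetic generator, the train/test
#' split, and weight initialization/shuffling, so one integer reproduces a
#' run end to end.
#'
#' @param dataset `"synthetic"`, `"wesad"` or `"swell"`.
#' @param path Input file for the non-synthetic sources.
#' @param n_classes Classes (4 for the chest-device protocol, 3 for the
#'   office-stress labels; free for synthetic).
#' @param window_size Trailing rows kept per class (default 10,000).
#' @param image_side Image side = channel count fed to the encoder.
#' @param points_per_class,noise_sd,class_separation Synthetic-generator
#'   settings (ignored for file sources).
#' @param epochs,batch_size,learning_rate,test_fraction Training settings;
#'   `test_fraction = 0.4` is the 3:2 train:test split.
#' @param gaf_method `"summation"` or `"difference"` image form.
#' @param per_block_normalization Quantile-normalize within class blocks
#'   (default) or globally.
#' @param temporal_split Use a temporal rather than random stratified
#'   split.
#' @param seed Master seed.
#' @param out_dir Output directory for artifacts (`NULL` = no files).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(dataset = c("synthetic", "wesad", "swell"),
                            path = NULL, n_classes = 4L,
                            window_size = 10000L, image_side = 8L,
                            points_per_class = 10000L, noise_sd = 0.3,
                            class_separation = 3,
                            epochs = 30L, batch_size = 32L,
                            learning_rate = 1e-3, test_fraction = 0.4,
                            gaf_method = "summation",
                            per_block_normalization = TRUE,
                            temporal_split = FALSE,
                            seed = 1L, out_dir = NULL) {
  dataset <- match.arg(dataset)
  if (dataset != "synthetic" && is.null(path)) {
    stop("`path` is required for dataset = \"", dataset, "\"",
         call. = FALSE)
  }
  if (dataset == "wesad" && n_classes != 4L) {
    stop("the chest-device protocol has 4 classes", call. = FALSE)
  }
  if (dataset == "swell" && n_classes != 3L) {
    stop("the office-stress labels have 3 classes", call. = FALSE)
  }
  if (image_side < 8L) {
    stop("`image_side` must be >= 8 (see build_architecture())",
         call. = FALSE)
  }
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full stress-classification pipeline
#'
#' Load or generate -> group by label -> trailing window -> quantile
#' normalization -> GAF encoding -> stratified split -> CNN training ->
#' evaluation. Logs row counts at each stage boundary. When
#' `config$out_dir` is set, persists: the config snapshot (YAML), the
#' per-epoch history (CSV), the model checkpoint (RDS), the per-class
#' report (CSV) and a confusion-matrix heatmap (PNG).
#'
#' @param config A [pipeline_config()].
#' @param class_names Optional display names for the report table.
#' @param verbose Print stage progress (default TRUE).
#' @return A list: `report` (the [metrics_from_confusion()] output on the
#'   held-out set), `model` (the fitted [gaf_cnn()]), `history`, `config`,
#'   and `table` (the formatted per-class report).
#' @examples
#' \donttest{
#' res <- run_pipeline(pipeline_config(points_per_class = 150,
#'                                     window_size = 150, epochs = 3))
#' res$report
#' }
#' @export
run_pipeline <- function(config, class_names = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop("pipeline stage `", name, "` failed: ",
           conditionMessage(e), call. = FALSE)
    })
    say("[%s] %.2fs", name, as.numeric(Sys.time() - t0, units = "secs"))
    out
  }

  cm <- stage("load", switch(config$dataset,
    synthetic = generate_synthetic(synthetic_config(
      n_classes = config$n_classes, n_channels = config$image_side,
      points_per_class = config$points_per_class,
      noise_sd = config$noise_sd,
      class_separation = config$class_separation, seed = config$seed)),
    wesad = load_wesad_chest(config$path),
    swell = load_swell(config$path, side = config$image_side)))
  say("  %d rows x %d channels", nrow(cm$values), ncol(cm$values))

  window <- min(config$window_size,
                min(table(cm$labels)))
  if (window < config$window_size) {
    say("  window reduced to %d (shortest class block)", window)
  }
  grouped <- stage("preprocess", preprocess_channels(
    cm, window_size = window,
    per_block = config$per_block_normalization))

  stack <- stage("encode", encode_dataset(grouped,
                                          method = config$gaf_method))
  say("  %d images of side %d", dim(stack$images)[1], stack$side)

  sp <- stage("split", split_train_test(
    stack, test_fraction = config$test_fraction,
    seed = config$seed + 1L, temporal = config$temporal_split))
  say("  train %d / test %d", length(sp$train$labels),
      length(sp$test$labels))

  model <- stage("train", gaf_cnn(
    sp$train, epochs = config$epochs, batch_size = config$batch_size,
    learning_rate = config$learning_rate, seed = config$seed + 2L,
    verbose = if (verbose) max(1L, config$epochs %/% 10L) else 0L))

  report <- stage("evaluate", evaluate_model(model, sp$test))
  if (is.null(class_names)) {
    class_names <- as.character(model$classes)
  }
  tab <- report_tables(report, class_names)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    snap <- config
    class(snap) <- NULL
    yaml::write_yaml(snap, file.path(config$out_dir, "config.yaml"))
    utils::write.csv(model$history,
                     file.path(config$out_dir, "history.csv"),
                     row.names = FALSE)
    save_gaf_cnn(model, file.path(config$out_dir, "model.rds"))
    report_tables(report, class_names,
                  path = file.path(config$out_dir, "report.csv"))
    utils::write.csv(as.data.frame(report$confusion),
                     file.path(config$out_dir, "confusion.csv"),
                     row.names = FALSE)
    plot_confusion(report, file.path(config$out_dir, "confusion.png"),
                   class_names = class_names)
    say("[artifacts] written to %s", config$out_dir)
  }

  list(report = report, model = model, history = model$history,
       config = config, table = tab)
}
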