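#' Configuration for the synthetic multichannel generator
#'
#' Describes a class-separable multichannel stream with the structural
#' properties the stress pipeline assumes: one integer label per time point,
#' contiguous per-class blocks, and class-dependent cross-channel profiles.
#'
#' Class `k` elevates the channels with `(channel - 1) %% n_classes == k` by
#' `class_separation` above a common per-channel baseline (this fixes the
#' class-conditional channel means `class_separation` apart). Every channel
#' additionally carries a zero-mean low-frequency sinusoid with a
#' class-specific temporal frequency (k full cycles per block) and a
#' channel phase step proportional to the class index, plus i.i.d.
#' Gaussian noise. The phase step makes each class a distinct *spatial*
#' frequency across the channel axis at every time point -- a signature
#' that survives both quantile normalization (a monotone map per channel)
#' and the min-max rescaling of the row-wise image encoding, which jointly
#' erase constant offsets. The sinusoid amplitude is
#' `drift_amplitude * class_separation`, so `class_separation = 0` yields
#' pure noise (chance-level classes) and `noise_sd = 0` a deterministic
#' stream. Separability requires `n_channels >= n_classes`.
#'
#' @param n_classes Number of classes (contiguous label blocks), >= 2.
#' @param n_channels Number of channels per time point, >= 3.
#' @param points_per_class Rows generated per class block.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param class_separation Offset (in signal units) between the
#'   class-conditional channel means of a class's own channels and the rest.
#' @param drift_amplitude Amplitude of the per-class sinusoidal drift,
#'   relative to `class_separation`.
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#'
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_classes = 4L, n_channels = 8L,
                             points_per_class = 10000L,
                             noise_sd = 0.3, class_separation = 3,
                             drift_amplitude = 0.5, seed = 1L) {
  cfg <- list(
    n_classes = as.integer(n_classes),
    n_channels = as.integer(n_channels),
    points_per_class = as.integer(points_per_class),
    noise_sd = as.numeric(noise_sd),
    class_separation = as.numeric(class_separation),
    drift_amplitude = as.numeric(drift_amplitude),
    seed = as.integer(seed)
  )
  if (cfg$n_classes < 2L) {
    stop("`n_classes` must be >= 2", call. = FALSE)
  }
  if (cfg$n_channels < 3L) {
    stop("`n_channels` must be >= 3", call. = FALSE)
  }
  if (cfg$points_per_class < 1L) {
    stop("`points_per_class` must be positive", call. = FALSE)
  }
  if (cfg$noise_sd < 0 || cfg$class_separation < 0) {
    stop("`noise_sd` and `class_separation` must be nonnegative",
         call. = FALSE)
  }
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic class-separable multichannel stream
#'
#' Emulates the structure of chest-worn wearable recordings (several slowly
#' varying physiological channels with a per-time-point stress label):
#' per-channel baseline + class-specific channel elevation + class-frequency
#' sinusoidal drift + Gaussian noise, in contiguous per-class label blocks.
#' Not a physiological waveform simulator -- no ECG/PPG morphology, no
#' sampling-rate or missing-data effects.
#'
#' @param config A [synthetic_config()].
#' @return A [channel_matrix()] with `n_classes * points_per_class` rows,
#'   `n_channels` columns and labels `0..n_classes-1` in contiguous blocks.
#' @examples
#' cm <- generate_synthetic(synthetic_config(points_per_class = 100))
#' table(cm$labels)
#' @export
generate_synthetic <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    config <- do.call(synthetic_config, as.list(config))
  }
  K <- config$n_classes
  C <- config$n_channels
  n <- config$points_per_class
  set.seed(config$seed)

  baseline <- (seq_len(C) - 1) / C          # mild fixed per-channel offsets
  t_idx <- seq_len(n) - 1
  blocks <- vector("list", K)
  for (k in seq_len(K)) {
    own <- ((seq_len(C) - 1) %% K) == (k - 1)
    mu <- baseline + config$class_separation * own
    # integer cycles per block => exactly zero mean drift per channel;
    # channel phase step 2*pi*k/C encodes the class as a spatial frequency
    phase <- 2 * pi * k * (seq_len(C) - 1) / C
    drift <- config$drift_amplitude * config$class_separation *
      sin(outer(2 * pi * k * t_idx / n, rep(1, C)) +
            matrix(phase, n, C, byrow = TRUE))
    noise <- matrix(stats::rnorm(n * C, sd = config$noise_sd), n, C)
    blocks[[k]] <- matrix(mu, n, C, byrow = TRUE) + drift + noise
  }
  values <- do.call(rbind, blocks)
  labels <- rep(seq_len(K) - 1L, each = n)
  channel_matrix(values, labels)
}

#' Write a channel matrix to CSV
#'
#' One row per time point: the channel columns followed by an integer
#' `label` column, so synthetic data round-trips through [load_swell()].
#'
#' @param cm A [channel_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_channels_csv <- function(cm, path) {
  stopifnot(inherits(cm, "channel_matrix"))
  df <- as.data.frame(cm$values)
  df$label <- cm$labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
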