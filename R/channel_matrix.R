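#' Multichannel time-series container
#'
#' A `channel_matrix` holds a multichannel biosignal stream as a numeric
#' matrix (rows = time points, columns = channels) together with an aligned
#' integer label vector, one label per time point. All loaders and the
#' synthetic generator produce this container; the preprocessing stage
#' consumes it.
#'
#' @param values Numeric matrix, rows are time points and columns channels.
#' @param labels Integer vector of per-row class labels (0-based codes as
#'   used by stress-study protocols, e.g. 0..3).
#' @param channel_names Optional character vector of channel names; defaults
#'   to the column names of `values` or `ch1..chC`.
#'
#' @return An object of class `channel_matrix`: a list with elements
#'   `values`, `labels` and `channel_names`.
#' @examples
#' cm <- channel_matrix(matrix(rnorm(20), 10, 2), labels = rep(0:1, each = 5))
#' cm
#' @export
channel_matrix <- function(values, labels, channel_names = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(values)) {
    stop("`values` contains missing values; loaders must drop or impute ",
         "incomplete rows before constructing a channel_matrix",
         call. = FALSE)
  }
  labels <- as.integer(labels)
  if (length(labels) != nrow(values)) {
    stop("`labels` must have one entry per row of `values` (",
         length(labels), " labels for ", nrow(values), " rows)",
         call. = FALSE)
  }
  if (anyNA(labels)) stop("`labels` contains missing values", call. = FALSE)
  if (is.null(channel_names)) {
    channel_names <- colnames(values)
    if (is.null(channel_names)) {
      channel_names <- paste0("ch", seq_len(ncol(values)))
    }
  }
  if (length(channel_names) != ncol(values)) {
    stop("`channel_names` must have one entry per column", call. = FALSE)
  }
  colnames(values) <- channel_names
  structure(
    list(values = values, labels = labels, channel_names = channel_names),
    class = "channel_matrix"
  )
}

#' @export
print.channel_matrix <- function(x, ...) {
  tab <- table(x$labels)
  cat("<channel_matrix> ", nrow(x$values), " time points x ",
      ncol(x$values), " channels\n", sep = "")
  cat("  channels: ", paste(x$channel_names, collapse = ", "), "\n", sep = "")
  cat("  labels:   ", paste(sprintf("%s (n=%d)", names(tab), tab),
                            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.channel_matrix <- function(x) dim(x$values)
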