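#' Group a channel matrix by class label
#'
#' Partitions the rows of a [channel_matrix()] into one matrix per label,
#' preserving the original temporal order within each block.
#'
#' @param data A [channel_matrix()].
#' @return A named list of numeric matrices, one per label in ascending
#'   label order; names are the label values.
#' @examples
#' cm <- channel_matrix(matrix(1:8, 4, 2), labels = c(0, 1, 0, 1))
#' group_by_label(cm)
#' @export
group_by_label <- function(data) {
  stopifnot(inherits(data, "channel_matrix"))
  if (length(data$labels) == 0L) {
    stop("channel matrix has no rows", call. = FALSE)
  }
  labs <- sort(unique(data$labels))
  out <- lapply(labs, function(l) {
    data$values[data$labels == l, , drop = FALSE]
  })
  names(out) <- labs
  out
}

#' Take the trailing window of each class block
#'
#' Truncates every per-label block to its final `n` rows, the fixed-size
#' window the classifier is trained on (10,000 points per stress level for
#' the full-scale wearable runs).
#'
#' @param blocks Named list of per-label matrices, as from
#'   [group_by_label()].
#' @param n Window size; every block must have at least `n` rows.
#' @return A `grouped_set`: list with `blocks` (each exactly `n` rows,
#'   temporal order preserved) and `window_size`.
#' @export
take_last_n <- function(blocks, n) {
  n <- as.integer(n)
  stopifnot(is.list(blocks), length(blocks) >= 1L, n >= 1L)
  short <- names(blocks)[vapply(blocks, nrow, 0L) < n]
  if (length(short)) {
    stop("class block(s) ", paste(short, collapse = ", "), " have fewer ",
         "than ", n, " rows; cannot take the trailing window", call. = FALSE)
  }
  out <- lapply(blocks, function(b) {
    b[seq.int(nrow(b) - n + 1L, nrow(b)), , drop = FALSE]
  })
  structure(list(blocks = out, window_size = n), class = "grouped_set")
}

#' @export
print.grouped_set <- function(x, ...) {
  cat("<grouped_set> ", length(x$blocks), " class blocks x ",
      x$window_size, " rows (", ncol(x$blocks[[1]]), " channels)\n",
      sep = "")
  invisible(x)
}

#' Quantile normalization
#'
#' Forces every column of a matrix to share an identical value
#' distribution: each column is sorted, the mean across columns is taken at
#' each sorted rank (the "mean quantile"), and each column's rank-r value is
#' replaced by the rank-r mean quantile. Within-column rank order is
#' preserved, and on tie-free input the operation is idempotent. Tied
#' input values receive the mean of the mean-quantiles over their tied
#' ranks, which keeps the map well defined; collapsing ties means the
#' output columns of a tied input need not share exactly identical
#' multisets, so exact idempotence holds only without ties.
#'
#' @param mat Numeric matrix (rows = samples, columns = channels/features),
#'   no missing values.
#' @return Matrix of the same shape; every column holds the same multiset
#'   of values.
#' @examples
#' quantile_normalize(cbind(A = c(3, 1, 2), B = c(6, 4, 5)))
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (!is.numeric(mat)) stop("`mat` must be numeric", call. = FALSE)
  if (anyNA(mat)) {
    stop("`mat` contains missing values; drop or impute before ",
         "normalization", call. = FALSE)
  }
  if (ncol(mat) == 1L) return(mat)
  mean_q <- rowMeans(apply(mat, 2L, sort))
  out <- mat
  for (j in seq_len(ncol(mat))) {
    r <- rank(mat[, j], ties.method = "min")
    # tie group spanning ranks r..r+t-1 gets the mean of those mean-quantiles
    runs <- tabulate(r, nbins = nrow(mat))
    grp_val <- vapply(which(runs > 0L), function(s) {
      mean(mean_q[seq.int(s, s + runs[s] - 1L)])
    }, 0)
    names(grp_val) <- which(runs > 0L)
    out[, j] <- grp_val[as.character(r)]
  }
  dimnames(out) <- dimnames(mat)
  out
}

#' Group, window and normalize a channel matrix
#'
#' Convenience wrapper chaining [group_by_label()], [take_last_n()] and
#' [quantile_normalize()]: the narrative preprocessing order of the
#' pipeline. Normalization is applied within each class block by default;
#' set `per_block = FALSE` to quantile-normalize the stacked windows as one
#' matrix instead.
#'
#' @param data A [channel_matrix()].
#' @param window_size Trailing rows kept per class (default 10,000).
#' @param per_block Normalize each class block independently (default) or
#'   the whole windowed matrix at once.
#' @return A `grouped_set` of normalized blocks.
#' @export
preprocess_channels <- function(data, window_size = 10000L,
                                per_block = TRUE) {
  gs <- take_last_n(group_by_label(data), window_size)
  if (per_block) {
    gs$blocks <- lapply(gs$blocks, quantile_normalize)
  } else {
    nm <- names(gs$blocks)
    stacked <- quantile_normalize(do.call(rbind, gs$blocks))
    idx <- rep(seq_along(gs$blocks), each = gs$window_size)
    gs$blocks <- lapply(seq_along(nm), function(k) {
      stacked[idx == k, , drop = FALSE]
    })
    names(gs$blocks) <- nm
  }
  gs
}
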