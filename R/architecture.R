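#' Parameter count for one layer
#'
#' Counting conventions match the standard framework summaries: a
#' convolution holds `kh * kw * c_in * c_out` weights plus `c_out` biases;
#' batch normalization holds 4 values per channel (scale, shift, moving
#' mean, moving variance -- the moving statistics are counted even though
#' they are not trained); a dense layer holds `n_in * n_out + n_out`;
#' pooling and flatten layers hold nothing.
#'
#' @param kind One of `"conv2d"`, `"batch_norm"`, `"max_pool"`,
#'   `"flatten"`, `"dense"`.
#' @param input_channels Input channel count (conv/batch_norm) or input
#'   width (dense).
#' @param output_channels Output channel count (conv) or width (dense).
#' @param kernel Kernel side for convolutions (default 3).
#' @return Nonnegative integer parameter count.
#' @examples
#' count_parameters("conv2d", 1, 64)    # 640
#' count_parameters("dense", 64, 6)     # 390
#' @export
count_parameters <- function(kind, input_channels = NULL,
                             output_channels = NULL, kernel = 3L) {
  kind <- match.arg(kind,
                    c("conv2d", "batch_norm", "max_pool", "flatten", "dense"))
  need <- function(x, what) {
    if (is.null(x) || is.na(x)) {
      stop("cannot count parameters for a ", kind, " layer with an ",
           "unresolved ", what, call. = FALSE)
    }
    as.integer(x)
  }
  switch(kind,
    conv2d = {
      cin <- need(input_channels, "input channel count")
      cout <- need(output_channels, "output channel count")
      kernel * kernel * cin * cout + cout
    },
    batch_norm = 4L * need(input_channels, "channel count"),
    dense = {
      nin <- need(input_channels, "input width")
      nout <- need(output_channels, "output width")
      nin * nout + nout
    },
    max_pool = 0L,
    flatten = 0L
  )
}

#' Build the small-CNN architecture specification
#'
#' The fixed layer sequence used throughout:
#' conv(64, 3x3, ReLU) -> BN -> conv(64, 3x3, ReLU) -> BN ->
#' conv(64, 3x3, ReLU) -> BN -> max-pool(2x2) -> flatten ->
#' dense(6, linear) -> dense(n_classes, softmax).
#' Convolutions are valid (unpadded), so each one shrinks the spatial side
#' by 2; an input side of at least 8 is required or the three convolutions
#' plus 2x2 pooling collapse the spatial extent to nothing. For the 8x8
#' input the spatial sizes run 8 -> 6 -> 4 -> 2 -> 1.
#'
#' @param input_side Side of the square input image (>= 8); equals the
#'   channel count of the encoded data.
#' @param n_classes Output width of the softmax layer (4 for the four-level
#'   chest-device protocol, 3 for the three-level office-stress labels).
#' @return An `architecture_spec`: a data frame with columns `layer`,
#'   `kind`, `activation`, `out_h`, `out_w`, `out_c`, `params`, plus
#'   attributes `input_side` and `n_classes`.
#' @examples
#' build_architecture(8, 4)
#' @export
build_architecture <- function(input_side = 8L, n_classes = 4L) {
  input_side <- as.integer(input_side)
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stop("`n_classes` must be >= 2", call. = FALSE)
  if (input_side < 8L) {
    stop("input side ", input_side, " is too small: three valid 3x3 ",
         "convolutions reduce it to ", input_side - 6L, " and the 2x2 ",
         "max-pool needs at least a 2x2 map; the minimum side is 8",
         call. = FALSE)
  }
  s <- input_side
  filters <- 64L
  dense1 <- 6L

  rows <- list()
  add <- function(layer, kind, act, h, w, c, params) {
    rows[[length(rows) + 1L]] <<- data.frame(
      layer = layer, kind = kind, activation = act,
      out_h = h, out_w = w, out_c = c, params = params,
      stringsAsFactors = FALSE)
  }
  cin <- 1L
  for (i in 1:3) {
    s <- s - 2L
    add(paste0("conv2d_", i), "conv2d", "relu", s, s, filters,
        count_parameters("conv2d", cin, filters))
    add(paste0("batch_norm_", i), "batch_norm", "none", s, s, filters,
        count_parameters("batch_norm", filters))
    cin <- filters
  }
  s <- s %/% 2L
  add("max_pool", "max_pool", "none", s, s, filters, 0L)
  flat <- s * s * filters
  add("flatten", "flatten", "none", NA_integer_, NA_integer_, flat, 0L)
  add("dense_1", "dense", "linear", NA_integer_, NA_integer_, dense1,
      count_parameters("dense", flat, dense1))
  add("output_dense", "dense", "softmax", NA_integer_, NA_integer_,
      n_classes, count_parameters("dense", dense1, n_classes))

  spec <- do.call(rbind, rows)
  attr(spec, "input_side") <- input_side
  attr(spec, "n_classes") <- n_classes
  class(spec) <- c("architecture_spec", "data.frame")
  spec
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat("Small-CNN architecture (input ", attr(x, "input_side"), "x",
      attr(x, "input_side"), "x1, ", attr(x, "n_classes"),
      " classes)\n", sep = "")
  df <- as.data.frame(x)
  df$output_shape <- ifelse(
    is.na(df$out_h),
    sprintf("(None,%d)", df$out_c),
    sprintf("(None,%d,%d,%d)", df$out_h, df$out_w, df$out_c))
  out <- df[, c("layer", "activation", "output_shape", "params")]
  out$params <- format(out$params, big.mark = ",", trim = TRUE)
  print(out, row.names = FALSE)
  cat("Total parameters:", format(sum(df$params), big.mark = ","), "\n")
  invisible(x)
}

#' Print and verify the reference architecture table
#'
#' Builds the (side 8, 4-class) model, prints its layer table, and checks
#' every per-layer parameter count against the reference values
#' 640, 256, 36928, 256, 36928, 256, 0, 0, 390, 28. Used as a self-check
#' entry point; returns invisibly whether the check passed.
#'
#' @param input_side,n_classes Architecture variant to print; the parameter
#'   check is only asserted for the (8, 4) reference variant.
#' @return Logical: `TRUE` if counts match (always `TRUE` for non-reference
#'   variants, which are printed without assertion), invisibly.
#' @export
verify_architecture <- function(input_side = 8L, n_classes = 4L) {
  spec <- build_architecture(input_side, n_classes)
  print(spec)
  ok <- TRUE
  if (input_side == 8L && n_classes == 4L) {
    ref <- c(640L, 256L, 36928L, 256L, 36928L, 256L, 0L, 0L, 390L, 28L)
    ok <- identical(as.integer(spec$params), ref)
    if (!ok) {
      warning("parameter counts deviate from the reference table",
              call. = FALSE)
    }
  }
  invisible(ok)
}
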