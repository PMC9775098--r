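#' Min-max rescale a vector onto [-1, 1]
#'
#' The polar-coordinate encoding needs every value inside the arccos
#' domain, so each sample (one row across channels) is affinely rescaled to
#' span exactly \[-1, 1\]. Constant rows, which carry no cross-channel
#' shape, map to the all-zeros vector by convention.
#'
#' @param row Numeric vector.
#' @return Numeric vector of the same length with values in \[-1, 1\].
#' @examples
#' rescale_to_unit(c(0, 5, 10))
#' @export
rescale_to_unit <- function(row) {
  row <- as.numeric(row)
  if (length(row) < 1L) stop("`row` must be nonempty", call. = FALSE)
  rng <- range(row)
  if (rng[1] == rng[2]) return(rep(0, length(row)))
  2 * (row - rng[1]) / (rng[2] - rng[1]) - 1
}

#' Encode one sample as a Gramian Angular Field image
#'
#' Rescales the row to \[-1, 1\], maps each value to an angle
#' `phi = arccos(x)`, and fills a square matrix with pairwise angular sums
#' `cos(phi_i + phi_j)` (the summation form, GASF) or angular differences
#' `sin(phi_i - phi_j)` (GADF). The summation form is symmetric, bounded in
#' \[-1, 1\], and has diagonal `2 x^2 - 1`; algebraically it equals
#' `x_i x_j - sqrt(1 - x_i^2) sqrt(1 - x_j^2)`. The sample's ordering
#' (channel order here) is encoded into the geometry of the matrix:
#' position (i, j) relates value i to value j.
#'
#' @param row Numeric vector of length equal to the image side.
#' @param side Expected image side; defaults to `length(row)`. A mismatch
#'   is an error so corrupt inputs fail loudly.
#' @param method `"summation"` (GASF, default) or `"difference"` (GADF).
#' @return A `gaf_image`: the side x side matrix with attribute `method`.
#' @examples
#' gaf_encode_row(c(0, 0.5, 1))
#' @export
gaf_encode_row <- function(row, side = length(row),
                           method = c("summation", "difference")) {
  method <- match.arg(method)
  row <- as.numeric(row)
  if (length(row) != side) {
    stop("row length ", length(row), " does not match the configured ",
         "image side ", side, call. = FALSE)
  }
  x <- rescale_to_unit(row)
  x <- pmin(1, pmax(-1, x))          # absorb floating-point overshoot
  phi <- acos(x)
  m <- if (method == "summation") {
    cos(outer(phi, phi, `+`))
  } else {
    sin(outer(phi, phi, `-`))
  }
  structure(m, class = c("gaf_image", "matrix", "array"), method = method)
}

#' @export
print.gaf_image <- function(x, ...) {
  cat("<gaf_image> ", nrow(x), "x", ncol(x), " (",
      attr(x, "method"), " form)\n", sep = "")
  print(unclass(x)[seq_len(min(4L, nrow(x))), seq_len(min(4L, ncol(x)))])
  if (nrow(x) > 4L) cat("...\n")
  invisible(x)
}

#' Encode a grouped, normalized dataset as a labeled image stack
#'
#' Encodes every row of every class block as one GAF image. Output order is
#' the concatenation of blocks in ascending label order with within-block
#' temporal order preserved.
#'
#' @param grouped A `grouped_set` from [take_last_n()] /
#'   [preprocess_channels()].
#' @param method GAF variant passed to [gaf_encode_row()].
#' @return A `gaf_stack`: list with `images` (array n x side x side) and
#'   `labels` (integer vector).
#' @export
encode_dataset <- function(grouped, method = c("summation", "difference")) {
  method <- match.arg(method)
  stopifnot(inherits(grouped, "grouped_set"))
  sides <- vapply(grouped$blocks, ncol, 0L)
  if (length(unique(sides)) != 1L) {
    stop("blocks disagree on channel count", call. = FALSE)
  }
  side <- sides[[1]]
  n <- sum(vapply(grouped$blocks, nrow, 0L))
  images <- array(NA_real_, dim = c(n, side, side))
  labels <- integer(n)
  i <- 0L
  for (lab in names(grouped$blocks)) {
    b <- grouped$blocks[[lab]]
    for (r in seq_len(nrow(b))) {
      i <- i + 1L
      images[i, , ] <- gaf_encode_row(b[r, ], side = side, method = method)
      labels[i] <- as.integer(lab)
    }
  }
  structure(list(images = images, labels = labels, side = side,
                 method = method),
            class = "gaf_stack")
}

#' @export
print.gaf_stack <- function(x, ...) {
  cat("<gaf_stack> ", dim(x$images)[1], " images of side ", x$side,
      " (", x$method, " form), labels: ",
      paste(sort(unique(x$labels)), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Render a GAF image to a PNG raster
#'
#' Visualization only -- the classifier always consumes the numeric matrix.
#' Values in \[-1, 1\] are mapped through the named palette; the written
#' pixel grid equals the matrix dimensions (no upscaling).
#'
#' @param image A `gaf_image` or plain numeric matrix.
#' @param path Output PNG path.
#' @param colormap `"rainbow"` or any palette name accepted by
#'   [grDevices::hcl.colors()] (e.g. `"viridis"`).
#' @param n_colors Palette resolution.
#' @return `path`, invisibly.
#' @export
render_gaf <- function(image, path, colormap = "rainbow",
                       n_colors = 256L) {
  m <- unclass(image)
  stopifnot(is.matrix(m), is.numeric(m))
  pal <- if (identical(colormap, "rainbow")) {
    grDevices::rainbow(n_colors)
  } else {
    if (!tolower(colormap) %in% tolower(grDevices::hcl.pals())) {
      stop("unknown colormap: ", colormap, call. = FALSE)
    }
    grDevices::hcl.colors(n_colors, palette = colormap)
  }
  idx <- pmin(n_colors, pmax(1L, 1L + floor((m + 1) / 2 * n_colors)))
  rgb <- grDevices::col2rgb(pal[idx]) / 255
  ras <- array(0, dim = c(nrow(m), ncol(m), 3L))
  for (ch in 1:3) ras[, , ch] <- matrix(rgb[ch, ], nrow(m), ncol(m))
  png::writePNG(ras, target = path)
  invisible(path)
}
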