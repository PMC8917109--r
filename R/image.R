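#' Single- or multi-channel intensity image
#'
#' Lightweight container used throughout the pipeline: a numeric matrix
#' (single channel) or an `H x W x 3` array (RGB) with intensities in
#' `[0, 1]`, plus an optional physical pixel size and a channel tag.
#' Pixel coordinates are 1-based `(row, col)` with the origin at the
#' top-left corner.
#'
#' @param pixels numeric matrix (`H x W`) or array (`H x W x 3`).
#' @param channel_tag one of `"red"`, `"green"`, `"blue"`, `"gray"`,
#'   `"rgb"`.
#' @param pixel_size optional physical pixel size in micrometres per
#'   pixel (positive scalar).
#' @param constant_input logical; set when the source raster was constant
#'   and min-max normalization degenerated to an all-zero image.
#' @return an object of class `intensity_image`.
#' @export
intensity_image <- function(pixels, channel_tag = "gray", pixel_size = NULL,
                            constant_input = FALSE) {
  if (!is.numeric(pixels)) stop("pixels must be numeric")
  nd <- length(dim(pixels))
  if (nd == 0L && is.matrix(pixels)) nd <- 2L
  if (!(nd %in% c(2L, 3L))) stop("pixels must be a matrix or an H x W x 3 array")
  if (nd == 3L && dim(pixels)[3] != 3L) stop("multi-channel images must have 3 channels")
  channel_tag <- match.arg(channel_tag, c("red", "green", "blue", "gray", "rgb"))
  if (!is.null(pixel_size)) {
    stopifnot(is.numeric(pixel_size), length(pixel_size) == 1L, pixel_size > 0)
  }
  if (dim(pixels)[1] < 3L || dim(pixels)[2] < 3L)
    stop("image must be at least 3 x 3 pixels")
  structure(
    list(pixels = pixels, channel_tag = channel_tag, pixel_size = pixel_size,
         constant_input = isTRUE(constant_input)),
    class = "intensity_image"
  )
}

#' @export
print.intensity_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("intensity_image: %d x %d (%s)%s%s\n", d[1], d[2], x$channel_tag,
              if (!is.null(x$pixel_size)) sprintf(", %.4g um/px", x$pixel_size) else "",
              if (x$constant_input) ", constant input" else ""))
  invisible(x)
}

#' @export
dim.intensity_image <- function(x) dim(x$pixels)

as_pixels <- function(img) {
  if (inherits(img, "intensity_image")) img$pixels else img
}

#' Min-max normalize a raster to [0, 1]
#'
#' Applies a single affine map across all channels jointly (one global
#' minimum and maximum per image), so relative channel intensities are
#' preserved. A constant raster maps to all zeros and raises a warning
#' (flagged in the result rather than failing, so batch runs survive
#' blank acquisitions).
#'
#' @param raw numeric matrix or `H x W x 3` array with arbitrary range
#'   (e.g. 0..255 integers).
#' @param pixel_size optional micrometres per pixel, carried through.
#' @return an [intensity_image] with values in `[0, 1]`.
#' @export
normalize_image <- function(raw, pixel_size = NULL) {
  px <- as_pixels(raw)
  if (!is.numeric(px) || length(px) == 0L) stop("raster must be non-empty numeric")
  if (!any(is.finite(px))) stop("raster has no finite pixels")
  lo <- min(px, na.rm = TRUE)
  hi <- max(px, na.rm = TRUE)
  tag <- if (length(dim(px)) == 3L) "rgb" else "gray"
  if (hi == lo) {
    warning("constant image: normalization degenerate, returning zeros")
    out <- px
    out[] <- 0
    return(intensity_image(out, tag, pixel_size, constant_input = TRUE))
  }
  intensity_image((px - lo) / (hi - lo), tag, pixel_size)
}

#' Extract the red or green channel from an RGB image
#'
#' The spectral projection of typical immunofluorescence vessel markers
#' falls on the red and green channels (e.g. CD31 / alpha-SMA secondary
#' antibodies), so channel choice is explicit and never inferred.
#'
#' @param img an RGB [intensity_image] (or `H x W x 3` array).
#' @param channel `"red"` or `"green"`.
#' @return a single-channel [intensity_image] tagged with the channel.
#' @export
extract_channel <- function(img, channel = c("red", "green")) {
  channel <- match.arg(channel)
  px <- as_pixels(img)
  if (length(dim(px)) != 3L)
    stop(sprintf("cannot extract '%s' channel: image is single-channel", channel))
  idx <- c(red = 1L, green = 2L)[[channel]]
  ps <- if (inherits(img, "intensity_image")) img$pixel_size else NULL
  ci <- if (inherits(img, "intensity_image")) img$constant_input else FALSE
  intensity_image(px[, , idx], channel, ps, constant_input = ci)
}

pad_replicate <- function(m, k = 1L) {
  ri <- c(rep(1L, k), seq_len(nrow(m)), rep(nrow(m), k))
  ci <- c(rep(1L, k), seq_len(ncol(m)), rep(ncol(m), k))
  m[ri, ci, drop = FALSE]
}

#' 3x3 mean filter with replicate padding
#'
#' Each pixel is replaced by the arithmetic mean of its 3x3
#' neighborhood; image borders are handled by replicating the edge
#' rows/columns, so constant images are fixed points. This is the
#' smoothing step applied to the selected channel to raise the
#' signal-to-noise ratio before thresholding.
#'
#' @param img single-channel [intensity_image] or matrix, at least 3x3.
#' @return smoothed image of the same class and size.
#' @export
smooth_mean3x3 <- function(img) {
  px <- as_pixels(img)
  if (length(dim(px)) != 2L) stop("smoothing expects a single-channel image")
  if (nrow(px) < 3L || ncol(px) < 3L) stop("image must be at least 3 x 3")
  p <- pad_replicate(px, 1L)
  h <- nrow(px); w <- ncol(px)
  acc <- matrix(0, h, w)
  for (dr in 0:2) for (dc in 0:2)
    acc <- acc + p[dr + seq_len(h), dc + seq_len(w)]
  out <- acc / 9
  if (inherits(img, "intensity_image"))
    intensity_image(out, img$channel_tag, img$pixel_size,
                    constant_input = img$constant_input)
  else out
}

#' Read a raster image file as an RGB or grayscale array
#'
#' Supports PNG and TIFF via the corresponding R packages, and JPEG when
#' the \pkg{jpeg} package is available. Values are returned in `[0, 1]`
#' (as scaled by bit depth); an alpha channel, if present, is dropped.
#'
#' @param path file path; format chosen by extension.
#' @return numeric matrix (grayscale file) or `H x W x 3` array.
#' @export
read_vessel_image <- function(path) {
  if (!file.exists(path)) stop("input image does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("reading JPEG requires the 'jpeg' package")
      jpeg::readJPEG(path)
    },
    stop("unsupported image format: .", ext)
  )
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] >= 3L) px <- px[, , 1:3, drop = FALSE]
    else px <- px[, , 1L]  # gray+alpha
  }
  px
}
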