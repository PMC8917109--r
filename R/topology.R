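gaussian_kernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# 2-D convolution with a separable Gaussian; out-of-bounds contributions
# are dropped (handled by the caller's border renormalization)
conv2_gauss <- function(m, sigma) {
  k <- gaussian_kernel1d(sigma)
  r <- (length(k) - 1L) / 2L
  h <- nrow(m); w <- ncol(m)
  tmp <- matrix(0, h, w)
  for (i in seq_along(k)) {
    dr <- i - r - 1L
    if (abs(dr) >= h) next
    rs <- max(1L, 1L + dr):min(h, h + dr)
    tmp[rs, ] <- tmp[rs, ] + k[i] * m[rs - dr, , drop = FALSE]
  }
  out <- matrix(0, h, w)
  for (i in seq_along(k)) {
    dc <- i - r - 1L
    if (abs(dc) >= w) next
    cs <- max(1L, 1L + dc):min(w, w + dc)
    out[, cs] <- out[, cs] + k[i] * tmp[, cs - dc, drop = FALSE]
  }
  out
}

#' Spatial density map of vessel centroids
#'
#' Bins vessel centroids from one or more congruent sections onto a
#' square grid, sums counts across sections, and applies
#' mass-conserving Gaussian smoothing: each centroid's unit mass is
#' redistributed with a kernel renormalized over the in-bounds grid
#' cells, so the smoothed grid total equals the centroid count exactly
#' (up to floating-point error). Sections are assumed pre-registered.
#'
#' @param centroid_sets a single `n x 2` matrix of `(row, col)`
#'   centroids, or a list of such matrices (one per section, all
#'   sharing the same source dimensions).
#' @param dims source image dimensions `c(height, width)` in pixels.
#' @param bin_size_px grid bin edge length in pixels (default 32).
#' @param smoothing_sigma_bins Gaussian sigma in bin units (default
#'   1.5; 0 disables smoothing).
#' @return object of class `density_map`: list with `grid` (smoothed),
#'   `raw` (binned counts), `bin_size_px`, `extent`, `n_sections`,
#'   `smoothing_sigma_bins`.
#' @export
build_density_map <- function(centroid_sets, dims, bin_size_px = 32L,
                              smoothing_sigma_bins = 1.5) {
  if (!is.list(centroid_sets)) centroid_sets <- list(centroid_sets)
  stopifnot(bin_size_px >= 1L, smoothing_sigma_bins >= 0)
  gh <- ceiling(dims[1] / bin_size_px)
  gw <- ceiling(dims[2] / bin_size_px)
  raw <- matrix(0, gh, gw)
  for (cen in centroid_sets) {
    cen <- as.matrix(cen)
    if (nrow(cen) == 0L) next
    if (any(cen[, 1L] < 0.5 | cen[, 1L] > dims[1] + 0.5 |
            cen[, 2L] < 0.5 | cen[, 2L] > dims[2] + 0.5))
      stop("centroids outside the image extent")
    br <- pmin(pmax(ceiling(cen[, 1L] / bin_size_px), 1L), gh)
    bc <- pmin(pmax(ceiling(cen[, 2L] / bin_size_px), 1L), gw)
    for (k in seq_along(br)) raw[br[k], bc[k]] <- raw[br[k], bc[k]] + 1
  }
  if (smoothing_sigma_bins > 0 && sum(raw) > 0) {
    W <- conv2_gauss(matrix(1, gh, gw), smoothing_sigma_bins)
    grid <- conv2_gauss(raw / W, smoothing_sigma_bins)
  } else grid <- raw
  structure(list(grid = grid, raw = raw,
                 bin_size_px = as.integer(bin_size_px),
                 extent = dims[1:2], n_sections = length(centroid_sets),
                 smoothing_sigma_bins = smoothing_sigma_bins),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("density_map: %d x %d bins (%d px), %d section(s), %.4g centroids\n",
              nrow(x$grid), ncol(x$grid), x$bin_size_px, x$n_sections,
              sum(x$raw)))
  invisible(x)
}

#' Write a density-map grid as CSV
#' @param map a `density_map`.
#' @param path output file.
#' @export
write_density_csv <- function(map, path) {
  utils::write.table(map$grid, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Render a density map as a heatmap
#'
#' Draws the smoothed grid with a perceptually uniform palette
#' (viridis) in image orientation (origin top-left).
#'
#' @param map a `density_map`.
#' @param ... passed to [graphics::image()].
#' @export
plot_density_map <- function(map, ...) {
  g <- map$grid
  graphics::image(x = seq_len(ncol(g)), y = seq_len(nrow(g)),
                  z = t(g[rev(seq_len(nrow(g))), , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "column bin", ylab = "row bin",
                  useRaster = TRUE, ...)
  invisible(map)
}
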