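#' Morphometric descriptors of one region
#'
#' Computes the standard region-properties descriptors from raw and
#' central second moments, with each pixel treated as a unit square:
#' the normalized central covariance gets a `+1/12` per-pixel variance
#' correction, and the moment-equivalent ellipse axes are
#' `4 * sqrt(eigenvalue)` (the MATLAB `regionprops` convention).
#' Orientation is the angle in degrees, in `(-90, 90]`, between the
#' column (x) axis and the ellipse major axis, measured
#' counter-clockwise with the row axis pointing down (image
#' convention). Perimeter is the length of the traced outer boundary
#' contour through pixel centers (edge steps 1, diagonal steps
#' `sqrt(2)`); a single pixel has perimeter 0.
#'
#' @param pixels `n x 2` matrix of 1-based `(row, col)` pixel
#'   coordinates of one connected region.
#' @return one-row data frame with columns `area_px`, `centroid_row`,
#'   `centroid_col`, `major_axis_px`, `minor_axis_px`, `eccentricity`,
#'   `orientation_deg`, `equivalent_diameter_px`, `perimeter_px`.
#' @export
compute_descriptors <- function(pixels) {
  pixels <- as.matrix(pixels)
  n <- nrow(pixels)
  if (n < 1L) stop("region must contain at least one pixel")
  rows <- pixels[, 1L]; cols <- pixels[, 2L]
  rbar <- mean(rows); cbar <- mean(cols)
  # normalized central second moments with unit-square pixel correction;
  # x = columns, y = rows
  uxx <- mean((cols - cbar)^2) + 1 / 12
  uyy <- mean((rows - rbar)^2) + 1 / 12
  uxy <- mean((cols - cbar) * (rows - rbar))
  common <- sqrt((uxx - uyy)^2 + 4 * uxy^2)
  major <- 2 * sqrt(2) * sqrt(uxx + uyy + common)
  minor <- 2 * sqrt(2) * sqrt(uxx + uyy - common)
  ecc <- sqrt(1 - (minor / major)^2)
  # y is negated: image rows increase downward, orientation is reported
  # in conventional (y up) orientation
  orient <- if (common == 0) 0 else 0.5 * atan2(-2 * uxy, uxx - uyy) * 180 / pi
  if (orient <= -90) orient <- orient + 180

  r0 <- min(rows) - 1L; c0 <- min(cols) - 1L
  local <- matrix(FALSE, max(rows) - r0, max(cols) - c0)
  local[cbind(rows - r0, cols - c0)] <- TRUE
  per <- trace_perimeter(local)

  data.frame(
    area_px = n,
    centroid_row = rbar, centroid_col = cbar,
    major_axis_px = major, minor_axis_px = minor,
    eccentricity = ecc, orientation_deg = orient,
    equivalent_diameter_px = 2 * sqrt(n / pi),
    perimeter_px = per
  )
}

#' Descriptor table for all components of a set
#'
#' @param cs a `component_set` (e.g. the relabeled vessels).
#' @return data frame with one row per component, a leading `label`
#'   column and the [compute_descriptors()] columns.
#' @export
region_table <- function(cs) {
  n <- length(cs$pixel_lists)
  if (n == 0L) {
    tab <- compute_descriptors(cbind(1L, 1L))[0, ]
    return(cbind(data.frame(label = integer()), tab))
  }
  tab <- do.call(rbind, lapply(cs$pixel_lists, compute_descriptors))
  rownames(tab) <- NULL
  cbind(data.frame(label = seq_len(n)), tab)
}

#' Convert pixel descriptors to physical units
#'
#' Adds micrometre-scaled columns to a vessel descriptor table:
#' areas scale by `pixel_size^2`, lengths by `pixel_size`. Without a
#' pixel size the table is returned unchanged (pixel columns intact,
#' no physical columns).
#'
#' @param vessels data frame from [region_table()] (or one row from
#'   [compute_descriptors()]).
#' @param pixel_size micrometres per pixel (positive scalar), or `NULL`.
#' @return the table with `area_um2`, `perimeter_um`, `major_axis_um`,
#'   `minor_axis_um`, `equivalent_diameter_um` columns appended.
#' @export
to_physical_units <- function(vessels, pixel_size = NULL) {
  if (is.null(pixel_size)) return(vessels)
  stopifnot(is.numeric(pixel_size), length(pixel_size) == 1L, pixel_size > 0)
  vessels$area_um2 <- vessels$area_px * pixel_size^2
  vessels$perimeter_um <- vessels$perimeter_px * pixel_size
  vessels$major_axis_um <- vessels$major_axis_px * pixel_size
  vessels$minor_axis_um <- vessels$minor_axis_px * pixel_size
  vessels$equivalent_diameter_um <- vessels$equivalent_diameter_px * pixel_size
  vessels
}

fixed_width_hist <- function(x, width) {
  if (length(x) == 0L)
    return(list(breaks = numeric(), counts = integer()))
  breaks <- seq(0, width * ceiling(max(x) / width + 1e-9), by = width)
  if (length(breaks) < 2L) breaks <- c(0, width)
  counts <- as.integer(table(cut(x, breaks, include.lowest = TRUE, right = TRUE)))
  list(breaks = breaks, counts = counts)
}

#' Image-level vascular summary
#'
#' Aggregates a vessel table into the per-image outputs: vessel count,
#' vascular area fraction (vessel pixels over total pixels), vessel
#' density per square millimetre when the physical scale is known, and
#' fixed-width histograms of equivalent diameter and area.
#'
#' @param vessels data frame from [region_table()].
#' @param dims image dimensions `c(height, width)` in pixels.
#' @param pixel_size optional micrometres per pixel.
#' @param diameter_bin histogram bin width for equivalent diameter:
#'   micrometres when `pixel_size` is given (default 5), else pixels
#'   (default 10).
#' @return list of class `image_summary` with `vessel_count`,
#'   `vascular_area_fraction`, `vessels_per_mm2` (NA without scale),
#'   `diameter_histogram`, `area_histogram`.
#' @export
summarize_image <- function(vessels, dims, pixel_size = NULL,
                            diameter_bin = if (is.null(pixel_size)) 10 else 5) {
  total_px <- prod(dims[1:2])
  count <- nrow(vessels)
  frac <- if (count == 0L) 0 else sum(vessels$area_px) / total_px
  if (!is.null(pixel_size)) {
    area_mm2 <- total_px * (pixel_size * 1e-3)^2
    density <- count / area_mm2
    diam <- vessels$equivalent_diameter_px * pixel_size
    areas <- vessels$area_px * pixel_size^2
    area_bin <- 100  # um^2
  } else {
    density <- NA_real_
    diam <- vessels$equivalent_diameter_px
    areas <- vessels$area_px
    area_bin <- 100  # px
  }
  structure(list(
    vessel_count = count,
    vascular_area_fraction = frac,
    vessels_per_mm2 = density,
    diameter_histogram = fixed_width_hist(diam, diameter_bin),
    area_histogram = fixed_width_hist(areas, area_bin)
  ), class = "image_summary")
}

#' @export
print.image_summary <- function(x, ...) {
  cat(sprintf("image_summary: %d vessels, vascular area fraction %.4f%s\n",
              x$vessel_count, x$vascular_area_fraction,
              if (is.finite(x$vessels_per_mm2))
                sprintf(", %.1f vessels/mm^2", x$vessels_per_mm2) else ""))
  invisible(x)
}
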