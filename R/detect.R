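#' Detection parameters
#'
#' Bundles the tunable parameters of the vessel detection pipeline.
#'
#' @param channel stained channel to analyze: `"red"` or `"green"`.
#' @param threshold `"auto"` for Otsu's suggestion, or a manual
#'   intensity threshold in `[0, 1]`.
#' @param min_area_px minimum component area kept (pixels). Default 50,
#'   which excludes speckle noise at typical magnifications
#'   (~0.5 um/px).
#' @param max_area_px maximum component area kept. `NULL` (default)
#'   resolves at run time to 10 percent of the image pixel count,
#'   excluding section-wide staining artifacts.
#' @param lumen_fraction lumen rule fraction; a hollow region counts as
#'   a lumen when strictly larger than this fraction of the component
#'   area. Default exactly 0.125.
#' @param circle_radius_range integer circle radius search range in
#'   pixels for the Hough lumen recovery, default `c(5, 50)`.
#' @param circle_score_min Hough acceptance metric threshold, default
#'   0.3.
#' @return list of class `detection_params`.
#' @export
detection_params <- function(channel = c("red", "green"),
                             threshold = "auto",
                             min_area_px = 50L,
                             max_area_px = NULL,
                             lumen_fraction = 0.125,
                             circle_radius_range = c(5L, 50L),
                             circle_score_min = 0.3) {
  channel <- match.arg(channel)
  if (!(identical(threshold, "auto") ||
        (is.numeric(threshold) && length(threshold) == 1L &&
         threshold >= 0 && threshold <= 1)))
    stop("threshold must be \"auto\" or a number in [0, 1]")
  stopifnot(min_area_px >= 1,
            is.null(max_area_px) || max_area_px > min_area_px,
            lumen_fraction > 0, lumen_fraction < 1,
            length(circle_radius_range) == 2L,
            circle_radius_range[1] >= 1,
            circle_radius_range[2] > circle_radius_range[1],
            circle_score_min > 0, circle_score_min <= 1)
  structure(list(
    channel = channel, threshold = threshold,
    min_area_px = as.integer(min_area_px),
    max_area_px = if (!is.null(max_area_px)) as.integer(max_area_px),
    lumen_fraction = lumen_fraction,
    circle_radius_range = as.integer(circle_radius_range),
    circle_score_min = circle_score_min
  ), class = "detection_params")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Detect blood vessels in an RGB immunofluorescence image
#'
#' Runs the full detection pipeline: joint min-max normalization to
#' `[0, 1]`, channel selection, 3x3 mean filtering, Otsu (or manual)
#' thresholding, 8-connected component extraction, area filtering,
#' circular-Hough lumen recovery of small hollow vessels, morphological
#' closing with hole filling, relabeling, and per-vessel morphometry.
#' The result is a pure function of the image and parameters.
#'
#' @param image RGB raster (`H x W x 3` numeric array, any range), a
#'   single-channel matrix, or an [intensity_image].
#' @param params a [detection_params()] list.
#' @param pixel_size optional micrometres per pixel; adds physical-unit
#'   descriptor columns and per-mm2 density.
#' @return object of class `vessel_detection`: list with `vessels`
#'   (descriptor data frame, one row per vessel), `labels` (integer
#'   label matrix), `mask` (final binary mask), `threshold` (the T
#'   used), `params`, `summary` (an [summarize_image()] result),
#'   `dims`, and `constant_input`.
#' @export
detect_vessels <- function(image, params = detection_params(),
                           pixel_size = NULL) {
  stopifnot(inherits(params, "detection_params"))
  norm <- with_stage("normalize", {
    if (inherits(image, "intensity_image")) {
      if (!is.null(image$pixel_size) && is.null(pixel_size))
        pixel_size <- image$pixel_size
      image
    } else normalize_image(image, pixel_size)
  })
  chan <- with_stage("extract_channel", {
    if (length(dim(norm$pixels)) == 3L) extract_channel(norm, params$channel)
    else norm
  })
  sm <- with_stage("smooth", smooth_mean3x3(chan))
  T_used <- with_stage("threshold", {
    if (identical(params$threshold, "auto")) {
      if (norm$constant_input) 0 else suggest_threshold(sm)
    } else params$threshold
  })
  mask0 <- with_stage("binarize", binarize(sm, T_used))
  cs <- with_stage("connected_components", connected_components(mask0))
  max_area <- if (is.null(params$max_area_px))
    as.integer(0.1 * prod(dim(mask0))) else params$max_area_px
  filt <- with_stage("filter_by_area",
                     filter_by_area(cs, params$min_area_px, max_area))
  recovered <- with_stage("lumen_recovery",
                          recover_lumened_vessels(mask0, filt$removed_small, params))
  mask1 <- component_mask(filt$kept) | component_mask(recovered)
  mask2 <- with_stage("close_and_fill", close_and_fill(mask1))
  final <- with_stage("relabel", connected_components(mask2))
  vessels <- with_stage("morphometry", {
    tab <- region_table(final)
    to_physical_units(tab, pixel_size)
  })
  summ <- summarize_image(vessels, dim(mask2), pixel_size)
  structure(list(
    vessels = vessels, labels = final$labels, mask = mask2,
    threshold = T_used, params = params, summary = summ,
    dims = dim(mask2), pixel_size = pixel_size,
    constant_input = norm$constant_input
  ), class = "vessel_detection")
}

#' @export
print.vessel_detection <- function(x, ...) {
  cat(sprintf("vessel_detection: %d vessels in %d x %d image (T = %.4f, channel %s)\n",
              nrow(x$vessels), x$dims[1], x$dims[2], x$threshold,
              x$params$channel))
  cat(sprintf("  vascular area fraction: %.4f\n",
              x$summary$vascular_area_fraction))
  if (nrow(x$vessels) > 0) {
    cat(sprintf("  equivalent diameter (px): median %.1f, range %.1f-%.1f\n",
                stats::median(x$vessels$equivalent_diameter_px),
                min(x$vessels$equivalent_diameter_px),
                max(x$vessels$equivalent_diameter_px)))
  }
  invisible(x)
}

#' Detection centroids as a matrix
#' @param result a `vessel_detection`.
#' @return `n x 2` matrix of `(row, col)` centroids.
#' @export
detection_centroids <- function(result) {
  cbind(row = result$vessels$centroid_row, col = result$vessels$centroid_col)
}
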