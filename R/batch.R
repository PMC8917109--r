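draw_segment <- function(canvas, r0, c0, r1, c1, value = 1) {
  n <- max(2L, ceiling(max(abs(r1 - r0), abs(c1 - c0))) + 1L)
  rr <- round(seq(r0, r1, length.out = n))
  cc <- round(seq(c0, c1, length.out = n))
  ok <- rr >= 1 & rr <= dim(canvas)[1] & cc >= 1 & cc <= dim(canvas)[2]
  for (ch in seq_len(dim(canvas)[3]))
    canvas[cbind(rr[ok], cc[ok], ch)] <- value
  canvas
}

#' Overlay detected vessels on the source image
#'
#' Draws white outlines around each detected vessel and a white arrow
#' pointing at each centroid, mirroring the marker overlay of the
#' original workflow.
#'
#' @param image the analyzed raster (`H x W x 3` array or matrix, any
#'   range; re-normalized for display).
#' @param result a `vessel_detection`.
#' @return `H x W x 3` array in `[0, 1]`.
#' @export
overlay_image <- function(image, result) {
  px <- as_pixels(normalize_image(image))
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  edges <- mask_edges(result$mask)
  for (ch in 1:3) {
    sl <- px[, , ch]
    sl[edges] <- 1
    px[, , ch] <- sl
  }
  cen <- detection_centroids(result)
  if (nrow(cen) > 0) {
    for (i in seq_len(nrow(cen))) {
      r <- cen[i, 1]; c <- cen[i, 2]
      # arrow shaft from upper-left, tip just off the centroid
      px <- draw_segment(px, r - 14, c - 14, r - 4, c - 4)
      px <- draw_segment(px, r - 4, c - 4, r - 9, c - 5)
      px <- draw_segment(px, r - 4, c - 4, r - 5, c - 9)
    }
  }
  px
}

#' Write a 16-bit label mask
#'
#' Labels are stored as 16-bit gray values in a TIFF file
#' (`label / 65535`), recoverable exactly for up to 65535 regions.
#'
#' @param labels integer label matrix.
#' @param path output `.tiff` path.
#' @export
write_label_mask <- function(labels, path) {
  if (max(labels) > 65535L) stop("more than 65535 labels")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a 16-bit label mask written by [write_label_mask()]
#' @param path `.tiff` path.
#' @return integer label matrix.
#' @export
read_label_mask <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Batch run configuration
#'
#' @param inputs character vector of image paths, or a single glob
#'   pattern (expanded with [Sys.glob()]).
#' @param out_dir output directory (created if missing).
#' @param params a [detection_params()].
#' @param pixel_size optional micrometres per pixel.
#' @param config_file optional YAML file of flat key-value settings
#'   (`channel`, `threshold`, `min_area_px`, `max_area_px`,
#'   `pixel_size`, ...); explicit arguments win on conflict.
#' @return list of class `run_config`.
#' @export
run_config <- function(inputs, out_dir, params = NULL, pixel_size = NULL,
                       config_file = NULL) {
  cfg <- list()
  if (!is.null(config_file)) {
    if (!file.exists(config_file)) stop("config file not found: ", config_file)
    cfg <- yaml::read_yaml(config_file)
  }
  if (is.null(params)) {
    pargs <- cfg[intersect(names(cfg),
                           c("channel", "threshold", "min_area_px",
                             "max_area_px", "lumen_fraction",
                             "circle_score_min"))]
    if (!is.null(pargs$threshold) && pargs$threshold != "auto")
      pargs$threshold <- as.numeric(pargs$threshold)
    params <- do.call(detection_params, pargs)
  }
  if (is.null(pixel_size) && !is.null(cfg$pixel_size))
    pixel_size <- as.numeric(cfg$pixel_size)
  files <- if (length(inputs) == 1L && grepl("[*?]", inputs))
    Sys.glob(inputs) else inputs
  structure(list(inputs = files, out_dir = out_dir, params = params,
                 pixel_size = pixel_size),
            class = "run_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(list(params = unclass(config$params),
            pixel_size = config$pixel_size), file = f)
  unname(tools::md5sum(f))
}

#' Run vessel detection over a batch of images
#'
#' For each readable input image, writes `<stem>_vessels.csv`
#' (per-vessel descriptors), `<stem>_summary.json`,
#' `<stem>_labels.tiff` (16-bit label mask) and `<stem>_overlay.png`
#' into the output directory, then an aggregate `batch_report.json`
#' recording, per image, the parameters and threshold used, the vessel
#' count and density, and a hash of the configuration. Unreadable
#' images are skipped with a logged error and flagged in the report.
#'
#' @param config a [run_config()].
#' @return invisibly, the batch report list; its `n_failed` entry is
#'   nonzero when any input could not be processed.
#' @export
run_batch <- function(config) {
  stopifnot(inherits(config, "run_config"))
  files <- config$inputs
  if (length(files) == 0L) stop("no input images matched")
  missing <- files[!file.exists(files)]
  if (length(missing) > 0L)
    stop("input path(s) do not exist: ", paste(missing, collapse = ", "))
  if (any(normalizePath(dirname(files)) ==
          suppressWarnings(normalizePath(config$out_dir, mustWork = FALSE))))
    stop("output directory must differ from the input directory")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  per_image <- list()
  n_failed <- 0L
  for (f in files) {
    stem <- tools::file_path_sans_ext(basename(f))
    rec <- tryCatch({
      img <- read_vessel_image(f)
      det <- detect_vessels(img, config$params, config$pixel_size)
      write.csv(det$vessels,
                file.path(config$out_dir, paste0(stem, "_vessels.csv")),
                row.names = FALSE)
      jsonlite::write_json(
        list(input = f, threshold = det$threshold,
             vessel_count = det$summary$vessel_count,
             vascular_area_fraction = det$summary$vascular_area_fraction,
             vessels_per_mm2 = det$summary$vessels_per_mm2,
             diameter_histogram = det$summary$diameter_histogram,
             area_histogram = det$summary$area_histogram),
        file.path(config$out_dir, paste0(stem, "_summary.json")),
        auto_unbox = TRUE, digits = NA, na = "null")
      write_label_mask(det$labels,
                       file.path(config$out_dir, paste0(stem, "_labels.tiff")))
      png::writePNG(overlay_image(img, det),
                    file.path(config$out_dir, paste0(stem, "_overlay.png")))
      list(input = f, ok = TRUE, threshold = det$threshold,
           vessel_count = det$summary$vessel_count,
           vascular_area_fraction = det$summary$vascular_area_fraction)
    }, error = function(e) {
      message(sprintf("skipping %s: %s", f, conditionMessage(e)))
      list(input = f, ok = FALSE, error = conditionMessage(e))
    })
    if (!isTRUE(rec$ok)) n_failed <- n_failed + 1L
    per_image[[length(per_image) + 1L]] <- rec
  }
  report <- list(
    config = list(channel = config$params$channel,
                  threshold = config$params$threshold,
                  min_area_px = config$params$min_area_px,
                  max_area_px = config$params$max_area_px,
                  lumen_fraction = config$params$lumen_fraction,
                  pixel_size = config$pixel_size,
                  hash = config_hash(config)),
    n_images = length(files), n_failed = n_failed,
    images = per_image)
  jsonlite::write_json(report, file.path(config$out_dir, "batch_report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(report)
}
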