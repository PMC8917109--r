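#' Phantom image specification
#'
#' Parameters of the synthetic validation images: vessel-like objects
#' (filled blobs, annuli with lumina, elongated profiles) rendered on a
#' near-black background in one stained channel, with optional noise
#' and artifact overlays, and exact ground truth by construction.
#'
#' Defaults reflect the validation conditions the detector is assessed
#' under: 512 x 512 frames, radii 6-30 px, a 0.4/0.3/0.3 mix of solid,
#' annular and elongated profiles, at least 15 px of clear background
#' between objects, vessel intensity 0.6-1.0, and additive Gaussian
#' noise with sigma 0.02.
#'
#' @param dims image dimensions `c(height, width)`.
#' @param n_vessels number of vessel objects.
#' @param shape_mix named proportions for `solid`, `annulus`,
#'   `elongated` (normalized internally).
#' @param radius_range_px bounding-radius range of the objects.
#' @param min_separation_px minimum edge-to-edge background gap between
#'   rendered objects, in pixels (which also bounds the pairwise
#'   centroid separation from below).
#' @param channel stained channel: `"red"` or `"green"`.
#' @param noise_sigma additive Gaussian noise SD on the `[0, 1]` scale
#'   (clipped after addition).
#' @param artifacts subset of `"fold_streak"`, `"haze"`,
#'   `"unspecific_blotch"`; rendered as labeled non-vessel structures.
#' @param seed RNG seed; generation is bit-reproducible for a fixed
#'   spec.
#' @param intensity_range per-object stain intensity range.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(512L, 512L), n_vessels = 25L,
                         shape_mix = c(solid = 0.4, annulus = 0.3,
                                       elongated = 0.3),
                         radius_range_px = c(6, 30),
                         min_separation_px = 15,
                         channel = c("red", "green"),
                         noise_sigma = 0.02,
                         artifacts = character(),
                         seed = 1L,
                         intensity_range = c(0.6, 1.0)) {
  channel <- match.arg(channel)
  stopifnot(length(dims) == 2L, all(dims >= 32L), n_vessels >= 0L,
            all(shape_mix >= 0), sum(shape_mix) > 0,
            radius_range_px[1] >= 3, radius_range_px[2] >= radius_range_px[1],
            min_separation_px >= 0, noise_sigma >= 0,
            all(artifacts %in% c("fold_streak", "haze", "unspecific_blotch")),
            intensity_range[1] > 0, intensity_range[2] <= 1)
  mix <- shape_mix[c("solid", "annulus", "elongated")]
  mix[is.na(mix)] <- 0
  names(mix) <- c("solid", "annulus", "elongated")
  structure(list(dims = as.integer(dims), n_vessels = as.integer(n_vessels),
                 shape_mix = mix / sum(mix),
                 radius_range_px = radius_range_px,
                 min_separation_px = min_separation_px, channel = channel,
                 noise_sigma = noise_sigma, artifacts = artifacts,
                 seed = as.integer(seed), intensity_range = intensity_range),
            class = "phantom_spec")
}

# pixels of a (possibly bent) thick-line profile: points within half-width
# w of a quadratic Bezier arc from A to B with control offset
capsule_pixels <- function(center, ang, half_len, w, bend, dims) {
  u <- c(cos(ang), sin(ang))          # (drow, dcol) direction
  v <- c(-sin(ang), cos(ang))
  A <- center - half_len * u
  B <- center + half_len * u
  C <- center + bend * v
  t <- seq(0, 1, length.out = 40)
  P <- outer((1 - t)^2, A) + outer(2 * (1 - t) * t, C) + outer(t^2, B)
  br <- half_len + w + abs(bend) + 1
  r0 <- max(1L, floor(center[1] - br)); r1 <- min(dims[1], ceiling(center[1] + br))
  c0 <- max(1L, floor(center[2] - br)); c1 <- min(dims[2], ceiling(center[2] + br))
  gr <- seq.int(r0, r1); gc <- seq.int(c0, c1)
  dd <- matrix(Inf, length(gr), length(gc))
  for (k in seq_len(nrow(P))) {
    dk <- outer((gr - P[k, 1])^2, (gc - P[k, 2])^2, "+")
    dd <- pmin(dd, dk)
  }
  hit <- which(dd <= w^2, arr.ind = TRUE)
  cbind(row = gr[hit[, 1L]], col = gc[hit[, 2L]])
}

ellipse_pixels <- function(center, a, b, phi, dims) {
  br <- max(a, b) + 1
  r0 <- max(1L, floor(center[1] - br)); r1 <- min(dims[1], ceiling(center[1] + br))
  c0 <- max(1L, floor(center[2] - br)); c1 <- min(dims[2], ceiling(center[2] + br))
  gr <- seq.int(r0, r1); gc <- seq.int(c0, c1)
  dr <- outer(gr - center[1], rep(1, length(gc)))
  dc <- outer(rep(1, length(gr)), gc - center[2])
  x <- dr * cos(phi) + dc * sin(phi)
  y <- -dr * sin(phi) + dc * cos(phi)
  hit <- which((x / a)^2 + (y / b)^2 <= 1, arr.ind = TRUE)
  cbind(row = gr[hit[, 1L]], col = gc[hit[, 2L]])
}

annulus_pixels <- function(center, r_out, r_in, dims) {
  r0 <- max(1L, floor(center[1] - r_out - 1)); r1 <- min(dims[1], ceiling(center[1] + r_out + 1))
  c0 <- max(1L, floor(center[2] - r_out - 1)); c1 <- min(dims[2], ceiling(center[2] + r_out + 1))
  gr <- seq.int(r0, r1); gc <- seq.int(c0, c1)
  d2 <- outer((gr - center[1])^2, (gc - center[2])^2, "+")
  hit <- which(d2 <= r_out^2 & d2 > r_in^2, arr.ind = TRUE)
  cbind(row = gr[hit[, 1L]], col = gc[hit[, 2L]])
}

with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a phantom validation image with exact ground truth
#'
#' Renders `n_vessels` non-overlapping vessel-like objects on a black
#' background in the stained channel. Object placement uses rejection
#' sampling (largest bounding radius first) honoring the minimum
#' background gap; annuli are constructed with a lumen strictly larger
#' than 12.5 percent of the ring area, so the lumen-recovery path of
#' the detector is exercised. Optional artifacts are rendered as
#' non-vessel structures and reported separately from the truth.
#' Generation is deterministic for a fixed spec (the caller's RNG state
#' is left untouched).
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom_image`: list with `image`
#'   (`H x W x 3` array in `[0, 1]`), `truth` (a [ground_truth_set()]
#'   whose label mask exactly covers the rendered vessel pixels,
#'   pre-noise), `objects` (data frame: id, shape, area_px, centroid,
#'   hole fraction for annuli), `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_preserved_rng(spec$seed, {
    dims <- spec$dims
    n <- spec$n_vessels
    shapes <- if (n > 0)
      sample(names(spec$shape_mix), n, replace = TRUE, prob = spec$shape_mix)
    else character()
    rr <- spec$radius_range_px
    geom <- lapply(shapes, function(sh) {
      r <- runif(1, rr[1], rr[2])
      switch(sh,
        solid = list(shape = "solid", r = r, b = r * runif(1, 0.7, 1),
                     phi = runif(1, 0, pi), br = r),
        annulus = list(shape = "annulus", r = r,
                       r_in = max(2, r * runif(1, 0.45, 0.7)), br = r),
        elongated = {
          hl <- runif(1, 0.8, 1.0) * r
          w <- runif(1, 3, max(3, min(6, 0.4 * r)))
          bend <- runif(1, 0, 0.5 * hl)
          list(shape = "elongated", hl = hl, w = w, bend = bend,
               phi = runif(1, 0, pi), br = hl + w + bend)
        })
    })
    ord <- order(-vapply(geom, `[[`, numeric(1), "br"))
    geom <- geom[ord]

    centers <- matrix(numeric(), 0, 2)
    brs <- numeric()
    for (g in geom) {
      placed <- FALSE
      if (g$br + 2 >= min(dims) - g$br - 1)
        stop(sprintf(paste0("object bounding radius %.1f px cannot fit in a ",
                            "%d x %d frame: shrink radius_range_px"),
                     g$br, dims[1], dims[2]))
      for (try in seq_len(500L)) {
        ctr <- c(runif(1, g$br + 2, dims[1] - g$br - 1),
                 runif(1, g$br + 2, dims[2] - g$br - 1))
        if (nrow(centers) == 0L ||
            all(sqrt((centers[, 1] - ctr[1])^2 + (centers[, 2] - ctr[2])^2) >=
                brs + g$br + spec$min_separation_px)) {
          centers <- rbind(centers, ctr)
          brs <- c(brs, g$br)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop(sprintf(paste0("phantom placement failed after 500 tries: ",
                            "reduce n_vessels or min_separation_px (= %g)"),
                     spec$min_separation_px))
    }

    chan_idx <- c(red = 1L, green = 2L)[[spec$channel]]
    img <- array(0, c(dims[1], dims[2], 3L))
    labels <- matrix(0L, dims[1], dims[2])
    objects <- list()
    for (i in seq_along(geom)) {
      g <- geom[[i]]
      ctr <- centers[i, ]
      px <- switch(g$shape,
        solid = ellipse_pixels(ctr, g$r, g$b, g$phi, dims),
        annulus = annulus_pixels(ctr, g$r, g$r_in, dims),
        elongated = capsule_pixels(ctr, g$phi, g$hl, g$w, g$bend, dims))
      hole_frac <- NA_real_
      if (g$shape == "annulus") {
        hole <- sum(outer((seq_len(dims[1]) - ctr[1])^2,
                          (seq_len(dims[2]) - ctr[2])^2, "+") <= g$r_in^2)
        hole_frac <- hole / nrow(px)
      }
      intensity <- runif(1, spec$intensity_range[1], spec$intensity_range[2])
      ch <- img[, , chan_idx]
      ch[px] <- intensity
      img[, , chan_idx] <- ch
      labels[px] <- i
      objects[[i]] <- data.frame(
        id = i, shape = g$shape, area_px = nrow(px),
        centroid_row = mean(px[, 1]), centroid_col = mean(px[, 2]),
        intensity = intensity, hole_fraction = hole_frac)
    }
    objects <- if (length(objects)) do.call(rbind, objects)
      else data.frame(id = integer(), shape = character(),
                      area_px = integer(), centroid_row = numeric(),
                      centroid_col = numeric(), intensity = numeric(),
                      hole_fraction = numeric())

    artifact_list <- list()
    for (a in spec$artifacts) {
      if (a == "fold_streak") {
        ctr <- c(runif(1, 0.25, 0.75) * dims[1], runif(1, 0.25, 0.75) * dims[2])
        px <- capsule_pixels(ctr, runif(1, 0, pi), 0.25 * min(dims),
                             runif(1, 1.5, 2.5), 0.1 * min(dims), dims)
        px <- px[labels[px] == 0L, , drop = FALSE]
        ch <- img[, , chan_idx]
        ch[px] <- pmax(ch[px], 0.75)
        img[, , chan_idx] <- ch
        artifact_list[[length(artifact_list) + 1L]] <-
          data.frame(type = a, centroid_row = ctr[1], centroid_col = ctr[2])
      } else if (a == "haze") {
        ang <- runif(1, 0, 2 * pi)
        g <- outer(seq(0, 1, length.out = dims[1]) * cos(ang),
                   rep(1, dims[2])) +
             outer(rep(1, dims[1]),
                   seq(0, 1, length.out = dims[2]) * sin(ang))
        g <- (g - min(g)) / max(1e-12, diff(range(g))) * 0.15
        img[, , chan_idx] <- pmin(1, img[, , chan_idx] + g)
        artifact_list[[length(artifact_list) + 1L]] <-
          data.frame(type = a, centroid_row = NA_real_, centroid_col = NA_real_)
      } else if (a == "unspecific_blotch") {
        off_idx <- if (chan_idx == 1L) 2L else 1L
        ctr <- c(runif(1, 0.2, 0.8) * dims[1], runif(1, 0.2, 0.8) * dims[2])
        sg <- runif(1, 20, 40)
        d2 <- outer((seq_len(dims[1]) - ctr[1])^2,
                    (seq_len(dims[2]) - ctr[2])^2, "+")
        img[, , off_idx] <- pmin(1, img[, , off_idx] + 0.4 * exp(-d2 / (2 * sg^2)))
        artifact_list[[length(artifact_list) + 1L]] <-
          data.frame(type = a, centroid_row = ctr[1], centroid_col = ctr[2])
      }
    }

    if (spec$noise_sigma > 0) {
      img <- img + array(rnorm(length(img), 0, spec$noise_sigma), dim(img))
      img <- pmin(pmax(img, 0), 1)
    }

    truth <- if (n > 0)
      ground_truth_set(centroids = cbind(row = objects$centroid_row,
                                         col = objects$centroid_col),
                       label_mask = labels)
    else ground_truth_set(centroids = cbind(row = numeric(), col = numeric()),
                          label_mask = labels)

    structure(list(image = img, truth = truth, objects = objects,
                   artifacts = if (length(artifact_list))
                     do.call(rbind, artifact_list) else NULL,
                   spec = spec),
              class = "phantom_image")
  })
}

#' @export
print.phantom_image <- function(x, ...) {
  cat(sprintf("phantom_image: %d x %d, %d vessels (%s channel), noise sigma %g\n",
              x$spec$dims[1], x$spec$dims[2], nrow(x$objects),
              x$spec$channel, x$spec$noise_sigma))
  invisible(x)
}

#' Generate a seeded batch of phantom images
#'
#' Convenience wrapper producing the standard validation batch: for
#' image `i`, the spec seed is `base_seed + i - 1` and the vessel count
#' is drawn uniformly from `n_vessels_range` under that seed.
#'
#' @param n_images number of phantoms (default 10).
#' @param base_seed seed of the first image (default 100).
#' @param n_vessels_range inclusive range for the per-image vessel
#'   count (default 15-40).
#' @param ... further arguments passed to [phantom_spec()].
#' @return list of `phantom_image` objects.
#' @export
phantom_batch <- function(n_images = 10L, base_seed = 100L,
                          n_vessels_range = c(15L, 40L), ...) {
  lapply(seq_len(n_images), function(i) {
    sd_i <- base_seed + i - 1L
    n_i <- with_preserved_rng(sd_i,
      sample(seq.int(n_vessels_range[1], n_vessels_range[2]), 1L))
    generate_phantom(phantom_spec(n_vessels = n_i, seed = sd_i, ...))
  })
}

#' Evaluate the detector on a batch of phantoms
#'
#' Runs [detect_vessels()] on each phantom, matches detections to the
#' exact ground truth, and reports both micro-averaged metrics (TP, FP
#' and FN pooled across images before computing precision, recall and
#' F-measure) and macro-averaged metrics (per-image metrics averaged).
#'
#' @param phantoms list of `phantom_image` objects (see
#'   [phantom_batch()]).
#' @param params a [detection_params()]; default parameters with the
#'   channel taken from each phantom's spec.
#' @param max_dist_px matching tolerance passed to
#'   [match_detections()].
#' @return list with `pooled` (a `metrics_report`), `macro`
#'   (mean per-image precision/recall/F), `counts` (pooled TP/FP/FN)
#'   and `per_image` (data frame).
#' @export
evaluate_batch <- function(phantoms, params = NULL, max_dist_px = 20) {
  rows <- lapply(seq_along(phantoms), function(i) {
    ph <- phantoms[[i]]
    p <- if (is.null(params)) detection_params(channel = ph$spec$channel)
         else params
    det <- detect_vessels(ph$image, p)
    m <- match_detections(det, ph$truth, max_dist_px = max_dist_px)
    pr <- precision_recall_f(m)
    data.frame(image = i, n_truth = ph$truth$n, n_detected = nrow(det$vessels),
               tp = m$true_positive, fp = m$false_positive,
               fn = m$false_negative, precision = pr$precision,
               recall = pr$recall, f_measure = pr$f_measure)
  })
  per_image <- do.call(rbind, rows)
  counts <- list(true_positive = sum(per_image$tp),
                 false_positive = sum(per_image$fp),
                 false_negative = sum(per_image$fn))
  pooled <- precision_recall_f(counts)
  macro <- list(precision = mean(per_image$precision),
                recall = mean(per_image$recall),
                f_measure = mean(per_image$f_measure))
  list(pooled = pooled, macro = macro, counts = counts,
       per_image = per_image)
}
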