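#' Ground-truth vessel set
#'
#' Reference vessels for evaluating a detector, given either as a
#' labeled mask (integer matrix, 0 = background) and/or a centroid
#' list. When only a mask is supplied, centroids are its per-label
#' pixel-coordinate means.
#'
#' @param centroids optional `n x 2` matrix / data frame of
#'   `(row, col)` centroids.
#' @param label_mask optional integer label matrix.
#' @return object of class `ground_truth_set` with `centroids`,
#'   `label_mask`, `areas` (when a mask is given) and `n`.
#' @export
ground_truth_set <- function(centroids = NULL, label_mask = NULL) {
  if (is.null(centroids) && is.null(label_mask))
    stop("supply centroids and/or a label mask")
  areas <- NULL
  if (!is.null(label_mask)) {
    storage.mode(label_mask) <- "integer"
    ids <- sort(unique(label_mask[label_mask > 0L]))
    if (is.null(centroids) && length(ids) > 0L) {
      idx <- which(label_mask > 0L)
      lab <- label_mask[idx]
      r <- (idx - 1L) %% nrow(label_mask) + 1L
      c <- (idx - 1L) %/% nrow(label_mask) + 1L
      centroids <- cbind(row = tapply(r, lab, mean)[as.character(ids)],
                         col = tapply(c, lab, mean)[as.character(ids)])
      rownames(centroids) <- NULL
    } else if (is.null(centroids)) {
      centroids <- cbind(row = numeric(), col = numeric())
    }
    areas <- as.integer(table(factor(label_mask[label_mask > 0L], levels = ids)))
  }
  centroids <- as.matrix(centroids)
  structure(list(centroids = centroids, label_mask = label_mask,
                 areas = areas, n = nrow(centroids)),
            class = "ground_truth_set")
}

#' @export
print.ground_truth_set <- function(x, ...) {
  cat(sprintf("ground_truth_set: %d reference vessels%s\n", x$n,
              if (!is.null(x$label_mask)) " (with label mask)" else ""))
  invisible(x)
}

#' Match detections to ground truth one-to-one
#'
#' Candidate pairs are those where the detection centroid falls inside
#' the ground-truth region (when a label mask is available) or the
#' centroid-to-centroid distance is at most `max_dist_px`. Pairs are
#' accepted greedily in ascending centroid distance, each detection and
#' each reference object used at most once, so
#' `TP + FP = detections` and `TP + FN = truth` always hold.
#'
#' @param detections a `vessel_detection`, or an `n x 2` centroid
#'   matrix.
#' @param truth a [ground_truth_set()].
#' @param max_dist_px matching tolerance in pixels (default 20, about
#'   10 um at typical magnification).
#' @return object of class `match_result`: list with counts
#'   `true_positive`, `false_positive`, `false_negative` and `pairs`
#'   (data frame `detection_id`, `truth_id`, `distance`).
#' @export
match_detections <- function(detections, truth, max_dist_px = 20) {
  det <- if (inherits(detections, "vessel_detection"))
    detection_centroids(detections) else as.matrix(detections)
  nd <- nrow(det); nt <- truth$n
  pairs <- data.frame(detection_id = integer(), truth_id = integer(),
                      distance = numeric())
  if (nd > 0L && nt > 0L) {
    dmat <- sqrt(outer(det[, 1L], truth$centroids[, 1L], "-")^2 +
                 outer(det[, 2L], truth$centroids[, 2L], "-")^2)
    ok <- dmat <= max_dist_px
    if (!is.null(truth$label_mask)) {
      h <- nrow(truth$label_mask); w <- ncol(truth$label_mask)
      rr <- pmin(pmax(round(det[, 1L]), 1L), h)
      cc <- pmin(pmax(round(det[, 2L]), 1L), w)
      inlab <- truth$label_mask[cbind(rr, cc)]
      ids <- sort(unique(truth$label_mask[truth$label_mask > 0L]))
      for (i in seq_len(nd))
        if (inlab[i] > 0L) ok[i, match(inlab[i], ids)] <- TRUE
    }
    cand <- which(ok, arr.ind = TRUE)
    if (nrow(cand) > 0L) {
      cd <- dmat[cand]
      ord <- order(cd, cand[, 1L], cand[, 2L])
      used_d <- logical(nd); used_t <- logical(nt)
      for (k in ord) {
        i <- cand[k, 1L]; j <- cand[k, 2L]
        if (!used_d[i] && !used_t[j]) {
          used_d[i] <- TRUE; used_t[j] <- TRUE
          pairs <- rbind(pairs, data.frame(detection_id = i, truth_id = j,
                                           distance = dmat[i, j]))
        }
      }
    }
  }
  tp <- nrow(pairs)
  structure(list(true_positive = tp, false_positive = nd - tp,
                 false_negative = nt - tp, pairs = pairs),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("match_result: TP %d, FP %d, FN %d\n",
              x$true_positive, x$false_positive, x$false_negative))
  invisible(x)
}

#' Harmonic mean of precision and recall
#'
#' @param precision,recall values in `[0, 1]`.
#' @return the F-measure `2 P R / (P + R)`; 0 when both are 0.
#' @export
f_measure <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Precision, recall and F-measure from matched counts
#'
#' Precision is `TP / (TP + FP)`, recall `TP / (TP + FN)`, and the
#' F-measure their harmonic mean. Undefined ratios (0/0) are reported
#' as 0 and flagged as degenerate.
#'
#' @param m a `match_result`, or a list/vector with `true_positive`,
#'   `false_positive`, `false_negative`.
#' @return object of class `metrics_report`: list with `precision`,
#'   `recall`, `f_measure`, `degenerate`.
#' @export
precision_recall_f <- function(m) {
  tp <- m$true_positive; fp <- m$false_positive; fn <- m$false_negative
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  degenerate <- character()
  if (tp + fp > 0) p <- tp / (tp + fp) else { p <- 0; degenerate <- c(degenerate, "precision") }
  if (tp + fn > 0) r <- tp / (tp + fn) else { r <- 0; degenerate <- c(degenerate, "recall") }
  structure(list(precision = p, recall = r, f_measure = f_measure(p, r),
                 degenerate = degenerate),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("precision %.1f%%, recall %.1f%%, F-measure %.1f%%%s\n",
              100 * x$precision, 100 * x$recall, 100 * x$f_measure,
              if (length(x$degenerate))
                paste0(" (degenerate: ", paste(x$degenerate, collapse = ", "), ")")
              else ""))
  invisible(x)
}

#' Bland-Altman agreement between two paired measurement series
#'
#' Computes the bias (mean of the paired differences `x - y`), the 95
#' percent limits of agreement `bias +/- 1.96 * SD` using the sample
#' (n-1) standard deviation, and the Pearson correlation of the paired
#' measurements. The conventional plot abscissa, the pairwise means, is
#' returned alongside the differences.
#'
#' @param x,y numeric vectors of equal length `n >= 2`.
#' @return object of class `agreement_report`: list with `bias`,
#'   `loa_low`, `loa_high`, `r`, `n`, `differences`, `means`,
#'   `degenerate` (flags when a series has zero variance and `r` is
#'   undefined).
#' @export
bland_altman <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 2L) stop("Bland-Altman needs at least 2 paired observations")
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  degenerate <- character()
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    r <- NA_real_
    degenerate <- "zero-variance series: correlation undefined"
  } else r <- stats::cor(x, y)
  structure(list(bias = bias, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s, r = r, n = n,
                 differences = d, means = (x + y) / 2,
                 degenerate = degenerate),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.3f, limits of agreement %.3f to %.3f",
              x$n, x$bias, x$loa_low, x$loa_high))
  if (is.finite(x$r)) cat(sprintf(", r = %.3f", x$r))
  cat("\n")
  invisible(x)
}

#' Standardize values to z-scores
#'
#' `(v - mean) / sd` with the sample (n-1) standard deviation, used to
#' compare measurements made on different scales (e.g. fluorescence
#' units vs. pixel counts).
#'
#' @param values numeric vector, `n >= 2`, with nonzero sample SD.
#' @return standardized vector with mean 0 and sample SD 1.
#' @export
zscore <- function(values) {
  stopifnot(is.numeric(values))
  if (length(values) < 2L) stop("z-scores need at least 2 values")
  s <- stats::sd(values)
  if (s == 0) stop("zero standard deviation: z-scores undefined")
  (values - mean(values)) / s
}

#' Corrected total glomerular fluorescence
#'
#' `CTGF = integrated density - ROI area * mean background
#' fluorescence`. The value may be negative (a dim region of interest
#' on a bright background) and is returned as-is.
#'
#' @param integrated_density sum of ROI pixel intensities.
#' @param roi_area pixel count of the selected glomerulus (> 0).
#' @param background_mean mean background fluorescence (>= 0).
#' @return the corrected fluorescence value.
#' @export
ctgf <- function(integrated_density, roi_area, background_mean) {
  stopifnot(roi_area > 0, background_mean >= 0)
  integrated_density - roi_area * background_mean
}

#' Fraction of stain-positive pixels within a region of interest
#'
#' Counts pixels whose intensity in the selected channel exceeds the
#' threshold, over the ROI size (the whole image when no ROI is given).
#'
#' @param img RGB [intensity_image] / array, or single-channel matrix.
#' @param channel `"red"` or `"green"` (ignored for single-channel
#'   input).
#' @param T intensity threshold in `[0, 1]`.
#' @param roi optional logical matrix selecting the ROI (non-empty).
#' @return fraction in `[0, 1]`.
#' @export
channel_positive_fraction <- function(img, channel = c("red", "green"), T,
                                      roi = NULL) {
  px <- as_pixels(img)
  if (length(dim(px)) == 3L)
    px <- as_pixels(extract_channel(img, match.arg(channel)))
  if (is.null(roi)) roi <- matrix(TRUE, nrow(px), ncol(px))
  stopifnot(identical(dim(roi), dim(px)))
  if (!any(roi)) stop("ROI is empty")
  sum(px[roi] > T) / sum(roi)
}
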