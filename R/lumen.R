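circle_offsets <- function(r) {
  n <- max(16L, ceiling(2 * pi * r) * 2L)
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  unique(cbind(as.integer(round(r * sin(th))), as.integer(round(r * cos(th)))))
}

mask_edges <- function(mask) {
  inner <- mask &
    shift_mask(mask, 1L, 0L, FALSE) & shift_mask(mask, -1L, 0L, FALSE) &
    shift_mask(mask, 0L, 1L, FALSE) & shift_mask(mask, 0L, -1L, FALSE)
  mask & !inner
}

#' Detect circular structures by a circular Hough transform
#'
#' Boundary pixels of the mask vote for candidate circle centers along
#' full circle perimeters at each integer radius in the range. The
#' accumulator is normalized by the number of perimeter offsets, so a
#' complete rasterized circle scores about 1. Candidate centers with a
#' score of at least `score_min` are kept after greedy non-maximum
#' suppression (strongest first; candidates within half the accepted
#' radius of an accepted center are suppressed).
#'
#' @param mask logical matrix.
#' @param r_min,r_max integer radius range in pixels (`r_min >= 1`).
#' @param score_min acceptance metric threshold in `(0, 1]`.
#' @return data frame with columns `row`, `col`, `r`, `score`,
#'   one row per accepted circle (may be empty).
#' @export
hough_circles <- function(mask, r_min = 5L, r_max = 50L, score_min = 0.3) {
  stopifnot(r_min >= 1L, r_max > r_min)
  edges <- which(mask_edges(mask), arr.ind = TRUE)
  cand <- list()
  if (nrow(edges) > 0L) {
    h <- nrow(mask); w <- ncol(mask)
    for (r in seq.int(r_min, r_max)) {
      off <- circle_offsets(r)
      acc <- hough_votes(edges[, 1L], edges[, 2L], h, w, off)
      score <- acc / nrow(off)
      hit <- which(score >= score_min, arr.ind = TRUE)
      if (nrow(hit) > 0L)
        cand[[length(cand) + 1L]] <- data.frame(
          row = hit[, 1L], col = hit[, 2L], r = r,
          score = score[hit])
    }
  }
  if (length(cand) == 0L)
    return(data.frame(row = integer(), col = integer(), r = integer(),
                      score = numeric()))
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$score, cand$r, cand$row, cand$col), , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    if (any(keep)) {
      acc_rows <- cand[keep, , drop = FALSE]
      d <- sqrt((acc_rows$row - cand$row[i])^2 + (acc_rows$col - cand$col[i])^2)
      if (any(d < pmax(3, 0.5 * pmax(acc_rows$r, cand$r[i])))) ok <- FALSE
    }
    keep[i] <- ok
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enclosed holes of a single component
#'
#' Returns the 4-connected background regions enclosed by the component
#' (computed within a 1-pixel padded bounding box, so background
#' connected around the outside of the component is never a hole).
#'
#' @param pixels `n x 2` matrix of 1-based `(row, col)` coordinates.
#' @return list of hole pixel matrices in the same global coordinates
#'   (empty list when the component is solid).
#' @keywords internal
component_holes <- function(pixels) {
  r0 <- min(pixels[, 1L]) - 1L; c0 <- min(pixels[, 2L]) - 1L
  h <- max(pixels[, 1L]) - r0 + 2L
  w <- max(pixels[, 2L]) - c0 + 2L
  local <- matrix(FALSE, h, w)
  local[cbind(pixels[, 1L] - r0 + 1L, pixels[, 2L] - c0 + 1L)] <- TRUE
  bg <- cc_label(!local, 4L)
  border <- unique(c(bg[1, ], bg[h, ], bg[, 1], bg[, w]))
  hole_ids <- setdiff(unique(as.vector(bg)), c(0L, border))
  lapply(hole_ids, function(id) {
    hp <- which(bg == id, arr.ind = TRUE)
    cbind(row = hp[, 1L] + r0 - 1L, col = hp[, 2L] + c0 - 1L)
  })
}

#' The 12.5 percent lumen rule
#'
#' A hollow region counts as a lumen when its area is strictly larger
#' than `lumen_fraction` times the area of the detected object (the
#' ring component as detected, before hole filling). At exactly the
#' fraction the rule does not fire.
#'
#' @param hole_area,component_area pixel counts.
#' @param lumen_fraction fraction in `(0, 1)`, default `0.125`.
#' @return logical.
#' @export
lumen_rule <- function(hole_area, component_area, lumen_fraction = 0.125) {
  hole_area > lumen_fraction * component_area
}

#' Reintroduce area-filtered components whose lumina match detected circles
#'
#' Implements the recovery step for small vessels with large lumina: a
#' removed component is reintroduced iff it overlaps a detected circle
#' and one of its enclosed hollow regions is contained in that circle
#' with hole area strictly larger than `lumen_fraction` times the
#' component area (see [lumen_rule()]).
#'
#' @param removed `component_set` of components removed by the area
#'   filter (candidates for recovery).
#' @param circles data frame as returned by [hough_circles()].
#' @param lumen_fraction fraction in `(0, 1)`, default `0.125`.
#' @return `component_set` of the components to reintroduce (possibly
#'   empty).
#' @export
reintroduce_components <- function(removed, circles, lumen_fraction = 0.125) {
  n <- length(removed$pixel_lists)
  if (n == 0L || nrow(circles) == 0L)
    return(subset_components(removed, integer()))
  keep <- logical(n)
  for (i in seq_len(n)) {
    pl <- removed$pixel_lists[[i]]
    holes <- component_holes(pl)
    if (length(holes) == 0L) next
    for (k in seq_len(nrow(circles))) {
      cy <- circles$row[k]; cx <- circles$col[k]; r <- circles$r[k]
      # (a) component overlaps the circle's disk
      if (!any((pl[, 1L] - cy)^2 + (pl[, 2L] - cx)^2 <= (r + 0.5)^2)) next
      for (hp in holes) {
        inside <- all((hp[, 1L] - cy)^2 + (hp[, 2L] - cx)^2 <= (r + 0.5)^2)
        if (inside && lumen_rule(nrow(hp), nrow(pl), lumen_fraction)) {
          keep[i] <- TRUE
          break
        }
      }
      if (keep[i]) break
    }
  }
  subset_components(removed, which(keep))
}

#' Recover small lumened vessels removed by the area filter
#'
#' Runs circular-Hough detection over the binary mask (only when some
#' removed component actually encloses a hollow region) and applies
#' [reintroduce_components()].
#'
#' @param mask the binary mask the components were extracted from.
#' @param removed `component_set` removed by the area filter.
#' @param params a [detection_params()] list (uses
#'   `circle_radius_range`, `circle_score_min`, `lumen_fraction`).
#' @return `component_set` of components to reintroduce.
#' @export
recover_lumened_vessels <- function(mask, removed, params = detection_params()) {
  n <- length(removed$pixel_lists)
  if (n == 0L) return(subset_components(removed, integer()))
  has_hole <- vapply(removed$pixel_lists,
                     function(pl) length(component_holes(pl)) > 0L, logical(1))
  if (!any(has_hole)) return(subset_components(removed, integer()))
  circles <- hough_circles(mask,
                           r_min = params$circle_radius_range[1],
                           r_max = params$circle_radius_range[2],
                           score_min = params$circle_score_min)
  reintroduce_components(removed, circles, params$lumen_fraction)
}
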