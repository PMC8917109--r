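#' Connected components of a binary mask
#'
#' Extracts maximal 8-connected components (pixels are neighbors when
#' their edges or corners are adjacent, the `bwconncomp` default).
#' Components are ordered deterministically by the raster-scan position
#' of their first pixel.
#'
#' @param mask logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return an object of class `component_set`: a list with `labels`
#'   (integer matrix, 0 = background), `pixel_lists` (list of
#'   `n_i x 2` integer matrices of 1-based `(row, col)` coordinates)
#'   and `dims`.
#' @export
connected_components <- function(mask, connectivity = 8L) {
  stopifnot(is.logical(mask), is.matrix(mask))
  labels <- cc_label(mask, as.integer(connectivity))
  component_set_from_labels(labels, dim(mask))
}

component_set_from_labels <- function(labels, dims) {
  n <- max(labels)
  if (n == 0L) {
    pls <- list()
  } else {
    idx <- which(labels > 0L)
    lab <- labels[idx]
    rc <- cbind(row = (idx - 1L) %% dims[1] + 1L,
                col = (idx - 1L) %/% dims[1] + 1L)
    ord <- order(lab)
    pls <- split.data.frame(rc[ord, , drop = FALSE], lab[ord])
    names(pls) <- NULL
  }
  structure(list(labels = labels, pixel_lists = pls, dims = dims),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("component_set: %d components in %d x %d mask\n",
              length(x$pixel_lists), x$dims[1], x$dims[2]))
  invisible(x)
}

#' @export
length.component_set <- function(x) length(x$pixel_lists)

#' Areas (pixel counts) of each component
#' @param cs a `component_set`.
#' @return integer vector of component areas.
#' @export
component_areas <- function(cs) {
  vapply(cs$pixel_lists, nrow, integer(1))
}

#' Rebuild the binary mask covered by a component set
#' @param cs a `component_set`.
#' @return logical matrix.
#' @export
component_mask <- function(cs) {
  m <- matrix(FALSE, cs$dims[1], cs$dims[2])
  for (pl in cs$pixel_lists) m[pl] <- TRUE
  m
}

subset_components <- function(cs, keep) {
  pls <- cs$pixel_lists[keep]
  labels <- matrix(0L, cs$dims[1], cs$dims[2])
  for (i in seq_along(pls)) labels[pls[[i]]] <- i
  structure(list(labels = labels, pixel_lists = pls, dims = cs$dims),
            class = "component_set")
}

#' Partition components by area
#'
#' Keeps components whose pixel count lies in
#' `[min_area_px, max_area_px]` (both bounds inclusive) and returns the
#' too-small and too-large remainders separately, so that small vessels
#' with large lumina can later be reconsidered by the lumen-recovery
#' rule.
#'
#' @param cs a `component_set`.
#' @param min_area_px,max_area_px inclusive area band in pixels
#'   (`min_area_px < max_area_px`).
#' @return list with `kept`, `removed_small`, `removed_large`
#'   component sets; the three partitions are exhaustive and disjoint.
#' @export
filter_by_area <- function(cs, min_area_px, max_area_px) {
  stopifnot(min_area_px < max_area_px, min_area_px > 0)
  a <- component_areas(cs)
  list(
    kept          = subset_components(cs, which(a >= min_area_px & a <= max_area_px)),
    removed_small = subset_components(cs, which(a < min_area_px)),
    removed_large = subset_components(cs, which(a > max_area_px))
  )
}
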