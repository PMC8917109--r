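shift_mask <- function(m, dr, dc, fill) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1L, 1L + dr):min(h, h + dr)
  cs <- max(1L, 1L + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Dilate a binary mask with a 3x3 square structuring element
#' @param mask logical matrix.
#' @return logical matrix; out-of-bounds neighbors count as background.
#' @export
dilate3x3 <- function(mask) {
  out <- mask
  for (dr in -1:1) for (dc in -1:1)
    if (dr != 0L || dc != 0L)
      out <- out | shift_mask(mask, dr, dc, FALSE)
  out
}

#' Erode a binary mask with a 3x3 square structuring element
#' @param mask logical matrix.
#' @return logical matrix; out-of-bounds neighbors count as foreground,
#'   so borders are not eroded by the image frame itself.
#' @export
erode3x3 <- function(mask) {
  out <- mask
  for (dr in -1:1) for (dc in -1:1)
    if (dr != 0L || dc != 0L)
      out <- out & shift_mask(mask, dr, dc, TRUE)
  out
}

#' Fill enclosed background holes
#'
#' Background regions that are not 4-connected to the image border
#' become foreground. Background connectivity is 4-connected —
#' complementary to the 8-connected foreground — which prevents fills
#' from leaking through diagonal gaps.
#'
#' @param mask logical matrix.
#' @return logical matrix with holes filled.
#' @export
fill_holes <- function(mask) {
  bg <- cc_label(!mask, 4L)
  if (max(bg) == 0L) return(mask)
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border_labels <- border_labels[border_labels > 0L]
  mask | !(bg %in% c(0L, border_labels))
}

#' Morphological closing then hole filling
#'
#' Closes the mask (dilation followed by erosion, 3x3 square structuring
#' element) to bridge small gaps in vessel walls, then fills enclosed
#' background regions so that lumina become part of the vessel region.
#' Closing is extensive, so no retained vessel can shrink below the area
#' band at this stage.
#'
#' @param mask logical matrix (vessel-retained components).
#' @return logical matrix.
#' @export
close_and_fill <- function(mask) {
  fill_holes(erode3x3(dilate3x3(mask)))
}
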