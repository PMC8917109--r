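#' Suggest an intensity threshold by Otsu's method
#'
#' Computes the threshold that minimizes intra-class intensity variance
#' (equivalently, maximizes between-class variance) on a 256-bin
#' histogram of `[0, 1]`. The returned threshold is the upper edge of
#' the last background bin, i.e. `k/256` for the argmax split index
#' `k`; ties are broken toward the smallest bin index, so the result is
#' deterministic for a fixed input and invariant to pixel permutations.
#'
#' @param img single-channel [intensity_image] or numeric matrix with
#'   values in `[0, 1]` (typically the smoothed channel).
#' @return threshold in `[0, 1]`. A single-valued histogram (constant
#'   image) returns 0 with a warning, mirroring the degenerate
#'   normalization behavior.
#' @seealso [binarize()]
#' @export
suggest_threshold <- function(img) {
  v <- as.vector(as_pixels(img))
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("no finite pixels")
  if (any(v < 0 | v > 1)) stop("intensities must lie in [0, 1]")
  nb <- 256L
  bin <- pmin(floor(v * nb) + 1L, nb)  # value 1.0 falls in the last bin
  counts <- tabulate(bin, nbins = nb)
  if (sum(counts > 0L) <= 1L) {
    warning("single-valued histogram: threshold undefined, returning 0")
    return(0)
  }
  p <- counts / sum(counts)
  mids <- (seq_len(nb) - 0.5) / nb
  w0 <- cumsum(p)[-nb]
  mu0 <- cumsum(p * mids)[-nb]
  mu_t <- sum(p * mids)
  w1 <- 1 - w0
  # between-class variance for split after bin k (background = bins 1..k)
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, nb - 1L)
  sigma_b[valid] <- (mu_t * w0[valid] - mu0[valid])^2 / (w0[valid] * w1[valid])
  k <- which.max(sigma_b)  # which.max takes the first maximum: smallest bin index
  k / nb
}

#' Binarize an intensity image at a threshold
#'
#' A pixel is foreground iff its intensity is strictly greater than `T`.
#'
#' @param img single-channel [intensity_image] or numeric matrix.
#' @param T threshold in `[0, 1]`.
#' @return logical matrix congruent with the image (the binary mask).
#' @export
binarize <- function(img, T) {
  stopifnot(is.numeric(T), length(T) == 1L, T >= 0, T <= 1)
  px <- as_pixels(img)
  if (length(dim(px)) != 2L) stop("binarize expects a single-channel image")
  px > T
}
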