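# Independent reference implementations used to check the package's
# primitives. They deliberately use different algorithms from the
# implementation (label propagation instead of BFS flood fill,
# numerical eigendecomposition instead of closed-form moments,
# value-space scans instead of histogram recursions).

# Connected-component labeling by iterated minimum-label propagation.
oracle_label <- function(mask, connectivity = 8L) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  lab[mask] <- seq_len(sum(mask))
  idx <- which(mask, arr.ind = TRUE)
  offs <- if (connectivity == 8L)
    rbind(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,1), c(1,-1), c(1,0), c(1,1))
  else rbind(c(-1,0), c(0,-1), c(0,1), c(1,0))
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(idx))) {
      r <- idx[k, 1]; c <- idx[k, 2]
      for (o in seq_len(nrow(offs))) {
        rr <- r + offs[o, 1]; cc <- c + offs[o, 2]
        if (rr >= 1 && rr <= h && cc >= 1 && cc <= w && mask[rr, cc] &&
            lab[rr, cc] < lab[r, c]) {
          lab[r, c] <- lab[rr, cc]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  lab
}

# canonical renumbering so two labelings can be compared directly:
# labels become 1..n in raster-scan order of first occurrence
canonical_labels <- function(lab) {
  seen <- unique(as.vector(lab)[as.vector(lab) > 0])
  out <- lab
  for (i in seq_along(seen)) out[lab == seen[i]] <- i
  out
}

# ellipse descriptors via numerical eigendecomposition of the corrected
# covariance of the pixel coordinates
oracle_moments <- function(px) {
  x <- px[, 2]; y <- px[, 1]
  n <- length(x)
  cxx <- mean((x - mean(x))^2) + 1 / 12
  cyy <- mean((y - mean(y))^2) + 1 / 12
  cxy <- mean((x - mean(x)) * (y - mean(y)))
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2), symmetric = TRUE)
  list(centroid = c(mean(y), mean(x)),
       major = 4 * sqrt(ev$values[1]),
       minor = 4 * sqrt(ev$values[2]),
       ecc = sqrt(1 - ev$values[2] / ev$values[1]))
}

# Otsu by direct minimization of pooled intra-class variance over the
# pixel values themselves; returns the split index k (threshold k/256)
oracle_otsu_bin <- function(v) {
  best <- Inf; best_k <- NA_integer_
  n <- length(v)
  for (k in 1:255) {
    t <- k / 256
    lo <- v[v < t]
    hi <- v[v >= t]
    if (length(lo) == 0 || length(hi) == 0) next
    pv <- function(z) if (length(z) > 1) mean((z - mean(z))^2) else 0
    intra <- (length(lo) * pv(lo) + length(hi) * pv(hi)) / n
    if (intra < best - 1e-15) { best <- intra; best_k <- k }
  }
  best_k
}

# rasterized annulus centred in a dims-sized mask
make_annulus_mask <- function(dims, center, r_out, r_in) {
  d2 <- outer((seq_len(dims[1]) - center[1])^2,
              (seq_len(dims[2]) - center[2])^2, "+")
  d2 <= r_out^2 & d2 > r_in^2
}
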