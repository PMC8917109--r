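test_that("matching is one-to-one and conserves counts", {
  tru <- ground_truth_set(centroids = cbind(c(10, 50, 90), c(10, 50, 90)))
  m <- match_detections(cbind(c(10, 50, 90), c(10, 50, 90)), tru)
  expect_equal(m$true_positive, 3L)
  expect_equal(m$false_positive, 0L)
  expect_equal(m$false_negative, 0L)

  m0 <- match_detections(cbind(numeric(), numeric()), tru)
  expect_equal(m0$true_positive, 0L)
  expect_equal(m0$false_negative, 3L)

  # two detections near one truth object: only one can match
  m2 <- match_detections(cbind(c(10, 12), c(10, 12)),
                         ground_truth_set(centroids = cbind(11, 11)))
  expect_equal(m2$true_positive, 1L)
  expect_equal(m2$false_positive, 1L)
  # the closer detection wins
  expect_equal(m2$pairs$detection_id, 1L)

  # conservation holds on random configurations
  set.seed(61)
  for (i in 1:10) {
    nd <- sample(0:12, 1); nt <- sample(0:12, 1)
    det <- cbind(runif(nd, 1, 100), runif(nd, 1, 100))
    tru <- ground_truth_set(centroids = cbind(runif(nt, 1, 100),
                                              runif(nt, 1, 100)))
    m <- match_detections(det, tru, max_dist_px = 30)
    expect_equal(m$true_positive + m$false_positive, nd)
    expect_equal(m$true_positive + m$false_negative, nt)
    expect_equal(anyDuplicated(m$pairs$detection_id), 0L)
    expect_equal(anyDuplicated(m$pairs$truth_id), 0L)
  }
})

test_that("centroid-in-region matching works through the label mask", {
  lm <- matrix(0L, 60, 60)
  lm[10:30, 10:30] <- 1L   # large truth region
  tru <- ground_truth_set(label_mask = lm)
  expect_equal(tru$n, 1L)
  expect_equal(unname(tru$centroids[1, ]), c(20, 20))
  # detection centroid 28 px away from the truth centroid but inside the
  # region: matched even though beyond max_dist_px
  m <- match_detections(cbind(29.6, 29.6), tru, max_dist_px = 5)
  expect_equal(m$true_positive, 1L)
  # outside the region and beyond the distance: unmatched
  m2 <- match_detections(cbind(45, 45), tru, max_dist_px = 5)
  expect_equal(m2$true_positive, 0L)
})

test_that("precision, recall and F-measure follow their defining ratios", {
  r <- precision_recall_f(list(true_positive = 89, false_positive = 11,
                               false_negative = 5))
  expect_equal(r$precision, 0.89)
  expect_equal(r$recall, 89 / 94, tolerance = 1e-12)
  expect_equal(r$f_measure, 2 * 0.89 * (89 / 94) / (0.89 + 89 / 94))

  # harmonic-mean identity and bracketing on random operating points
  set.seed(62)
  for (i in 1:25) {
    p <- runif(1, 0.01, 1); q <- runif(1, 0.01, 1)
    f <- f_measure(p, q)
    expect_equal(f, 2 * p * q / (p + q))
    expect_gte(f, min(p, q) - 1e-12)
    expect_lte(f, max(p, q) + 1e-12)
  }

  deg <- precision_recall_f(list(true_positive = 0, false_positive = 0,
                                 false_negative = 0))
  expect_equal(deg$precision, 0)
  expect_true(all(c("precision", "recall") %in% deg$degenerate))
})

test_that("Bland-Altman reports bias, 1.96-SD limits and correlation", {
  x <- c(3, 5, 9, 11)
  same <- bland_altman(x, x)
  expect_equal(same$bias, 0)
  expect_equal(same$loa_low, 0)
  expect_equal(same$loa_high, 0)

  # differences {+1, -1}: sample SD sqrt(2), limits +/- 1.96 sqrt(2)
  ba <- bland_altman(c(2, 3), c(1, 4))
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_high, 1.96 * sqrt(2))
  expect_equal(ba$loa_low, -1.96 * sqrt(2))

  # antisymmetry
  set.seed(63)
  a <- rnorm(20, 10, 2); b <- a + rnorm(20, 0.5, 1)
  f <- bland_altman(a, b); g <- bland_altman(b, a)
  expect_equal(f$bias, -g$bias)
  expect_equal(f$loa_low, -g$loa_high)
  expect_equal(f$loa_high, -g$loa_low)
  expect_equal(f$r, g$r)
  expect_true(f$loa_low <= f$bias && f$bias <= f$loa_high)

  expect_error(bland_altman(1, 2), "at least 2")
  cst <- bland_altman(c(1, 1, 1), c(2, 3, 4))
  expect_true(is.na(cst$r))
  expect_length(cst$degenerate, 1L)
})

test_that("z-scores standardize to mean 0 and unit sample SD", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(64)
  v <- rnorm(30, 50, 7)
  z <- zscore(v)
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_equal(zscore(3 * v + 11), z)   # affine invariance
  expect_error(zscore(rep(2, 5)), "zero standard deviation")
})

test_that("corrected total fluorescence subtracts area-scaled background", {
  expect_equal(ctgf(500, 50, 2), 400)
  expect_equal(ctgf(123.4, 10, 0), 123.4)
  # uniform ROI whose intensity equals the background mean nets zero
  expect_equal(ctgf(0.3 * 200, 200, 0.3), 0)
  # dim ROI on bright background goes negative and is returned as-is
  expect_lt(ctgf(10, 100, 1), 0)
})

test_that("positive-pixel fraction counts strictly above-threshold pixels in the ROI", {
  img <- array(0, c(10, 10, 3))
  img[, , 1][1:50] <- 0.9
  expect_equal(channel_positive_fraction(img, "red", 0.5), 0.5)
  expect_equal(channel_positive_fraction(img, "red", 0.95), 0)
  expect_equal(channel_positive_fraction(img, "green", 0.5), 0)
  roi <- matrix(FALSE, 10, 10); roi[1:5, 1:10] <- TRUE
  frac <- channel_positive_fraction(img, "red", 0.5, roi)
  expect_equal(frac, sum(img[, , 1][roi] > 0.5) / 50)
  expect_error(channel_positive_fraction(img, "red", 0.5,
                                         matrix(FALSE, 10, 10)), "empty")
})
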