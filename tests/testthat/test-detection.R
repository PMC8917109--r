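test_that("normalization maps the global range onto [0,1] jointly across channels", {
  raw <- array(0, c(4, 4, 3))
  raw[, , 1] <- 255; raw[, , 2] <- 128; raw[1, 1, 3] <- 0
  img <- normalize_image(raw)
  expect_equal(max(img$pixels), 1)
  expect_equal(min(img$pixels), 0)
  expect_equal(img$pixels[2, 2, 2], 128 / 255)

  m <- matrix(c(10, 110, 210, 60), 4, 4)
  n <- normalize_image(m)
  expect_equal(n$pixels[2, 1], 0.5)  # (110 - 10) / (210 - 10)

  expect_warning(z <- normalize_image(matrix(17, 5, 5)), "constant")
  expect_true(all(z$pixels == 0))
  expect_true(z$constant_input)
})

test_that("channel extraction returns the requested channel and rejects grayscale", {
  raw <- array(0, c(3, 3, 3))
  raw[, , 1] <- 0.8; raw[2, 2, 2] <- 0.9; raw[2, 2, 3] <- 0.1; raw[2, 2, 1] <- 0.2
  img <- intensity_image(raw, "rgb")
  expect_equal(as.vector(extract_channel(img, "red")$pixels[1, 1]), 0.8)
  expect_equal(as.vector(extract_channel(img, "green")$pixels[2, 2]), 0.9)
  expect_equal(extract_channel(img, "green")$channel_tag, "green")
  expect_error(extract_channel(matrix(0.5, 3, 3), "green"), "green")
})

test_that("3x3 mean filter averages neighborhoods and fixes constants", {
  m <- matrix(0, 7, 7); m[4, 4] <- 0.9
  s <- smooth_mean3x3(m)
  expect_equal(s[3:5, 3:5], matrix(0.9 / 9, 3, 3))
  expect_equal(sum(s), 0.9)  # mean filter conserves mass away from borders

  cimg <- matrix(0.37, 5, 6)
  expect_equal(smooth_mean3x3(cimg), cimg)
  expect_equal(smooth_mean3x3(matrix(1, 3, 3)), matrix(1, 3, 3))
})

test_that("Otsu threshold matches a brute-force intra-class variance scan", {
  img <- matrix(c(rep(0.2, 50), rep(0.8, 50)), 10, 10)
  T <- suggest_threshold(img)
  expect_gt(T, 0.2)
  expect_lt(T, 0.8)
  # bin-center-valued images: compare against the value-space oracle
  set.seed(11)
  for (i in 1:5) {
    v <- (sample(0:255, 400, replace = TRUE,
                 prob = c(rep(4, 64), rep(1, 128), rep(4, 64))) + 0.5) / 256
    img <- matrix(v, 20, 20)
    expect_equal(suggest_threshold(img), oracle_otsu_bin(v) / 256)
  }
  # permutation invariance
  set.seed(12)
  v <- runif(144)
  expect_equal(suggest_threshold(matrix(v, 12, 12)),
               suggest_threshold(matrix(sample(v), 12, 12)))
  expect_warning(T0 <- suggest_threshold(matrix(0.5, 4, 4)), "single-valued")
  expect_equal(T0, 0)
})

test_that("binarization is strict and monotone in the threshold", {
  img <- matrix(c(0.2, 0.8), 4, 4)
  expect_equal(binarize(img, 0.5), img > 0.5)
  expect_true(all(!binarize(img, 1)))
  expect_true(binarize(matrix(c(0.01, rep(0, 8)), 3, 3), 0)[1, 1])
  set.seed(3)
  img <- matrix(runif(400), 20, 20)
  counts <- vapply(seq(0, 1, by = 0.05), function(T) sum(binarize(img, T)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("connected components are 8-connected and match the propagation oracle", {
  m <- matrix(FALSE, 5, 5); m[2, 2] <- TRUE; m[3, 3] <- TRUE  # corner contact
  expect_equal(length(connected_components(m)), 1L)
  m2 <- matrix(FALSE, 3, 5); m2[2, 2] <- TRUE; m2[2, 4] <- TRUE
  expect_equal(length(connected_components(m2)), 2L)
  expect_equal(length(connected_components(matrix(FALSE, 4, 4))), 0L)

  set.seed(21)
  for (i in 1:20) {
    m <- matrix(runif(32 * 32) < runif(1, 0.2, 0.7), 32, 32)
    cs <- connected_components(m)
    expect_identical(canonical_labels(cs$labels),
                     canonical_labels(oracle_label(m, 8L)))
  }
  # component order is the raster-scan order of each first pixel
  m <- matrix(FALSE, 6, 6); m[5, 1] <- TRUE; m[1, 5] <- TRUE; m[3, 3] <- TRUE
  cs <- connected_components(m)
  firsts <- t(vapply(cs$pixel_lists, function(p) p[1, ], numeric(2)))
  expect_equal(firsts[, 1], c(1, 3, 5))
})

test_that("area filter partitions components exhaustively with inclusive bounds", {
  m <- matrix(FALSE, 40, 600)
  m[2, 1:5] <- TRUE                    # area 5
  m[10:19, 101:110] <- TRUE            # area 100
  m[21:40, 200:599] <- TRUE            # area 8000
  cs <- connected_components(m)
  f <- filter_by_area(cs, 50, 5000)
  expect_equal(component_areas(f$kept), 100L)
  expect_equal(component_areas(f$removed_small), 5L)
  expect_equal(component_areas(f$removed_large), 8000L)
  expect_equal(length(f$kept) + length(f$removed_small) + length(f$removed_large),
               length(cs))
  # boundary inclusive
  f2 <- filter_by_area(cs, 100, 8000)
  expect_setequal(component_areas(f2$kept), c(100L, 8000L))
  # identity band
  f3 <- filter_by_area(cs, 1, .Machine$integer.max)
  expect_equal(length(f3$kept), length(cs))
})

test_that("lumen recovery reintroduces hollow rings and honors the strict 12.5% rule", {
  # annulus r_out = 10, r_in = 6: hole 113 px, ring 204 px, ratio 0.554
  mask <- make_annulus_mask(c(40, 40), c(20, 20), 10, 6)
  cs <- connected_components(mask)
  expect_equal(component_areas(cs), 204L)
  rec <- recover_lumened_vessels(mask, cs, detection_params())
  expect_equal(length(rec), 1L)

  # solid disk: no hollow region, never reintroduced
  solid <- make_annulus_mask(c(40, 40), c(20, 20), 10, -1)
  cs2 <- connected_components(solid)
  expect_equal(length(recover_lumened_vessels(solid, cs2, detection_params())), 0L)

  # exact boundary: hole = 0.125 * component area does not fire;
  # one more hole pixel does
  expect_false(lumen_rule(7, 56, 0.125))
  expect_true(lumen_rule(8, 56, 0.125))
  ring9x7 <- matrix(TRUE, 7, 9)
  ring9x7[4, 2:8] <- FALSE  # 7-px enclosed hole, component area 56
  cs3 <- connected_components(ring9x7)
  circles <- data.frame(row = 4, col = 5, r = 8, score = 1)
  expect_equal(length(reintroduce_components(cs3, circles, 0.125)), 0L)
  ring2 <- matrix(TRUE, 7, 10)
  ring2[4, 2:9] <- FALSE    # 8-px hole, component area 62: 8/62 > 0.125
  cs4 <- connected_components(ring2)
  expect_equal(length(reintroduce_components(cs4, circles, 0.125)), 1L)
})

test_that("Hough transform finds circle centers and radii on rasterized rings", {
  mask <- make_annulus_mask(c(64, 64), c(30, 33), 12, 8)
  circ <- hough_circles(mask, 5, 20)
  expect_gt(nrow(circ), 0)
  best <- circ[1, ]
  expect_lte(abs(best$row - 30), 2)
  expect_lte(abs(best$col - 33), 2)
  expect_true(best$r %in% 6:14)  # inner and outer walls are both circles
  expect_equal(nrow(hough_circles(matrix(FALSE, 20, 20), 5, 10)), 0L)
})

test_that("closing bridges small gaps and matches an independent implementation", {
  # C shape: interior connects to border background, fill leaves it open
  cshape <- matrix(FALSE, 12, 12)
  cshape[3:9, 3] <- TRUE; cshape[3, 3:9] <- TRUE; cshape[9, 3:9] <- TRUE
  expect_equal(close_and_fill(cshape) & !cshape, matrix(FALSE, 12, 12))

  # closed ring becomes a filled disk
  ring <- make_annulus_mask(c(30, 30), c(15, 15), 9, 6)
  filled <- close_and_fill(ring)
  expect_true(all(filled[make_annulus_mask(c(30, 30), c(15, 15), 6, -1)]))

  # already-solid convex blob unchanged; on staircase boundaries the
  # operation is extensive and idempotent
  rect <- matrix(FALSE, 20, 20); rect[5:15, 4:17] <- TRUE
  expect_equal(close_and_fill(rect), rect)
  blob <- make_annulus_mask(c(30, 30), c(15, 15), 8, -1)
  once <- close_and_fill(blob)
  expect_true(all(once[blob]))
  expect_equal(close_and_fill(once), once)

  # cross-check against an independent implementation on random masks;
  # masks keep a clear 2-px margin because the reference library pads
  # image borders differently (our erosion treats out-of-bounds as
  # foreground, the morphological convention that keeps closing extensive)
  skip_if_not_installed("EBImage")
  set.seed(31)
  for (i in 1:10) {
    m <- matrix(runif(900) < 0.4, 30, 30)
    m[c(1:2, 29:30), ] <- FALSE
    m[, c(1:2, 29:30)] <- FALSE
    mine <- erode3x3(dilate3x3(m))
    ref <- EBImage::closing(m * 1, EBImage::makeBrush(3, "box")) > 0.5
    expect_identical(mine, ref)
  }
})

test_that("hole filling fills only background not 4-connected to the border", {
  m <- matrix(FALSE, 9, 9)
  m[c(3, 5), 3:5] <- TRUE; m[4, c(3, 5)] <- TRUE   # 1-px enclosed hole
  expect_true(fill_holes(m)[4, 4])
  # diagonal gap: background leaks through for 4-connectivity, no fill
  g <- matrix(FALSE, 7, 7)
  g[2:6, 2] <- TRUE; g[2, 2:6] <- TRUE; g[2:6, 6] <- TRUE; g[6, 2:5] <- TRUE
  g[6, 5] <- FALSE; g[5, 6] <- FALSE  # open a diagonal gap at the corner
  expect_false(all(fill_holes(g)[3:5, 3:5]))
})

test_that("detect_vessels is deterministic, bounded and counts phantom vessels", {
  expect_warning(d0 <- detect_vessels(array(0, c(32, 32, 3))), "constant")
  expect_equal(nrow(d0$vessels), 0L)

  ph <- generate_phantom(phantom_spec(dims = c(256L, 256L), n_vessels = 8,
                                      radius_range_px = c(5, 14),
                                      noise_sigma = 0, seed = 5))
  d1 <- detect_vessels(ph$image, detection_params(channel = "red"))
  d2 <- detect_vessels(ph$image, detection_params(channel = "red"))
  expect_identical(d1$vessels, d2$vessels)
  expect_identical(d1$labels, d2$labels)
  expect_equal(nrow(d1$vessels), 8L)

  # every reported vessel is within bounds and at least the minimum area
  expect_true(all(d1$vessels$area_px >= d1$params$min_area_px))
  expect_true(all(d1$vessels$centroid_row >= 1 &
                  d1$vessels$centroid_row <= d1$dims[1]))
  expect_true(all(d1$vessels$centroid_col >= 1 &
                  d1$vessels$centroid_col <= d1$dims[2]))

  # stage errors carry the stage name
  suppressWarnings(expect_error(detect_vessels(matrix(1, 2, 2)), "normalize"))
})
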