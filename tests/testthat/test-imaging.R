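# BF processing: background subtraction, mean-based binarisation, blob
# detection and the four BF biomarkers against analytic fixtures.

op05 <- optics_model(noise_sd = 0)  # 0.5 um/px

test_that("subtract_background is the absolute deviation", {
  bg <- matrix(100, 10, 10)
  expect_true(all(subtract_background(bg, bg) == 0))
  fr <- bg; fr[3, 4] <- 110
  d <- subtract_background(fr, bg)
  expect_equal(d[3, 4], 10)
  expect_equal(sum(d), 10)
  fr[3, 4] <- 90
  expect_equal(subtract_background(fr, bg)[3, 4], 10)
  expect_error(subtract_background(matrix(0, 2, 2), bg), "dimensions")
})

test_that("binarize_bf thresholds at k times the grid mean", {
  expect_false(any(binarize_bf(matrix(0, 50, 50))))
  g <- matrix(0, 100, 100)
  g[40, 40] <- 100  # mean 0.01, threshold 0.03
  m <- binarize_bf(g, k = 3)
  expect_identical(sum(m), 1L)
  expect_true(m[40, 40])
  expect_false(any(binarize_bf(matrix(5, 20, 20), k = 3)))
  expect_error(binarize_bf(matrix(-1, 2, 2)), "nonnegative")
})

test_that("detect_blobs: connectivity, size floor, hole filling", {
  m <- matrix(FALSE, 40, 40)
  m[2:11, 2:11] <- TRUE
  m[20:29, 20:29] <- TRUE
  expect_length(detect_blobs(m, op05)$blobs, 2)

  tiny <- matrix(FALSE, 10, 10)
  tiny[4:5, 4:5] <- TRUE  # 4 px = 1 um^2 < 10 um^2 floor
  expect_length(detect_blobs(tiny, op05)$blobs, 0)

  diag2 <- matrix(FALSE, 12, 12)
  diag2[3:5, 3:5] <- TRUE
  diag2[6:12, 6:12] <- TRUE  # touch only at one diagonal corner
  expect_length(detect_blobs(diag2, op05, min_area_um2 = 0)$blobs, 1)

  ring <- rect_mask(12, 12)
  ring[8:11, 8:11] <- FALSE  # interior hole
  b <- single_blob(ring, op05)
  expect_equal(measure_area(b, op05), 12 * 12 * 0.25)  # hole filled
})

test_that("area matches pixel-count and analytic-disk oracles", {
  sq <- rect_mask(20, 20)
  expect_equal(measure_area(single_blob(sq, op05), op05), 100)
  dk <- disk_mask(20)
  a <- measure_area(single_blob(dk, op05), op05)
  expect_lt(abs(a - pi * 10^2) / (pi * 10^2), 0.05)
  expect_error(measure_area(list(pixels = NULL), op05), "empty")
})

test_that("Crofton perimeter is within tolerance of analytic shapes", {
  dk <- disk_mask(20)  # r = 10 um at 0.5 um/px
  p <- measure_perimeter(single_blob(dk, op05), op05)
  expect_lt(abs(p - 2 * pi * 10) / (2 * pi * 10), 0.08)
  sq <- rect_mask(20, 20)  # 10 um side
  p2 <- measure_perimeter(single_blob(sq, op05), op05)
  expect_lt(abs(p2 - 40) / 40, 0.08)
  # floor-sized blob still yields a positive finite value
  fl <- rect_mask(7, 6)  # 42 px > 10 um^2
  p3 <- measure_perimeter(single_blob(fl, op05), op05)
  expect_true(is.finite(p3) && p3 > 0)
})

test_that("aspect ratio from the minimum-area rotated rectangle", {
  expect_equal(measure_aspect_ratio(single_blob(rect_mask(20, 20), op05)),
               1, tolerance = 0.05)
  expect_equal(measure_aspect_ratio(single_blob(rect_mask(10, 40), op05)),
               4, tolerance = 0.1 / 4)
  expect_equal(measure_aspect_ratio(single_blob(disk_mask(15), op05)),
               1, tolerance = 0.05)
  # rotated rectangle: a diagonal bar must not read as square
  bar <- disks_mask(cbind(seq(10, 40, length.out = 16),
                          seq(10, 40, length.out = 16)), 3, 50, 50)
  expect_gt(measure_aspect_ratio(single_blob(bar, op05)), 2.5)
})

test_that("watershed cell counting recovers disk unions", {
  # single cell: disk radius 4 um = 8 px
  one <- disk_mask(8)
  expect_identical(estimate_cell_count_bf(single_blob(one, op05), op05), 1L)
  # two overlapping disks (radius 5.5 um), centres 10 um apart
  two <- disks_mask(cbind(c(25, 25), c(20, 40)), 11, 50, 62)
  expect_identical(estimate_cell_count_bf(single_blob(two, op05), op05), 2L)
  # small attached bump (3 um^2 = 12 px, r ~ 2 px) stays below the floor
  bump <- disk_mask(8, dim = 30)
  bump <- bump | disks_mask(cbind(15.5, 24.5), 1.95, 30, 30)
  expect_identical(estimate_cell_count_bf(single_blob(bump, op05), op05), 1L)
})

test_that("cell counts exact for 1-4 disks at >= 8 um spacing", {
  for (n in 1:4) {
    centers <- cbind(25, 16 * (0:(n - 1)) + 15)  # 8 um spacing at 0.5 um/px
    m <- disks_mask(centers, 9, 50, 16 * n + 30)  # radius 4.5 um, overlapping
    expect_identical(
      estimate_cell_count_bf(single_blob(m, op05), op05), as.integer(n),
      label = paste(n, "disks"))
  }
})

test_that("blob properties: disjointness, isoperimetry, rotation", {
  set.seed(21)
  pop <- default_population(11, "positive")
  st <- stream_model(frame_height = op05$frame_height)
  for (rep in 1:5) {
    objs <- replicate(4, sample_object(pop, op05), simplify = FALSE)
    fp <- render_frame_pair(objs, op05, st)
    d <- subtract_background(fp$bf, op05$bf_background_level)
    bs <- detect_blobs(binarize_bf(d), op05)
    # blobs partition their pixels: no label overlap by construction,
    # total area bounded by foreground + filled holes
    areas <- vapply(bs$blobs, measure_area, 0, op05)
    expect_equal(sum(bs$labels > 0), sum(vapply(bs$blobs, function(b)
      nrow(b$pixels), 0L)))
    for (b in bs$blobs) {
      ar <- measure_aspect_ratio(b)
      expect_gte(ar, 1)
      # 90 degree rotation invariance of the aspect ratio
      rot <- cbind(b$pixels[, 2], max(b$pixels[, 1]) + 1 - b$pixels[, 1])
      ar90 <- measure_aspect_ratio(list(pixels = rot))
      expect_lt(abs(ar - ar90) / ar, 0.02)
    }
  }
  # isoperimetric sanity for rendered disks
  for (rpx in c(6, 10, 16, 24)) {
    b <- single_blob(disk_mask(rpx), op05)
    a <- measure_area(b, op05)
    p <- measure_perimeter(b, op05)
    expect_gte(p^2 / (4 * pi * a), 0.9)
  }
})

test_that("noise-free frames give perfect blob recall and 10% areas", {
  cfg <- quiet_config()
  set.seed(77)
  pop <- default_population(11, "positive")
  bg <- background_model(cfg$optics)
  total_truth <- 0L
  total_found <- 0L
  for (i in 1:10) {
    objs <- replicate(3, sample_object(pop, cfg$optics), simplify = FALSE)
    fp <- render_frame_pair(objs, cfg$optics, cfg$stream)
    rec <- analyze_frame_pair(fp, bg, cfg)
    total_truth <- total_truth + nrow(fp$truth)
    total_found <- total_found + nrow(rec)
    # match by nearest centroid; every truth object recovered
    for (j in seq_len(nrow(fp$truth))) {
      d2 <- (rec$centroid_row - fp$truth$centroid_row[j])^2 +
        (rec$centroid_col - fp$truth$centroid_col[j])^2
      k <- which.min(d2)
      expect_lt(sqrt(d2[k]), 3)
      if (fp$truth$true_area[j] >= 40 * cfg$optics$pixel_size^2)
        expect_lt(abs(rec$area_um2[k] - fp$truth$true_area[j]) /
                    fp$truth$true_area[j], 0.1)
    }
  }
  expect_identical(total_found, total_truth)  # precision = recall = 100%
})
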