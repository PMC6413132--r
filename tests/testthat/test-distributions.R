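# Histogram construction, peak detection, band fractions, joint
# cell/nucleus maps, average cell size and total-variation comparison.

test_that("build_histogram: half-open percent bins summing to 100", {
  h <- build_histogram(c(15, 15, 55, 55), "area")
  expect_equal(h$N, 4)
  expect_equal(h$freq_pct[1], 50)  # [10, 30)
  expect_equal(h$freq_pct[3], 50)  # [50, 70)
  expect_equal(sum(h$freq_pct), 100, tolerance = 1e-9)
  h0 <- build_histogram(numeric(0), "area")
  expect_equal(h0$N, 0)
  expect_true(all(h0$freq_pct == 0))
  # boundary values land in the right (upper) bin
  hb <- build_histogram(c(30, 29.999), "area")
  expect_equal(hb$counts[1:2], c(1L, 1L))
  # below-origin values fall outside the binned range
  hd <- build_histogram(c(5, 15), "area")
  expect_equal(hd$N, 1)
})

test_that("histogram frequencies match a direct counting oracle", {
  set.seed(101)
  x <- rlnorm(10000, log(60), 0.5)
  x <- x[x >= 10]
  h <- build_histogram(x, "area")
  # independent oracle: explicit per-bin comparison count
  for (i in seq_along(h$counts)) {
    lo <- h$breaks[i]; hi <- h$breaks[i + 1]
    expect_identical(h$counts[i], sum(x >= lo & x < hi))
  }
  expect_equal(sum(h$freq_pct), 100, tolerance = 1e-9)
})

test_that("detect_peaks finds planted modes and ignores flat input", {
  # unimodal
  h1 <- build_histogram(rep(c(55, 75), c(80, 20)), "area")
  p1 <- detect_peaks(h1)
  expect_identical(nrow(p1), 1L)
  expect_equal(p1$bin_center, 60)
  # two planted modes at 60 and 180 um^2
  set.seed(5)
  x <- c(rnorm(6000, 60, 8), rnorm(1500, 180, 12))
  x <- x[x >= 10]
  p2 <- detect_peaks(build_histogram(x, "area"))
  expect_identical(nrow(p2), 2L)
  expect_lte(abs(p2$bin_center[1] - 60), 20)
  expect_lte(abs(p2$bin_center[2] - 180), 20)
  # flat histogram: no peaks
  hf <- build_histogram(rep(seq(15, 195, 20), each = 10), "area")
  expect_identical(nrow(detect_peaks(hf)), 0L)
  # empty histogram: no peaks
  expect_identical(nrow(detect_peaks(build_histogram(numeric(0), "area"))),
                   0L)
})

test_that("band fractions and the irregular-cell fraction", {
  rec <- data.frame(area_um2 = c(rep(60, 99), 200),
                    nucleus_count = c(rep(1L, 99), 2L))
  bf <- band_fractions(rec)
  expect_equal(bf$irregular_fraction_pct, 100 * 1 / 99)
  expect_equal(bf$counts[["wbc"]], 99L)
  expect_equal(sum(bf$percent), 100)
  # no clusters
  rec2 <- data.frame(area_um2 = rep(60, 10), nucleus_count = rep(1L, 10))
  expect_equal(band_fractions(rec2)$irregular_fraction_pct, 0)
  # no wbc: undefined flag
  rec3 <- data.frame(area_um2 = rep(20, 5), nucleus_count = rep(1L, 5))
  bf3 <- band_fractions(rec3)
  expect_true(is.na(bf3$irregular_fraction_pct))
  expect_false(bf3$irregular_defined)
})

test_that("cell-count/nucleus-count map splits diagonal masses", {
  rec <- data.frame(cell_count_bf = c(1L, 1L, 1L, 3L, 2L),
                    nucleus_count = c(1L, 1L, 1L, 0L, 3L))
  m <- cellcount_nucleus_map(rec)
  expect_equal(m$diagonal_pct, 60)
  expect_equal(m$below_diagonal_pct, 20)  # (3, 0) debris-suspect
  expect_equal(m$above_diagonal_pct, 20)  # (2, 3) multinucleate
  expect_equal(sum(m$table$frequency_pct), 100)
  m1 <- cellcount_nucleus_map(data.frame(cell_count_bf = rep(1L, 4),
                                         nucleus_count = rep(1L, 4)))
  expect_equal(m1$diagonal_pct, 100)
})

test_that("average cell size divides by nucleus count with debris guard", {
  expect_equal(average_cell_size(200, 2L), 100)
  expect_equal(average_cell_size(60, 0L), 60)
  expect_equal(average_cell_size(180, 3L), 60)
  expect_equal(average_cell_size(c(200, 60), c(2L, 0L)), c(100, 60))
})

test_that("total-variation comparison: identity, disjointness, padding", {
  a <- build_histogram(c(15, 35, 55), "area")
  expect_equal(compare_distributions(a, a)$tv, 0)
  b <- build_histogram(c(95, 115), "area")
  expect_equal(compare_distributions(a, b)$tv, 1)
  # differing bin counts are padded, not an error
  expect_equal(compare_distributions(b, a)$tv, 1)
  expect_error(compare_distributions(a, build_histogram(1.1,
                                                        "aspect_ratio")),
               "bin conventions")
})

test_that("generator replicates are distributionally stable (TV < 0.05)", {
  pop <- default_population(11, "positive")
  op <- optics_model()
  a <- sample_objects(4000, pop, op, seed = 31)
  b <- sample_objects(4000, pop, op, seed = 32)
  ha <- build_histogram(vapply(a, `[[`, 0, "true_area"), "area")
  hb <- build_histogram(vapply(b, `[[`, 0, "true_area"), "area")
  expect_lt(compare_distributions(ha, hb)$tv, 0.05)
  # count stability is assessed under smoothing: unsmoothed, the 0.2-pp
  # prominence floor sits ~2 SE above per-bin noise at this n
  expect_identical(nrow(detect_peaks(ha, smoothing_window = 3)),
                   nrow(detect_peaks(hb, smoothing_window = 3)))
})

test_that("timecourse summary assembles days and symmetric TV matrix", {
  set.seed(8)
  mk <- function(n, shift = 0) data.frame(
    area_um2 = pmax(10, rlnorm(n, log(60 + shift), 0.3)),
    nucleus_count = rep(1L, n))
  ts <- timecourse_summary(list(`2` = mk(300), `7` = mk(300, 40),
                                `11` = mk(300, 120)))
  expect_identical(names(ts$histograms), c("2", "7", "11"))
  expect_equal(ts$tv_distance, t(ts$tv_distance))
  expect_true(all(diag(ts$tv_distance) == 0))
  expect_true(all(ts$tv_distance >= 0 & ts$tv_distance <= 1))
  # larger day shift, larger distance
  expect_gt(ts$tv_distance["2", "11"], ts$tv_distance["2", "7"])
})
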