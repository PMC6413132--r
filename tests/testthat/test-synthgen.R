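# Synthetic paired-frame generator: mixtures, geometry, rendering,
# determinism.

test_that("debris components carry no nuclei and clusters enough", {
  op <- optics_model(noise_sd = 0)
  pop_debris <- population_model(list(
    pop_component("rbc_debris", 1, area_median = 20, area_log_sd = 0.2,
                  area_range = c(10, 30))))
  set.seed(7)
  for (i in 1:20) {
    ob <- sample_object(pop_debris, op)
    expect_identical(ob$true_nucleus_count, 0L)
    expect_identical(ob$true_cell_count, 0L)
    expect_false(any(ob$nuc_mask))
  }
  pop_cl <- population_model(list(
    pop_component("cluster", 1, area_median = 100, area_log_sd = 0.1,
                  area_range = c(88, 250), cell_counts = 3L,
                  cell_count_probs = 1, nuclei_per_cell_probs = c(0.5, 0.5))))
  for (i in 1:20) {
    ob <- sample_object(pop_cl, op)
    expect_identical(ob$true_cell_count, 3L)
    expect_gte(ob$true_nucleus_count, 3L)
  }
})

test_that("component proportions match weights (multinomial oracle)", {
  pop <- default_population(11, "positive")
  w <- vapply(pop$components, `[[`, 0, "weight")
  set.seed(1)
  op <- optics_model(noise_sd = 0)
  n <- 10000
  labs <- vapply(seq_len(n),
                 function(i) sample_object(pop, op)$label, "")
  for (comp in names(w)) {
    p_hat <- mean(labs == comp)
    se <- sqrt(w[comp] * (1 - w[comp]) / n)
    expect_lt(abs(p_hat - w[comp]), 3 * se + 1e-12,
              label = paste("proportion of", comp))
  }
})

test_that("rasterised area agrees with analytic disk area", {
  op <- optics_model(noise_sd = 0)
  pop <- population_model(list(
    pop_component("wbc", 1, area_median = 60, area_log_sd = 0.1,
                  area_range = c(50, 70),
                  nuclei_per_cell_probs = 1)))
  set.seed(42)
  for (i in 1:50) {
    ob <- sample_object(pop, op)
    analytic <- pi * ob$cells[1, "r"]^2
    expect_gt(sum(ob$mask), 40)  # all wbc exceed 40 px at 0.5 um/px
    expect_lt(abs(ob$true_area - analytic) / analytic, 0.1)
    expect_equal(sum(ob$mask) * op$pixel_size^2, ob$true_area)
  }
})

test_that("empty and debris-only frames render background exactly", {
  op <- optics_model(noise_sd = 0)
  st <- stream_model(frame_height = op$frame_height)
  fp0 <- render_frame_pair(list(), op, st)
  expect_true(all(fp0$bf == op$bf_background_level))
  expect_true(all(fp0$fl == op$fl_background_level))
  expect_identical(nrow(fp0$truth), 0L)

  pop_debris <- population_model(list(
    pop_component("rbc_debris", 1, area_median = 20, area_log_sd = 0.2,
                  area_range = c(10, 30))))
  set.seed(3)
  fp <- render_frame_pair(list(sample_object(pop_debris, op)), op, st)
  expect_true(all(fp$fl == op$fl_background_level))
  expect_true(any(fp$bf != op$bf_background_level))
})

test_that("a 2-cell cluster renders exactly 2 FL components (flood oracle)", {
  op <- optics_model(noise_sd = 0)
  st <- stream_model(frame_height = op$frame_height)
  pop <- population_model(list(
    pop_component("cluster", 1, area_median = 100, area_log_sd = 0.1,
                  area_range = c(88, 250), cell_counts = 2L,
                  cell_count_probs = 1, nuclei_per_cell_probs = 1)))
  set.seed(11)
  for (i in 1:10) {
    ob <- sample_object(pop, op)
    fp <- render_frame_pair(list(ob), op, st)
    fl_fg <- fp$fl - op$fl_background_level > 16
    expect_identical(flood_count(fl_fg), 2L)
    # nucleus pixels sit inside the BF footprint
    expect_true(all(fp$labels[fl_fg] > 0))
  }
})

test_that("nucleus fluorescence never leaks outside object footprints", {
  cfg <- quiet_config()
  set.seed(5)
  pop <- default_population(11, "positive")
  st <- cfg$stream
  for (i in 1:10) {
    objs <- replicate(3, sample_object(pop, cfg$optics), simplify = FALSE)
    fp <- render_frame_pair(objs, cfg$optics, st)
    hot <- fp$fl - cfg$optics$fl_background_level > 16
    expect_true(all(fp$labels[hot] > 0))
  }
})

test_that("generate_stream is bit-reproducible and respects spacing", {
  op <- optics_model(noise_sd = 1)
  st <- stream_model(frame_height = op$frame_height)
  pop <- default_population(11, "positive")
  a <- generate_stream(pop, op, st, n_frames = 20, seed = 123)
  b <- generate_stream(pop, op, st, n_frames = 20, seed = 123)
  expect_identical(a$truth, b$truth)
  for (i in seq_along(a$frames)) {
    expect_identical(a$frames[[i]]$bf, b$frames[[i]]$bf)
    expect_identical(a$frames[[i]]$fl, b$frames[[i]]$fl)
  }
  # neighbour spacing within each frame
  spacing_px <- st$min_spacing_um / op$pixel_size
  for (f in unique(a$truth$frame)) {
    cols <- sort(a$truth$centroid_col[a$truth$frame == f])
    if (length(cols) > 1)
      expect_gte(min(diff(cols)), spacing_px - 5)
  }
})

test_that("arrival process totals follow the Poisson oracle", {
  op <- optics_model(noise_sd = 0)
  st <- stream_model(arrival_rate = 2, frame_height = op$frame_height)
  pop <- default_population(11, "control")
  sim <- generate_stream(pop, op, st, n_frames = 1000, seed = 9)
  expected <- 2 * 1000
  expect_lt(abs(nrow(sim$truth) - expected), 3 * sqrt(expected))
  # rate 0 gives empty frames
  st0 <- stream_model(arrival_rate = 0, frame_height = op$frame_height)
  sim0 <- generate_stream(pop, op, st0, n_frames = 5, seed = 1)
  expect_identical(nrow(sim0$truth), 0L)
})

test_that("day-11 positive mixture places the tumour components", {
  pop <- default_population(11, "positive")
  labs <- names(pop$components)
  expect_true("cluster" %in% labs && "large_single" %in% labs)
  cl <- pop$components$cluster
  expect_true(all(cl$cell_counts >= 2))
  # minimum 2-cell union area stays at/above the cluster band edge:
  # two equal disks with centres 1.2 r apart overlap by ~14.3% of their
  # summed area (lens-area formula), so union >= 0.857 * 2 * a_min
  expect_gte(0.857 * 2 * cl$area_range[1], 150)
  ls <- pop$components$large_single
  expect_gte(ls$area_range[1], 90)
  expect_lte(ls$area_range[2], 130)
  # invalid configurations are rejected
  expect_error(pop_component("rbc_debris", 1, 20, 0.2,
                             nuclei_per_cell_probs = 1),
               "no nuclei")
  expect_error(pop_component("wbc", 1, 60, 0.1, area_range = c(0, 70)))
  expect_error(population_model(list(
    pop_component("wbc", 0.5, 60, 0.1, nuclei_per_cell_probs = 1))),
    "sum to 1")
})
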