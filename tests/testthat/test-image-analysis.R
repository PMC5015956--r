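test_that("grid detection recovers a perfect Gaussian-spot lattice within 1 px", {
  lay <- plate_layout(96)
  sp <- spot_lattice(lay, px = 20)
  g <- detect_grid(sp$img, lay)
  expect_s3_class(g, "plate_grid")
  expect_lt(max(abs(g$centers_y - sp$centers_y)), 1)
  expect_lt(max(abs(g$centers_x - sp$centers_x)), 1)
  expect_equal(g$pitch, c(20, 20), tolerance = 0.02)
})

test_that("grid detection completes the lattice when 10% of spots are missing", {
  lay <- plate_layout(96)
  set.seed(5)
  drop <- sample(96, 10)
  sp <- spot_lattice(lay, px = 20, drop = drop)
  g <- detect_grid(sp$img, lay)
  expect_length(g$centers_y, lay$rows)
  expect_length(g$centers_x, lay$cols)
  expect_lt(max(abs(g$centers_y - sp$centers_y)), 2)
  expect_lt(max(abs(g$centers_x - sp$centers_x)), 2)
})

test_that("grid detection fails informatively on blank images", {
  lay <- plate_layout(96)
  blank <- opacity_image(matrix(3, 160, 240), time = 1)
  expect_error(detect_grid(blank, lay), "gridding failure")
  # pure noise, no lattice
  set.seed(1)
  noise <- opacity_image(matrix(rnorm(160 * 240, 10, 6), 160, 240), time = 1)
  expect_error(detect_grid(noise, lay), "gridding failure")
})

test_that("segmentation partitions the window and finds the centered disc", {
  grid <- single_window_grid(41)
  img <- opacity_image(draw_discs(c(41, 41), cbind(21, 21), 6, 50), time = 0)
  seg <- segment_colony(img, grid, 0, 0, margin = 2)
  masks <- seg$colony + seg$background + seg$trash
  expect_true(all(masks == 1))           # exact partition
  truth_disc <- draw_discs(c(41, 41), cbind(21, 21), 6, 1) == 1
  expect_equal(seg$colony, truth_disc)
  # the dilated safety ring is never background
  ring <- draw_discs(c(41, 41), cbind(21, 21), 8, 1) == 1 & !truth_disc
  expect_false(any(seg$background & ring))
  expect_true(all(seg$trash[ring] | seg$colony[ring]))
})

test_that("uniform windows yield an empty colony; off-center blobs become trash", {
  grid <- single_window_grid(41)
  flat <- opacity_image(matrix(7, 41, 41), time = 0)
  seg <- segment_colony(flat, grid, 0, 0)
  expect_equal(sum(seg$colony), 0L)
  expect_true(all(seg$background))
  two <- opacity_image(
    draw_discs(c(41, 41), rbind(c(21, 21), c(5, 5)), c(6, 3), c(50, 80)),
    time = 0)
  seg2 <- segment_colony(two, grid, 0, 0)
  truth_disc <- draw_discs(c(41, 41), cbind(21, 21), 6, 1) == 1
  expect_equal(seg2$colony, truth_disc)          # center disc is the colony
  corner <- draw_discs(c(41, 41), cbind(5, 5), 3, 1) == 1
  expect_true(all(seg2$trash[corner]))           # corner disc is trash
})

test_that("colony measurement is background-subtracted sum of calibrated pixels", {
  grid <- single_window_grid(41)
  cal <- identity_cell_cal()
  disc <- draw_discs(c(41, 41), cbind(21, 21), 6, 1) == 1
  n <- sum(disc)
  img <- opacity_image(draw_discs(c(41, 41), cbind(21, 21), 6, 50), time = 2)
  seg <- segment_colony(img, grid, 0, 0)
  m <- measure_colony(seg, img, cal)
  expect_equal(m$population, n * 50)
  expect_equal(m$area_px, n)
  expect_equal(m$background, 0)
  expect_equal(m$time, 2)
  # over a uniform background b: population = n * (o - b)
  imgb <- opacity_image(
    draw_discs(c(41, 41), cbind(21, 21), 6, 50, background = 8), time = 2)
  segb <- segment_colony(imgb, grid, 0, 0)
  mb <- measure_colony(segb, imgb, cal)
  expect_equal(mb$population, n * (50 - 8))
  expect_equal(mb$background, 8)
  # linear calibration slope 2 doubles the cell estimate
  cal2 <- fit_cell_calibration(seq(1, 50, length.out = 10),
                               2 * seq(1, 50, length.out = 10), degree = 1)
  m2 <- measure_colony(seg, img, cal2)
  expect_equal(m2$population, 2 * n * 50, tolerance = 1e-9)
})

test_that("measurement recovers rendered populations within 3% under pixel noise", {
  lay <- plate_layout(96)
  sim <- simulate_growth_curves(lay, bias_amplitude = 0, pinning_cv = 0,
                                noise_cv = 0, t_end = 6, interval_min = 60,
                                seed = 9)
  imgs <- render_plate_series(sim, px_per_colony = 24, pixel_noise_sd = 1,
                              seed = 10)
  cal <- identity_cell_cal()
  g <- detect_grid(imgs[[length(imgs)]], lay)
  last <- length(imgs)
  errs <- vapply(seq_len(20), function(i) {
    seg <- segment_colony(imgs[[last]], g, sim$truth$row[i], sim$truth$col[i])
    m <- measure_colony(seg, imgs[[last]], cal)
    abs(m$population - sim$true_pop[i, last]) / sim$true_pop[i, last]
  }, numeric(1))
  expect_lt(max(errs), 0.03)
})

test_that("series analysis reuses the last image's grid and matches ground truth", {
  lay <- plate_layout(96)
  sim <- simulate_growth_curves(lay, bias_amplitude = 0, pinning_cv = 0.05,
                                noise_cv = 0, t_end = 8, interval_min = 60,
                                seed = 3)
  imgs <- render_plate_series(sim, px_per_colony = 24, pixel_noise_sd = 0,
                              seed = 4)
  ser <- analyze_series(imgs, lay, identity_cell_cal())
  expect_equal(nrow(ser), 96L * length(imgs))
  expect_true(all(ser$valid))
  truth_flat <- as.vector(t(sim$true_pop))
  expect_equal(ser$population_cells, truth_flat, tolerance = 1e-9)
  expect_gt(cor(ser$population_cells, truth_flat), 0.99)
  curves <- series_to_curves(ser)
  expect_length(curves, 96L)
  expect_length(curves[[1]]$times, length(imgs))
})

test_that("series analysis validates its inputs", {
  lay <- plate_layout(96)
  sim <- simulate_growth_curves(lay, bias_amplitude = 0, noise_cv = 0,
                                t_end = 2, interval_min = 60, seed = 3)
  imgs <- render_plate_series(sim, px_per_colony = 24, pixel_noise_sd = 0,
                              seed = 4)
  # single image: curves of length 1
  ser1 <- analyze_series(imgs[3], lay, identity_cell_cal())
  expect_equal(nrow(ser1), 96L)
  # unsorted timestamps rejected
  bad <- imgs[c(2, 1, 3)]
  expect_error(analyze_series(bad, lay, identity_cell_cal()),
               "strictly increasing")
})

test_that("plate images survive a 16-bit file round trip", {
  lay <- plate_layout(96)
  sp <- spot_lattice(lay, px = 20)
  path <- withr::local_tempfile(fileext = ".tif")
  write_plate_image(sp$img, path, max_opacity = 120)
  back <- read_plate_image(path, time = 1)
  # stored as 16-bit fractions of 255: rescale to compare
  rel <- max(abs(back$opacity / 255 * 120 - sp$img$opacity))
  expect_lt(rel, 120 / 65535 * 2)
})
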