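test_that("a single dome segment yields exactly one footprint", {
  g <- generate_plate(plate_params(
    image_size_px = 340, dish_outer_diameter_mm = 30, n_colonies = 1,
    group_fraction = 0, border_fraction = 0, artifact_count = 0, seed = 6))
  d <- small_detect(g)
  expect_equal(nrow(d$fps$footprints), 1)
  expect_equal(d$fps$footprints$n_colonies_in_parent_segment, 1L)
})

test_that("touching pairs split into footprints near the true centres", {
  g <- generate_plate(plate_params(
    image_size_px = 340, dish_outer_diameter_mm = 30, n_colonies = 2,
    group_fraction = 1, border_fraction = 0, artifact_count = 0,
    colony_radius_range_mm = c(1.2, 1.8), seed = 17))
  co <- g$truth$colonies
  expect_true(all(!is.na(co$group_id)))  # the two colonies form one group
  d <- small_detect(g)
  fp <- d$fps$footprints
  expect_equal(nrow(fp), 2)
  # each true centre has a footprint centroid within 0.5 mm
  gx <- fp$x + d$seg$crop$origin[1] - 1
  gy <- fp$y + d$seg$crop$origin[2] - 1
  dmm <- sqrt(outer(gx, co$x_px, `-`)^2 + outer(gy, co$y_px, `-`)^2) * 0.1
  expect_true(all(apply(dmm, 2, min) < 0.5))
})

test_that("a two-dome segment is split and its sublabel revised", {
  # one segment covering two overlapping Gaussian domes 1.6 mm apart
  W <- 80
  d1 <- dist_from_px(W, c(32, 40)); d2 <- dist_from_px(W, c(48, 40))
  gray <- 0.4 + 0.45 * pmax(exp(-d1^2 / (2 * 5^2)) * (d1 <= 10),
                            exp(-d2^2 / (2 * 5^2)) * (d2 <= 10))
  seg_mask <- d1 <= 10 | d2 <= 10
  labels <- matrix(2L, W, W); labels[seg_mask] <- 3L
  segmap <- structure(list(
    labels = labels,
    segments = data.frame(id = 1:3,
                          supercategory = c("background", "background", "colonies"),
                          sublabel = c("out of plate", "0 colonies", "1 colony"),
                          area_px = tabulate(labels, nbins = 3)),
    crop_origin = c(1, 1), center_local = c(40, 40),
    geom = structure(list(radius_px = 45, scale_mm_per_px = 0.1),
                     class = "dish_geometry")), class = "segment_map")
  fps <- split_groups(segmap, gray)
  expect_equal(nrow(fps$footprints), 2)
  expect_equal(fps$segmap$segments$sublabel[3], "2 colonies")
  expect_equal(fps$footprints$n_colonies_in_parent_segment, c(2L, 2L))
  # child masks partition the parent segment
  expect_identical(fps$labels > 0, seg_mask)
  # centroids sit near the dome centres
  fp <- fps$footprints[order(fps$footprints$x), ]
  expect_lt(abs(fp$x[1] - 32), 2); expect_lt(abs(fp$x[2] - 48), 2)
})

test_that("splitting partitions parent segments without losing pixels", {
  g <- small_plate(n = 40, seed = 19, group_fraction = 0.2)
  d <- small_detect(g)
  seg_mask <- d$seg$segmap$labels > 2
  expect_identical(d$fps$labels > 0, seg_mask)
  # child counts per parent sum to the footprint total
  expect_equal(sum(tapply(d$fps$footprints$id,
                          d$fps$footprints$parent_segment, length)),
               nrow(d$fps$footprints))
})

test_that("measurements follow their definitions", {
  # uniform pure-blue square footprint: hue 240, area from the pixel count
  W <- 40
  labels <- matrix(0L, W, W); labels[11:20, 11:20] <- 1L
  rgbc <- array(0, dim = c(W, W, 3)); rgbc[, , 3] <- 1
  fps <- structure(list(
    labels = labels,
    footprints = data.frame(id = 1L, parent_segment = 3L, x = 15.5, y = 15.5,
                            area_px = 100L, n_colonies_in_parent_segment = 1L),
    segmap = NULL), class = "colony_footprints")
  m <- measure_footprints(fps, rgbc, NULL, scale_mm_per_px = 0.1)
  expect_equal(m$footprints$mean_h, 240)
  expect_equal(m$footprints$area_mm2, 1.0)
  expect_equal(m$footprints$equivalent_diameter_mm, 2 * sqrt(1 / pi))
  expect_true(is.na(m$footprints$mean_fluorescence))

  # scale covariance: doubling the scale quadruples area, doubles diameter
  m2 <- measure_footprints(fps, rgbc, NULL, scale_mm_per_px = 0.2)
  expect_equal(m2$footprints$area_mm2, 4 * m$footprints$area_mm2)
  expect_equal(m2$footprints$equivalent_diameter_mm,
               2 * m$footprints$equivalent_diameter_mm)
  expect_error(measure_footprints(fps, rgbc, NULL, 0), "scale")

  # circular hue averaging: reds straddling the wrap average to ~0, not 180
  rgbw <- array(0, dim = c(W, W, 3))
  rgbw[, , 1] <- 1
  half <- matrix(rep(c(TRUE, FALSE), length.out = W), W, W)
  rgbw[, , 2][half] <- 0.1   # hue ~6 deg
  rgbw[, , 3][!half] <- 0.1  # hue ~354 deg
  mw <- measure_footprints(fps, rgbw, NULL, 0.1)
  h <- mw$footprints$mean_h
  expect_true(h < 10 || h > 350)
})

test_that("fluorescence is measured to within the sensor noise", {
  lv <- list(list(level = 200, fraction = 1))
  g <- small_plate(n = 8, seed = 23, fluorescence_levels = lv,
                   group_fraction = 0, border_fraction = 0, artifact_count = 0)
  # measurement contract checked on the true masks
  W <- dim(g$plate$fluor)[1]
  labels <- matrix(0L, W, W)
  co <- g$truth$colonies
  for (i in seq_len(nrow(co))) {
    d <- dist_from_px(W, c(co$x_px[i], co$y_px[i]))
    labels[d <= co$radius_px[i] - 1] <- i
  }
  fps <- structure(list(
    labels = labels,
    footprints = data.frame(id = co$id, parent_segment = co$id + 2L,
                            x = co$x_px, y = co$y_px,
                            area_px = tabulate(labels[labels > 0]),
                            n_colonies_in_parent_segment = 1L),
    segmap = NULL), class = "colony_footprints")
  m <- measure_footprints(fps, g$plate$rgb, g$plate$fluor, 0.1)
  expect_true(all(abs(m$footprints$mean_fluorescence - 200) < 3))
})

test_that("fluorescence ranking of detected colonies follows the levels", {
  lv <- list(list(level = 60, fraction = 0.5), list(level = 220, fraction = 0.5))
  g <- small_plate(n = 14, seed = 29, fluorescence_levels = lv,
                   group_fraction = 0, border_fraction = 0, artifact_count = 0)
  d <- small_detect(g, fluor = TRUE)
  idx <- nearest_truth(d$fps, g$truth, d$seg$crop$origin)
  lev <- g$truth$colonies$fluor_level[idx]
  f <- d$fps$footprints$mean_fluorescence
  expect_true(min(f[lev == 220]) > max(f[lev == 60]))
})

test_that("pickability combines the wall margin with the size limit", {
  g <- small_plate(n = 30, seed = 31, border_fraction = 0.2)
  d <- small_detect(g)
  fp <- d$fps$footprints
  ctr <- d$fps$segmap$center_local
  dctr <- sqrt((fp$x - ctr[1])^2 + (fp$y - ctr[2])^2)
  lim <- d$seg$geom$radius_px - (2 + 2) / 0.1
  expect_equal(fp$pickable, dctr <= lim & fp$equivalent_diameter_mm >= 1)
  # a tiny footprint is unpickable regardless of position
  d2 <- d$fps
  d2$footprints$equivalent_diameter_mm[1] <- 0.5
  d2 <- flag_pickable(d2, d$seg$geom)
  expect_false(d2$footprints$pickable[1])
  expect_error(flag_pickable(d$fps, d$seg$geom, margin_mm = -1), "margin")
})
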