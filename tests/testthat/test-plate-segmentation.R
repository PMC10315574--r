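test_that("dish detection recovers centre, radius and labware offset", {
  # centred dish: offset to labware (image centre) is ~0
  g <- small_plate(n = 10, seed = 2)
  geom <- detect_dish(g$plate, diameter_range_mm = small_dish_range)
  expect_lt(max(abs(geom$offset_to_labware_px)), 1.5)
  expect_lt(abs(geom$radius_px - g$truth$dish$r_out_px), 2)

  # displaced dish: offset equals the constructed displacement
  gd <- generate_plate(plate_params(
    image_size_px = 360, dish_outer_diameter_mm = 30,
    dish_center_px = c(195, 165), n_colonies = 10, seed = 3))
  geom_d <- detect_dish(gd$plate, labware_center_px = c(180.5, 180.5),
                        diameter_range_mm = small_dish_range)
  expect_equal(geom_d$offset_to_labware_px, c(14.5, -15.5), tolerance = 0.15)

  # radius accurate across seeds
  for (seed in 4:6) {
    gi <- small_plate(n = 40, seed = seed)
    gmi <- detect_dish(gi$plate, diameter_range_mm = small_dish_range)
    expect_lt(abs(gmi$radius_px - gi$truth$dish$r_out_px), 2)
  }
})

test_that("detection fails loudly when no dish is present", {
  blank <- structure(list(
    rgb = array(0.1, dim = c(200, 200, 3)), fluor = NULL,
    meta = list(scale_mm_per_px = 0.1, labware_center_px = c(100.5, 100.5),
                image_size_px = 200L)), class = "plate_image")
  expect_error(detect_dish(blank, diameter_range_mm = c(85, 89)),
               "no dish found")
})

test_that("cropping records origin and crop-local dish centre", {
  g <- small_plate(n = 10, seed = 2)
  geom <- detect_dish(g$plate, diameter_range_mm = small_dish_range)
  crop <- crop_dish(g$plate, geom)
  b <- geom$bbox
  expect_identical(dim(crop$rgb)[1:2],
                   c(b[3] - b[1] + 1L, b[4] - b[2] + 1L))
  expect_equal(crop$center_local, geom$center_px - crop$origin + 1)

  # bbox equal to the whole image: crop is the identity
  geom_full <- geom
  geom_full$bbox <- c(1L, 1L, dim(g$plate$rgb)[1], dim(g$plate$rgb)[2])
  expect_identical(crop_dish(g$plate, geom_full)$rgb, g$plate$rgb)

  geom_bad <- geom; geom_bad$bbox <- c(10L, 10L, 10L, 10L)
  expect_error(crop_dish(g$plate, geom_bad), "degenerate")
})

test_that("blank agar yields an empty inner mask", {
  g <- generate_plate(plate_params(image_size_px = 340,
                                   dish_outer_diameter_mm = 30,
                                   n_colonies = 0, artifact_count = 0))
  s <- small_segment(g)
  expect_equal(sum(s$segmap$labels > 2), 0)
})

test_that("inner segmentation components equal their own convex hulls", {
  g <- small_plate(n = 25, seed = 8)
  geom <- detect_dish(g$plate, diameter_range_mm = small_dish_range)
  crop <- crop_dish(g$plate, geom)
  mask <- segment_inner(crop)
  refilled <- colonyscreen:::fill_convex_components(mask)
  expect_identical(refilled, mask)   # hulling is idempotent
  expect_gt(max(EBImage::bwlabel(mask)), 0)
})

test_that("noiseless well-separated plates are counted exactly", {
  g <- generate_plate(plate_params(
    image_size_px = 340, dish_outer_diameter_mm = 30,
    n_colonies = 22, group_fraction = 0, border_fraction = 0,
    artifact_count = 0, illumination_gradient = 0, noise_sigma = 0,
    seed = 12))
  s <- small_segment(g)
  expect_equal(sum(s$segmap$segments$supercategory == "colonies"), 22)
})

test_that("border pipeline returns blobs for wall-straddling colonies only", {
  # a large white colony placed inside the security margin straddles the wall
  white_only <- list(list(name = "white", rgb = c(222, 218, 202), fraction = 1))
  g <- generate_plate(plate_params(
    n_colonies = 1, group_fraction = 0, border_fraction = 1,
    artifact_count = 0, colony_radius_range_mm = c(2, 2.3),
    color_phenotypes = white_only, seed = 5))
  geom <- detect_dish(g$plate)
  crop <- crop_dish(g$plate, geom)
  bm <- segment_border(crop)
  expect_gt(sum(bm), 0)
  # masking contract: output pixels lie inside the annulus (which abuts the
  # guarded inner disc)
  bp <- border_params(geom$scale_mm_per_px)
  D <- dist_from_px(dim(bm)[1], crop$center_local)
  expect_true(all(D[bm] > geom$radius_px - bp$wall_px - bp$edge_guard_px))

  # a colony-free annulus (plastic wall only) gives an empty mask
  g0 <- generate_plate(plate_params(image_size_px = 340,
                                    dish_outer_diameter_mm = 30,
                                    n_colonies = 0, artifact_count = 0))
  s0 <- small_segment(g0)
  bm0 <- segment_border(s0$crop)
  expect_equal(sum(bm0), 0)
})

test_that("segment maps partition the crop with the category scheme", {
  g <- small_plate(n = 15, seed = 4)
  s <- small_segment(g)
  sm <- s$segmap
  ids <- sort(unique(as.vector(sm$labels)))
  expect_identical(ids, sm$segments$id)     # every id present, none missing
  expect_true(all(sm$labels >= 1))          # ids tile the crop
  expect_identical(sm$segments$sublabel[1:2], c("out of plate", "0 colonies"))
  expect_true(all(sm$segments$supercategory[-(1:2)] == "colonies"))
  expect_equal(sm$segments$area_px, tabulate(sm$labels, nbins = max(ids)))

  # empty masks give exactly the two background segments
  e <- matrix(FALSE, 50, 50)
  crop_stub <- structure(list(origin = c(1, 1), center_local = c(25, 25)),
                         class = "crop_image")
  geom_stub <- structure(list(radius_px = 20, scale_mm_per_px = 0.1),
                         class = "dish_geometry")
  sm0 <- build_segment_map(e, e, crop_stub, geom_stub)
  expect_equal(nrow(sm0$segments), 2)

  # five disjoint components give 5 + 2 segments
  m5 <- matrix(FALSE, 50, 50)
  for (cx in c(10, 18, 26, 34, 42)) m5[cx + 0:2, 24:26] <- TRUE
  sm5 <- build_segment_map(m5, e, crop_stub, geom_stub)
  expect_equal(nrow(sm5$segments), 7)
})

test_that("segmenting a quarter-rotated plate preserves the colony count", {
  g <- generate_plate(plate_params(
    image_size_px = 340, dish_outer_diameter_mm = 30,
    n_colonies = 18, group_fraction = 0, border_fraction = 0,
    artifact_count = 0, illumination_gradient = 0, noise_sigma = 0,
    seed = 14))
  n0 <- sum(small_segment(g)$segmap$segments$supercategory == "colonies")

  rot <- g$plate
  rot$rgb <- colonyscreen:::apply_transform(g$plate$rgb, 90L, "none")
  n90 <- sum(small_segment(list(plate = rot))$segmap$segments$supercategory ==
               "colonies")
  expect_equal(n90, n0)
  expect_equal(n0, 18)
})
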