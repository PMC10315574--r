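# Shared fixtures: small (30 mm dish, 340 px) synthetic plates keep the
# image-processing tests fast.  Generated objects are cached per test file.

.fixtures <- new.env(parent = emptyenv())

small_dish_range <- c(28, 32)

small_plate <- function(n = 20, seed = 1, ...) {
  key <- paste0("plate_", n, "_", seed, "_",
                paste(deparse(substitute(list(...))), collapse = ""))
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  g <- generate_plate(plate_params(
    image_size_px = 340, dish_outer_diameter_mm = 30,
    colony_radius_range_mm = c(0.6, 1.2),
    n_colonies = n, seed = seed, ...))
  .fixtures[[key]] <- g
  g
}

small_segment <- function(g) {
  segment_plate(g$plate, diameter_range_mm = small_dish_range)
}

# full detection chain on a small plate: segment, split, measure, flag
small_detect <- function(g, fluor = FALSE) {
  s <- small_segment(g)
  fps <- split_groups(s$segmap, s$crop$gray)
  fps <- measure_footprints(fps, s$crop$rgb,
                            if (fluor) s$crop$fluor else NULL,
                            s$geom$scale_mm_per_px)
  fps <- flag_pickable(fps)
  list(seg = s, fps = fps)
}

dist_from_px <- function(W, center) {
  sqrt(outer((seq_len(W) - center[1])^2, (seq_len(W) - center[2])^2, `+`))
}

# footprint table sufficient for the screening functions, no pixel masks
make_screening_fps <- function(df) {
  defaults <- data.frame(area_mm2 = 1, equivalent_diameter_mm = 1.13,
                         mean_h = 0, mean_s = 0, mean_v = 1,
                         mean_fluorescence = NA_real_, pickable = TRUE)
  for (nm in names(defaults)) {
    if (is.null(df[[nm]])) df[[nm]] <- rep(defaults[[nm]], length.out = nrow(df))
  }
  structure(list(labels = NULL, footprints = df, segmap = NULL),
            class = "colony_footprints")
}

# phenotype of the nearest ground-truth colony for each footprint
nearest_truth <- function(fps, truth, crop_origin) {
  fp <- fps$footprints
  gx <- fp$x + crop_origin[1] - 1
  gy <- fp$y + crop_origin[2] - 1
  d <- sqrt(outer(gx, truth$colonies$x_px, `-`)^2 +
              outer(gy, truth$colonies$y_px, `-`)^2)
  apply(d, 1, which.min)
}
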