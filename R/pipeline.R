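#' Assemble a validated pipeline run configuration
#'
#' @param image path to the plate image, or a `plate_image` object.
#' @param fluor_image optional path to the co-registered fluorescence image.
#' @param labware_center_px labware reference point `c(x, y)` px; default
#'   image centre.
#' @param scale_mm_per_px camera scale; `NA` to estimate it from the detected
#'   dish diameter and `known_diameter_mm`.
#' @param known_diameter_mm dish diameter used for scale estimation.
#' @param diameter_range_mm admissible dish diameters for detection.
#' @param axis_signs robot axis signs, see [camera_frame()].
#' @param margin_mm,min_diameter_mm pickability rule, see [flag_pickable()].
#' @param w_size,w_color,w_fluor,target_color,color_mode,color_range,size_range_mm,k
#'   screening criteria, see [screening_criteria()].
#' @param dest_rows,dest_cols destination plate layout.
#' @param out_dir output directory for the run artefacts.
#' @param seed integer seed recorded for the run.
#' @param verbose emit per-stage progress messages.
#' @return object of class `run_config`.
#' @export
run_config <- function(image,
                       fluor_image = NULL,
                       labware_center_px = NULL,
                       scale_mm_per_px = 0.1,
                       known_diameter_mm = 87,
                       diameter_range_mm = c(85, 89),
                       axis_signs = c(1, 1),
                       margin_mm = 2,
                       min_diameter_mm = 1,
                       w_size = 1, w_color = 0, w_fluor = 0,
                       target_color = c(110, 130, 212),
                       color_mode = "similar",
                       color_range = NULL,
                       size_range_mm = NULL,
                       k = 10L,
                       dest_rows = 8L, dest_cols = 12L,
                       out_dir = tempfile("colonyscreen_run_"),
                       seed = 1L,
                       verbose = FALSE) {
  if (is.character(image) && !file.exists(image)) {
    stop_ctx("input image not found: '%s'", image)
  }
  if (!is.null(fluor_image) && is.character(fluor_image) &&
      !file.exists(fluor_image)) {
    stop_ctx("fluorescence image not found: '%s'", fluor_image)
  }
  structure(list(
    image = image, fluor_image = fluor_image,
    labware_center_px = labware_center_px,
    scale_mm_per_px = scale_mm_per_px,
    known_diameter_mm = known_diameter_mm,
    diameter_range_mm = diameter_range_mm,
    axis_signs = axis_signs,
    margin_mm = margin_mm, min_diameter_mm = min_diameter_mm,
    w_size = w_size, w_color = w_color, w_fluor = w_fluor,
    target_color = target_color, color_mode = color_mode,
    color_range = color_range, size_range_mm = size_range_mm,
    k = as.integer(k),
    dest_rows = as.integer(dest_rows), dest_cols = as.integer(dest_cols),
    out_dir = out_dir, seed = as.integer(seed), verbose = isTRUE(verbose)
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected with a message naming them, so a typo in a
#' config file fails loudly instead of silently using a default.
#'
#' @param path YAML file; keys are the arguments of [run_config()].
#' @param ... overrides applied on top of the file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path)) stop_ctx("config file not found: '%s'", path)
  vals <- yaml::read_yaml(path)
  dots <- list(...)
  vals[names(dots)] <- dots
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop_ctx("unknown config key(s): %s", paste(bad, collapse = ", "))
  for (nm in c("labware_center_px", "diameter_range_mm", "axis_signs",
               "target_color", "size_range_mm")) {
    if (!is.null(vals[[nm]])) vals[[nm]] <- as.numeric(unlist(vals[[nm]]))
  }
  do.call(run_config, vals)
}

draw_ring <- function(img, cx, cy, r, col, thick = 1.5) {
  W <- dim(img)[1]; H <- dim(img)[2]
  x0 <- max(1L, floor(cx - r - 2)); x1 <- min(W, ceiling(cx + r + 2))
  y0 <- max(1L, floor(cy - r - 2)); y1 <- min(H, ceiling(cy + r + 2))
  if (x0 > x1 || y0 > y1) return(img)
  d <- sqrt(outer((x0:x1 - cx)^2, (y0:y1 - cy)^2, `+`))
  on <- abs(d - r) <= thick
  for (ch in 1:3) {
    patch <- img[x0:x1, y0:y1, ch]
    patch[on] <- col[ch]
    img[x0:x1, y0:y1, ch] <- patch
  }
  img
}

#' Render a detection/selection overlay image
#'
#' Yellow rings mark every detected colony footprint, red rings the selected
#' ones.
#'
#' @param crop a `crop_image`.
#' @param fps measured `colony_footprints`.
#' @param selection ids of selected colonies.
#' @return RGB array `[x, y, 3]`.
#' @export
draw_overlay <- function(crop, fps, selection = integer(0)) {
  img <- crop$rgb
  fp <- fps$footprints
  for (i in seq_len(nrow(fp))) {
    r_px <- fp$equivalent_diameter_mm[i] / 2 / crop$geom$scale_mm_per_px
    col <- if (fp$id[i] %in% selection) c(1, 0.15, 0.15) else c(1, 0.9, 0.2)
    img <- draw_ring(img, fp$x[i], fp$y[i], r_px + 2, col)
  }
  img
}

#' Run the full screening pipeline on one plate image
#'
#' Chains dish detection, cropping, inner/border segmentation, group
#' splitting, measurement, pickability flagging, colour/size filtering,
#' scoring, ranking, destination assignment and picklist generation, and
#' writes `picklist.csv`, `footprints.csv`, `report.json` and `overlay.png`
#' to the configured output directory.  An empty selection (e.g. a blank
#' plate) produces a header-only picklist with a warning; a missing dish
#' raises an error of class `no_dish_error`.
#'
#' @param cfg a [run_config()] (or path to a YAML config).
#' @param detector optional replacement detector, a
#'   `function(plate, ...) -> list(geom=, crop=, segmap=)`; defaults to the
#'   classical [segment_plate()].  This is the slot a learned panoptic
#'   segmentation model can occupy.
#' @return invisibly, a list with the output `paths` and the in-memory
#'   `picklist`, `footprints`, `scores` and `stages` (per-stage counts).
#' @export
run_pipeline <- function(cfg, detector = segment_plate) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  say <- function(fmt, ...) if (cfg$verbose) message(sprintf(fmt, ...))

  plate <- if (inherits(cfg$image, "plate_image")) cfg$image else
    read_plate_image(cfg$image, cfg$fluor_image, cfg$scale_mm_per_px,
                     cfg$labware_center_px)
  say("image: %d x %d px", dim(plate$rgb)[1], dim(plate$rgb)[2])

  seg <- tryCatch(
    detector(plate, labware_center_px = cfg$labware_center_px,
             diameter_range_mm = cfg$diameter_range_mm,
             scale_mm_per_px = cfg$scale_mm_per_px),
    error = function(e) {
      if (grepl("no dish found", conditionMessage(e))) {
        stop(structure(class = c("no_dish_error", "error", "condition"),
                       list(message = conditionMessage(e), call = NULL)))
      }
      stop(e)
    })
  geom <- seg$geom; crop <- seg$crop; segmap <- seg$segmap
  scale <- geom$scale_mm_per_px
  n_seg <- sum(segmap$segments$supercategory == "colonies")
  say("dish r=%.1f px, %d colony segments", geom$radius_px, n_seg)

  fps <- split_groups(segmap, crop$gray)
  fps <- measure_footprints(fps, crop$rgb, crop$fluor, scale)
  fps <- flag_pickable(fps, geom, cfg$margin_mm, scale, cfg$min_diameter_mm)
  n_fp <- nrow(fps$footprints)
  n_pick <- sum(fps$footprints$pickable)
  say("%d footprints, %d pickable", n_fp, n_pick)

  criteria <- screening_criteria(cfg$w_size, cfg$w_color, cfg$w_fluor,
                                 cfg$target_color, cfg$color_mode,
                                 cfg$color_range, cfg$size_range_mm, cfg$k)
  cand <- fps
  cand$footprints <- cand$footprints[cand$footprints$pickable, , drop = FALSE]
  cand <- color_filter(cand, cfg$color_range)
  n_cand <- nrow(cand$footprints)
  say("%d candidates after filtering", n_cand)

  frame <- camera_frame(plate$meta$labware_center_px %||% cfg$labware_center_px,
                        scale, cfg$axis_signs)
  if (n_cand == 0) {
    warning("no colonies remain after filtering; writing an empty picklist",
            call. = FALSE)
    scores <- NULL
    selection <- integer(0)
    dest <- data.frame(colony_id = integer(0), dest_well = character(0))
  } else {
    scores <- score_colonies(cand, criteria)
    selection <- rank_and_select(scores, cfg$k)
    dest <- assign_destinations(selection,
                                well_layout(cfg$dest_rows, cfg$dest_cols))
  }
  picklist <- build_picklist(selection, fps, geom, frame, dest, scores)

  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  paths <- list(
    picklist = file.path(cfg$out_dir, "picklist.csv"),
    footprints = file.path(cfg$out_dir, "footprints.csv"),
    report = file.path(cfg$out_dir, "report.json"),
    overlay = file.path(cfg$out_dir, "overlay.png")
  )
  write_picklist_csv(picklist, paths$picklist)
  write_footprints_csv(fps, paths$footprints)
  stages <- list(segments = n_seg, footprints = n_fp, pickable = n_pick,
                 candidates = n_cand, selected = length(selection),
                 dish = list(center_px = geom$center_px,
                             radius_px = geom$radius_px,
                             offset_to_labware_px = geom$offset_to_labware_px),
                 seed = cfg$seed)
  jsonlite::write_json(stages, paths$report, auto_unbox = TRUE, digits = NA)
  png::writePNG(aperm(draw_overlay(crop, fps, selection), c(2, 1, 3)),
                paths$overlay)
  say("picklist: %d targets -> %s", nrow(picklist), paths$picklist)
  invisible(list(paths = paths, picklist = picklist, footprints = fps,
                 scores = scores, stages = stages, geom = geom))
}
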