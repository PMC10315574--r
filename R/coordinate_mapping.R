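#' Camera-to-robot frame description
#'
#' @param labware_center_px fixed labware reference point `O_lab` in image px.
#' @param scale_mm_per_px camera pixel-to-mm conversion factor (> 0).
#' @param axis_signs `c(+1/-1, +1/-1)` per robot axis, applied after the
#'   rotation; lets a deployment match its physical camera mount without code
#'   changes.
#' @return object of class `camera_frame`.
#' @export
camera_frame <- function(labware_center_px, scale_mm_per_px,
                         axis_signs = c(1, 1)) {
  if (scale_mm_per_px <= 0) stop_ctx("scale_mm_per_px must be > 0")
  if (!all(axis_signs %in% c(-1, 1))) stop_ctx("axis_signs must be +/-1")
  structure(list(labware_center_px = labware_center_px,
                 scale_mm_per_px = scale_mm_per_px,
                 axis_signs = axis_signs),
            class = "camera_frame")
}

#' Pixel offset of a colony from the labware centre
#'
#' Vector sum of the dish-to-labware offset and the colony-to-dish-centre
#' offset measured in the crop: `(c_i - O_Pet') + (O_Pet - O_lab)`.
#'
#' @param c_i colony centroid, crop-local px (vector or n x 2 matrix).
#' @param o_pet_prime crop-local dish centre `O_Pet'`.
#' @param dish_offset_px dish-to-labware pixel offset (from
#'   `dish_geometry$offset_to_labware_px`).
#' @return offset(s) in px, same shape as `c_i`.
#' @export
colony_offset_pixels <- function(c_i, o_pet_prime, dish_offset_px) {
  if (is.matrix(c_i)) {
    cbind(c_i[, 1] - o_pet_prime[1] + dish_offset_px[1],
          c_i[, 2] - o_pet_prime[2] + dish_offset_px[2])
  } else {
    c(c_i[1] - o_pet_prime[1] + dish_offset_px[1],
      c_i[2] - o_pet_prime[2] + dish_offset_px[2])
  }
}

#' Convert a pixel offset to robot-frame millimetres
#'
#' The pixel offset is scaled to mm, the image vector is converted to a
#' right-handed frame (image y points down, so y is negated), the frame is
#' rotated 90 degrees anticlockwise (`(u, v) -> (-v, u)`), and the configured
#' axis signs are applied last.
#'
#' @param offset_px pixel offset (vector or n x 2 matrix).
#' @param frame a [camera_frame()].
#' @return mm offset(s), same shape.
#' @export
pixel_to_robot <- function(offset_px, frame) {
  one <- !is.matrix(offset_px)
  if (one) offset_px <- matrix(offset_px, 1, 2)
  u <- offset_px[, 1] * frame$scale_mm_per_px
  v <- -offset_px[, 2] * frame$scale_mm_per_px  # right-handed image frame
  out <- cbind(frame$axis_signs[1] * (-v), frame$axis_signs[2] * u)
  if (one) out[1, ] else out
}

#' @rdname pixel_to_robot
#' @param offset_mm robot-frame mm offset(s) to map back to image pixels.
#' @export
robot_to_pixel <- function(offset_mm, frame) {
  one <- !is.matrix(offset_mm)
  if (one) offset_mm <- matrix(offset_mm, 1, 2)
  rv <- offset_mm[, 1] / frame$axis_signs[1]
  ru <- offset_mm[, 2] / frame$axis_signs[2]
  u <- ru
  v <- -rv
  out <- cbind(u / frame$scale_mm_per_px, -v / frame$scale_mm_per_px)
  if (one) out[1, ] else out
}

#' Build the picklist for a selection of colonies
#'
#' One `pick_target` row per selected colony, in selection order: robot-frame
#' mm offset from the labware centre (via [colony_offset_pixels()] and
#' [pixel_to_robot()]), score, pick order and destination well.
#'
#' @param selection ordered colony ids (from [rank_and_select()]).
#' @param fps the measured, pickability-flagged `colony_footprints`.
#' @param geom the `dish_geometry`.
#' @param frame a [camera_frame()].
#' @param destinations data frame from [assign_destinations()].
#' @param scores optional `colony_scores` to carry scores into the picklist.
#' @return data frame of class `picklist`: `colony_id`, `dx_mm`, `dy_mm`,
#'   `score`, `pick_order`, `dest_well`.
#' @export
build_picklist <- function(selection, fps, geom, frame, destinations,
                           scores = NULL) {
  fp <- fps$footprints
  sel <- match(selection, fp$id)
  if (anyNA(sel)) {
    stop_ctx("selected colony id(s) %s not among footprints",
             paste(selection[is.na(sel)], collapse = ", "))
  }
  if (length(sel) > 0 && !all(fp$pickable[sel])) {
    stop_ctx("selected colony id(s) %s are not pickable",
             paste(fp$id[sel][!fp$pickable[sel]], collapse = ", "))
  }
  if (length(sel) == 0) {
    return(structure(data.frame(colony_id = integer(0), dx_mm = numeric(0),
                                dy_mm = numeric(0), score = numeric(0),
                                pick_order = integer(0),
                                dest_well = character(0),
                                stringsAsFactors = FALSE),
                     class = c("picklist", "data.frame")))
  }
  ci <- cbind(fp$x[sel], fp$y[sel])
  off_px <- colony_offset_pixels(ci, fps$segmap$center_local,
                                 geom$offset_to_labware_px)
  off_mm <- pixel_to_robot(off_px, frame)
  sc <- if (!is.null(scores)) scores$score[match(selection, scores$id)] else
    rep(NA_real_, length(sel))
  structure(data.frame(
    colony_id = fp$id[sel],
    dx_mm = off_mm[, 1], dy_mm = off_mm[, 2],
    score = sc,
    pick_order = seq_along(sel),
    dest_well = destinations$dest_well[match(selection, destinations$colony_id)],
    stringsAsFactors = FALSE
  ), class = c("picklist", "data.frame"))
}

#' Write / read a picklist CSV
#'
#' Header `colony_id,dx_mm,dy_mm,score,pick_order,dest_well`; mm written with
#' six decimal places.  This is the file a liquid handler consumes to execute
#' the physical picks.
#'
#' @param picklist a `picklist` data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_picklist_csv <- function(picklist, path) {
  df <- data.frame(
    colony_id = picklist$colony_id,
    dx_mm = sprintf("%.6f", picklist$dx_mm),
    dy_mm = sprintf("%.6f", picklist$dy_mm),
    score = ifelse(is.na(picklist$score), "", sprintf("%.6f", picklist$score)),
    pick_order = picklist$pick_order,
    dest_well = picklist$dest_well,
    stringsAsFactors = FALSE
  )
  ok <- try(utils::write.csv(df, path, row.names = FALSE, quote = FALSE),
            silent = TRUE)
  if (inherits(ok, "try-error")) stop_ctx("cannot write picklist to '%s'", path)
  invisible(path)
}

#' @rdname write_picklist_csv
#' @export
read_picklist_csv <- function(path) {
  if (!file.exists(path)) stop_ctx("picklist file not found: '%s'", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(dest_well = "character"))
  structure(df, class = c("picklist", "data.frame"))
}
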