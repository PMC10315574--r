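#' Parameters for colony-group splitting
#'
#' The grayscale is smoothed with a Gaussian of about 0.3 mm before the
#' regional-maximum search, and two maxima must be at least 0.8 mm apart to
#' count as distinct colonies — below the minimum colony diameter, so true
#' touching pairs split, and above the smoothing/noise scale, so single
#' colonies rarely do.
#'
#' @param scale_mm_per_px camera scale, mm per pixel.
#' @param smooth_sigma_mm,d_min_mm overrides, mm.
#' @return list of pixel-domain parameters.
#' @export
split_params <- function(scale_mm_per_px,
                         smooth_sigma_mm = 0.3,
                         d_min_mm = 0.8) {
  list(smooth_sigma_px = smooth_sigma_mm / scale_mm_per_px,
       d_min_px = d_min_mm / scale_mm_per_px)
}

#' Split multi-colony segments by local-maximum search
#'
#' For every "colonies" segment, regional maxima of the Gaussian-smoothed
#' grayscale inside the segment are located; maxima closer than `d_min` are
#' merged (brightest wins).  Segments holding k >= 2 accepted maxima are
#' split into k footprints by marker-controlled watershed (seeded region
#' growing on the smoothed intensity), and their sublabel in the segment map
#' is revised to `"k colonies"`.  Child masks always partition the parent
#' segment.
#'
#' @param segmap a `segment_map` (updated in the returned object).
#' @param gray_crop grayscale crop aligned with the segment map; defaults to
#'   luminance recomputed by the caller.
#' @param p parameters from [split_params()].
#' @return object of class `colony_footprints`: integer `labels` matrix of
#'   footprint ids, a `footprints` data frame (id, parent segment, centroid,
#'   area, n_colonies_in_parent_segment), and the revised `segmap`.
#' @export
split_groups <- function(segmap, gray_crop,
                         p = split_params(segmap$geom$scale_mm_per_px)) {
  stopifnot(identical(dim(segmap$labels), dim(gray_crop)))
  colony_mask <- segmap$labels > 2L
  W <- dim(gray_crop)[1]; H <- dim(gray_crop)[2]
  n_seg <- max(segmap$labels) - 2L
  empty <- data.frame(id = integer(0), parent_segment = integer(0),
                      x = numeric(0), y = numeric(0), area_px = integer(0),
                      n_colonies_in_parent_segment = integer(0))
  if (n_seg < 1 || !any(colony_mask)) {
    return(structure(list(labels = matrix(0L, W, H), footprints = empty,
                          segmap = segmap),
                     class = "colony_footprints"))
  }

  sm <- EBImage::gblur(gray_crop, p$smooth_sigma_px)
  win <- odd(p$d_min_px)
  dil <- EBImage::dilate(sm, EBImage::makeBrush(win, "disc"))
  cand <- which(sm >= dil - 1e-12 & colony_mask)
  cx <- (cand - 1) %% W + 1
  cy <- (cand - 1) %/% W + 1
  cseg <- segmap$labels[cand]
  cval <- sm[cand]

  # greedy acceptance per segment: brightest first, enforce pairwise d_min
  seeds <- matrix(0L, W, H)
  seed_seg <- integer(0)
  next_id <- 0L
  for (s in unique(cseg)) {
    sel <- which(cseg == s)
    sel <- sel[order(-cval[sel])]
    ax <- numeric(0); ay <- numeric(0)
    for (j in sel) {
      if (length(ax) == 0 ||
          all((cx[j] - ax)^2 + (cy[j] - ay)^2 >= p$d_min_px^2)) {
        ax <- c(ax, cx[j]); ay <- c(ay, cy[j])
        next_id <- next_id + 1L
        seeds[cx[j], cy[j]] <- next_id
        seed_seg <- c(seed_seg, s)
      }
    }
  }
  # segments whose maxima all fell on plateaus outside `cand` resolution:
  # guarantee at least one seed per segment
  seg_ids <- 3:(n_seg + 2L)
  missing <- setdiff(seg_ids, unique(seed_seg))
  for (s in missing) {
    pix <- which(segmap$labels == s)
    j <- pix[which.max(sm[pix])]
    next_id <- next_id + 1L
    seeds[(j - 1) %% W + 1, (j - 1) %/% W + 1] <- next_id
    seed_seg <- c(seed_seg, s)
  }

  labels <- EBImage::propagate(sm, seeds = seeds, mask = colony_mask)
  labels <- matrix(as.integer(labels), W, H)

  n_fp <- next_id
  area <- tabulate(labels[labels > 0L], nbins = n_fp)
  idx <- which(labels > 0L)
  lv <- labels[idx]
  fx <- group_mean((idx - 1) %% W + 1, lv, n_fp)
  fy <- group_mean((idx - 1) %/% W + 1, lv, n_fp)
  per_seg <- tabulate(seed_seg, nbins = n_seg + 2L)
  fp <- data.frame(
    id = seq_len(n_fp),
    parent_segment = seed_seg,
    x = fx, y = fy,
    area_px = area,
    n_colonies_in_parent_segment = per_seg[seed_seg]
  )
  segmap$segments$sublabel[seg_ids] <- sprintf(
    "%d colon%s", per_seg[seg_ids], ifelse(per_seg[seg_ids] == 1, "y", "ies"))
  structure(list(labels = labels, footprints = fp, segmap = segmap),
            class = "colony_footprints")
}

#' @export
print.colony_footprints <- function(x, ...) {
  cat(sprintf("<colony_footprints> %d footprints in %d segments\n",
              nrow(x$footprints),
              length(unique(x$footprints$parent_segment))))
  invisible(x)
}

#' Measure size, colour and fluorescence of every footprint
#'
#' Adds physical area (`area_mm2 = area_px * scale^2`), equivalent diameter
#' (`2 * sqrt(area_mm2 / pi)`), the pixel-average HSV colour over the mask
#' (hue averaged circularly on the unit circle, so a population straddling
#' the 0/360 wrap is handled correctly) and, when a fluorescence channel is
#' present, the mean fluorescence (0-255 scale) under the mask.
#'
#' @param fps a `colony_footprints` object.
#' @param rgb_crop crop-local RGB array `[x, y, 3]`.
#' @param fluor_crop optional crop-local fluorescence matrix (0-1 scale).
#' @param scale_mm_per_px camera scale, mm per pixel (> 0).
#' @return `fps` with measurement columns added to `$footprints`.
#' @export
measure_footprints <- function(fps, rgb_crop, fluor_crop = NULL,
                               scale_mm_per_px) {
  if (scale_mm_per_px <= 0) stop_ctx("scale_mm_per_px must be > 0")
  fp <- fps$footprints
  n <- nrow(fp)
  if (n > 0 && any(fp$area_px == 0)) stop_ctx("empty footprint mask")
  fp$area_mm2 <- fp$area_px * scale_mm_per_px^2
  fp$equivalent_diameter_mm <- 2 * sqrt(fp$area_mm2 / pi)
  fp$mean_h <- fp$mean_s <- fp$mean_v <- rep(NA_real_, n)
  fp$mean_fluorescence <- rep(NA_real_, n)
  if (n > 0) {
    idx <- which(fps$labels > 0L)
    lv <- fps$labels[idx]
    W <- dim(rgb_crop)[1]; H <- dim(rgb_crop)[2]
    r <- rgb_crop[, , 1][idx]; g <- rgb_crop[, , 2][idx]; b <- rgb_crop[, , 3][idx]
    hsv <- grDevices::rgb2hsv(rbind(r, g, b) * 255, maxColorValue = 255)
    hrad <- hsv[1, ] * 2 * pi
    sinm <- group_mean(sin(hrad), lv, n)
    cosm <- group_mean(cos(hrad), lv, n)
    fp$mean_h <- (atan2(sinm, cosm) * 180 / pi + 360) %% 360
    fp$mean_s <- group_mean(hsv[2, ], lv, n)
    fp$mean_v <- group_mean(hsv[3, ], lv, n)
    if (!is.null(fluor_crop)) {
      stopifnot(identical(dim(fluor_crop), dim(fps$labels)))
      fp$mean_fluorescence <- group_mean(fluor_crop[idx] * 255, lv, n)
    }
  }
  fps$footprints <- fp
  fps
}

#' Flag colonies a picking robot can reach
#'
#' A colony is pickable when its centroid keeps the security margin from the
#' inner dish wall (centre distance <= dish radius - wall - margin) and its
#' equivalent diameter is at least `min_diameter_mm` (tips misplace smaller
#' colonies).
#'
#' @param fps a measured `colony_footprints` object.
#' @param geom the `dish_geometry` (defaults to the segment map's).
#' @param margin_mm security margin from the inner wall, mm (>= 0).
#' @param scale_mm_per_px camera scale.
#' @param min_diameter_mm minimum pickable equivalent diameter, mm.
#' @param wall_mm plastic wall thickness, mm.
#' @return `fps` with a logical `pickable` column.
#' @export
flag_pickable <- function(fps, geom = fps$segmap$geom, margin_mm = 2,
                          scale_mm_per_px = geom$scale_mm_per_px,
                          min_diameter_mm = 1, wall_mm = 2) {
  if (margin_mm < 0) stop_ctx("margin_mm must be >= 0")
  fp <- fps$footprints
  ctr <- fps$segmap$center_local
  d <- sqrt((fp$x - ctr[1])^2 + (fp$y - ctr[2])^2)
  lim <- geom$radius_px - (wall_mm + margin_mm) / scale_mm_per_px
  fp$pickable <- d <= lim & fp$equivalent_diameter_mm >= min_diameter_mm
  fps$footprints <- fp
  fps
}

#' Write measured footprints as CSV
#'
#' One row per colony with centroid (crop-local px), area, HSV colour,
#' fluorescence and pickability.
#'
#' @param fps a measured `colony_footprints` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_footprints_csv <- function(fps, path) {
  ok <- try(utils::write.csv(fps$footprints, path, row.names = FALSE, na = ""),
            silent = TRUE)
  if (inherits(ok, "try-error")) stop_ctx("cannot write footprints to '%s'", path)
  invisible(path)
}
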