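#' Detect the Petri dish by circular Hough voting over an edge map
#'
#' Finds the dish wall circle: Sobel gradients are computed, the strongest
#' edge pixels vote for circle centres along their gradient direction over the
#' admissible radius range, the accumulator peak seeds an algebraic circle fit
#' (Kasa least squares) on the outer wall edge, iterated once on refreshed
#' inliers.
#'
#' @param plate a `plate_image`.
#' @param labware_center_px fixed labware reference point `c(x, y)` in px;
#'   default: the plate's recorded labware centre (image centre for synthetic
#'   plates).
#' @param diameter_range_mm admissible dish outer diameters, mm.
#' @param scale_mm_per_px camera scale; default from plate metadata.  When
#'   `NA`, radii are searched over a generic fraction of the image and the
#'   scale can later be estimated via `known_diameter_mm / detected diameter`.
#' @param known_diameter_mm optional known outer diameter used to estimate the
#'   scale when `scale_mm_per_px` is `NA`.
#' @return object of class `dish_geometry`: `center_px`, `radius_px`, `bbox`
#'   (`c(x0, y0, x1, y1)`), `offset_to_labware_px` (= centre - labware centre)
#'   and `scale_mm_per_px`.
#' @export
detect_dish <- function(plate, labware_center_px = NULL,
                        diameter_range_mm = c(85, 89),
                        scale_mm_per_px = NULL,
                        known_diameter_mm = NULL) {
  gray <- luminance(plate$rgb)
  W <- dim(gray)[1]; H <- dim(gray)[2]
  if (is.null(labware_center_px)) labware_center_px <- plate$meta$labware_center_px
  if (is.null(scale_mm_per_px)) scale_mm_per_px <- plate$meta$scale_mm_per_px

  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- EBImage::filter2(gray, kx)
  gy <- EBImage::filter2(gray, t(kx))
  mag <- sqrt(gx^2 + gy^2)

  n_pts <- 6000L
  thr <- stats::quantile(mag, 1 - min(2 * n_pts, length(mag) - 1) / length(mag))
  idx <- which(mag >= thr & mag > 1e-4)
  if (length(idx) < 50) stop_ctx("no dish found within the configured diameter range")
  if (length(idx) > n_pts) idx <- idx[round(seq(1, length(idx), length.out = n_pts))]
  px <- (idx - 1) %% W + 1
  py <- (idx - 1) %/% W + 1
  m <- mag[idx]
  ux <- gx[idx] / m; uy <- gy[idx] / m

  if (!is.na(scale_mm_per_px)) {
    r_lo <- diameter_range_mm[1] / (2 * scale_mm_per_px) - 5
    r_hi <- diameter_range_mm[2] / (2 * scale_mm_per_px) + 5
  } else {
    r_lo <- 0.25 * min(W, H); r_hi <- 0.49 * min(W, H)
  }
  radii <- seq(r_lo, r_hi, by = 2)

  bin <- 2
  nbx <- ceiling(W / bin); nby <- ceiling(H / bin)
  acc <- integer(nbx * nby)
  for (s in c(-1, 1)) {
    for (r in radii) {
      cx <- px + s * r * ux
      cy <- py + s * r * uy
      ok <- cx >= 1 & cx <= W & cy >= 1 & cy <= H
      if (!any(ok)) next
      ib <- pmin(nbx, pmax(1L, as.integer(round(cx[ok] / bin)))) +
        (pmin(nby, pmax(1L, as.integer(round(cy[ok] / bin)))) - 1L) * nbx
      tb <- tabulate(ib, nbins = nbx * nby)
      acc <- acc + tb
    }
  }
  best <- which.max(acc)
  if (acc[best] < 25) stop_ctx("no dish found within the configured diameter range")
  ctr <- c(((best - 1) %% nbx + 1) * bin, ((best - 1) %/% nbx + 1) * bin)

  # radius: histogram of edge-point distances, take the outermost strong peak
  d <- sqrt((px - ctr[1])^2 + (py - ctr[2])^2)
  brk <- seq(floor(r_lo), ceiling(r_hi) + 1, by = 1)
  hs <- d[d >= brk[1] & d <= brk[length(brk)]]
  if (length(hs) < 25) stop_ctx("no dish found within the configured diameter range")
  hcnt <- graphics::hist(hs, breaks = brk, plot = FALSE)$counts
  peaks <- which(hcnt >= 0.5 * max(hcnt))
  r_est <- brk[max(peaks)] + 0.5

  for (it in 1:2) {
    inl <- abs(d - r_est) <= 3
    if (sum(inl) < 10) break
    fit <- kasa_circle(px[inl], py[inl])
    ctr <- fit$center; r_est <- fit$radius
    d <- sqrt((px - ctr[1])^2 + (py - ctr[2])^2)
  }

  if (is.na(scale_mm_per_px) && !is.null(known_diameter_mm)) {
    scale_mm_per_px <- known_diameter_mm / (2 * r_est)
  }
  if (!is.na(scale_mm_per_px)) {
    dia_mm <- 2 * r_est * scale_mm_per_px
    if (dia_mm < diameter_range_mm[1] - 3 || dia_mm > diameter_range_mm[2] + 3) {
      stop_ctx("no dish found within the configured diameter range (got %.1f mm)",
               dia_mm)
    }
  }
  bbox <- as.integer(c(max(1, floor(ctr[1] - r_est)),
                       max(1, floor(ctr[2] - r_est)),
                       min(W, ceiling(ctr[1] + r_est)),
                       min(H, ceiling(ctr[2] + r_est))))
  structure(list(center_px = ctr, radius_px = r_est, bbox = bbox,
                 offset_to_labware_px = ctr - labware_center_px,
                 scale_mm_per_px = scale_mm_per_px),
            class = "dish_geometry")
}

#' @export
print.dish_geometry <- function(x, ...) {
  cat(sprintf("<dish_geometry> centre (%.1f, %.1f) px, r=%.1f px, offset (%.1f, %.1f) px\n",
              x$center_px[1], x$center_px[2], x$radius_px,
              x$offset_to_labware_px[1], x$offset_to_labware_px[2]))
  invisible(x)
}

# Algebraic (Kasa) circle fit: x^2 + y^2 + D x + E y + F = 0.
kasa_circle <- function(x, y) {
  A <- cbind(x, y, 1)
  b <- -(x^2 + y^2)
  sol <- qr.solve(A, b)
  ctr <- c(-sol[1] / 2, -sol[2] / 2)
  r <- sqrt(sum(ctr^2) - sol[3])
  list(center = unname(ctr), radius = unname(r))
}

#' Crop a plate to the dish bounding box
#'
#' Records the crop origin so crop-local coordinates map back to the full
#' image (`global = local + origin - 1`), and the crop-local dish centre.
#'
#' @param plate a `plate_image`.
#' @param geom a `dish_geometry` from [detect_dish()].
#' @return object of class `crop_image`: `rgb`, `gray`, optional `fluor`,
#'   `origin`, `center_local`, `geom`.
#' @export
crop_dish <- function(plate, geom) {
  b <- geom$bbox
  if (b[3] <= b[1] || b[4] <= b[2]) stop_ctx("degenerate dish bounding box")
  rgb <- plate$rgb[b[1]:b[3], b[2]:b[4], , drop = FALSE]
  fluor <- if (!is.null(plate$fluor)) plate$fluor[b[1]:b[3], b[2]:b[4]] else NULL
  structure(list(
    rgb = rgb, gray = luminance(rgb), fluor = fluor,
    origin = c(b[1], b[2]),
    center_local = geom$center_px - c(b[1], b[2]) + 1,
    geom = geom
  ), class = "crop_image")
}

#' Tuning parameters for inner-plate and border-annulus segmentation
#'
#' Scale-aware defaults: the adaptive-threshold block is about 2.5 mm (about
#' the largest colony diameter, so even the flat apex of a large low-contrast
#' colony rises above its neighbourhood mean), the Gaussian blur is 0.15 mm,
#' the brightness offset is -3 gray levels (a pixel must exceed its
#' Gaussian-weighted neighbourhood mean by 3/255 to be foreground; about five
#' sigma of the post-blur noise floor), and components smaller than a
#' 0.3 mm-radius disc are discarded as sensor specks.
#'
#' @param scale_mm_per_px camera scale, mm per pixel.
#' @param blur_sigma_mm,block_mm,offset_gray,min_area_mm2,wall_mm overrides.
#' @return list of pixel-domain parameters.
#' @export
inner_params <- function(scale_mm_per_px,
                         blur_sigma_mm = 0.15,
                         block_mm = 2.5,
                         offset_gray = -3,
                         min_area_mm2 = pi * 0.3^2,
                         wall_mm = 2,
                         edge_guard_mm = 0.5) {
  list(
    blur_sigma_px = blur_sigma_mm / scale_mm_per_px,
    block_px = odd(block_mm / scale_mm_per_px),
    offset_gray = offset_gray,
    min_area_px = min_area_mm2 / scale_mm_per_px^2,
    wall_px = wall_mm / scale_mm_per_px,
    edge_guard_px = edge_guard_mm / scale_mm_per_px
  )
}

#' @rdname inner_params
#' @param speckle_amp amplitude of the multiplicative uniform speckle noise
#'   injected in the annulus before edge detection.
#' @param canny_lo,canny_hi hysteresis thresholds as fractions of the annulus
#'   intensity range.
#' @param tophat_radius_mm structuring-element radius of the final top-hat
#'   debris filter.
#' @param speckle_seed fixed internal seed of the speckle step, so border
#'   segmentation stays deterministic.
#' @export
border_params <- function(scale_mm_per_px,
                          speckle_amp = 0.2,
                          canny_sigma_mm = 0.2,
                          canny_lo = 0.1,
                          canny_hi = 0.3,
                          tophat_radius_mm = 0.5,
                          wall_mm = 2,
                          edge_guard_mm = 0.5,
                          speckle_seed = 7L) {
  list(
    speckle_amp = speckle_amp,
    canny_sigma_px = canny_sigma_mm / scale_mm_per_px,
    canny_lo = canny_lo,
    canny_hi = canny_hi,
    tophat_px = odd(2 * tophat_radius_mm / scale_mm_per_px),
    wall_px = wall_mm / scale_mm_per_px,
    edge_guard_px = edge_guard_mm / scale_mm_per_px,
    speckle_seed = speckle_seed
  )
}

# Replace every connected component of a binary mask by its filled convex
# hull (Sklansky-style: grDevices::chull vertices, scanline rasterized).
fill_convex_components <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n == 0) return(mask)
  out <- mask
  idx <- which(lab > 0)
  W <- dim(mask)[1]
  xs_all <- (idx - 1) %% W + 1
  ys_all <- (idx - 1) %/% W + 1
  labs <- lab[idx]
  ord <- order(labs)
  xs_all <- xs_all[ord]; ys_all <- ys_all[ord]; labs <- labs[ord]
  starts <- c(1, which(diff(labs) > 0) + 1, length(labs) + 1)
  for (k in seq_len(n)) {
    sel <- starts[k]:(starts[k + 1] - 1)
    xs <- xs_all[sel]; ys <- ys_all[sel]
    if (length(xs) < 3) next
    hidx <- grDevices::chull(xs, ys)
    vx <- xs[hidx]; vy <- ys[hidx]
    if (length(vx) < 3) next
    vx2 <- c(vx, vx[1]); vy2 <- c(vy, vy[1])
    for (yr in seq(min(vy), max(vy))) {
      xi <- numeric(0)
      for (e in seq_len(length(vx))) {
        y1 <- vy2[e]; y2 <- vy2[e + 1]
        if ((y1 <= yr && y2 >= yr) || (y2 <= yr && y1 >= yr)) {
          if (y1 == y2) {
            xi <- c(xi, vx2[e], vx2[e + 1])
          } else {
            xi <- c(xi, vx2[e] + (yr - y1) * (vx2[e + 1] - vx2[e]) / (y2 - y1))
          }
        }
      }
      if (length(xi) >= 1) {
        x0 <- ceiling(min(xi) - 1e-9); x1 <- floor(max(xi) + 1e-9)
        if (x1 >= x0) out[x0:x1, yr] <- TRUE
      }
    }
  }
  out
}

#' Binarize the inner plate region
#'
#' Gaussian blur followed by adaptive Gaussian thresholding (a pixel is
#' foreground when it exceeds its Gaussian-weighted local mean minus the
#' offset), restricted to the inner disc (dish radius minus the plastic
#' wall); small components are removed and every remaining component is
#' replaced by its convex hull.
#'
#' @param crop a `crop_image`.
#' @param p parameters from [inner_params()].
#' @return logical matrix (crop-local foreground mask).
#' @export
segment_inner <- function(crop, p = inner_params(crop$geom$scale_mm_per_px)) {
  gray <- crop$gray
  blur <- EBImage::gblur(gray, p$blur_sigma_px)
  block <- min(p$block_px, odd(min(dim(gray)) - 2))
  lm <- EBImage::filter2(blur, gaussian_mean_kernel(block))
  fg <- blur > lm - p$offset_gray / 255
  D <- dist_from(dim(gray)[1], dim(gray)[2], crop$center_local)
  # the guard keeps the agar-to-wall brightness ramp (smeared inwards by the
  # blur, and shifted by dish-detection error) out of the threshold output
  r_in <- crop$geom$radius_px - p$wall_px - p$edge_guard_px
  fg <- fg & (D <= r_in)
  lab <- EBImage::bwlabel(fg)
  if (max(lab) > 0) {
    area <- tabulate(lab[lab > 0], nbins = max(lab))
    drop <- which(area < p$min_area_px)
    if (length(drop)) fg[lab %in% drop] <- FALSE
  }
  fill_convex_components(fg)
}

#' Segment colony-like blobs in the border annulus
#'
#' Operates in the annulus between the inner disc and the crop bounds.  The
#' fixed stage order is: multiplicative speckle-noise injection (to break the
#' smooth plastic-wall gradient), Canny-style hysteresis edge detection
#' (during which edge pixels whose gradient is radial and which sit on the
#' fitted wall circles are identified as plastic border and removed),
#' erosion, hole filling, and a final top-hat debris filter whose output is
#' subtracted from the mask.
#'
#' @param crop a `crop_image`.
#' @param geom the `dish_geometry` (defaults to the crop's own).
#' @param p parameters from [border_params()].
#' @return logical matrix; `TRUE` only inside the annulus.
#' @export
segment_border <- function(crop, geom = crop$geom,
                           p = border_params(geom$scale_mm_per_px)) {
  gray <- crop$gray
  W <- dim(gray)[1]; H <- dim(gray)[2]
  D <- dist_from(W, H, crop$center_local)
  r_in <- geom$radius_px - p$wall_px
  # the annulus abuts the guarded inner disc so the two masks tile the crop
  # without a gap that would split a wall-straddling colony in two
  ann <- D > r_in - p$edge_guard_px
  if (!any(ann)) return(matrix(FALSE, W, H))

  sp <- gray
  n_ann <- sum(ann)
  sp[ann] <- with_seed(p$speckle_seed,
                       gray[ann] * (1 + runif(n_ann, -p$speckle_amp, p$speckle_amp)))

  # Canny stage: Gaussian derivative (smoothing is part of the operator)
  sp <- EBImage::gblur(sp, p$canny_sigma_px)
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- EBImage::filter2(sp, kx)
  gy <- EBImage::filter2(sp, t(kx))
  mag <- sqrt(gx^2 + gy^2)
  rng <- range(sp[ann])
  lo <- p$canny_lo * diff(rng); hi <- p$canny_hi * diff(rng)

  # edges over the whole crop so outlines of wall-straddling colonies stay
  # closed and can be hole-filled; the annulus restriction is applied last
  weak <- mag > lo
  strong <- mag > hi
  # plastic-border removal: radial gradients on the fitted wall circles
  xs <- matrix(seq_len(W) - crop$center_local[1], W, H)
  ys <- matrix(seq_len(H) - crop$center_local[2], W, H, byrow = TRUE)
  dd <- pmax(D, 1e-6)
  dotr <- abs((gx * xs + gy * ys) / (pmax(mag, 1e-9) * dd))
  on_wall <- (abs(D - r_in) < 4 | abs(D - geom$radius_px) < 4) & dotr > 0.94
  weak[on_wall] <- FALSE
  strong[on_wall] <- FALSE

  weak <- EBImage::dilate(weak, EBImage::makeBrush(3, "box"))
  lw <- EBImage::bwlabel(weak)
  keep <- unique(lw[strong & lw > 0])
  edges <- matrix(lw %in% keep & lw > 0, W, H)

  er <- EBImage::erode(edges, EBImage::makeBrush(3, "box"))
  filled <- EBImage::fillHull(er) > 0
  th <- EBImage::whiteTopHat(filled + 0, EBImage::makeBrush(p$tophat_px, "disc")) > 0.5
  out <- filled & !th
  out & ann
}

#' Assemble a category-labelled segment map
#'
#' The union of the inner and border foreground masks becomes the "colonies"
#' segments (initial sublabel `"1 colony"`, revised by [split_groups()]);
#' remaining pixels inside the dish circle form one `"0 colonies"` (agar)
#' segment and pixels outside it one `"out of plate"` segment, so segment ids
#' tile the crop.
#'
#' @param inner_mask,border_mask logical crop-local masks (overlap resolved by
#'   union).
#' @param crop the `crop_image` the masks refer to.
#' @param geom the `dish_geometry` (defaults to the crop's own).
#' @return object of class `segment_map`: integer `labels` matrix (id 1 =
#'   out of plate, 2 = agar, 3.. = colony segments) and a `segments` data
#'   frame with `id`, `supercategory`, `sublabel`, `area_px`.
#' @export
build_segment_map <- function(inner_mask, border_mask, crop, geom = crop$geom) {
  stopifnot(identical(dim(inner_mask), dim(border_mask)))
  fg <- inner_mask | border_mask
  lab <- EBImage::bwlabel(fg)
  n <- max(lab)
  W <- dim(fg)[1]; H <- dim(fg)[2]
  D <- dist_from(W, H, crop$center_local)
  labels <- matrix(2L, W, H)
  labels[D > geom$radius_px] <- 1L
  labels[fg] <- lab[fg] + 2L
  areas <- tabulate(labels, nbins = n + 2L)
  segments <- data.frame(
    id = seq_len(n + 2L),
    supercategory = c("background", "background", rep("colonies", n)),
    sublabel = c("out of plate", "0 colonies", rep("1 colony", n)),
    area_px = areas,
    stringsAsFactors = FALSE
  )
  structure(list(labels = labels, segments = segments,
                 crop_origin = crop$origin,
                 center_local = crop$center_local,
                 geom = geom),
            class = "segment_map")
}

#' @export
print.segment_map <- function(x, ...) {
  n <- sum(x$segments$supercategory == "colonies")
  cat(sprintf("<segment_map> %d x %d px, %d colony segments\n",
              dim(x$labels)[1], dim(x$labels)[2], n))
  invisible(x)
}

#' Run the full classical detector: dish, crop, inner + border segmentation
#'
#' Convenience wrapper chaining [detect_dish()], [crop_dish()],
#' [segment_inner()], [segment_border()] and [build_segment_map()].  Any
#' callable with the same signature (`plate`, `...` -> `segment_map`) can
#' stand in for it downstream, which is the slot a learned panoptic model
#' would occupy.
#'
#' @param plate a `plate_image`.
#' @param labware_center_px,diameter_range_mm,scale_mm_per_px passed to
#'   [detect_dish()].
#' @param inner,border parameter lists from [inner_params()] /
#'   [border_params()]; defaults derived from the scale.
#' @return list with `geom`, `crop` and `segmap`.
#' @export
segment_plate <- function(plate, labware_center_px = NULL,
                          diameter_range_mm = c(85, 89),
                          scale_mm_per_px = NULL,
                          inner = NULL, border = NULL) {
  geom <- detect_dish(plate, labware_center_px, diameter_range_mm,
                      scale_mm_per_px)
  crop <- crop_dish(plate, geom)
  if (is.null(inner)) inner <- inner_params(geom$scale_mm_per_px)
  if (is.null(border)) border <- border_params(geom$scale_mm_per_px)
  im <- segment_inner(crop, inner)
  bm <- segment_border(crop, geom, border)
  segmap <- build_segment_map(im, bm, crop, geom)
  list(geom = geom, crop = crop, segmap = segmap)
}
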