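#' Parameters for a synthetic Petri-dish plate
#'
#' Bundles everything the plate renderer needs: dish geometry, colony load,
#' grouping/border fractions, phenotype colours, fluorescence levels,
#' illumination and noise. Defaults emulate a standard 87 mm dish imaged at
#' 0.1 mm/px with a mixed white/blue colony population.
#'
#' @param image_size_px side of the square output image, px.
#' @param dish_outer_diameter_mm outer diameter of the dish, mm (commercial
#'   dishes run 85-89 mm).
#' @param dish_center_px dish centre `c(x, y)` in px; default image centre.
#' @param scale_mm_per_px camera scale, mm per pixel.
#' @param n_colonies number of colonies to place.
#' @param group_fraction fraction of colonies placed in touching pairs/triples.
#' @param border_fraction fraction of colonies placed inside the unpickable
#'   security margin next to the dish wall.
#' @param artifact_count number of small non-colony specks (dust-like).
#' @param color_phenotypes list of phenotypes, each
#'   `list(name=, rgb=c(r,g,b) 0-255, fraction=)`; fractions sum to 1.
#' @param fluorescence_levels optional list of `list(level= 0-255, fraction=)`;
#'   when given, a co-registered 8-bit fluorescence channel is rendered.
#' @param illumination_gradient maximum relative deviation of the linear
#'   illumination ramp across the image (e.g. 0.10 for +/-10%).
#' @param noise_sigma Gaussian sensor noise, 8-bit gray levels.
#' @param colony_radius_range_mm `c(min, max)` colony radius, mm.
#' @param margin_mm unpickable security margin measured from the inner dish
#'   wall, mm.
#' @param wall_mm thickness of the plastic dish wall, mm.
#' @param min_pick_diameter_mm smallest colony diameter a robot tip can
#'   transfer reliably, mm.
#' @param seed integer RNG seed; a fixed seed makes the render bit-identical.
#' @return object of class `plate_params`.
#' @export
plate_params <- function(image_size_px = 940,
                         dish_outer_diameter_mm = 87,
                         dish_center_px = NULL,
                         scale_mm_per_px = 0.1,
                         n_colonies = 50,
                         group_fraction = 0.1,
                         border_fraction = 0.05,
                         artifact_count = 3,
                         color_phenotypes = default_phenotypes(),
                         fluorescence_levels = NULL,
                         illumination_gradient = 0.10,
                         noise_sigma = 3,
                         colony_radius_range_mm = c(0.6, 2.5),
                         margin_mm = 2,
                         wall_mm = 2,
                         min_pick_diameter_mm = 1,
                         seed = 1L) {
  if (is.null(dish_center_px)) {
    dish_center_px <- c(1, 1) + (image_size_px - 1) / 2
  }
  p <- structure(list(
    image_size_px = as.integer(image_size_px),
    dish_outer_diameter_mm = dish_outer_diameter_mm,
    dish_center_px = dish_center_px,
    scale_mm_per_px = scale_mm_per_px,
    n_colonies = as.integer(n_colonies),
    group_fraction = group_fraction,
    border_fraction = border_fraction,
    artifact_count = as.integer(artifact_count),
    color_phenotypes = color_phenotypes,
    fluorescence_levels = fluorescence_levels,
    illumination_gradient = illumination_gradient,
    noise_sigma = noise_sigma,
    colony_radius_range_mm = colony_radius_range_mm,
    margin_mm = margin_mm,
    wall_mm = wall_mm,
    min_pick_diameter_mm = min_pick_diameter_mm,
    seed = as.integer(seed)
  ), class = "plate_params")
  validate_plate_params(p)
  p
}

#' @export
print.plate_params <- function(x, ...) {
  cat(sprintf(
    "<plate_params> %d px, dish %.1f mm @ %.3f mm/px, %d colonies (%.0f%% grouped, %.0f%% border), %d artifacts, seed %d\n",
    x$image_size_px, x$dish_outer_diameter_mm, x$scale_mm_per_px,
    x$n_colonies, 100 * x$group_fraction, 100 * x$border_fraction,
    x$artifact_count, x$seed))
  invisible(x)
}

#' Default white/blue phenotype mix
#'
#' Two colour phenotypes mimicking a blue/white screen: plain white colonies
#' and X-gal blue colonies, mixed 50/50.
#' @return list of phenotype descriptors.
#' @export
default_phenotypes <- function() {
  list(
    list(name = "white", rgb = c(222, 218, 202), fraction = 0.5),
    list(name = "blue",  rgb = c(110, 130, 212), fraction = 0.5)
  )
}

validate_plate_params <- function(p) {
  if (p$n_colonies < 0) stop_ctx("n_colonies must be >= 0")
  fr <- c(p$group_fraction, p$border_fraction,
          vapply(p$color_phenotypes, `[[`, numeric(1), "fraction"))
  if (any(fr < 0 | fr > 1)) stop_ctx("fractions must lie in [0, 1]")
  if (p$scale_mm_per_px <= 0) stop_ctx("scale_mm_per_px must be > 0")
  r_out <- p$dish_outer_diameter_mm / (2 * p$scale_mm_per_px)
  ctr <- p$dish_center_px
  if (ctr[1] - r_out < 1 || ctr[2] - r_out < 1 ||
      ctr[1] + r_out > p$image_size_px || ctr[2] + r_out > p$image_size_px) {
    stop_ctx("dish does not fit inside the image")
  }
  if (p$wall_mm + p$margin_mm >= p$dish_outer_diameter_mm / 2) {
    stop_ctx("wall + margin exceed dish radius")
  }
  invisible(p)
}

# Rejection-sampling placement of all colonies and artifacts.  Returns a
# data.frame of colony records and one of artifact records, both in image px.
place_colonies <- function(p) {
  r_out <- p$dish_outer_diameter_mm / (2 * p$scale_mm_per_px)
  r_in <- r_out - p$wall_mm / p$scale_mm_per_px
  margin_px <- p$margin_mm / p$scale_mm_per_px
  rr_px <- p$colony_radius_range_mm / p$scale_mm_per_px
  ctr <- p$dish_center_px
  n <- p$n_colonies
  budget <- 10000L  # per-colony retry budget

  n_grouped <- round(p$group_fraction * n)
  if (n_grouped < 2) n_grouped <- 0L
  n_triples <- if (n_grouped %% 2 == 1) 1L else 0L
  n_pairs <- (n_grouped - 3L * n_triples) / 2L
  group_sizes <- c(rep(3L, n_triples), rep(2L, n_pairs))
  n_border <- min(round(p$border_fraction * n), n - n_grouped)
  n_single <- n - n_grouped - n_border

  xs <- ys <- rs <- numeric(0)
  gid <- integer(0)
  border <- logical(0)

  fits <- function(x, y, r, skip_group = NA_integer_) {
    if (length(xs) == 0) return(TRUE)
    keep <- if (is.na(skip_group)) rep(TRUE, length(xs)) else
      (is.na(gid) | gid != skip_group)
    if (!any(keep)) return(TRUE)
    all((x - xs[keep])^2 + (y - ys[keep])^2 >= (r + rs[keep] + 2)^2)
  }
  draw_r <- function() runif(1, rr_px[1], rr_px[2])
  draw_xy <- function(dmax, dmin = 0) {
    d <- sqrt(runif(1, (dmin / dmax)^2, 1)) * dmax
    a <- runif(1, 0, 2 * pi)
    c(ctr[1] + d * cos(a), ctr[2] + d * sin(a))
  }
  add <- function(x, y, r, g, b) {
    xs <<- c(xs, x); ys <<- c(ys, y); rs <<- c(rs, r)
    gid <<- c(gid, g); border <<- c(border, b)
  }
  place_one <- function(kind, group = NA_integer_, anchor = NULL) {
    for (try in seq_len(budget)) {
      r <- draw_r()
      if (kind == "border") {
        dmax <- r_in - 2
        dmin <- max(0, r_in - margin_px + 1)
        if (dmin >= dmax) dmin <- dmax * 0.98
        pt <- draw_xy(dmax, dmin)
      } else if (kind == "companion") {
        sep <- runif(1, 0.78, 0.95) * (r + anchor$r)
        a <- runif(1, 0, 2 * pi)
        pt <- c(anchor$x + sep * cos(a), anchor$y + sep * sin(a))
        if (sqrt(sum((pt - ctr)^2)) > r_in - margin_px - r) next
      } else {
        dmax <- max(1, r_in - margin_px - r)
        pt <- draw_xy(dmax)
      }
      if (fits(pt[1], pt[2], r, skip_group = group)) {
        add(pt[1], pt[2], r, group, kind == "border")
        return(TRUE)
      }
    }
    stop_ctx("placement-retry budget exhausted: cannot place %d colonies on this dish",
             p$n_colonies)
  }

  g <- 0L
  for (sz in group_sizes) {
    g <- g + 1L
    place_one("interior", group = g)
    for (k in seq_len(sz - 1L)) {
      i_anchor <- length(xs)
      place_one("companion", group = g,
                anchor = list(x = xs[i_anchor], y = ys[i_anchor], r = rs[i_anchor]))
    }
  }
  for (k in seq_len(n_single)) place_one("interior")
  for (k in seq_len(n_border)) place_one("border")

  ph_idx <- if (n > 0) {
    sample.int(length(p$color_phenotypes), n, replace = TRUE,
               prob = vapply(p$color_phenotypes, `[[`, numeric(1), "fraction"))
  } else integer(0)
  fl <- rep(NA_real_, n)
  if (!is.null(p$fluorescence_levels) && n > 0) {
    li <- sample.int(length(p$fluorescence_levels), n, replace = TRUE,
                     prob = vapply(p$fluorescence_levels, `[[`, numeric(1), "fraction"))
    fl <- vapply(p$fluorescence_levels, `[[`, numeric(1), "level")[li]
  }

  d_ctr <- sqrt((xs - ctr[1])^2 + (ys - ctr[2])^2)
  colonies <- data.frame(
    id = seq_len(n),
    x_px = xs, y_px = ys,
    x_mm = (xs - ctr[1]) * p$scale_mm_per_px,
    y_mm = (ys - ctr[2]) * p$scale_mm_per_px,
    radius_px = rs,
    radius_mm = rs * p$scale_mm_per_px,
    phenotype = if (n > 0)
      vapply(p$color_phenotypes, `[[`, character(1), "name")[ph_idx] else character(0),
    fluor_level = fl,
    group_id = gid,
    border = border,
    pickable = d_ctr <= r_in - margin_px &
      2 * rs * p$scale_mm_per_px >= p$min_pick_diameter_mm,
    stringsAsFactors = FALSE
  )

  n_art <- p$artifact_count
  ax <- ay <- ar <- numeric(0)
  for (k in seq_len(n_art)) {
    for (try in seq_len(budget)) {
      r <- runif(1, 0.10, 0.25) / p$scale_mm_per_px
      pt <- draw_xy(max(1, r_in - margin_px - r))
      ok <- length(xs) == 0 ||
        all((pt[1] - xs)^2 + (pt[2] - ys)^2 >= (r + rs + 3)^2)
      if (ok && (length(ax) == 0 ||
                 all((pt[1] - ax)^2 + (pt[2] - ay)^2 >= (r + ar + 3)^2))) {
        ax <- c(ax, pt[1]); ay <- c(ay, pt[2]); ar <- c(ar, r)
        break
      }
      if (try == budget) stop_ctx("placement-retry budget exhausted for artifacts")
    }
  }
  artifacts <- data.frame(id = seq_len(n_art), x_px = ax, y_px = ay,
                          radius_px = ar)

  list(colonies = colonies, artifacts = artifacts,
       dish = list(center_px = ctr, r_out_px = r_out, r_in_px = r_in,
                   margin_px = margin_px, wall_mm = p$wall_mm,
                   outer_diameter_mm = p$dish_outer_diameter_mm,
                   scale_mm_per_px = p$scale_mm_per_px))
}

# Alpha-blend a radially decaying dome (truncated Gaussian, sigma = r/2) of
# colour `col` into `img` ([x, y, 3]) at centre (cx, cy), radius r px.
blend_dome <- function(img, cx, cy, r, col) {
  w <- dim(img)[1]; h <- dim(img)[2]
  x0 <- max(1L, floor(cx - r - 1)); x1 <- min(w, ceiling(cx + r + 1))
  y0 <- max(1L, floor(cy - r - 1)); y1 <- min(h, ceiling(cy + r + 1))
  if (x0 > x1 || y0 > y1) return(img)
  dx2 <- (x0:x1 - cx)^2
  dy2 <- (y0:y1 - cy)^2
  d2 <- outer(dx2, dy2, `+`)
  f <- exp(-d2 / (2 * (r / 2)^2))
  f[d2 > r^2] <- 0
  for (ch in 1:3) {
    patch <- img[x0:x1, y0:y1, ch]
    img[x0:x1, y0:y1, ch] <- patch + f * (col[ch] - patch)
  }
  img
}

#' Render a synthetic plate image with exhaustive ground truth
#'
#' Renders a circular Petri dish (bright plastic wall, agar fill) on a dark
#' background, places colonies as radially decaying bright domes (including
#' touching groups and colonies inside the wall margin), adds dust-like
#' specks, a linear illumination ramp and Gaussian sensor noise, and
#' quantizes to 8 bits.  A co-registered fluorescence channel is rendered
#' when `params$fluorescence_levels` is set.  The render is deterministic
#' for a fixed seed.
#'
#' @param params a [plate_params()] object.
#' @return list with `plate` (class `plate_image`: `rgb` array `[x, y, 3]` in
#'   \[0, 1\], optional `fluor` matrix, `meta`) and `truth` (class
#'   `gt_plate`: `colonies` and `artifacts` data frames plus dish geometry).
#' @export
generate_plate <- function(params) {
  validate_plate_params(params)
  with_seed(params$seed, {
    placed <- place_colonies(params)
    W <- params$image_size_px
    ctr <- params$dish_center_px
    dish <- placed$dish

    bg <- c(0.080, 0.080, 0.085)
    agar <- c(0.400, 0.380, 0.310)
    wallc <- c(0.590, 0.580, 0.550)
    D <- dist_from(W, W, ctr)
    t_out <- clamp01((dish$r_out_px - D) / 1.5)
    t_in <- clamp01((dish$r_in_px - D) / 1.5)
    img <- array(0, dim = c(W, W, 3))
    for (ch in 1:3) {
      img[, , ch] <- bg[ch] + t_out * (wallc[ch] - bg[ch]) +
        t_in * (agar[ch] - wallc[ch])
    }

    ph_cols <- lapply(params$color_phenotypes, function(x) x$rgb / 255)
    names(ph_cols) <- vapply(params$color_phenotypes, `[[`, character(1), "name")
    co <- placed$colonies
    for (i in seq_len(nrow(co))) {
      img <- blend_dome(img, co$x_px[i], co$y_px[i], co$radius_px[i],
                        ph_cols[[co$phenotype[i]]])
    }
    ar <- placed$artifacts
    for (i in seq_len(nrow(ar))) {
      img <- blend_dome(img, ar$x_px[i], ar$y_px[i], ar$radius_px[i],
                        c(0.92, 0.92, 0.90))
    }

    if (params$illumination_gradient > 0) {
      th <- runif(1, 0, 2 * pi)
      ramp <- outer(seq_len(W) - ctr[1], seq_len(W) - ctr[2],
                    function(dx, dy) dx * cos(th) + dy * sin(th)) / (W / 2)
      gain <- 1 + params$illumination_gradient * ramp
      for (ch in 1:3) img[, , ch] <- img[, , ch] * gain
    }
    if (params$noise_sigma > 0) {
      img <- img + array(rnorm(length(img), 0, params$noise_sigma / 255),
                         dim = dim(img))
    }
    img <- quantize8(img)

    fluor <- NULL
    if (!is.null(params$fluorescence_levels)) {
      fluor <- matrix(0.02, W, W)
      fluor[D <= dish$r_in_px] <- 0.04
      for (i in seq_len(nrow(co))) {
        x0 <- max(1L, floor(co$x_px[i] - co$radius_px[i] - 1))
        x1 <- min(W, ceiling(co$x_px[i] + co$radius_px[i] + 1))
        y0 <- max(1L, floor(co$y_px[i] - co$radius_px[i] - 1))
        y1 <- min(W, ceiling(co$y_px[i] + co$radius_px[i] + 1))
        d <- sqrt(outer((x0:x1 - co$x_px[i])^2, (y0:y1 - co$y_px[i])^2, `+`))
        a <- clamp01(co$radius_px[i] - d)  # flat disc, 1 px soft edge
        patch <- fluor[x0:x1, y0:y1]
        fluor[x0:x1, y0:y1] <- patch + a * (co$fluor_level[i] / 255 - patch)
      }
      if (params$noise_sigma > 0) {
        fluor <- fluor + matrix(rnorm(length(fluor), 0, params$noise_sigma / 255), W, W)
      }
      fluor <- quantize8(fluor)
    }

    plate <- structure(list(
      rgb = img, fluor = fluor,
      meta = list(scale_mm_per_px = params$scale_mm_per_px,
                  labware_center_px = c(1, 1) + (W - 1) / 2,
                  image_size_px = W)
    ), class = "plate_image")
    truth <- structure(list(
      colonies = placed$colonies, artifacts = placed$artifacts,
      dish = dish, params = params
    ), class = "gt_plate")
    list(plate = plate, truth = truth)
  })
}

#' @export
print.plate_image <- function(x, ...) {
  cat(sprintf("<plate_image> %d x %d px, %s fluorescence channel, %.3f mm/px\n",
              dim(x$rgb)[1], dim(x$rgb)[2],
              if (is.null(x$fluor)) "no" else "with",
              x$meta$scale_mm_per_px))
  invisible(x)
}

#' @export
print.gt_plate <- function(x, ...) {
  cat(sprintf("<gt_plate> %d colonies (%d pickable), %d artifacts, dish r=%.1f px\n",
              nrow(x$colonies), sum(x$colonies$pickable), nrow(x$artifacts),
              x$dish$r_out_px))
  invisible(x)
}

#' Canonical synthetic benchmark profile
#'
#' `"benchmark-v1"` is fixed in code: 20 plates under master seed 42, per-plate
#' colony counts drawn uniformly from 12-453, 10% of colonies in touching
#' groups, 5% inside the wall margin, 3 dust specks per plate, 10%
#' illumination gradient, noise sigma 3 gray levels, colony radii 0.6-2.5 mm,
#' two colour phenotypes, 0.1 mm/px.
#'
#' @param profile profile name; only `"benchmark-v1"` is defined.
#' @param n_plates,master_seed,n_colonies_range overrides for reduced
#'   exploratory runs; the canonical profile leaves them at their defaults.
#' @return object of class `benchmark_params`.
#' @export
benchmark_params <- function(profile = "benchmark-v1",
                             n_plates = 20L,
                             master_seed = 42L,
                             n_colonies_range = c(12L, 453L)) {
  if (!identical(profile, "benchmark-v1")) {
    stop_ctx("unknown benchmark profile: %s", profile)
  }
  structure(list(
    profile = profile,
    n_plates = as.integer(n_plates),
    master_seed = as.integer(master_seed),
    n_colonies_range = as.integer(n_colonies_range),
    group_fraction = 0.10,
    border_fraction = 0.05,
    artifact_count = 3L,
    illumination_gradient = 0.10,
    noise_sigma = 3,
    colony_radius_range_mm = c(0.6, 2.5),
    scale_mm_per_px = 0.1,
    image_size_px = 940L,
    dish_diameter_range_mm = c(85, 89)
  ), class = "benchmark_params")
}

#' Plate parameters for one benchmark plate
#'
#' Per-plate colony counts, dish diameters and centre jitter are drawn once
#' from the benchmark's master seed, so plate `i` is identical no matter how
#' many of its siblings are generated (streaming-friendly).
#'
#' @param bench a [benchmark_params()] object.
#' @param i plate index, 1-based.
#' @return a [plate_params()] object.
#' @export
benchmark_plate_params <- function(bench, i) {
  stopifnot(i >= 1, i <= bench$n_plates)
  draws <- with_seed(bench$master_seed, {
    data.frame(
      n = sample(bench$n_colonies_range[1]:bench$n_colonies_range[2],
                 bench$n_plates, replace = TRUE),
      d = runif(bench$n_plates, bench$dish_diameter_range_mm[1],
                bench$dish_diameter_range_mm[2]),
      jx = runif(bench$n_plates, -8, 8),
      jy = runif(bench$n_plates, -8, 8)
    )
  })
  ctr <- c(1, 1) + (bench$image_size_px - 1) / 2
  plate_params(
    image_size_px = bench$image_size_px,
    dish_outer_diameter_mm = draws$d[i],
    dish_center_px = ctr + c(draws$jx[i], draws$jy[i]),
    scale_mm_per_px = bench$scale_mm_per_px,
    n_colonies = draws$n[i],
    group_fraction = bench$group_fraction,
    border_fraction = bench$border_fraction,
    artifact_count = bench$artifact_count,
    illumination_gradient = bench$illumination_gradient,
    noise_sigma = bench$noise_sigma,
    colony_radius_range_mm = bench$colony_radius_range_mm,
    seed = bench$master_seed * 10000L + as.integer(i)
  )
}

#' Generate every plate of a benchmark
#'
#' @param bench a [benchmark_params()] object.
#' @return list of `list(plate=, truth=)`, one per plate.  For memory-lean
#'   streaming over large benchmarks, call [benchmark_plate_params()] and
#'   [generate_plate()] per index instead.
#' @export
generate_benchmark <- function(bench) {
  lapply(seq_len(bench$n_plates), function(i) {
    generate_plate(benchmark_plate_params(bench, i))
  })
}

gt_csv_cols <- c("record_type", "id", "x_px", "y_px", "x_mm", "y_mm",
                 "radius_px", "radius_mm", "phenotype", "fluor_level",
                 "group_id", "border", "pickable",
                 "dish_cx_px", "dish_cy_px", "dish_r_out_px", "dish_r_in_px",
                 "margin_px", "scale_mm_per_px")

#' Write / read plate ground truth as CSV
#'
#' One row per colony and per artifact (`record_type` column distinguishes
#' them); the constant dish-geometry columns make the file self-describing so
#' it round-trips losslessly through [read_ground_truth()].
#'
#' @param gt a `gt_plate` object from [generate_plate()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  co <- gt$colonies
  n <- nrow(co)
  rows <- data.frame(
    record_type = rep("colony", n), id = co$id,
    x_px = co$x_px, y_px = co$y_px, x_mm = co$x_mm, y_mm = co$y_mm,
    radius_px = co$radius_px, radius_mm = co$radius_mm,
    phenotype = co$phenotype, fluor_level = co$fluor_level,
    group_id = co$group_id, border = co$border, pickable = co$pickable,
    stringsAsFactors = FALSE
  )
  ar <- gt$artifacts
  if (nrow(ar) > 0) {
    arows <- data.frame(
      record_type = "artifact", id = ar$id,
      x_px = ar$x_px, y_px = ar$y_px, x_mm = NA_real_, y_mm = NA_real_,
      radius_px = ar$radius_px, radius_mm = NA_real_,
      phenotype = NA_character_, fluor_level = NA_real_,
      group_id = NA_integer_, border = NA, pickable = NA,
      stringsAsFactors = FALSE
    )
    rows <- rbind(rows, arows)
  }
  d <- gt$dish
  nr <- nrow(rows)
  rows$dish_cx_px <- rep(d$center_px[1], nr)
  rows$dish_cy_px <- rep(d$center_px[2], nr)
  rows$dish_r_out_px <- rep(d$r_out_px, nr)
  rows$dish_r_in_px <- rep(d$r_in_px, nr)
  rows$margin_px <- rep(d$margin_px, nr)
  rows$scale_mm_per_px <- rep(d$scale_mm_per_px, nr)
  ok <- try(utils::write.csv(rows[, gt_csv_cols], path, row.names = FALSE,
                             na = ""), silent = TRUE)
  if (inherits(ok, "try-error")) stop_ctx("cannot write ground truth to '%s'", path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @param dish fallback dish geometry for header-only files (a list like
#'   `gt$dish`); normally recovered from the file itself.
#' @return for the reader, a `gt_plate` object (without the params echo).
#' @export
read_ground_truth <- function(path, dish = NULL) {
  if (!file.exists(path)) stop_ctx("ground truth file not found: '%s'", path)
  rows <- utils::read.csv(path, stringsAsFactors = FALSE)
  co <- rows[rows$record_type == "colony", , drop = FALSE]
  ar <- rows[rows$record_type == "artifact", , drop = FALSE]
  if (nrow(rows) > 0) {
    dish <- list(center_px = c(rows$dish_cx_px[1], rows$dish_cy_px[1]),
                 r_out_px = rows$dish_r_out_px[1],
                 r_in_px = rows$dish_r_in_px[1],
                 margin_px = rows$margin_px[1],
                 scale_mm_per_px = rows$scale_mm_per_px[1])
  }
  colonies <- data.frame(
    id = as.integer(co$id), x_px = co$x_px, y_px = co$y_px,
    x_mm = co$x_mm, y_mm = co$y_mm, radius_px = co$radius_px,
    radius_mm = co$radius_mm, phenotype = as.character(co$phenotype),
    fluor_level = as.numeric(co$fluor_level),
    group_id = as.integer(co$group_id),
    border = as.logical(co$border), pickable = as.logical(co$pickable),
    stringsAsFactors = FALSE
  )
  artifacts <- data.frame(id = as.integer(ar$id), x_px = ar$x_px,
                          y_px = ar$y_px, radius_px = ar$radius_px)
  structure(list(colonies = colonies, artifacts = artifacts, dish = dish,
                 params = NULL), class = "gt_plate")
}

#' Write a plate image (and optional fluorescence channel) as 8-bit PNG
#'
#' @param plate a `plate_image`.
#' @param path RGB PNG path.
#' @param fluor_path optional grayscale PNG path for the fluorescence channel.
#' @return `path`, invisibly.
#' @export
write_plate_image <- function(plate, path, fluor_path = NULL) {
  png::writePNG(aperm(plate$rgb, c(2, 1, 3)), path)
  if (!is.null(fluor_path)) {
    if (is.null(plate$fluor)) stop_ctx("plate has no fluorescence channel")
    png::writePNG(t(plate$fluor), fluor_path)
  }
  invisible(path)
}

#' Read a plate image from PNG/TIFF files
#'
#' @param path RGB image path (PNG or TIFF, 8-bit).
#' @param fluor_path optional co-registered grayscale fluorescence image.
#' @param scale_mm_per_px camera scale to record in the metadata.
#' @param labware_center_px labware reference point in px; default image
#'   centre.
#' @return a `plate_image`.
#' @export
read_plate_image <- function(path, fluor_path = NULL, scale_mm_per_px = NA,
                             labware_center_px = NULL) {
  read_any <- function(f) {
    if (grepl("\\.tiff?$", f, ignore.case = TRUE)) {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop_ctx("the 'tiff' package is required to read '%s'", f)
      }
      tiff::readTIFF(f)
    } else {
      png::readPNG(f)
    }
  }
  a <- read_any(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
  rgb <- aperm(a[, , 1:3, drop = FALSE], c(2, 1, 3))
  fluor <- NULL
  if (!is.null(fluor_path)) {
    f <- read_any(fluor_path)
    if (length(dim(f)) == 3) f <- f[, , 1]
    fluor <- t(f)
  }
  W <- dim(rgb)[1]; H <- dim(rgb)[2]
  if (is.null(labware_center_px)) labware_center_px <- c(1 + (W - 1) / 2, 1 + (H - 1) / 2)
  structure(list(rgb = rgb, fluor = fluor,
                 meta = list(scale_mm_per_px = scale_mm_per_px,
                             labware_center_px = labware_center_px,
                             image_size_px = W)),
            class = "plate_image")
}
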