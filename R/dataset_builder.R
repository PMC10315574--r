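# 15-fold augmentation, COCO-panoptic export and grouped train/validation
# splitting for building colony-detection training corpora.

flip_x <- function(m) {
  if (length(dim(m)) == 3) m[rev(seq_len(dim(m)[1])), , , drop = FALSE]
  else m[rev(seq_len(nrow(m))), , drop = FALSE]
}
flip_y <- function(m) {
  if (length(dim(m)) == 3) m[, rev(seq_len(dim(m)[2])), , drop = FALSE]
  else m[, rev(seq_len(ncol(m))), drop = FALSE]
}
rot90_once <- function(m) {
  if (length(dim(m)) == 3) {
    out <- array(0, dim = c(dim(m)[2], dim(m)[1], dim(m)[3]))
    for (ch in seq_len(dim(m)[3])) out[, , ch] <- rot90_once(m[, , ch])
    out
  } else {
    flip_y(t(m))
  }
}

apply_transform <- function(m, rot, mirror) {
  if (mirror %in% c("h", "hv")) m <- flip_x(m)
  if (mirror %in% c("v", "hv")) m <- flip_y(m)
  for (q in seq_len(rot / 90)) m <- rot90_once(m)
  m
}

transform_table <- function() {
  tt <- expand.grid(rot = c(0L, 90L, 180L, 270L),
                    mirror = c("none", "h", "v", "hv"),
                    stringsAsFactors = FALSE)
  tt$name <- sprintf("rot%03d_mir%s", tt$rot, tt$mirror)
  tt[!(tt$rot == 0L & tt$mirror == "none"), ]
}

#' Produce the 15 rotation/mirror derivatives of an annotated image
#'
#' Enumerates the 16 combinations of quarter-turn rotation and
#' horizontal/vertical mirroring, drops the identity and applies the 15
#' remaining transforms to the image and its segment map together.  Only 8 of
#' the 16 combinations are geometrically distinct (the dihedral group), so
#' some derivatives coincide pixel-wise; they are nevertheless kept as
#' separate dataset entries, which reproduces the established 15-fold
#' augmentation bookkeeping.
#'
#' @param image image array `[x, y, 3]` (or matrix).
#' @param segmap a `segment_map` aligned with the image.
#' @return list of 15 entries `list(image=, segmap=, transform=)`.  Geometry
#'   fields of the transformed segment maps (crop origin, dish centre) are
#'   not updated; derivatives are dataset items, not measurement inputs.
#' @export
augment_image <- function(image, segmap) {
  stopifnot(identical(dim(image)[1:2], dim(segmap$labels)))
  tt <- transform_table()
  lapply(seq_len(nrow(tt)), function(i) {
    sm <- segmap
    sm$labels <- apply_transform(segmap$labels, tt$rot[i], tt$mirror[i])
    list(image = apply_transform(image, tt$rot[i], tt$mirror[i]),
         segmap = sm,
         transform = tt$name[i])
  })
}

panoptic_categories <- function(max_k = 12L) {
  data.frame(
    id = c(1L, 2L, 2L + seq_len(max_k)),
    name = c("out of plate", "0 colonies",
             sprintf("%d colon%s", seq_len(max_k),
                     ifelse(seq_len(max_k) == 1, "y", "ies"))),
    supercategory = c("background", "background", rep("colonies", max_k)),
    stringsAsFactors = FALSE
  )
}

sublabel_to_category <- function(sublabel) {
  k <- ifelse(sublabel == "out of plate", -1L,
              ifelse(sublabel == "0 colonies", 0L,
                     suppressWarnings(as.integer(sub(" .*", "", sublabel)))))
  ifelse(k < 0, 1L, 2L + pmax(k, 0L) * (k > 0) + (k == 0) * 0L)
}

#' Export a segment map as a COCO-panoptic annotation pair
#'
#' The mask PNG encodes each pixel's segment id as `id = R + 256 G + 256^2 B`
#' (8-bit channels); the JSON lists the image, the category table
#' ("colonies" sublabels "1 colony", "2 colonies", ... and "background"
#' sublabels "out of plate", "0 colonies") and per-segment records with id,
#' category, area and bounding box.
#'
#' @param image image array to copy alongside the annotation (written as
#'   `<stem>_image.png`); pass `NULL` to skip.
#' @param segmap a `segment_map`.
#' @param image_id integer id recorded in the JSON.
#' @param out_dir output directory (created if needed).
#' @param stem file stem; files are `<stem>.json`, `<stem>.png`.
#' @return named character vector with `json` and `png` paths.
#' @export
export_panoptic <- function(image, segmap, image_id, out_dir,
                            stem = sprintf("plate_%05d", image_id)) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  lab <- segmap$labels
  if (max(lab) > 2^24 - 1) stop_ctx("segment id overflow beyond 2^24-1")
  png_path <- file.path(out_dir, paste0(stem, ".png"))
  json_path <- file.path(out_dir, paste0(stem, ".json"))
  enc <- array(0, dim = c(dim(lab), 3))
  enc[, , 1] <- (lab %% 256) / 255
  enc[, , 2] <- ((lab %/% 256) %% 256) / 255
  enc[, , 3] <- (lab %/% 65536) / 255
  png::writePNG(aperm(enc, c(2, 1, 3)), png_path)
  if (!is.null(image)) {
    png::writePNG(aperm(image, c(2, 1, 3)), file.path(out_dir, paste0(stem, "_image.png")))
  }

  W <- dim(lab)[1]; H <- dim(lab)[2]
  segs <- segmap$segments
  seg_info <- lapply(seq_len(nrow(segs)), function(i) {
    id <- segs$id[i]
    idx <- which(lab == id)
    if (length(idx) == 0) return(NULL)
    xs <- (idx - 1) %% W; ys <- (idx - 1) %/% W  # 0-based, COCO style
    list(id = id,
         category_id = sublabel_to_category(segs$sublabel[i]),
         area = length(idx),
         bbox = c(min(xs), min(ys), max(xs) - min(xs) + 1, max(ys) - min(ys) + 1))
  })
  seg_info <- Filter(Negate(is.null), seg_info)
  max_k <- max(c(1L, suppressWarnings(as.integer(
    sub(" .*", "", segs$sublabel[segs$supercategory == "colonies"])))), na.rm = TRUE)
  doc <- list(
    images = list(list(id = image_id, width = W, height = H,
                       file_name = paste0(stem, "_image.png"))),
    annotations = list(list(image_id = image_id,
                            file_name = basename(png_path),
                            segments_info = seg_info)),
    categories = panoptic_categories(max_k)
  )
  jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA)
  c(json = json_path, png = png_path)
}

#' Decode a COCO-panoptic mask PNG back to a label matrix
#'
#' @param png_path mask written by [export_panoptic()].
#' @return integer label matrix `[x, y]`.
#' @export
decode_panoptic <- function(png_path) {
  a <- png::readPNG(png_path)
  a <- aperm(a, c(2, 1, 3))
  matrix(as.integer(round(a[, , 1] * 255) + 256 * round(a[, , 2] * 255) +
                      65536 * round(a[, , 3] * 255)),
         dim(a)[1], dim(a)[2])
}

#' Build a dataset manifest from annotated source images
#'
#' Every source contributes its 15 rotation/mirror derivatives; when
#' `out_dir` is given the derivative images and panoptic annotation pairs are
#' written to disk, otherwise the manifest is bookkeeping-only.
#'
#' @param sources list of `list(image=, segmap=)` pairs (e.g. from
#'   [generate_plate()] + [segment_plate()]).
#' @param out_dir optional output directory.
#' @return data frame of class `dataset_manifest`: `item_id`, `source_id`,
#'   `transform`, `image_file`, `json_file`, `mask_file`.
#' @export
build_dataset <- function(sources, out_dir = NULL) {
  rows <- list()
  item <- 0L
  for (s in seq_along(sources)) {
    derivs <- augment_image(sources[[s]]$image, sources[[s]]$segmap)
    for (d in derivs) {
      item <- item + 1L
      img_f <- json_f <- mask_f <- NA_character_
      if (!is.null(out_dir)) {
        stem <- sprintf("src%04d_%s", s, d$transform)
        paths <- export_panoptic(d$image, d$segmap, item, out_dir, stem)
        json_f <- paths[["json"]]; mask_f <- paths[["png"]]
        img_f <- file.path(out_dir, paste0(stem, "_image.png"))
      }
      rows[[item]] <- data.frame(
        item_id = item, source_id = s, transform = d$transform,
        image_file = img_f, json_file = json_f, mask_file = mask_f,
        stringsAsFactors = FALSE
      )
    }
  }
  man <- do.call(rbind, rows)
  class(man) <- c("dataset_manifest", "data.frame")
  man
}

#' Split a dataset into training and validation subsets
#'
#' Splitting is grouped by source image: all derivatives of one source land
#' in the same subset, so augmented copies cannot leak across the split.
#' Source order is shuffled under the seed and sources are accumulated until
#' the training side is as close as possible to `round(train_frac * n)`
#' items.
#'
#' @param manifest a `dataset_manifest`.
#' @param train_frac fraction of items for training (0 < f < 1).
#' @param seed RNG seed making the split reproducible.
#' @return list with `train` and `val` manifests (disjoint, exhaustive).
#' @export
split_dataset <- function(manifest, train_frac = 0.75, seed = 1L) {
  if (nrow(manifest) == 0) stop_ctx("empty dataset manifest")
  if (train_frac <= 0 || train_frac >= 1) stop_ctx("train_frac must be in (0, 1)")
  target <- round(train_frac * nrow(manifest))
  srcs <- unique(manifest$source_id)
  ord <- with_seed(seed, sample(srcs))
  sizes <- as.integer(table(manifest$source_id)[as.character(ord)])
  csum <- cumsum(sizes)
  m <- which.min(abs(csum - target))
  if (abs(csum[m] - target) == abs(c(0, csum)[m] - target)) m <- m - 1L
  train_src <- ord[seq_len(max(0L, m))]
  tr <- manifest$source_id %in% train_src
  list(train = manifest[tr, , drop = FALSE],
       val = manifest[!tr, , drop = FALSE])
}
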