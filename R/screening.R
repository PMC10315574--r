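#' Screening criteria for colony selection
#'
#' Describes how detected colonies are filtered and ranked: optional HSV
#' colour-box and size-range filters, then a normalized weighted score over
#' three marks (size, colour, fluorescence), each in \[0, 1\].
#'
#' @param w_size,w_color,w_fluor non-negative weights of the three marks;
#'   normalized to sum to 1.
#' @param target_color RGB triplet (0-255) the colour mark compares against.
#' @param color_mode `"similar"` (closer to the target scores higher) or
#'   `"dissimilar"`.
#' @param color_range optional HSV inclusion/exclusion box, a list like
#'   `list(h = c(180, 300), s = c(0, 1), v = c(0, 1), mode = "select")`; the
#'   hue interval may wrap through 360.
#' @param size_range_mm optional `c(min, max)` equivalent-diameter filter.
#' @param k number of colonies to pick.
#' @return object of class `screening_criteria`.
#' @export
screening_criteria <- function(w_size = 0, w_color = 0, w_fluor = 0,
                               target_color = c(110, 130, 212),
                               color_mode = c("similar", "dissimilar"),
                               color_range = NULL,
                               size_range_mm = NULL,
                               k = 0L) {
  color_mode <- match.arg(color_mode)
  w <- c(w_size, w_color, w_fluor)
  if (any(w < 0)) stop_ctx("weights must be >= 0")
  if (sum(w) == 0) w <- c(1, 0, 0) else w <- w / sum(w)
  if (k < 0) stop_ctx("k must be >= 0")
  structure(list(w_size = w[1], w_color = w[2], w_fluor = w[3],
                 target_color = target_color, color_mode = color_mode,
                 color_range = color_range, size_range_mm = size_range_mm,
                 k = as.integer(k)),
            class = "screening_criteria")
}

# Embed HSV in the colour cone: (S V cos H, S V sin H, V).  Euclidean
# distance there handles the hue wrap and collapses hue for desaturated or
# dark colours, where hue is meaningless.
hsv_cone <- function(h_deg, s, v) {
  hr <- h_deg * pi / 180
  cbind(s * v * cos(hr), s * v * sin(hr), v)
}

rgb_to_hsv_deg <- function(rgb) {
  x <- grDevices::rgb2hsv(matrix(rgb, 3, 1), maxColorValue = 255)
  c(h = unname(x[1, 1] * 360), s = unname(x[2, 1]), v = unname(x[3, 1]))
}

hue_in_interval <- function(h, lo, hi) {
  if (hi - lo >= 360) return(rep(TRUE, length(h)))
  h <- h %% 360; lo <- lo %% 360; hi <- hi %% 360
  if (lo <= hi) h >= lo & h <= hi else h >= lo | h <= hi
}

#' Filter colonies by an HSV colour box
#'
#' Keeps (select mode) or drops (exclude mode) colonies whose mean HSV lies
#' inside the box; the hue interval may wrap through 0/360.
#'
#' @param fps a measured `colony_footprints` object.
#' @param color_range HSV box as in [screening_criteria()]; `mode` entry
#'   `"select"` (default) or `"exclude"`.
#' @return `fps` with non-matching footprints removed from the table (masks
#'   are left untouched).
#' @export
color_filter <- function(fps, color_range) {
  fp <- fps$footprints
  if (nrow(fp) == 0 || is.null(color_range)) return(fps)
  h <- color_range$h %||% c(0, 360)
  s <- color_range$s %||% c(0, 1)
  v <- color_range$v %||% c(0, 1)
  mode <- color_range$mode %||% "select"
  inside <- hue_in_interval(fp$mean_h, h[1], h[2]) &
    fp$mean_s >= s[1] & fp$mean_s <= s[2] &
    fp$mean_v >= v[1] & fp$mean_v <= v[2]
  keep <- if (identical(mode, "exclude")) !inside else inside
  fps$footprints <- fp[keep, , drop = FALSE]
  fps
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score colonies by the weighted multi-criteria rule
#'
#' Per-candidate-set marks: `m_size` is the min-max normalized area,
#' `m_fluor` the mean fluorescence divided by 255, and `m_color` is
#' `1 - d/d_max` (similar mode) or `d/d_max` (dissimilar mode) where `d` is
#' the HSV cone distance to the target colour and `d_max` its maximum over
#' the candidates.  The total is the weighted sum, so every score lies in
#' \[0, 1\].  Degenerate normalizations (single candidate, all-equal values)
#' give a mark of 1.
#'
#' @param fps a measured (optionally filtered) `colony_footprints` object.
#' @param criteria a [screening_criteria()] object.
#' @return data frame of class `colony_scores`: `id`, `m_size`, `m_color`,
#'   `m_fluor`, `score`.
#' @export
score_colonies <- function(fps, criteria) {
  fp <- fps$footprints
  if (nrow(fp) == 0) stop_ctx("no candidate colonies to score")
  if (!is.null(criteria$size_range_mm)) {
    fp <- fp[fp$equivalent_diameter_mm >= criteria$size_range_mm[1] &
               fp$equivalent_diameter_mm <= criteria$size_range_mm[2], ,
             drop = FALSE]
    if (nrow(fp) == 0) stop_ctx("no candidate colonies after size filtering")
  }
  n <- nrow(fp)
  rng <- range(fp$area_mm2)
  m_size <- if (diff(rng) <= 0) rep(1, n) else (fp$area_mm2 - rng[1]) / diff(rng)
  m_fluor <- if (all(is.na(fp$mean_fluorescence))) rep(0, n) else
    clamp01(fp$mean_fluorescence / 255)
  if (criteria$w_fluor > 0 && all(is.na(fp$mean_fluorescence))) {
    stop_ctx("fluorescence weight is positive but no fluorescence was measured")
  }
  tgt <- rgb_to_hsv_deg(criteria$target_color)
  pc <- hsv_cone(fp$mean_h, fp$mean_s, fp$mean_v)
  tc <- hsv_cone(tgt["h"], tgt["s"], tgt["v"])
  d <- sqrt((pc[, 1] - tc[1])^2 + (pc[, 2] - tc[2])^2 + (pc[, 3] - tc[3])^2)
  dmax <- max(d)
  m_color <- if (dmax <= 0) rep(1, n) else if (criteria$color_mode == "similar")
    1 - d / dmax else d / dmax
  score <- criteria$w_size * m_size + criteria$w_color * m_color +
    criteria$w_fluor * m_fluor
  structure(data.frame(id = fp$id, m_size = m_size, m_color = m_color,
                       m_fluor = m_fluor, score = score),
            class = c("colony_scores", "data.frame"))
}

#' Rank scored colonies and select the top k
#'
#' Deterministic ordering: descending total score, ties broken by ascending
#' colony id.
#'
#' @param scores a `colony_scores` data frame.
#' @param k number to select; truncated to the candidate count.
#' @return integer vector of selected colony ids, best first.
#' @export
rank_and_select <- function(scores, k) {
  ord <- order(-scores$score, scores$id)
  utils::head(scores$id[ord], max(0L, as.integer(k)))
}

#' Destination-plate layout
#'
#' @param rows,cols numbers of rows and columns (default 96-well: 8 x 12).
#' @return object of class `dest_layout`.
#' @export
well_layout <- function(rows = 8L, cols = 12L) {
  structure(list(rows = as.integer(rows), cols = as.integer(cols)),
            class = "dest_layout")
}

#' Assign destination wells column-wise
#'
#' Wells fill down each column before advancing (A1, B1, ..., H1, A2, ...),
#' the order a column-wise picking run deposits into.
#'
#' @param selection ordered colony ids from [rank_and_select()].
#' @param layout a [well_layout()].
#' @return data frame with `colony_id` and `dest_well`.
#' @export
assign_destinations <- function(selection, layout = well_layout()) {
  n <- length(selection)
  if (n > layout$rows * layout$cols) {
    stop_ctx("selection (%d) overflows the %dx%d destination layout",
             n, layout$rows, layout$cols)
  }
  i <- seq_len(n)
  row <- (i - 1) %% layout$rows + 1
  col <- (i - 1) %/% layout$rows + 1
  data.frame(colony_id = selection,
             dest_well = paste0(LETTERS[row], col),
             stringsAsFactors = FALSE)
}
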