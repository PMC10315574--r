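# Internal helpers shared across modules.
#
# Image convention used throughout the package: a grayscale image is a numeric
# matrix indexed [x, y] with x = column from the left and y = row from the top
# (the EBImage layout); RGB images are [x, y, 3] arrays with values in [0, 1].
# Pixel coordinates are 1-based at pixel centres.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Quantize to 8-bit levels (stored on [0, 1]); makes renders byte-stable.
quantize8 <- function(x) round(clamp01(x) * 255) / 255

# Nearest odd integer >= 3.
odd <- function(x) {
  n <- max(3L, as.integer(round(x)))
  if (n %% 2L == 0L) n + 1L else n
}

# Rec. 601 luma of an [x, y, 3] array.
luminance <- function(rgb) {
  0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
}

# Matrix of Euclidean distances (px) of every pixel from `center` = c(x, y).
dist_from <- function(w, h, center) {
  dx2 <- (seq_len(w) - center[1])^2
  dy2 <- (seq_len(h) - center[2])^2
  sqrt(outer(dx2, dy2, `+`))
}

# Normalized Gaussian averaging kernel of odd side `size`.
gaussian_mean_kernel <- function(size) {
  b <- EBImage::makeBrush(size, shape = "gaussian", sigma = size / 4)
  b / sum(b)
}

# Circular mean of hues given in degrees [0, 360).
circular_mean_hue <- function(h_deg, w = NULL) {
  rad <- h_deg * pi / 180
  if (is.null(w)) w <- rep(1, length(rad))
  s <- sum(w * sin(rad))
  c_ <- sum(w * cos(rad))
  ang <- atan2(s, c_) * 180 / pi
  (ang + 360) %% 360
}

# Grouped means of `x` by positive integer labels 1..n; returns length-n vector.
group_mean <- function(x, labels, n) {
  sums <- rowsum(x, labels, reorder = FALSE)
  cnts <- tabulate(labels, nbins = n)
  out <- numeric(n)
  out[as.integer(rownames(sums))] <- sums[, 1]
  out / pmax(cnts, 1)
}

stop_ctx <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
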