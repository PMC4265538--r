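#' Otsu threshold of a 256-bin histogram
#'
#' Returns the bin index `t` in `[0, 255]` that minimizes the within-class
#' variance (equivalently maximizes the between-class variance) of the split
#' `[0..t]` versus `[t+1..255]`.  The smallest optimal `t` is returned on
#' ties.  A histogram with a single occupied bin admits no split; that bin is
#' returned with a warning.
#'
#' @param counts integer vector of 256 non-negative pixel counts.
#' @return integer bin index in `[0, 255]`.
#' @export
otsu_threshold <- function(counts) {
  if (length(counts) != 256L) stop("histogram must have 256 bins")
  if (any(counts < 0)) stop("histogram counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stop("empty histogram")
  occupied <- which(counts > 0)
  if (length(occupied) == 1L) {
    warning("degenerate histogram: single occupied bin, no split exists")
    return(occupied - 1L)
  }
  p <- counts / total
  bins <- 0:255
  w0 <- cumsum(p)
  m0 <- cumsum(p * bins)          # unnormalized class-0 mean mass
  mt <- m0[256]                   # global mean
  w1 <- 1 - w0
  sigma_b <- (mt * w0 - m0)^2 / (w0 * w1)
  sigma_b[!is.finite(sigma_b)] <- -Inf  # splits with an empty class
  as.integer(which.max(sigma_b) - 1L)   # which.max picks the lowest tie
}

quantize256 <- function(x) {
  b <- as.integer(round(x * 255))
  pmin(pmax(b, 0L), 255L)
}

hist256 <- function(bins) tabulate(as.integer(bins) + 1L, nbins = 256L)

#' Inner-boundary pixels of a binary mask
#'
#' A foreground pixel is a boundary pixel when at least one of its
#' 4-neighbours is background.  `outside_is_background` controls whether
#' pixels on the image border count their out-of-image neighbours as
#' background (region growing uses `TRUE`: a region filling the whole raster
#' has the raster border as its boundary) or replicate their own value
#' (threshold detectors use `FALSE`: only genuine intensity transitions
#' become edges).
#'
#' @param mask logical matrix.
#' @param outside_is_background logical flag, see above.
#' @return logical matrix of boundary pixels.
#' @export
boundary_pixels <- function(mask, outside_is_background = FALSE) {
  mask <- edge_map(mask)
  h <- nrow(mask)
  w <- ncol(mask)
  shift <- function(dr, dc) {
    out <- shift_replicate(mask, dr, dc)
    if (outside_is_background) {
      if (dr == -1L) out[1, ] <- FALSE
      if (dr ==  1L) out[h, ] <- FALSE
      if (dc == -1L) out[, 1] <- FALSE
      if (dc ==  1L) out[, w] <- FALSE
    }
    out
  }
  interior <- shift(-1L, 0L) & shift(1L, 0L) & shift(0L, -1L) & shift(0L, 1L)
  mask & !interior
}

#' Otsu edge detection
#'
#' Quantizes the raster to 256 bins, splits it at the Otsu threshold, and
#' marks the inner boundary of the above-threshold (foreground) region as
#' edges.
#'
#' @param img numeric matrix in `[0, 1]` (GrayRaster).
#' @return logical matrix (EdgeMap).
#' @export
otsu_edges <- function(img) {
  img <- gray_raster(img)
  bins <- quantize256(img)
  t <- otsu_threshold(hist256(bins))
  fg <- matrix(bins > t, nrow(img), ncol(img))
  boundary_pixels(fg, outside_is_background = FALSE)
}

mean3 <- function(img) {
  acc <- matrix(0, nrow(img), ncol(img))
  for (dr in -1:1) {
    for (dc in -1:1) {
      acc <- acc + shift_replicate(img, dr, dc)
    }
  }
  acc / 9
}

gradient_magnitude <- function(img) {
  gx <- (shift_replicate(img, 0L, 1L) - shift_replicate(img, 0L, -1L)) / 2
  gy <- (shift_replicate(img, 1L, 0L) - shift_replicate(img, -1L, 0L)) / 2
  sqrt(gx^2 + gy^2)
}

#' Watershed edge detection
#'
#' Floods the gradient-magnitude surface of the (optionally smoothed) raster
#' from its regional minima; dam pixels, where two catchment basins meet,
#' form the edge map.  `n_smooth` passes of a 3x3 mean filter before the
#' gradient control oversegmentation, and gradients below `gradient_floor`
#' are treated as flat (set to zero) so that residual sensor noise on flat
#' terrain does not spawn a catchment basin per noise dimple.
#'
#' @param img numeric matrix in `[0, 1]` (GrayRaster).
#' @param n_smooth number of 3x3 mean pre-smoothing passes (default 1).
#' @param gradient_floor gradient magnitudes below this value count as flat
#'   (default 0.02, about 4x the residual noise gradient after one
#'   smoothing pass at 2% image noise; genuine step edges sit an order of
#'   magnitude higher).
#' @return logical matrix (EdgeMap) of dam pixels.
#' @export
watershed_edges <- function(img, n_smooth = 1L, gradient_floor = 0.02) {
  lab <- watershed_basins(img, n_smooth, gradient_floor)
  edge_map(lab == 0L)
}

#' Watershed basin labels
#'
#' Same flooding as [watershed_edges()] but returns the integer basin label
#' matrix (dams are 0), for inspection of the segmentation itself.
#'
#' @inheritParams watershed_edges
#' @return integer matrix; basins are labelled `1..n`, dam pixels are 0.
#' @export
watershed_basins <- function(img, n_smooth = 1L, gradient_floor = 0.02) {
  img <- gray_raster(img)
  n_smooth <- as.integer(n_smooth)
  if (n_smooth < 0L) stop("n_smooth must be >= 0")
  if (!is.finite(gradient_floor) || gradient_floor < 0) {
    stop("gradient_floor must be >= 0")
  }
  for (i in seq_len(n_smooth)) img <- mean3(img)
  g <- gradient_magnitude(img)
  g[g < gradient_floor] <- 0
  .watershed_cpp(g)
}

#' Seeded region-growing edge detection
#'
#' Grows a 4-connected region from the seed pixel, admitting a frontier pixel
#' when its intensity differs from the current region mean by at most
#' `tolerance`; the mean is updated after every admission and the frontier is
#' processed in FIFO order, so the result is deterministic.  The edge map is
#' the boundary of the final region (out-of-image neighbours count as
#' outside, so a region filling the raster yields the raster border).
#'
#' @param img numeric matrix in `[0, 1]` (GrayRaster).
#' @param seed integer `(row, col)` seed coordinate, 1-based.
#' @param tolerance maximum `|pixel - region mean|` for admission (>= 0).
#' @return logical matrix (EdgeMap).
#' @export
region_growing_edges <- function(img, seed, tolerance = 0.1) {
  region <- grow_region(img, seed, tolerance)
  boundary_pixels(region, outside_is_background = TRUE)
}

#' Seeded region growing (region mask)
#'
#' The region itself, as grown by [region_growing_edges()].
#'
#' @inheritParams region_growing_edges
#' @return logical matrix, `TRUE` inside the grown region.
#' @export
grow_region <- function(img, seed, tolerance = 0.1) {
  img <- gray_raster(img)
  seed <- as.integer(seed)
  if (length(seed) != 2L) stop("seed must be a (row, col) pair")
  if (seed[1] < 1L || seed[1] > nrow(img) ||
      seed[2] < 1L || seed[2] > ncol(img)) {
    stop("seed (", seed[1], ", ", seed[2], ") is outside the raster")
  }
  if (!is.finite(tolerance) || tolerance < 0) {
    stop("tolerance must be a non-negative number")
  }
  .region_grow_cpp(img, seed[1] - 1L, seed[2] - 1L, tolerance)
}
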