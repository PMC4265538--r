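#' Phantom specification
#'
#' Parameters of the synthetic CT-slice generator.  Defaults mirror the
#' regime the candidate detector targets: a 256x256 slice with 6
#' non-overlapping nodules of 3-5 px diameter (so clusters pass the 5-unit
#' size limit), 30% elliptical, contrast 0.5 over a 0.2 background, 3 thin
#' bright lines standing in for lung edges / vessels as false-positive
#' sources, gaussian noise of sigma 0.02, and half of the nodules malignant
#' (drawn from the upper half of the diameter range, at +10% contrast).
#'
#' @param height,width raster size in pixels (default 256).
#' @param n_nodules number of nodules (default 6).
#' @param diameter_range `(min, max)` nodule diameters in pixels (default
#'   `c(3, 5)`).
#' @param elliptical_fraction probability that a nodule is elliptical
#'   (default 0.3).
#' @param contrast nodule mean minus background mean, in `(0, 1]` (default
#'   0.5; `background_level + contrast` must not exceed 1).
#' @param background_level background intensity in `[0, 1)` (default 0.2).
#' @param noise_sigma additive gaussian noise sigma (default 0.02).
#' @param n_lines number of thin bright polylines (default 3).
#' @param malignant_fraction fraction of nodules labelled malignant
#'   (default 0.5).
#' @param seed integer seed (default 1).
#' @return a list of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 256L, width = 256L, n_nodules = 6L,
                         diameter_range = c(3, 5), elliptical_fraction = 0.3,
                         contrast = 0.5, background_level = 0.2,
                         noise_sigma = 0.02, n_lines = 3L,
                         malignant_fraction = 0.5, seed = 1L) {
  if (height < 1L || width < 1L) stop("height and width must be positive")
  if (n_nodules < 0L) stop("n_nodules must be >= 0")
  if (length(diameter_range) != 2L || diameter_range[1] > diameter_range[2] ||
      diameter_range[1] <= 0) {
    stop("diameter_range must be (min, max) with 0 < min <= max")
  }
  if (contrast <= 0 || contrast > 1) stop("contrast must lie in (0, 1]")
  if (background_level < 0 || background_level >= 1) {
    stop("background_level must lie in [0, 1)")
  }
  if (background_level + contrast > 1) {
    stop("background_level + contrast must not exceed 1")
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (elliptical_fraction < 0 || elliptical_fraction > 1 ||
      malignant_fraction < 0 || malignant_fraction > 1) {
    stop("fractions must lie in [0, 1]")
  }
  structure(
    list(height = as.integer(height), width = as.integer(width),
         n_nodules = as.integer(n_nodules),
         diameter_range = as.numeric(diameter_range),
         elliptical_fraction = elliptical_fraction, contrast = contrast,
         background_level = background_level, noise_sigma = noise_sigma,
         n_lines = as.integer(n_lines),
         malignant_fraction = malignant_fraction, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# pixel coverage of an ellipse by 4x4 subsampling; returns the updated
# raster and the nodule mask (coverage >= 0.5)
draw_ellipse <- function(raster, mask, cr, cc, a, b, theta, level, bg) {
  h <- nrow(raster)
  w <- ncol(raster)
  rmax <- max(a, b) + 1
  rows <- max(1L, floor(cr - rmax)):min(h, ceiling(cr + rmax))
  cols <- max(1L, floor(cc - rmax)):min(w, ceiling(cc + rmax))
  sub <- (seq_len(4L) - 2.5) / 4 # subpixel offsets -0.375 .. 0.375
  cov <- matrix(0, length(rows), length(cols))
  ct <- cos(theta)
  st <- sin(theta)
  for (dr in sub) {
    for (dc in sub) {
      ry <- outer(rows + dr - cr, rep(1, length(cols)))
      cx <- outer(rep(1, length(rows)), cols + dc - cc)
      u <- ry * ct + cx * st
      v <- -ry * st + cx * ct
      cov <- cov + ((u / a)^2 + (v / b)^2 <= 1)
    }
  }
  cov <- cov / 16
  patch <- raster[rows, cols, drop = FALSE]
  raster[rows, cols] <- pmax(patch, bg + (level - bg) * cov)
  mask[rows, cols] <- mask[rows, cols] | (cov >= 0.5)
  list(raster = raster, mask = mask)
}

# pixels of a random polyline, or NULL when it strays out of bounds
polyline_pixels <- function(h, w, n_segments = 3L, seg_len = c(20, 45)) {
  r <- runif(1, 1, h)
  c <- runif(1, 1, w)
  heading <- runif(1, 0, 2 * pi)
  pts <- matrix(numeric(0), ncol = 2)
  for (s in seq_len(n_segments)) {
    len <- runif(1, seg_len[1], seg_len[2])
    nstep <- ceiling(len * 2)
    t <- seq(0, len, length.out = nstep)
    pr <- r + t * sin(heading)
    pc <- c + t * cos(heading)
    pts <- rbind(pts, cbind(pr, pc))
    r <- pr[nstep]
    c <- pc[nstep]
    heading <- heading + runif(1, -0.6, 0.6)
  }
  px <- unique(cbind(round(pts[, 1]), round(pts[, 2])))
  if (any(px[, 1] < 1 | px[, 1] > h | px[, 2] < 1 | px[, 2] > w)) {
    return(NULL)
  }
  px
}

#' Generate a synthetic CT-slice phantom with ground truth
#'
#' Renders anti-aliased bright nodules (disks and ellipses) on a dark
#' background, adds thin bright polylines at the nodule intensity as
#' false-positive sources, and finishes with additive gaussian noise
#' clipped to `[0, 1]`.  Malignant nodules draw their diameter from the
#' upper half of `diameter_range` and get +10% contrast; benign nodules
#' draw from the lower half.  Nodules are placed by rejection sampling with
#' a 5 px clearance between edge bands (and lines are kept clear of
#' nodules) so that every ground-truth object maps to its own edge
#' component.  All randomness derives from `spec$seed`, so one seed gives
#' one byte stream.
#'
#' @param spec a [phantom_spec()] list.
#' @return a list with `image` (GrayRaster) and `truth`: a list with
#'   `nodules` (data frame `nodule_id`, `row`, `col`, `diameter`, `shape`,
#'   `label`) and `mask` (logical matrix of nodule pixels).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  with_seed(spec$seed, {
    h <- spec$height
    w <- spec$width
    n <- spec$n_nodules
    bg <- spec$background_level
    dmin <- spec$diameter_range[1]
    dmax <- spec$diameter_range[2]
    dmid <- (dmin + dmax) / 2

    n_mal <- round(spec$malignant_fraction * n)
    labels <- sample(c(rep("malignant", n_mal), rep("benign", n - n_mal)))
    shapes <- ifelse(runif(n) < spec$elliptical_fraction,
                     "elliptical", "spherical")
    diam <- ifelse(labels == "malignant",
                   runif(n, dmid, dmax), runif(n, dmin, dmid))
    theta <- runif(n, 0, pi)

    centers <- matrix(NA_real_, n, 2)
    for (i in seq_len(n)) {
      margin <- diam[i] / 2 + 6
      placed <- FALSE
      for (attempt in seq_len(1000L)) {
        cr <- runif(1, 1 + margin, h - margin)
        cc <- runif(1, 1 + margin, w - margin)
        ok <- TRUE
        if (i > 1L) {
          prev <- seq_len(i - 1L)
          dd <- sqrt((centers[prev, 1] - cr)^2 + (centers[prev, 2] - cc)^2)
          ok <- all(dd >= (diam[prev] + diam[i]) / 2 + 5)
        }
        if (ok) {
          centers[i, ] <- c(cr, cc)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("could not place nodule ", i, " after 1000 attempts; ",
             "use fewer or smaller nodules")
      }
    }

    raster <- matrix(bg, h, w)
    mask <- matrix(FALSE, h, w)
    for (i in seq_len(n)) {
      level <- if (labels[i] == "malignant") {
        min(1, bg + 1.1 * spec$contrast)
      } else {
        bg + spec$contrast
      }
      if (shapes[i] == "elliptical") {
        # axis ratio 2 at equal area: a * b = (d/2)^2
        a <- diam[i] / 2 * sqrt(2)
        b <- diam[i] / 2 / sqrt(2)
      } else {
        a <- b <- diam[i] / 2
      }
      drawn <- draw_ellipse(raster, mask, centers[i, 1], centers[i, 2],
                            a, b, theta[i], level, bg)
      raster <- drawn$raster
      mask <- drawn$mask
    }

    line_level <- bg + spec$contrast
    for (l in seq_len(spec$n_lines)) {
      placed <- FALSE
      for (attempt in seq_len(1000L)) {
        px <- polyline_pixels(h, w)
        if (is.null(px)) next
        ok <- TRUE
        if (n > 0L) {
          for (i in seq_len(n)) {
            dd <- sqrt((px[, 1] - centers[i, 1])^2 +
                         (px[, 2] - centers[i, 2])^2)
            if (any(dd < diam[i] / 2 + 6)) {
              ok <- FALSE
              break
            }
          }
        }
        if (ok) {
          raster[px] <- line_level
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("could not place line ", l, " clear of the nodules; ",
             "use fewer nodules or lines")
      }
    }

    if (spec$noise_sigma > 0) {
      raster <- raster + matrix(rnorm(h * w, 0, spec$noise_sigma), h, w)
    }
    raster <- pmin(pmax(raster, 0), 1)

    nodules <- data.frame(
      nodule_id = seq_len(n),
      row = centers[, 1], col = centers[, 2],
      diameter = diam, shape = shapes, label = labels,
      stringsAsFactors = FALSE
    )
    list(image = gray_raster(raster),
         truth = list(nodules = nodules, mask = edge_map(mask)))
  })
}

#' The standard phantom suite
#'
#' `n_images` phantoms generated from the default [phantom_spec()] with
#' seeds `base_seed + 1, ..., base_seed + n_images`.  This fixed suite is
#' the surface on which cross-algorithm comparisons are run.
#'
#' @param n_images number of phantoms (default 10).
#' @param base_seed integer base seed (default 42).
#' @param spec optional [phantom_spec()] whose non-seed fields override the
#'   defaults.
#' @return list of `generate_phantom()` results.
#' @export
standard_suite <- function(n_images = 10L, base_seed = 42L,
                           spec = phantom_spec()) {
  n_images <- as.integer(n_images)
  if (n_images < 1L) stop("n_images must be positive")
  lapply(seq_len(n_images), function(i) {
    s <- spec
    s$seed <- as.integer(base_seed + i)
    generate_phantom(s)
  })
}
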