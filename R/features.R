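#' Mean intensity over a circular region
#'
#' Mean of the raster over pixels whose centre lies within euclidean
#' distance `radius` of `center`, clipped to the raster; `radius = 0` gives
#' the centre pixel's value.
#'
#' @param img numeric matrix in `[0, 1]` (GrayRaster).
#' @param center integer `(row, col)`, 1-based, inside the raster.
#' @param radius non-negative radius in pixels.
#' @return mean intensity, a number in `[0, 1]`.
#' @export
circular_mean_intensity <- function(img, center, radius) {
  img <- gray_raster(img)
  center <- as.numeric(center)
  if (length(center) != 2L) stop("center must be a (row, col) pair")
  h <- nrow(img)
  w <- ncol(img)
  if (center[1] < 1 || center[1] > h || center[2] < 1 || center[2] > w) {
    stop("center (", center[1], ", ", center[2], ") is outside the raster")
  }
  if (!is.finite(radius) || radius < 0) stop("radius must be >= 0")
  rows <- max(1L, ceiling(center[1] - radius)):min(h, floor(center[1] + radius))
  cols <- max(1L, ceiling(center[2] - radius)):min(w, floor(center[2] + radius))
  d2 <- outer((rows - center[1])^2, (cols - center[2])^2, `+`)
  sel <- d2 <= radius^2
  mean(img[rows, cols, drop = FALSE][sel])
}

#' Build the per-candidate feature matrix with intensity filtering
#'
#' For each candidate, the mean intensity of the ORIGINAL raster is measured
#' over a disk around the candidate centre (radius = the candidate's
#' equivalent radius under the default `"equiv"` policy, or `fixed_radius`
#' under `"fixed"`).  Candidates whose mean exceeds `intensity_threshold`
#' survive and yield one feature row each; the rest are dropped, which is
#' the intensity-based false-positive filter.
#'
#' @param img numeric matrix in `[0, 1]` — the original image, not the edge
#'   map.
#' @param candidates data frame from [detect_candidates()].
#' @param intensity_threshold keep a candidate iff its circular mean
#'   intensity is strictly above this value, in `[0, 1]` (default 0.5).
#' @param radius_policy `"equiv"` (candidate equivalent radius, default) or
#'   `"fixed"`.
#' @param fixed_radius radius in pixels used under the `"fixed"` policy.
#' @param center_search_radius non-negative integer (default 0).  When
#'   positive, the probe disk is placed at the position within this
#'   euclidean distance of the candidate centre that maximizes the circular
#'   mean, compensating the centre-estimation error of an upstream detector
#'   whose components are partial arcs.  A bright disk (nodule) then always
#'   presents its full core to the probe, while a thin bright line cannot
#'   fill the probe disk from any position, so the filter still rejects it.
#' @param age optional patient age in years, replicated into an `age` column.
#' @return data frame with columns `candidate_id`, `row`, `col`,
#'   `mean_intensity`, `area_px`, `shape` (and `age` when supplied).
#' @export
build_feature_matrix <- function(img, candidates, intensity_threshold = 0.5,
                                 radius_policy = c("equiv", "fixed"),
                                 fixed_radius = 2, center_search_radius = 0,
                                 age = NULL) {
  img <- gray_raster(img)
  radius_policy <- match.arg(radius_policy)
  if (!is.finite(intensity_threshold) || intensity_threshold < 0 ||
      intensity_threshold > 1) {
    stop("intensity_threshold must lie in [0, 1]")
  }
  if (!is.finite(center_search_radius) || center_search_radius < 0) {
    stop("center_search_radius must be >= 0")
  }
  s <- as.integer(center_search_radius)
  offsets <- expand.grid(dr = -s:s, dc = -s:s)
  offsets <- offsets[offsets$dr^2 + offsets$dc^2 <= s^2, , drop = FALSE]
  n <- nrow(candidates)
  means <- numeric(n)
  for (i in seq_len(n)) {
    r <- if (radius_policy == "equiv") {
      candidates$equiv_diameter[i] / 2
    } else {
      fixed_radius
    }
    best <- -Inf
    for (o in seq_len(nrow(offsets))) {
      ctr <- c(candidates$row[i] + offsets$dr[o],
               candidates$col[i] + offsets$dc[o])
      ctr <- pmin(pmax(ctr, 1), dim(img))
      best <- max(best, circular_mean_intensity(img, ctr, r))
    }
    means[i] <- best
  }
  keep <- means > intensity_threshold
  out <- data.frame(
    candidate_id = candidates$id[keep],
    row = candidates$row[keep],
    col = candidates$col[keep],
    mean_intensity = means[keep],
    area_px = candidates$area_px[keep],
    shape = candidates$shape[keep],
    stringsAsFactors = FALSE
  )
  if (!is.null(age)) {
    if (!is.finite(age) || age < 0) stop("age must be a non-negative number")
    out$age <- rep(as.numeric(age), nrow(out))
  }
  rownames(out) <- NULL
  out
}

#' Numeric feature columns for clustering
#'
#' Encodes the feature rows as a numeric matrix: `mean_intensity`, `area_px`
#' and `shape` (spherical = 0, elliptical = 1), plus `age` when present.
#'
#' @param features data frame from [build_feature_matrix()].
#' @return numeric matrix with one row per feature row.
#' @export
feature_columns <- function(features) {
  m <- cbind(
    mean_intensity = features$mean_intensity,
    area_px = as.numeric(features$area_px),
    shape = as.numeric(features$shape == "elliptical")
  )
  if (!is.null(features$age)) m <- cbind(m, age = features$age)
  m
}
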