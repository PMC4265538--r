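#' Connected components of an edge map
#'
#' Partitions the foreground pixels into maximal connected components under
#' 4- or 8-connectivity.  Components are returned in deterministic order, by
#' `(min_row, min_col)` of their bounding boxes.
#'
#' @param map logical matrix (EdgeMap).
#' @param connectivity 4 or 8 (default 8).
#' @return a list of components; each is a list with `pixels` (n x 2 matrix
#'   of `(row, col)`), `area`, `bbox` (`min_row, min_col, max_row, max_col`)
#'   and `extent_major` / `extent_minor` (bounding-box side lengths,
#'   major >= minor).
#' @export
find_components <- function(map, connectivity = 8L) {
  map <- edge_map(map)
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  lab <- .label_components_cpp(map, connectivity)
  n <- max(lab)
  if (n == 0L) return(list())
  idx <- which(lab > 0L)
  coords <- arrayInd(idx, dim(lab))
  comps <- lapply(split.data.frame(coords, lab[idx]), function(px) {
    px <- px[order(px[, 1], px[, 2]), , drop = FALSE]
    dimnames(px) <- list(NULL, c("row", "col"))
    bbox <- c(min_row = min(px[, 1]), min_col = min(px[, 2]),
              max_row = max(px[, 1]), max_col = max(px[, 2]))
    ext <- c(bbox["max_row"] - bbox["min_row"] + 1L,
             bbox["max_col"] - bbox["min_col"] + 1L)
    list(pixels = px, area = nrow(px), bbox = bbox,
         extent_major = max(ext), extent_minor = min(ext))
  })
  ord <- order(vapply(comps, function(co) co$bbox[["min_row"]], numeric(1)),
               vapply(comps, function(co) co$bbox[["min_col"]], numeric(1)))
  unname(comps[ord])
}

#' Is a component a thin line (lung edge) rather than a nodule blob?
#'
#' Lung edges appear as thin, elongated pixel runs, nodules as compact
#' clusters.  A component is rejected as line-like when its bounding-box
#' fill ratio `area / (extent_major * extent_minor)` is below
#' `fill_ratio_min`, or its bounding-box aspect `extent_major / extent_minor`
#' exceeds `aspect_max`.
#'
#' @param comp a component from [find_components()].
#' @param fill_ratio_min minimum fill ratio for a blob (default 0.5).
#' @param aspect_max maximum bounding-box aspect for a blob (default 3).
#' @return `TRUE` when the component is line-like.
#' @export
is_line_like <- function(comp, fill_ratio_min = 0.5, aspect_max = 3) {
  fill <- comp$area / (comp$extent_major * comp$extent_minor)
  aspect <- comp$extent_major / comp$extent_minor
  fill < fill_ratio_min || aspect > aspect_max
}

round_half_down <- function(x) as.integer(ceiling(x - 0.5))

#' Turn a compact component into a nodule candidate
#'
#' The candidate's equivalent diameter is `2 * sqrt(area / pi)`; components
#' above `d_max` are rejected (returned as `NULL`, not an error).  The
#' candidate centre is the pixel-rounded centroid (ties in rounding go to
#' the smaller index) and the shape class is `"spherical"` when the
#' bounding-box aspect is at most `ecc_threshold`, `"elliptical"` otherwise.
#'
#' @param comp a component from [find_components()] (not line-like).
#' @param d_max maximum equivalent diameter in pixels (default 5; nodule
#'   units are taken as pixels and must be re-scanned per image resolution).
#' @param ecc_threshold bounding-box aspect separating spherical from
#'   elliptical (default 1.5).
#' @param center_policy `"centroid"` (default): centre = pixel centroid of
#'   the component; `"bbox"`: centre = bounding-box centre, which estimates
#'   the underlying blob centre with less bias when the component is a
#'   partial arc of a nodule's edge ring.
#' @return a list with `center`, `equiv_diameter`, `shape` and `area`, or
#'   `NULL` when the component exceeds `d_max`.
#' @export
candidate_from_component <- function(comp, d_max = 5, ecc_threshold = 1.5,
                                     center_policy = c("centroid", "bbox")) {
  center_policy <- match.arg(center_policy)
  ed <- 2 * sqrt(comp$area / pi)
  if (ed > d_max) return(NULL)
  ctr <- if (center_policy == "bbox") {
    c(round_half_down((comp$bbox[["min_row"]] + comp$bbox[["max_row"]]) / 2),
      round_half_down((comp$bbox[["min_col"]] + comp$bbox[["max_col"]]) / 2))
  } else {
    c(round_half_down(mean(comp$pixels[, 1])),
      round_half_down(mean(comp$pixels[, 2])))
  }
  aspect <- comp$extent_major / comp$extent_minor
  list(center = ctr,
       equiv_diameter = ed,
       shape = if (aspect <= ecc_threshold) "spherical" else "elliptical",
       area = comp$area)
}

#' Detect nodule candidates in an edge map (black circular neighbourhood)
#'
#' Composition of [find_components()], the [is_line_like()] filter and
#' [candidate_from_component()]: clustered edge pixels become candidates,
#' thin lung-edge lines and oversized clusters are dropped.  Candidates are
#' returned in stable `(row, col)` centre order.
#'
#' @param map logical matrix (EdgeMap).
#' @param connectivity 4 or 8 (default 8; diagonal bridges merge).
#' @param fill_ratio_min,aspect_max line-rejection thresholds, see
#'   [is_line_like()].
#' @param d_max,ecc_threshold,center_policy size/shape/centre options, see
#'   [candidate_from_component()].
#' @return a data frame with columns `id`, `row`, `col`, `area_px`,
#'   `equiv_diameter`, `shape`; the accepted components are attached as the
#'   `"components"` attribute, aligned with the rows.
#' @export
detect_candidates <- function(map, connectivity = 8L, fill_ratio_min = 0.5,
                              aspect_max = 3, d_max = 5,
                              ecc_threshold = 1.5,
                              center_policy = c("centroid", "bbox")) {
  center_policy <- match.arg(center_policy)
  comps <- find_components(map, connectivity)
  keep <- list()
  cand <- list()
  for (co in comps) {
    if (is_line_like(co, fill_ratio_min, aspect_max)) next
    ca <- candidate_from_component(co, d_max, ecc_threshold, center_policy)
    if (is.null(ca)) next
    keep[[length(keep) + 1L]] <- co
    cand[[length(cand) + 1L]] <- ca
  }
  if (length(cand) == 0L) {
    out <- data.frame(id = integer(0), row = integer(0), col = integer(0),
                      area_px = integer(0), equiv_diameter = numeric(0),
                      shape = character(0), stringsAsFactors = FALSE)
    attr(out, "components") <- list()
    return(out)
  }
  out <- data.frame(
    row = vapply(cand, function(ca) ca$center[1], integer(1)),
    col = vapply(cand, function(ca) ca$center[2], integer(1)),
    area_px = vapply(cand, function(ca) as.integer(ca$area), integer(1)),
    equiv_diameter = vapply(cand, function(ca) ca$equiv_diameter, numeric(1)),
    shape = vapply(cand, function(ca) ca$shape, character(1)),
    stringsAsFactors = FALSE
  )
  ord <- order(out$row, out$col)
  out <- out[ord, , drop = FALSE]
  out <- cbind(id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  attr(out, "components") <- keep[ord]
  out
}
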