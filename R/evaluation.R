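#' Object-level matching of candidates against true nodules
#'
#' Greedy one-to-one matching by ascending centre distance: the closest
#' admissible candidate-truth pair is matched first, both are removed, and
#' so on.  A pair is admissible when its euclidean centre distance is at
#' most `max_dist` (a scalar), or — by default, `max_dist = NULL` — at most
#' that truth nodule's own radius (`diameter / 2`), so matching scales with
#' nodule size.  Matched pairs are TP, unmatched candidates FP, unmatched
#' truths FN; TN is undefined at object level.
#'
#' @param candidates data frame with `row`, `col` columns (candidate
#'   centres).
#' @param truth data frame with `row`, `col` and (when `max_dist` is
#'   `NULL`) `diameter` columns.
#' @param max_dist scalar matching distance, or `NULL` for the per-truth
#'   radius.
#' @return a list with integer `tp`, `fp`, `fn`, `tn = NA` and a `matches`
#'   data frame (`candidate`, `truth`, `dist`).
#' @export
match_objects <- function(candidates, truth, max_dist = NULL) {
  if (!is.null(max_dist) && (!is.finite(max_dist) || max_dist <= 0)) {
    stop("max_dist must be positive (or NULL for per-truth radii)")
  }
  nc <- if (is.null(candidates)) 0L else nrow(candidates)
  nt <- if (is.null(truth)) 0L else nrow(truth)
  matches <- data.frame(candidate = integer(0), truth = integer(0),
                        dist = numeric(0))
  if (nc == 0L || nt == 0L) {
    return(list(tp = 0L, fp = nc, fn = nt, tn = NA_integer_,
                matches = matches))
  }
  limit <- if (is.null(max_dist)) truth$diameter / 2 else rep(max_dist, nt)
  d <- sqrt(outer(candidates$row, truth$row, `-`)^2 +
              outer(candidates$col, truth$col, `-`)^2)
  admissible <- which(d <= rep(limit, each = nc), arr.ind = TRUE)
  if (nrow(admissible) > 0L) {
    dist_adm <- d[admissible]
    ord <- order(dist_adm, admissible[, 2], admissible[, 1])
    cand_used <- rep(FALSE, nc)
    truth_used <- rep(FALSE, nt)
    for (i in ord) {
      ci <- admissible[i, 1]
      ti <- admissible[i, 2]
      if (cand_used[ci] || truth_used[ti]) next
      cand_used[ci] <- TRUE
      truth_used[ti] <- TRUE
      matches <- rbind(matches, data.frame(candidate = ci, truth = ti,
                                           dist = d[ci, ti]))
    }
  }
  tp <- nrow(matches)
  list(tp = as.integer(tp), fp = as.integer(nc - tp),
       fn = as.integer(nt - tp), tn = NA_integer_, matches = matches)
}

#' Pixel-level confusion counts between two masks
#'
#' Per-pixel contingency of detected versus true foreground; this is the
#' mode that supplies the true negatives that specificity and paper-style
#' accuracy need.
#'
#' @param detected_mask,truth_mask logical matrices of the same shape.
#' @return a list with integer `tp`, `fp`, `fn`, `tn`.
#' @export
pixel_confusion <- function(detected_mask, truth_mask) {
  detected_mask <- edge_map(detected_mask)
  truth_mask <- edge_map(truth_mask)
  if (!identical(dim(detected_mask), dim(truth_mask))) {
    stop("masks must have the same shape")
  }
  list(tp = as.integer(sum(detected_mask & truth_mask)),
       fp = as.integer(sum(detected_mask & !truth_mask)),
       fn = as.integer(sum(!detected_mask & truth_mask)),
       tn = as.integer(sum(!detected_mask & !truth_mask)))
}

safe_ratio <- function(num, den) {
  if (is.na(den) || den == 0) NA_real_ else num / den
}

#' Detection metrics from confusion counts
#'
#' Sensitivity `tp/(tp+fn)`, precision `tp/(tp+fp)`, specificity
#' `tn/(tn+fp)` (pixel mode only), accuracy `(tp+tn)/(tp+tn+fp+fn)` in
#' pixel mode or the Jaccard-style `tp/(tp+fp+fn)` in object mode (no
#' negative class exists there), and recall ratio = detected count / true
#' count.  The recall ratio may exceed 1 under over-detection; every other
#' defined metric lies in `[0, 1]`.  A metric whose denominator is zero is
#' reported as `NA`, never divided.
#'
#' @param counts list with `tp`, `fp`, `fn` and (pixel mode) `tn`; `tn`
#'   absent or `NA` selects object mode.
#' @param n_detected number of detected candidates (for the recall ratio).
#' @param n_truth number of true nodules (for the recall ratio).
#' @return a list with `mode`, the four counts, `recall_ratio`,
#'   `sensitivity`, `specificity`, `accuracy`, `precision`.
#' @export
compute_metrics <- function(counts, n_detected = NULL, n_truth = NULL) {
  tp <- counts$tp
  fp <- counts$fp
  fn <- counts$fn
  tn <- counts$tn %||% NA_integer_
  vals <- c(tp, fp, fn, if (!is.na(tn)) tn)
  if (any(vals < 0)) stop("confusion counts must be non-negative")
  pixel_mode <- !is.na(tn)
  list(
    mode = if (pixel_mode) "pixel" else "object",
    tp = tp, fp = fp, fn = fn, tn = tn,
    recall_ratio = if (is.null(n_detected) || is.null(n_truth)) {
      NA_real_
    } else {
      safe_ratio(n_detected, n_truth)
    },
    sensitivity = safe_ratio(tp, tp + fn),
    specificity = if (pixel_mode) safe_ratio(tn, tn + fp) else NA_real_,
    accuracy = if (pixel_mode) {
      safe_ratio(tp + tn, tp + tn + fp + fn)
    } else {
      safe_ratio(tp, tp + fp + fn)
    },
    precision = safe_ratio(tp, tp + fp)
  )
}
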