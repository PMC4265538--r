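#' Refined ACO: self-feeding edge detection rounds
#'
#' Round 1 is [aco_edges()] on the input image; each later round re-runs the
#' detector on the previous round's edge map cast to a grayscale raster
#' (`TRUE` -> 1.0).  Iteration stops when the Hamming fraction (differing
#' pixels / total pixels) between consecutive rounds drops to `tol`, or when
#' `max_rounds` is reached.  Round `r` uses seed `params$seed + r - 1`, so
#' rounds are independent yet reproducible and a single-round run equals
#' `aco_edges(img, params)` exactly.
#'
#' @param img numeric matrix in `[0, 1]` (GrayRaster).
#' @param params an [aco_params()] list.
#' @param max_rounds maximum number of rounds (>= 1).
#' @param tol convergence tolerance on the Hamming fraction, in `[0, 1]`.
#' @return an object of class `refined_run`: a list with `rounds` (list of
#'   EdgeMaps) and `diffs` (numeric, one fewer than the rounds).
#' @export
refined_aco <- function(img, params = aco_params(), max_rounds = 5L,
                        tol = 0.01) {
  img <- gray_raster(img)
  max_rounds <- as.integer(max_rounds)
  if (max_rounds < 1L) stop("max_rounds must be >= 1")
  if (!is.finite(tol) || tol < 0 || tol > 1) stop("tol must lie in [0, 1]")
  params <- resolve_aco_params(params, img)
  base_seed <- params$seed
  rounds <- vector("list", 0L)
  diffs <- numeric(0)
  current <- img
  for (r in seq_len(max_rounds)) {
    params$seed <- base_seed + r - 1L
    m <- aco_edges(current, params)
    rounds[[r]] <- m
    if (r > 1L) {
      d <- mean(m != rounds[[r - 1L]])
      diffs <- c(diffs, d)
      if (d <= tol) break
    }
    current <- as_gray(m)
  }
  structure(list(rounds = rounds, diffs = diffs), class = "refined_run")
}

#' Logical ACO: XOR of the final and pre-final refined rounds
#'
#' Pixelwise exclusive-or of two same-shape edge maps.  Called with a
#' `refined_run`, it uses the run's last and second-to-last rounds; a run
#' with a single round is an error (there is no pre-final map to combine).
#'
#' @param final EdgeMap, or a `refined_run` from [refined_aco()].
#' @param prefinal EdgeMap; ignored when `final` is a `refined_run`.
#' @return logical matrix (EdgeMap).
#' @export
logical_aco <- function(final, prefinal) {
  if (inherits(final, "refined_run")) {
    n <- length(final$rounds)
    if (n < 2L) {
      stop("logical ACO needs at least two refined rounds; got ", n)
    }
    prefinal <- final$rounds[[n - 1L]]
    final <- final$rounds[[n]]
  }
  final <- edge_map(final)
  prefinal <- edge_map(prefinal)
  if (!identical(dim(final), dim(prefinal))) {
    stop("edge maps must have the same shape")
  }
  edge_map(xor(final, prefinal))
}

#' Variant ACO: ACO on the Otsu edge map
#'
#' The image is first edge-detected with [otsu_edges()]; the resulting
#' binary map, cast to a grayscale raster, is the input to [aco_edges()].
#' Running the ants on an already-binarized edge image removes the low-level
#' intensity noise that attracts stray deposits, which is what cuts false
#' positives relative to plain ACO.
#'
#' @inheritParams run_aco
#' @return logical matrix (EdgeMap).
#' @export
variant_aco <- function(img, params = aco_params()) {
  aco_edges(as_gray(otsu_edges(img)), params)
}
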