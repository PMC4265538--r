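#' ACO parameter set
#'
#' Parameters of the ant-colony edge detector.  Defaults follow the standard
#' ACO image-edge parameterization: pheromone exponent `alpha = 1`, heuristic
#' exponent `beta = 2`, evaporation `rho = 0.1`, initial pheromone
#' `tau0 = 0.1`, 10 construction rounds of 40 steps per ant, and (when
#' `n_ants` is `NULL`) one ant per `sqrt(H * W)` pixels, resolved at run
#' time from the image size.
#'
#' @param n_ants positive integer, or `NULL` to use `round(sqrt(H * W))`.
#' @param n_iterations positive integer; construction rounds.
#' @param steps_per_ant positive integer; moves per ant per round.
#' @param alpha pheromone exponent (>= 0).
#' @param beta heuristic exponent (>= 0).
#' @param rho evaporation rate, strictly inside (0, 1).
#' @param tau0 initial pheromone (> 0).
#' @param seed integer seed for the single random stream.
#' @return a list of class `aco_params`.
#' @export
aco_params <- function(n_ants = NULL, n_iterations = 10L, steps_per_ant = 40L,
                       alpha = 1, beta = 2, rho = 0.1, tau0 = 0.1,
                       seed = 1L) {
  if (!is.null(n_ants) && (n_ants < 1L)) stop("n_ants must be positive")
  if (n_iterations < 1L) stop("n_iterations must be positive")
  if (steps_per_ant < 1L) stop("steps_per_ant must be positive")
  if (alpha < 0 || beta < 0) stop("alpha and beta must be >= 0")
  if (!is.finite(rho) || rho <= 0 || rho >= 1) {
    stop("rho must lie strictly inside (0, 1)")
  }
  if (!is.finite(tau0) || tau0 <= 0) stop("tau0 must be > 0")
  structure(
    list(n_ants = if (is.null(n_ants)) NULL else as.integer(n_ants),
         n_iterations = as.integer(n_iterations),
         steps_per_ant = as.integer(steps_per_ant),
         alpha = alpha, beta = beta, rho = rho, tau0 = tau0,
         seed = as.integer(seed)),
    class = "aco_params"
  )
}

resolve_aco_params <- function(params, img) {
  if (!inherits(params, "aco_params")) {
    params <- do.call(aco_params, params)
  }
  if (is.null(params$n_ants)) {
    params$n_ants <- max(1L, as.integer(round(sqrt(nrow(img) * ncol(img)))))
  }
  params
}

#' Heuristic field: normalized local intensity variation
#'
#' For every pixel, the local variation is the largest absolute intensity
#' difference across the four pixel pairs straddling it (vertical,
#' horizontal and both diagonals; border neighbours are clamped).  The field
#' is normalized by its maximum, so its maximum is 1 unless the raster is
#' constant, in which case the field is all zero.  Absolute differences make
#' the field invariant under intensity inversion.
#'
#' @param img numeric matrix in `[0, 1]` (GrayRaster).
#' @return numeric matrix in `[0, 1]` (HeuristicField).
#' @export
compute_heuristic <- function(img) {
  img <- gray_raster(img)
  v <- pmax(
    abs(shift_replicate(img, -1L, 0L) - shift_replicate(img, 1L, 0L)),
    abs(shift_replicate(img, 0L, -1L) - shift_replicate(img, 0L, 1L)),
    abs(shift_replicate(img, -1L, -1L) - shift_replicate(img, 1L, 1L)),
    abs(shift_replicate(img, -1L, 1L) - shift_replicate(img, 1L, -1L))
  )
  m <- max(v)
  if (m > 0) v / m else v
}

#' Run the ant colony and return the pheromone field
#'
#' The field is initialized to `tau0`.  Each iteration, each ant starts at a
#' random pixel and performs `steps_per_ant` moves over the 8-neighbourhood;
#' the move to neighbour `j` has probability proportional to
#' `tau(j)^alpha * eta(j)^beta` over the neighbours not yet visited by that
#' ant (uniform among them when all weights are zero; an ant with no
#' admissible neighbour respawns at a fresh random pixel).  After each
#' iteration the field evaporates, `tau <- (1 - rho) * tau`, and every
#' visited pixel `j` gains `rho * eta(j)`.  The whole move sequence is
#' driven by a single random stream fixed by `params$seed` (ants in index
#' order, moves in step order), so identical inputs give bitwise-identical
#' fields.
#'
#' @param img numeric matrix in `[0, 1]`, at least 2x2 (GrayRaster).
#' @param params an [aco_params()] list.
#' @return numeric matrix of non-negative pheromone values (PheromoneField).
#' @export
run_aco <- function(img, params = aco_params()) {
  img <- gray_raster(img)
  if (nrow(img) < 2L || ncol(img) < 2L) {
    stop("ACO needs a raster of at least 2x2 pixels")
  }
  params <- resolve_aco_params(params, img)
  eta <- compute_heuristic(img)
  with_seed(params$seed, {
    .aco_walk_cpp(eta, params$n_ants, params$n_iterations,
                  params$steps_per_ant, params$alpha, params$beta,
                  params$rho, params$tau0)
  })
}

#' Binarize a pheromone field into an edge map
#'
#' The field is linearly quantized to 256 bins between its minimum and
#' maximum and split at the Otsu threshold; above-threshold pixels become
#' edges.  Quantization is rank-preserving, so a positive affine rescaling
#' of the field leaves the edge map unchanged.  A constant field has no
#' split: an empty map is returned with a warning.
#'
#' @param field numeric matrix of non-negative finite values.
#' @return logical matrix (EdgeMap).
#' @export
binarize_pheromone <- function(field) {
  if (!is.matrix(field) || !is.numeric(field)) {
    stop("pheromone field must be a numeric matrix")
  }
  if (!all(is.finite(field)) || any(field < 0)) {
    stop("pheromone field must be finite and non-negative")
  }
  rng <- range(field)
  if (rng[1] == rng[2]) {
    warning("constant pheromone field: no edges")
    return(edge_map(matrix(FALSE, nrow(field), ncol(field))))
  }
  bins <- quantize256((field - rng[1]) / (rng[2] - rng[1]))
  t <- otsu_threshold(hist256(bins))
  edge_map(matrix(bins > t, nrow(field), ncol(field)))
}

#' ACO edge detection
#'
#' Composition of [compute_heuristic()], [run_aco()] and
#' [binarize_pheromone()].
#'
#' @inheritParams run_aco
#' @return logical matrix (EdgeMap).
#' @export
aco_edges <- function(img, params = aco_params()) {
  binarize_pheromone(run_aco(img, params))
}
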