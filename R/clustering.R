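#' Standardize feature columns
#'
#' Centres each column to zero mean and scales it to unit standard
#' deviation; constant columns are left at 0.  Size (pixel counts) and
#' intensity (`[0, 1]`) are incommensurate, so unstandardized euclidean
#' distances would be size-dominated.
#'
#' @param x numeric matrix (points in rows).
#' @return standardized matrix with `"center"` and `"scale"` attributes so
#'   cluster centres can be mapped back to raw units.
#' @export
standardize_columns <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  s[!is.finite(s) | s == 0] <- 1
  z <- sweep(sweep(x, 2, mu, `-`), 2, s, `/`)
  attr(z, "center") <- mu
  attr(z, "scale") <- s
  z
}

nearest_center <- function(x, centers) {
  d2 <- vapply(seq_len(nrow(centers)), function(j) {
    rowSums(sweep(x, 2, centers[j, ], `-`)^2)
  }, numeric(nrow(x)))
  d2 <- matrix(d2, nrow = nrow(x))
  list(assign = max.col(-d2, ties.method = "first"),
       sse = sum(d2[cbind(seq_len(nrow(x)), max.col(-d2, ties.method = "first"))]))
}

#' Seeded k-means (Lloyd) initialization
#'
#' Lloyd iterations from `k` distinct points drawn at random (seeded), run
#' until the assignments are stable or 100 iterations; a cluster that
#' empties is re-seeded with the point farthest from its assigned centre.
#'
#' @param points numeric matrix, one point per row.
#' @param k number of clusters; must not exceed the number of distinct
#'   points.
#' @param seed integer seed.
#' @return a list with `centers` (k x d matrix), `assignments`, `sse`, and
#'   `sse_trace` (SSE after each Lloyd iteration, non-increasing).
#' @export
kmeans_init <- function(points, k, seed = 1L) {
  x <- as.matrix(points)
  k <- as.integer(k)
  if (k < 1L) stop("k must be positive")
  ux <- unique(x)
  if (k > nrow(ux)) {
    stop("k = ", k, " exceeds the number of distinct points (", nrow(ux), ")")
  }
  with_seed(seed, {
    centers <- ux[sample.int(nrow(ux), k), , drop = FALSE]
    assign_old <- rep(0L, nrow(x))
    trace <- numeric(0)
    for (it in seq_len(100L)) {
      nc <- nearest_center(x, centers)
      # re-seed empty clusters with the farthest point from its centre
      for (j in seq_len(k)) {
        if (!any(nc$assign == j)) {
          d2 <- rowSums((x - centers[nc$assign, , drop = FALSE])^2)
          far <- which.max(d2)
          centers[j, ] <- x[far, ]
          nc <- nearest_center(x, centers)
        }
      }
      trace <- c(trace, nc$sse)
      if (identical(nc$assign, assign_old)) break
      assign_old <- nc$assign
      for (j in seq_len(k)) {
        centers[j, ] <- colMeans(x[nc$assign == j, , drop = FALSE])
      }
    }
    final <- nearest_center(x, centers)
    list(centers = centers, assignments = final$assign, sse = final$sse,
         sse_trace = trace)
  })
}

#' GA parameter set for cluster-centre refinement
#'
#' @param population population size (default 20).
#' @param generations number of generations (default 100).
#' @param crossover_prob single-point crossover probability (default 0.8).
#' @param mutation_prob per-gene gaussian mutation probability (default
#'   0.05; mutation scale is 0.1 x the column spread).
#' @param elitism number of best chromosomes copied unchanged (default 1,
#'   must be smaller than the population).
#' @param seed integer seed.
#' @return a list of class `ga_params`.
#' @export
ga_params <- function(population = 20L, generations = 100L,
                      crossover_prob = 0.8, mutation_prob = 0.05,
                      elitism = 1L, seed = 1L) {
  if (population < 2L) stop("population must be >= 2")
  if (generations < 0L) stop("generations must be >= 0")
  if (crossover_prob < 0 || crossover_prob > 1) {
    stop("crossover_prob must lie in [0, 1]")
  }
  if (mutation_prob < 0 || mutation_prob > 1) {
    stop("mutation_prob must lie in [0, 1]")
  }
  if (elitism < 1L || elitism >= population) {
    stop("elitism must be positive and smaller than the population")
  }
  structure(
    list(population = as.integer(population),
         generations = as.integer(generations),
         crossover_prob = crossover_prob, mutation_prob = mutation_prob,
         elitism = as.integer(elitism), seed = as.integer(seed)),
    class = "ga_params"
  )
}

#' Genetic-algorithm refinement of cluster centres
#'
#' A chromosome is the concatenation of the `k` cluster centres (length
#' `k * d`) with fitness `1 / (1 + SSE)`, where SSE is the total squared
#' distance of the points to their nearest encoded centre.  The population
#' is initialized with the k-means chromosome plus gaussian perturbations of
#' it; each generation applies tournament selection (size 2), single-point
#' crossover on the gene vector, per-gene gaussian mutation (scale 0.1 x
#' column spread), and elitism.  Elitism makes the best fitness
#' non-decreasing, so the returned SSE never exceeds the initializer's.
#'
#' @param points numeric matrix, one point per row.
#' @param init_centers k x d matrix of starting centres (typically from
#'   [kmeans_init()]).
#' @param params a [ga_params()] list.
#' @return a list with `centers`, `assignments`, `sse`, `fitness`, and
#'   `fitness_trace` (best fitness per generation, non-decreasing).
#' @export
ga_refine <- function(points, init_centers, params = ga_params()) {
  x <- as.matrix(points)
  centers0 <- as.matrix(init_centers)
  k <- nrow(centers0)
  d <- ncol(centers0)
  if (ncol(x) != d) stop("points and centres must share dimensionality")
  if (nrow(unique(x)) == 1L) {
    warning("all points are identical: clustering is degenerate")
    ctr <- matrix(rep(x[1, ], each = k), nrow = k)
    return(list(centers = ctr, assignments = rep(1L, nrow(x)), sse = 0,
                fitness = 1, fitness_trace = numeric(0)))
  }
  spread <- apply(x, 2, stats::sd)
  spread[!is.finite(spread) | spread == 0] <- 1e-8
  gene_scale <- rep(0.1 * spread, k) # gene j belongs to column rep pattern
  L <- k * d
  sse_of <- function(genes) {
    nearest_center(x, matrix(genes, nrow = k, byrow = TRUE))$sse
  }
  genes0 <- as.vector(t(centers0))
  with_seed(params$seed, {
    pop <- vector("list", params$population)
    pop[[1]] <- genes0
    for (i in seq.int(2L, params$population)) {
      pop[[i]] <- genes0 + stats::rnorm(L, 0, gene_scale)
    }
    fit <- vapply(pop, function(g) 1 / (1 + sse_of(g)), numeric(1))
    trace <- numeric(params$generations)
    for (gen in seq_len(params$generations)) {
      ord <- order(fit, decreasing = TRUE)
      newpop <- pop[ord[seq_len(params$elitism)]]
      tournament <- function() {
        ij <- sample.int(params$population, 2L, replace = TRUE)
        if (fit[ij[1]] >= fit[ij[2]]) pop[[ij[1]]] else pop[[ij[2]]]
      }
      while (length(newpop) < params$population) {
        p1 <- tournament()
        p2 <- tournament()
        if (stats::runif(1) < params$crossover_prob && L > 1L) {
          cp <- sample.int(L - 1L, 1L)
          c1 <- c(p1[seq_len(cp)], p2[seq.int(cp + 1L, L)])
          c2 <- c(p2[seq_len(cp)], p1[seq.int(cp + 1L, L)])
        } else {
          c1 <- p1
          c2 <- p2
        }
        for (child in list(c1, c2)) {
          mut <- stats::runif(L) < params$mutation_prob
          if (any(mut)) {
            child[mut] <- child[mut] +
              stats::rnorm(sum(mut), 0, gene_scale[mut])
          }
          if (length(newpop) < params$population) {
            newpop[[length(newpop) + 1L]] <- child
          }
        }
      }
      pop <- newpop
      fit <- vapply(pop, function(g) 1 / (1 + sse_of(g)), numeric(1))
      trace[gen] <- max(fit)
    }
    best <- which.max(fit)
    centers <- matrix(pop[[best]], nrow = k, byrow = TRUE)
    nc <- nearest_center(x, centers)
    list(centers = centers, assignments = nc$assign, sse = nc$sse,
         fitness = 1 / (1 + nc$sse), fitness_trace = trace)
  })
}

#' Single-linkage hierarchical clustering
#'
#' Agglomerative clustering with nearest-neighbour (single) linkage and
#' euclidean dissimilarity: the pair of groups with the smallest
#' dissimilarity is merged until `k` groups remain.
#'
#' @param points numeric matrix, one point per row.
#' @param k number of clusters, at most the number of points.
#' @return integer vector of cluster assignments in `1..k`.
#' @export
hierarchical_cluster <- function(points, k) {
  x <- as.matrix(points)
  k <- as.integer(k)
  if (k < 1L) stop("k must be positive")
  if (k > nrow(x)) {
    stop("k = ", k, " exceeds the number of points (", nrow(x), ")")
  }
  if (k == nrow(x)) return(seq_len(nrow(x)))
  hc <- stats::hclust(stats::dist(x), method = "single")
  as.integer(stats::cutree(hc, k = k))
}

#' Label two clusters as benign / malignant
#'
#' Malignant nodules are larger than benign ones, so the cluster with the
#' larger mean size column is labelled malignant; on a tie, the cluster with
#' the larger mean intensity.  With `k != 2` there is no binary reading:
#' cluster indices are returned as labels with a warning.
#'
#' @param assignments integer cluster assignments.
#' @param features data frame with `area_px` and `mean_intensity` columns,
#'   aligned with `assignments`.
#' @return named character vector mapping each cluster id to `"benign"` /
#'   `"malignant"` (or to its own index when `k != 2`).
#' @export
label_malignancy <- function(assignments, features) {
  ids <- sort(unique(assignments))
  if (length(ids) != 2L) {
    warning("malignancy labelling needs exactly 2 clusters; returning ",
            "cluster indices")
    out <- as.character(ids)
    names(out) <- as.character(ids)
    return(out)
  }
  mean_size <- vapply(ids, function(g) {
    mean(features$area_px[assignments == g])
  }, numeric(1))
  mean_int <- vapply(ids, function(g) {
    mean(features$mean_intensity[assignments == g])
  }, numeric(1))
  mal <- if (mean_size[1] != mean_size[2]) {
    ids[which.max(mean_size)]
  } else {
    ids[which.max(mean_int)]
  }
  out <- ifelse(ids == mal, "malignant", "benign")
  names(out) <- as.character(ids)
  out
}

#' GA-refined k-means clustering of a feature matrix
#'
#' Convenience wrapper for the primary clustering route: standardize the
#' numeric feature columns, initialize with seeded k-means, refine the
#' centres with the genetic algorithm, and (for `k = 2`) label the clusters
#' benign / malignant.
#'
#' @param features data frame from [build_feature_matrix()].
#' @param k number of clusters (default 2, benign vs malignant).
#' @param params a [ga_params()] list.
#' @return a list with `assignments`, `cluster_labels`, `point_labels`,
#'   `centers` (standardized space), `sse` and `fitness_trace`.
#' @export
ga_cluster <- function(features, k = 2L, params = ga_params()) {
  x <- standardize_columns(feature_columns(features))
  km <- kmeans_init(x, k, seed = params$seed)
  ga <- ga_refine(x, km$centers, params)
  labels <- if (k == 2L) {
    label_malignancy(ga$assignments, features)
  } else {
    ids <- sort(unique(ga$assignments))
    stats::setNames(as.character(ids), as.character(ids))
  }
  list(assignments = ga$assignments,
       cluster_labels = labels,
       point_labels = unname(labels[as.character(ga$assignments)]),
       centers = ga$centers, sse = ga$sse, kmeans_sse = km$sse,
       fitness_trace = ga$fitness_trace)
}
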