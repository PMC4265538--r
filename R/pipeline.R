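PIPELINE_METHODS <- c("otsu", "watershed", "region", "aco", "refined-aco",
                      "logical-aco", "variant-aco")

#' Pipeline configuration
#'
#' Fully resolved parameter set for [run_pipeline()].  Detection defaults
#' here differ from the standalone module defaults in four places, all
#' driven by the shape of the ACO edge response (a band ~2 px wider than
#' the structure underneath it, binarized from an evaporating pheromone
#' field and therefore often a *partial* ring): the candidate size limit is
#' `d_max = 8` px (the 5 px nodule limit plus the band width); the
#' fill-ratio gate is relaxed to 0.3 because a ragged partial ring is
#' sparser in its bounding box than a solid blob; candidate centres use the
#' `"bbox"` policy, which is far less biased than the pixel centroid when
#' the component is an open arc; and the intensity probe uses a fixed
#' 1.5 px core radius instead of the candidate's band-inflated equivalent
#' radius, so the probe samples the candidate core rather than diluting it
#' with surrounding background.  Thin bright lines remain rejected because
#' a 1 px wide line fills only ~2/(pi*r) of a probe disk, keeping its mean
#' intensity near background.
#'
#' @param method one of `"otsu"`, `"watershed"`, `"region"`, `"aco"`,
#'   `"refined-aco"`, `"logical-aco"`, `"variant-aco"`.
#' @param aco an [aco_params()] list (ACO-family methods).
#' @param max_rounds,tol refined-ACO stopping rule (see [refined_aco()]).
#' @param n_smooth watershed pre-smoothing passes.
#' @param region_seed `(row, col)` seed for region growing, or `NULL` for
#'   the raster centre.
#' @param region_tolerance region-growing admission tolerance.
#' @param connectivity,fill_ratio_min,aspect_max,d_max,ecc_threshold,center_policy
#'   candidate-detection knobs (see [detect_candidates()]).
#' @param intensity_threshold,radius_policy,fixed_radius,center_search_radius,age
#'   feature-stage knobs (see [build_feature_matrix()]).
#' @param cluster_algo `"ga"` (default) or `"hier"`.
#' @param k number of clusters (default 2).
#' @param ga a [ga_params()] list.
#' @param max_dist object-matching distance, or `NULL` for per-truth radii.
#' @param seed integer master seed; `aco$seed` and `ga$seed` default to it.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(method = "variant-aco", aco = NULL,
                            max_rounds = 5L, tol = 0.01, n_smooth = 1L,
                            region_seed = NULL, region_tolerance = 0.1,
                            connectivity = 8L, fill_ratio_min = 0.3,
                            aspect_max = 3, d_max = 8, ecc_threshold = 1.5,
                            center_policy = "bbox",
                            intensity_threshold = 0.5,
                            radius_policy = "fixed", fixed_radius = 1.5,
                            center_search_radius = 2,
                            age = NULL, cluster_algo = "ga", k = 2L,
                            ga = NULL, max_dist = NULL, seed = 1L) {
  if (!method %in% PIPELINE_METHODS) {
    stop("unknown method '", method, "'; valid methods: ",
         paste(PIPELINE_METHODS, collapse = ", "))
  }
  if (!cluster_algo %in% c("ga", "hier")) {
    stop("cluster_algo must be 'ga' or 'hier'")
  }
  seed <- as.integer(seed)
  aco <- if (is.null(aco)) aco_params(seed = seed) else aco
  ga <- if (is.null(ga)) ga_params(seed = seed) else ga
  structure(
    list(method = method, aco = aco, max_rounds = as.integer(max_rounds),
         tol = tol, n_smooth = as.integer(n_smooth),
         region_seed = region_seed, region_tolerance = region_tolerance,
         connectivity = as.integer(connectivity),
         fill_ratio_min = fill_ratio_min, aspect_max = aspect_max,
         d_max = d_max, ecc_threshold = ecc_threshold,
         center_policy = center_policy,
         intensity_threshold = intensity_threshold,
         radius_policy = radius_policy, fixed_radius = fixed_radius,
         center_search_radius = center_search_radius,
         age = age, cluster_algo = cluster_algo, k = as.integer(k), ga = ga,
         max_dist = max_dist, seed = seed),
    class = "pipeline_config"
  )
}

#' Detect edges with any of the seven methods
#'
#' Method dispatch shared by the pipeline and the CLI.
#'
#' @param img numeric matrix in `[0, 1]` (GrayRaster).
#' @param cfg a [pipeline_config()] list.
#' @return logical matrix (EdgeMap).
#' @export
detect_edges <- function(img, cfg = pipeline_config()) {
  img <- gray_raster(img)
  switch(cfg$method,
    otsu = otsu_edges(img),
    watershed = watershed_edges(img, cfg$n_smooth),
    region = {
      seed <- cfg$region_seed %||%
        c(round(nrow(img) / 2), round(ncol(img) / 2))
      region_growing_edges(img, seed, cfg$region_tolerance)
    },
    aco = aco_edges(img, cfg$aco),
    `refined-aco` = {
      run <- refined_aco(img, cfg$aco, cfg$max_rounds, cfg$tol)
      run$rounds[[length(run$rounds)]]
    },
    `logical-aco` = {
      run <- refined_aco(img, cfg$aco, max(cfg$max_rounds, 2L), cfg$tol)
      logical_aco(run)
    },
    `variant-aco` = variant_aco(img, cfg$aco)
  )
}

#' Run the full detection pipeline on one image
#'
#' Edge detection (default method: variant ACO) -> candidate detection ->
#' intensity-based filtering -> clustering into benign/malignant -> (when
#' ground truth is supplied) object- and pixel-level evaluation.  With
#' `outdir` set, stage outputs are persisted as `edges.png`,
#' `candidates.csv`, `features.csv`, `clusters.csv`, `report.json` and a
#' `manifest.json` capturing the fully resolved configuration and package
#' version; re-running from the manifest reproduces every output.
#'
#' @param img numeric matrix in `[0, 1]` (GrayRaster).
#' @param truth optional ground truth (list with `nodules` and `mask`, as
#'   produced by [generate_phantom()]).
#' @param cfg a [pipeline_config()] list.
#' @param outdir optional output directory (created if missing).
#' @return a list with `edges`, `candidates`, `features`, `clusters`,
#'   `report` (object- and pixel-mode metrics, or `NULL` without truth) and
#'   `config`.
#' @export
run_pipeline <- function(img, truth = NULL, cfg = pipeline_config(),
                         outdir = NULL) {
  img <- gray_raster(img)
  edges <- detect_edges(img, cfg)
  candidates <- detect_candidates(
    edges, connectivity = cfg$connectivity,
    fill_ratio_min = cfg$fill_ratio_min, aspect_max = cfg$aspect_max,
    d_max = cfg$d_max, ecc_threshold = cfg$ecc_threshold,
    center_policy = cfg$center_policy
  )
  features <- build_feature_matrix(
    img, candidates, intensity_threshold = cfg$intensity_threshold,
    radius_policy = cfg$radius_policy, fixed_radius = cfg$fixed_radius,
    center_search_radius = cfg$center_search_radius, age = cfg$age
  )

  clusters <- NULL
  n_distinct <- nrow(unique(feature_columns(features)))
  if (nrow(features) >= 2L && n_distinct >= cfg$k) {
    if (cfg$cluster_algo == "ga") {
      cl <- ga_cluster(features, k = cfg$k, params = cfg$ga)
      clusters <- data.frame(candidate_id = features$candidate_id,
                             cluster = cl$assignments,
                             label = cl$point_labels,
                             stringsAsFactors = FALSE)
    } else {
      x <- standardize_columns(feature_columns(features))
      assign <- hierarchical_cluster(x, cfg$k)
      labels <- if (cfg$k == 2L) {
        label_malignancy(assign, features)
      } else {
        stats::setNames(as.character(sort(unique(assign))),
                        as.character(sort(unique(assign))))
      }
      clusters <- data.frame(candidate_id = features$candidate_id,
                             cluster = assign,
                             label = unname(labels[as.character(assign)]),
                             stringsAsFactors = FALSE)
    }
  }

  report <- NULL
  if (!is.null(truth)) {
    obj <- match_objects(features, truth$nodules, cfg$max_dist)
    object_metrics <- compute_metrics(obj, n_detected = nrow(features),
                                      n_truth = nrow(truth$nodules))
    detected_mask <- matrix(FALSE, nrow(img), ncol(img))
    comps <- attr(candidates, "components")
    kept <- match(features$candidate_id, candidates$id)
    for (i in kept) detected_mask[comps[[i]]$pixels] <- TRUE
    pixel_metrics <- compute_metrics(pixel_confusion(detected_mask,
                                                     truth$mask))
    report <- list(object = object_metrics, pixel = pixel_metrics,
                   matches = obj$matches)
  }

  result <- list(edges = edges, candidates = candidates,
                 features = features, clusters = clusters, report = report,
                 config = cfg)
  if (!is.null(outdir)) write_pipeline_outputs(result, img, outdir)
  invisible(result)
}

write_pipeline_outputs <- function(result, img, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  save_edge_map(result$edges, file.path(outdir, "edges.png"))
  cand <- result$candidates
  attr(cand, "components") <- NULL
  utils::write.csv(cand, file.path(outdir, "candidates.csv"),
                   row.names = FALSE)
  utils::write.csv(result$features, file.path(outdir, "features.csv"),
                   row.names = FALSE)
  if (!is.null(result$clusters)) {
    utils::write.csv(result$clusters, file.path(outdir, "clusters.csv"),
                     row.names = FALSE)
  }
  if (!is.null(result$report)) {
    rep <- result$report
    rep$matches <- NULL
    jsonlite::write_json(rep, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
  }
  manifest <- list(
    package = "noduleant",
    version = as.character(utils::packageVersion("noduleant")),
    config = unclass_config(result$config)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(outdir)
}

unclass_config <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$aco <- unclass(cfg$aco)
  cfg$ga <- unclass(cfg$ga)
  cfg
}

#' Rebuild a pipeline configuration from a run manifest
#'
#' @param path path to a `manifest.json` written by [run_pipeline()].
#' @return a [pipeline_config()] list identical to the recorded one.
#' @export
config_from_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- m$config
  aco <- do.call(aco_params, cfg$aco[!vapply(cfg$aco, is.null, logical(1))])
  ga <- do.call(ga_params, cfg$ga)
  pipeline_config(
    method = cfg$method, aco = aco, max_rounds = cfg$max_rounds,
    tol = cfg$tol, n_smooth = cfg$n_smooth,
    region_seed = cfg$region_seed, region_tolerance = cfg$region_tolerance,
    connectivity = cfg$connectivity, fill_ratio_min = cfg$fill_ratio_min,
    aspect_max = cfg$aspect_max, d_max = cfg$d_max,
    ecc_threshold = cfg$ecc_threshold, center_policy = cfg$center_policy,
    intensity_threshold = cfg$intensity_threshold,
    radius_policy = cfg$radius_policy, fixed_radius = cfg$fixed_radius,
    center_search_radius = cfg$center_search_radius,
    age = cfg$age, cluster_algo = cfg$cluster_algo, k = cfg$k, ga = ga,
    max_dist = cfg$max_dist, seed = cfg$seed
  )
}

#' Compare the seven edge-detection methods over a phantom suite
#'
#' Runs the full pipeline with each method on every suite image and
#' averages the per-image metrics: recall ratio, sensitivity and precision
#' from object-level matching, specificity and accuracy from pixel-level
#' confusion of the detected candidate mask against the truth mask (the
#' negative class only exists per pixel).  Undefined per-image metrics are
#' skipped in the averages.  The per-method ACO seed is derived from the
#' configuration seed plus the image index, so the comparison is
#' deterministic.
#'
#' @param suite list of phantoms from [standard_suite()].
#' @param methods character vector of method names (default: all seven).
#' @param cfg base [pipeline_config()]; its `method` field is overridden.
#' @return data frame with columns `method`, `recall_ratio`, `sensitivity`,
#'   `specificity`, `accuracy`, `precision`; total object-level confusion
#'   counts per method are attached as the `"totals"` attribute.
#' @export
compare_methods <- function(suite, methods = PIPELINE_METHODS,
                            cfg = pipeline_config()) {
  bad <- setdiff(methods, PIPELINE_METHODS)
  if (length(bad) > 0L) {
    stop("unknown method(s) ", paste(bad, collapse = ", "),
         "; valid methods: ", paste(PIPELINE_METHODS, collapse = ", "))
  }
  rows <- list()
  totals <- list()
  for (method in methods) {
    per <- matrix(NA_real_, length(suite), 5,
                  dimnames = list(NULL, c("recall_ratio", "sensitivity",
                                          "specificity", "accuracy",
                                          "precision")))
    tot <- c(tp = 0L, fp = 0L, fn = 0L)
    for (i in seq_along(suite)) {
      ci <- cfg
      ci$method <- method
      ci$aco$seed <- cfg$aco$seed + i
      res <- run_pipeline(suite[[i]]$image, suite[[i]]$truth, ci)
      ob <- res$report$object
      px <- res$report$pixel
      per[i, ] <- c(ob$recall_ratio, ob$sensitivity, px$specificity,
                    px$accuracy, ob$precision)
      tot <- tot + c(tp = ob$tp, fp = ob$fp, fn = ob$fn)
    }
    rows[[method]] <- colMeans(per, na.rm = TRUE)
    totals[[method]] <- tot
  }
  out <- data.frame(method = methods,
                    do.call(rbind, rows[methods]),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "totals") <- totals
  out
}
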