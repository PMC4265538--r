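# Fixtures built in code, plus cached suite-level results shared by the
# slower acceptance checks (computed once per test run).

disk_image <- function(h = 32, w = 32, center = c(16, 16), diameter = 9,
                       bg = 0.1, fg = 0.9) {
  img <- matrix(bg, h, w)
  d2 <- outer((seq_len(h) - center[1])^2, (seq_len(w) - center[2])^2, `+`)
  img[d2 <= (diameter / 2)^2] <- fg
  img
}

disk_mask <- function(h, w, center, diameter) {
  d2 <- outer((seq_len(h) - center[1])^2, (seq_len(w) - center[2])^2, `+`)
  d2 <= (diameter / 2)^2
}

step_image <- function(h = 8, w = 8, split = w / 2, low = 0, high = 1) {
  img <- matrix(low, h, w)
  img[, seq.int(split + 1, w)] <- high
  img
}

random_map <- function(h, w, p = 0.3) {
  matrix(runif(h * w) < p, h, w)
}

small_aco_params <- function(seed = 1L) {
  aco_params(n_ants = 64L, n_iterations = 5L, steps_per_ant = 30L,
             seed = seed)
}

# --- cached fixed-suite results -------------------------------------------
.suite_cache <- new.env(parent = emptyenv())

fixed_suite <- function() {
  if (is.null(.suite_cache$suite)) {
    .suite_cache$suite <- standard_suite(10, base_seed = 42)
  }
  .suite_cache$suite
}

# full pipeline runs on the fixed suite for one method, aco seed 42 + image
suite_pipeline <- function(method) {
  key <- paste0("pipe_", method)
  if (is.null(.suite_cache[[key]])) {
    suite <- fixed_suite()
    cfg <- pipeline_config(method = method, seed = 42)
    .suite_cache[[key]] <- lapply(seq_along(suite), function(i) {
      ci <- cfg
      ci$aco$seed <- 42L + i
      suppressWarnings(
        run_pipeline(suite[[i]]$image, suite[[i]]$truth, ci)
      )
    })
  }
  .suite_cache[[key]]
}

# edge maps of the fixed suite for one raw detector
suite_edges <- function(detector) {
  key <- paste0("edges_", detector)
  if (is.null(.suite_cache[[key]])) {
    suite <- fixed_suite()
    .suite_cache[[key]] <- lapply(seq_along(suite), function(i) {
      prm <- aco_params(seed = 42L + i)
      suppressWarnings(switch(detector,
        aco = aco_edges(suite[[i]]$image, prm),
        `variant-aco` = variant_aco(suite[[i]]$image, prm)
      ))
    })
  }
  .suite_cache[[key]]
}

# refined runs on the fixed suite
suite_refined <- function(max_rounds = 5L, tol = 0.01) {
  key <- "refined"
  if (is.null(.suite_cache[[key]])) {
    suite <- fixed_suite()
    .suite_cache[[key]] <- lapply(seq_along(suite), function(i) {
      suppressWarnings(
        refined_aco(suite[[i]]$image, aco_params(seed = 42L + i),
                    max_rounds = max_rounds, tol = tol)
      )
    })
  }
  .suite_cache[[key]]
}
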