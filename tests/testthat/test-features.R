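test_that("circular mean intensity enumerates the disk pixels", {
  img <- matrix(0.42, 7, 7)
  expect_equal(circular_mean_intensity(img, c(4, 4), 2.5), 0.42)
  expect_equal(circular_mean_intensity(img, c(1, 1), 10), 0.42)

  img2 <- matrix(0, 5, 5)
  img2[3, 3] <- 1
  img2[2, 3] <- img2[4, 3] <- img2[3, 2] <- img2[3, 4] <- 0.5
  expect_equal(circular_mean_intensity(img2, c(3, 3), 0), 1)
  expect_equal(circular_mean_intensity(img2, c(3, 3), 1), (1 + 4 * 0.5) / 5)

  expect_error(circular_mean_intensity(img2, c(0, 3), 1), "outside")
  expect_error(circular_mean_intensity(img2, c(3, 6), 1), "outside")
  expect_error(circular_mean_intensity(img2, c(3, 3), -1), "radius")
})

make_two_plateau <- function() {
  # two 3x3 plateaus at 0.8 and 0.3 on a zero background
  img <- matrix(0, 20, 20)
  img[4:6, 4:6] <- 0.8
  img[14:16, 14:16] <- 0.3
  cand <- data.frame(id = 1:2, row = c(5L, 15L), col = c(5L, 15L),
                     area_px = c(9L, 9L),
                     equiv_diameter = rep(2 * sqrt(9 / pi), 2),
                     shape = c("spherical", "spherical"),
                     stringsAsFactors = FALSE)
  list(img = img, cand = cand)
}

test_that("intensity filtering keeps exactly the bright candidates", {
  tp <- make_two_plateau()
  f0 <- build_feature_matrix(tp$img, tp$cand, intensity_threshold = 0)
  expect_equal(nrow(f0), 2L)
  f1 <- build_feature_matrix(tp$img, tp$cand, intensity_threshold = 1)
  expect_equal(nrow(f1), 0L)
  f <- build_feature_matrix(tp$img, tp$cand, intensity_threshold = 0.5,
                            radius_policy = "fixed", fixed_radius = 1)
  expect_equal(f$candidate_id, 1L)
  expect_equal(f$mean_intensity, 0.8)

  expect_error(build_feature_matrix(tp$img, tp$cand,
                                    intensity_threshold = 1.2), "\\[0, 1\\]")
})

test_that("filtering is monotone in the threshold", {
  tp <- make_two_plateau()
  ns <- vapply(c(0, 0.2, 0.4, 0.6, 0.9), function(th) {
    nrow(build_feature_matrix(tp$img, tp$cand, intensity_threshold = th))
  }, numeric(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("feature rows reproduce an independent intensity recomputation", {
  tp <- make_two_plateau()
  f <- build_feature_matrix(tp$img, tp$cand, intensity_threshold = 0)
  for (i in seq_len(nrow(f))) {
    r <- tp$cand$equiv_diameter[tp$cand$id == f$candidate_id[i]] / 2
    ctr <- c(f$row[i], f$col[i])
    px <- which(outer((seq_len(20) - ctr[1])^2,
                      (seq_len(20) - ctr[2])^2, `+`) <= r^2)
    expect_equal(f$mean_intensity[i], mean(tp$img[px]))
  }
})

test_that("probe position search finds an offset bright core", {
  img <- matrix(0.1, 15, 15)
  img[disk_mask(15, 15, c(8, 8), 5)] <- 0.9
  cand <- data.frame(id = 1L, row = 10L, col = 8L, area_px = 9L,
                     equiv_diameter = 3, shape = "spherical",
                     stringsAsFactors = FALSE)  # centre 2 px off the disk
  f_fixed <- build_feature_matrix(img, cand, intensity_threshold = 0,
                                  radius_policy = "fixed", fixed_radius = 1.5)
  f_search <- build_feature_matrix(img, cand, intensity_threshold = 0,
                                   radius_policy = "fixed",
                                   fixed_radius = 1.5,
                                   center_search_radius = 2)
  expect_gt(f_search$mean_intensity, f_fixed$mean_intensity)
  expect_equal(f_search$mean_intensity, 0.9)
})

test_that("age and shape are carried into the feature columns", {
  tp <- make_two_plateau()
  tp$cand$shape <- c("spherical", "elliptical")
  f <- build_feature_matrix(tp$img, tp$cand, intensity_threshold = 0,
                            age = 61)
  expect_equal(f$age, c(61, 61))
  x <- feature_columns(f)
  expect_identical(colnames(x), c("mean_intensity", "area_px", "shape", "age"))
  expect_equal(x[, "shape"], c(0, 1))
})
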