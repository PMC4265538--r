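two_clouds <- function(seed, n = 50, sigma = 1, sep = 10) {
  with_seed(seed, {
    m1 <- c(0, 0)
    m2 <- c(sep * sigma, 0)
    x <- rbind(
      cbind(rnorm(n, m1[1], sigma), rnorm(n, m1[2], sigma)),
      cbind(rnorm(n, m2[1], sigma), rnorm(n, m2[2], sigma))
    )
    list(x = x, means = rbind(m1, m2), sigma = sigma)
  })
}

center_error <- function(centers, means) {
  # best assignment of found centres to true means (k = 2)
  e1 <- max(sqrt(rowSums((centers - means)^2)))
  e2 <- max(sqrt(rowSums((centers - means[2:1, ])^2)))
  min(e1, e2)
}

test_that("kmeans_init recovers separated clouds and decreases SSE", {
  one <- matrix(c(0.3, 0.7), 1, 2)
  km1 <- kmeans_init(one, 1, seed = 1)
  expect_equal(km1$centers, one, ignore_attr = TRUE)

  tc <- two_clouds(101)
  km <- kmeans_init(tc$x, 2, seed = 5)
  expect_lt(center_error(km$centers, tc$means), 0.5 * tc$sigma)
  expect_true(all(diff(km$sse_trace) <= 1e-9))

  expect_error(kmeans_init(rbind(c(1, 1), c(1, 1)), 2), "distinct")
})

test_that("kmeans_init matches stats::kmeans on well-separated data", {
  tc <- two_clouds(202)
  km <- kmeans_init(tc$x, 2, seed = 3)
  ref <- stats::kmeans(tc$x, centers = 2, nstart = 5)
  expect_equal(km$sse, ref$tot.withinss, tolerance = 1e-6)
})

test_that("GA refinement never does worse than its k-means start", {
  p <- ga_params(population = 16L, generations = 25L, seed = 7L)
  for (s in c(301, 302, 303)) {
    tc <- two_clouds(s)
    km <- kmeans_init(tc$x, 2, seed = s)
    ga <- ga_refine(tc$x, km$centers, p)
    expect_lte(ga$sse, km$sse + 1e-9)
    expect_gte(ga$fitness, 1 / (1 + km$sse) - 1e-12)
    expect_true(all(diff(ga$fitness_trace) >= -1e-12))
    expect_lt(center_error(ga$centers, tc$means), 0.5 * tc$sigma)
  }
})

test_that("GA with zero generations returns the initializer unchanged", {
  tc <- two_clouds(404)
  km <- kmeans_init(tc$x, 2, seed = 1)
  ga <- ga_refine(tc$x, km$centers,
                  ga_params(population = 8L, generations = 0L, seed = 1L))
  expect_equal(ga$centers, km$centers)
  expect_equal(ga$sse, km$sse)
})

test_that("GA on identical points degenerates with a warning", {
  x <- matrix(1, 5, 2)
  expect_warning(ga <- ga_refine(x, matrix(1, 2, 2), ga_params(seed = 1)),
                 "identical")
  expect_equal(ga$sse, 0)
  expect_true(all(ga$assignments == 1L))
})

test_that("assignments partition the points", {
  tc <- two_clouds(505)
  km <- kmeans_init(tc$x, 2, seed = 2)
  ga <- ga_refine(tc$x, km$centers,
                  ga_params(population = 10L, generations = 10L, seed = 2L))
  expect_length(ga$assignments, nrow(tc$x))
  expect_true(all(ga$assignments %in% 1:2))
})

test_that("hierarchical clustering follows single linkage", {
  x <- matrix(c(0, 1, 10), ncol = 1)
  expect_true(same_partition(hierarchical_cluster(x, 2), c(1, 1, 2)))
  expect_identical(hierarchical_cluster(x, 3), 1:3)
  expect_error(hierarchical_cluster(x, 4), "exceeds")

  set.seed(61)
  for (i in 1:15) {
    n <- sample(4:8, 1)
    pts <- matrix(runif(n * 2, 0, 10), n, 2)
    k <- sample(2:(n - 1), 1)
    expect_true(same_partition(hierarchical_cluster(pts, k),
                               single_linkage_oracle(pts, k)))
  }
})

test_that("malignancy labels follow size, then intensity", {
  feats <- data.frame(area_px = c(30, 31, 8, 7),
                      mean_intensity = c(0.5, 0.5, 0.5, 0.5))
  lab <- label_malignancy(c(1, 1, 2, 2), feats)
  expect_identical(unname(lab["1"]), "malignant")
  expect_identical(unname(lab["2"]), "benign")

  feats2 <- data.frame(area_px = c(10, 10), mean_intensity = c(0.9, 0.4))
  lab2 <- label_malignancy(c(1, 2), feats2)
  expect_identical(unname(lab2["1"]), "malignant")

  expect_warning(lab3 <- label_malignancy(c(1, 2, 3),
                                          data.frame(area_px = 1:3,
                                                     mean_intensity = 1:3)),
                 "2 clusters")
  expect_identical(unname(lab3), c("1", "2", "3"))
})

test_that("standardization zero-centres and unit-scales columns", {
  x <- cbind(a = c(1, 2, 3, 4), b = rep(5, 4))
  z <- standardize_columns(x)
  expect_equal(mean(z[, 1]), 0)
  expect_equal(stats::sd(z[, 1]), 1)
  expect_true(all(z[, 2] == 0))
})
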