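test_that("otsu_threshold handles two-point, degenerate and empty inputs", {
  h <- integer(256)
  h[10 + 1] <- 40
  h[200 + 1] <- 60
  expect_identical(otsu_threshold(h), 10L)  # any t in [10,199] optimal; lowest wins

  h1 <- integer(256)
  h1[77 + 1] <- 5
  expect_warning(t1 <- otsu_threshold(h1), "single occupied bin")
  expect_identical(t1, 77L)

  expect_error(otsu_threshold(integer(256)), "empty histogram")
  expect_error(otsu_threshold(integer(10)), "256")
})

test_that("otsu_threshold agrees with the exhaustive-scan oracle", {
  set.seed(11)
  for (i in 1:50) {
    counts <- rpois(256, lambda = runif(1, 0.5, 20))
    if (sum(counts > 0) < 2) next
    sigma <- brute_otsu(counts)
    t <- otsu_threshold(counts)
    best <- max(sigma)
    expect_lt(abs(sigma[t + 1] - best), 1e-9 * max(best, 1))
    expect_identical(t, as.integer(min(which(sigma > best - 1e-9 * max(best, 1))) - 1L))
  }
})

test_that("otsu_edges marks the inner foreground boundary", {
  img <- step_image(6, 8, split = 4, low = 0.1, high = 0.9)
  e <- otsu_edges(img)
  expected <- matrix(FALSE, 6, 8)
  expected[, 5] <- TRUE  # one column wide, on the bright side
  expect_identical(e, expected)

  expect_warning(e0 <- otsu_edges(matrix(0.5, 5, 5)), "single occupied bin")
  expect_true(!any(e0))

  img2 <- disk_image(24, 24, c(12, 12), diameter = 11)
  fg <- disk_mask(24, 24, c(12, 12), 11)
  ring <- fg & !(shift_oracle(fg, -1, 0) & shift_oracle(fg, 1, 0) &
                   shift_oracle(fg, 0, -1) & shift_oracle(fg, 0, 1))
  expect_identical(otsu_edges(img2), ring)
})

test_that("watershed: constant image gives one basin and no dams", {
  expect_true(!any(watershed_edges(matrix(0.3, 10, 10))))
  expect_equal(max(watershed_basins(matrix(0.3, 10, 10))), 1L)
})

test_that("watershed dams separate the basins of a two-valley surface", {
  # two flat plateaus joined by a ramp: gradient is zero on the plateaus and
  # positive on the ramp, so flooding meets along the ramp
  img <- matrix(0, 20, 24)
  ramp_cols <- 9:16
  img[, ramp_cols] <- rep((seq_along(ramp_cols)) / 9, each = 20)
  img[, 17:24] <- 1
  lab <- watershed_basins(img, n_smooth = 0, gradient_floor = 0)
  dams <- lab == 0
  basins <- setdiff(unique(as.vector(lab)), 0L)
  expect_equal(length(basins), 2L)
  expect_true(any(dams))
  expect_true(all(which(dams, arr.ind = TRUE)[, 2] %in% 8:17))
  # removing dam pixels leaves no 4-path between different basins
  open <- lab != 0
  comps <- flood_fill_components(open, 4)
  for (comp in comps) {
    expect_equal(length(unique(lab[comp])), 1L)
  }
})

test_that("smoothing never increases the basin count on a fixed raster", {
  set.seed(21)
  img <- matrix(runif(40 * 40), 40, 40)
  counts <- vapply(0:3, function(ns) {
    max(watershed_basins(img, n_smooth = ns, gradient_floor = 0))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("region growing follows the running-mean admission rule", {
  set.seed(31)
  img <- matrix(runif(12 * 12, 0.2, 0.8), 12, 12)
  # tolerance >= 1 admits everything: the edge is the raster border
  e <- region_growing_edges(img, c(6, 6), tolerance = 1)
  border <- matrix(FALSE, 12, 12)
  border[c(1, 12), ] <- TRUE
  border[, c(1, 12)] <- TRUE
  expect_identical(e, border)

  # tolerance 0 with a unique seed value: region and edge are the seed alone
  img2 <- matrix(0.2, 5, 5)
  img2[3, 3] <- 0.9
  e2 <- region_growing_edges(img2, c(3, 3), tolerance = 0)
  expect_identical(which(e2), which(matrix(seq_len(25), 5, 5) == 13))

  # uniform disk: the grown region is exactly the disk
  img3 <- disk_image(24, 24, c(12, 12), diameter = 9, bg = 0.1, fg = 0.9)
  fg <- disk_mask(24, 24, c(12, 12), 9)
  expect_identical(grow_region(img3, c(12, 12), tolerance = 0.2), fg)
  ring <- fg & !(shift_oracle(fg, -1, 0) & shift_oracle(fg, 1, 0) &
                   shift_oracle(fg, 0, -1) & shift_oracle(fg, 0, 1))
  expect_identical(region_growing_edges(img3, c(12, 12), 0.2), ring)

  expect_error(region_growing_edges(img3, c(0, 5), 0.1), "outside")
  expect_error(region_growing_edges(img3, c(25, 5), 0.1), "outside")
})

test_that("the grown region is 4-connected and contains the seed", {
  set.seed(41)
  for (i in 1:5) {
    img <- matrix(runif(100), 10, 10)
    seed <- c(sample(10, 1), sample(10, 1))
    reg <- grow_region(img, seed, tolerance = 0.2)
    expect_true(reg[seed[1], seed[2]])
    comps <- flood_fill_components(reg, 4)
    expect_equal(length(comps), 1L)
  }
})
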