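test_that("connectivity semantics match the definition", {
  m <- matrix(FALSE, 4, 4)
  m[2, 2] <- TRUE
  comps <- find_components(m, 4)
  expect_length(comps, 1L)
  expect_equal(comps[[1]]$area, 1L)

  diag2 <- matrix(FALSE, 4, 4)
  diag2[2, 2] <- diag2[3, 3] <- TRUE
  expect_length(find_components(diag2, 4), 2L)
  expect_length(find_components(diag2, 8), 1L)

  expect_length(find_components(matrix(FALSE, 3, 3)), 0L)
  expect_error(find_components(m, 6), "connectivity")
})

test_that("components match the flood-fill oracle on random maps", {
  set.seed(19)
  for (i in 1:12) {
    m <- random_map(24, 24, runif(1, 0.2, 0.6))
    for (conn in c(4L, 8L)) {
      expect_identical(component_indices(find_components(m, conn), nrow(m)),
                       flood_fill_components(m, conn))
    }
  }
})

test_that("components partition the foreground deterministically", {
  set.seed(29)
  m <- random_map(32, 32, 0.35)
  comps <- find_components(m, 8)
  all_pix <- do.call(rbind, lapply(comps, `[[`, "pixels"))
  expect_equal(nrow(all_pix), sum(m))
  expect_false(any(duplicated(all_pix)))
  starts <- t(vapply(comps, function(co) co$bbox[c("min_row", "min_col")],
                     numeric(2)))
  expect_false(is.unsorted(order(starts[, 1], starts[, 2])))
  for (co in comps) {
    expect_lte(co$area, co$extent_major * co$extent_minor)
  }
})

test_that("line rejection uses fill ratio and bounding-box aspect", {
  run <- matrix(FALSE, 5, 24)
  run[3, 2:21] <- TRUE  # 1x20 run: full fill but aspect 20
  comp <- find_components(run)[[1]]
  expect_true(is_line_like(comp))

  sq <- matrix(FALSE, 5, 5)
  sq[2:4, 2:4] <- TRUE  # 3x3 solid block
  expect_false(is_line_like(find_components(sq)[[1]]))

  # L-shaped one-pixel path in a 10x10 bbox: 19 pixels, fill 0.19
  ell <- matrix(FALSE, 12, 12)
  ell[2:11, 2] <- TRUE
  ell[11, 2:11] <- TRUE
  comp_l <- find_components(ell)[[1]]
  expect_equal(comp_l$area, 19L)
  expect_true(is_line_like(comp_l))
})

test_that("candidates carry the equivalent-diameter size rule", {
  sq <- matrix(FALSE, 5, 5)
  sq[2:4, 2:4] <- TRUE
  comp <- find_components(sq)[[1]]
  ca <- candidate_from_component(comp)
  expect_equal(ca$equiv_diameter, 2 * sqrt(9 / pi), tolerance = 1e-12)
  expect_identical(ca$center, c(3L, 3L))
  expect_identical(ca$shape, "spherical")

  big <- matrix(FALSE, 16, 16)
  big[disk_mask(16, 16, c(8, 8), 9)] <- TRUE
  comp_big <- find_components(big)[[1]]
  expect_gt(2 * sqrt(comp_big$area / pi), 5)
  expect_null(candidate_from_component(comp_big))

  rect <- matrix(FALSE, 6, 9)
  rect[2:4, 2:7] <- TRUE  # 3x6: aspect 2 -> elliptical, ed ~ 4.79
  ca_r <- candidate_from_component(find_components(rect)[[1]])
  expect_identical(ca_r$shape, "elliptical")
  expect_equal(ca_r$equiv_diameter, 2 * sqrt(18 / pi), tolerance = 1e-12)
})

test_that("bbox centre policy centres open arcs better than the centroid", {
  fg <- disk_mask(18, 18, c(9, 9), 11)
  ring <- fg & !(shift_oracle(fg, -1, 0) & shift_oracle(fg, 1, 0) &
                   shift_oracle(fg, 0, -1) & shift_oracle(fg, 0, 1))
  arc <- ring
  arc[, 1:8] <- FALSE  # keep the right half-arc only
  comp <- find_components(arc)[[1]]
  cen <- candidate_from_component(comp, d_max = 20)$center
  box <- candidate_from_component(comp, d_max = 20,
                                  center_policy = "bbox")$center
  truth <- c(9, 9)
  expect_lt(sqrt(sum((box - truth)^2)), sqrt(sum((cen - truth)^2)))
})

test_that("detect_candidates keeps blobs and drops lines", {
  expect_equal(nrow(detect_candidates(matrix(FALSE, 8, 8))), 0L)

  m <- matrix(FALSE, 12, 30)
  m[2:4, 2:4] <- TRUE     # compact blob
  m[8, 5:24] <- TRUE      # 1x20 line
  cand <- detect_candidates(m)
  expect_equal(nrow(cand), 1L)
  expect_identical(c(cand$row, cand$col), c(3L, 3L))

  # k disjoint small blobs -> k candidates
  k_img <- matrix(FALSE, 30, 30)
  centers <- rbind(c(5, 5), c(5, 20), c(15, 10), c(25, 25), c(25, 5))
  for (i in seq_len(nrow(centers))) {
    k_img[centers[i, 1] + (-1:1), centers[i, 2] + (-1:1)] <- TRUE
  }
  cand_k <- detect_candidates(k_img)
  expect_equal(nrow(cand_k), 5L)
  expect_identical(cand_k$id, 1:5)
  for (i in seq_len(5)) {
    co <- attr(cand_k, "components")[[i]]
    expect_true(cand_k$row[i] >= co$bbox[["min_row"]] &&
                  cand_k$row[i] <= co$bbox[["max_row"]])
    expect_true(cand_k$col[i] >= co$bbox[["min_col"]] &&
                  cand_k$col[i] <= co$bbox[["max_col"]])
    expect_lte(cand_k$equiv_diameter[i], 5)
  }
})
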