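test_that("object matching is greedy, one-to-one, and radius-scaled", {
  truth3 <- data.frame(row = c(10, 20, 30), col = c(10, 20, 30),
                       diameter = rep(4, 3))
  m0 <- match_objects(data.frame(row = numeric(0), col = numeric(0)), truth3)
  expect_equal(c(m0$tp, m0$fp, m0$fn), c(0L, 0L, 3L))

  exact <- data.frame(row = c(10, 20), col = c(10, 20))
  m1 <- match_objects(exact, truth3[1:2, ])
  expect_equal(c(m1$tp, m1$fp, m1$fn), c(2L, 0L, 0L))
  expect_true(is.na(m1$tn))

  # two candidates near one truth: one TP, the surplus is FP
  two <- data.frame(row = c(10.5, 9.5), col = c(10, 10))
  m2 <- match_objects(two, truth3[1, , drop = FALSE], max_dist = 3)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(1L, 1L, 0L))

  expect_error(match_objects(two, truth3, max_dist = 0), "max_dist")
})

test_that("matching counts are invariant to truth-list order", {
  set.seed(77)
  truth <- data.frame(row = runif(8, 5, 60), col = runif(8, 5, 60),
                      diameter = runif(8, 3, 6))
  cand <- data.frame(row = runif(10, 5, 60), col = runif(10, 5, 60))
  m <- match_objects(cand, truth)
  perm <- sample(8)
  m_p <- match_objects(cand, truth[perm, ])
  expect_equal(m$tp, m_p$tp)
  expect_equal(m$fp, m_p$fp)
  expect_equal(m$fn, m_p$fn)
})

test_that("pixel confusion tallies every pixel exactly once", {
  a <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  same <- pixel_confusion(a, a)
  expect_equal(c(same$fp, same$fn), c(0L, 0L))

  comp <- pixel_confusion(a, !a)
  expect_equal(c(comp$tp, comp$tn), c(0L, 0L))

  set.seed(88)
  x <- random_map(8, 8)
  y <- random_map(8, 8)
  pc <- pixel_confusion(x, y)
  tally <- c(0L, 0L, 0L, 0L)
  for (i in 1:8) for (j in 1:8) {
    tally <- tally + c(x[i, j] && y[i, j], x[i, j] && !y[i, j],
                       !x[i, j] && y[i, j], !x[i, j] && !y[i, j])
  }
  expect_equal(c(pc$tp, pc$fp, pc$fn, pc$tn), tally)
  expect_equal(pc$tp + pc$fp + pc$fn + pc$tn, 64L)

  expect_error(pixel_confusion(x, random_map(7, 8)), "same shape")
})

test_that("metrics follow their definitions and never divide by zero", {
  m <- compute_metrics(list(tp = 3L, fp = 1L, fn = 2L, tn = 4L))
  expect_equal(m$sensitivity, 0.6)
  expect_equal(m$precision, 0.75)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$accuracy, 0.7)
  expect_identical(m$mode, "pixel")

  perfect <- compute_metrics(list(tp = 5L, fp = 0L, fn = 0L, tn = 10L),
                             n_detected = 5, n_truth = 5)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall_ratio, 1)

  # over-detection pushes the recall ratio above 1
  over <- compute_metrics(list(tp = 2L, fp = 1L, fn = 0L, tn = NA_integer_),
                          n_detected = 3, n_truth = 2)
  expect_equal(over$recall_ratio, 1.5)
  expect_identical(over$mode, "object")
  expect_equal(over$accuracy, 2 / 3)  # Jaccard-style without a negative class
  expect_true(is.na(over$specificity))

  nothing <- compute_metrics(list(tp = 0L, fp = 0L, fn = 0L,
                                  tn = NA_integer_))
  expect_true(is.na(nothing$sensitivity))
  expect_true(is.na(nothing$precision))

  expect_error(compute_metrics(list(tp = -1L, fp = 0L, fn = 0L, tn = 0L)),
               "non-negative")
})

test_that("defined ratio metrics stay inside [0, 1]", {
  set.seed(91)
  for (i in 1:25) {
    counts <- list(tp = sample(0:20, 1), fp = sample(0:20, 1),
                   fn = sample(0:20, 1), tn = sample(0:20, 1))
    m <- compute_metrics(counts, n_detected = sample(0:30, 1),
                         n_truth = sample(1:10, 1))
    for (name in c("sensitivity", "specificity", "accuracy", "precision")) {
      if (!is.na(m[[name]])) {
        expect_gte(m[[name]], 0)
        expect_lte(m[[name]], 1)
      }
    }
    expect_gte(m$recall_ratio, 0)
  }
})
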