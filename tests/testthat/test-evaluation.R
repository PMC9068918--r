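test_that("pixel error rate counts disagreements after thresholding", {
  t <- matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 0), 3, 3)
  expect_equal(pixel_error_rate(t, t), 0)
  expect_equal(pixel_error_rate(1 - t, t), 1)

  # flip one cell pixel and one empty pixel: 2 of 9 wrong
  p <- t; p[1, 1] <- 0; p[3, 3] <- 1
  expect_equal(pixel_error_rate(p, t), 2 / 9)

  set.seed(8)
  pr <- matrix(runif(2601), 51, 51)
  tr <- matrix(rbinom(2601, 1, 0.4), 51, 51)
  acc <- mean((pr > 0.5) == (tr > 0.5))
  expect_equal(pixel_error_rate(pr, tr), 1 - acc)
  expect_error(pixel_error_rate(matrix(0, 2, 2), tr), "shape")
})

test_that("depth metrics give exact-class accuracy and max class error", {
  expect_equal(depth_metrics(0:19, 0:19), list(accuracy = 1, max_error_um = 0))
  p <- c(0:8, 10); t <- c(0:9)
  expect_equal(depth_metrics(p, t), list(accuracy = 0.9, max_error_um = 100))
  expect_error(depth_metrics(integer(0), integer(0)), "empty")
})

test_that("sensitivity and specificity follow their confusion definitions", {
  perfect <- list(matrix(c(1, 1, 0, 0), 2, 2))
  m <- sensitivity_specificity(perfect, perfect)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)

  allcell <- list(matrix(1, 2, 2))
  m2 <- sensitivity_specificity(allcell, perfect)
  expect_equal(m2$sensitivity, 1)
  expect_equal(m2$specificity, 0)

  # TP=3 FN=1 TN=4 FP=1 -> sens 0.75, spec 0.8
  tr <- matrix(c(1, 1, 1, 1, 0, 0, 0, 0, 0), 3, 3)
  pr <- matrix(c(1, 1, 1, 0, 1, 0, 0, 0, 0), 3, 3)
  m3 <- sensitivity_specificity(list(pr), list(tr))
  expect_equal(m3$sensitivity, 0.75)
  expect_equal(m3$specificity, 0.8)
  expect_equal(m3$per_layer$error_rate, 2 / 9)

  # dual-route agreement: confusion-matrix result equals a direct pixel scan
  set.seed(31)
  for (i in 1:5) {
    p <- matrix(runif(400), 20, 20)
    t <- matrix(rbinom(400, 1, 0.3), 20, 20)
    m <- sensitivity_specificity(list(p), list(t))
    pb <- p > 0.5
    expect_equal(m$sensitivity, sum(pb[t == 1]) / sum(t == 1))
    expect_equal(m$specificity, sum(!pb[t == 0]) / sum(t == 0))
  }

  empty <- list(matrix(0, 2, 2))
  expect_warning(me <- sensitivity_specificity(list(matrix(0.2, 2, 2)), empty),
                 "excluded")
  expect_true(is.na(me$per_layer$sensitivity))
})

test_that("roc curve matches the rank statistic and is transform-invariant", {
  t <- matrix(rbinom(400, 1, 0.4), 20, 20)
  r1 <- roc_curve(t * 1.0, t, n_thresholds = 51)
  expect_equal(r1$auc, 1)

  set.seed(12)
  p <- matrix(runif(400), 20, 20)
  r <- roc_curve(p, t, n_thresholds = 401)
  # rank-statistic definition of AUC (no ties with continuous scores)
  pos <- p[t == 1]; neg <- p[t == 0]
  auc_rank <- mean(outer(pos, neg, ">"))
  expect_equal(r$auc, auc_rank, tolerance = 0.01)

  # invariant under strictly monotone transforms of the scores
  r3 <- roc_curve(p^3, t, n_thresholds = 401)
  expect_equal(r3$auc, r$auc, tolerance = 0.01)

  expect_true(all(diff(r$points$tpr) >= 0))
  expect_true(all(diff(r$points$fpr) >= 0))

  # pooled uniform noise: AUC near one half
  set.seed(77)
  tn <- matrix(rbinom(51 * 51 * 20, 1, 0.4), 51 * 51, 20)
  pn <- matrix(runif(length(tn)), nrow(tn), ncol(tn))
  rn <- roc_curve(pn, tn, n_thresholds = 201)
  expect_lt(abs(rn$auc - 0.5), 0.05)

  expect_error(roc_curve(p, matrix(1, 20, 20)), class = "degenerate_curve")
})

test_that("roc agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  p <- runif(3000)
  t <- rbinom(3000, 1, plogis(3 * (p - 0.5)))
  ours <- roc_curve(matrix(p, 50, 60), matrix(t, 50, 60), n_thresholds = 2001)
  ref <- suppressMessages(pROC::auc(pROC::roc(t, p, quiet = TRUE)))
  expect_equal(ours$auc, as.numeric(ref), tolerance = 0.005)
})

test_that("3d reconstruction places planes and survives a round trip", {
  geom <- sensor_geometry(1000)
  zero <- replicate(4, matrix(0, 51, 51), simplify = FALSE)
  rec0 <- reconstruct_3d(zero, c(100, 350, 600, 850), geom)
  expect_equal(sum(rec0$occupancy == 1L), 0)
  expect_equal(sum(rec0$occupancy == 2L), 2 * 51 * 51)  # the two sensor slabs

  ones <- zero; ones[[2]] <- matrix(1, 51, 51)
  rec1 <- reconstruct_3d(ones, c(100, 350, 600, 850), geom)
  slab <- rec1$plane_slice[2]
  expect_equal(sum(rec1$occupancy[, , slab] == 1L), 51 * 51)

  set.seed(2)
  planes <- replicate(4, matrix(runif(2601), 51, 51), simplify = FALSE)
  rec <- reconstruct_3d(planes, c(120, 380, 640, 900), geom)
  dir <- withr::local_tempdir()
  write_reconstruction(rec, dir)
  back <- read_reconstruction(dir)
  expect_identical(back$occupancy, rec$occupancy)
  expect_equal(back$depths_um, rec$depths_um)

  expect_error(reconstruct_3d(planes, c(120, 380, 640, 1200), geom), "separation")
  expect_error(reconstruct_3d(planes[1:3], c(1, 2, 3), geom), "4 planes")
})
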