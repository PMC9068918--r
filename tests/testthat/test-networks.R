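# Finite-difference verification of the training engine, capacity checks and
# inference contracts. FD probes use MSE and jittered biases: ReLU nets with
# all-zero biases sit exactly on activation kinks, and sigmoid saturation
# flattens the BCE landscape, so those configurations would probe subgradient
# choices rather than the backward pass.

fd_check <- function(spec, loss, ylen, B = 2, eps = 1e-6, n_probe = 4) {
  layers <- cellstack3d:::build_network(spec, seed = 3)
  for (li in seq_along(layers)) for (fld in c("b", "b2", "bp"))
    if (!is.null(layers[[li]][[fld]]))
      layers[[li]][[fld]] <- layers[[li]][[fld]] +
        rnorm(length(layers[[li]][[fld]]), sd = 0.3)
  X <- matrix(runif(prod(spec$input_shape) * spec$in_channels * B), ncol = B)
  Y <- matrix(runif(ylen * B), ncol = B)
  g <- cellstack3d:::cpp_nn_grad(layers, X, Y, loss)
  worst <- 0
  for (li in seq_along(layers)) {
    flds <- intersect(c("W", "b", "W2", "b2", "Wp", "bp", "gamma", "beta"),
                      names(layers[[li]]))
    for (fld in flds) {
      ga <- switch(fld, gamma = g[[li]]$W, beta = g[[li]]$b, g[[li]][[fld]])
      if (is.null(ga) || !length(ga)) next
      for (j in sample(length(ga), min(n_probe, length(ga)))) {
        lp <- layers; lp[[li]][[fld]][j] <- lp[[li]][[fld]][j] + eps
        lm <- layers; lm[[li]][[fld]][j] <- lm[[li]][[fld]][j] - eps
        fd <- (cellstack3d:::cpp_nn_loss(lp, X, Y, loss) -
               cellstack3d:::cpp_nn_loss(lm, X, Y, loss)) / (2 * eps)
        worst <- max(worst, abs(fd - ga[j]) / max(1e-4, abs(fd) + abs(ga[j])))
      }
    }
  }
  worst
}

test_that("analytic gradients match finite differences for every layer type", {
  set.seed(10)
  expect_lt(fd_check(depth_classifier_spec(channels = c(3, 4, 5, 5), fc = 8,
                                           n_classes = 6, dropout = 0,
                                           input_shape = c(11, 11)),
                     "mse", 6), 1e-4)
  expect_lt(fd_check(encoder_decoder_spec(1, 1, channels = c(3, 4, 5),
                                          input_shape = c(9, 9)),
                     "mse", 81), 1e-4)
  expect_lt(fd_check(encoder_decoder_spec(2, 4, channels = c(3, 4, 5),
                                          input_shape = c(9, 9)),
                     "mse", 81 * 4), 1e-4)
  expect_lt(fd_check(resnet_detector_spec(2, 4, width = 3,
                                          input_shape = c(9, 9)),
                     "mse", 81 * 4), 1e-3)
})

test_that("each architecture can fit a 16-sample training set", {
  # Capacity checks. The encoder-decoder losses floor at the per-pixel noise
  # the 7x7 bottleneck cannot reproduce, so the dense tasks are checked
  # against thresholds well below the initial loss rather than zero; the
  # classifier is checked for exact memorization of the 16 labels.
  cfg <- default_config(fast = TRUE)
  d <- build_depth_dataset(16, 2, seed = 31, config = cfg)
  m <- train_depth_classifier(d$train, train_config(epochs = 250,
                                                    batch_size = 8,
                                                    seed = 1), n_members = 1)
  cls <- vapply(d$train$samples, `[[`, numeric(1), "depth_class")
  expect_equal(predict(m, d$train)$depth_class, cls)

  db <- build_deblur_dataset(16, seed = 32, config = cfg)
  md <- train_deblur_net(db, train_config(epochs = 150, batch_size = 8,
                                          learning_rate = 3e-3, seed = 1))
  expect_lt(utils::tail(md$history$loss, 1), 0.025)
  expect_lt(utils::tail(md$history$loss, 1), 0.3 * md$history$loss[1])

  ov <- build_overlap_dataset(16, dual = TRUE, seed = 33, config = cfg)
  mo <- train_detector(ov, cfg = train_config(epochs = 150, batch_size = 8,
                                              learning_rate = 3e-3, seed = 1))
  expect_lt(utils::tail(mo$history$loss, 1), 0.45)
  expect_lt(utils::tail(mo$history$loss, 1), 0.7 * mo$history$loss[1])

  # the plain residual trunk trains slowly from scratch; trainability check
  mr <- train_detector(ov, resnet_detector_spec(2, 4, width = 6),
                       cfg = train_config(epochs = 100, batch_size = 8,
                                          learning_rate = 2e-3, seed = 1))
  expect_lt(utils::tail(mr$history$loss, 1), 0.8 * mr$history$loss[1])
})

test_that("training is reproducible under a fixed seed", {
  cfg <- default_config(fast = TRUE)
  db <- build_deblur_dataset(24, seed = 35, config = cfg)
  m1 <- train_deblur_net(db, train_config(epochs = 3, batch_size = 8, seed = 4))
  m2 <- train_deblur_net(db, train_config(epochs = 3, batch_size = 8, seed = 4))
  expect_identical(m1$history, m2$history)
  expect_identical(m1$layers[[1]]$W, m2$layers[[1]]$W)
  m3 <- train_deblur_net(db, train_config(epochs = 3, batch_size = 8, seed = 5))
  expect_false(identical(m1$layers[[1]]$W, m3$layers[[1]]$W))
})

test_that("two extreme depths are near-perfectly separable", {
  cfg <- default_config(fast = TRUE)
  d <- build_depth_dataset(400, 60, seed = 36, config = cfg)
  keep <- function(ds) {
    idx <- vapply(ds$samples, function(s) s$depth_class %in% c(0, 19),
                  logical(1))
    ds$samples <- ds$samples[idx]
    ds
  }
  tr <- keep(d$train); te <- keep(d$test)
  expect_gte(length(tr$samples), 30)
  m <- train_depth_classifier(tr, train_config(epochs = 20, batch_size = 8,
                                               seed = 2), n_members = 1)
  pred <- predict(m, te)$depth_class
  truth <- vapply(te$samples, `[[`, numeric(1), "depth_class")
  expect_gte(mean(pred == truth), 0.95)
})

test_that("training loss trends downward", {
  cfg <- default_config(fast = TRUE)
  db <- build_deblur_dataset(64, seed = 37, config = cfg)
  m <- train_deblur_net(db, train_config(epochs = 8, batch_size = 8, seed = 1))
  sm <- stats::filter(m$history$loss, rep(1 / 3, 3), sides = 1)
  expect_lt(utils::tail(stats::na.omit(sm), 1), sm[3])
})

test_that("inference contracts hold", {
  cfg <- default_config(fast = TRUE)
  ov <- build_overlap_dataset(12, dual = TRUE, seed = 38, config = cfg)
  m <- train_detector(ov, cfg = tiny_train_cfg())
  pred <- predict(m, ov)
  expect_length(pred, 12)
  expect_length(pred[[1]], 4)
  for (pl in pred[[1]]) {
    expect_true(all(pl >= 0 & pl <= 1))
    expect_equal(dim(pl), c(51, 51))
  }
  # thresholding at 0.5 defines the binary labeling
  bin <- pred[[1]][[1]] > 0.5
  expect_identical(bin, (pred[[1]][[1]] > 0.5))

  # per-view normalization makes predictions invariant to offset and gain
  shifted <- ov
  shifted$samples <- lapply(shifted$samples, function(s) {
    s$view <- 3 * s$view + 120; s$view_b <- 3 * s$view_b + 120; s
  })
  pred2 <- predict(m, shifted)
  expect_equal(pred2[[1]][[1]], pred[[1]][[1]], tolerance = 1e-10)

  # channel mismatch is a configuration error
  single <- build_overlap_dataset(4, dual = FALSE, seed = 39, config = cfg)
  expect_error(train_detector(single, encoder_decoder_spec(2, 4)),
               class = "config_error")
  expect_error(predict(m, single), "features")

  dc <- build_depth_dataset(30, 4, seed = 40, config = cfg)
  mc <- train_depth_classifier(dc$train, tiny_train_cfg(), n_members = 1)
  p <- predict(mc, dc$test)
  expect_true(all(p$depth_class >= 0 & p$depth_class <= 19))
  expect_equal(p$depth_um, 50 + 100 * p$depth_class)
})

test_that("empty and degenerate training sets error", {
  expect_error(train_deblur_net(list(samples = list())), "empty")
  cfg <- default_config(fast = TRUE)
  d <- build_depth_dataset(10, 2, seed = 41, config = cfg)
  one <- d$train
  one$samples <- Filter(function(s) s$depth_class == one$samples[[1]]$depth_class,
                        one$samples)
  expect_error(train_depth_classifier(one), "2 depth classes")
})
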