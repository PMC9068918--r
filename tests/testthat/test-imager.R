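test_that("psf kernels are normalized, odd-sided and depth-monotone", {
  m0 <- psf_model(sigma0_px = 0, slope_px_per_mm = 4)
  expect_identical(psf_kernel(m0, 0), matrix(1, 1, 1))

  m <- psf_model(sigma0_px = 0.5, slope_px_per_mm = 4)
  widths <- vapply(seq(0, 2000, by = 100), function(d) {
    k <- psf_kernel(m, d)
    expect_lt(abs(sum(k) - 1), 1e-9)
    expect_true(all(k >= 0))
    expect_equal(nrow(k) %% 2, 1)
    nrow(k)
  }, numeric(1))
  expect_true(all(diff(widths) >= 0))

  md <- psf_model("disc", sigma0_px = 2, slope_px_per_mm = 4)
  kd <- psf_kernel(md, 500)
  expect_lt(abs(sum(kd) - 1), 1e-9)
  expect_identical(kd, kd[rev(seq_len(nrow(kd))), rev(seq_len(ncol(kd)))])

  expect_error(psf_kernel(m, -5), "non-negative")
  expect_error(psf_model("measured"), class = "config_error")
})

test_that("gaussian kernel values match direct pointwise evaluation", {
  m <- psf_model(sigma0_px = 1, slope_px_per_mm = 4)
  k <- psf_kernel(m, 500)          # sigma = 1 + 4 * 0.5 = 3 px
  sigma <- 3
  r <- (nrow(k) - 1) / 2
  expect_equal(r, ceiling(3 * sigma))
  ref <- outer(-r:r, -r:r, function(a, b) exp(-(a^2 + b^2) / (2 * sigma^2)))
  ref <- ref / sum(ref)
  expect_equal(k, ref, tolerance = 1e-12)
})

test_that("measured kernels use nearest-depth lookup", {
  bank <- list("100" = matrix(c(0, 1, 0, 1, 4, 1, 0, 1, 0) / 8, 3, 3),
               "600" = matrix(1 / 9, 3, 3))
  m <- psf_model("measured", kernel_bank = bank)
  expect_equal(psf_kernel(m, 120), bank[["100"]])
  expect_equal(psf_kernel(m, 580), bank[["600"]])

  # calibration banks round-trip through psf_<depth>.tif files
  dir <- withr::local_tempdir()
  tiff::writeTIFF(bank[["100"]], file.path(dir, "psf_100.tif"),
                  bits.per.sample = 32)
  tiff::writeTIFF(bank[["600"]], file.path(dir, "psf_600.tif"),
                  bits.per.sample = 32)
  loaded <- read_kernel_bank(dir)
  expect_equal(names(loaded), c("100", "600"))
  m2 <- psf_model("measured", kernel_bank = loaded)
  expect_equal(psf_kernel(m2, 90), bank[["100"]], tolerance = 1e-6)
  expect_error(read_kernel_bank(withr::local_tempdir()),
               class = "config_error")
})

test_that("blur is a zero-padded convolution with the depth kernel", {
  model <- psf_model()
  expect_equal(blur(matrix(0, 51, 51), 400, model), matrix(0, 51, 51))

  imp <- matrix(0, 51, 51); imp[26, 26] <- 1
  k <- psf_kernel(model, 600)
  r <- (nrow(k) - 1) / 2
  out <- blur(imp, 600, model)
  expect_equal(out[26 + (-r:r), 26 + (-r:r)], k, tolerance = 1e-10)

  set.seed(11)
  x <- matrix(runif(51 * 51, 0, 100), 51, 51)
  direct <- brute_convolve(x, psf_kernel(model, 700))
  expect_lt(max(abs(blur(x, 700, model) - direct)) / max(abs(direct)), 1e-6)
})

test_that("blur conserves flux for interior-supported images", {
  model <- psf_model()
  x <- matrix(0, 51, 51)
  set.seed(4)
  x[10:42, 10:42] <- runif(33 * 33, 0, 50)
  for (d in c(0, 150, 350)) {   # kernel radius <= the 9-px empty border
    y <- blur(x, d, model)
    expect_lt(abs(sum(y) - sum(x)) / sum(x), 1e-6)
  }
})

test_that("image contrast degrades monotonically with depth", {
  img <- generate_cell_image(seed = 21)
  model <- psf_model()
  s <- vapply(seq(0, 2000, by = 200),
              function(d) stats::sd(blur(img, d, model)), numeric(1))
  expect_true(all(diff(s) <= 1e-9))
})

test_that("stack composition is linear and respects the dual geometry", {
  model <- psf_model()
  geom <- sensor_geometry(1000)
  imgs <- lapply(1:4, function(k) generate_cell_image(seed = 30 + k))
  depths <- c(100, 350, 600, 850)
  stack <- layer_stack(imgs, depths)

  one <- layer_stack(imgs[1], depths[1])
  expect_equal(compose_stack(one, model, "A", geom)$image,
               blur(imgs[[1]], depths[1], model))

  # a layer at 300 um seen from B across 1 mm is blurred as if at 700 um
  l300 <- layer_stack(imgs[2], 300)
  expect_equal(compose_stack(l300, model, "B", geom)$image,
               blur(imgs[[2]], 700, model))

  full <- compose_stack(stack, model, "A", geom)$image
  parts <- Reduce(`+`, lapply(1:4, function(k)
    compose_stack(layer_stack(imgs[k], depths[k]), model, "A", geom)$image))
  expect_equal(full, parts)

  # sensor A view of the stack equals sensor B view of the mirrored stack
  mirror <- layer_stack(rev(imgs), sort(1000 - depths))
  expect_equal(full, compose_stack(mirror, model, "B", geom)$image)

  expect_error(compose_stack(layer_stack(imgs[1], 1200), model, "A", geom),
               "separation")
  expect_error(layer_stack(imgs[1:2], c(500, 200)), "increasing")
})

test_that("overlap subtraction clears exactly the shared pixels", {
  i1 <- generate_cell_image(seed = 51)
  i2 <- generate_cell_image(seed = 52)
  ov <- i1$mask$mask == 1 & i2$mask$mask == 1
  expect_gt(sum(ov), 0)   # defaults overlap heavily
  out <- subtract_overlap(i1, i2, seed = 3)
  expect_no_mask_overlap(out[[1]]$mask$mask, out[[2]]$mask$mask)
  expect_identical(out[[1]]$intensity[!ov], i1$intensity[!ov])
  expect_identical(out[[2]]$intensity[!ov], i2$intensity[!ov])
  expect_true(all(out[[1]]$mask$mask[ov] == 0))

  # disjoint masks pass through untouched
  a <- i1; b <- i2
  b$mask$mask <- 1L - a$mask$mask
  out2 <- subtract_overlap(a, b)
  expect_identical(out2[[1]]$intensity, a$intensity)
  expect_identical(out2[[2]]$intensity, b$intensity)

  # identical masks are fully cleared
  out3 <- subtract_overlap(i1, i1, seed = 5)
  expect_equal(sum(out3[[1]]$mask$mask), 0)
  expect_equal(sum(out3[[2]]$mask$mask), 0)
})
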