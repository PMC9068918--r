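cfg_fast <- default_config(fast = TRUE)

test_that("depth dataset uses the 20-bin grid with balanced classes", {
  d <- build_depth_dataset(1500, 60, seed = 3, config = cfg_fast)
  expect_length(d$test$samples, 60)
  for (s in d$test$samples) {
    expect_true(s$depth_um %in% seq(50, 1950, by = 100))
    expect_equal(s$depth_class, (s$depth_um - 50) / 100)
    expect_true(s$depth_class >= 0 && s$depth_class <= 19)
  }
  freq <- table(factor(vapply(d$train$samples, `[[`, numeric(1), "depth_class"),
                       levels = 0:19)) / 1500
  expect_true(all(abs(freq - 0.05) < 0.02))
  validate_dataset(d$train)

  # disjoint seed streams: train and test draws differ
  expect_false(identical(d$train$samples[[1]]$view, d$test$samples[[1]]$view))
})

test_that("deblur pairs blur their own target at a uniform depth", {
  d <- build_deblur_dataset(200, seed = 4, config = cfg_fast)
  depths <- vapply(d$samples, `[[`, numeric(1), "depth_um")
  expect_gte(min(depths), 0)
  expect_lte(max(depths), 1000)
  model <- cellstack3d:::psf_from_config(cfg_fast)
  s <- d$samples[[7]]
  expect_equal(s$view, blur(s$target, s$depth_um, model))
  validate_dataset(d)

  # a zero-width PSF at depth zero leaves the target untouched
  cfg0 <- cfg_fast; cfg0$optics$sigma0_px <- 0
  d0 <- build_deblur_dataset(5, seed = 4, config = cfg0)
  i0 <- which.min(vapply(d0$samples, `[[`, numeric(1), "depth_um"))
  s0 <- d0$samples[[i0]]
  expect_lt(max(abs(s0$view - blur(s0$target, s0$depth_um,
                                   cellstack3d:::psf_from_config(cfg0)))), 1e-12)
})

test_that("classical wiener inversion recovers well-conditioned targets", {
  # Classical inversion is defined where the halo is contained in the frame
  # and the Gaussian MTF stays numerically invertible (shallow depths at the
  # default optics); there the forward model must be consistent with it.
  model <- cellstack3d:::psf_from_config(cfg_fast)
  for (case in 1:5) {
    depth <- c(30, 80, 120, 160, 200)[case]
    img <- generate_cell_image(seed = 500 + case)
    tgt <- img$intensity
    tgt[c(1:8, 44:51), ] <- 0
    tgt[, c(1:8, 44:51)] <- 0
    blurred <- blur(tgt, depth, model)
    rec <- wiener_deblur(blurred, psf_kernel(model, depth), eps = 1e-8)
    relerr <- sqrt(sum((rec - tgt)^2) / sum(tgt^2))
    expect_lt(relerr, 0.1)
  }
})

test_that("two-layer samples respect the 500 um gap and disjoint labels", {
  d <- build_nonoverlap_dataset(100, seed = 5, config = cfg_fast)
  for (s in d$samples) {
    expect_gte(diff(s$depths_um), 500)
    expect_true(all(s$depths_um >= 0 & s$depths_um <= 1000))
    expect_no_mask_overlap(s$images[[1]]$mask$mask, s$images[[2]]$mask$mask)
    labs <- setdiff(unique(as.numeric(s$depth_map)), 0)
    expect_lte(length(labs), 2)
    if (length(labs) == 2) expect_gte(abs(diff(labs)), 0.5)
  }
  validate_dataset(d)
})

test_that("four-layer samples sit one per bin with 200 um gaps", {
  d <- build_overlap_dataset(100, dual = TRUE, seed = 6, config = cfg_fast)
  for (s in d$samples) {
    expect_true(all(diff(s$depths_um) >= 200))
    expect_true(all(s$depths_um >= 0 & s$depths_um <= 1000))
    expect_true(all(floor(s$depths_um / 250) == 0:3))
    for (k in 1:4)
      expect_identical(s$label_planes[[k]], s$images[[k]]$mask$mask)
    expect_false(is.null(s$view_b))
  }
  validate_dataset(d)
})

test_that("dual views obey the mirror symmetry of the geometry", {
  d <- build_overlap_dataset(3, dual = TRUE, seed = 8, config = cfg_fast)
  model <- cellstack3d:::psf_from_config(cfg_fast)
  geom <- sensor_geometry(cfg_fast$optics$separation_um)
  for (s in d$samples) {
    mirrored <- layer_stack(rev(s$images), sort(1000 - s$depths_um))
    expect_equal(s$view_b, compose_stack(mirrored, model, "A", geom)$image,
                 tolerance = 1e-10)
  }
})

test_that("moving-cluster sequences move one cluster without changing totals", {
  d <- build_moving_cluster_set(5, seed = 9, config = cfg_fast)
  for (q in d$samples) {
    expect_length(q$steps, 4)
    expect_equal(q$cluster_layer_at_step, 0:3)
    counts <- vapply(q$steps, function(st)
      sum(vapply(st$label_planes, sum, numeric(1))), numeric(1))
    expect_equal(length(unique(counts)), 1L)
    cl <- q$cluster_mask == 1
    expect_gt(sum(cl), 0)
    for (t in 1:4) {
      for (k in 1:4) {
        plane <- q$steps[[t]]$label_planes[[k]]
        if (k == t) {
          expect_true(all(plane[cl] == 1))
        } else {
          expect_true(all(plane[cl] == 0))
        }
        # background foci identical across steps outside the cluster
        expect_identical(plane[!cl], q$steps[[1]]$label_planes[[k]][!cl])
      }
    }
  }
  validate_dataset(d)
})

test_that("datasets are reproducible from (config, seed)", {
  a <- build_overlap_dataset(3, dual = TRUE, seed = 42, config = cfg_fast)
  b <- build_overlap_dataset(3, dual = TRUE, seed = 42, config = cfg_fast)
  expect_identical(a$samples[[2]]$view, b$samples[[2]]$view)
  expect_identical(a$manifest, b$manifest)
  c2 <- build_overlap_dataset(3, dual = TRUE, seed = 43, config = cfg_fast)
  expect_false(identical(a$samples[[2]]$view, c2$samples[[2]]$view))
})

test_that("dataset directories round-trip and validate from disk", {
  d <- build_nonoverlap_dataset(4, seed = 12, config = cfg_fast)
  dir <- withr::local_tempdir()
  write_dataset(d, dir)
  back <- read_dataset(dir)
  expect_equal(back$samples[[2]]$view, d$samples[[2]]$view, tolerance = 1e-6)
  expect_identical(back$samples[[2]]$label_planes[[1]],
                   d$samples[[2]]$images[[1]]$mask$mask)

  v <- validate_manifest(dir)
  expect_true(v$pass)

  # inject a too-small gap into the manifest
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  man$depths_um[2] <- "100;250"
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  v2 <- validate_manifest(dir)
  expect_false(v2$pass)
  expect_match(paste(v2$violations, collapse = " "), "sample 2")

  # truncate an image file
  utils::write.csv(utils::read.csv(file.path(dir, "manifest.csv")) |>
                     transform(depths_um = sub("100;250", "100;700", depths_um)),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  writeLines("not a tiff", file.path(dir, "sample_00003_view.tif"))
  v3 <- validate_manifest(dir)
  expect_false(v3$pass)
  expect_match(paste(v3$violations, collapse = " "), "unreadable")
})
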