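#' Build the single-layer depth-classification dataset
#'
#' Each sample is a fresh phantom blurred at one of 20 depths, 50 to 1950
#' micrometers in 100 micrometer steps (class `k` sits at `50 + 100 k`).
#' Train and test draws use disjoint seed streams.
#'
#' @param n_train,n_test sample counts (>= 1).
#' @param seed root seed; per-sample child seeds are `seed + index`.
#' @param config experiment configuration (see [default_config()]).
#' @return List with `train` and `test` datasets; each has `samples` (lists
#'   with `view`, `depth_um`, `depth_class`) and a tibble `manifest`.
#' @export
build_depth_dataset <- function(n_train, n_test, seed = 1,
                                config = default_config()) {
  stopifnot(n_train >= 1, n_test >= 1)
  model <- psf_from_config(config)
  make <- function(n, stream) {
    classes <- with_seed(child_seed(stream, 0),
                         sample.int(20, n, replace = TRUE) - 1L)
    samples <- lapply(seq_len(n), function(i) {
      depth <- 50 + 100 * classes[i]
      img <- generate_cell_image(seed = child_seed(stream, i), config = config)
      list(view = blur(img, depth, model), image = img,
           depth_um = depth, depth_class = classes[i],
           seed = child_seed(stream, i))
    })
    new_dataset(samples, "depth", config, stream,
      manifest = tibble::tibble(
        sample_id = seq_len(n), seed = child_seed(stream, seq_len(n)),
        depth_um = 50 + 100 * classes, depth_class = classes))
  }
  list(train = make(n_train, seed),
       test = make(n_test, child_seed(seed, 500000L)))
}

#' Build the deblurring dataset
#'
#' Pairs of an unblurred phantom and its acquisition blurred at a continuous
#' uniform depth in \[0, 1000\] micrometers.
#'
#' @param n number of pairs.
#' @inheritParams build_depth_dataset
#' @export
build_deblur_dataset <- function(n, seed = 1, config = default_config()) {
  stopifnot(n >= 1)
  model <- psf_from_config(config)
  depths <- with_seed(child_seed(seed, 0), runif(n, 0, 1000))
  samples <- lapply(seq_len(n), function(i) {
    img <- generate_cell_image(seed = child_seed(seed, i), config = config)
    list(view = blur(img, depths[i], model), target = img$intensity,
         image = img, depth_um = depths[i], seed = child_seed(seed, i))
  })
  new_dataset(samples, "deblur", config, seed,
    manifest = tibble::tibble(sample_id = seq_len(n),
                              seed = child_seed(seed, seq_len(n)),
                              depth_um = depths))
}

#' Build the non-overlapping two-layer dataset
#'
#' Two phantoms at depths in \[0, 1000\] micrometers at least 500 apart;
#' overlapping cell regions are subtracted ([subtract_overlap()]) before
#' blurring and summing, so every cell pixel belongs to exactly one layer.
#' The label is a per-pixel depth map: pixels of the layer at depth d carry
#' `d / 1000`, background 0.
#'
#' @inheritParams build_deblur_dataset
#' @export
build_nonoverlap_dataset <- function(n, seed = 1, config = default_config()) {
  stopifnot(n >= 1)
  model <- psf_from_config(config)
  gap <- config$dataset$min_gap_two_layer_um
  samples <- lapply(seq_len(n), function(i) {
    s <- child_seed(seed, i)
    depths <- with_seed(child_seed(s, 0), {
      repeat {
        d <- sort(runif(2, 0, 1000))
        if (diff(d) >= gap) break
      }
      d
    })
    imgs <- lapply(1:2, function(k)
      generate_cell_image(seed = child_seed(s, k), config = config))
    imgs <- subtract_overlap(imgs[[1]], imgs[[2]], seed = child_seed(s, 3))
    view <- blur(imgs[[1]], depths[1], model) + blur(imgs[[2]], depths[2], model)
    dm <- imgs[[1]]$mask$mask * (depths[1] / 1000) +
          imgs[[2]]$mask$mask * (depths[2] / 1000)
    list(view = view, depth_map = dm, images = imgs, depths_um = depths,
         seed = s)
  })
  new_dataset(samples, "nonoverlap", config, seed,
    manifest = tibble::tibble(
      sample_id = seq_along(samples),
      seed = vapply(samples, `[[`, numeric(1), "seed"),
      depth1_um = vapply(samples, function(s) s$depths_um[1], numeric(1)),
      depth2_um = vapply(samples, function(s) s$depths_um[2], numeric(1))))
}

# One depth per 250 um bin with adjacent gaps >= min_gap; rejection-sampled.
draw_four_depths <- function(seed, bin_um = 250, min_gap_um = 200,
                             max_attempts = 1000) {
  with_seed(seed, {
    for (a in seq_len(max_attempts)) {
      d <- sort(bin_um * (0:3) + runif(4, 0, bin_um))
      if (all(diff(d) >= min_gap_um)) return(d)
    }
    abort("could not satisfy the four-layer depth constraints")
  })
}

#' Build the overlapping four-layer dataset
#'
#' Four independent phantoms at depths in \[0, 1000\] micrometers, one per
#' 250 micrometer bin with adjacent layers at least 200 micrometers apart.
#' Overlaps are NOT subtracted. Labels are the four binary layer masks ordered
#' by distance from sensor A. With `dual = TRUE` both opposing sensor views
#' are composed (`view` for sensor A, `view_b` for sensor B).
#'
#' @param dual compose both sensors of the opposing geometry?
#' @inheritParams build_deblur_dataset
#' @export
build_overlap_dataset <- function(n, dual = TRUE, seed = 1,
                                  config = default_config()) {
  stopifnot(n >= 1)
  model <- psf_from_config(config)
  geom <- sensor_geometry(config$optics$separation_um)
  ds <- config$dataset
  samples <- lapply(seq_len(n), function(i) {
    s <- child_seed(seed, i)
    depths <- draw_four_depths(child_seed(s, 0), ds$depth_bin_um,
                               ds$min_gap_four_layer_um)
    imgs <- lapply(1:4, function(k)
      generate_cell_image(seed = child_seed(s, k), config = config))
    stack <- layer_stack(imgs, depths)
    out <- list(view = compose_stack(stack, model, "A", geom)$image,
                label_planes = lapply(imgs, function(im) im$mask$mask),
                images = imgs, depths_um = depths, seed = s)
    if (dual) out$view_b <- compose_stack(stack, model, "B", geom)$image
    out
  })
  new_dataset(samples, if (dual) "overlap_dual" else "overlap_single",
              config, seed,
    manifest = tibble::tibble(
      sample_id = seq_along(samples),
      seed = vapply(samples, `[[`, numeric(1), "seed"),
      depth1_um = vapply(samples, function(s) s$depths_um[1], numeric(1)),
      depth2_um = vapply(samples, function(s) s$depths_um[2], numeric(1)),
      depth3_um = vapply(samples, function(s) s$depths_um[3], numeric(1)),
      depth4_um = vapply(samples, function(s) s$depths_um[4], numeric(1))))
}

#' Build the moving-cluster trajectory set
#'
#' Each sequence holds a fixed four-layer background scene (generated at a
#' sparser mask threshold so foci do not tile the frame) plus one connected
#' cell cluster that hops from layer 1 to layer 4 across the four steps,
#' emulating a cluster migrating from sensor A towards sensor B. The cluster's
#' lateral position is fixed and chosen empty in all four background masks, so
#' the total cell count across planes is constant along the sequence.
#'
#' @param n_sequences number of trajectories.
#' @inheritParams build_deblur_dataset
#' @return A dataset whose samples are sequences: each has `steps` (4
#'   four-layer samples), `cluster_mask` and `cluster_layer_at_step = 0:3`.
#' @export
build_moving_cluster_set <- function(n_sequences, seed = 1,
                                     config = default_config()) {
  stopifnot(n_sequences >= 1)
  model <- psf_from_config(config)
  geom <- sensor_geometry(config$optics$separation_um)
  ds <- config$dataset
  cfg2 <- config
  cfg2$phantom$threshold <- config$phantom$dynamics_threshold
  sequences <- lapply(seq_len(n_sequences), function(i) {
    s <- child_seed(seed, i * 13L)
    for (attempt in 1:50) {
      sa <- child_seed(s, attempt * 101L)
      depths <- draw_four_depths(child_seed(sa, 0), ds$depth_bin_um,
                                 ds$min_gap_four_layer_um)
      imgs <- lapply(1:4, function(k)
        generate_cell_image(seed = child_seed(sa, k), config = cfg2))
      cl <- make_cluster(child_seed(sa, 5), cfg2,
                         lapply(imgs, function(im) im$mask$mask))
      if (!is.null(cl)) break
      cl <- NULL
    }
    if (is.null(cl)) abort("could not place a disjoint cluster")
    steps <- lapply(0:3, function(t) {
      imgs_t <- imgs
      host <- imgs_t[[t + 1]]
      sig <- with_seed(child_seed(sa, 6),
        pmax(rnorm(sum(cl$mask), host$stats$signal_mean,
                   host$stats$signal_std), 0))
      host$intensity[cl$mask == 1] <- sig
      host$mask$mask <- pmax(host$mask$mask, cl$mask)
      imgs_t[[t + 1]] <- host
      stack <- layer_stack(imgs_t, depths)
      list(view = compose_stack(stack, model, "A", geom)$image,
           view_b = compose_stack(stack, model, "B", geom)$image,
           label_planes = lapply(imgs_t, function(im) im$mask$mask),
           images = imgs_t, depths_um = depths, seed = sa)
    })
    list(steps = steps, cluster_mask = cl$mask, cluster_layer_at_step = 0:3,
         depths_um = depths, seed = sa)
  })
  new_dataset(sequences, "dynamics", config, seed,
    manifest = tibble::tibble(
      sequence_id = seq_len(n_sequences),
      seed = vapply(sequences, `[[`, numeric(1), "seed"),
      n_steps = 4L,
      cluster_px = vapply(sequences, function(q) sum(q$cluster_mask),
                          numeric(1))))
}

# A connected Perlin focus, shifted to a lateral site empty in all layer
# masks; NULL if no disjoint placement is found.
make_cluster <- function(seed, config, bg_masks, max_shifts = 200) {
  p <- config$phantom
  f <- generate_perlin_field(p$shape, grid_period = 6, octaves = 1,
                             persistence = p$persistence,
                             seed = child_seed(seed, 0))
  m <- (f$values > 0.78) * 1
  lab <- EBImage::bwlabel(m)
  sizes <- tabulate(lab[lab > 0])
  if (!length(sizes)) return(NULL)
  comp <- which.min(abs(sizes - 40))
  base <- (lab == comp) * 1L
  h <- nrow(base); w <- ncol(base)
  any_bg <- Reduce(`+`, bg_masks) > 0
  shifts <- with_seed(child_seed(seed, 1),
                      cbind(sample(-h:h, max_shifts, TRUE),
                            sample(-w:w, max_shifts, TRUE)))
  for (k in seq_len(max_shifts)) {
    sh <- shift_mask(base, shifts[k, 1], shifts[k, 2])
    if (sum(sh) == sum(base) && !any(sh == 1 & any_bg)) return(list(mask = sh))
  }
  NULL
}

shift_mask <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0L, h, w)
  on <- which(m == 1, arr.ind = TRUE)
  if (!nrow(on)) return(out)
  y2 <- on[, 1] + dy; x2 <- on[, 2] + dx
  ok <- y2 >= 1 & y2 <= h & x2 >= 1 & x2 <= w
  out[cbind(y2[ok], x2[ok])] <- 1L
  out
}

new_dataset <- function(samples, task, config, seed, manifest) {
  manifest$split <- NA_character_
  structure(list(samples = samples, task = task, manifest = manifest,
                 config = config, config_hash = config_hash(config),
                 seed = seed),
            class = "cs3d_dataset")
}

#' @export
print.cs3d_dataset <- function(x, ...) {
  cat(sprintf("<cs3d_dataset task=%s | %d samples | config %s>\n",
              x$task, length(x$samples), substr(x$config_hash, 1, 8)))
  invisible(x)
}

#' Re-check dataset invariants
#'
#' Validates every sample of an in-memory dataset against its task's
#' constraints: depth ranges and class binning (depth task), minimum depth
#' gaps (two- and four-layer tasks), mask disjointness after overlap
#' subtraction, label-plane bookkeeping, and constant cell count along
#' moving-cluster sequences.
#'
#' @param dataset a `cs3d_dataset`.
#' @return Invisibly `TRUE`; aborts with the offending sample otherwise.
#' @export
validate_dataset <- function(dataset) {
  fails <- character()
  add <- function(msg) fails <<- c(fails, msg)
  for (i in seq_along(dataset$samples)) {
    s <- dataset$samples[[i]]
    switch(dataset$task,
      depth = {
        if (!s$depth_um %in% seq(50, 1950, 100))
          add(sprintf("sample %d: depth %g off-grid", i, s$depth_um))
        if (s$depth_class != (s$depth_um - 50) / 100)
          add(sprintf("sample %d: class/depth mismatch", i))
      },
      deblur = {
        if (s$depth_um < 0 || s$depth_um > 1000)
          add(sprintf("sample %d: depth %g out of range", i, s$depth_um))
      },
      nonoverlap = {
        if (diff(s$depths_um) < dataset$config$dataset$min_gap_two_layer_um)
          add(sprintf("sample %d: two-layer gap %.0f um too small", i,
                      diff(s$depths_um)))
        if (any(s$images[[1]]$mask$mask & s$images[[2]]$mask$mask))
          add(sprintf("sample %d: masks not disjoint", i))
      },
      dynamics = {
        counts <- vapply(s$steps, function(st)
          sum(vapply(st$label_planes, sum, numeric(1))), numeric(1))
        if (length(unique(counts)) != 1)
          add(sprintf("sequence %d: cell count varies across steps", i))
      },
      { # overlap_single / overlap_dual
        if (any(diff(s$depths_um) < dataset$config$dataset$min_gap_four_layer_um))
          add(sprintf("sample %d: four-layer gap too small", i))
        if (min(s$depths_um) < 0 || max(s$depths_um) > 1000)
          add(sprintf("sample %d: depth out of [0, 1000]", i))
        for (k in 1:4)
          if (!identical(s$label_planes[[k]], s$images[[k]]$mask$mask))
            add(sprintf("sample %d: label plane %d mismatch", i, k))
      })
  }
  if (length(fails))
    abort(c("dataset validation failed", utils::head(fails, 10)),
          class = "validation_error")
  invisible(TRUE)
}
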