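#' Depth-dependent point-spread-function model
#'
#' The lensless imager has no focusing optics, so its PSF widens with the
#' distance between the emitting layer and the sensor surface. The default
#' model is an isotropic Gaussian whose width grows linearly with depth,
#' `sigma(z) = sigma0_px + slope_px_per_mm * z / 1000` (z in micrometers); a
#' `disc` kind (uniform pillbox of radius sigma(z)) and a `measured` kind
#' (nearest-depth lookup in a calibration kernel bank) are also available.
#' Every kernel is non-negative and normalized to unit sum, so blurring
#' conserves flux and depth attenuation arises only from spreading.
#'
#' @param kind one of `"gaussian"`, `"disc"`, `"measured"`.
#' @param sigma0_px blur width at depth 0, pixels (>= 0).
#' @param slope_px_per_mm blur growth per millimeter of depth, pixels (>= 0).
#' @param truncation_radius_sigmas kernel half-size in units of sigma.
#' @param kernel_bank for `kind = "measured"`: named list mapping depth in
#'   micrometers (names coercible to numeric) to kernel matrices.
#' @return A `psf_model` object.
#' @export
psf_model <- function(kind = c("gaussian", "disc", "measured"),
                      sigma0_px = 0.5, slope_px_per_mm = 4,
                      truncation_radius_sigmas = 3, kernel_bank = NULL) {
  kind <- match.arg(kind)
  if (sigma0_px < 0 || slope_px_per_mm < 0)
    abort("PSF width parameters must be non-negative")
  if (kind == "measured" && (is.null(kernel_bank) || !length(kernel_bank)))
    abort("measured PSF requires a non-empty `kernel_bank`", class = "config_error")
  structure(list(kind = kind, sigma0_px = sigma0_px,
                 slope_px_per_mm = slope_px_per_mm,
                 truncation_radius_sigmas = truncation_radius_sigmas,
                 kernel_bank = kernel_bank),
            class = "psf_model")
}

#' Load a measured PSF kernel bank from TIFF calibration files
#'
#' Reads every `psf_<depth>.tif` in a directory (depth in micrometers encoded
#' in the file name) into the named-list form accepted by
#' `psf_model(kind = "measured")`. Kernels are clipped at zero and normalized
#' to unit sum on lookup.
#'
#' @param dir directory of single-page TIFF kernels named `psf_<depth>.tif`.
#' @return Named list of kernel matrices, names are depths in micrometers.
#' @export
read_kernel_bank <- function(dir) {
  files <- list.files(dir, pattern = "^psf_[0-9]+\\.tif$", full.names = TRUE)
  if (!length(files)) abort("no psf_<depth>.tif files found",
                            class = "config_error")
  depths <- sub("^psf_([0-9]+)\\.tif$", "\\1", basename(files))
  bank <- lapply(files, function(f) {
    k <- tiff::readTIFF(f)
    if (length(dim(k)) > 2) k <- k[, , 1]
    k
  })
  names(bank) <- depths
  bank[order(as.numeric(depths))]
}

#' Evaluate the PSF kernel at a depth
#'
#' @param model a [psf_model()].
#' @param depth_um depth in micrometers (>= 0).
#' @return An odd-sided, unit-sum, non-negative kernel matrix.
#' @examples
#' k <- psf_kernel(psf_model(sigma0_px = 1, slope_px_per_mm = 4), 500)
#' sum(k)
#' @export
psf_kernel <- function(model, depth_um) {
  if (depth_um < 0) abort("`depth_um` must be non-negative")
  if (model$kind == "measured") {
    depths <- as.numeric(names(model$kernel_bank))
    k <- model$kernel_bank[[which.min(abs(depths - depth_um))]]
    k[k < 0] <- 0
    return(k / sum(k))
  }
  sigma <- model$sigma0_px + model$slope_px_per_mm * depth_um / 1000
  if (sigma < 1e-9) return(matrix(1, 1, 1))
  r <- max(1L, ceiling(model$truncation_radius_sigmas * sigma))
  off <- (-r):r
  if (model$kind == "gaussian") {
    g <- exp(-off^2 / (2 * sigma^2))
    k <- outer(g, g)
  } else { # disc: uniform pillbox of radius sigma (area-sampled at pixel centers)
    d2 <- outer(off^2, off^2, "+")
    k <- (d2 <= sigma^2) * 1
    if (sum(k) == 0) k[r + 1, r + 1] <- 1
  }
  k / sum(k)
}

#' Blur an image with the depth-dependent PSF
#'
#' 2D convolution of the intensity grid with the PSF kernel at the given
#' depth. The frame is zero-padded: tissue outside the field of view is dark.
#'
#' @param image a `cell_image`, or a numeric matrix.
#' @param depth_um layer depth in micrometers.
#' @param model a [psf_model()].
#' @return A numeric matrix of the same shape (a sensor-plane view).
#' @export
blur <- function(image, depth_um, model) {
  x <- if (inherits(image, "cell_image")) image$intensity else image
  k <- psf_kernel(model, depth_um)
  if (length(k) == 1) return(x * k[1])
  if (nrow(k) > nrow(x) || ncol(k) > ncol(x)) {
    # pad the frame so the kernel fits, filter, crop back
    pr <- max(0, ceiling((nrow(k) - nrow(x)) / 2))
    pc <- max(0, ceiling((ncol(k) - ncol(x)) / 2))
    xp <- matrix(0, nrow(x) + 2 * pr, ncol(x) + 2 * pc)
    xp[pr + seq_len(nrow(x)), pc + seq_len(ncol(x))] <- x
    y <- unclass(EBImage::filter2(xp, k, boundary = 0))
    return(y[pr + seq_len(nrow(x)), pc + seq_len(ncol(x))])
  }
  unclass(EBImage::filter2(x, k, boundary = 0))
}

#' Ordered stack of cell layers
#'
#' Depths are measured from sensor A's surface, increasing away from it, and
#' must be strictly increasing.
#'
#' @param images list of `cell_image` objects.
#' @param depths_um numeric vector of layer depths, micrometers.
#' @return A `layer_stack`.
#' @export
layer_stack <- function(images, depths_um) {
  if (length(images) != length(depths_um)) abort("one depth per layer required")
  if (is.unsorted(depths_um, strictly = TRUE))
    abort("layer depths must be strictly increasing")
  if (any(depths_um < 0)) abort("depths must be non-negative")
  structure(list(images = images, depths_um = depths_um), class = "layer_stack")
}

#' Opposing dual-sensor geometry
#'
#' Two sensors face each other across the specimen: A at depth 0, B at
#' `separation_um`. A layer at depth z is seen by B at effective depth
#' `separation_um - z`, so the effective depths always sum to the separation.
#'
#' @param separation_um sensor separation, micrometers (default 1000).
#' @export
sensor_geometry <- function(separation_um = 1000) {
  structure(list(separation_um = separation_um), class = "sensor_geometry")
}

#' Compose a multi-layer acquisition for one sensor
#'
#' Each layer is blurred at its effective depth for the chosen sensor and the
#' blurred layers are summed into the single raw image the sensor records.
#'
#' @param stack a [layer_stack()].
#' @param model a [psf_model()].
#' @param sensor `"A"` (at depth 0) or `"B"` (at the far side).
#' @param geometry a [sensor_geometry()].
#' @return A `sensor_view`: list with `image` matrix and `sensor_id`.
#' @export
compose_stack <- function(stack, model, sensor = c("A", "B"),
                          geometry = sensor_geometry()) {
  sensor <- match.arg(sensor)
  if (!length(stack$images)) abort("stack must be non-empty")
  if (max(stack$depths_um) > geometry$separation_um)
    abort("layer deeper than the sensor separation")
  eff <- effective_depths(stack$depths_um, sensor, geometry)
  img <- Reduce(`+`, Map(function(im, d) blur(im, d, model), stack$images, eff))
  structure(list(image = img, sensor_id = sensor), class = "sensor_view")
}

effective_depths <- function(depths_um, sensor, geometry) {
  if (sensor == "A") depths_um else geometry$separation_um - depths_um
}

#' Remove overlapping cell regions from a pair of layers
#'
#' For the non-overlapping two-layer task, pixels where both layer masks are
#' set are reset in both images to freshly drawn background intensity and
#' cleared from both masks, so the returned masks are disjoint. Pixels outside
#' the overlap are untouched.
#'
#' @param img1,img2 `cell_image` objects of the same shape.
#' @param seed integer seed for the replacement background draws.
#' @return A list of the two modified `cell_image`s.
#' @export
subtract_overlap <- function(img1, img2, seed = 1) {
  if (!all(dim(img1$intensity) == dim(img2$intensity)))
    abort("images must share a shape")
  ov <- img1$mask$mask == 1 & img2$mask$mask == 1
  n <- sum(ov)
  if (n > 0) {
    repl <- with_seed(seed, list(
      a = pmax(rnorm(n, img1$stats$background_mean, img1$stats$background_std), 0),
      b = pmax(rnorm(n, img2$stats$background_mean, img2$stats$background_std), 0)))
    img1$intensity[ov] <- repl$a
    img2$intensity[ov] <- repl$b
    img1$mask$mask[ov] <- 0L
    img2$mask$mask[ov] <- 0L
  }
  list(img1, img2)
}

# Per-view min-max normalization to [0,1]; what the dense-prediction
# networks see.
normalize_view <- function(x) {
  r <- range(x)
  if (diff(r) <= 0) return(x * 0)
  (x - r[1]) / diff(r)
}

# Per-view mean-relative contrast; the depth classifier's input convention.
# Dividing by the view mean removes the (random) fluorescence gain while
# preserving absolute contrast, which decays monotonically with depth because
# flux-conserving blur shrinks spatial variance but not the mean.
mean_relative_view <- function(x) {
  m <- mean(x)
  if (m <= 0) return(x * 0)
  x / m - 1
}
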