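#' Generate a 2D lattice-gradient (Perlin) noise field
#'
#' Classic Perlin noise: pseudorandom unit gradients on an integer lattice,
#' smoothstep-interpolated dot products, with optional octaves summed under a
#' geometric persistence. The field is min-max normalized to \[0, 1\], so its
#' smooth ridges can be thresholded into connected cell foci.
#'
#' @param shape integer vector `c(H, W)`, both >= 8.
#' @param grid_period lattice spacing in pixels (>= 2); sets the correlation
#'   length of the base octave.
#' @param octaves number of octaves (>= 1); each successive octave halves the
#'   period and scales amplitude by `persistence`.
#' @param persistence amplitude decay per octave, in (0, 1].
#' @param seed integer seed; identical arguments give a bit-identical field.
#' @return A `noise_field` object: list with `values` (H x W matrix in
#'   \[0, 1\]), plus the generating parameters.
#' @examples
#' f <- generate_perlin_field(c(51, 51), grid_period = 10, seed = 7)
#' range(f$values)
#' @export
generate_perlin_field <- function(shape = c(51, 51), grid_period = 10,
                                  octaves = 1, persistence = 0.5, seed = 1) {
  if (length(shape) != 2 || any(shape < 8))
    abort("`shape` must be two dimensions, each >= 8")
  if (grid_period < 2) abort("`grid_period` must be >= 2")
  if (octaves < 1) abort("`octaves` must be >= 1")
  if (persistence <= 0 || persistence > 1) abort("`persistence` must be in (0, 1]")
  h <- shape[1]; w <- shape[2]
  perm <- with_seed(seed, sample.int(256L) - 1L)  # permutation table
  total <- matrix(0, h, w)
  for (o in seq_len(octaves) - 1L) {
    period <- max(grid_period / 2^o, 1.5)
    total <- total + persistence^o * perlin_octave(h, w, period, perm)
  }
  rng <- range(total)
  values <- if (diff(rng) > 0) (total - rng[1]) / diff(rng) else total * 0
  structure(list(values = values, grid_period = grid_period, octaves = octaves,
                 persistence = persistence, seed = seed),
            class = "noise_field")
}

# One octave of classic 2D Perlin noise at a given lattice period, using a
# seeded permutation table to hash lattice nodes to one of 16 unit gradients.
perlin_octave <- function(h, w, period, perm) {
  grad_angle <- 2 * pi * (0:15) / 16
  gx_tab <- cos(grad_angle); gy_tab <- sin(grad_angle)
  y <- (seq_len(h) - 1) / period
  x <- (seq_len(w) - 1) / period
  yi <- floor(y); xi <- floor(x)
  yf <- y - yi;  xf <- x - xi
  hash2 <- function(ix, iy) {
    # perm is 0-based values; R indexing is 1-based
    a <- perm[(ix %% 256L) + 1L]
    perm[((a + iy) %% 256L) + 1L] %% 16L
  }
  grid <- function(dx, dy) {
    # dot product of corner gradient with offset vector, over the full image
    ixm <- outer(yi * 0, xi + dx, "+")      # h x w of corner x-index
    iym <- outer(yi + dy, xi * 0, "+")
    idx <- hash2(as.integer(ixm), as.integer(iym)) + 1L
    offx <- outer(rep(1, h), xf - dx)
    offy <- outer(yf - dy, rep(1, w))
    matrix(gx_tab[idx], h, w) * offx + matrix(gy_tab[idx], h, w) * offy
  }
  n00 <- grid(0, 0); n10 <- grid(1, 0); n01 <- grid(0, 1); n11 <- grid(1, 1)
  fade <- function(t) t^3 * (t * (t * 6 - 15) + 10)
  u <- outer(rep(1, h), fade(xf))
  v <- outer(fade(yf), rep(1, w))
  nx0 <- n00 + u * (n10 - n00)
  nx1 <- n01 + u * (n11 - n01)
  nx0 + v * (nx1 - nx0)
}

#' Threshold a noise field into a binary tumor mask
#'
#' Pixels with field value above the threshold are marked as tumor; the
#' coherent structure of the field makes the foreground smooth connected foci
#' rather than speckle.
#'
#' @param field a `noise_field` (or a numeric matrix in \[0, 1\]).
#' @param threshold scalar in (0, 1); default 0.5.
#' @return A `tumor_mask`: list with binary `mask` matrix and `threshold`.
#' @export
threshold_mask <- function(field, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) abort("`threshold` must be in (0, 1)")
  values <- if (inherits(field, "noise_field")) field$values else field
  structure(list(mask = (values > threshold) * 1L, threshold = threshold),
            class = "tumor_mask")
}

#' Draw intensity statistics for phantom rendering
#'
#' Samples the first two moments of signal and background fluorescence for one
#' phantom: a uniform background mean, a uniform signal-to-background ratio
#' (SNR), and standard deviations set by a common coefficient of variation.
#'
#' @param snr_range `c(lo, hi)` with `1 < lo <= hi`; signal mean is
#'   `background_mean * snr`.
#' @param background_mean_range `c(lo, hi)` background mean, arbitrary units.
#' @param cv coefficient of variation; each std is `cv * mean`.
#' @param seed integer seed.
#' @return An `intensity_stats` list: `signal_mean`, `signal_std`,
#'   `background_mean`, `background_std`, `snr`.
#' @export
sample_stats <- function(snr_range = c(2, 10),
                         background_mean_range = c(50, 150),
                         cv = 0.15, seed = 1) {
  if (snr_range[1] <= 1) abort("`snr_range` lower bound must exceed 1")
  if (snr_range[2] < snr_range[1]) abort("`snr_range` must be non-decreasing")
  with_seed(seed, {
    snr <- runif(1, snr_range[1], snr_range[2])
    bg <- runif(1, background_mean_range[1], background_mean_range[2])
    intensity_stats(signal_mean = bg * snr, background_mean = bg, cv = cv)
  })
}

#' @rdname sample_stats
#' @param signal_mean,background_mean means of the two pixel populations.
#' @export
intensity_stats <- function(signal_mean, background_mean, cv = 0.15) {
  if (signal_mean <= background_mean)
    abort("signal mean must exceed background mean")
  structure(list(signal_mean = signal_mean, signal_std = cv * signal_mean,
                 background_mean = background_mean,
                 background_std = cv * background_mean,
                 snr = signal_mean / background_mean),
            class = "intensity_stats")
}

#' Render a phantom cell image from a mask and intensity statistics
#'
#' Each pixel is drawn independently: Normal(signal mean, signal sd^2) on mask
#' pixels, Normal(background mean, background sd^2) elsewhere, clipped at zero
#' (no negative fluorescence).
#'
#' @param mask a `tumor_mask`.
#' @param stats an `intensity_stats`.
#' @param seed integer seed; rendering is deterministic given the seed.
#' @return A `cell_image`: list with `intensity` matrix, `mask`, `stats`,
#'   `seed`.
#' @export
render_cell_image <- function(mask, stats, seed = 1) {
  m <- mask$mask
  mu <- ifelse(m == 1, stats$signal_mean, stats$background_mean)
  sd <- ifelse(m == 1, stats$signal_std, stats$background_std)
  intensity <- with_seed(seed, {
    matrix(pmax(rnorm(length(m), mean = mu, sd = sd), 0), nrow(m), ncol(m))
  })
  structure(list(intensity = intensity, mask = mask, stats = stats, seed = seed),
            class = "cell_image")
}

#' Generate a complete phantom cell image
#'
#' Convenience wrapper: Perlin field -> threshold -> intensity rendering, all
#' driven by one seed (sub-seeds are derived for the field and the rendering).
#'
#' @inheritParams generate_perlin_field
#' @inheritParams threshold_mask
#' @inheritParams sample_stats
#' @param config optional phantom config list (see [default_config()]);
#'   explicit arguments override it.
#' @return A `cell_image`.
#' @examples
#' img <- generate_cell_image(seed = 42)
#' mean(img$intensity[img$mask$mask == 1]) > mean(img$intensity[img$mask$mask == 0])
#' @export
generate_cell_image <- function(seed = 1, shape = NULL, grid_period = NULL,
                                octaves = NULL, persistence = NULL,
                                threshold = NULL, snr_range = NULL,
                                background_mean_range = NULL, cv = NULL,
                                config = NULL) {
  p <- (config %||% default_config())$phantom
  shape <- shape %||% p$shape
  field <- generate_perlin_field(shape, grid_period %||% p$grid_period,
                                 octaves %||% p$octaves,
                                 persistence %||% p$persistence,
                                 seed = child_seed(seed, 0))
  mask <- threshold_mask(field, threshold %||% p$threshold)
  stats <- sample_stats(snr_range %||% p$snr_range,
                        background_mean_range %||% p$background_mean_range,
                        cv %||% p$cv, seed = child_seed(seed, 1))
  render_cell_image(mask, stats, seed = child_seed(seed, 2))
}

#' @export
print.cell_image <- function(x, ...) {
  cat(sprintf("<cell_image %dx%d | %d cell px | SNR %.2f>\n",
              nrow(x$intensity), ncol(x$intensity), sum(x$mask$mask),
              x$stats$snr))
  invisible(x)
}
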