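#' Default experiment configuration
#'
#' Nested configuration driving every stage: phantom synthesis, optics,
#' dataset sizes and training. All values are exposed so sensitivity studies
#' can move them; the defaults are the package's study conditions.
#'
#' @param fast if `TRUE`, use the reduced desk-scale profile (smaller training
#'   sets and fewer epochs) intended for single-CPU runs.
#' @return A nested named list with blocks `phantom`, `optics`, `dataset`,
#'   `train`.
#' @export
default_config <- function(fast = FALSE) {
  cfg <- list(
    phantom = list(
      shape = c(51, 51),
      grid_period = 10,
      octaves = 1,
      persistence = 0.5,
      threshold = 0.5,
      snr_range = c(2, 10),
      background_mean_range = c(50, 150),
      cv = 0.15,
      dynamics_threshold = 0.70  # sparser foci for the moving-cluster task
    ),
    optics = list(
      kind = "gaussian",
      sigma0_px = 0.5,
      slope_px_per_mm = 4,
      truncation_radius_sigmas = 3,
      separation_um = 1000,
      pixel_pitch_um = 55  # documentation / plot axes only
    ),
    dataset = list(
      n_train = 20000,
      n_test = 1000,
      n_sequences = 100,
      min_gap_two_layer_um = 500,
      min_gap_four_layer_um = 200,
      depth_bin_um = 250
    ),
    train = list(
      epochs = c(depth = 60, deblur = 25, detector = 20, depthmap = 20),
      batch_size = 32,
      learning_rate = c(depth = 1e-3, deblur = 3e-3, detector = 1e-3,
                        depthmap = 3e-3)
    )
  )
  if (fast) {
    cfg$dataset$n_train <- 2000
    cfg$dataset$n_test <- 200
    cfg$dataset$n_sequences <- 10
    cfg$dataset$n_train_detector <- 1200
    cfg$train$epochs <- c(depth = 60, deblur = 20, detector = 12,
                          depthmap = 16)
  }
  cfg
}

#' Read / write a YAML experiment configuration
#'
#' Missing blocks are filled from [default_config()].
#'
#' @param path file path.
#' @param config a configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Stable hash of a configuration
#'
#' Embedded in manifests and model metadata so every artifact is traceable to
#' the exact configuration and seed that produced it.
#' @param config a configuration list.
#' @export
config_hash <- function(config) rlang::hash(config)

psf_from_config <- function(config) {
  o <- config$optics
  psf_model(kind = o$kind, sigma0_px = o$sigma0_px,
            slope_px_per_mm = o$slope_px_per_mm,
            truncation_radius_sigmas = o$truncation_radius_sigmas)
}
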