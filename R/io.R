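# Dataset directories: 32-bit float TIFF views/targets, PNG masks, a CSV
# manifest and a YAML config snapshot; enough to re-validate every invariant
# from disk.

#' Write a dataset to a directory
#'
#' Views (and targets / label planes / depth maps where the task has them) are
#' written per sample, alongside `manifest.csv` and `config_snapshot.yaml`.
#'
#' @param dataset a `cs3d_dataset`.
#' @param dir output directory.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  samples <- dataset$samples
  if (dataset$task == "dynamics") {
    samples <- unlist(lapply(seq_along(dataset$samples), function(i)
      lapply(dataset$samples[[i]]$steps, function(st) {
        st$sequence_id <- i; st
      })), recursive = FALSE)
  }
  scale <- max(vapply(samples, function(s) max(s$view), numeric(1)), 1)
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    base <- sprintf("sample_%05d", i)
    tiff::writeTIFF(s$view / scale, file.path(dir, paste0(base, "_view.tif")),
                    bits.per.sample = 32)
    if (!is.null(s$view_b))
      tiff::writeTIFF(s$view_b / scale,
                      file.path(dir, paste0(base, "_viewB.tif")),
                      bits.per.sample = 32)
    if (!is.null(s$target))
      tiff::writeTIFF(s$target / scale,
                      file.path(dir, paste0(base, "_target.tif")),
                      bits.per.sample = 32)
    if (!is.null(s$depth_map))
      tiff::writeTIFF(s$depth_map, file.path(dir, paste0(base, "_depthmap.tif")),
                      bits.per.sample = 32)
    masks <- if (!is.null(s$label_planes)) s$label_planes
      else if (!is.null(s$images)) lapply(s$images, function(im) im$mask$mask)
      else if (!is.null(s$image)) list(s$image$mask$mask)
    for (k in seq_along(masks))
      png::writePNG(masks[[k]] * 1.0,
                    file.path(dir, sprintf("%s_mask%d.png", base, k)))
    depths <- s$depths_um %||% s$depth_um
    tibble::tibble(sample_id = i, file = paste0(base, "_view.tif"),
                   n_masks = length(masks),
                   dual = !is.null(s$view_b),
                   depths_um = paste(round(depths, 3), collapse = ";"),
                   seed = s$seed %||% NA_real_)
  })
  manifest <- dplyr::bind_rows(rows)
  manifest$task <- dataset$task
  manifest$config_hash <- dataset$config_hash
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  write_config(dataset$config, file.path(dir, "config_snapshot.yaml"))
  jsonlite::write_json(list(scale = scale), file.path(dir, "scale.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  manifest <- tibble::as_tibble(utils::read.csv(file.path(dir, "manifest.csv")))
  config <- read_config(file.path(dir, "config_snapshot.yaml"))
  scale <- jsonlite::read_json(file.path(dir, "scale.json"))$scale
  samples <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    base <- sub("_view\\.tif$", "", row$file)
    s <- list(view = tiff::readTIFF(file.path(dir, row$file)) * scale,
              depths_um = as.numeric(strsplit(row$depths_um, ";")[[1]]),
              seed = row$seed)
    if (isTRUE(row$dual))
      s$view_b <- tiff::readTIFF(file.path(dir, paste0(base, "_viewB.tif"))) * scale
    tf <- file.path(dir, paste0(base, "_target.tif"))
    if (file.exists(tf)) s$target <- tiff::readTIFF(tf) * scale
    df <- file.path(dir, paste0(base, "_depthmap.tif"))
    if (file.exists(df)) s$depth_map <- tiff::readTIFF(df)
    if (row$n_masks > 0)
      s$label_planes <- lapply(seq_len(row$n_masks), function(k) {
        m <- png::readPNG(file.path(dir, sprintf("%s_mask%d.png", base, k)))
        (m > 0.5) * 1L
      })
    if (manifest$task[1] == "depth") {
      s$depth_um <- s$depths_um[1]
      s$depth_class <- as.integer((s$depth_um - 50) / 100)
    }
    s
  })
  structure(list(samples = samples, task = manifest$task[1],
                 manifest = manifest, config = config,
                 config_hash = manifest$config_hash[1], seed = NA),
            class = "cs3d_dataset")
}

#' Validate a dataset directory against its manifest
#'
#' Re-checks, from the files on disk: readability of every image, depth
#' ranges, the per-task minimum depth gaps and (for the two-layer task) mask
#' disjointness.
#'
#' @param path dataset directory containing `manifest.csv`.
#' @return A list with `pass` (logical) and a character vector `violations`.
#' @export
validate_manifest <- function(path) {
  violations <- character()
  manifest_path <- file.path(path, "manifest.csv")
  if (!file.exists(manifest_path))
    return(list(pass = FALSE, violations = "manifest.csv missing"))
  manifest <- utils::read.csv(manifest_path)
  config <- read_config(file.path(path, "config_snapshot.yaml"))
  task <- manifest$task[1]
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    id <- sprintf("sample %d", row$sample_id)
    v <- tryCatch(tiff::readTIFF(file.path(path, row$file)),
                  error = function(e) NULL)
    if (is.null(v)) {
      violations <- c(violations, paste(id, ": unreadable view file"))
      next
    }
    depths <- as.numeric(strsplit(as.character(row$depths_um), ";")[[1]])
    if (task == "depth" && !depths[1] %in% seq(50, 1950, 100))
      violations <- c(violations, paste(id, ": depth off the 100 um grid"))
    if (task %in% c("deblur", "nonoverlap", "overlap_single", "overlap_dual",
                    "dynamics") && (min(depths) < 0 || max(depths) > 1000))
      violations <- c(violations, paste(id, ": depth out of [0, 1000] um"))
    if (task == "nonoverlap") {
      if (diff(depths) < config$dataset$min_gap_two_layer_um)
        violations <- c(violations,
                        sprintf("%s: two-layer gap %.0f um below %.0f", id,
                                diff(depths), config$dataset$min_gap_two_layer_um))
      base <- sub("_view\\.tif$", "", row$file)
      m1 <- png::readPNG(file.path(path, paste0(base, "_mask1.png"))) > 0.5
      m2 <- png::readPNG(file.path(path, paste0(base, "_mask2.png"))) > 0.5
      if (any(m1 & m2))
        violations <- c(violations, paste(id, ": layer masks overlap"))
    }
    if (task %in% c("overlap_single", "overlap_dual", "dynamics") &&
        any(diff(depths) < config$dataset$min_gap_four_layer_um))
      violations <- c(violations,
                      sprintf("%s: adjacent gap below %.0f um", id,
                              config$dataset$min_gap_four_layer_um))
  }
  list(pass = length(violations) == 0, violations = violations)
}
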