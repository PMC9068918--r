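#' Assemble a voxel-level 3D reconstruction from detector planes
#'
#' Places the four thresholded prediction planes at their layer depths inside
#' a voxel grid spanning the inter-sensor space, with marker slabs for the
#' two sensors at depth 0 and at the separation. Voxel codes: 0 empty, 1
#' cell, 2 sensor.
#'
#' @param pred_planes list of 4 probability (or binary) planes.
#' @param depths_um numeric vector of 4 layer depths.
#' @param geometry a [sensor_geometry()].
#' @param z_step_um axial voxel size, micrometers.
#' @param threshold decision threshold applied to the planes.
#' @return A `voxel_reconstruction`: 3D occupancy array (H x W x Z), the z
#'   axis in micrometers, and the plane-to-slice assignment.
#' @export
reconstruct_3d <- function(pred_planes, depths_um,
                           geometry = sensor_geometry(), z_step_um = 50,
                           threshold = 0.5) {
  if (length(pred_planes) != 4 || length(depths_um) != 4)
    abort("expected 4 planes and 4 depths")
  if (any(depths_um < 0 | depths_um > geometry$separation_um))
    abort("depth outside [0, separation]")
  z_um <- seq(0, geometry$separation_um, by = z_step_um)
  h <- nrow(pred_planes[[1]]); w <- ncol(pred_planes[[1]])
  occ <- array(0L, c(h, w, length(z_um)))
  occ[, , 1] <- 2L
  occ[, , length(z_um)] <- 2L
  slice <- vapply(depths_um, function(d) which.min(abs(z_um - d)), integer(1))
  for (k in 1:4) {
    plane <- (pred_planes[[k]] > threshold) * 1L
    occ[, , slice[k]] <- pmax(occ[, , slice[k]], plane)
  }
  structure(list(occupancy = occ, z_um = z_um, plane_slice = slice,
                 depths_um = depths_um, geometry = geometry,
                 threshold = threshold),
            class = "voxel_reconstruction")
}

#' @export
print.voxel_reconstruction <- function(x, ...) {
  cat(sprintf("<voxel_reconstruction %dx%dx%d | %d cell voxels>\n",
              dim(x$occupancy)[1], dim(x$occupancy)[2], dim(x$occupancy)[3],
              sum(x$occupancy == 1L)))
  invisible(x)
}

#' Write / read a voxel reconstruction
#'
#' `write_reconstruction()` writes a CSV voxel list (x, y, z_um, value for all
#' non-empty voxels) and a multi-page 8-bit TIFF image stack; reading the CSV
#' back reproduces the occupancy exactly.
#'
#' @param recon a `voxel_reconstruction`.
#' @param dir output directory (created if needed).
#' @export
write_reconstruction <- function(recon, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  occ <- recon$occupancy
  idx <- which(occ != 0L, arr.ind = TRUE)
  df <- data.frame(x = idx[, 1], y = idx[, 2],
                   z_um = recon$z_um[idx[, 3]],
                   value = occ[idx])
  utils::write.csv(df, file.path(dir, "voxels.csv"), row.names = FALSE)
  pages <- lapply(seq_along(recon$z_um), function(i) occ[, , i] / 2)
  tiff::writeTIFF(pages, file.path(dir, "stack.tif"), bits.per.sample = 8)
  jsonlite::write_json(list(z_um = recon$z_um, depths_um = recon$depths_um,
                            separation_um = recon$geometry$separation_um,
                            threshold = recon$threshold),
                       file.path(dir, "reconstruction.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_reconstruction
#' @export
read_reconstruction <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "reconstruction.json"),
                              simplifyVector = TRUE)
  df <- utils::read.csv(file.path(dir, "voxels.csv"))
  z_um <- meta$z_um
  pages <- tiff::readTIFF(file.path(dir, "stack.tif"), all = TRUE)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  occ <- array(0L, c(h, w, length(z_um)))
  zi <- match(df$z_um, z_um)
  occ[cbind(df$x, df$y, zi)] <- as.integer(df$value)
  structure(list(occupancy = occ, z_um = z_um,
                 plane_slice = vapply(meta$depths_um,
                                      function(d) which.min(abs(z_um - d)),
                                      integer(1)),
                 depths_um = meta$depths_um,
                 geometry = sensor_geometry(meta$separation_um),
                 threshold = meta$threshold),
            class = "voxel_reconstruction")
}
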