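# External interfaces: TIFF images, CSV tables (clusters, fiducials,
# polylines, height maps) and JSON (transforms, configs, summaries).

#' Write a reconstructed image as multi-channel TIFF
#'
#' One TIFF page per channel (and per z-plane for stacks). Intensities are
#' stored normalized to `[0, 1]` by the global maximum; the scale factor is
#' returned invisibly and also written to a `<path>.json` sidecar together
#' with the pixel size, so counts can be restored on read.
#'
#' @param image A [recon_image()].
#' @param path Output file path.
#' @return Invisibly, the normalization scale.
#' @export
write_image_tiff <- function(image, path) {
  stopifnot(inherits(image, "recon_image"))
  d <- dim(image$data)
  scale <- max(image$data, 1e-12)
  pages <- list()
  nz <- if (length(d) == 4) d[4] else 1
  for (z in seq_len(nz)) {
    for (ch in seq_len(d[3])) {
      pl <- if (length(d) == 4) image$data[, , ch, z] else image$data[, , ch]
      pages[[length(pages) + 1]] <- pl / scale
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(
    list(scale = scale, pixel_nm = image$pixel_nm, channels = image$channels,
         z_planes = nz, z_step_nm = image$z_step_nm),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(scale)
}

#' Read a reconstructed image written by [write_image_tiff()]
#'
#' @param path TIFF path (the `.json` sidecar must sit beside it).
#' @return A [recon_image()].
#' @export
read_image_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nch <- length(meta$channels)
  nz <- meta$z_planes
  d <- dim(pages[[1]])
  data <- if (nz > 1) array(0, c(d, nch, nz)) else array(0, c(d, nch))
  k <- 1
  for (z in seq_len(nz)) for (ch in seq_len(nch)) {
    if (nz > 1) data[, , ch, z] <- pages[[k]] * meta$scale
    else data[, , ch] <- pages[[k]] * meta$scale
    k <- k + 1
  }
  recon_image(data, pixel_nm = meta$pixel_nm, channels = meta$channels,
              z_step_nm = meta$z_step_nm)
}

#' Write / read fiducial pairs as 4-column CSV
#'
#' Columns `src_x, src_y, dst_x, dst_y` in nm.
#'
#' @param pairs Fiducial pair tibble.
#' @param path CSV path.
#' @return `read_fiducials_csv()` returns the tibble.
#' @export
write_fiducials_csv <- function(pairs, path) {
  write.csv(pairs[, c("src_x", "src_y", "dst_x", "dst_y")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_fiducials_csv
#' @export
read_fiducials_csv <- function(path) {
  as_tibble(read.csv(path))
}

#' Serialize / deserialize an affine transform as JSON
#'
#' Six coefficients, row-major: `a11, a12, tx, a21, a22, ty`.
#'
#' @param transform An [affine2d()].
#' @param path JSON path.
#' @return `read_transform_json()` returns the [affine2d()].
#' @export
write_transform_json <- function(transform, path) {
  co <- c(transform$linear[1, ], transform$translation[1],
          transform$linear[2, ], transform$translation[2])
  jsonlite::write_json(list(coefficients = co), path, digits = NA)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  co <- jsonlite::read_json(path, simplifyVector = TRUE)$coefficients
  affine2d(matrix(co[c(1, 2, 4, 5)], 2, 2, byrow = TRUE), co[c(3, 6)])
}

#' Write / read a height map as CSV grid
#'
#' Plain numeric grid, one row per y line; the spacing is stored in a
#' header comment line `# spacing_nm=<s>`.
#'
#' @param surface A [height_map()].
#' @param path CSV path.
#' @return `read_height_map_csv()` returns the [height_map()].
#' @export
write_height_map_csv <- function(surface, path) {
  con <- file(path, "w")
  writeLines(sprintf("# spacing_nm=%.10g", surface$spacing_nm), con)
  write.table(surface$z, con, row.names = FALSE, col.names = FALSE,
              sep = ",")
  close(con)
  invisible(path)
}

#' @rdname write_height_map_csv
#' @export
read_height_map_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  spacing <- as.numeric(sub("# spacing_nm=", "", hdr))
  z <- as.matrix(read.csv(path, header = FALSE, skip = 1))
  dimnames(z) <- NULL
  height_map(z, spacing)
}

#' Write a cluster table (list columns dropped) as CSV
#' @param clusters Cluster tibble.
#' @param path CSV path.
#' @export
write_clusters_csv <- function(clusters, path) {
  flat <- clusters[, !vapply(clusters, is.list, logical(1))]
  write.csv(flat, path, row.names = FALSE)
  invisible(path)
}
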