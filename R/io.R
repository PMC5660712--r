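#' Write / read a label volume as multi-page TIFF with a YAML sidecar
#'
#' Pages are z-slices (z-major order); labels are stored as 32-bit floats
#' holding integer values.  Voxel size and origin metadata go to
#' `<path>.yaml`.
#'
#' @param volume a `label_volume`.
#' @param path output `.tif` path.
#' @export
write_label_tiff <- function(volume, path) {
  d <- dim(volume$labels)
  scale <- max(volume$labels, 1L)    # floats stored in [0, 1]
  pages <- lapply(seq_len(d[3]), function(z) {
    m <- matrix(volume$labels[, , z] / scale, d[1], d[2])
    t(m)   # TIFF rows = y
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  yaml::write_yaml(list(voxel_size_nm = volume$voxel_size,
                        origin_nm = volume$origin,
                        shape_vox = d, label_scale = scale, kind = "labels"),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_label_tiff
#' @return a `label_volume`.
#' @export
read_label_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  scale <- if (is.null(meta$label_scale)) 1 else meta$label_scale
  arr <- array(0L, unlist(meta$shape_vox))
  for (z in seq_along(pages)) arr[, , z] <- as.integer(round(t(pages[[z]]) * scale))
  label_volume(arr, unlist(meta$voxel_size_nm), unlist(meta$origin_nm))
}

#' Write / read an image stack as multi-page float TIFF with a YAML sidecar
#' @param stack an `image_stack` (single channel).
#' @param path output `.tif` path.
#' @export
write_stack_tiff <- function(stack, path) {
  arr <- stack$data
  stopifnot(length(dim(arr)) == 3)
  mx <- max(arr, 1)
  pages <- lapply(seq_len(dim(arr)[3]), function(z) t(arr[, , z]) / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  yaml::write_yaml(list(xy_pitch_nm = stack$xy_pitch, z_step_nm = stack$z_step,
                        snr_poisson = stack$snr_poisson, snr_read = stack$snr_read,
                        intensity_scale = mx, shape_vox = dim(arr), kind = "stack"),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_stack_tiff
#' @return an `image_stack`.
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  d <- unlist(meta$shape_vox)
  arr <- array(0, d)
  for (z in seq_along(pages)) arr[, , z] <- t(pages[[z]]) * meta$intensity_scale
  image_stack(arr, meta$xy_pitch_nm, meta$z_step_nm,
              unlist(meta$snr_poisson), unlist(meta$snr_read))
}

#' Write / read barcodes as CSV (`x_nm, y_nm, z_nm, identity`)
#' @param barcodes a `barcode_set`.
#' @param path output `.csv` path.
#' @export
write_barcodes_csv <- function(barcodes, path) {
  df <- data.frame(x_nm = barcodes$x, y_nm = barcodes$y, z_nm = barcodes$z,
                   identity = barcodes$identity)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_barcodes_csv
#' @param extent_nm volume extent metadata (optional).
#' @return a `barcode_set`.
#' @export
read_barcodes_csv <- function(path, extent_nm = NULL) {
  df <- utils::read.csv(path)
  structure(data.frame(x = df$x_nm, y = df$y_nm, z = df$z_nm,
                       identity = as.integer(df$identity)),
            density = NA_real_, extent_nm = extent_nm,
            class = c("barcode_set", "data.frame"))
}

#' Serialize / deserialize a segmentation tree as JSON
#' @param tree a `seg_tree`.
#' @param path output `.json` path.
#' @export
write_segtree_json <- function(tree, path) {
  jsonlite::write_json(list(n_leaves = tree$n_leaves, nodes = tree$nodes,
                            thresholds = tree$thresholds,
                            voxel_size = tree$voxel_size),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_segtree_json
#' @return a `seg_tree`.
#' @export
read_segtree_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as.data.frame(obj$nodes)
  if (nrow(nodes) == 0)
    nodes <- data.frame(id = numeric(0), left = numeric(0), right = numeric(0),
                        threshold = numeric(0))
  structure(list(nodes = nodes, n_leaves = obj$n_leaves,
                 thresholds = obj$thresholds, voxel_size = obj$voxel_size),
            class = "seg_tree")
}

#' Cache a PSF kernel on disk (multi-page float TIFF + YAML attributes)
#'
#' Avoids recomputing the Debye integral between runs; the sidecar records
#' NA, wavelengths, pitch and expansion factor.
#'
#' @param psf a `psf_kernel`.
#' @param path output `.tif` path.
#' @export
write_psf_tiff <- function(psf, path) {
  d <- dim(psf$intensity)
  mx <- max(psf$intensity)
  pages <- lapply(seq_len(d[3]), function(z) t(psf$intensity[, , z]) / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  yaml::write_yaml(list(voxel_pitch_nm = psf$voxel_pitch, na = psf$na,
                        wavelength_ex = psf$wavelength_ex,
                        wavelength_em = psf$wavelength_em,
                        n_immersion = psf$n_immersion,
                        expansion_factor = psf$expansion_factor,
                        intensity_scale = mx, shape_vox = d, kind = "psf"),
                   paste0(path, ".yaml"), precision = 15)
  invisible(path)
}

#' @rdname write_psf_tiff
#' @return a `psf_kernel` (intensity renormalized to unit sum).
#' @export
read_psf_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  d <- unlist(meta$shape_vox)
  arr <- array(0, d)
  for (z in seq_along(pages)) arr[, , z] <- t(pages[[z]]) * meta$intensity_scale
  structure(list(intensity = arr / sum(arr),
                 voxel_pitch = unlist(meta$voxel_pitch_nm),
                 wavelength_ex = meta$wavelength_ex,
                 wavelength_em = meta$wavelength_em, na = meta$na,
                 n_immersion = meta$n_immersion,
                 expansion_factor = meta$expansion_factor),
            class = "psf_kernel")
}

#' Write a BPM as multi-page float TIFF
#' @param bpm a `bpm` object or 3D array in \[0,1\].
#' @param path output `.tif` path.
#' @export
write_bpm_tiff <- function(bpm, path) {
  p <- if (inherits(bpm, "bpm")) bpm$prob else bpm
  pages <- lapply(seq_len(dim(p)[3]), function(z) t(p[, , z]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  invisible(path)
}
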