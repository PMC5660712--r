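#' Dense 3D label volume
#'
#' Container for a dense segmentation of a tissue block: a 3D integer array of
#' neuron IDs on a regular voxel grid (0 = extracellular / unassigned), with
#' the physical voxel pitch in nanometres.  Ground-truth volumes and final
#' reconstructions share this type.
#'
#' @param labels 3D array of non-negative integers.
#' @param voxel_size voxel edge length in nm.  Isotropic grids use a single
#'   number; anisotropic grids (image-resolution label volumes) a length-3
#'   vector `(dx, dy, dz)`.
#' @param origin nm offset of voxel (1,1,1)'s corner, length 3.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, voxel_size = 6, origin = c(0, 0, 0)) {
  stopifnot(length(dim(labels)) == 3, all(voxel_size > 0),
            length(origin) == 3)
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  labels <- array(as.integer(labels), dim(labels))
  if (any(labels < 0)) stop("labels must be non-negative")
  structure(list(labels = labels, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("label_volume: %d x %d x %d voxels @ (%g, %g, %g) nm, %d labels\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              length(setdiff(unique(as.vector(x$labels)), 0L))))
  invisible(x)
}

#' @export
dim.label_volume <- function(x) dim(x$labels)

#' Physical extent of a label volume in nm
#' @param volume a `label_volume`.
#' @return length-3 numeric, nm.
#' @export
volume_extent_nm <- function(volume) dim(volume$labels) * volume$voxel_size

#' Generate a dense synthetic ground-truth volume of packed neurites
#'
#' Emulates the morphology of densely packed cortical neuropil as a
#' space-filling arrangement of tubular neurites plus a few ellipsoidal
#' somata/boutons.  Each neurite follows a persistent random walk through the
#' block and is dilated to a radius sampled log-uniformly from `radius_range`;
#' remaining space is assigned to the nearest structure (breadth-first
#' nearest-structure fill) so that, like electron-microscopy neuropil, the
#' tissue tiles the volume with no extracellular gaps by default.
#'
#' @param shape_vox integer length-3, voxels per axis (each >= 16).
#' @param voxel_size nm per voxel edge (isotropic), default 6.
#' @param neurite_params list with elements `count` (number of structures),
#'   `radius_range` nm (default c(50, 400), sampled log-uniformly),
#'   `tortuosity` (direction diffusion per step, default 0.25) and
#'   `soma_fraction` (fraction of structures drawn as ellipsoidal blobs,
#'   default 0.1).
#' @param seed integer seed; the output is bit-reproducible given the seed.
#' @param gap_nm extracellular gap half-width in nm (default 0 = space
#'   filling); positive values carve label-0 clefts between structures.
#' @return A `label_volume` whose nonzero labels are `1..count` (some may be
#'   absorbed when structures fully overlap).
#' @export
generate_ground_truth <- function(shape_vox, voxel_size = 6,
                                  neurite_params = list(), seed = 1,
                                  gap_nm = 0) {
  shape_vox <- as.integer(shape_vox)
  if (length(shape_vox) != 3 || any(shape_vox < 16))
    stop("shape_vox must be three integers >= 16")
  p <- utils::modifyList(list(count = 10, radius_range = c(50, 400),
                              tortuosity = 0.25, soma_fraction = 0.1),
                         neurite_params)
  if (is.null(p$count) || p$count < 0) stop("neurite_params$count must be >= 0")
  if (p$count == 0)
    return(label_volume(array(0L, shape_vox), voxel_size))
  rr <- p$radius_range
  if (length(rr) != 2 || rr[1] <= voxel_size || rr[2] > min(shape_vox) * voxel_size)
    stop("radius_range must lie within (voxel_size, volume extent)")

  withr::with_seed(seed, {
    extent <- shape_vox            # work in voxel units
    rvox <- exp(stats::runif(p$count, log(rr[1]), log(rr[2]))) / voxel_size
    is_soma <- stats::runif(p$count) < p$soma_fraction
    centers <- list(); radii <- list(); labs <- list()
    for (i in seq_len(p$count)) {
      if (is_soma[i]) {
        # ellipsoidal blob: one center stamped as overlapping spheres along
        # a short principal axis
        c0 <- stats::runif(3, 0.2, 0.8) * extent
        ax <- rnorm3_unit()
        len <- rvox[i] * stats::runif(1, 0.5, 1.5)
        tvals <- seq(-len, len, by = max(rvox[i] / 3, 0.5))
        pts <- t(vapply(tvals, function(t) c0 + t * ax, numeric(3)))
        centers[[i]] <- pts
        radii[[i]] <- rep(rvox[i], nrow(pts))
      } else {
        pts <- persistent_walk(extent, step = max(rvox[i] / 2, 1),
                               tortuosity = p$tortuosity)
        centers[[i]] <- pts
        radii[[i]] <- rep(rvox[i], nrow(pts))
      }
      labs[[i]] <- rep(i, nrow(centers[[i]]))
    }
    # stamp one guaranteed seed voxel per structure first (first-come wins at
    # overlaps, so every requested label survives in the output)
    anchor <- do.call(rbind, lapply(centers, function(m) m[1, , drop = FALSE]))
    centers <- rbind(anchor, do.call(rbind, centers))
    radii <- c(rep(0.9, p$count), unlist(radii))
    labs <- c(seq_len(p$count), unlist(labs))
    seeded <- cpp_stamp_spheres(shape_vox, centers, radii, as.integer(labs))
    filled <- cpp_flood_nearest(seeded, shape_vox)
    lab <- array(filled, shape_vox)
    if (gap_nm > 0) {
      vol <- label_volume(lab, voxel_size)
      b <- extract_membrane(vol)
      d <- array(cpp_edt(as.integer(b$mask), dim(lab), rep(voxel_size, 3)),
                 dim(lab))
      lab[b$mask | d < gap_nm] <- 0L
    }
    label_volume(lab, voxel_size)
  })
}

rnorm3_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# Persistent random walk through a box (voxel units); reflects at the walls.
persistent_walk <- function(extent, step, tortuosity) {
  pos <- stats::runif(3, 0.1, 0.9) * extent
  dir <- rnorm3_unit()
  max_len <- 3 * sum(extent)        # generous cap on total path length
  n <- ceiling(max_len / step)
  pts <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    pts[i, ] <- pos
    dir <- dir + tortuosity * stats::rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    pos <- pos + step * dir
    for (a in 1:3) {                # reflect at faces
      if (pos[a] < 0) { pos[a] <- -pos[a]; dir[a] <- -dir[a] }
      if (pos[a] > extent[a]) { pos[a] <- 2 * extent[a] - pos[a]; dir[a] <- -dir[a] }
    }
  }
  pts
}

#' Nearest-neighbor resampling of a label volume onto a new isotropic grid
#'
#' Every output voxel takes the label of the input voxel containing its
#' center, so the label set can only shrink, never grow.
#'
#' @param volume a `label_volume`.
#' @param target_voxel target voxel size in nm (> 0).
#' @return A `label_volume` on the target grid covering the same extent.
#' @export
resample_isotropic <- function(volume, target_voxel) {
  stopifnot(inherits(volume, "label_volume"), target_voxel > 0)
  if (all(volume$voxel_size == target_voxel)) return(volume)
  ext <- volume_extent_nm(volume)
  nd <- pmax(1L, as.integer(floor(ext / target_voxel)))
  idx <- lapply(1:3, function(a) {
    centers <- (seq_len(nd[a]) - 0.5) * target_voxel
    pmin(dim(volume$labels)[a], pmax(1L, as.integer(floor(centers / volume$voxel_size[a])) + 1L))
  })
  label_volume(volume$labels[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
               target_voxel, volume$origin)
}

#' Membrane (boundary) mask of a label volume
#'
#' A voxel is membrane iff at least one of its 6 face neighbors carries a
#' different label; out-of-bounds neighbors do not create membrane.  The mask
#' keeps per-voxel ownership (the parent voxel's label).
#'
#' @param volume a `label_volume`.
#' @return An object of class `membrane_mask`: list with `mask` (3D logical),
#'   `owner` (3D integer, label where mask is TRUE, 0 elsewhere), and the
#'   parent grid metadata.
#' @export
extract_membrane <- function(volume) {
  stopifnot(inherits(volume, "label_volume"))
  d <- dim(volume$labels)
  m <- array(cpp_boundary6(volume$labels, d), d)
  owner <- array(0L, d)
  owner[m] <- volume$labels[m]
  structure(list(mask = m, owner = owner, voxel_size = volume$voxel_size,
                 origin = volume$origin),
            class = "membrane_mask")
}

#' @export
print.membrane_mask <- function(x, ...) {
  cat(sprintf("membrane_mask: %s voxels, %.1f%% membrane\n",
              paste(dim(x$mask), collapse = " x "),
              100 * mean(x$mask)))
  invisible(x)
}
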