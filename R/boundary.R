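#' Project a fine-grid label volume onto the confocal image grid
#'
#' The image grid keeps the lateral pitch of the fine grid and samples one
#' plane per `z_step`, at the same plane positions the renderer samples.
#'
#' @param volume isotropic fine-grid `label_volume`.
#' @param z_step image z step in nm.
#' @return anisotropic `label_volume` on the image grid.
#' @export
project_to_image_grid <- function(volume, z_step = 120) {
  vs <- volume$voxel_size[1]
  ratio <- max(1L, as.integer(round(z_step / vs)))
  d <- dim(volume$labels)
  nz_img <- max(1L, d[3] %/% ratio)           # one plane per complete z bin
  zsel <- pmin((seq_len(nz_img) - 1L) * ratio + ceiling(ratio / 2), d[3])
  label_volume(volume$labels[, , zsel, drop = FALSE],
               c(vs, vs, ratio * vs), volume$origin)
}

#' Ground-truth boundary map on the image grid
#'
#' The fine-grid membrane mask (6-connectivity) max-pooled into each
#' anisotropic image voxel: an image voxel is boundary if any fine voxel in
#' its z-bin is membrane.
#'
#' @param volume isotropic fine-grid `label_volume`.
#' @param z_step image z step in nm.
#' @return 3D logical array on the image grid.
#' @export
boundary_on_image_grid <- function(volume, z_step = 120) {
  vs <- volume$voxel_size[1]
  ratio <- max(1L, as.integer(round(z_step / vs)))
  m <- extract_membrane(volume)$mask
  d <- dim(m)
  nz_img <- d[3] %/% ratio
  if (nz_img < 1) nz_img <- 1L
  out <- array(FALSE, c(d[1], d[2], nz_img))
  for (k in seq_len(nz_img)) {
    zbin <- ((k - 1) * ratio + 1):min(k * ratio, d[3])
    out[, , k] <- apply(m[, , zbin, drop = FALSE], c(1, 2), any)
  }
  out
}

# the 8 axial flips/rotations of a patch (x/y dihedral group); op in 0..7
dihedral_xy <- function(patch, op) {
  if (op %/% 4 == 1) patch <- patch[dim(patch)[1]:1, , , drop = FALSE]
  r <- op %% 4
  for (i in seq_len(r)) {
    patch <- aperm(patch, c(2, 1, 3))
    patch <- patch[dim(patch)[1]:1, , , drop = FALSE]
  }
  patch
}

# augmentation group for a patch shape: full dihedral group for square
# in-plane patches, axis flips only for rectangular ones
n_augment_ops <- function(patch_shape) if (patch_shape[1] == patch_shape[2]) 8L else 4L

augment_patch <- function(patch, op, square) {
  if (square) return(dihedral_xy(patch, op))
  if (op %% 2L == 1L) patch <- patch[dim(patch)[1]:1, , , drop = FALSE]
  if (op %/% 2L == 1L) patch <- patch[, dim(patch)[2]:1, , drop = FALSE]
  patch
}

#' Build a balanced patch sampler from simulated stacks and ground truth
#'
#' Yields center-labeled patches sampled uniformly from the training stacks,
#' balanced 1:1 between boundary and non-boundary center voxels (matching
#' the class-imbalance handling of patch sampling), augmented by the 8 axial
#' flips/rotations.
#'
#' @param stacks list of `image_stack` (or 3D arrays).
#' @param gts list of fine-grid ground-truth `label_volume`s, parallel to
#'   `stacks`.
#' @param patch_shape patch size (x, y, z-slices).
#' @param slice_stride z-slice sampling stride.
#' @param orientation "xy" (native axes) or "xz/yz" (volumes permuted so a
#'   lateral axis becomes the slice axis; both permutations are pooled).
#' @param augment apply random dihedral augmentation (default TRUE).
#' @param normalize divide each stack by its max (default TRUE).
#' @return a sampler: list with `sample(n)` returning `patches` (list of 4D
#'   arrays) and `labels` (0/1), plus `volumes` metadata.
#' @export
make_training_set <- function(stacks, gts, patch_shape, slice_stride = 1L,
                              orientation = c("xy", "xz/yz"),
                              augment = TRUE, normalize = TRUE) {
  orientation <- match.arg(orientation)
  # xz view: (x, z, y); yz view: (y, z, x) -- the thin z axis always becomes
  # the second in-plane axis, the remaining lateral axis the slice axis
  perms <- if (orientation == "xy") list(c(1L, 2L, 3L))
           else list(c(1L, 3L, 2L), c(2L, 3L, 1L))
  px <- patch_shape[1]; py <- patch_shape[2]; pz <- patch_shape[3]
  rfz <- (pz - 1L) * slice_stride + 1L
  vols <- list()
  for (i in seq_along(stacks)) {
    arr <- if (inherits(stacks[[i]], "image_stack")) stacks[[i]]$data else stacks[[i]]
    if (normalize && max(arr) > 0) arr <- arr / max(arr)
    zs <- if (inherits(stacks[[i]], "image_stack")) stacks[[i]]$z_step else 120
    bnd <- boundary_on_image_grid(gts[[i]], zs)
    stopifnot(identical(dim(arr), dim(bnd)))
    for (pm in perms) {
      a <- aperm(arr, pm); b <- aperm(bnd, pm)
      # mirror-pad any axis too small to host a patch
      need <- pmax(0L, c(px, py, rfz) + 2L - dim(a))
      if (any(need > 0)) {
        bef <- need %/% 2L; aft <- need - bef
        a <- pad_reflect(a, bef, aft)
        b <- array(pad_reflect(b + 0, bef, aft) > 0, dim(a))
      }
      vols[[length(vols) + 1]] <- list(img = a, bnd = b)
    }
  }
  # valid center positions per volume and class
  centers <- lapply(vols, function(v) {
    d <- dim(v$img)
    ox <- (px - 1L) %/% 2L; oy <- (py - 1L) %/% 2L; oz <- ((pz - 1L) %/% 2L) * slice_stride
    valid <- array(FALSE, d)
    valid[(ox + 1):(d[1] - (px - 1L - ox)), (oy + 1):(d[2] - (py - 1L - oy)),
          (oz + 1):(d[3] - (rfz - 1L - oz))] <- TRUE
    list(pos = which(valid & v$bnd), neg = which(valid & !v$bnd),
         offset = c(ox, oy, oz))
  })
  if (any(vapply(centers, function(cc) length(cc$pos) == 0 || length(cc$neg) == 0, logical(1))))
    stop("insufficient boundary (or non-boundary) voxels to sample patches")
  square <- px == py
  n_ops <- n_augment_ops(patch_shape)
  sample_fun <- function(n) {
    labels <- integer(n)
    labels[seq_len(n) %% 2L == 1L] <- 1L     # strict 1:1 balance
    x <- array(0, c(px, py, pz, 1L, n))
    for (i in seq_len(n)) {
      vi <- sample.int(length(vols), 1)
      cc <- centers[[vi]]
      pool <- if (labels[i] == 1L) cc$pos else cc$neg
      ctr <- arrayInd(pool[sample.int(length(pool), 1)], dim(vols[[vi]]$img))
      corner <- as.integer(ctr) - cc$offset
      p <- vols[[vi]]$img[corner[1]:(corner[1] + px - 1L),
                          corner[2]:(corner[2] + py - 1L),
                          seq.int(corner[3], by = slice_stride, length.out = pz),
                          drop = FALSE]
      if (augment) p <- augment_patch(p, sample.int(n_ops, 1) - 1L, square)
      x[, , , 1L, i] <- p
    }
    list(x = x, labels = labels)
  }
  list(sample = sample_fun, volumes = vols, centers = centers,
       patch_shape = patch_shape, slice_stride = slice_stride)
}

#' Train the boundary detector: 2D pretraining, then 3D fine-tuning
#'
#' Implements the two-stage protocol: a 2D network (same architecture with
#' depth-1 kernels) is trained first; its convolution weights initialize the
#' matching layers of the 3D network, which is then fine-tuned.  Two such
#' detectors are trained: one on native xy patches and one on axis-permuted
#' xz/yz patches.
#'
#' @param stacks,gts training stacks and fine-grid ground truths.
#' @param config_fn function(dims) returning a `net_config` for "2d"/"3d"
#'   (default [net_config_small()]).
#' @param ortho_config_fn like `config_fn` but for the axis-permuted xz/yz
#'   orientations; defaults to [net_config_small_ortho()] when `config_fn`
#'   is the small preset, else to `config_fn`.
#' @param iterations_2d,iterations_3d SGD steps per stage.
#' @param lr,momentum,batch optimizer settings (defaults 0.001 / 0.9 / 100).
#' @param seed integer seed; the whole procedure is reproducible.
#' @param orientations train the xz/yz companion net too (default TRUE).
#' @return list with `net_xy`, `net_xzyz` (or NULL), and the 2D nets and loss
#'   traces in attributes.
#' @export
train_2d_then_3d <- function(stacks, gts, config_fn = net_config_small,
                             ortho_config_fn = NULL,
                             iterations_2d = 60, iterations_3d = 60,
                             lr = 0.001, momentum = 0.9, batch = 100,
                             seed = 1, orientations = TRUE) {
  if (is.null(ortho_config_fn))
    ortho_config_fn <- if (identical(config_fn, net_config_small))
      net_config_small_ortho else config_fn
  train_one <- function(orient, cfg_fn, sd) {
    cfg2 <- cfg_fn("2d"); cfg3 <- cfg_fn("3d")
    sampler <- make_training_set(stacks, gts, cfg2$patch_shape,
                                 cfg2$slice_stride, orientation = orient)
    net2 <- build_convnet(cfg2, seed = sd)
    net2 <- train_net(net2, sampler, iterations_2d, lr, momentum, batch,
                      seed = sd + 1L)
    net3 <- build_convnet(cfg3, seed = sd + 2L)
    net3 <- transfer_weights(net3, net2)
    net3 <- train_net(net3, sampler, iterations_3d, lr, momentum, batch,
                      seed = sd + 3L)
    list(net3 = net3, net2 = net2)
  }
  xy <- train_one("xy", config_fn, as.integer(seed))
  out <- list(net_xy = xy$net3, net_xzyz = NULL)
  attr(out, "net2d_xy") <- xy$net2
  if (orientations) {
    pz <- train_one("xz/yz", ortho_config_fn, as.integer(seed) + 100L)
    out$net_xzyz <- pz$net3
    attr(out, "net2d_xzyz") <- pz$net2
  }
  out
}

#' Boundary probability map from a stack
#'
#' Dense inference in the xy orientation plus (when the xz/yz net is
#' supplied) in the two permuted orientations; the three maps are combined
#' by voxelwise median, then smoothed with a 3D median filter.
#'
#' @param stack an `image_stack` or 3D array.
#' @param nets output of [train_2d_then_3d()] (or a list with `net_xy` and
#'   optionally `net_xzyz`).
#' @param median_filter_size 3D median window (default 3; 0 disables).
#' @param normalize divide the stack by its max before inference (must match
#'   training; default TRUE).
#' @return object of class `bpm`: list with `prob` (3D array in \[0,1\]) and
#'   `provenance` (which orientations contributed).
#' @export
infer_bpm <- function(stack, nets, median_filter_size = 3, normalize = TRUE) {
  arr <- if (inherits(stack, "image_stack")) stack$data else stack
  if (normalize && max(arr) > 0) arr <- arr / max(arr)
  maps <- list(xy = predict_dense(nets$net_xy, arr))
  if (!is.null(nets$net_xzyz)) {
    # views match the training permutations: xz = (x, z, y), yz = (y, z, x)
    m_xz <- aperm(predict_dense(nets$net_xzyz, aperm(arr, c(1, 3, 2))), c(1, 3, 2))
    m_yz <- aperm(predict_dense(nets$net_xzyz, aperm(arr, c(2, 3, 1))), c(3, 1, 2))
    maps$xz <- m_xz; maps$yz <- m_yz
  }
  prob <- if (length(maps) == 1) maps[[1]] else {
    # vectorized median of three
    a <- maps[[1]]; b <- maps[[2]]; c3 <- maps[[3]]
    a + b + c3 - pmax(a, b, c3) - pmin(a, b, c3)
  }
  if (median_filter_size > 0)
    prob <- array(cpp_median3d(prob, dim(prob), rep(as.integer(median_filter_size), 3)),
                  dim(prob))
  prob[prob < 0] <- 0; prob[prob > 1] <- 1
  structure(list(prob = prob, provenance = names(maps)), class = "bpm")
}
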