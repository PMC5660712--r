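#' Boundary-detector network configuration
#'
#' Describes a patch-classifying convolutional network: a stack of valid
#' (un-padded) convolution layers with ReLU activations, max-pooling layers,
#' and trailing fully-connected layers (realized as convolutions whose kernel
#' covers the remaining feature-map extent), ending in a 2-way softmax
#' (boundary / non-boundary of the patch's center voxel).
#'
#' `patch_shape` gives the input patch in (x, y, z-slices); `slice_stride`
#' subsamples z so that `pz` slices span `(pz-1)*slice_stride + 1` planes of
#' the stack, providing wider volumetric context without redundant planes.
#'
#' @param layers list of layer specs from `conv_spec()` / `pool_spec()` /
#'   `fc_spec()`.
#' @param patch_shape integer length-3.
#' @param slice_stride z-slice sampling stride (default 1).
#' @return object of class `net_config`.
#' @export
net_config <- function(layers, patch_shape, slice_stride = 1L) {
  structure(list(layers = layers, patch_shape = as.integer(patch_shape),
                 slice_stride = as.integer(slice_stride)),
            class = "net_config")
}

#' @rdname net_config
#' @param kernel conv kernel size (x, y, z).
#' @param out output channel width.
#' @export
conv_spec <- function(kernel, out) list(type = "conv", kernel = as.integer(kernel), out = as.integer(out))

#' @rdname net_config
#' @param size pooling window (x, y, z).
#' @export
pool_spec <- function(size = c(2, 2, 1)) list(type = "pool", size = as.integer(size))

#' @rdname net_config
#' @export
fc_spec <- function(out) list(type = "fc", out = as.integer(out))

#' Compact preset for CPU-scale runs
#'
#' Four convolution layers (widths 8-8-12-12), one max-pooling layer, two
#' fully-connected layers and softmax; 19 x 19 x 5 patches with consecutive
#' slices (odd extent, so the center voxel is preserved by the dihedral
#' augmentation).  The `dims` argument selects the 2D-pretraining variant
#' (all conv kernels depth 1) or the 3D variant (last conv layer depth 3).
#'
#' @param dims "2d" or "3d".
#' @param widths channel widths of the four conv layers.
#' @param fc width of the first fully-connected layer.
#' @return a `net_config`.
#' @export
net_config_small <- function(dims = c("3d", "2d"), widths = c(8, 8, 12, 12),
                             fc = 24) {
  dims <- match.arg(dims)
  kz <- if (dims == "3d") 3L else 1L
  net_config(list(
    conv_spec(c(3, 3, 1), widths[1]),
    conv_spec(c(3, 3, 1), widths[2]),
    pool_spec(c(3, 3, 1)),
    conv_spec(c(3, 3, 1), widths[3]),
    conv_spec(c(3, 3, kz), widths[4]),
    fc_spec(fc),
    fc_spec(2)
  ), patch_shape = c(19, 19, 5), slice_stride = 1L)
}

#' Compact preset for the xz / yz orientations
#'
#' Companion to [net_config_small()] for axis-permuted stacks, whose second
#' in-plane axis is the (thin) z axis: the patch is 19 voxels along the
#' lateral axis but only 5 along z, so it fits inside a shallow stack
#' without excessive mirror padding.  Same layer count and widths as the xy
#' preset; pooling only along the lateral axis.
#'
#' @param dims "2d" or "3d".
#' @param widths channel widths of the four conv layers.
#' @param fc width of the first fully-connected layer.
#' @return a `net_config`.
#' @export
net_config_small_ortho <- function(dims = c("3d", "2d"), widths = c(8, 8, 12, 12),
                                   fc = 24) {
  dims <- match.arg(dims)
  kz <- if (dims == "3d") 3L else 1L
  net_config(list(
    conv_spec(c(3, 3, 1), widths[1]),
    conv_spec(c(3, 3, 1), widths[2]),
    pool_spec(c(3, 1, 1)),
    conv_spec(c(3, 1, 1), widths[3]),
    conv_spec(c(3, 1, kz), widths[4]),
    fc_spec(fc),
    fc_spec(2)
  ), patch_shape = c(19, 5, 5), slice_stride = 1L)
}

#' Full-scale preset
#'
#' Nine convolution layers, three max-pooling layers (after conv 2, 4, 6),
#' two fully-connected layers and softmax, ReLU throughout; 85 x 85 x 7
#' patches sampling every third z-slice.  Channel widths follow the VD2D3D
#' lineage (24-24-36-36-48-48-60-60-100).  Only the last convolution layer
#' is depth-3 in the 3D variant; the 2D-pretraining variant uses depth-1
#' kernels everywhere, and transfer copies the eight matching conv layers.
#'
#' @param dims "2d" or "3d".
#' @return a `net_config`.
#' @export
net_config_full <- function(dims = c("3d", "2d")) {
  dims <- match.arg(dims)
  kz <- if (dims == "3d") 3L else 1L
  w <- c(24, 24, 36, 36, 48, 48, 60, 60, 100)
  layers <- list()
  for (i in 1:9) {
    layers <- c(layers, list(conv_spec(c(3, 3, if (i == 9) kz else 1), w[i])))
    if (i %in% c(2, 4, 6)) layers <- c(layers, list(pool_spec(c(2, 2, 1))))
  }
  layers <- c(layers, list(fc_spec(200), fc_spec(2)))
  net_config(layers, patch_shape = c(85, 85, 7), slice_stride = 3L)
}

# He-style initialization
init_w <- function(dims) {
  fan_in <- prod(dims[1:4])
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

#' Instantiate a network from a configuration
#'
#' Resolves fully-connected layers to convolutions over the remaining
#' feature-map extent, initializes weights (He normal), and records the
#' receptive field.
#'
#' @param config a `net_config`.
#' @param in_channels input channels (default 1).
#' @param seed optional integer seed for the initialization.
#' @return object of class `convnet`.
#' @export
build_convnet <- function(config, in_channels = 1L, seed = NULL) {
  run <- function() {
    shape <- config$patch_shape
    ci <- as.integer(in_channels)
    layers <- list()
    nconv <- 0L
    specs <- config$layers
    for (si in seq_along(specs)) {
      s <- specs[[si]]
      if (s$type == "pool") {
        shape <- (shape - 1L - (s$size - 1L)) %/% s$size + 1L
        layers[[length(layers) + 1]] <- list(type = "pool", size = s$size)
        next
      }
      kernel <- if (s$type == "fc") {
        if (any(shape < 1)) stop("patch too small for the layer stack")
        k <- shape; shape <- c(1L, 1L, 1L); k
      } else {
        shape <- shape - (s$kernel - 1L)
        if (any(shape < 1)) stop("patch too small for the layer stack")
        s$kernel
      }
      nconv <- nconv + 1L
      is_last <- si == length(specs)
      layers[[length(layers) + 1]] <- list(
        type = "conv", w = init_w(c(kernel, ci, s$out)), b = numeric(s$out),
        relu = !is_last, conv_index = nconv, is_fc = s$type == "fc")
      ci <- s$out
    }
    if (!all(shape == 1L)) stop("patch_shape does not reduce to a single output")
    structure(list(layers = layers, config = config), class = "convnet")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Receptive field of a network in stack voxels
#'
#' @param net a `convnet`.
#' @return list with `rf` (x, y, z extent in stack voxels, accounting for the
#'   slice stride) and `offset` (0-based corner-to-center offset).
#' @export
net_receptive_field <- function(net) {
  p <- net$config$patch_shape
  s <- net$config$slice_stride
  rf <- c(p[1], p[2], (p[3] - 1L) * s + 1L)
  offset <- c((p[1] - 1L) %/% 2L, (p[2] - 1L) %/% 2L, ((p[3] - 1L) %/% 2L) * s)
  list(rf = rf, offset = offset)
}

# Forward pass.  x: 4D array (x, y, z, c).  dense = FALSE evaluates a patch
# (pooling stride = window); dense = TRUE evaluates every position via
# stride-1 pooling with accumulated dilation (max-pooling fragmentation),
# exactly equivalent to sliding the patch window over the volume.
net_forward <- function(net, x, dense = FALSE, base_dil = c(1L, 1L, 1L),
                        keep = FALSE) {
  dil <- as.integer(base_dil)
  caches <- if (keep) vector("list", length(net$layers)) else NULL
  for (li in seq_along(net$layers)) {
    l <- net$layers[[li]]
    if (l$type == "pool") {
      if (dense) {
        res <- cpp_maxpool_fwd(x, dim(x), l$size, c(1L, 1L, 1L), dil)
        dil <- dil * l$size
      } else {
        res <- cpp_maxpool_fwd(x, dim(x), l$size, l$size, c(1L, 1L, 1L))
      }
      if (keep) caches[[li]] <- list(xd = dim(x), argmax = res$argmax)
      x <- res$y
    } else {
      use_dil <- if (dense) dil else c(1L, 1L, 1L)
      y <- cpp_conv3d_fwd(x, dim(x), l$w, dim(l$w), l$b, use_dil)
      if (l$relu) {
        mask <- y > 0
        y <- y * mask
        if (keep) caches[[li]] <- list(x = x, mask = mask)
      } else if (keep) caches[[li]] <- list(x = x)
      x <- y
    }
  }
  list(logits = x, caches = caches)
}

# Softmax over the channel (4th) dimension; accepts a trailing batch axis.
softmax4 <- function(logits) {
  d <- dim(logits)
  n1 <- prod(d[1:3])
  nb <- if (length(d) > 4) d[5] else 1L
  m <- array(logits, c(n1, d[4], nb))
  mm <- pmax(m[, 1, ], m[, 2, ])
  e1 <- exp(m[, 1, ] - mm)
  e2 <- exp(m[, 2, ] - mm)
  p2 <- e2 / (e1 + e2)
  out <- array(0, c(n1, 2, nb))
  out[, 1, ] <- 1 - p2
  out[, 2, ] <- p2
  dim(out) <- d
  out
}

# Backward pass for a single patch; returns per-conv-layer gradients.
net_backward <- function(net, caches, glogits) {
  g <- glogits
  grads <- vector("list", length(net$layers))
  for (li in rev(seq_along(net$layers))) {
    l <- net$layers[[li]]
    if (l$type == "pool") {
      g <- cpp_maxpool_bwd(caches[[li]]$xd, caches[[li]]$argmax, g)
    } else {
      if (l$relu) g <- g * caches[[li]]$mask
      r <- cpp_conv3d_bwd(caches[[li]]$x, dim(caches[[li]]$x), l$w, dim(l$w),
                          g, c(1L, 1L, 1L))
      grads[[li]] <- list(gw = r$gw, gb = r$gb)
      g <- r$gx
    }
  }
  grads
}

#' Train a network by SGD with momentum
#'
#' Patchwise stochastic gradient descent on the softmax cross-entropy of the
#' center-voxel boundary label, with the optimizer settings used throughout:
#' learning rate 0.001, momentum 0.9, batch size 100.
#'
#' @param net a `convnet`.
#' @param sampler a patch sampler from [make_training_set()] (its patch shape
#'   must match the net's).
#' @param iterations number of SGD steps.
#' @param lr,momentum,batch optimizer settings.
#' @param seed optional integer seed (sampling is part of the seeded stream).
#' @return the trained `convnet`, with a `loss` attribute (per-iteration
#'   mean cross-entropy).
#' @export
train_net <- function(net, sampler, iterations = 100, lr = 0.001,
                      momentum = 0.9, batch = 100, seed = NULL) {
  run <- function() {
    vel <- lapply(net$layers, function(l)
      if (l$type == "conv") list(w = array(0, dim(l$w)), b = numeric(length(l$b))))
    losses <- numeric(iterations)
    for (it in seq_len(iterations)) {
      pb <- sampler$sample(batch)
      fw <- net_forward(net, pb$x, keep = TRUE)
      p <- softmax4(fw$logits)                  # (1,1,1,2,batch)
      y <- pb$labels                            # 1 = boundary
      pc <- pmax(p[cbind(1, 1, 1, y + 1L, seq_len(batch))], 1e-12)
      losses[it] <- -mean(log(pc))
      if (!is.finite(losses[it])) stop("training diverged (non-finite loss) at iteration ", it)
      gl <- p
      gl[cbind(1, 1, 1, y + 1L, seq_len(batch))] <-
        gl[cbind(1, 1, 1, y + 1L, seq_len(batch))] - 1
      grads <- net_backward(net, fw$caches, gl)
      for (li in seq_along(net$layers)) if (net$layers[[li]]$type == "conv") {
        vel[[li]]$w <- momentum * vel[[li]]$w - lr * grads[[li]]$gw / batch
        vel[[li]]$b <- momentum * vel[[li]]$b - lr * grads[[li]]$gb / batch
        net$layers[[li]]$w <- net$layers[[li]]$w + vel[[li]]$w
        net$layers[[li]]$b <- net$layers[[li]]$b + vel[[li]]$b
      }
    }
    attr(net, "loss") <- losses
    net
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Boundary probability of center voxels for a batch of patches
#'
#' @param net a `convnet`.
#' @param x5 array `(px, py, pz, 1, n)` of patches.
#' @return numeric vector of boundary probabilities, length n.
#' @export
predict_patches <- function(net, x5) {
  p <- softmax4(net_forward(net, x5)$logits)
  as.vector(p[1, 1, 1, 2, ])
}

#' Transfer pretrained 2D convolution weights into a 3D network
#'
#' Copies, bitwise, the weights and biases of every convolution layer whose
#' kernel shape matches between the source (2D-pretrained) and target (3D)
#' networks; depth-changed layers (3x3x1 -> 3x3x3) and the fully-connected
#' layers are left at their fresh initialization.
#'
#' @param net3d target `convnet`.
#' @param net2d source `convnet`.
#' @return `net3d` with transferred weights; the indices of copied conv
#'   layers are recorded in attribute `transferred`.
#' @export
transfer_weights <- function(net3d, net2d) {
  copied <- integer(0)
  for (li in seq_along(net3d$layers)) {
    a <- net3d$layers[[li]]; b <- net2d$layers[[li]]
    if (a$type == "conv" && b$type == "conv" && !a$is_fc &&
        identical(dim(a$w), dim(b$w))) {
      net3d$layers[[li]]$w <- b$w
      net3d$layers[[li]]$b <- b$b
      copied <- c(copied, a$conv_index)
    }
  }
  attr(net3d, "transferred") <- copied
  net3d
}

# Mirror-extend an array along each axis (edge-inclusive reflection, applied
# periodically so pads larger than the axis are allowed).
pad_reflect <- function(arr, before, after) {
  d <- dim(arr)
  idx <- lapply(1:3, function(a) {
    n <- d[a]
    pos <- (1 - before[a]):(n + after[a])
    if (n == 1) return(rep(1L, length(pos)))
    p <- (pos - 1) %% (2 * n - 2)
    as.integer(ifelse(p < n, p + 1, 2 * n - 1 - p))
  })
  arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Dense (sliding-window-equivalent) boundary probability over a volume
#'
#' Evaluates the patch classifier at every voxel of `vol` using dilated
#' convolutions and stride-1 max-pooling (max-pooling fragmentation), which
#' is voxel-exact equivalent to sliding the patch window.  The volume is
#' mirror-padded so the output covers every voxel.
#'
#' @param net a trained `convnet`.
#' @param vol 3D numeric array (one channel).
#' @return 3D array of boundary probabilities in the same shape as `vol`.
#' @export
predict_dense <- function(net, vol) {
  rf <- net_receptive_field(net)
  before <- rf$offset
  after <- rf$rf - 1L - rf$offset
  x <- pad_reflect(vol, before, after)
  dim(x) <- c(dim(x), 1L)
  s <- net$config$slice_stride
  out <- net_forward(net, x, dense = TRUE, base_dil = c(1L, 1L, s))
  p <- softmax4(out$logits)
  array(p[, , , 2], dim(vol))
}

#' Save / load a network checkpoint (portable JSON)
#'
#' @param net a `convnet`.
#' @param path file path.
#' @export
save_convnet <- function(net, path) {
  ser <- list(
    config = list(
      layers = net$config$layers,
      patch_shape = net$config$patch_shape,
      slice_stride = net$config$slice_stride),
    layers = lapply(net$layers, function(l) {
      if (l$type == "pool") list(type = "pool", size = l$size)
      else list(type = "conv", dim = dim(l$w), w = as.vector(l$w), b = l$b,
                relu = l$relu, conv_index = l$conv_index, is_fc = l$is_fc)
    }))
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_convnet
#' @export
load_convnet <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  cfg <- net_config(
    lapply(ser$config$layers, function(s) {
      s$type <- as.character(s$type)
      if (!is.null(s$kernel)) s$kernel <- as.integer(s$kernel)
      if (!is.null(s$out)) s$out <- as.integer(s$out)
      if (!is.null(s$size)) s$size <- as.integer(s$size)
      s
    }),
    as.integer(ser$config$patch_shape), as.integer(ser$config$slice_stride))
  layers <- lapply(ser$layers, function(l) {
    if (l$type == "pool") list(type = "pool", size = as.integer(unlist(l$size)))
    else list(type = "conv",
              w = array(as.numeric(unlist(l$w)), as.integer(unlist(l$dim))),
              b = as.numeric(unlist(l$b)), relu = isTRUE(l$relu),
              conv_index = as.integer(l$conv_index), is_fc = isTRUE(l$is_fc))
  })
  structure(list(layers = layers, config = cfg), class = "convnet")
}
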