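# toy stack with bright membranes on a dark interior, isotropic z for speed
toy_task <- function(shape = c(40, 40, 40), seed = 5, noise = 0) {
  gt <- generate_ground_truth(shape, 6, list(count = 4, radius_range = c(40, 120)),
                              seed = seed)
  bnd <- extract_membrane(gt)$mask
  img <- array(0.1, dim(bnd)); img[bnd] <- 0.9
  if (noise > 0) img <- pmax(img + array(rnorm(length(img), 0, noise), dim(img)), 0)
  list(gt = gt, stack = image_stack(img, 6, 6))
}

test_that("patch sampler balances classes and is seed-reproducible", {
  tk <- toy_task()
  sampler <- make_training_set(list(tk$stack), list(tk$gt), c(13, 13, 3), 1)
  set.seed(1)
  pb <- sampler$sample(10000)
  expect_equal(mean(pb$labels), 0.5, tolerance = 0.02)
  # labels match the center voxel of the (normalized) patch
  ctr <- pb$x[7, 7, 2, 1, ]
  expect_true(all((ctr > 0.5) == (pb$labels == 1)))
  set.seed(42); a <- sampler$sample(50)
  set.seed(42); b <- sampler$sample(50)
  expect_identical(a, b)
  expect_error(make_training_set(list(tk$stack),
                                 list(label_volume(array(1L, dim(tk$gt$labels)), 6)),
                                 c(13, 13, 3), 1),
               "insufficient")
})

test_that("dihedral augmentation is closed under a further rotation", {
  set.seed(2)
  p <- array(rnorm(9 * 9 * 3), c(9, 9, 3))
  aug <- lapply(0:7, function(op) exmrecon:::dihedral_xy(p, op))
  rot <- lapply(aug, function(q) exmrecon:::dihedral_xy(q, 1))
  for (q in rot)
    expect_true(any(vapply(aug, function(a) identical(a, q), logical(1))))
  # center voxel preserved by every op
  for (q in aug) expect_identical(q[5, 5, 2], p[5, 5, 2])
})

test_that("2D-to-3D transfer copies matching conv layers bitwise", {
  net2 <- build_convnet(net_config_small("2d"), seed = 1)
  net3 <- build_convnet(net_config_small("3d"), seed = 2)
  net3t <- transfer_weights(net3, net2)
  copied <- attr(net3t, "transferred")
  expect_identical(copied, 1:3)   # conv4 changes depth; fc layers re-resolved
  for (li in seq_along(net3t$layers)) {
    l3 <- net3t$layers[[li]]; l2 <- net2$layers[[li]]
    if (l3$type == "conv" && l3$conv_index %in% copied) {
      expect_identical(l3$w, l2$w)
      expect_identical(l3$b, l2$b)
    }
  }
  # depth-changed layer keeps its fresh (different-shaped) weights
  expect_false(identical(dim(net3t$layers[[5]]$w), dim(net2$layers[[5]]$w)))
})

test_that("dense inference equals sliding-window patch evaluation voxel-exactly", {
  for (mk in list(net_config_small, net_config_small_ortho)) {
    net <- build_convnet(mk("3d"), seed = 3)
    set.seed(10)
    vol <- array(runif(27 * 25 * 8), c(27, 25, 8))
    dense <- predict_dense(net, vol)
    expect_equal(dim(dense), dim(vol))
    rf <- net_receptive_field(net)
    x <- exmrecon:::pad_reflect(vol, rf$offset, rf$rf - 1L - rf$offset)
    ps <- net$config$patch_shape
    for (i in c(1, 9, 17)) for (j in c(2, 11)) for (k in c(1, 4)) {
      p <- x[i:(i + ps[1] - 1), j:(j + ps[2] - 1), k:(k + ps[3] - 1), drop = FALSE]
      dim(p) <- c(dim(p), 1L, 1L)
      expect_equal(predict_patches(net, p), dense[i, j, k], tolerance = 1e-12)
    }
  }
})

test_that("dense inference with slice stride matches strided sliding windows", {
  cfg <- net_config(list(conv_spec(c(3, 3, 1), 4), conv_spec(c(3, 3, 3), 4),
                         fc_spec(8), fc_spec(2)),
                    c(7, 7, 3), slice_stride = 3L)
  net <- build_convnet(cfg, seed = 5)
  set.seed(6)
  vol <- array(runif(16 * 16 * 12), c(16, 16, 12))
  dn <- predict_dense(net, vol)
  rf <- net_receptive_field(net)
  expect_equal(rf$rf[3], 7)          # 3 slices at stride 3
  x <- exmrecon:::pad_reflect(vol, rf$offset, rf$rf - 1L - rf$offset)
  for (i in c(1, 9)) for (k in c(1, 6)) {
    p <- x[i:(i + 6), 3:9, seq(k, by = 3, length.out = 3), drop = FALSE]
    dim(p) <- c(dim(p), 1L, 1L)
    expect_equal(predict_patches(net, p), dn[i, 3, k], tolerance = 1e-12)
  }
})

test_that("backpropagation matches numeric gradients", {
  set.seed(7)
  cfg <- tiny_net_config("3d", widths = c(4, 4), fc = 6)
  nt <- build_convnet(cfg, seed = 7)
  x <- array(rnorm(prod(cfg$patch_shape) * 2), c(cfg$patch_shape, 1, 2))
  y <- c(1L, 0L)
  fw <- exmrecon:::net_forward(nt, x, keep = TRUE)
  p0 <- exmrecon:::softmax4(fw$logits)
  loss0 <- -sum(log(p0[cbind(1, 1, 1, y + 1, 1:2)]))
  gl <- p0
  for (b in 1:2) gl[1, 1, 1, y[b] + 1, b] <- gl[1, 1, 1, y[b] + 1, b] - 1
  gr <- exmrecon:::net_backward(nt, fw$caches, gl)
  eps <- 1e-6
  for (li in seq_along(nt$layers)) {
    if (nt$layers[[li]]$type != "conv") next
    set.seed(li)
    for (ii in sample(length(nt$layers[[li]]$w), 3)) {
      num <- nt
      num$layers[[li]]$w[ii] <- num$layers[[li]]$w[ii] + eps
      p1 <- exmrecon:::softmax4(exmrecon:::net_forward(num, x)$logits)
      l1 <- -sum(log(p1[cbind(1, 1, 1, y + 1, 1:2)]))
      g_num <- (l1 - loss0) / eps
      expect_equal(gr[[li]]$gw[ii], g_num, tolerance = 1e-3)
    }
  }
})

test_that("training learns a separable boundary task; equivariance follows", {
  tk <- toy_task()
  cfg2 <- tiny_net_config("2d")
  sampler <- make_training_set(list(tk$stack), list(tk$gt), cfg2$patch_shape, 1)
  net <- build_convnet(cfg2, seed = 1)
  net <- train_net(net, sampler, iterations = 800, batch = 100, seed = 9)
  l <- attr(net, "loss")
  expect_lt(mean(tail(l, 20)), mean(head(l, 20)))
  set.seed(30)
  pb <- sampler$sample(800)
  pr <- predict_patches(net, pb$x)
  expect_gt(mean((pr > 0.5) == (pb$labels == 1)), 0.95)

  # with symmetric augmentation, 90-degree rotation changes the map little
  vol <- tk$stack$data[1:24, 1:24, 1:6]
  a <- predict_dense(net, vol)
  rot <- function(v) aperm(v, c(2, 1, 3))[dim(v)[2]:1, , , drop = FALSE]
  unrot <- function(v) aperm(v[dim(v)[1]:1, , , drop = FALSE], c(2, 1, 3))
  b <- unrot(predict_dense(net, rot(vol)))
  expect_lt(mean(abs(a - b)), 0.05)

  # reproducibility under a fixed seed
  net_b <- build_convnet(cfg2, seed = 1)
  net_b <- train_net(net_b, sampler, iterations = 5, batch = 20, seed = 9)
  net_c <- build_convnet(cfg2, seed = 1)
  net_c <- train_net(net_c, sampler, iterations = 5, batch = 20, seed = 9)
  expect_identical(net_b$layers, net_c$layers)
})

test_that("BPM combination: median of identical maps, bounded output", {
  net <- build_convnet(tiny_net_config("3d"), seed = 2)
  set.seed(4)
  vol <- array(runif(20 * 20 * 6), c(20, 20, 6))
  nets1 <- list(net_xy = net, net_xzyz = NULL)
  b1 <- infer_bpm(vol, nets1, median_filter_size = 0)
  expect_true(all(b1$prob >= 0 & b1$prob <= 1))
  expect_identical(b1$provenance, "xy")
  # median of three identical maps equals the map
  m <- b1$prob
  med <- m + m + m - pmax(m, m, m) - pmin(m, m, m)
  expect_equal(med, m)
})

test_that("network checkpoints round-trip through JSON", {
  net <- build_convnet(tiny_net_config("3d"), seed = 6)
  path <- tempfile(fileext = ".json")
  save_convnet(net, path)
  net2 <- load_convnet(path)
  expect_equal(net2$layers, net$layers, tolerance = 1e-12)
  expect_equal(net2$config$patch_shape, net$config$patch_shape)
  set.seed(1)
  vol <- array(runif(16 * 16 * 5), c(16, 16, 5))
  expect_equal(predict_dense(net2, vol), predict_dense(net, vol), tolerance = 1e-12)
})

test_that("inference rejects inputs smaller than the receptive field", {
  net <- build_convnet(tiny_net_config("3d"), seed = 1)
  expect_error(exmrecon:::net_forward(net, array(0, c(4, 4, 2, 1))), "smaller")
})
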