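test_that("constant BPM floods to a single supervoxel", {
  sv <- oversegment(array(0.4, c(10, 10, 4)), 0.01)
  expect_equal(sv$count, 1)
  expect_true(all(sv$labels == 1L))
})

test_that("H-minima separates or merges basins exactly at the depth threshold", {
  # deep basins: ridge 0.8, floors 0.1 -> two supervoxels
  b <- two_basin_bpm(12, ridge = 0.8, floor1 = 0.1, floor2 = 0.1)
  expect_equal(oversegment(b, 0.01)$count, 2)
  # the dividing minimum shallower than h -> single supervoxel
  b2 <- two_basin_bpm(12, ridge = 0.105, floor1 = 0.1, floor2 = 0.1)
  expect_equal(oversegment(b2, 0.01)$count, 1)
  # exhaustive minima enumeration oracle on the deep landscape
  hm <- -exmrecon:::cpp_reconstruct_dilation(-(b + 0.01), -b, dim(b))
  mins <- exmrecon:::cpp_regional_minima(hm, dim(b))
  expect_equal(max(mins), 2)
})

test_that("supervoxel count is non-increasing in the H-minima depth", {
  set.seed(5)
  f <- array(runif(18 * 18 * 6), c(18, 18, 6))
  f <- array(exmrecon:::cpp_median3d(f, dim(f), c(3L, 3L, 3L)), dim(f))
  counts <- vapply(c(0.001, 0.01, 0.05, 0.2, 0.5),
                   function(h) oversegment(f, h)$count, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("watershed assigns every voxel and respects ridges deeper than h", {
  b <- two_basin_bpm(16, ridge = 0.9)
  sv <- oversegment(b, 0.01)
  expect_true(all(sv$labels > 0))
  # no supervoxel spans both basins
  left <- unique(as.vector(sv$labels[1:6, , ]))
  right <- unique(as.vector(sv$labels[11:16, , ]))
  expect_length(intersect(left, right), 0)
  expect_error(oversegment(array(1.5, c(8, 8, 2))), "\\[0, 1\\]")
})

test_that("edge features are symmetric in the two bodies and fixed-length", {
  set.seed(2)
  lab <- array(1L, c(12, 12, 4)); lab[7:12, , ] <- 2L
  v1 <- array(runif(prod(dim(lab))), dim(lab))
  v2 <- array(runif(prod(dim(lab))), dim(lab))
  E <- exmrecon:::cpp_edge_stats(lab, dim(lab), v1, v2, 10L)
  bodies <- exmrecon:::cpp_body_stats(lab, v1, v2, 2L, 10L)
  fab <- exmrecon:::edge_features(exmrecon:::edge_stat_vec(E[1, ]),
                                  bodies[1, ], bodies[2, ])
  fba <- exmrecon:::edge_features(exmrecon:::edge_stat_vec(E[1, ]),
                                  bodies[2, ], bodies[1, ])
  expect_identical(fab, fba)
  expect_length(fab, length(exmrecon:::edge_feature_names()))
  # contact area equals the shared-face count
  expect_equal(E[1, 3], 12 * 4)
})

test_that("merge policy separates true and false edges when the BPM is exact", {
  set.seed(3)
  gt <- tiny_gt(c(40, 40, 40), count = 5, seed = 21, radius_range = c(40, 120))
  bnd <- extract_membrane(gt)$mask
  bpm <- array(0.05 + 0.9 * bnd, dim(bnd))
  sv <- oversegment(bpm, 0.01, c(6, 6, 6))
  expect_gt(sv$count, 5)
  gimg <- label_volume(gt$labels, c(6, 6, 6))
  pol <- train_merge_policy(sv, bpm, bpm, gimg, ntree = 60, seed = 2)
  # held-out volume
  gt2 <- tiny_gt(c(40, 40, 40), count = 5, seed = 22, radius_range = c(40, 120))
  bnd2 <- extract_membrane(gt2)$mask
  bpm2 <- array(0.05 + 0.9 * bnd2, dim(bnd2))
  sv2 <- oversegment(bpm2, 0.01, c(6, 6, 6))
  E <- exmrecon:::cpp_edge_stats(sv2$labels, dim(sv2$labels), bpm2, bpm2, 10L)
  bodies <- exmrecon:::cpp_body_stats(sv2$labels, bpm2, bpm2, sv2$count, 10L)
  own <- exmrecon:::majority_owner(sv2$labels, gt2$labels, sv2$count)
  y <- own[E[, 1]] == own[E[, 2]]
  p <- exmrecon:::policy_prob(pol, exmrecon:::features_for_edges(E, bodies))
  expect_gt(rank_auc(p, y), 0.9)
  # determinism of training under a fixed seed
  pol2 <- train_merge_policy(sv, bpm, bpm, gimg, ntree = 60, seed = 2)
  p2 <- exmrecon:::policy_prob(pol2, exmrecon:::features_for_edges(E, bodies))
  expect_identical(p, p2)
})

test_that("hierarchy levels are nested partitions that coarsen with threshold", {
  set.seed(4)
  gt <- tiny_gt(c(32, 32, 32), count = 4, seed = 13)
  bnd <- extract_membrane(gt)$mask
  bpm <- pmin(pmax(array(bnd + rnorm(length(bnd), 0, 0.1), dim(bnd)), 0), 1)
  sv <- oversegment(bpm, 0.01, c(6, 6, 6))
  own <- exmrecon:::majority_owner(sv$labels, gt$labels, sv$count)
  tree <- build_hierarchy(sv, oracle_policy(own), bpm, bpm)
  sizes <- table(factor(sv$labels, 1:sv$count))
  prev <- NULL
  nseg <- c()
  for (t in seq(0.1, 0.9, by = 0.1)) {
    lev <- tree_level(tree, t)
    nseg <- c(nseg, length(unique(lev)))
    # partition: voxel counts are conserved through the mapping
    agg <- rowsum(as.vector(sizes), lev)
    expect_equal(sum(agg), prod(dim(bpm)))
    if (!is.null(prev)) {
      # nesting: the previous (finer) level refines the current one
      expect_true(all(tapply(lev, prev, function(v) length(unique(v))) == 1))
    }
    prev <- lev
  }
  expect_true(all(diff(nseg) <= 0))
})

test_that("a perfect policy recovers ground truth at mid thresholds", {
  # 4 supervoxels, 2 ground-truth neurons
  lab <- array(0L, c(8, 8, 2))
  lab[1:4, 1:4, ] <- 1L; lab[5:8, 1:4, ] <- 2L
  lab[1:4, 5:8, ] <- 3L; lab[5:8, 5:8, ] <- 4L
  sv <- structure(list(labels = lab, count = 4L, voxel_size = c(6, 6, 6)),
                  class = "supervoxels")
  own <- c(1L, 1L, 2L, 2L)   # gt: left half = neuron 1, right = neuron 2
  bpm <- array(0.5, dim(lab))
  tree <- build_hierarchy(sv, oracle_policy(own), bpm, bpm)
  lev <- tree_level(tree, 0.5)
  expect_length(unique(lev), 2)
  expect_equal(lev[1], lev[2])
  expect_equal(lev[3], lev[4])
  gt <- label_volume(array(own[lab], dim(lab)), c(6, 6, 6))
  pred <- relabel_supervoxels(sv, lev)
  sc <- score_report(pred, gt, foreground_restricted = FALSE)
  expect_equal(sc$rand_f, 1)
})

test_that("degenerate single-supervoxel training is rejected", {
  sv1 <- structure(list(labels = array(1L, c(6, 6, 2)), count = 1L,
                        voxel_size = c(6, 6, 6)), class = "supervoxels")
  b <- array(0.5, c(6, 6, 2))
  expect_error(train_merge_policy(sv1, b, b, label_volume(array(1L, c(6, 6, 2)), 6)),
               "degenerate")
})
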