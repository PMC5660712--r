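# Shared fixtures and independent oracles for the test suite.

# small dense ground-truth volume for structural tests
tiny_gt <- function(shape = c(48, 48, 48), count = 5, seed = 7,
                    radius_range = c(30, 100)) {
  generate_ground_truth(shape, 6, list(count = count, radius_range = radius_range),
                        seed = seed)
}

# exhaustive 6-neighbor membrane scan, independent of the C++ implementation
brute_membrane <- function(labels) {
  d <- dim(labels)
  out <- array(FALSE, d)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    l <- labels[x, y, z]
    nb <- c(if (x > 1) labels[x - 1, y, z], if (x < d[1]) labels[x + 1, y, z],
            if (y > 1) labels[x, y - 1, z], if (y < d[2]) labels[x, y + 1, z],
            if (z > 1) labels[x, y, z - 1], if (z < d[3]) labels[x, y, z + 1])
    out[x, y, z] <- any(nb != l)
  }
  out
}

# brute-force Rand scores from the printed formulas, via an explicit dense
# joint count table (independent of the package's sparse path)
brute_rand <- function(pred, gt) {
  tab <- table(factor(pred), factor(gt))
  s2 <- sum(tab^2)
  list(split = s2 / sum(rowSums(tab)^2),
       merge = s2 / sum(colSums(tab)^2))
}

# brute-force VI scores from explicit probabilities
brute_vi <- function(pred, gt) {
  tab <- table(factor(pred), factor(gt)) / length(pred)
  px <- rowSums(tab); py <- colSums(tab)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  mi <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab)))
    if (tab[i, j] > 0) mi <- mi + tab[i, j] * log(tab[i, j] / (px[i] * py[j]))
  list(split = unname(mi / ent(px)), merge = unname(mi / ent(py)))
}

# hand-built segmentation tree: leaves 1..4, A = (1,2), B = (3,4),
# root = (A, B); thresholds 0.2 / 0.3 / 0.8
fig_tree <- function() {
  structure(list(
    nodes = data.frame(id = c(5, 6, 7), left = c(1, 3, 5), right = c(2, 4, 6),
                       threshold = c(0.2, 0.3, 0.8)),
    n_leaves = 4L, thresholds = seq(0.1, 0.9, by = 0.1),
    voxel_size = c(6, 6, 120)),
    class = "seg_tree")
}

# annotate a tree directly with per-leaf barcode identity lists
annotate_fixture <- function(tree, leaf_barcodes) {
  exmrecon:::annotate_tree(tree, leaf_barcodes,
                           n_assigned = sum(lengths(leaf_barcodes)),
                           n_ignored = 0L, n_outside = 0L)
}

# two-basin boundary-probability landscape: ridge of height `ridge` at the
# midplane, basin floors at `floor1`/`floor2`
two_basin_bpm <- function(n = 12, ridge = 0.8, floor1 = 0.1, floor2 = 0.1) {
  x <- array(0, c(n, n, 3))
  mid <- n %/% 2
  for (i in seq_len(n))
    x[i, , ] <- if (i <= mid - 1) floor1 else if (i >= mid + 2) floor2 else ridge
  x
}

# deterministic merge policy from a leaf -> owner mapping (oracle policy)
oracle_policy <- function(owner) {
  function(feat, ma, mb) {
    vapply(seq_along(ma), function(i) {
      oa <- unique(owner[ma[[i]]]); ob <- unique(owner[mb[[i]]])
      if (length(oa) == 1 && length(ob) == 1 && oa == ob) 0.95 else 0.05
    }, numeric(1))
  }
}

# ROC AUC of a score against a logical label (rank statistic)
rank_auc <- function(score, label) {
  r <- rank(score)
  (mean(r[label]) - (sum(label) + 1) / 2) / sum(!label)
}

# tiny net config for fast training tests
tiny_net_config <- function(dims = "3d", widths = c(6, 8), fc = 12) {
  kz <- if (dims == "3d") 3L else 1L
  net_config(list(
    conv_spec(c(3, 3, 1), widths[1]),
    conv_spec(c(3, 3, 1), widths[1]),
    pool_spec(c(3, 3, 1)),
    conv_spec(c(3, 3, kz), widths[2]),
    fc_spec(fc),
    fc_spec(2)
  ), patch_shape = c(13, 13, 3), slice_stride = 1L)
}
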