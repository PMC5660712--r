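#' Watershed over-segmentation of a boundary probability map
#'
#' Pre-processes the BPM with an H-minima transform (suppressing regional
#' minima shallower than `h_min`, default 0.01) and floods a seeded watershed
#' (6-connectivity, deterministic lexicographic tie-break) from the surviving
#' regional minima.  Every voxel is assigned to exactly one supervoxel.
#'
#' @param bpm a `bpm` object or 3D array in \[0, 1\].
#' @param h_min H-minima depth threshold (default 0.01).
#' @param voxel_size grid pitch metadata carried to downstream steps.
#' @return object of class `supervoxels`: list with `labels` (3D int array,
#'   1..count), `count`, `voxel_size`.
#' @export
oversegment <- function(bpm, h_min = 0.01, voxel_size = c(6, 6, 120)) {
  f <- if (inherits(bpm, "bpm")) bpm$prob else bpm
  if (min(f) < 0 || max(f) > 1) stop("BPM values must lie in [0, 1]")
  d <- dim(f)
  hm <- -cpp_reconstruct_dilation(-(f + h_min), -f, d)   # H-minima by duality
  seeds <- cpp_regional_minima(hm, d)
  labels <- cpp_watershed(hm, seeds, d)
  structure(list(labels = array(labels, d), count = max(labels),
                 voxel_size = voxel_size),
            class = "supervoxels")
}

#' @export
print.supervoxels <- function(x, ...) {
  cat(sprintf("supervoxels: %s voxels, %d supervoxels\n",
              paste(dim(x$labels), collapse = " x "), x$count))
  invisible(x)
}

# ---- merge-policy features -------------------------------------------------
# Statistic blocks are additive power sums + histograms (10 bins) of the BPM
# and image intensity over a voxel set, produced by cpp_edge_stats /
# cpp_body_stats.  A block of raw sums is turned into
# (mean, sd, skew, kurtosis, normalized histogram).

NBINS <- 10L

moments_from_sums <- function(n, s1, s2, s3, s4) {
  if (n <= 0) return(c(0, 0, 0, 0))
  m <- s1 / n
  v <- max(s2 / n - m^2, 0)
  if (v < 1e-12) return(c(m, sqrt(v), 0, 0))
  m3 <- s3 / n - 3 * m * s2 / n + 2 * m^3
  m4 <- s4 / n - 4 * m * s3 / n + 6 * m^2 * s2 / n - 3 * m^4
  c(m, sqrt(v), m3 / v^1.5, m4 / v^2)
}

# stats vector: (count, s1..s4 + hist for channel 1, same for channel 2)
block_features <- function(stat) {
  n <- stat[1]
  f <- c()
  off <- 1
  for (ch in 1:2) {
    mm <- moments_from_sums(n * 2, stat[off + 1], stat[off + 2], stat[off + 3], stat[off + 4])
    # histogram counts sum to the number of accumulated values
    h <- stat[off + 4 + seq_len(NBINS)]
    hs <- sum(h)
    f <- c(f, mm, if (hs > 0) h / hs else h)
    off <- off + 4 + NBINS
  }
  c(log1p(n), f)
}

edge_feature_names <- function() {
  blk <- function(p) c(paste0(p, "_size"),
                       paste0(p, c("_bpm_mean", "_bpm_sd", "_bpm_skew", "_bpm_kurt")),
                       paste0(p, "_bpm_h", seq_len(NBINS)),
                       paste0(p, c("_img_mean", "_img_sd", "_img_skew", "_img_kurt")),
                       paste0(p, "_img_h", seq_len(NBINS)))
  c(blk("iface"), blk("body_mean"), blk("body_diff"))
}

# Symmetric feature vector for one edge: interface block plus the mean and
# absolute difference of the two body blocks.
edge_features <- function(iface_stat, body_a, body_b) {
  fi <- block_features(iface_stat)
  fa <- block_features(body_a)
  fb <- block_features(body_b)
  c(fi, (fa + fb) / 2, abs(fa - fb))
}

# edge stat row layout from cpp_edge_stats: a, b, then a stats vector whose
# count is the face-pair count (values accumulated are 2 per face)
edge_stat_vec <- function(row) row[-(1:2)]

# Build feature matrix for a set of edges given body stats matrix.
features_for_edges <- function(E, bodies) {
  if (nrow(E) == 0) return(matrix(0, 0, length(edge_feature_names()),
                                  dimnames = list(NULL, edge_feature_names())))
  out <- t(vapply(seq_len(nrow(E)), function(i) {
    edge_features(edge_stat_vec(E[i, ]), bodies[E[i, 1], ], bodies[E[i, 2], ])
  }, numeric(length(edge_feature_names()))))
  colnames(out) <- edge_feature_names()
  out
}

# normalize an image array to [0,1] for feature histograms
norm01 <- function(x) {
  mx <- max(x)
  if (mx > 0) x / mx else x
}

# Aggregate duplicate edges (same unordered endpoints) by summing their stats.
collapse_edges <- function(E) {
  if (nrow(E) == 0) return(E)
  a <- pmin(E[, 1], E[, 2]); b <- pmax(E[, 1], E[, 2])
  key <- paste(a, b)
  E[, 1] <- a; E[, 2] <- b
  if (!anyDuplicated(key)) return(E)
  stats <- rowsum(E[, -(1:2), drop = FALSE], key, reorder = FALSE)
  ab <- do.call(rbind, strsplit(rownames(stats), " "))
  cbind(as.numeric(ab[, 1]), as.numeric(ab[, 2]), unname(stats))
}

#' Train the supervoxel merge policy (agglomerative learning)
#'
#' Learns a classifier that scores whether two adjacent supervoxels belong to
#' the same neuron, from moment and histogram features of the BPM and image
#' intensity over the two bodies and their contact interface (plus contact
#' area).  Training follows the agglomerative scheme: edges of the current
#' segmentation are labeled by ground-truth agreement (majority ground-truth
#' owner of each body), all true merges are applied, and feature collection
#' repeats on the coarsened graph until no true merge remains.  The examples
#' are fit with a random forest.
#'
#' @param svs supervoxels (or list of them, one per training volume).
#' @param bpms,images matching BPM arrays/objects and image arrays (or
#'   `image_stack`s), single or lists.
#' @param gts ground-truth `label_volume`s on the image grid, single or list.
#' @param ntree random-forest size (default 100).
#' @param seed integer seed.
#' @return object of class `merge_policy` wrapping the fitted classifier.
#' @export
train_merge_policy <- function(svs, bpms, images, gts, ntree = 100, seed = 1) {
  as_list <- function(x, cls) {
    if (inherits(x, cls) || is.array(x)) list(x)
    else if (is.list(x)) x
    else list(x)
  }
  svs <- as_list(svs, "supervoxels"); bpms <- as_list(bpms, "bpm")
  if (!is.list(images)) images <- list(images)
  gts <- as_list(gts, "label_volume")
  feats <- list(); labels <- list()
  for (vi in seq_along(svs)) {
    sv <- svs[[vi]]
    if (sv$count < 2) stop("degenerate training volume: a single supervoxel")
    f <- if (inherits(bpms[[vi]], "bpm")) bpms[[vi]]$prob else bpms[[vi]]
    img <- norm01(if (inherits(images[[vi]], "image_stack")) images[[vi]]$data else images[[vi]])
    gt <- gts[[vi]]$labels
    d <- dim(sv$labels)
    E <- cpp_edge_stats(sv$labels, d, f, img, NBINS)
    bodies <- cpp_body_stats(sv$labels, f, img, sv$count, NBINS)
    owner <- majority_owner(sv$labels, gt, sv$count)
    parent <- seq_len(sv$count)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    repeat {
      fm <- features_for_edges(E, bodies)
      y <- owner[E[, 1]] == owner[E[, 2]]
      feats[[length(feats) + 1]] <- fm
      labels[[length(labels) + 1]] <- y
      if (!any(y)) break
      # merge every true pair (union-find), then re-aggregate the graph
      for (i in which(y)) {
        ra <- find(E[i, 1]); rb <- find(E[i, 2])
        if (ra != rb) {
          root <- min(ra, rb)
          parent[max(ra, rb)] <- root
          bodies[root, ] <- bodies[ra, ] + bodies[rb, ]
        }
      }
      roots_a <- vapply(E[, 1], find, numeric(1))
      roots_b <- vapply(E[, 2], find, numeric(1))
      keep <- roots_a != roots_b
      if (!any(keep)) break
      # merged bodies keep the (shared) owner of their root, so owner[] of
      # root indices stays valid across epochs
      E <- collapse_edges(cbind(roots_a[keep], roots_b[keep],
                                E[keep, -(1:2), drop = FALSE]))
    }
  }
  X <- do.call(rbind, feats)
  y <- factor(as.integer(unlist(labels)), levels = c(0, 1))
  if (length(unique(y)) < 2) {
    # degenerate training graph (one class only): fall back to scoring edges
    # by their interface boundary probability
    warning("merge-policy training saw a single edge class; ",
            "falling back to the interface boundary-probability heuristic")
    return(structure(list(model = NULL, feature_names = edge_feature_names()),
                     class = "merge_policy"))
  }
  rf <- withr::with_seed(seed,
    randomForest::randomForest(X, y, ntree = ntree))
  structure(list(model = rf, feature_names = edge_feature_names()),
            class = "merge_policy")
}

# majority ground-truth owner of each supervoxel
majority_owner <- function(sv_labels, gt_labels, count) {
  dt <- data.table::data.table(sv = as.vector(sv_labels), gt = as.vector(gt_labels))
  cnt <- dt[, .N, by = c("sv", "gt")]
  data.table::setorderv(cnt, c("sv", "N", "gt"), c(1, -1, 1))
  top <- cnt[!duplicated(cnt$sv)]
  owner <- integer(count)
  owner[top$sv] <- top$gt
  owner
}

# merge probability for a feature matrix under a policy (or a plain function
# for constructed policies in tests)
policy_prob <- function(policy, feat, members_a = NULL, members_b = NULL) {
  if (is.function(policy)) return(policy(feat, members_a, members_b))
  if (is.null(policy$model))   # heuristic fallback: bright interface = split
    return(pmin(pmax(1 - feat[, "iface_bpm_mean"], 0), 1))
  unname(stats::predict(policy$model, newdata = feat, type = "prob")[, "1"])
}

#' Greedy agglomeration into a hierarchical segmentation tree
#'
#' Edges are merged in ascending order of merge cost (1 - merge probability);
#' every merge creates an internal node tagged with the threshold at which it
#' formed (clamped to be non-decreasing from leaves to root, so levels cut at
#' the nine thresholds 0.1..0.9 are nested coarsenings).  Disconnected
#' components are finally joined at threshold 1 so the tree has one root.
#'
#' @param sv a `supervoxels`.
#' @param policy a `merge_policy` (or a function
#'   `(features, members_a, members_b) -> merge probability` for constructed
#'   policies).
#' @param bpm,image the BPM and image the features are computed from.
#' @param thresholds level thresholds stored on the tree (default
#'   `seq(0.1, 0.9, by = 0.1)`).
#' @return object of class `seg_tree`: `nodes` data.frame (id, left, right,
#'   threshold), `n_leaves`, `thresholds`, `voxel_size`.
#' @export
build_hierarchy <- function(sv, policy, bpm, image,
                            thresholds = seq(0.1, 0.9, by = 0.1)) {
  f <- if (inherits(bpm, "bpm")) bpm$prob else bpm
  img <- norm01(if (inherits(image, "image_stack")) image$data else image)
  d <- dim(sv$labels)
  K <- sv$count
  E <- cpp_edge_stats(sv$labels, d, f, img, NBINS)
  bodies <- cpp_body_stats(sv$labels, f, img, K, NBINS)
  bodies <- rbind(bodies, matrix(0, max(K - 1, 1), ncol(bodies)))
  members <- c(as.list(seq_len(K)), vector("list", max(K - 1, 1)))
  node_thr <- numeric(2 * K)            # threshold at which node formed
  nodes <- matrix(NA_real_, 0, 4, dimnames = list(NULL, c("id", "left", "right", "threshold")))
  nxt <- K
  active <- rep(TRUE, nrow(E))
  w <- if (nrow(E) == 0) numeric(0) else
    1 - policy_prob(policy, features_for_edges(E, bodies),
                    members[E[, 1]], members[E[, 2]])
  while (any(active)) {
    i <- which(active)[which.min(w[active])]
    a <- E[i, 1]; b <- E[i, 2]
    nxt <- nxt + 1
    thr <- max(w[i], node_thr[a], node_thr[b])   # monotone clamp
    node_thr[nxt] <- thr
    nodes <- rbind(nodes, c(nxt, a, b, thr))
    bodies[nxt, ] <- bodies[a, ] + bodies[b, ]
    members[[nxt]] <- c(members[[a]], members[[b]])
    active[i] <- FALSE
    touch <- which(active & (E[, 1] %in% c(a, b) | E[, 2] %in% c(a, b)))
    if (length(touch)) {
      E[touch, 1:2] <- t(apply(E[touch, 1:2, drop = FALSE], 1, function(ab) {
        ab[ab %in% c(a, b)] <- nxt
        sort(ab)
      }))
      # combine duplicate edges between the same pair
      key <- paste(E[touch, 1], E[touch, 2])
      if (anyDuplicated(key)) {
        for (k in unique(key[duplicated(key)])) {
          ii <- touch[key == k]
          E[ii[1], -(1:2)] <- colSums(E[ii, -(1:2), drop = FALSE])
          active[ii[-1]] <- FALSE
        }
      }
      touch <- touch[active[touch]]
      if (length(touch))
        w[touch] <- 1 - policy_prob(policy, features_for_edges(E[touch, , drop = FALSE], bodies),
                                    members[E[touch, 1]], members[E[touch, 2]])
    }
  }
  # join disconnected components (if any) at threshold 1
  all_children <- nodes[, c("left", "right")]
  roots <- setdiff(c(seq_len(K), nodes[, "id"]), as.vector(all_children))
  while (length(roots) > 1) {
    nxt <- nxt + 1
    nodes <- rbind(nodes, c(nxt, roots[1], roots[2], 1))
    members[[nxt]] <- c(members[[roots[1]]], members[[roots[2]]])
    node_thr[nxt] <- 1
    roots <- c(nxt, roots[-(1:2)])
  }
  structure(list(nodes = as.data.frame(nodes), n_leaves = K,
                 thresholds = thresholds, voxel_size = sv$voxel_size),
            class = "seg_tree")
}

#' @export
print.seg_tree <- function(x, ...) {
  cat(sprintf("seg_tree: %d leaves, %d merges, levels at {%s}\n",
              x$n_leaves, nrow(x$nodes),
              paste(x$thresholds, collapse = ", ")))
  invisible(x)
}

#' Leaf-to-segment mapping of a tree level
#'
#' Applies every merge whose threshold does not exceed `t`; the result is a
#' partition of the leaves (nested across increasing `t`).
#'
#' @param tree a `seg_tree`.
#' @param t threshold in \[0, 1\].
#' @return integer vector mapping leaf id (1..n_leaves) to segment id.
#' @export
tree_level <- function(tree, t) {
  K <- tree$n_leaves
  parent <- seq_len(K + nrow(tree$nodes))
  nd <- tree$nodes
  for (i in seq_len(nrow(nd))) {
    if (nd$threshold[i] <= t) {
      parent[nd$left[i]] <- nd$id[i]
      parent[nd$right[i]] <- nd$id[i]
    }
  }
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  vapply(seq_len(K), find, numeric(1))
}

#' Apply a leaf mapping to the supervoxel volume
#'
#' @param sv a `supervoxels`.
#' @param mapping integer vector over leaf ids (from [tree_level()] or
#'   [consolidate()]).
#' @return a `label_volume` on the supervoxel grid.
#' @export
relabel_supervoxels <- function(sv, mapping) {
  mapping <- as.integer(as.factor(mapping))  # compact ids
  label_volume(array(mapping[sv$labels], dim(sv$labels)), sv$voxel_size)
}

#' Per-node leaf sets of a segmentation tree
#' @param tree a `seg_tree`.
#' @return list indexed by node id (1..max id) of integer leaf vectors.
#' @export
segtree_members <- function(tree) {
  n <- tree$n_leaves + nrow(tree$nodes)
  members <- c(as.list(seq_len(tree$n_leaves)), vector("list", nrow(tree$nodes)))
  nd <- tree$nodes
  for (i in seq_len(nrow(nd)))
    members[[nd$id[i]]] <- c(members[[nd$left[i]]], members[[nd$right[i]]])
  members
}
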