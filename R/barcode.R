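#' Assign barcodes to the leaves of a segmentation tree
#'
#' Each barcode maps to the watershed supervoxel (tree leaf) containing its
#' position.  Barcodes closer than `exclusion_nm` (default 30 nm) to an
#' inter-supervoxel boundary are ignored, because localization error could
#' place such a barcode on the wrong side of the boundary; the distance is an
#' anisotropic Euclidean distance transform of the supervoxel boundary in nm.
#' Barcodes outside the volume are skipped (counted, with a warning).
#'
#' @param tree a `seg_tree`.
#' @param sv the `supervoxels` the tree was built on.
#' @param barcodes a `barcode_set` (columns `x`, `y`, `z` nm, `identity`).
#' @param exclusion_nm boundary exclusion radius, nm.
#' @return object of class `annotated_seg_tree`: the tree plus
#'   `leaf_barcodes` (list of integer identity vectors per leaf) and counts
#'   `n_assigned`, `n_ignored`, `n_outside`.
#' @export
assign_barcodes <- function(tree, sv, barcodes, exclusion_nm = 30) {
  stopifnot(inherits(tree, "seg_tree"), inherits(sv, "supervoxels"))
  d <- dim(sv$labels)
  vs <- sv$voxel_size
  if (length(vs) == 1) vs <- rep(vs, 3)
  pos <- cbind(barcodes$x, barcodes$y, barcodes$z)
  n <- nrow(pos)
  leaf_barcodes <- vector("list", tree$n_leaves)
  if (n == 0)
    return(annotate_tree(tree, leaf_barcodes, 0L, 0L, 0L))
  ext <- d * vs
  inside <- pos[, 1] >= 0 & pos[, 1] <= ext[1] & pos[, 2] >= 0 & pos[, 2] <= ext[2] &
            pos[, 3] >= 0 & pos[, 3] <= ext[3]
  vox <- floor(sweep(pos, 2, vs, "/")) + 1
  vox <- pmin(pmax(vox, 1L), matrix(d, nrow(vox), 3, byrow = TRUE))  # points on the far face
  n_outside <- sum(!inside)
  if (n_outside > 0)
    warning(n_outside, " barcode(s) outside the volume were skipped")
  bnd <- cpp_boundary6(sv$labels, d)
  dist_nm <- array(cpp_edt(as.integer(bnd), d, vs), d)
  vi <- vox[inside, , drop = FALSE]
  dvals <- dist_nm[cbind(vi[, 1], vi[, 2], vi[, 3])]
  keep <- dvals >= exclusion_nm
  leaf <- sv$labels[cbind(vi[, 1], vi[, 2], vi[, 3])][keep]
  ident <- barcodes$identity[inside][keep]
  for (i in seq_along(leaf))
    leaf_barcodes[[leaf[i]]] <- c(leaf_barcodes[[leaf[i]]], ident[i])
  annotate_tree(tree, leaf_barcodes, sum(keep), sum(!keep), n_outside)
}

annotate_tree <- function(tree, leaf_barcodes, n_assigned, n_ignored, n_outside) {
  tree$leaf_barcodes <- lapply(leaf_barcodes, function(b)
    if (is.null(b)) integer(0) else as.integer(b))
  tree$n_assigned <- as.integer(n_assigned)
  tree$n_ignored <- as.integer(n_ignored)
  tree$n_outside <- as.integer(n_outside)
  class(tree) <- c("annotated_seg_tree", class(tree))
  tree
}

# distinct barcode set per node (bottom-up union; children precede parents)
node_barcode_sets <- function(tree) {
  n <- tree$n_leaves + nrow(tree$nodes)
  sets <- vector("list", n)
  for (i in seq_len(tree$n_leaves))
    sets[[i]] <- as.integer(sort(unique(tree$leaf_barcodes[[i]])))
  nd <- tree$nodes
  for (i in seq_len(nrow(nd)))
    sets[[nd$id[i]]] <- as.integer(sort(unique(c(sets[[nd$left[i]]], sets[[nd$right[i]]]))))
  sets
}

#' Barcode-consistency consolidation of a segmentation tree
#'
#' The core barcode-guided merging step: every tree node is a segmentation
#' hypothesis, approved when it contains at most one distinct barcode.
#' Starting from the root, the highest consistent nodes are selected (if a
#' node is consistent it is selected and descent stops; otherwise its
#' children are examined), so every leaf is covered exactly once.  Each
#' selected node becomes one segment; finally, segments carrying the same
#' barcode are merged into a single label even when spatially disconnected.
#' Zero-barcode nodes are consistent but keep their own labels (they are
#' never merged across).  A leaf that itself contains several distinct
#' barcodes cannot be split further and is kept as its own segment.
#'
#' @param tree an `annotated_seg_tree` from [assign_barcodes()].
#' @param sv optional `supervoxels`; when supplied the consolidated
#'   `label_volume` is returned, otherwise the leaf mapping.
#' @return if `sv` is given, a `label_volume`; otherwise an integer leaf ->
#'   segment mapping with attribute `selected` (the selected node ids).
#' @export
consolidate <- function(tree, sv = NULL) {
  stopifnot(inherits(tree, "annotated_seg_tree"))
  sets <- node_barcode_sets(tree)
  members <- segtree_members(tree)
  nd <- tree$nodes
  children <- list()
  for (i in seq_len(nrow(nd)))
    children[[nd$id[i]]] <- c(nd$left[i], nd$right[i])
  roots <- setdiff(c(seq_len(tree$n_leaves), nd$id),
                   as.vector(as.matrix(nd[, c("left", "right")])))
  selected <- integer(0)
  stack <- roots
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (length(sets[[v]]) <= 1 || v <= tree$n_leaves) {
      selected <- c(selected, v)
    } else {
      stack <- c(children[[v]], stack)
    }
  }
  # segment label per selected node; same-barcode segments share a label
  mapping <- integer(tree$n_leaves)
  seg_of_barcode <- new.env(parent = emptyenv())
  nxt <- 0L
  for (v in selected) {
    bc <- sets[[v]]
    lab <- if (length(bc) == 1) {
      key <- as.character(bc)
      if (is.null(seg_of_barcode[[key]])) {
        nxt <- nxt + 1L
        assign(key, nxt, envir = seg_of_barcode)
      }
      get(key, envir = seg_of_barcode)
    } else {
      nxt <- nxt + 1L
      nxt
    }
    mapping[members[[v]]] <- lab
  }
  attr(mapping, "selected") <- selected
  if (is.null(sv)) mapping else relabel_supervoxels(sv, mapping)
}

#' Segmentation quality as a function of barcode density
#'
#' For each density and trial, a fresh set of uniformly distributed barcodes
#' is generated for the otherwise identical data set (fixed tree and
#' supervoxels), assigned and consolidated, and the result is scored against
#' ground truth.  Reproduces the density-sweep protocol.
#'
#' @param tree a `seg_tree`.
#' @param sv the `supervoxels`.
#' @param gt_fine fine-grid ground-truth `label_volume` (barcodes are placed
#'   in the full volume).
#' @param gt_image image-grid ground-truth `label_volume` (scoring grid).
#' @param densities barcodes per um^3 (default `c(5, 10, 30, 100, 300)`).
#' @param trials trials per density (default 5).
#' @param exclusion_nm boundary exclusion radius, nm.
#' @param seed integer seed; trial `t` at density index `d` uses an
#'   independent derived seed.
#' @param foreground_restricted restrict scoring to non-boundary ground
#'   truth voxels (default TRUE).
#' @return data.frame with columns `density`, `trial`, `n_barcodes`,
#'   `rand_split`, `rand_merge`, `rand_f`, `vi_split`, `vi_merge`, `vi_f`.
#' @export
density_sweep <- function(tree, sv, gt_fine, gt_image,
                          densities = c(5, 10, 30, 100, 300), trials = 5,
                          exclusion_nm = 30, seed = 1,
                          foreground_restricted = TRUE) {
  out <- list()
  for (di in seq_along(densities)) {
    for (tr in seq_len(trials)) {
      s <- stage_seed(seed, sprintf("sweep_%d_%d", di, tr))
      bc <- place_barcodes(gt_fine, densities[di], seed = s)
      at <- assign_barcodes(tree, sv, bc, exclusion_nm)
      pred <- consolidate(at, sv)
      tab <- contingency(pred, gt_image, foreground_restricted)
      r <- rand_scores(tab)
      # VI is undefined for a degenerate single-segment prediction; the Rand
      # family is still reported for such trials
      v <- tryCatch(vi_scores(tab), error = function(e)
        c(split = NA_real_, merge = NA_real_, f = NA_real_))
      out[[length(out) + 1]] <- data.frame(
        density = densities[di], trial = tr, n_barcodes = nrow(bc),
        rand_split = r["split"], rand_merge = r["merge"], rand_f = r["f"],
        vi_split = v["split"], vi_merge = v["merge"], vi_f = v["f"],
        row.names = NULL)
    }
  }
  do.call(rbind, out)
}
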