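#' Contingency table between a predicted and a ground-truth segmentation
#'
#' Joint voxel counts n_ij between segment i of the prediction X and segment
#' j of the ground truth Y.  With `foreground_restricted = TRUE` (the
#' reported mode), voxels that are boundary (membrane, 6-connectivity) in
#' the ground truth are excluded, making the scores insensitive to small
#' border shifts.
#'
#' @param pred,gt `label_volume`s (or plain integer arrays) on the same grid.
#' @param foreground_restricted exclude ground-truth boundary voxels.
#' @return object of class `contingency_table`: data.frame `i`, `j`, `n`
#'   with attributes `n_total` and `restricted`.
#' @export
contingency <- function(pred, gt, foreground_restricted = TRUE) {
  p <- if (inherits(pred, "label_volume")) pred$labels else pred
  g <- if (inherits(gt, "label_volume")) gt$labels else gt
  if (!identical(dim(p), dim(g))) stop("pred and gt grids differ")
  keep <- rep(TRUE, length(g))
  if (foreground_restricted)
    keep <- !cpp_boundary6(as.integer(g), dim(g))
  dt <- data.table::data.table(i = as.vector(p)[keep], j = as.vector(g)[keep])
  tab <- dt[, .N, by = c("i", "j")]
  data.table::setorderv(tab, c("i", "j"))
  out <- data.frame(i = tab$i, j = tab$j, n = tab$N)
  attr(out, "n_total") <- sum(out$n)
  attr(out, "restricted") <- foreground_restricted
  class(out) <- c("contingency_table", "data.frame")
  out
}

#' Rand split, merge and F-scores
#'
#' From the contingency counts n_ij:
#' split = sum n_ij^2 / sum_i (sum_j n_ij)^2,
#' merge = sum n_ij^2 / sum_j (sum_i n_ij)^2,
#' and the F-score is their harmonic mean.  Note that under this form a pure
#' over-segmentation (prediction refines ground truth) attains a perfect
#' split score.
#'
#' @param table a `contingency_table`.
#' @return named numeric `(split, merge, f)`.
#' @export
rand_scores <- function(table) {
  if (nrow(table) == 0) stop("empty contingency table")
  s2 <- sum(table$n^2)
  px <- rowsum(table$n, table$i)
  py <- rowsum(table$n, table$j)
  split <- s2 / sum(px^2)
  merge <- s2 / sum(py^2)
  c(split = split, merge = merge, f = 2 / (1 / split + 1 / merge))
}

#' Information-theoretic (VI) split, merge and F-scores
#'
#' split = I(X,Y)/H(X), merge = I(X,Y)/H(Y), F = harmonic mean, with
#' entropies from the table marginals (natural log; the ratios are
#' base-invariant) and 0 log 0 = 0.  Under this form a pure over-segmentation
#' attains a perfect merge score.  The degenerate single-segment case returns
#' (1, 1, 1) when both segmentations are the same trivial partition and
#' raises otherwise.
#'
#' @param table a `contingency_table`.
#' @return named numeric `(split, merge, f)`.
#' @export
vi_scores <- function(table) {
  if (nrow(table) == 0) stop("empty contingency table")
  n <- sum(table$n)
  pij <- table$n / n
  px <- rowsum(pij, table$i)
  py <- rowsum(pij, table$j)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  hx <- ent(px); hy <- ent(py)
  pxi <- px[match(table$i, rownames(px))]
  pyj <- py[match(table$j, rownames(py))]
  mi <- sum(ifelse(pij > 0, pij * log(pij / (pxi * pyj)), 0))
  if (hx == 0 && hy == 0) {
    if (nrow(table) == 1) return(c(split = 1, merge = 1, f = 1))
    stop("degenerate table")
  }
  if (hx == 0 || hy == 0)
    stop("degenerate single-segment segmentation: VI score undefined")
  split <- mi / hx
  merge <- mi / hy
  f <- if (split + merge == 0) 0 else 2 * split * merge / (split + merge)
  c(split = split, merge = merge, f = f)
}

#' Full score report for a reconstruction
#'
#' @param pred,gt `label_volume`s (or arrays) on the same grid.
#' @param foreground_restricted exclude ground-truth membrane voxels
#'   (default TRUE, the reported mode).
#' @return object of class `score_report`: named list with `rand_split`,
#'   `rand_merge`, `rand_f`, `vi_split`, `vi_merge`, `vi_f`, all in \[0, 1\].
#' @export
score_report <- function(pred, gt, foreground_restricted = TRUE) {
  tab <- contingency(pred, gt, foreground_restricted)
  r <- rand_scores(tab)
  v <- vi_scores(tab)
  structure(list(rand_split = unname(r["split"]), rand_merge = unname(r["merge"]),
                 rand_f = unname(r["f"]), vi_split = unname(v["split"]),
                 vi_merge = unname(v["merge"]), vi_f = unname(v["f"])),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("Rand  split %.4f  merge %.4f  F %.4f\n", x$rand_split, x$rand_merge, x$rand_f))
  cat(sprintf("VI    split %.4f  merge %.4f  F %.4f\n", x$vi_split, x$vi_merge, x$vi_f))
  invisible(x)
}
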