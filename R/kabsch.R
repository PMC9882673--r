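# Rigid-body superposition and RMSD-based conformational classification.

#' Optimal rigid superposition (Kabsch) RMSD
#'
#' Least-squares superposition of point set `a` onto point set `b`
#' (points matched row-by-row), restricted to proper rotations so that the
#' chirality of the DNA path is preserved.
#'
#' @param a,b `n x 3` matrices with matched rows, `n >= 3`.
#' @return a list with `rmsd` (Angstrom), `rotation` (3x3) and
#'   `translation` (length 3) such that `a %*% t(rotation) + translation`
#'   superposes onto `b`.
#' @export
kabsch_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b)))
    stop("point sets must have matching dimensions")
  if (nrow(a) < 3) stop("need at least 3 points")
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  H <- t(a0) %*% b0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  fitted <- a0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - b0)^2)))
  list(rmsd = rmsd, rotation = R, translation = as.vector(cb - R %*% ca))
}

# Weighted Kabsch superposition (proper rotation), used by the robust
# alignment in wrapped-interval detection.
kabsch_weighted <- function(a, b, w) {
  w <- w / sum(w)
  ca <- colSums(a * w); cb <- colSums(b * w)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  H <- t(a0 * w) %*% b0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(rotation = R, translation = as.vector(cb - R %*% ca))
}

#' Pairwise superposition-RMSD matrix
#'
#' @param models list of `nuca_model` sharing one template (traces are
#'   matched by bp index).
#' @return an `n x n` symmetric matrix of minimized RMSDs with model labels
#'   as dimnames.
#' @export
rmsd_matrix <- function(models) {
  if (!length(models)) stop("empty model list")
  tot <- vapply(models, function(m) m$template$total_bp, integer(1))
  if (length(unique(tot)) != 1L ||
      length(unique(vapply(models, function(m) m$template$n_ncp,
                           integer(1)))) != 1L)
    stop("models must share a template")
  n <- length(models)
  M <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    M[i, j] <- M[j, i] <- kabsch_rmsd(models[[i]]$trace,
                                      models[[j]]$trace)$rmsd
  }
  labs <- vapply(models, function(m) m$label, character(1))
  dimnames(M) <- list(labs, labs)
  M
}

#' Single-linkage ordering of conformations
#'
#' Agglomerates an RMSD matrix by single linkage (minimum spanning tree
#' heights) and returns the dendrogram leaf order together with the merge
#' records.
#'
#' @param matrix symmetric RMSD matrix (`n >= 2`).
#' @return list with `order` (leaf permutation), `merge`, `height`, and the
#'   underlying `hclust` object.
#' @export
single_linkage_order <- function(matrix) {
  n <- nrow(matrix)
  if (is.null(n) || n < 2) stop("need at least 2 models to cluster")
  if (max(abs(matrix - t(matrix))) > 1e-9 || any(diag(matrix) != 0))
    stop("matrix must be symmetric with zero diagonal")
  hc <- stats::hclust(stats::as.dist(matrix), method = "single")
  list(order = hc$order, merge = hc$merge, height = hc$height, hclust = hc)
}

#' Export a single-linkage dendrogram as a Newick string
#'
#' @param cluster result of [single_linkage_order()].
#' @param path optional output file.
#' @return the Newick string, invisibly if written to `path`.
#' @export
cluster_newick <- function(cluster, path = NULL) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("the 'ape' package is required for Newick export")
  phy <- ape::as.phylo(cluster$hclust)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
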