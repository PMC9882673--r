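# NCP coordinate-frame fitting from wrapped DNA points.

#' Fit the NCP coordinate frame from wrapped-path points
#'
#' Least-squares superhelix fit: the ideal wrapped path (41.8 A radius,
#' 25 A pitch, left-handed, known twist and rise per bp), with its dyad at
#' the geometric midpoint of the run, is rigidly superposed on the points
#' by Kabsch with fixed base-pair correspondence. The frame is the
#' superposed canonical frame: Z along the superhelical axis oriented
#' entry to exit, origin at the helix center, Y toward the dyad base pair,
#' X = Y x Z. Using the full helix structure (phase and rise, not only the
#' radial spread of a cylinder fit) makes the axis estimate markedly less
#' noise-sensitive, and the construction is exactly equivariant under
#' rigid motion of the input.
#'
#' @param wrapped_points `n x 3` matrix, `n >= 40`, ordered entry to exit,
#'   one point per consecutive wrapped bp.
#' @return a `nuca_frame`.
#' @export
fit_ncp_frame <- function(wrapped_points) {
  p <- as.matrix(wrapped_points)
  n <- nrow(p)
  if (n < 40) stop("need at least 40 wrapped points to fit a frame")
  ctr <- colMeans(p)
  p0 <- sweep(p, 2, ctr)
  ev <- eigen(crossprod(p0) / n, symmetric = TRUE)
  if (ev$values[2] < 1e-8 * ev$values[1])
    stop("degenerate (collinear) points: cannot fit a helix axis")
  canon <- superhelix_points(seq_len(n) - 1L, dyad_t = (n - 1) / 2)
  k <- kabsch_rmsd(canon, p)
  R <- k$rotation
  ncp_frame(k$translation, R[, 1], R[, 2], R[, 3])
}
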