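#' Inter-NCP center distances and discoidal-plane dihedrals
#'
#' For every pair of placed NCPs `(n, n + m)`, the center-to-center distance
#' between the frame origins and the dihedral angle between the discoidal
#' (XY) planes, `arccos(|z_n . z_(n+m)|)`, folded into [0, 90] degrees.
#'
#' @param placements list of `nuca_placement` (absent ones are skipped).
#' @param m index separation (>= 1).
#' @return data.frame with columns `i`, `j`, `m`, `distance_A`,
#'   `dihedral_deg` (zero rows if fewer than `m + 1` placements present).
#' @export
pair_geometry <- function(placements, m = 1L) {
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("m must be a positive integer")
  present <- which(!vapply(placements, function(p) p$absent, logical(1)))
  out <- list()
  for (a in present) {
    b <- a + m
    if (!(b %in% present)) next
    fa <- placements[[a]]$frame; fb <- placements[[b]]$frame
    D <- vnorm(fa$origin - fb$origin)
    cz <- abs(sum(fa$z_axis * fb$z_axis))
    out[[length(out) + 1L]] <- data.frame(
      i = a, j = b, m = m, distance_A = D,
      dihedral_deg = acos(max(-1, min(1, cz))) * DEG)
  }
  if (!length(out))
    return(data.frame(i = integer(), j = integer(), m = integer(),
                      distance_A = numeric(), dihedral_deg = numeric()))
  do.call(rbind, out)
}
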