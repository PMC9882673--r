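# Small vector-algebra helpers shared across the package. All coordinates are
# in Angstrom unless a function name says otherwise; all angles returned to
# users are in degrees.

DEG <- 180 / pi

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @noRd
# Rotation matrix about an arbitrary unit axis (Rodrigues), angle in degrees.
rot_axis <- function(axis, angle_deg) {
  u <- unit(axis)
  th <- angle_deg / DEG
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Minimal-angle rotation carrying unit vector a onto unit vector b.
rot_between <- function(a, b) {
  a <- unit(a); b <- unit(b)
  v <- cross3(a, b)
  s <- vnorm(v)
  c_ <- sum(a * b)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate 180 degrees about any axis orthogonal to a
    ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- unit(cross3(a, ref))
    return(rot_axis(ax, 180))
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K * ((1 - c_) / s^2)
}

# Uniform random rotation matrix (quaternion method).
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / vnorm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

# Signed angle (degrees, (-180, 180]) from 2D vector a to b, CCW positive.
signed_angle_2d <- function(a, b) {
  ang <- atan2(a[1] * b[2] - a[2] * b[1], sum(a * b)) * DEG
  if (ang <= -180) ang <- ang + 360
  ang
}

# Unsigned angle (degrees, [0, 180]) between two 3-vectors.
angle_between <- function(a, b) {
  acos(max(-1, min(1, sum(unit(a) * unit(b))))) * DEG
}

# Squared distances from each row of p (n x 3) to each row of q (m x 3).
cross_dist2 <- function(p, q) {
  pp <- rowSums(p^2)
  qq <- rowSums(q^2)
  outer(pp, qq, "+") - 2 * p %*% t(q)
}

# Minimum distance from each row of p to the polyline with vertices q
# (distance to segments, not just vertices).
dist_to_polyline <- function(p, q) {
  n <- nrow(p)
  m <- nrow(q)
  d2v <- cross_dist2(p, q)            # to vertices
  best <- apply(d2v, 1, min)
  # refine against each segment
  a <- q[-m, , drop = FALSE]
  b <- q[-1, , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  for (s in seq_len(m - 1)) {
    ap <- sweep(p, 2, a[s, ])
    t_ <- (ap %*% ab[s, ]) / len2[s]
    t_ <- pmin(1, pmax(0, t_))
    proj <- outer(as.vector(t_), ab[s, ])
    d2 <- rowSums((ap - proj)^2)
    best <- pmin(best, d2)
  }
  sqrt(pmax(best, 0))
}

# Deterministic child seed derivation, kept below 2^31.
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a
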