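# The ideal nucleosomal DNA path: a left-handed superhelix of radius 41.8 A
# and pitch 25.0 A making 1.7 turns over 147 bp. This single parameterisation
# is used by the synthetic generator (to lay down wrapped base pairs), by
# wrapped-interval detection (the 8 A overlap criterion) and by the coarse
# footprint. The NCP frame is: Z along the superhelical axis pointing in the
# entry-to-exit direction of advance, Y toward the dyad base pair, X = Y x Z.

SH_RADIUS <- 41.8      # A
SH_PITCH <- 25.0       # A per turn
SH_TURNS <- 1.7        # turns over the full 147-bp wrap
NCP_BP <- 147L
BP_RISE <- 3.4         # A per bp of straight linker/arm DNA
DEG_PER_BP <- 360 * SH_TURNS / NCP_BP   # unwrapping angle per bp, ~4.163 deg

# Per-bp superhelical phase (radians) and axial rise (A).
SH_DPHI <- 2 * pi * SH_TURNS / NCP_BP
SH_RISE <- SH_PITCH * SH_TURNS / NCP_BP

#' Ideal wrapped-path coordinates in the canonical NCP frame
#'
#' Returns the helical-center coordinates of base pairs on the ideal
#' superhelical wrap, in the canonical NCP frame (origin at the NCP center,
#' dyad along +Y, superhelical axis along +Z pointing entry to exit).
#' Position `t = 0` is the designed entry boundary of the 147-bp wrap and
#' `t = 146` the designed exit boundary; fractional and out-of-range `t` are
#' allowed (the helix extends smoothly), which detection uses to tolerate
#' modest over-wrapping.
#'
#' @param t numeric vector of base-pair positions along the wrap.
#' @param dyad_t position of the dyad base pair (default the designed
#'   midpoint, 73).
#' @return an `length(t) x 3` matrix of coordinates (Angstrom).
#' @keywords internal
superhelix_points <- function(t, dyad_t = (NCP_BP - 1) / 2) {
  phi <- pi / 2 + (dyad_t - t) * SH_DPHI   # left-handed: phi decreases with t
  cbind(SH_RADIUS * cos(phi), SH_RADIUS * sin(phi), (t - dyad_t) * SH_RISE)
}

# Unit tangent of the ideal path in the direction of increasing t,
# at positions t (canonical frame).
superhelix_tangent <- function(t, dyad_t = (NCP_BP - 1) / 2) {
  phi <- pi / 2 + (dyad_t - t) * SH_DPHI
  d <- cbind(SH_RADIUS * sin(phi) * SH_DPHI,
             -SH_RADIUS * cos(phi) * SH_DPHI,
             rep(SH_RISE, length(t)))
  d / sqrt(rowSums(d^2))
}

# In-plane "away" tangent used as the alpha reference: the XY projection of
# the wrapped-path tangent at the arm origin, pointing away from the wrap
# (upstream for the entry side, downstream for the exit side). Given the
# radial direction r_hat (XY, canonical frame) of the origin base pair:
#   increasing-t tangent (XY)  = -(z_hat x r_hat)
# so the away tangent is +(z x r) for entry and -(z x r) for exit.
inplane_away_tangent <- function(r_hat_xy, side) {
  zxr <- c(-r_hat_xy[2], r_hat_xy[1])
  if (side == "entry") zxr else -zxr
}

# Sign such that rotating the away tangent toward the outward radial
# direction is the positive alpha sense (-1 at entry, +1 at exit).
alpha_outward_sign <- function(side) if (side == "entry") -1 else 1

# Build a unit arm direction in the canonical frame from wrapping angle alpha
# and bending angle beta (degrees) at superhelical position t.
# The direction points away from the NCP along the arm.
arm_direction_canonical <- function(t, side, alpha_deg, beta_deg,
                                    dyad_t = (NCP_BP - 1) / 2) {
  p <- superhelix_points(t, dyad_t)[1, ]
  r_hat <- unit(c(p[1], p[2], 0))
  taway <- inplane_away_tangent(r_hat[1:2], side)
  s <- alpha_outward_sign(side)
  # rotate the away tangent in-plane by alpha toward the outward radial
  th <- s * alpha_deg / DEG
  u0 <- c(cos(th) * taway[1] - sin(th) * taway[2],
          sin(th) * taway[1] + cos(th) * taway[2], 0)
  b <- beta_deg / DEG
  cos(b) * u0 + c(0, 0, sin(b))
}
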