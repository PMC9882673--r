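# Arm-vector construction and the angle definitions.
#
# Sign conventions (fixed package-wide):
#   theta       unsigned 3D angle between the entry and exit arm vectors,
#               both pointing away from the NCP                  [0, 180]
#   theta_par   signed angle about +Z from the XY projection of the entry
#               arm to that of the exit arm                      (-180, 180]
#   theta_perp  signed angle about +X between the YZ projections (-180, 180]
#   alpha       signed in-plane angle from the local wrapped-path tangent
#               (pointing away from the wrap) to the arm's XY projection,
#               positive = rotating radially outward             (-180, 180]
#   beta        arcsin(arm . Z), positive toward +Z              [-90, 90]
#   closed arm  theta_par < 0 (strict; theta_par = 0 is open)
#   deltas      negative = unwrapped relative to the 147-bp repeat

#' Arm vector from the 20-bp segment at a wrap boundary
#'
#' @param trace coordinate matrix.
#' @param origin_bp 0-based trace index of the arm origin (wrap boundary).
#' @param side `"entry"` (vector points upstream, away from the NCP) or
#'   `"exit"` (downstream).
#' @param length_bp segment length (default 20).
#' @param guard_bp bp skipped between the origin and the start of the
#'   fitted segment; a small guard keeps bp still on the wrapped path (when
#'   the detected boundary errs inward) out of the arm direction without
#'   changing it for a straight arm (default 0).
#' @return list(side, origin_bp, direction, length_bp).
#' @export
arm_vector <- function(trace, origin_bp, side = c("entry", "exit"),
                       length_bp = 20L, guard_bp = 0L) {
  side <- match.arg(side)
  n <- nrow(trace)
  near <- if (side == "entry") origin_bp - guard_bp else origin_bp + guard_bp
  other <- if (side == "entry") near - length_bp else near + length_bp
  if (other < 0L || other > n - 1L)
    stop(sprintf("arm-too-short: %s arm needs %d bp beyond bp %d",
                 side, length_bp + guard_bp, origin_bp))
  # principal-axis direction of the whole 20-bp segment (less sensitive to
  # per-bp coordinate noise than the two endpoints), oriented away from
  # the NCP
  seg <- trace[(min(near, other) + 1L):(max(near, other) + 1L), ,
               drop = FALSE]
  ctr <- colMeans(seg)
  dir <- svd(sweep(seg, 2, ctr), nu = 0, nv = 1)$v[, 1]
  away <- trace[other + 1L, ] - trace[origin_bp + 1L, ]
  if (sum(dir * away) < 0) dir <- -dir
  list(side = side, origin_bp = as.integer(origin_bp), direction = dir,
       length_bp = as.integer(length_bp), centroid = ctr)
}

#' Measure the arm angles of one NCP placement
#'
#' @param placement a non-absent `nuca_placement` with a fitted frame.
#' @param trace the model's coordinate matrix (or a `nuca_model`).
#' @return list with `theta_deg`, `theta_par_deg`, `theta_perp_deg`,
#'   `alpha_entry_deg`, `alpha_exit_deg`, `beta_entry_deg`, `beta_exit_deg`
#'   and `arm_state` (`"open"`/`"closed"`).
#' @export
measure_angles <- function(placement, trace) {
  if (inherits(trace, "nuca_model")) trace <- trace$trace
  stopifnot(inherits(placement, "nuca_placement"))
  if (placement$absent) stop("cannot measure an absent placement")
  f <- placement$frame
  iv <- placement$wrap_interval
  en <- arm_vector(trace, iv[1], "entry", guard_bp = 2L)
  ex <- arm_vector(trace, iv[2] - 1L, "exit", guard_bp = 2L)

  Rf <- frame_rotation(f)
  en_loc <- as.vector(t(Rf) %*% en$direction)
  ex_loc <- as.vector(t(Rf) %*% ex$direction)

  theta <- angle_between(en$direction, ex$direction)
  theta_par <- signed_angle_2d(en_loc[1:2], ex_loc[1:2])
  theta_perp <- signed_angle_2d(en_loc[2:3], ex_loc[2:3])

  # The wrapped run in frame coordinates follows the superhelix
  # phi(t) = phase0 - dphi*t, z(t) = z0 + rise*t; phase0 and z0 come from
  # regressions over all wrapped bp (known twist and rise per bp, free
  # intercepts), which averages per-bp coordinate noise out of the
  # reference geometry.
  qw <- to_frame(trace[(iv[1] + 1L):iv[2], , drop = FALSE], f)
  nw <- nrow(qw)
  tt <- seq_len(nw) - 1L
  phase0 <- Arg(mean(exp(1i * (atan2(qw[, 2], qw[, 1]) + SH_DPHI * tt))))
  z0 <- mean(qw[, 3] - SH_RISE * tt)
  helix_local <- function(t)
    cbind(SH_RADIUS * cos(phase0 - SH_DPHI * t),
          SH_RADIUS * sin(phase0 - SH_DPHI * t),
          z0 + SH_RISE * t)

  # The alpha reference tangent is evaluated at the contact point, located
  # as the closest approach of the measured arm LINE to the fitted
  # superhelix. This continuous estimate does not inherit the +-bp jitter
  # of the discrete wrap boundary (a 1-bp boundary error rotates the
  # tangent by ~4.2 degrees).
  alpha_one <- function(arm, d_loc) {
    if (vnorm(d_loc[1:2]) < 1e-9) return(NA_real_)
    c_loc <- as.vector(t(Rf) %*% (arm$centroid - f$origin))
    t_anchor <- if (arm$side == "entry") 0 else nw - 1
    dist2 <- function(t) {
      h <- helix_local(t)[1, ]
      rel <- h - c_loc
      sum(rel^2) - sum(rel * d_loc)^2
    }
    # fine grid near the boundary anchor (the function can have spurious
    # minima where the line re-approaches the helix further away)
    tg <- seq(t_anchor - 2, t_anchor + 2, by = 0.1)
    t_star <- tg[which.min(vapply(tg, dist2, numeric(1)))]
    phi <- phase0 - SH_DPHI * t_star
    taway <- inplane_away_tangent(c(cos(phi), sin(phi)), arm$side)
    alpha_outward_sign(arm$side) * signed_angle_2d(taway, d_loc[1:2])
  }
  beta_one <- function(d_loc) asin(max(-1, min(1, d_loc[3]))) * DEG

  theta_par_v <- theta_par
  list(theta_deg = theta,
       theta_par_deg = theta_par_v,
       theta_perp_deg = theta_perp,
       alpha_entry_deg = alpha_one(en, en_loc),
       alpha_exit_deg = alpha_one(ex, ex_loc),
       beta_entry_deg = beta_one(en_loc),
       beta_exit_deg = beta_one(ex_loc),
       arm_state = if (theta_par_v < 0) "closed" else "open")
}

#' Per-side unwrapping angles
#'
#' Converts bp deltas into unwrapping angles at 360 x 1.7 / 147 ~ 4.163
#' degrees per bp, signed negative when unwrapped.
#'
#' @param delta_entry_bp,delta_exit_bp signed bp deltas.
#' @return list(theta_en_deg, theta_ex_deg, theta_sum_deg, degrees_per_bp).
#' @export
unwrap_angles <- function(delta_entry_bp, delta_exit_bp) {
  list(theta_en_deg = delta_entry_bp * DEG_PER_BP,
       theta_ex_deg = delta_exit_bp * DEG_PER_BP,
       theta_sum_deg = (delta_entry_bp + delta_exit_bp) * DEG_PER_BP,
       degrees_per_bp = DEG_PER_BP)
}
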