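# Wrapped-interval detection: find, for one designed repeat, the run of
# trace base pairs lying on the ideal superhelical wrap.
#
# Stage 1 aligns the ideal path to the repeat region (index-correspondence
# Kabsch followed by nearest-point ICP refinement) and collects the base
# pairs within the 8 A overlap radius, bridging gaps of <= 2 bp.
# Stage 2 refines each boundary by a changepoint criterion: base pairs on
# the wrapped side are scored against the ideal path, base pairs on the arm
# side against a straight line fitted to the adjacent arm segment. The
# refinement exists because a straight arm leaving the wrap at a shallow
# angle stays within 8 A of the continuing ideal path for its first 2-3 bp,
# which would otherwise bias the boundary systematically outward.

ICP_MATCH_RADIUS <- 15   # A, correspondence cutoff during alignment
CANON_EXT <- 15L         # bp of ideal-path extension beyond the 147-bp wrap

#' Detect the wrapped interval of one designed repeat
#'
#' @param trace `total_bp x 3` coordinate matrix (or a `nuca_model`, whose
#'   trace is used).
#' @param repeat_index which designed repeat (1-based).
#' @param template the `nuca_template` the trace is laid on.
#' @param reference_frame_hint optional `nuca_frame` used to initialise the
#'   alignment instead of the index-correspondence fit.
#' @param contact_radius overlap criterion radius, Angstrom (default 8).
#' @param gap_tol run gap tolerance in bp (default 2).
#' @param refine apply the changepoint boundary refinement (default TRUE).
#' @return a `nuca_placement`; flagged absent when no base pair of the
#'   repeat region lies within `contact_radius` of the aligned ideal path.
#' @export
detect_wrapped_interval <- function(trace, repeat_index, template,
                                    reference_frame_hint = NULL,
                                    contact_radius = 8, gap_tol = 2L,
                                    refine = TRUE) {
  if (inherits(trace, "nuca_model")) trace <- trace$trace
  validate_template(template)
  iv <- template$nps_intervals[[repeat_index]]
  total <- template$total_bp

  # candidate window around the designed repeat (0-based bp indices)
  lo <- max(0L, iv[1] - 45L)
  hi <- min(total - 1L, iv[2] - 1L + 45L)
  if (repeat_index > 1L)
    lo <- max(lo, template$nps_intervals[[repeat_index - 1L]][2] - 10L)
  if (repeat_index < template$n_ncp)
    hi <- min(hi, template$nps_intervals[[repeat_index + 1L]][1] + 9L)
  win_bp <- lo:hi
  win <- trace[win_bp + 1L, , drop = FALSE]

  t_ext <- seq.int(-CANON_EXT, NCP_BP - 1L + CANON_EXT)
  canon_ext <- superhelix_points(t_ext)

  # --- stage 1: alignment ---------------------------------------------------
  # The positioning sequence fixes the registration: wrapped trace bp j sits
  # at canonical position t = j - repeat_start. Alignment is therefore a
  # robust fixed-correspondence superposition; pairs whose residual exceeds
  # a shrinking radius (arm/linker bp) are excluded iteratively.
  t_win <- win_bp - iv[1]
  in_canon <- t_win >= -CANON_EXT & t_win <= NCP_BP - 1L + CANON_EXT
  canon_win <- superhelix_points(t_win[in_canon])
  pw <- win[in_canon, , drop = FALSE]
  if (!is.null(reference_frame_hint)) {
    R <- frame_rotation(reference_frame_hint)
    o <- reference_frame_hint$origin
  } else {
    mid <- t_win >= 10L & t_win <= NCP_BP - 11L   # core, least arm-affected
    k <- kabsch_rmsd(superhelix_points(t_win[mid]),
                     win[mid, , drop = FALSE])
    R <- k$rotation; o <- k$translation
  }
  # phase A: soft iteratively-reweighted superposition (Cauchy weights)
  # stabilises the alignment without the inlier collapse hard trimming can
  # suffer far from the optimum
  for (it in 1:8) {
    g <- sweep(canon_win %*% t(R), 2, o, "+")
    r2 <- rowSums((pw - g)^2)
    w <- 1 / (1 + r2 / 16)   # c = 4 A
    k <- kabsch_weighted(canon_win, pw, w)
    R <- k$rotation; o <- k$translation
  }
  # phase B: hard-trimmed refinement down to the residual scale
  radius <- ICP_MATCH_RADIUS
  for (it in 1:25) {
    g <- sweep(canon_win %*% t(R), 2, o, "+")
    nd <- sqrt(pmax(0, rowSums((pw - g)^2)))
    sel <- nd < radius
    if (sum(sel) < 20L) break
    k <- kabsch_rmsd(canon_win[sel, , drop = FALSE],
                     pw[sel, , drop = FALSE])
    R <- k$rotation; o <- k$translation
    # residual scale of the inliers under the refreshed fit decides the
    # next trimming radius
    g <- sweep(canon_win %*% t(R), 2, o, "+")
    nd_new <- sqrt(pmax(0, rowSums((pw[sel, , drop = FALSE] -
                                      g[sel, , drop = FALSE])^2)))
    new_radius <- max(2.5 * stats::median(nd_new), 0.3)
    if (abs(new_radius - radius) < 1e-9 && it > 2) break
    radius <- new_radius
  }

  g <- sweep(canon_ext %*% t(R), 2, o, "+")
  dists <- dist_to_polyline(win, g)
  contact <- dists < contact_radius
  if (!any(contact)) return(ncp_placement(NULL, NULL, NA, NA, absent = TRUE))

  # --- maximal contiguous run with gap tolerance ----------------------------
  # short gaps (<= gap_tol bp) are always bridged; longer interior gaps are
  # bridged when every gap bp stays within 1.5x the contact radius (noise
  # excursions just past the criterion must not split the wrapped run)
  idx <- which(contact)
  breaks <- which(diff(idx) > gap_tol + 1L)
  keep_break <- vapply(breaks, function(b) {
    gap_bp <- (idx[b] + 1L):(idx[b + 1L] - 1L)
    any(dists[gap_bp] >= 1.5 * contact_radius)
  }, logical(1))
  breaks <- breaks[keep_break]
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(idx))
  run_len <- idx[ends] - idx[starts] + 1L
  best <- which.max(run_len)
  r0 <- idx[starts[best]]; r1 <- idx[ends[best]]   # window-local, inclusive
  w_start <- win_bp[r0]; w_end_incl <- win_bp[r1]  # 0-based bp indices

  if (refine) {
    # the straight-arm fit window may extend along the full linker/arm but
    # must never reach into a neighbouring repeat's wrap
    arm_lo <- if (repeat_index > 1L)
      template$nps_intervals[[repeat_index - 1L]][2] else 0L
    arm_hi <- if (repeat_index < template$n_ncp)
      template$nps_intervals[[repeat_index + 1L]][1] - 1L else total - 1L
    w_start <- refine_boundary(trace, w_start, iv[1], "entry", lo, hi,
                               arm_lo, arm_hi, wrap_cap = w_end_incl)
    w_end_incl <- refine_boundary(trace, w_end_incl, iv[1], "exit", lo, hi,
                                  arm_lo, arm_hi, wrap_cap = w_start)
  }
  if (w_end_incl <= w_start)
    return(ncp_placement(NULL, NULL, NA, NA, absent = TRUE))

  d_en <- iv[1] - w_start
  d_ex <- (w_end_incl + 1L) - iv[2]
  if (d_en < -NCP_BP || d_ex < -NCP_BP || d_en > 53L || d_ex > 53L)
    return(ncp_placement(NULL, NULL, NA, NA, absent = TRUE))

  wrapped <- trace[(w_start + 1L):(w_end_incl + 1L), , drop = FALSE]
  frame <- tryCatch(fit_ncp_frame(wrapped), error = function(e) NULL)
  if (is.null(frame)) return(ncp_placement(NULL, NULL, NA, NA, absent = TRUE))
  ncp_placement(frame, c(w_start, w_end_incl + 1L), d_en, d_ex)
}

# Changepoint refinement of one boundary. `boundary` is the 0-based index
# of the outermost wrapped bp on that side (from the coarse 8 A run). Two
# local models are each fitted ONCE on windows safely outside the contested
# +-halfwin zone -- the ideal helix re-superposed (fixed bp-to-path
# correspondence) on up to 40 bp inward, a straight line on up to 40 bp of
# the arm outward -- and every contested bp is then scored out-of-sample
# against both. Fitting outside the zone keeps the comparison symmetric
# under slowly varying trace noise (neither model gets to absorb the bp it
# is claiming), which keeps the boundary estimate unbiased.
refine_boundary <- function(trace, boundary, start_bp, side, lo, hi,
                            arm_lo = 0L, arm_hi = NULL, wrap_cap = NULL,
                            shrink_bp = 10L, extend_bp = 2L, seg_bp = 20L) {
  total <- nrow(trace)
  if (is.null(arm_hi)) arm_hi <- total - 1L
  # the 8 A overlap criterion over-extends into a grazing arm but does not
  # drop wrapped bp (short gaps are bridged), so the coarse boundary is
  # allowed to move well inward but only marginally outward
  cand <- if (side == "entry") (boundary - extend_bp):(boundary + shrink_bp)
          else (boundary - shrink_bp):(boundary + extend_bp)
  cand <- cand[cand >= max(0L, lo) & cand <= min(total - 1L, hi)]
  zone_bp <- min(cand):max(cand)

  score <- vapply(cand, function(cb) {
    if (side == "entry") {
      wrap_fit <- seq.int(cb, cb + seg_bp - 1L)
      arm_fit <- seq.int(cb - seg_bp, cb - 1L)
      wrap_zone <- zone_bp[zone_bp >= cb]
      if (!is.null(wrap_cap)) wrap_fit <- wrap_fit[wrap_fit <= wrap_cap]
    } else {
      wrap_fit <- seq.int(cb - seg_bp + 1L, cb)
      arm_fit <- seq.int(cb + 1L, cb + seg_bp)
      wrap_zone <- zone_bp[zone_bp <= cb]
      if (!is.null(wrap_cap)) wrap_fit <- wrap_fit[wrap_fit >= wrap_cap]
    }
    wrap_fit <- wrap_fit[wrap_fit >= 0L & wrap_fit <= total - 1L]
    arm_fit <- arm_fit[arm_fit >= max(0L, arm_lo) &
                         arm_fit <= min(total - 1L, arm_hi)]
    arm_zone <- intersect(zone_bp, arm_fit)
    s <- 0
    if (length(wrap_fit) >= 4L && length(wrap_zone)) {
      k <- kabsch_rmsd(superhelix_points(wrap_fit - start_bp),
                       trace[wrap_fit + 1L, , drop = FALSE])
      tv <- range(c(wrap_fit, wrap_zone)) - start_bp
      gg <- sweep(superhelix_points(seq.int(tv[1] - 1L, tv[2] + 1L)) %*%
                    t(k$rotation), 2, k$translation, "+")
      s <- s + sum(dist_to_polyline(trace[wrap_zone + 1L, , drop = FALSE],
                                    gg)^2)
    }
    if (length(arm_fit) >= 3L && length(arm_zone)) {
      pts <- trace[arm_fit + 1L, , drop = FALSE]
      ctr <- colMeans(pts)
      dirv <- svd(sweep(pts, 2, ctr), nu = 0, nv = 1)$v[, 1]
      q0 <- sweep(trace[arm_zone + 1L, , drop = FALSE], 2, ctr)
      s <- s + sum(pmax(0, rowSums(q0^2) - as.vector(q0 %*% dirv)^2))
    }
    s
  }, numeric(1))
  # The origin bp lies on both the wrapped path and the straight arm, so
  # the score ties across it: break ties toward the maximal wrap.
  eps <- 1e-6
  best <- cand[score <= min(score) + eps]
  if (side == "entry") min(best) else max(best)
}
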