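# The central measurable object: a DNA base-pair helical-center trace plus
# ordered NCP placements on a declared template.

#' Construct an NCP coordinate frame
#'
#' @param origin NCP center (length-3, Angstrom).
#' @param x_axis,y_axis,z_axis orthonormal right-handed axes
#'   (`x = y x z`): Z along the superhelical axis (entry-to-exit advance),
#'   Y toward the dyad, X completing the frame.
#' @return an object of class `nuca_frame`.
#' @export
ncp_frame <- function(origin, x_axis, y_axis, z_axis) {
  f <- structure(list(origin = as.numeric(origin),
                      x_axis = as.numeric(x_axis),
                      y_axis = as.numeric(y_axis),
                      z_axis = as.numeric(z_axis)),
                 class = "nuca_frame")
  validate_frame(f)
}

validate_frame <- function(f, tol = 1e-6) {
  stopifnot(inherits(f, "nuca_frame"))
  ax <- rbind(f$x_axis, f$y_axis, f$z_axis)
  if (max(abs(ax %*% t(ax) - diag(3))) > tol)
    stop("frame axes are not orthonormal")
  if (max(abs(cross3(f$y_axis, f$z_axis) - f$x_axis)) > tol)
    stop("frame is not right-handed (x != y x z)")
  invisible(f)
}

# rotation matrix with frame axes as columns: local -> global is
# R %*% v + origin
frame_rotation <- function(f) cbind(f$x_axis, f$y_axis, f$z_axis)

# global points (n x 3) -> frame-local coordinates
to_frame <- function(points, f) {
  sweep(points, 2, f$origin) %*% frame_rotation(f)
}

#' Construct an NCP placement
#'
#' A placement records where on the trace one nucleosome's wrapped interval
#' lies and how far it deviates from the designed 147-bp repeat. Deltas are
#' signed with negative meaning unwrapped (peeled) DNA, so
#' `wrap_length_bp = 147 + delta_entry_bp + delta_exit_bp`.
#'
#' @param frame `nuca_frame` (may be `NULL` for an absent placement).
#' @param wrap_interval half-open 0-based `c(start, end)` on the trace.
#' @param delta_entry_bp,delta_exit_bp signed bp deltas.
#' @param absent flag for off-template/undetected NCPs (kept, not deleted,
#'   so repeat indices stay stable).
#' @return an object of class `nuca_placement`.
#' @export
ncp_placement <- function(frame, wrap_interval, delta_entry_bp, delta_exit_bp,
                          absent = FALSE) {
  if (absent) {
    return(structure(list(frame = NULL, wrap_interval = NULL,
                          delta_entry_bp = NA_integer_,
                          delta_exit_bp = NA_integer_,
                          wrap_length_bp = NA_integer_, absent = TRUE),
                     class = "nuca_placement"))
  }
  wrap_interval <- as.integer(wrap_interval)
  delta_entry_bp <- as.integer(delta_entry_bp)
  delta_exit_bp <- as.integer(delta_exit_bp)
  wl <- wrap_interval[2] - wrap_interval[1]
  if (wl != NCP_BP + delta_entry_bp + delta_exit_bp)
    stop("wrap_length_bp != 147 + delta_entry_bp + delta_exit_bp")
  if (any(c(delta_entry_bp, delta_exit_bp) < -NCP_BP) ||
      any(c(delta_entry_bp, delta_exit_bp) > 53L))
    stop("deltas must lie in [-147, +53]")
  structure(list(frame = frame, wrap_interval = wrap_interval,
                 delta_entry_bp = delta_entry_bp,
                 delta_exit_bp = delta_exit_bp,
                 wrap_length_bp = as.integer(wl), absent = FALSE),
            class = "nuca_placement")
}

#' Construct a nucleosome array model
#'
#' @param template a `nuca_template`.
#' @param trace `total_bp x 3` matrix of base-pair helical-center coordinates
#'   (Angstrom), index 0 at the 5' end of the entry arm.
#' @param placements list of `nuca_placement`, one per designed repeat.
#' @param label free-text label.
#' @param provenance `"synthetic"` or `"fitted"`.
#' @param ground_truth optional generator ground truth; carried for recovery
#'   tests and never read by measurement code.
#' @return an object of class `nuca_model`.
#' @export
array_model <- function(template, trace, placements, label = "",
                        provenance = c("synthetic", "fitted"),
                        ground_truth = NULL) {
  provenance <- match.arg(provenance)
  m <- structure(list(template = template, trace = trace,
                      placements = placements, label = label,
                      provenance = provenance, ground_truth = ground_truth),
                 class = "nuca_model")
  validate_model(m)
}

validate_model <- function(m) {
  stopifnot(inherits(m, "nuca_model"))
  validate_template(m$template)
  if (!is.matrix(m$trace) || ncol(m$trace) != 3)
    stop("trace must be an n x 3 matrix")
  if (nrow(m$trace) != m$template$total_bp)
    stop(sprintf("trace length (%d) != template total_bp (%d)",
                 nrow(m$trace), m$template$total_bp))
  steps <- sqrt(rowSums((m$trace[-1, , drop = FALSE] -
                           m$trace[-nrow(m$trace), , drop = FALSE])^2))
  if (any(steps < 2.0 | steps > 7.0))
    stop("consecutive trace spacing outside the [2, 7] A sanity bound")
  if (length(m$placements) != m$template$n_ncp)
    stop("placements count != template n_ncp")
  last_end <- -1L
  for (p in m$placements) {
    stopifnot(inherits(p, "nuca_placement"))
    if (p$absent) next
    if (p$wrap_interval[1] <= last_end)
      stop("placements must be ordered with disjoint wrap intervals")
    if (p$wrap_interval[1] < 0 || p$wrap_interval[2] > m$template$total_bp)
      stop("wrap interval outside the trace")
    last_end <- p$wrap_interval[2] - 1L
  }
  invisible(m)
}

#' @export
print.nuca_model <- function(x, ...) {
  np <- sum(!vapply(x$placements, function(p) p$absent, logical(1)))
  cat(sprintf("<nuca_model> '%s' (%s): %d bp trace, %d/%d NCP placed\n",
              x$label, x$provenance, nrow(x$trace), np, x$template$n_ncp))
  invisible(x)
}
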