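# Coarse-grained chromatin fiber simulator. An NCP unit is a hard sphere
# (default radius 50 A) carrying the ideal superhelical DNA track; its two
# 20-bp linker arms leave the track at origins set by sampled unwrapping
# deltas, in directions sampled from the (alpha, beta) distributions of a
# condition preset. Units are chained sequentially: the exit arm of unit i
# is collinear with the entry arm of unit i+1 across a straight linker at
# 3.4 A/bp, each linker applies a 70 degree left-handed twist, and a
# placement clashing with any previous unit (center distance < 100 A) is
# resampled, with backtracking when a position is stuck.

NCP_SPHERE_RADIUS <- 50    # A
CLASH_DIST <- 100          # A, minimum center-center distance
UM_PER_COUNT_PER_NM3 <- 1e6 / 0.602214076  # counts/nm^3 -> micromolar

#' Sample one coarse-grained NCP unit
#'
#' @param params a `nuca_params` (condition preset).
#' @param rng_seed optional seed; when NULL the current RNG stream is used.
#' @param unwrap sample unwrapping deltas (TRUE) or pin the arm origins at
#'   the designed 147-bp boundaries (FALSE).
#' @return list: sampled `alpha_*`, `beta_*`, `delta_*`, local arm origin
#'   points/directions on the canonical track, and `radius_A`.
#' @export
sample_unit <- function(params, rng_seed = NULL, unwrap = TRUE) {
  stopifnot(inherits(params, "nuca_params"))
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed %% 2147483647))
  d_en <- if (unwrap) sample_delta(1L, params$delta_entry, params$delta_clamp)
          else 0L
  d_ex <- if (unwrap) sample_delta(1L, params$delta_exit, params$delta_clamp)
          else 0L
  a_en <- sample_mixture(1L, params$alpha)
  a_ex <- sample_mixture(1L, params$alpha)
  b_en <- stats::rnorm(1L, params$beta$mean, params$beta$sd)
  b_ex <- stats::rnorm(1L, params$beta$mean, params$beta$sd)
  t_en <- -d_en; t_ex <- NCP_BP - 1L + d_ex
  list(alpha_entry = a_en, alpha_exit = a_ex,
       beta_entry = b_en, beta_exit = b_ex,
       delta_entry = d_en, delta_exit = d_ex,
       entry_origin_t = t_en, exit_origin_t = t_ex,
       entry_pt = superhelix_points(t_en)[1, ],
       exit_pt = superhelix_points(t_ex)[1, ],
       entry_dir = arm_direction_canonical(t_en, "entry", a_en, b_en),
       exit_dir = arm_direction_canonical(t_ex, "exit", a_ex, b_ex),
       radius_A = NCP_SPHERE_RADIUS)
}

#' Build a coarse-grained chromatin fiber
#'
#' @param params a `nuca_params` condition preset.
#' @param n_ncp number of NCP units (default 100).
#' @param rng_seed integer seed; the whole build is deterministic in it.
#' @param unwrap sample unwrapping of the arm origins (default TRUE).
#' @param linker_bp designed linker length (default 40 bp).
#' @param retry_cap resamples allowed per position before backtracking.
#' @param restarts full-build restarts (fresh derived seed) after the
#'   in-build clash budget is exhausted.
#' @return object of class `nuca_fiber`: `centers` (n x 3, Angstrom),
#'   `frames`, `units`, `n_ncp`, `radius_A`, `rng_seed`, `preset`.
#' @export
build_fiber <- function(params, n_ncp = 100L, rng_seed = 1L, unwrap = TRUE,
                        linker_bp = 40L, retry_cap = 100L, restarts = 10L) {
  for (r in 0:restarts) {
    f <- tryCatch(
      build_fiber_once(params, n_ncp, derive_seed(rng_seed, 131L * r),
                       unwrap, linker_bp, retry_cap),
      error = function(e) if (r < restarts) NULL else stop(e))
    if (!is.null(f)) {
      f$rng_seed <- rng_seed
      return(f)
    }
  }
}

build_fiber_once <- function(params, n_ncp, seed, unwrap, linker_bp,
                             retry_cap) {
  n_ncp <- as.integer(n_ncp)
  if (n_ncp < 2L) stop("n_ncp must be >= 2")
  set.seed(as.integer(seed %% 2147483647))
  budget <- 100L * n_ncp
  units <- vector("list", n_ncp)
  Rs <- vector("list", n_ncp)
  centers <- matrix(NA_real_, n_ncp, 3)

  units[[1L]] <- sample_unit(params, unwrap = unwrap)
  Rs[[1L]] <- diag(3)
  centers[1L, ] <- c(0, 0, 0)
  os <- vector("list", n_ncp)
  os[[1L]] <- c(0, 0, 0)

  i <- 1L
  spent <- 0L
  stuck <- 0L
  while (i < n_ncp) {
    placed <- FALSE
    for (a in seq_len(retry_cap)) {
      spent <- spent + 1L
      if (spent > budget)
        stop(sprintf("assembly-failed: clash budget exhausted at %d units",
                     i))
      u_prev <- units[[i]]
      exit_pt_g <- as.vector(Rs[[i]] %*% u_prev$exit_pt + os[[i]])
      dir_g <- as.vector(Rs[[i]] %*% u_prev$exit_dir)
      u <- sample_unit(params, unwrap = unwrap)
      # the linker stays at its designed length; unwrapping varies where
      # the arm origins sit on the wrapped track, not the linker itself
      gap_bp <- linker_bp + 1L
      entry_pt_g <- exit_pt_g + gap_bp * BP_RISE * dir_g
      M <- rot_between(u$entry_dir, -dir_g)
      R <- rot_axis(dir_g, params$linker_twist_deg) %*% M
      o <- entry_pt_g - as.vector(R %*% u$entry_pt)
      d2 <- rowSums(sweep(centers[seq_len(i), , drop = FALSE], 2, o)^2)
      if (min(d2) >= CLASH_DIST^2) {
        i <- i + 1L
        units[[i]] <- u; Rs[[i]] <- R; os[[i]] <- o
        centers[i, ] <- o
        placed <- TRUE
        stuck <- 0L
        break
      }
    }
    if (!placed) {
      # escalating backtrack: repeated failures at the same depth unwind
      # progressively more of the chain to escape clash pockets
      stuck <- stuck + 1L
      back <- min(i - 1L, stuck)
      if (back < 1L) stop("assembly-failed: stuck at the first junction")
      i <- i - back
    }
  }
  frames <- lapply(seq_len(n_ncp), function(k)
    ncp_frame(os[[k]], Rs[[k]][, 1], Rs[[k]][, 2], Rs[[k]][, 3]))
  structure(list(centers = centers, frames = frames, units = units,
                 n_ncp = n_ncp, radius_A = NCP_SPHERE_RADIUS,
                 linker_bp = linker_bp, rng_seed = seed,
                 preset = params$name, unwrap = unwrap),
            class = "nuca_fiber")
}

#' @export
print.nuca_fiber <- function(x, ...) {
  cat(sprintf("<nuca_fiber> %d NCPs (preset %s, seed %s)\n",
              x$n_ncp, x$preset, format(x$rng_seed)))
  invisible(x)
}

# Moving-average smoothed centerline of the NCP centers, in nm.
fiber_centerline <- function(fiber, window = 5L) {
  cen <- fiber$centers / 10   # nm
  n <- nrow(cen)
  if (n < window) return(cen)
  half <- (window - 1L) %/% 2L
  sm <- vapply(seq_len(n), function(k) {
    # symmetric window that shrinks near the ends (keeps the endpoints)
    h <- min(half, k - 1L, n - k)
    idx <- (k - h):(k + h)
    colMeans(cen[idx, , drop = FALSE])
  }, numeric(3))
  t(sm)
}

#' Contour length and width of a simulated fiber
#'
#' The contour length is the arc length of the smoothed centerline (moving
#' average of the NCP centers, window 5); the width is twice the sum of the
#' RMS transverse distance of the NCP centers from that centerline and the
#' unit sphere radius.
#'
#' @param fiber a `nuca_fiber` with at least 5 units.
#' @return list: `contour_length_nm`, `width_nm`.
#' @export
fiber_dimensions <- function(fiber) {
  if (fiber$n_ncp < 5L) stop("too-short: need at least 5 units")
  cl <- fiber_centerline(fiber)
  seg <- cl[-1, , drop = FALSE] - cl[-nrow(cl), , drop = FALSE]
  contour <- sum(sqrt(rowSums(seg^2)))
  dev <- dist_to_polyline(fiber$centers / 10, cl)
  width <- 2 * (sqrt(mean(dev^2)) + fiber$radius_A / 10)
  list(contour_length_nm = contour, width_nm = width)
}

#' Persistence length from tangent autocorrelation
#'
#' Resamples a centerline at fixed arc step `d_nm`, computes the
#' tangent-tangent correlation `<cos theta(s)>` and fits the exponential
#' decay `exp(-s / P)` by least squares on the log-correlations over the
#' first decade of decay (lags with correlation in (0.1, 1], plus the first
#' lag below 0.1). Near-straight chains whose correlations do not decay are
#' reported at the documented cap of 1e5 nm.
#'
#' @param centerline an `n x 3` matrix in nm, or a list of them (the
#'   correlation is then averaged over the ensemble before fitting).
#' @param d_nm segment length (default 15 nm).
#' @param p_cap cap for non-decaying chains (default 1e5 nm).
#' @return persistence length in nm.
#' @export
persistence_length <- function(centerline, d_nm = 15, p_cap = 1e5) {
  chains <- if (is.list(centerline)) centerline else list(centerline)
  tangents <- lapply(chains, function(cl) {
    pts <- resample_polyline(as.matrix(cl), d_nm)
    if (nrow(pts) < 4L) stop("too-short: need >= 3 segments after resampling")
    seg <- pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE]
    seg / sqrt(rowSums(seg^2))
  })
  max_lag <- min(vapply(tangents, nrow, integer(1))) - 1L
  corr <- vapply(seq_len(max_lag), function(m) {
    mean(unlist(lapply(tangents, function(tg) {
      n <- nrow(tg)
      rowSums(tg[1:(n - m), , drop = FALSE] * tg[(1 + m):n, , drop = FALSE])
    })))
  }, numeric(1))

  pos <- corr > 0
  below <- which(corr < 0.1 | !pos)
  last <- if (length(below)) min(below) else max_lag
  use <- seq_len(last)
  use <- use[corr[use] > 0]
  if (!length(use)) return(p_cap)
  s <- use * d_nm
  lc <- log(corr[use])
  inv_p <- -sum(s * lc) / sum(s^2)
  if (inv_p <= 1 / p_cap) return(p_cap)
  1 / inv_p
}

# Resample a polyline at fixed arc step d (same units as the points).
resample_polyline <- function(pts, d) {
  seg <- pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE]
  lens <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(lens))
  total <- cum[length(cum)]
  ss <- seq(0, total, by = d)
  t(vapply(ss, function(s) {
    j <- findInterval(s, cum, rightmost.closed = TRUE)
    j <- min(j, length(lens))
    frac <- if (lens[j] > 0) (s - cum[j]) / lens[j] else 0
    pts[j, ] + frac * seg[j, ]
  }, numeric(3)))
}

#' Simulate a discrete worm-like chain
#'
#' Draws each tangent from a von Mises-Fisher distribution about the
#' previous one with concentration chosen so the per-step correlation is
#' exactly `exp(-d_nm / p_nm)`. Used as the generative reference when
#' validating the persistence-length estimator.
#'
#' @param n_segments number of segments.
#' @param d_nm segment length (nm).
#' @param p_nm persistence length (nm).
#' @return `(n_segments + 1) x 3` matrix of vertices in nm.
#' @export
simulate_wlc <- function(n_segments, d_nm = 15, p_nm = 50) {
  target <- exp(-d_nm / p_nm)
  kappa <- stats::uniroot(function(k) 1 / tanh(k) - 1 / k - target,
                          c(1e-6, 1e4), tol = 1e-10)$root
  pts <- matrix(0, n_segments + 1L, 3)
  t_hat <- c(0, 0, 1)
  for (i in seq_len(n_segments)) {
    u <- stats::runif(1)
    w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
    phi <- stats::runif(1, 0, 2 * pi)
    ref <- if (abs(t_hat[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- unit(cross3(t_hat, ref))
    e2 <- cross3(t_hat, e1)
    t_hat <- w * t_hat + sqrt(max(0, 1 - w^2)) *
      (cos(phi) * e1 + sin(phi) * e2)
    t_hat <- unit(t_hat)
    pts[i + 1L, ] <- pts[i, ] + d_nm * t_hat
  }
  pts
}

#' Worm-like-chain fiber metrics
#'
#' Radius of gyration from the worm-like-chain expression
#' `R_g^2 = (1/3) P L [1 - (P/L)(1 - exp(-L/P))]`, hydrodynamic radius
#' `R_h = 0.662 R_g`, and NCP density `n / ((4/3) pi R_g^3)` reported both
#' as a count per nm^3 and in micromolar.
#'
#' @param p_nm persistence length (> 0, nm).
#' @param contour_l_nm contour length (> 0, nm).
#' @param n_ncp number of NCPs (>= 1).
#' @return list: `persistence_nm`, `contour_length_nm`, `gyration_radius_nm`,
#'   `hydrodynamic_radius_nm`, `ncp_per_nm3`, `ncp_density_uM`, `n_ncp`,
#'   `segment_length_nm`.
#' @export
wlc_metrics <- function(p_nm, contour_l_nm, n_ncp) {
  if (!is.finite(p_nm) || p_nm <= 0 || !is.finite(contour_l_nm) ||
      contour_l_nm <= 0 || n_ncp < 1)
    stop("invalid-argument: P, L must be positive and n_ncp >= 1")
  ratio <- p_nm / contour_l_nm
  rg2 <- (1 / 3) * p_nm * contour_l_nm *
    (1 - ratio * (1 - exp(-contour_l_nm / p_nm)))
  rg <- sqrt(rg2)
  vol <- (4 / 3) * pi * rg^3
  list(persistence_nm = p_nm, contour_length_nm = contour_l_nm,
       gyration_radius_nm = rg, hydrodynamic_radius_nm = 0.662 * rg,
       ncp_per_nm3 = n_ncp / vol,
       ncp_density_uM = UM_PER_COUNT_PER_NM3 * n_ncp / vol,
       n_ncp = n_ncp, segment_length_nm = 15)
}

#' Full metrics for one simulated fiber
#'
#' @param fiber a `nuca_fiber`.
#' @param d_nm persistence-length segment size (default 15 nm).
#' @return list combining [fiber_dimensions()] and [wlc_metrics()].
#' @export
fiber_metrics <- function(fiber, d_nm = 15) {
  dims <- fiber_dimensions(fiber)
  p <- persistence_length(fiber_centerline(fiber), d_nm = d_nm)
  c(dims[c("contour_length_nm", "width_nm")],
    wlc_metrics(p, dims$contour_length_nm, fiber$n_ncp))
}

#' Export fiber NCP centers as a pseudo-atom PDB
#'
#' One HETATM carbon pseudo-atom per NCP center (coordinates in Angstrom),
#' for quick visualization of simulated fibers.
#'
#' @param fiber a `nuca_fiber`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_fiber_pdb <- function(fiber, path) {
  centers_pseudo_pdb(fiber$centers, path,
                     sprintf("nucarray fiber export: preset %s seed %s",
                             fiber$preset, format(fiber$rng_seed)))
}

centers_pseudo_pdb <- function(centers, path, remark) {
  if (nrow(centers) > 99999L)
    stop("too many centers for the PDB field width")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("REMARK   %s", remark), con)
  fmt <- "%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  for (i in seq_len(nrow(centers)))
    writeLines(sprintf(fmt, "HETATM", i, "NCP", "", "NCP", "B",
                       i %% 10000L, "", centers[i, 1], centers[i, 2],
                       centers[i, 3], 1, 0, "C"), con)
  writeLines("END", con)
  invisible(path)
}

#' Export a fiber (centers and frames) as JSON
#'
#' @param fiber a `nuca_fiber`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fiber <- function(fiber, path) {
  obj <- list(preset = fiber$preset, n_ncp = fiber$n_ncp,
              rng_seed = fiber$rng_seed, radius_A = fiber$radius_A,
              centers = unname(fiber$centers),
              frames = lapply(fiber$frames, function(f)
                list(origin = f$origin, x_axis = f$x_axis,
                     y_axis = f$y_axis, z_axis = f$z_axis)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}
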