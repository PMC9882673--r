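# Synthetic nucleosome-array generator. Arrays are assembled from the same
# geometric primitives the measurement framework assumes: an ideal 41.8 A /
# 25 A-pitch / 1.7-turn superhelical wrap per NCP (trimmed by sampled
# unwrapping deltas), straight arms and linkers at 3.4 A/bp pointing in
# directions sampled from per-side (alpha, beta) distributions, a fixed 70
# degree left-handed twist per linker, isotropic Gaussian coordinate noise,
# and a random global rigid motion. Every sampled quantity is stored as
# ground truth alongside the model; measurement code never reads it.

#' Synthetic-array generating parameters
#'
#' @param template a `nuca_template`.
#' @param alpha list(weights, means, sds) in degrees: a 1- or 2-component
#'   Gaussian mixture for the wrapping angle, applied to both sides.
#' @param beta list(mean, sd) in degrees for the bending angle.
#' @param delta_entry,delta_exit list(mean, sd) in bp for the signed
#'   unwrapping deltas (sampled Gaussian, rounded to integers, clamped).
#' @param noise_sd isotropic Gaussian coordinate noise, Angstrom (default 2).
#' @param linker_twist_deg signed twist applied about each linker axis when
#'   connecting consecutive NCPs; negative = left-handed (default -70).
#' @param delta_clamp range deltas are clamped into after rounding.
#' @param name preset name, carried into model labels.
#' @param partially_specified flag set on presets whose dispersions are
#'   defaults rather than condition-specific values.
#' @return an object of class `nuca_params`.
#' @export
synthetic_params <- function(template, alpha, beta, delta_entry, delta_exit,
                             noise_sd = 2, linker_twist_deg = -70,
                             delta_clamp = c(-40L, 10L), name = "custom",
                             partially_specified = FALSE) {
  validate_template(template)
  w <- alpha$weights
  if (abs(sum(w) - 1) > 1e-9) stop("alpha mixture weights must sum to 1")
  if (any(alpha$sds <= 0) || beta$sd <= 0 ||
      delta_entry$sd < 0 || delta_exit$sd < 0)
    stop("distribution sds must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(template = template, alpha = alpha, beta = beta,
                 delta_entry = delta_entry, delta_exit = delta_exit,
                 noise_sd = noise_sd, linker_twist_deg = linker_twist_deg,
                 delta_clamp = as.integer(delta_clamp), name = name,
                 partially_specified = partially_specified),
            class = "nuca_params")
}

# Smoothly correlated per-bp displacement noise (moving average of iid
# Gaussians over `window` bp, rescaled to marginal sd `sd`). Map-fitting
# error varies slowly along the DNA, so neighbouring base pairs share most
# of their displacement; this also keeps consecutive-bp spacing inside the
# model's [2, 7] A sanity bound.
smooth_noise <- function(n, sd, window = 15L) {
  pad <- window %/% 2L
  z <- matrix(stats::rnorm((n + 2L * pad) * 3L), ncol = 3L)
  sm <- apply(z, 2, function(col)
    as.numeric(stats::filter(col, rep(1 / window, window), sides = 2)))
  sm <- sm[(pad + 1L):(pad + n), , drop = FALSE]
  sm * sd * sqrt(window)
}

# Nudge consecutive points along their step direction until every spacing
# lies inside the BpTrace sanity bound; corrections are local and small
# relative to the noise amplitude.
enforce_spacing <- function(trace, lo = 2.2, hi = 6.8, max_iter = 200L) {
  for (it in seq_len(max_iter)) {
    d <- trace[-1, , drop = FALSE] - trace[-nrow(trace), , drop = FALSE]
    len <- sqrt(rowSums(d^2))
    viol <- which(len < lo | len > hi)
    if (!length(viol)) return(trace)
    for (j in viol) {
      u <- d[j, ] / len[j]
      shift <- (pmin(hi, pmax(lo, len[j])) - len[j]) / 2
      trace[j, ] <- trace[j, ] - u * shift
      trace[j + 1L, ] <- trace[j + 1L, ] + u * shift
    }
  }
  trace
}

sample_mixture <- function(n, mix) {
  k <- sample.int(length(mix$weights), n, replace = TRUE, prob = mix$weights)
  stats::rnorm(n, mix$means[k], mix$sds[k])
}

sample_delta <- function(n, d, clamp) {
  as.integer(pmin(clamp[2], pmax(clamp[1],
                                 round(stats::rnorm(n, d$mean, d$sd)))))
}

#' Generate one synthetic nucleosome array model
#'
#' Assembles the trace NCP by NCP: sampled deltas trim the ideal wrap,
#' sampled per-side (alpha, beta) set the straight arm directions, each
#' linker applies the configured left-handed twist, and the designed number
#' of base pairs is conserved exactly. A model whose NCP centers come closer
#' than `min_center_dist` is resampled (fresh sub-seed) up to `max_retry`
#' times.
#'
#' @param params a `nuca_params`.
#' @param rng_seed integer seed; the same seed reproduces the model exactly.
#' @param min_center_dist self-clash threshold between NCP centers, Angstrom.
#' @param max_retry resampling budget for self-clashing draws.
#' @return a `nuca_model` with `provenance = "synthetic"` and a
#'   `ground_truth` block holding every sampled value.
#' @export
generate_array <- function(params, rng_seed, min_center_dist = 100,
                           max_retry = 50L) {
  stopifnot(inherits(params, "nuca_params"))
  for (try_ in 0:max_retry) {
    m <- generate_array_once(params, derive_seed(rng_seed, try_))
    if (is.null(min_center_dist) || params$template$n_ncp == 1L) return(m)
    centers <- t(vapply(m$placements, function(p) p$frame$origin, numeric(3)))
    if (params$template$n_ncp >= 2L) {
      dmin <- min(stats::dist(centers))
      if (dmin >= min_center_dist) return(m)
    }
  }
  stop("generation error: self-clash persisted past the retry budget")
}

generate_array_once <- function(params, seed) {
  set.seed(as.integer(seed %% 2147483647))
  tpl <- params$template
  n <- tpl$n_ncp

  d_en <- sample_delta(n, params$delta_entry, params$delta_clamp)
  d_ex <- sample_delta(n, params$delta_exit, params$delta_clamp)
  a_en <- sample_mixture(n, params$alpha)
  a_ex <- sample_mixture(n, params$alpha)
  b_en <- stats::rnorm(n, params$beta$mean, params$beta$sd)
  b_ex <- stats::rnorm(n, params$beta$mean, params$beta$sd)

  trace <- matrix(NA_real_, tpl$total_bp, 3)
  placements <- vector("list", n)
  gt_frames <- vector("list", n)

  R_i <- diag(3); o_i <- c(0, 0, 0)   # local->global for the current NCP
  for (i in seq_len(n)) {
    iv <- tpl$nps_intervals[[i]]
    w_start <- iv[1] - d_en[i]         # negative delta shifts the start inward
    w_end <- iv[2] + d_ex[i]
    t_en <- -d_en[i]; t_ex <- NCP_BP - 1L + d_ex[i]
    ts <- seq.int(t_en, t_ex)
    local_pts <- superhelix_points(ts)
    if (i > 1) {
      # connect this NCP's entry arm to the previous exit arm: the entry
      # origin has already been placed; orient so the local entry-away
      # direction maps onto the back-pointing linker axis, then twist.
      u <- arm_direction_canonical(t_en, "entry", a_en[i], b_en[i])
      M <- rot_between(u, -link_dir)
      R_i <- rot_axis(link_dir, params$linker_twist_deg) %*% M
      o_i <- entry_pt - R_i %*% superhelix_points(t_en)[1, ]
    }
    pts <- t(R_i %*% t(local_pts) + as.vector(o_i))
    trace[(w_start + 1):w_end, ] <- pts

    frame <- ncp_frame(as.vector(o_i), R_i[, 1], R_i[, 2], R_i[, 3])
    placements[[i]] <- ncp_placement(frame, c(w_start, w_end),
                                     d_en[i], d_ex[i])
    gt_frames[[i]] <- frame

    if (i == 1) {
      # entry arm: straight, pointing away from the NCP (toward bp 0)
      dir_en <- as.vector(R_i %*% arm_direction_canonical(
        t_en, "entry", a_en[i], b_en[i]))
      k <- seq_len(w_start)
      if (length(k))
        trace[w_start + 1 - k, ] <- sweep(outer(k * BP_RISE, dir_en), 2,
                                          pts[1, ], "+")
    }
    dir_ex <- as.vector(R_i %*% arm_direction_canonical(
      t_ex, "exit", a_ex[i], b_ex[i]))
    exit_pt <- pts[nrow(pts), ]
    if (i < n) {
      gap_bp <- (tpl$nps_intervals[[i + 1]][1] - d_en[i + 1]) - (w_end - 1L)
      if (gap_bp < 2L)
        stop("generation error: sampled deltas leave no linker between NCPs")
      kk <- seq_len(gap_bp - 1L)
      trace[w_end + kk, ] <- sweep(outer(kk * BP_RISE, dir_ex), 2,
                                   exit_pt, "+")
      entry_pt <- exit_pt + gap_bp * BP_RISE * dir_ex
      link_dir <- dir_ex
    } else {
      kk <- seq_len(tpl$total_bp - w_end)
      if (length(kk))
        trace[w_end + kk, ] <- sweep(outer(kk * BP_RISE, dir_ex), 2,
                                     exit_pt, "+")
    }
  }

  # random global rigid motion, then coordinate noise
  Rg <- random_rotation()
  tg <- stats::runif(3, -200, 200)
  trace <- t(Rg %*% t(trace) + tg)
  if (params$noise_sd > 0)
    trace <- enforce_spacing(trace + smooth_noise(nrow(trace),
                                                  params$noise_sd))
  placements <- lapply(placements, function(p) {
    R <- Rg %*% frame_rotation(p$frame)
    p$frame <- ncp_frame(as.vector(Rg %*% p$frame$origin + tg),
                         R[, 1], R[, 2], R[, 3])
    p
  })

  gt <- list(preset = params$name, seed = seed,
             delta_entry = d_en, delta_exit = d_ex,
             alpha_entry = a_en, alpha_exit = a_ex,
             beta_entry = b_en, beta_exit = b_ex,
             noise_sd = params$noise_sd)
  array_model(tpl, trace, placements,
              label = sprintf("%s:%d", params$name, seed),
              provenance = "synthetic", ground_truth = gt)
}

#' Generate a population of independent synthetic models
#'
#' @param params a `nuca_params`.
#' @param n number of models (>= 1).
#' @param seed master seed; per-model seeds are derived deterministically.
#' @param ... passed to [generate_array()].
#' @return a list of `nuca_model`.
#' @export
generate_population <- function(params, n, seed, ...) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1")
  lapply(seq_len(n), function(i)
    generate_array(params, derive_seed(seed, 1000 + i), ...))
}
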