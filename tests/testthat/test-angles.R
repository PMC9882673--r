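# Construct a synthetic placement whose arm directions are set by hand in
# the canonical frame, to exercise each angle definition directly.
synthetic_placement_trace <- function(dir_en, dir_ex, n_wrap = 147L,
                                      arm_bp = 30L) {
  canon <- nucarray:::superhelix_points(seq_len(n_wrap) - 1L,
                                        dyad_t = (n_wrap - 1) / 2)
  entry_arm <- sweep(outer(rev(seq_len(arm_bp)) * 3.4, unit_v(dir_en)), 2,
                     canon[1, ], "+")
  exit_arm <- sweep(outer(seq_len(arm_bp) * 3.4, unit_v(dir_ex)), 2,
                    canon[n_wrap, ], "+")
  trace <- rbind(entry_arm, canon, exit_arm)
  frame <- ncp_frame(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  pl <- ncp_placement(frame, c(arm_bp, arm_bp + n_wrap), 0L, 0L)
  list(trace = trace, placement = pl)
}
unit_v <- function(v) v / sqrt(sum(v^2))

test_that("parallel arms give theta = 0 and theta_par = 0", {
  d <- unit_v(c(0.3, 0.8, 0.2))
  s <- synthetic_placement_trace(d, d)
  ang <- measure_angles(s$placement, s$trace)
  expect_lt(ang$theta_deg, 1e-6)
  expect_lt(abs(ang$theta_par_deg), 1e-6)
  expect_equal(ang$arm_state, "open")
})

test_that("an arm along +Z has beta = 90", {
  s <- synthetic_placement_trace(c(0, 0, 1), c(1, 0, 0))
  ang <- measure_angles(s$placement, s$trace)
  expect_equal(ang$beta_entry_deg, 90, tolerance = 1e-6)
  expect_equal(ang$theta_deg, 90, tolerance = 1e-6)
})

test_that("an in-plane arm along the local tangent has alpha = beta = 0", {
  # entry-side away tangent at the canonical entry boundary
  canon <- nucarray:::superhelix_points(0:146)
  r_hat <- unit_v(c(canon[1, 1], canon[1, 2], 0))
  taway <- nucarray:::inplane_away_tangent(r_hat[1:2], "entry")
  s <- synthetic_placement_trace(c(taway, 0), c(1, 0, 0))
  ang <- measure_angles(s$placement, s$trace)
  expect_lt(abs(ang$alpha_entry_deg), 0.75)
  expect_lt(abs(ang$beta_entry_deg), 1e-6)
})

test_that("generated arm angles are measured back within 0.5 degrees", {
  # echoes the reported mono peaks: alpha 39, beta -9
  m <- generate_array(mono_params_fixed(0L, 0L, alpha = 39, beta = -9),
                      rng_seed = 14)
  pl <- detect_wrapped_interval(m$trace, 1, m$template)
  ang <- measure_angles(pl, m$trace)
  expect_lt(abs(ang$alpha_entry_deg - 39), 0.5)
  expect_lt(abs(ang$alpha_exit_deg - 39), 0.5)
  expect_lt(abs(ang$beta_entry_deg + 9), 0.5)
  expect_lt(abs(ang$beta_exit_deg + 9), 0.5)
})

test_that("closed-arm classification follows the sign of theta_par", {
  p <- preset_table("tetra_50mM", noise_sd = 2)
  m <- generate_array(p, rng_seed = 10)
  meas <- measure_models(m)
  ok <- meas$ncp$present
  expect_equal(meas$ncp$arm_state[ok] == "closed",
               meas$ncp$theta_par_deg[ok] < 0)
})

test_that("mirroring through the disc plane negates beta and theta_perp", {
  p <- preset_table("mono_5mM", noise_sd = 0)
  m <- generate_array(p, rng_seed = 18)
  pl <- detect_wrapped_interval(m$trace, 1, m$template)
  ang <- measure_angles(pl, m$trace)

  f <- pl$frame
  Rf <- cbind(f$x_axis, f$y_axis, f$z_axis)
  loc <- sweep(m$trace, 2, f$origin) %*% Rf
  loc[, 3] <- -loc[, 3]
  mirrored <- sweep(loc %*% t(Rf), 2, f$origin, "+")
  angm <- measure_angles(pl, mirrored)

  expect_equal(angm$beta_entry_deg, -ang$beta_entry_deg, tolerance = 1e-6)
  expect_equal(angm$beta_exit_deg, -ang$beta_exit_deg, tolerance = 1e-6)
  expect_equal(angm$theta_perp_deg, -ang$theta_perp_deg, tolerance = 1e-6)
  expect_equal(angm$theta_deg, ang$theta_deg, tolerance = 1e-6)
})

test_that("arms shorter than the 20-bp segment raise an error", {
  canon <- nucarray:::superhelix_points(0:146)
  arm <- sweep(outer(seq_len(10) * 3.4, c(1, 0, 0)), 2, canon[147, ], "+")
  trace <- rbind(canon, arm)
  frame <- ncp_frame(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  pl <- ncp_placement(frame, c(0L, 147L), 0L, 0L)
  expect_error(measure_angles(pl, trace), "arm-too-short")
})

test_that("unwrap angles convert deltas at ~4.163 degrees per bp", {
  ua <- unwrap_angles(-5L, -11L)
  expect_equal(ua$degrees_per_bp, 360 * 1.7 / 147)
  expect_equal(ua$theta_sum_deg, -16 * 360 * 1.7 / 147)
  expect_equal(ua$theta_sum_deg, ua$theta_en_deg + ua$theta_ex_deg)
})
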